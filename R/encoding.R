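#' One-hot encode a single nucleotide
#'
#' Fixed mapping used throughout the package, with column order (A, T/U, G, C):
#' `A -> c(1,0,0,0)`, `T`/`U -> c(0,1,0,0)`, `G -> c(0,0,1,0)`,
#' `C -> c(0,0,0,1)`, `N -> c(0,0,0,0)`. The zero vector for N is shared with
#' padding rows, so ambiguous bases contribute nothing to a convolution.
#'
#' @param base A single character; case-insensitive.
#' @param strict If `TRUE` (default), any character outside `{A,T,U,G,C,N}`
#'   is an error; if `FALSE` it maps to the N (all-zero) vector with a
#'   warning.
#' @return A numeric vector of length 4.
#' @examples
#' encode_base("A")
#' encode_base("u") # same as T
#' @export
encode_base <- function(base, strict = TRUE) {
  stopifnot(length(base) == 1, nchar(base) == 1)
  b <- toupper(base)
  row <- match(b, c("A", "T", "U", "G", "C", "N"))
  if (is.na(row)) {
    if (strict) {
      stop("unknown base '", base, "' (strict alphabet {A,T,U,G,C,N})",
           call. = FALSE)
    }
    warning("unknown base '", base, "' mapped to N", call. = FALSE)
    return(c(0, 0, 0, 0))
  }
  base_map()[row, ]
}

base_map <- function() {
  matrix(c(1, 0, 0, 0,   # A
           0, 1, 0, 0,   # T
           0, 1, 0, 0,   # U
           0, 0, 1, 0,   # G
           0, 0, 0, 1,   # C
           0, 0, 0, 0),  # N
         nrow = 6, byrow = TRUE,
         dimnames = list(c("A", "T", "U", "G", "C", "N"),
                         c("A", "TU", "G", "C")))
}

#' One-hot encode a nucleotide sequence with trailing zero padding
#'
#' Produces a `max_len` x 4 numeric matrix: row *i* is the one-hot vector of
#' the *i*-th base, and all rows beyond the sequence length are zero. Padding
#' is trailing-only, so every encoded dataset shares one shape and can be
#' batched. A sequence longer than `max_len` is an error, never truncated.
#'
#' @param seq A nucleotide string over `{A,T,U,G,C,N}` (case-insensitive).
#' @param max_len Padded length in nt; must be `>= nchar(seq)`.
#' @param strict See [encode_base()].
#' @return A numeric matrix of shape `(max_len, 4)` with attributes
#'   `source_length` (original length) and `max_len`.
#' @examples
#' encode_sequence("ACG", max_len = 5)
#' @export
encode_sequence <- function(seq, max_len, strict = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1,
            is.numeric(max_len), length(max_len) == 1, max_len >= 1)
  n <- nchar(seq)
  if (n > max_len) {
    stop("sequence length ", n, " exceeds max_len ", max_len,
         " (refusing to truncate)", call. = FALSE)
  }
  out <- matrix(0, nrow = max_len, ncol = 4,
                dimnames = list(NULL, c("A", "TU", "G", "C")))
  if (n > 0) {
    chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
    rows <- match(chars, c("A", "T", "U", "G", "C", "N"))
    if (anyNA(rows)) {
      bad <- which(is.na(rows))[1]
      if (strict) {
        stop("unknown base '", chars[bad], "' at position ", bad,
             " (strict alphabet {A,T,U,G,C,N})", call. = FALSE)
      }
      warning(sum(is.na(rows)), " unknown base(s) mapped to N",
              call. = FALSE)
      rows[is.na(rows)] <- 6L
    }
    out[seq_len(n), ] <- base_map()[rows, , drop = FALSE]
  }
  attr(out, "source_length") <- n
  attr(out, "max_len") <- as.integer(max_len)
  out
}

#' Decode an encoded matrix back to a sequence
#'
#' Inverse of [encode_sequence()] up to T/U normalization (T and U share one
#' column; the output uses `rna = TRUE` to pick U or T) and up to trailing Ns,
#' which are indistinguishable from padding and are dropped.
#'
#' @param mat An encoded matrix as returned by [encode_sequence()].
#' @param rna Emit U (default) or T for the T/U column.
#' @return A nucleotide string.
#' @export
decode_matrix <- function(mat, rna = TRUE) {
  alphabet <- c("A", if (rna) "U" else "T", "G", "C")
  hit <- apply(mat, 1, function(r) {
    j <- which(r == 1)
    if (length(j) == 1) alphabet[j] else "N"
  })
  paste(hit[seq_len(max(c(0, which(hit != "N"))))], collapse = "")
}

#' Maximum sequence length of a dataset
#'
#' The default padded length for encoding and for the model input; for the
#' merged human pre-miRNA corpus this is 164 nt.
#'
#' @inheritParams write_fasta
#' @return A positive integer.
#' @export
dataset_max_length <- function(dataset) {
  if (nrow(dataset) == 0) stop("dataset is empty", call. = FALSE)
  max(nchar(dataset$sequence))
}

#' Encode every sequence of a dataset
#'
#' @inheritParams write_fasta
#' @param max_len Padded length; defaults to [dataset_max_length()] of the
#'   dataset itself.
#' @param strict See [encode_base()].
#' @return A list of class `encoded_dataset`: `x` (list of `max_len` x 4
#'   matrices), `y` (label factor), `id`, `max_len`.
#' @export
encode_dataset <- function(dataset, max_len = dataset_max_length(dataset),
                           strict = TRUE) {
  x <- lapply(dataset$sequence, encode_sequence, max_len = max_len,
              strict = strict)
  structure(
    list(x = x,
         y = factor(as.character(dataset$label), levels = class_levels()),
         id = dataset$id,
         max_len = as.integer(max_len)),
    class = "encoded_dataset"
  )
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat("Encoded dataset:", length(x$x), "records, shape (",
      x$max_len, ", 4 ) each\n")
  invisible(x)
}

#' Cache an encoded dataset on disk
#'
#' Writes a simple binary container: an ASCII header line
#' `mirtroncnn-enc1 <n> <max_len>` followed by, per record, the id and label
#' as NUL-terminated strings and the `max_len * 4` matrix values as
#' little-endian doubles in row-major order. Regeneration from the same FASTA
#' is bit-identical.
#'
#' @param encoded An `encoded_dataset` from [encode_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_encoded_cache <- function(encoded, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("mirtroncnn-enc1 %d %d\n",
                             length(encoded$x), encoded$max_len)), con)
  for (i in seq_along(encoded$x)) {
    writeBin(encoded$id[i], con)
    writeBin(as.character(encoded$y[i]), con)
    writeBin(as.vector(t(encoded$x[[i]])), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read an encoded dataset cache
#'
#' @param path File written by [write_encoded_cache()].
#' @return An `encoded_dataset`.
#' @export
read_encoded_cache <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ch <- readBin(con, "raw", 1)
    if (length(ch) == 0 || ch == charToRaw("\n")) break
    header <- c(header, rawToChar(ch))
  }
  parts <- strsplit(paste(header, collapse = ""), " ")[[1]]
  if (length(parts) != 3 || parts[1] != "mirtroncnn-enc1") {
    stop("not a mirtroncnn encoded cache: ", path, call. = FALSE)
  }
  n <- as.integer(parts[2]); max_len <- as.integer(parts[3])
  ids <- character(n); labels <- character(n); x <- vector("list", n)
  for (i in seq_len(n)) {
    ids[i] <- readBin(con, "character", 1)
    labels[i] <- readBin(con, "character", 1)
    vals <- readBin(con, "double", max_len * 4, size = 8, endian = "little")
    m <- matrix(vals, nrow = max_len, ncol = 4, byrow = TRUE,
                dimnames = list(NULL, c("A", "TU", "G", "C")))
    attr(m, "source_length") <- max(c(0, which(rowSums(m) > 0)))
    attr(m, "max_len") <- max_len
    x[[i]] <- m
  }
  structure(list(x = x, y = factor(labels, levels = class_levels()),
                 id = ids, max_len = max_len),
            class = "encoded_dataset")
}
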