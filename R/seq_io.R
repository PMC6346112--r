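#' Read a FASTA file into a labeled sequence tibble
#'
#' Parses a (possibly line-wrapped) FASTA file and attaches a class label to
#' every record, either a single label for the whole file (the usual case for
#' class-segregated source files) or a per-record lookup table.
#'
#' Sequences are uppercased on read; T and U are preserved as read, since the
#' one-hot encoding treats them identically (see [encode_base()]).
#'
#' @param path Path to a FASTA file. An empty file yields an empty dataset.
#' @param label A single class label, `"canonical"` or `"mirtron"`, applied
#'   to every record. Exactly one of `label` and `label_table` must be given.
#' @param label_table A data frame with columns `id` and `label` mapping each
#'   record identifier to its class (see [read_label_table()]).
#' @param provenance Free-text source tag stored as the `"provenance"`
#'   attribute of the result.
#'
#' @return A tibble with columns `id` (character), `sequence` (character,
#'   uppercase) and `label` (factor with levels `canonical`, `mirtron`), one
#'   row per FASTA record in file order.
#' @seealso [write_fasta()], [merge_datasets()], [stratified_split()]
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGU", ">b", "GGC"), fa)
#' read_labeled_fasta(fa, label = "mirtron")
#' @export
read_labeled_fasta <- function(path, label = NULL, label_table = NULL,
                               provenance = basename(path)) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  if (is.null(label) == is.null(label_table)) {
    stop("supply exactly one of `label` or `label_table`", call. = FALSE)
  }
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(seqs))
  sequence <- toupper(as.character(seqs))
  if (is.null(label_table)) {
    labels <- rep(validate_label(label), length(ids))
  } else {
    label_table <- as_label_table(label_table)
    hit <- match(ids, label_table$id)
    if (anyNA(hit) && length(ids) > 0) {
      missing_ids <- ids[is.na(hit)]
      stop("no label for record(s): ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    }
    labels <- as.character(label_table$label[hit])
  }
  new_labeled_dataset(ids, unname(sequence), labels, provenance)
}

#' Read a tab-separated id-to-label table
#'
#' @param path Path to a TSV file with two columns, `id` and `label`
#'   (header optional; labels must be `canonical` or `mirtron`).
#' @return A tibble with columns `id` and `label`.
#' @export
read_label_table <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, col.names = c("id", "label"),
                           colClasses = "character", blank.lines.skip = TRUE)
  if (nrow(raw) > 0 && identical(tolower(raw$id[1]), "id")) {
    raw <- raw[-1, , drop = FALSE]
  }
  as_label_table(raw)
}

as_label_table <- function(df) {
  stopifnot(all(c("id", "label") %in% names(df)))
  bad <- setdiff(unique(as.character(df$label)), class_levels())
  if (length(bad) > 0) {
    stop("unknown label(s): ", paste(bad, collapse = ", "),
         " (expected canonical or mirtron)", call. = FALSE)
  }
  tibble::tibble(id = as.character(df$id),
                 label = factor(df$label, levels = class_levels()))
}

validate_label <- function(label) {
  label <- as.character(label)
  if (length(label) != 1 || !label %in% class_levels()) {
    stop("label must be one of: ", paste(class_levels(), collapse = ", "),
         call. = FALSE)
  }
  label
}

class_levels <- function() c("canonical", "mirtron")

new_labeled_dataset <- function(id, sequence, label, provenance = NA_character_) {
  out <- tibble::tibble(
    id = as.character(id),
    sequence = as.character(sequence),
    label = factor(as.character(label), levels = class_levels())
  )
  if (anyDuplicated(out$id)) {
    dup <- unique(out$id[duplicated(out$id)])
    stop("duplicate record id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(out$sequence) < 1)) {
    stop("every sequence must have length >= 1", call. = FALSE)
  }
  attr(out, "provenance") <- provenance
  out
}

#' Write a labeled dataset back to FASTA
#'
#' Writes one record per row, unwrapped (one sequence line per record), so
#' that a read/write round trip is byte-stable for normalized input.
#'
#' @param dataset A labeled dataset tibble (columns `id`, `sequence`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dataset, path) {
  lines <- as.vector(rbind(paste0(">", dataset$id), dataset$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-record label table as TSV
#'
#' @inheritParams write_fasta
#' @param path Output file path (columns `id`, `label`, no header).
#' @return `path`, invisibly.
#' @export
write_label_table <- function(dataset, path) {
  utils::write.table(dataset[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge labeled datasets
#'
#' Concatenates datasets in the order given; class counts of the result are
#' the sums of the inputs. Duplicate ids across inputs are an error by
#' default because silent duplication would corrupt the disjointness of a
#' later train/test split; with `allow_duplicates = TRUE` colliding ids are
#' renamed with a numeric suffix instead.
#'
#' @param ... Labeled dataset tibbles, or a single list of them.
#' @param allow_duplicates Rename colliding ids (`id_2`, `id_3`, ...) instead
#'   of failing.
#' @return A labeled dataset tibble with all records.
#' @examples
#' a <- tibble::tibble(id = c("m1", "m2"), sequence = c("ACGU", "GGCA"),
#'                     label = "mirtron")
#' b <- tibble::tibble(id = "c1", sequence = "AUGC", label = "canonical")
#' merge_datasets(a, b)
#' @export
merge_datasets <- function(..., allow_duplicates = FALSE) {
  inputs <- list(...)
  if (length(inputs) == 1 && is.list(inputs[[1]]) &&
      !is.data.frame(inputs[[1]])) {
    inputs <- inputs[[1]]
  }
  if (length(inputs) == 0) stop("no datasets to merge", call. = FALSE)
  ids <- unlist(lapply(inputs, function(d) d$id), use.names = FALSE)
  if (anyDuplicated(ids)) {
    if (!allow_duplicates) {
      dup <- unique(ids[duplicated(ids)])
      stop("duplicate ids across datasets: ", paste(dup, collapse = ", "),
           " (use allow_duplicates = TRUE to rename)", call. = FALSE)
    }
    ids <- make.unique(ids, sep = "_")
  }
  merged <- dplyr::bind_rows(lapply(inputs, function(d) {
    tibble::tibble(id = d$id, sequence = d$sequence,
                   label = factor(as.character(d$label),
                                  levels = class_levels()))
  }))
  merged$id <- ids
  prov <- paste(vapply(inputs, function(d) {
    p <- attr(d, "provenance")
    if (is.null(p) || is.na(p)) "unknown" else p
  }, character(1)), collapse = " + ")
  attr(merged, "provenance") <- prov
  merged
}

#' Count records per class
#'
#' @inheritParams write_fasta
#' @return A tibble with columns `label` and `n` covering both classes
#'   (zero counts included).
#' @export
class_counts <- function(dataset) {
  tab <- table(factor(dataset$label, levels = class_levels()))
  tibble::tibble(label = names(tab), n = as.integer(tab))
}

round_half_away <- function(x) {
  # round-half-away-from-zero: 0.30 * 417 = 125.1 -> 125, 0.5 -> 1
  sign(x) * floor(abs(x) + 0.5)
}

#' Stratified train/test split
#'
#' Splits a labeled dataset into disjoint train and test partitions keeping
#' the two classes in the same proportion: each class contributes
#' `round(test_fraction * class size)` records to the test set, with
#' round-half-away-from-zero rounding. Within a class the assignment is a
#' uniformly random, seed-reproducible permutation, so the same
#' `(dataset, test_fraction, seed)` always yields the identical split.
#'
#' With the 417 mirtron / 707 canonical pre-miRNA corpus and the default
#' `test_fraction = 0.30` this reproduces a 292/495 train and 125/212 test
#' partition.
#'
#' @inheritParams write_fasta
#' @param test_fraction Proportion of each class assigned to the test set,
#'   in \[0, 1\]. Default 0.30.
#' @param seed Integer seed controlling the within-class permutation.
#' @return A list of class `split_result` with elements `train` and `test`
#'   (labeled dataset tibbles), `test_fraction` and `seed`.
#' @examples
#' d <- generate_dataset(20, 30, seed = 1)
#' sp <- stratified_split(d, test_fraction = 0.3, seed = 42)
#' class_counts(sp$test)
#' @export
stratified_split <- function(dataset, test_fraction = 0.30, seed = 1L) {
  if (!is.numeric(test_fraction) || length(test_fraction) != 1 ||
      is.na(test_fraction) || test_fraction < 0 || test_fraction > 1) {
    stop("test_fraction must be a single number in [0, 1]", call. = FALSE)
  }
  if (nrow(dataset) == 0) stop("dataset is empty", call. = FALSE)
  in_test <- logical(nrow(dataset))
  withr::with_seed(seed, {
    for (cls in class_levels()) {
      idx <- which(dataset$label == cls)
      n_test <- as.integer(round_half_away(test_fraction * length(idx)))
      if (length(idx) > 0 && n_test > 0) {
        in_test[sample(idx)[seq_len(n_test)]] <- TRUE
      }
    }
  })
  structure(
    list(
      train = keep_provenance(dataset[!in_test, ], dataset),
      test = keep_provenance(dataset[in_test, ], dataset),
      test_fraction = test_fraction,
      seed = as.integer(seed)
    ),
    class = "split_result"
  )
}

keep_provenance <- function(subset, parent) {
  attr(subset, "provenance") <- attr(parent, "provenance")
  subset
}

#' @export
print.split_result <- function(x, ...) {
  cat("Stratified split (test_fraction =", x$test_fraction,
      ", seed =", x$seed, ")\n")
  cat("train:", nrow(x$train), "records; test:", nrow(x$test), "records\n")
  invisible(x)
}

#' Write a split manifest
#'
#' Emits a TSV with columns `id`, `partition` (`train`/`test`) and `label`,
#' one row per record of the original dataset.
#'
#' @param split A `split_result` from [stratified_split()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  manifest <- dplyr::bind_rows(
    tibble::tibble(id = split$train$id, partition = "train",
                   label = as.character(split$train$label)),
    tibble::tibble(id = split$test$id, partition = "test",
                   label = as.character(split$test$label))
  )
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
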