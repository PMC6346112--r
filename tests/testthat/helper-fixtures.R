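# Shared fixtures: tiny FASTA writers and dataset builders used across tests.

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

toy_dataset <- function(n_mirtron, n_canonical, seq_len = 10, seed = 1) {
  withr::with_seed(seed, {
    n <- n_mirtron + n_canonical
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "U"), seq_len, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  tibble::tibble(
    id = sprintf("rec%03d", seq_len(n_mirtron + n_canonical)),
    sequence = seqs,
    label = factor(c(rep("mirtron", n_mirtron),
                     rep("canonical", n_canonical)),
                   levels = c("canonical", "mirtron"))
  )
}

# A hand-sized spec for numerical tests (38 trainable parameters).
tiny_spec <- function(input_length = 6) {
  spec <- build_concat_spec(filter_heights = 3, input_length = input_length,
                            dropout_rate = 0)
  spec$branches[[1]]$out_channels <- 2L
  spec$dense_width <- 2L
  spec
}

flatten_weights <- function(w) {
  unlist(w, use.names = FALSE)
}

unflatten_weights <- function(flat, template) {
  relist(flat, template)
}
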