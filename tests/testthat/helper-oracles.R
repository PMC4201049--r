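# Shared fixtures and independent brute-force oracles. The oracles
# deliberately avoid the package's indexed/vectorised code paths: plain
# loops and substring scans only.

# write records to a temporary FASTA file
tmp_fasta <- function(records) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  lines <- character()
  for (i in seq_len(nrow(records))) {
    header <- paste0(">", records$id[i])
    if (nzchar(records$description[i] %||% "")) {
      header <- paste(header, records$description[i])
    }
    lines <- c(lines, header, records$sequence[i])
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ids of proteome records containing the k-mer as an exact substring
naive_kmer_hits <- function(proteome, kmer) {
  hit <- vapply(
    proteome$sequence,
    function(s) grepl(kmer, s, fixed = TRUE),
    logical(1)
  )
  proteome$id[hit]
}

# O(n * w) centered running mean, truncated at the ends
naive_window_mean <- function(values, window) {
  n <- length(values)
  h <- (window - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- mean(values[max(1, i - h):min(n, i + h)])
  }
  out
}

# O(n^2) competition ranking: 1 + number of strictly better scores
naive_competition_rank <- function(scores) {
  vapply(scores, function(s) 1L + sum(scores > s), integer(1))
}

# all-pairs interval overlap check
naive_overlap_flags <- function(windows, features, kinds) {
  vapply(seq_len(nrow(windows)), function(i) {
    any(vapply(seq_len(nrow(features)), function(j) {
      features$kind[j] %in% kinds &&
        max(windows$start[i], features$start[j]) <=
          min(windows$end[i], features$end[j])
    }, logical(1)))
  }, logical(1))
}

# the printed example peptides used across tests
AQP2_PEPTIDE <- "EPDTDWEEREVRRRQ"
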