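# Deterministic synthetic-data generator: random proteins, planted shared
# epitopes, planted features, toy proteomes and mutated orthologs. Every
# module is testable offline against these fixtures.
#
# Randomness uses R's Mersenne-Twister generator with sample.kind
# "Rejection" under an explicit integer seed (via withr::with_seed), so a
# given seed yields the same fixtures on every platform and R release in
# this package's support range.

sample_sequence <- function(length, composition = NULL) {
  if (is.null(composition)) {
    composition <- setNames(rep(1, 20), STANDARD_AA)
  }
  letters <- names(composition)
  paste(
    sample(letters, length, replace = TRUE, prob = composition),
    collapse = ""
  )
}

with_fixture_seed <- function(seed, code) {
  withr::with_seed(
    as.integer(seed), code,
    .rng_kind = "Mersenne-Twister", .rng_sample_kind = "Rejection"
  )
}

#' Simulate a synthetic proteome
#'
#' Sequences are drawn residue-by-residue from `composition` (uniform over
#' the 20 standard letters by default); planted k-mers are overwritten at
#' their stated positions after sampling, so they are recovered by the
#' epitope index with probability 1. Ids are `SYN001`, `SYN002`, ...
#'
#' @param n_proteins Number of records.
#' @param length_range Two integers: min and max sequence length
#'   (inclusive); lengths are drawn uniformly.
#' @param seed Integer seed (required; fixtures are deterministic).
#' @param composition Optional named sampling weights, residue -> weight.
#' @param planted_kmers Optional tibble/data.frame with columns `kmer`,
#'   `protein` (record index) and `position` (1-based plant position).
#' @param planted_features Optional tibble with columns `protein`, `kind`,
#'   `start`, `end`, `note`: features attached to the stated record.
#' @param id_prefix Prefix for record ids.
#' @return A protein record tibble.
#' @export
#' @examples
#' simulate_proteome(3, c(50, 80), seed = 1)
simulate_proteome <- function(n_proteins, length_range = c(80, 300), seed,
                              composition = NULL, planted_kmers = NULL,
                              planted_features = NULL, id_prefix = "SYN") {
  stopifnot(n_proteins >= 1, length(length_range) == 2)
  recs <- with_fixture_seed(seed, {
    len <- length_range[1] - 1L +
      sample.int(length_range[2] - length_range[1] + 1L, n_proteins,
        replace = TRUE
      )
    tibble(
      id = sprintf("%s%03d", id_prefix, seq_len(n_proteins)),
      description = sprintf("synthetic protein %d", seq_len(n_proteins)),
      sequence = vapply(len, sample_sequence, "", composition = composition)
    )
  })
  if (!is.null(planted_kmers)) {
    for (i in seq_len(nrow(planted_kmers))) {
      p <- planted_kmers$protein[i]
      pos <- planted_kmers$position[i]
      km <- toupper(planted_kmers$kmer[i])
      s <- recs$sequence[p]
      if (pos < 1 || pos + nchar(km) - 1 > nchar(s)) {
        abort(
          paste0(
            "planted k-mer '", km, "' at position ", pos,
            " exceeds the bounds of record ", p, " (length ", nchar(s), ")"
          ),
          class = "immunopep_parameter_error"
        )
      }
      substr(s, pos, pos + nchar(km) - 1L) <- km
      recs$sequence[p] <- s
    }
  }
  feats <- rep(list(feature_table()), n_proteins)
  if (!is.null(planted_features)) {
    for (p in unique(planted_features$protein)) {
      rows <- planted_features[planted_features$protein == p, , drop = FALSE]
      feats[[p]] <- feature_table(
        rows$kind, rows$start, rows$end,
        if ("note" %in% names(rows)) rows$note else ""
      )
    }
  }
  protein_record(recs$id, recs$sequence, recs$description, feats)
}

#' Simulate one synthetic protein
#'
#' @param length Sequence length in residues.
#' @param seed Integer seed.
#' @param id Record id.
#' @inheritParams simulate_proteome
#' @return A one-row protein record tibble.
#' @export
simulate_protein <- function(length, seed, id = "SYN001",
                             composition = NULL) {
  seq <- with_fixture_seed(seed, sample_sequence(length, composition))
  protein_record(id, seq, "synthetic protein")
}

#' Simulate an ortholog by point substitution
#'
#' Each position is independently replaced, with the given probability, by
#' a different standard residue drawn uniformly. Emulates conserved
#' (low-rate) through diverged (high-rate) ortholog situations; no indels.
#'
#' @param protein A protein record tibble (first row used) or sequence
#'   string.
#' @param substitution_rate Per-position substitution probability in
#'   \[0, 1\].
#' @param seed Integer seed.
#' @param id Id of the resulting record.
#' @return A one-row protein record tibble.
#' @export
#' @examples
#' simulate_ortholog(simulate_protein(60, 1), 0.1, seed = 2)
simulate_ortholog <- function(protein, substitution_rate, seed,
                              id = "ORTH001") {
  if (substitution_rate < 0 || substitution_rate > 1) {
    abort("substitution_rate must be in [0, 1]",
      class = "immunopep_parameter_error"
    )
  }
  res <- residues_of(as_sequence(protein))
  mutated <- with_fixture_seed(seed, {
    hit <- stats::runif(length(res)) < substitution_rate
    res[hit] <- vapply(
      res[hit],
      function(a) sample(setdiff(STANDARD_AA, a), 1),
      ""
    )
    res
  })
  protein_record(id, paste(mutated, collapse = ""), "synthetic ortholog")
}
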