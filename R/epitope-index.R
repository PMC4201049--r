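# Exact k-mer indexing over proteomes: the engine behind per-window
# uniqueness (predictor of antibody specificity) and cross-species
# conservation (predictor of multi-species cross-reactivity).
#
# Matching is exact, case-insensitive substring matching of epitope-length
# k-mers; k-mers containing nonstandard letters (B, Z, X, U, O) are never
# indexed and never queried as hits.

# all k-mers of a sequence, flagged clean when they contain only the 20
# standard letters
sequence_kmers <- function(sequence, k) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < k) {
    return(character())
  }
  start <- seq_len(n - k + 1L)
  substring(sequence, start, start + k - 1L)
}

is_clean_kmer <- function(kmers) {
  grepl(paste0("^[", paste(STANDARD_AA, collapse = ""), "]+$"), kmers)
}

#' Build an epitope k-mer index over a proteome
#'
#' Maps every clean epitope-length k-mer of every record to the set of
#' protein ids containing it as a substring (deduplicated; internal repeats
#' post a protein id once).
#'
#' @param proteome A protein record tibble (columns `id`, `sequence`).
#' @param epitope_length k-mer length E (>= 1).
#' @param species_label Optional free-text label carried on the index.
#' @return An `epitope_index` object.
#' @export
#' @examples
#' idx <- build_epitope_index(protein_record("p1", "MKNPDGSQRW"), 4)
#' index_lookup(idx, "KNPD")
build_epitope_index <- function(proteome, epitope_length,
                                species_label = NA_character_) {
  E <- as.integer(epitope_length)
  if (is.na(E) || E < 1) {
    abort("epitope_length must be a positive integer",
      class = "immunopep_parameter_error"
    )
  }
  if (!is.data.frame(proteome) || nrow(proteome) == 0) {
    abort("proteome must be a non-empty protein record tibble",
      class = "immunopep_parameter_error"
    )
  }
  if (anyDuplicated(proteome$id)) {
    abort("proteome record ids must be unique",
      class = "immunopep_parameter_error"
    )
  }
  postings <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(proteome))) {
    km <- sequence_kmers(proteome$sequence[i], E)
    km <- unique(km[is_clean_kmer(km)])
    id <- proteome$id[i]
    for (x in km) {
      postings[[x]] <- c(postings[[x]], id)
    }
  }
  structure(
    list(
      k = E, postings = postings,
      n_proteins = nrow(proteome), species_label = species_label
    ),
    class = "epitope_index"
  )
}

#' @export
print.epitope_index <- function(x, ...) {
  cat(
    "epitope index: k =", x$k, "|", length(ls(x$postings)), "k-mers from",
    x$n_proteins, "proteins\n"
  )
  invisible(x)
}

#' Look up a k-mer in an epitope index
#'
#' @param index An `epitope_index`.
#' @param kmer A k-mer string of the index's epitope length.
#' @return Character vector of protein ids containing the k-mer (empty when
#'   absent).
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "epitope_index"))
  index$postings[[toupper(kmer)]] %||% character()
}

#' Per-window uniqueness against a background proteome
#'
#' The uniqueness score of a window is the fraction of its epitope-length
#' k-mers found in no off-target protein of the proteome. K-mers containing
#' nonstandard letters count as having zero off-target hits but are flagged.
#' Internal repeats within the target are self-matches, never off-target.
#'
#' @param windows A window tibble (columns `start`, `end`, `peptide`).
#' @param index An `epitope_index` built over the background proteome with
#'   the run's epitope length.
#' @param target_ids Protein ids to treat as self (the target and its
#'   isoforms).
#' @return The window tibble with columns `uniqueness_score`,
#'   `off_target_ids` (list of character), `has_nonstandard_epitope`, and a
#'   `per_epitope` list-column of per-k-mer off-target counts.
#' @export
uniqueness <- function(windows, index, target_ids) {
  stopifnot(is.data.frame(windows), inherits(index, "epitope_index"))
  E <- index$k
  L <- nchar(windows$peptide)
  if (any(L < E)) {
    abort(
      paste0("window shorter than the epitope length (", E, ")"),
      class = "immunopep_parameter_error"
    )
  }
  per <- map(windows$peptide, function(p) {
    km <- sequence_kmers(p, E)
    clean <- is_clean_kmer(km)
    hits <- map(km, function(x) {
      if (!is_clean_kmer(x)) character() else setdiff(index_lookup(index, x), target_ids)
    })
    tibble(
      epitope = km,
      clean = clean,
      n_off_target = lengths(hits),
      off_target_ids = hits
    )
  })
  mutate(windows,
    uniqueness_score = map_dbl(per, ~ mean(.x$n_off_target == 0)),
    off_target_ids = map(per, ~ sort(unique(unlist(.x$off_target_ids)))),
    has_nonstandard_epitope = map_lgl(per, ~ any(!.x$clean)),
    per_epitope = per
  )
}

#' Per-window conservation across ortholog sets
#'
#' For each species, the conservation fraction of a window is the fraction
#' of its epitope-length k-mers present anywhere in that species' ortholog
#' sequences (presence, not position, is what antibody cross-reactivity
#' needs). The overall score is the arithmetic mean across species.
#'
#' @param windows A window tibble (columns `start`, `end`, `peptide`).
#' @param ortholog_sets Named list: species label -> protein record tibble.
#' @param epitope_length k-mer length E.
#' @return The window tibble with one `conservation_<label>` column per
#'   species plus `conservation_overall`.
#' @export
conservation <- function(windows, ortholog_sets, epitope_length) {
  stopifnot(is.data.frame(windows))
  if (length(ortholog_sets) == 0) {
    abort("at least one species of orthologs is required",
      class = "immunopep_parameter_error"
    )
  }
  labels <- names(ortholog_sets)
  if (is.null(labels) || any(!nzchar(labels))) {
    abort("ortholog_sets must be a named list (species labels as names)",
      class = "immunopep_parameter_error"
    )
  }
  E <- as.integer(epitope_length)
  win_kmers <- map(windows$peptide, function(p) {
    km <- sequence_kmers(p, E)
    km[is_clean_kmer(km)]
  })
  n_kmers <- nchar(windows$peptide) - E + 1L
  frac <- matrix(0, nrow = nrow(windows), ncol = length(labels),
    dimnames = list(NULL, labels)
  )
  for (sp in labels) {
    orth <- ortholog_sets[[sp]]
    if (is.null(orth) || nrow(orth) == 0) {
      warn(paste0("species '", sp, "' has no ortholog sequences; scoring 0"))
      next
    }
    idx <- build_epitope_index(orth, E, species_label = sp)
    frac[, sp] <- vapply(seq_len(nrow(windows)), function(i) {
      km <- win_kmers[[i]]
      sum(vapply(km, function(x) length(index_lookup(idx, x)) > 0, logical(1))) /
        n_kmers[i]
    }, numeric(1))
  }
  out <- windows
  for (sp in labels) {
    out[[paste0("conservation_", sp)]] <- unname(frac[, sp])
  }
  out$conservation_overall <- unname(rowMeans(frac))
  out
}

#' Default self-id set for a target protein
#'
#' The target's own id plus any proteome ids sharing its accession root
#' before a hyphen (the UniProt isoform convention, e.g. `P12345-2`), so
#' isoform hits count as self.
#'
#' @param target_id The target protein id.
#' @param proteome_ids Character vector of proteome ids.
#' @return Character vector of ids treated as self.
#' @export
default_target_ids <- function(target_id, proteome_ids = character()) {
  root <- sub("-.*$", "", target_id)
  unique(c(
    target_id,
    proteome_ids[sub("-.*$", "", proteome_ids) == root]
  ))
}
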