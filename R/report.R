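# The integrated design report: every candidate window with its Ig-score
# and rank, uniqueness, per-species conservation, feature flags, and the
# per-track normalization metadata an external heat-map renderer needs.

REPORT_SCHEMA_VERSION <- "1.0"

CONJUGATION_NOTE <- paste(
  "A terminal cysteine may be added to the synthesized peptide for",
  "carrier (e.g. KLH) conjugation; sequences here are unmodified."
)

#' Run the full peptide-immunogen design pipeline
#'
#' Enumerates all windows of the requested peptide length, scores and
#' ranks them for immunogenicity, and adds uniqueness (when a background
#' proteome is given), per-species conservation (when orthologs are
#' given) and feature-overlap flags. Tracks that cannot be computed for
#' lack of inputs are reported as `NA`, which is distinct from a computed
#' zero.
#'
#' @param target A protein record tibble (first row used) or amino-acid
#'   string.
#' @param params A [design_params()] object.
#' @param proteome Optional background proteome (protein record tibble)
#'   for uniqueness.
#' @param orthologs Named list of protein record tibbles, one per species,
#'   for conservation.
#' @param features Optional feature tibble; defaults to the features
#'   attached to `target`.
#' @param target_ids Ids treated as self during uniqueness; defaults to
#'   [default_target_ids()] over the target id and the proteome.
#' @param exclude_ptm,exclude_transmem Optional filters dropping windows
#'   that overlap PTM sites / transmembrane segments (flags are advisory
#'   by default; these switches make them exclusions).
#' @return A `design_report` object: window rows (`$rows`, sorted by
#'   `start`), per-residue display tracks (`$tracks`), normalization
#'   metadata (`$normalization`), and run metadata.
#' @export
#' @examples
#' rep <- run_design(simulate_protein(80, 1), design_params(15))
#' glance(rep)
run_design <- function(target, params, proteome = NULL, orthologs = list(),
                       features = NULL, target_ids = NULL,
                       exclude_ptm = FALSE, exclude_transmem = FALSE) {
  stopifnot(inherits(params, "design_params"))
  if (!is.data.frame(target)) {
    target <- protein_record("target", as_sequence(target))
  }
  sequence <- as_sequence(target)
  n <- nchar(sequence)
  target_id <- target$id[[1]]
  features <- features %||%
    (if ("features" %in% names(target)) target$features[[1]] else feature_table())
  check_feature_bounds(features, n, paste0("target ", target_id))

  rows <- enumerate_windows(target, params$peptide_length) |>
    score_windows(n, params) |>
    rank_windows()

  species <- character()
  if (!is.null(proteome)) {
    target_ids <- target_ids %||% default_target_ids(target_id, proteome$id)
    idx <- build_epitope_index(proteome, params$epitope_length)
    rows <- uniqueness(rows, idx, target_ids) |>
      select(-"per_epitope")
  } else {
    rows <- mutate(rows,
      uniqueness_score = NA_real_, off_target_ids = list(character()),
      has_nonstandard_epitope = NA
    )
  }
  if (length(orthologs) > 0) {
    species <- names(orthologs)
    rows <- conservation(rows, orthologs, params$epitope_length)
  } else {
    rows <- mutate(rows, conservation_overall = NA_real_)
  }
  rows <- flag_windows(rows, features)
  if (exclude_ptm) {
    rows <- filter(rows, !.data$ptm_overlap)
  }
  if (exclude_transmem) {
    rows <- filter(rows, !.data$transmem_overlap)
  }
  rows <- arrange(rows, .data$start)

  normalization <- bind_rows(
    norm_meta("ig_score", rows$ig_score),
    norm_meta("uniqueness_score", rows$uniqueness_score),
    norm_meta("conservation_overall", rows$conservation_overall)
  )
  rows <- rows |>
    mutate(
      ig_score_norm = norm_values(.data$ig_score),
      uniqueness_norm = norm_values(.data$uniqueness_score),
      conservation_norm = norm_values(.data$conservation_overall),
      note = CONJUGATION_NOTE
    )

  hw <- min(9L, if (n %% 2L == 0L) n - 1L else n)
  tracks <- hydropathy_track(sequence, window = max(hw, 1L)) |>
    left_join(
      select(secondary_structure_track(sequence), "position", "ss_class"),
      by = "position"
    )

  structure(
    list(
      protein_id = target_id,
      protein_length = n,
      params = params,
      species = species,
      rows = rows,
      tracks = tracks,
      normalization = normalization,
      schema_version = REPORT_SCHEMA_VERSION
    ),
    class = "design_report"
  )
}

# heat-map normalization: (x - min) / (max - min), 0 when the track is
# constant; all-NA tracks stay NA
norm_values <- function(x) {
  if (all(is.na(x))) {
    return(rep(NA_real_, length(x)))
  }
  lo <- min(x, na.rm = TRUE)
  hi <- max(x, na.rm = TRUE)
  if (hi == lo) rep(0, length(x)) else (x - lo) / (hi - lo)
}

norm_meta <- function(track, x) {
  if (all(is.na(x))) {
    tibble(track = track, min = NA_real_, max = NA_real_)
  } else {
    tibble(track = track, min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE))
  }
}

#' @export
print.design_report <- function(x, n = 5, ...) {
  cat(
    "peptide design report for", x$protein_id,
    paste0("(", x$protein_length, " aa)"), "\n"
  )
  print(x$params)
  cat(nrow(x$rows), "candidate windows; top ranked:\n")
  top <- head(arrange(x$rows, .data$ig_rank, .data$start), n)
  print(select(
    top, "start", "end", "peptide", "ig_score", "ig_rank",
    dplyr::any_of(c("uniqueness_score", "conservation_overall"))
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a design report into its per-window tibble
#'
#' @param x A `design_report`.
#' @param ... Unused.
#' @return The per-window tibble, sorted by position.
#' @export
tidy.design_report <- function(x, ...) {
  x$rows
}

#' One-row summary of a design report
#'
#' @param x A `design_report`.
#' @param ... Unused.
#' @return A one-row tibble: protein id and length, window count, the
#'   number of windows at or above the high-immunogenicity threshold, the
#'   top Ig-score, and which optional tracks were computed.
#' @export
glance.design_report <- function(x, ...) {
  tibble(
    protein_id = x$protein_id,
    protein_length = x$protein_length,
    n_windows = nrow(x$rows),
    peptide_length = x$params$peptide_length,
    epitope_length = x$params$epitope_length,
    n_high_ig = sum(x$rows$ig_score >= x$params$high_ig_threshold),
    top_ig_score = max(x$rows$ig_score),
    has_uniqueness = !all(is.na(x$rows$uniqueness_score)),
    has_conservation = !all(is.na(x$rows$conservation_overall))
  )
}

# fixed column order of the TSV output
report_columns <- function(report) {
  c(
    "start", "end", "peptide", "ig_score", "ig_rank",
    "hydrophilicity", "turn_propensity", "tail_bonus", "ig_score_norm",
    "uniqueness_score", "uniqueness_norm", "off_target_ids",
    if (length(report$species) > 0) {
      paste0("conservation_", report$species)
    } else {
      character(0)
    },
    "conservation_overall", "conservation_norm",
    "ptm_overlap", "variant_overlap", "splice_conflict_overlap",
    "transmem_overlap", "ptm_detail", "domain_context", "note"
  )
}

#' Write a design report as TSV
#'
#' One header row; columns in a documented fixed order; floats with 3
#' decimal places; list cells joined by `;` (an empty set is an empty
#' cell, not `NA`); absent tracks are the sentinel `NA`. Output rows are
#' sorted by `start`; rank is a column.
#'
#' @param report A `design_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  stopifnot(inherits(report, "design_report"))
  cols <- report_columns(report)
  rows <- report$rows[, cols]
  cells <- lapply(rows, function(col) {
    if (is.list(col)) {
      vapply(col, function(x) paste(x, collapse = ";"), "")
    } else if (is.double(col)) {
      ifelse(is.na(col), "NA", sprintf("%.3f", col))
    } else if (is.logical(col)) {
      ifelse(is.na(col), "NA", ifelse(col, "TRUE", "FALSE"))
    } else {
      as.character(col)
    }
  })
  lines <- c(
    paste(cols, collapse = "\t"),
    do.call(paste, c(cells, sep = "\t"))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write a design report as JSON
#'
#' A full-fidelity structured dump: schema version, protein metadata, all
#' run parameters, normalization metadata, and every row value at full
#' precision. Schema version is `"1.0"`.
#'
#' @param report A `design_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "design_report"))
  payload <- list(
    schema_version = report$schema_version,
    protein = list(id = report$protein_id, length = report$protein_length),
    params = unclass(report$params),
    species = as.list(report$species),
    normalization = report$normalization,
    rows = report$rows[, report_columns(report)]
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' Plot the aligned design tracks
#'
#' A track-aligned view of a design report: per-window heat tiles for the
#' normalized Ig-score, uniqueness and conservation tracks (each tile at
#' the window midpoint) over the per-residue hydropathy and
#' secondary-structure tracks.
#'
#' @param object A `design_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.design_report <- function(object, ...) {
  mid <- (object$rows$start + object$rows$end) / 2
  win_long <- tibble(
    position = rep(mid, 3),
    track = rep(c("Ig-score", "uniqueness", "conservation"), each = length(mid)),
    value = c(
      object$rows$ig_score_norm, object$rows$uniqueness_norm,
      object$rows$conservation_norm
    )
  )
  res_long <- tibble(
    position = object$tracks$position,
    track = "hydrophilicity",
    # brightest = most hydrophilic, i.e. lowest Kyte-Doolittle value
    value = norm_values(-object$tracks$hydropathy)
  )
  ss <- tibble(
    position = object$tracks$position,
    track = "secondary structure",
    ss_class = object$tracks$ss_class
  )
  lv <- c(
    "Ig-score", "uniqueness", "conservation", "hydrophilicity",
    "secondary structure"
  )
  ggplot2::ggplot() +
    ggplot2::geom_tile(
      data = dplyr::bind_rows(win_long, res_long),
      ggplot2::aes(
        x = .data$position, y = factor(.data$track, levels = rev(lv)),
        fill = .data$value
      )
    ) +
    ggplot2::geom_tile(
      data = ss,
      ggplot2::aes(
        x = .data$position, y = factor(.data$track, levels = rev(lv)),
        alpha = .data$ss_class
      ),
      fill = "grey20"
    ) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", limits = c(0, 1)) +
    ggplot2::scale_alpha_manual(
      values = c(
        HELIX = 0.45, SHEET = 0.9, TURN_STRONG = 0.7,
        TURN_WEAK = 0.3, NONE = 0.05
      ),
      drop = FALSE
    ) +
    ggplot2::labs(
      x = "residue position", y = NULL,
      title = paste0(object$protein_id, " (", object$protein_length, " aa)"),
      fill = "normalized\nscore", alpha = "Chou-Fasman\nclass"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
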