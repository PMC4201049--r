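# Candidate-window enumeration and the composite immunogenicity (Ig) score.
#
# The Ig-score of a window is a normalized product
#
#   ig = 10 * hydrophilicity * turn_propensity * tail_bonus
#
# where hydrophilicity = clamp((4.5 - meanKD) / 9, 0, 1) rescales the mean
# Kyte-Doolittle hydropathy of the window from its [-4.5, 4.5] range so the
# most hydrophilic window scores 1, turn_propensity =
# clamp((meanPt - 0.47) / 1.09, 0, 1) rescales the mean Chou-Fasman turn
# parameter from its [0.47, 1.56] range over the 20 residues, and
# tail_bonus is B when the window lies entirely within T residues of either
# protein terminus (terminal tails are typically accessible and
# disordered), else 1. Scores of 7 or more are considered high
# immunogenicity.

#' Design parameters for a peptide-immunogen run
#'
#' @param peptide_length Length L of the immunizing peptide windows, in
#'   residues.
#' @param epitope_length Length E of the contiguous epitope k-mers used for
#'   uniqueness and conservation; default 7.
#' @param tail_length Extent T of the terminal tail regions, in residues
#'   from each terminus; windows lying entirely inside a tail get the tail
#'   bonus. Default 60.
#' @param tail_bonus Multiplier B (>= 1) applied to tail windows. Default 2.
#' @param high_ig_threshold Ig-score at or above which a window is called
#'   highly immunogenic. Default 7.
#' @return A `design_params` list.
#' @export
#' @examples
#' design_params(peptide_length = 18)
design_params <- function(peptide_length, epitope_length = 7,
                          tail_length = 60, tail_bonus = 2,
                          high_ig_threshold = 7) {
  L <- as.integer(peptide_length)
  E <- as.integer(epitope_length)
  if (is.na(L) || L < 1) {
    abort("peptide_length must be a positive integer",
      class = "immunopep_parameter_error"
    )
  }
  if (is.na(E) || E < 1 || E > L) {
    abort(
      paste0(
        "epitope_length (", epitope_length,
        ") must satisfy 1 <= E <= peptide_length (", L, ")"
      ),
      class = "immunopep_parameter_error"
    )
  }
  if (tail_length < 0) {
    abort("tail_length must be >= 0", class = "immunopep_parameter_error")
  }
  if (tail_bonus < 1) {
    abort("tail_bonus must be >= 1", class = "immunopep_parameter_error")
  }
  structure(
    list(
      peptide_length = L, epitope_length = E,
      tail_length = as.integer(tail_length),
      tail_bonus = as.numeric(tail_bonus),
      high_ig_threshold = as.numeric(high_ig_threshold)
    ),
    class = "design_params"
  )
}

#' @export
print.design_params <- function(x, ...) {
  cat(
    "design parameters: L =", x$peptide_length, "E =", x$epitope_length,
    "T =", x$tail_length, "B =", x$tail_bonus,
    "high-Ig threshold =", x$high_ig_threshold, "\n"
  )
  invisible(x)
}

#' Enumerate all candidate peptide windows
#'
#' @param protein A protein record tibble (first row used) or a plain
#'   amino-acid string.
#' @param peptide_length Window length L in residues.
#' @return A tibble with one row per window (`length - L + 1` rows) and
#'   columns `start`, `end`, `peptide`, in position order.
#' @export
#' @examples
#' enumerate_windows("MKNPDGSQRW", 7)
enumerate_windows <- function(protein, peptide_length) {
  sequence <- as_sequence(protein)
  n <- nchar(sequence)
  L <- as.integer(peptide_length)
  if (is.na(L) || L < 1 || L > n) {
    abort(
      paste0(
        "peptide_length (", peptide_length,
        ") must be between 1 and the protein length (", n, ")"
      ),
      class = "immunopep_parameter_error"
    )
  }
  start <- seq_len(n - L + 1L)
  tibble(
    start = start,
    end = start + L - 1L,
    peptide = substring(sequence, start, start + L - 1L)
  )
}

# accept a record tibble or a bare sequence string
as_sequence <- function(protein) {
  if (is.data.frame(protein)) {
    if (!"sequence" %in% names(protein) || nrow(protein) == 0) {
      abort("protein tibble must have a 'sequence' column",
        class = "immunopep_parameter_error"
      )
    }
    toupper(protein$sequence[[1]])
  } else {
    toupper(as.character(protein)[[1]])
  }
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# mean scale value over each peptide string (depends only on the peptide)
peptide_mean_scale <- function(peptides, scale) {
  vapply(
    strsplit(toupper(peptides), "", fixed = TRUE),
    function(res) mean(scale_values(res, scale)),
    numeric(1)
  )
}

#' Score peptide windows for immunogenicity
#'
#' Adds the Ig-score and its components to a window tibble. The score of a
#' window depends only on its own sequence and on whether it lies entirely
#' inside a terminal tail region (within `tail_length` residues of either
#' protein terminus).
#'
#' @param windows A window tibble from [enumerate_windows()] (columns
#'   `start`, `end`, `peptide`).
#' @param protein_length Length of the parent protein, for the tail test.
#' @param params A [design_params()] object.
#' @return The window tibble with columns `mean_kd`, `mean_pt`,
#'   `hydrophilicity`, `turn_propensity`, `tail_bonus`, `ig_score` added.
#' @export
score_windows <- function(windows, protein_length, params) {
  stopifnot(is.data.frame(windows), inherits(params, "design_params"))
  mean_kd <- peptide_mean_scale(windows$peptide, ip_scale("kd"))
  mean_pt <- peptide_mean_scale(windows$peptide, ip_scale("pt"))
  hydrophilicity <- clamp01((4.5 - mean_kd) / 9)
  turn_propensity <- clamp01((mean_pt - 0.47) / 1.09)
  in_tail <- windows$end <= params$tail_length |
    windows$start >= protein_length - params$tail_length + 1L
  tail_bonus <- ifelse(in_tail, params$tail_bonus, 1)
  mutate(windows,
    mean_kd = mean_kd, mean_pt = mean_pt,
    hydrophilicity = hydrophilicity, turn_propensity = turn_propensity,
    tail_bonus = tail_bonus,
    ig_score = 10 * hydrophilicity * turn_propensity * tail_bonus
  )
}

#' Ig-score of a single peptide window
#'
#' @param peptide The window sequence.
#' @param start 1-based start coordinate of the window in the protein.
#' @param protein_length Length of the parent protein.
#' @param params A [design_params()] object (its `peptide_length` must
#'   equal `nchar(peptide)`).
#' @return A one-row scored window tibble (see [score_windows()]).
#' @export
#' @examples
#' ig_score("EPDTDWEEREVRRRQ", 1, 15, design_params(15))
ig_score <- function(peptide, start, protein_length, params) {
  L <- nchar(peptide)
  if (L != params$peptide_length) {
    abort(
      paste0(
        "peptide length ", L, " does not match params$peptide_length ",
        params$peptide_length
      ),
      class = "immunopep_parameter_error"
    )
  }
  w <- tibble(
    start = as.integer(start),
    end = as.integer(start) + L - 1L, peptide = toupper(peptide)
  )
  if (w$end > protein_length) {
    abort("window extends beyond the protein",
      class = "immunopep_parameter_error"
    )
  }
  score_windows(w, protein_length, params)
}

#' Rank scored windows by Ig-score
#'
#' Competition ranking on descending Ig-score: tied scores share the
#' smallest rank and the next distinct score gets rank equal to one plus
#' the number of strictly better windows.
#'
#' @param windows A scored window tibble (column `ig_score`).
#' @return The tibble with an `ig_rank` column, sorted by rank ascending
#'   and ties by `start` ascending.
#' @export
rank_windows <- function(windows) {
  if (!is.data.frame(windows) || nrow(windows) == 0) {
    abort("no windows to rank", class = "immunopep_parameter_error")
  }
  windows |>
    mutate(ig_rank = as.integer(rank(-.data$ig_score, ties.method = "min"))) |>
    arrange(.data$ig_rank, .data$start)
}
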