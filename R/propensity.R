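# Per-residue display tracks: window-averaged Kyte-Doolittle hydropathy and
# a simplified Chou-Fasman secondary-structure class.

# split a sequence string into residue letters
residues_of <- function(sequence) {
  strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
}

# centered running mean with the window truncated at the sequence ends:
# value at i is the mean over positions max(1, i-h) .. min(n, i+h)
truncated_window_mean <- function(values, window) {
  n <- length(values)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(values))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Window-averaged Kyte-Doolittle hydropathy track
#'
#' The value at each position is the arithmetic mean of the Kyte-Doolittle
#' hydropathy index over a window centered there, truncated at the sequence
#' ends. Nonstandard letters contribute the scale's neutral default (0).
#'
#' @param sequence Amino-acid string.
#' @param window Odd positive window width, at most the sequence length.
#'   The default 9 is the conventional width for hydropathy plots.
#' @param scale Optional replacement scale, as returned by [read_scale()].
#' @return A tibble with columns `position`, `residue`, `hydropathy`.
#' @export
#' @examples
#' hydropathy_track("MKNPDGSQRW", window = 3)
hydropathy_track <- function(sequence, window = 9, scale = NULL) {
  res <- residues_of(sequence)
  if (window < 1 || window %% 2 == 0) {
    abort(paste0("window must be an odd positive integer, got ", window),
      class = "immunopep_parameter_error"
    )
  }
  if (window > length(res)) {
    abort(
      paste0(
        "window (", window, ") exceeds sequence length (", length(res), ")"
      ),
      class = "immunopep_parameter_error"
    )
  }
  scale <- scale %||% ip_scale("kd")
  tibble(
    position = seq_along(res),
    residue = res,
    hydropathy = truncated_window_mean(scale_values(res, scale), window)
  )
}

#' Simplified Chou-Fasman secondary-structure track
#'
#' A display-only classification (the immunogenicity score does not use
#' it). For each residue the 5-wide centered means of the Chou-Fasman
#' conformational parameters Pa, Pb, Pt are computed (truncated at the
#' ends) and the residue is labelled, in priority order:
#' `TURN_STRONG` (mPt >= 1.10 and mPt >= max(mPa, mPb)),
#' `TURN_WEAK` (1.00 <= mPt < 1.10 and mPt >= max(mPa, mPb)),
#' `HELIX` (mPa >= 1.06 and mPa > mPb),
#' `SHEET` (mPb >= 1.05 and mPb >= mPa), else `NONE`.
#' The thresholds are the classic former/breaker cutoffs; the full
#' Chou-Fasman nucleation/extension algorithm is intentionally not
#' implemented.
#'
#' @param sequence Amino-acid string (nonstandard letters take the neutral
#'   propensity 1).
#' @return A tibble with columns `position`, `residue`, `ss_class` (factor
#'   over HELIX, SHEET, TURN_STRONG, TURN_WEAK, NONE).
#' @export
#' @examples
#' secondary_structure_track("NGNGNGNG")
secondary_structure_track <- function(sequence) {
  res <- residues_of(sequence)
  if (length(res) == 0) {
    abort("sequence is empty", class = "immunopep_parameter_error")
  }
  m_pa <- truncated_window_mean(scale_values(res, ip_scale("pa")), 5L)
  m_pb <- truncated_window_mean(scale_values(res, ip_scale("pb")), 5L)
  m_pt <- truncated_window_mean(scale_values(res, ip_scale("pt")), 5L)
  m_ab <- pmax(m_pa, m_pb)
  cls <- rep("NONE", length(res))
  cls[m_pb >= 1.05 & m_pb >= m_pa] <- "SHEET"
  cls[m_pa >= 1.06 & m_pa > m_pb] <- "HELIX"
  cls[m_pt >= 1.00 & m_pt < 1.10 & m_pt >= m_ab] <- "TURN_WEAK"
  cls[m_pt >= 1.10 & m_pt >= m_ab] <- "TURN_STRONG"
  tibble(
    position = seq_along(res),
    residue = res,
    ss_class = factor(cls, levels = SS_CLASSES)
  )
}
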