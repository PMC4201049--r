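# Residue propensity scales.
#
# The packaged constants are transcribed from the cited publications (see
# the provenance headers of the TSV files under inst/extdata/scales): the
# Kyte-Doolittle hydropathy index and the Chou-Fasman conformational
# parameters Pa (helix), Pb (sheet), Pt (turn). The TSV files are the
# canonical copies; they are parsed once per session through the same
# reader exposed to users.

.scale_cache <- new.env(parent = emptyenv())

#' Read a residue propensity scale from a tab-separated file
#'
#' A scale file has one `residue<TAB>value` pair per line; `#` lines are
#' provenance comments. All 20 standard residues must be present.
#'
#' @param path Path to the scale file.
#' @param default_value Value used for residue letters absent from the file
#'   (nonstandard letters such as B, Z, X, U, O).
#' @return A named numeric vector over the residue letters found, with the
#'   default recorded in attribute `default_value`.
#' @export
#' @examples
#' kd <- read_scale(system.file("extdata/scales/kyte_doolittle.tsv",
#'   package = "immunopep"
#' ))
#' kd[["I"]] # 4.5
read_scale <- function(path, default_value = 0) {
  if (!file.exists(path)) {
    abort(paste0("scale file not found: ", path), class = "immunopep_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    abort(paste0("malformed scale line: ", lines[bad[1]]),
      class = "immunopep_format_error"
    )
  }
  res <- toupper(vapply(parts, `[[`, "", 1))
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  if (anyNA(val)) {
    abort(paste0("non-numeric scale value: ", lines[which(is.na(val))[1]]),
      class = "immunopep_format_error"
    )
  }
  missing_aa <- setdiff(STANDARD_AA, res)
  if (length(missing_aa) > 0) {
    abort(
      paste0(
        "scale is missing standard residues: ",
        paste(missing_aa, collapse = ", ")
      ),
      class = "immunopep_format_error"
    )
  }
  out <- setNames(val, res)
  attr(out, "default_value") <- default_value
  out
}

# packaged scale lookup, cached per session; KD defaults nonstandard letters
# to 0 (neutral hydropathy), Chou-Fasman parameters to 1 (neutral propensity)
ip_scale <- function(name = c("kd", "pa", "pb", "pt")) {
  name <- match.arg(name)
  if (!is.null(.scale_cache[[name]])) {
    return(.scale_cache[[name]])
  }
  file <- switch(name,
    kd = "kyte_doolittle.tsv",
    pa = "chou_fasman_pa.tsv",
    pb = "chou_fasman_pb.tsv",
    pt = "chou_fasman_pt.tsv"
  )
  default <- if (name == "kd") 0 else 1
  path <- system.file("extdata", "scales", file,
    package = "immunopep", mustWork = TRUE
  )
  sc <- read_scale(path, default_value = default)
  assign(name, sc, envir = .scale_cache)
  sc
}

# vectorised per-residue lookup with the scale's default for unknown letters
scale_values <- function(residues, scale) {
  default <- attr(scale, "default_value") %||% 0
  v <- unname(scale[residues])
  v[is.na(v)] <- default
  v
}

#' Packaged residue propensity scales
#'
#' One row per standard amino acid with the Kyte-Doolittle hydropathy index
#' (`kd`) and the Chou-Fasman helix / sheet / turn conformational parameters
#' (`pa`, `pb`, `pt`).
#'
#' @return A tibble with columns `residue`, `kd`, `pa`, `pb`, `pt`.
#' @export
#' @examples
#' propensity_scales()
propensity_scales <- function() {
  tibble(
    residue = STANDARD_AA,
    kd = scale_values(STANDARD_AA, ip_scale("kd")),
    pa = scale_values(STANDARD_AA, ip_scale("pa")),
    pb = scale_values(STANDARD_AA, ip_scale("pb")),
    pt = scale_values(STANDARD_AA, ip_scale("pt"))
  )
}
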