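# Sequence and annotation input/output: FASTA (via Biostrings), a subset of
# the UniProt/Swiss-Prot flat-text record, and a plain tabular feature file.
#
# Protein records are plain tibbles with columns id, description, sequence
# and a `features` list-column of feature tibbles; coordinates are 1-based
# inclusive throughout (the UniProt convention), shared by features and
# peptide windows alike.

#' Construct a feature table
#'
#' @param kind Character vector of feature kinds. Kinds outside the
#'   controlled vocabulary (`MOD_RES`, `CARBOHYD`, `LIPID`, `DISULFID`,
#'   `TRANSMEM`, `TOPO_DOM`, `SIGNAL`, `DOMAIN`, `VARIANT`, `VAR_SEQ`,
#'   `CONFLICT`) are mapped to `OTHER` with the original key prepended to
#'   `note`.
#' @param start,end 1-based inclusive positions (`start <= end`).
#' @param note Free text.
#' @return A tibble with columns `kind`, `start`, `end`, `note`.
#' @export
#' @examples
#' feature_table("MOD_RES", 256, 256, "Phosphoserine")
feature_table <- function(kind = character(), start = integer(),
                          end = integer(), note = "") {
  n <- length(kind)
  start <- as.integer(start)
  end <- as.integer(end)
  note <- rep_len(as.character(note), n)
  if (anyNA(start) || anyNA(end)) {
    abort("feature coordinates must be integers",
      class = "immunopep_format_error"
    )
  }
  kind <- toupper(kind)
  unknown <- !(kind %in% FEATURE_KINDS)
  if (any(unknown)) {
    note[unknown] <- ifelse(
      nzchar(note[unknown]),
      paste0("[", kind[unknown], "] ", note[unknown]),
      paste0("[", kind[unknown], "]")
    )
    kind[unknown] <- "OTHER"
  }
  bad <- which(start < 1L | start > end)
  if (length(bad) > 0) {
    abort(
      paste0(
        "invalid feature interval: ", kind[bad[1]], " ",
        start[bad[1]], "..", end[bad[1]]
      ),
      class = "immunopep_format_error"
    )
  }
  tibble(kind = kind, start = start, end = end, note = note)
}

# assert every feature interval lies within [1, seq_length]
check_feature_bounds <- function(features, seq_length, context = "record") {
  if (nrow(features) == 0) {
    return(invisible(features))
  }
  bad <- which(features$end > seq_length)
  if (length(bad) > 0) {
    abort(
      paste0(
        "feature ", features$kind[bad[1]], " ", features$start[bad[1]],
        "..", features$end[bad[1]], " exceeds sequence length ",
        seq_length, " in ", context
      ),
      class = "immunopep_format_error"
    )
  }
  invisible(features)
}

#' Construct a protein record tibble
#'
#' @param id Identifier (accession or user string), one per record.
#' @param sequence Amino-acid sequence; lowercase letters are uppercased,
#'   nonstandard letters (B, Z, X, U, O) are retained.
#' @param description Free-text description.
#' @param features A feature tibble (see [feature_table()]) or a list of
#'   them, one per record.
#' @return A tibble with columns `id`, `description`, `sequence`,
#'   `features`.
#' @export
#' @examples
#' protein_record("p1", "MKNPDGSQRW")
protein_record <- function(id, sequence, description = "",
                           features = NULL) {
  n <- length(id)
  sequence <- toupper(as.character(sequence))
  description <- rep_len(as.character(description), n)
  if (any(!nzchar(sequence)) || any(!grepl("^[A-Z]+$", sequence))) {
    i <- which(!nzchar(sequence) | !grepl("^[A-Z]+$", sequence))[1]
    abort(
      paste0("record '", id[i], "' has an empty or non-letter sequence"),
      class = "immunopep_format_error"
    )
  }
  if (is.null(features)) {
    features <- rep(list(feature_table()), n)
  } else if (is.data.frame(features)) {
    features <- list(features)
  }
  rec <- tibble(
    id = as.character(id), description = description,
    sequence = sequence, features = features
  )
  for (i in seq_len(n)) {
    check_feature_bounds(rec$features[[i]], nchar(rec$sequence[i]), rec$id[i])
  }
  rec
}

#' Read protein records from a FASTA file
#'
#' @param path Path to a FASTA file ('>' headers, wrapped or unwrapped
#'   sequence lines).
#' @return A protein record tibble; `id` is the first whitespace-delimited
#'   header token, `description` the remainder; input order is preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "immunopep_io_error")
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      abort(paste0("not readable as FASTA: ", path, " (", conditionMessage(e), ")"),
        class = "immunopep_format_error"
      )
    }
  )
  if (length(set) == 0) {
    abort(paste0("no FASTA records in ", path),
      class = "immunopep_format_error"
    )
  }
  headers <- names(set)
  if (any(Biostrings::width(set) == 0)) {
    h <- headers[which(Biostrings::width(set) == 0)[1]]
    abort(paste0("empty sequence for FASTA record '>", h, "'"),
      class = "immunopep_format_error"
    )
  }
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
    sub("^\\S+\\s+", "", headers), ""
  )
  protein_record(id, as.character(set), description)
}

#' Write protein records to a FASTA file
#'
#' Round-trip property: `read_fasta(write_fasta(r, path))` reproduces ids
#' and sequences exactly.
#'
#' @param records A protein record tibble (non-empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("no records to write", class = "immunopep_parameter_error")
  }
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- ifelse(nzchar(records$description),
    paste(records$id, records$description), records$id
  )
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read one protein record from a UniProt/Swiss-Prot flat-text file
#'
#' Supports the modern qualifier-style FT dialect only: feature key and span
#' (`a..b`, or a single position) on the first line, `/note="..."` on
#' continuation lines. Features with unknown positions (`?`, `<`, `>`) are
#' skipped with a warning.
#'
#' @param path Path to a flat-text record (ID/AC lines, FT lines, SQ block
#'   terminated by `//`).
#' @return A one-row protein record tibble with the parsed features
#'   attached.
#' @export
read_uniprot_text <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "immunopep_io_error")
  }
  lines <- readLines(path, warn = FALSE)

  ac <- grep("^AC   ", lines, value = TRUE)
  id_line <- grep("^ID   ", lines, value = TRUE)
  id <- if (length(ac) > 0) {
    sub(";.*$", "", sub("^AC   ", "", ac[1]))
  } else if (length(id_line) > 0) {
    sub("\\s.*$", "", sub("^ID   ", "", id_line[1]))
  } else {
    abort("no ID or AC line in record", class = "immunopep_format_error")
  }
  de <- grep("^DE   ", lines, value = TRUE)
  description <- if (length(de) > 0) {
    trimws(sub("^DE\\s+(RecName:\\s*Full=)?", "", de[1]))
  } else {
    ""
  }

  sq_at <- grep("^SQ   ", lines)
  if (length(sq_at) == 0) {
    abort("no SQ block in record", class = "immunopep_format_error")
  }
  declared <- suppressWarnings(as.integer(
    sub("^SQ\\s+SEQUENCE\\s+(\\d+)\\s+AA.*$", "\\1", lines[sq_at[1]])
  ))
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at) > 0) end_at[1] else length(lines) + 1L
  seq_lines <- lines[seq(sq_at[1] + 1L, end_at - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) {
    abort("empty sequence in SQ block", class = "immunopep_format_error")
  }
  if (!is.na(declared) && declared != nchar(sequence)) {
    abort(
      paste0(
        "SQ block declares ", declared, " AA but the assembled sequence has ",
        nchar(sequence)
      ),
      class = "immunopep_format_error"
    )
  }

  feats <- parse_ft_lines(lines)
  check_feature_bounds(feats, nchar(sequence), paste0("record ", id))
  protein_record(id, sequence, description, feats)
}

# FT lines: "FT   KEY             38..58" opens a feature; continuation
# lines are "FT                   /note=..." (column 6 blank)
parse_ft_lines <- function(lines) {
  ft <- lines[startsWith(lines, "FT   ")]
  if (length(ft) == 0) {
    return(feature_table())
  }
  opens <- grepl("^FT   \\S", ft)
  group <- cumsum(opens)
  kinds <- character()
  starts <- integer()
  ends <- integer()
  notes <- character()
  for (g in unique(group[opens])) {
    block <- ft[group == g]
    m <- regmatches(
      block[1],
      regexec("^FT   (\\S+)\\s+(\\S+)\\s*$", block[1])
    )[[1]]
    if (length(m) < 3) {
      warn(paste0("skipping unparseable FT line: ", block[1]))
      next
    }
    key <- m[2]
    span <- m[3]
    if (grepl("[?<>]", span)) {
      warn(paste0("skipping feature with unknown position: ", key, " ", span))
      next
    }
    if (grepl("^\\d+\\.\\.\\d+$", span)) {
      se <- as.integer(strsplit(span, "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", span)) {
      se <- rep(as.integer(span), 2L)
    } else {
      warn(paste0("skipping feature with unknown position: ", key, " ", span))
      next
    }
    note <- ""
    nm <- regmatches(block, regexec("/note=\"([^\"]*)\"?", block))
    hit <- which(lengths(nm) == 2)
    if (length(hit) > 0) {
      note <- nm[[hit[1]]][2]
    }
    kinds <- c(kinds, key)
    starts <- c(starts, se[1])
    ends <- c(ends, se[2])
    notes <- c(notes, note)
  }
  if (length(kinds) == 0) {
    return(feature_table())
  }
  feature_table(kinds, starts, ends, notes)
}

#' Read a tab-separated feature table file
#'
#' A fallback annotation source when no Swiss-Prot record is available.
#' Columns are `kind`, `start`, `end`, `note` (note optional); `#` comment
#' lines are ignored.
#'
#' @param path Path to the TSV file.
#' @return A feature tibble (see [feature_table()]).
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "immunopep_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    return(feature_table())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    p <- parts[[i]]
    if (length(p) < 3) {
      abort(paste0("line ", lineno[i], ": expected at least 3 tab-separated columns"),
        class = "immunopep_format_error"
      )
    }
    se <- suppressWarnings(as.integer(p[2:3]))
    if (anyNA(se) || !all(grepl("^\\d+$", p[2:3]))) {
      abort(paste0("line ", lineno[i], ": non-integer coordinates"),
        class = "immunopep_format_error"
      )
    }
    if (se[1] > se[2] || se[1] < 1) {
      abort(paste0("line ", lineno[i], ": invalid interval ", se[1], "..", se[2]),
        class = "immunopep_format_error"
      )
    }
    out[[i]] <- feature_table(p[1], se[1], se[2], if (length(p) >= 4) p[4] else "")
  }
  bind_rows(out)
}
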