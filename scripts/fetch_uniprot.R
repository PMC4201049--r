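#!/usr/bin/env Rscript
# Download UniProt records for use as local inputs (the package itself is
# offline-only). Needs network access; excluded from the test suite.
#
#   Rscript scripts/fetch_uniprot.R P34080 [more accessions...] [--dir DIR]
#
# Writes <accession>.txt (flat text, with FT features) and
# <accession>.fasta per accession.

args <- commandArgs(trailingOnly = TRUE)
dir_i <- which(args == "--dir")
dir <- if (length(dir_i) == 1 && dir_i < length(args)) {
  args[dir_i + 1]
} else {
  "."
}
accessions <- setdiff(args, c("--dir", if (length(dir_i)) args[dir_i + 1]))
if (length(accessions) == 0) {
  stop("usage: Rscript scripts/fetch_uniprot.R ACCESSION... [--dir DIR]")
}
dir.create(dir, recursive = TRUE, showWarnings = FALSE)
for (acc in accessions) {
  for (fmt in c("txt", "fasta")) {
    url <- sprintf("https://rest.uniprot.org/uniprotkb/%s.%s", acc, fmt)
    dest <- file.path(dir, paste0(acc, ".", fmt))
    message("fetching ", url)
    utils::download.file(url, dest, quiet = TRUE)
  }
}
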