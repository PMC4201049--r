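#!/usr/bin/env Rscript
# Optional accession-anchored checks against real UniProt records. These
# need files fetched beforehand with scripts/fetch_uniprot.R (network);
# the offline test suite does not depend on them.
#
#   Rscript scripts/fetch_uniprot.R O60500 Q9NP85 O14791 P34080 --dir records
#   Rscript scripts/accession_check.R --dir records
#
# Checks, per protein:
#   nephrin  O60500: canonical length 1241; immunogen 18-mer starts at 1039
#   podocin  Q9NP85: canonical length 383;  immunogen 18-mer starts at 366
#   ApoL1    O14791: canonical length 398;  immunogen 15-mer starts at 125
#   rat Aqp2 P34080: the C-terminal 15-mer scores >= 7 and ranks second
#                    among all 15-residue windows under default parameters

suppressPackageStartupMessages(library(immunopep))

args <- commandArgs(trailingOnly = TRUE)
dir_i <- which(args == "--dir")
dir <- if (length(dir_i) == 1) args[dir_i + 1] else "records"

checks <- list(
  list(
    acc = "O60500", peptide = "HQPSGEPEDQLPTEPPSG",
    length = 1241, start = 1039
  ),
  list(
    acc = "Q9NP85", peptide = "PSKPVEPLNPKKKDSPML",
    length = 383, start = 366
  ),
  list(
    acc = "O14791", peptide = "KDKNWHDKGQQYRNW",
    length = 398, start = 125
  )
)

ok <- TRUE
report <- function(label, passed, detail = "") {
  status <- if (passed) "PASS" else "FAIL"
  cat(sprintf("%-4s %s %s\n", status, label, detail))
  ok <<- ok && passed
}

for (ck in checks) {
  path <- file.path(dir, paste0(ck$acc, ".fasta"))
  rec <- read_fasta(path)
  n <- nchar(rec$sequence[1])
  report(paste0(ck$acc, " length"), n == ck$length, paste0("(", n, ")"))
  windows <- enumerate_windows(rec, nchar(ck$peptide))
  hit <- windows[windows$peptide == ck$peptide, ]
  report(
    paste0(ck$acc, " peptide start"),
    nrow(hit) == 1 && hit$start == ck$start,
    paste0("(", paste(hit$start, collapse = ","), ")")
  )
}

# rat Aqp2: score every 15-mer of the full protein and locate the printed
# peptide in the ranking
aqp2 <- read_fasta(file.path(dir, "P34080.fasta"))
params <- design_params(peptide_length = 15)
rep <- run_design(aqp2, params)
row <- tidy(rep)[tidy(rep)$peptide == "EPDTDWEEREVRRRQ", ]
report(
  "P34080 peptide high Ig", nrow(row) == 1 && row$ig_score >= 7,
  sprintf("(Ig = %.3f)", row$ig_score)
)
report(
  "P34080 peptide rank 2", nrow(row) == 1 && row$ig_rank == 2,
  sprintf("(rank = %d)", row$ig_rank)
)

quit(save = "no", status = if (ok) 0 else 1)
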