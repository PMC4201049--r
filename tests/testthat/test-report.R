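test_that("a minimal run fills Ig columns and leaves absent tracks NA", {
  rec <- simulate_protein(80, 3)
  rep <- run_design(rec, design_params(15))
  expect_s3_class(rep, "design_report")
  expect_equal(nrow(rep$rows), 80 - 15 + 1)
  expect_false(anyNA(rep$rows$ig_score))
  expect_true(all(is.na(rep$rows$uniqueness_score)))
  expect_true(all(is.na(rep$rows$conservation_overall)))
  expect_false(any(rep$rows$ptm_overlap | rep$rows$transmem_overlap))
  expect_equal(rep$rows$start, 1:66) # file order is by position
  expect_equal(nrow(rep$tracks), 80)

  td <- tidy(rep)
  expect_identical(td, rep$rows)
  gl <- glance(rep)
  expect_equal(gl$n_windows, 66L)
  expect_false(gl$has_uniqueness)
})

test_that("a target embedded in its own proteome is fully unique to itself", {
  rec <- simulate_protein(100, 7, id = "P00001")
  proteome <- dplyr::bind_rows(
    rec,
    protein_record("P00001-2", rec$sequence), # isoform: self by convention
    simulate_proteome(4, c(60, 90), seed = 8)
  )
  rep <- run_design(rec, design_params(15), proteome = proteome)
  expect_true(all(rep$rows$uniqueness_score == 1))
  expect_true(all(lengths(rep$rows$off_target_ids) == 0))
})

test_that("the toy uniqueness example survives the integrated pipeline", {
  target <- protein_record("tgt", "MKNPDGSQRW")
  proteome <- dplyr::bind_rows(target, protein_record("off1", "AAADGSQAAA"))
  rep <- run_design(
    target, design_params(7, epitope_length = 4),
    proteome = proteome
  )
  row <- rep$rows[rep$rows$peptide == "KNPDGSQ", ]
  expect_equal(row$uniqueness_score, 0.75)
  expect_equal(row$off_target_ids[[1]], "off1")
})

test_that("normalized heat-map columns span [0, 1] and attain 1 at the max", {
  rec <- simulate_protein(120, 19, id = "T1")
  orth <- simulate_ortholog(rec, 0.2, seed = 20, id = "O1")
  rep <- run_design(
    rec, design_params(15),
    proteome = dplyr::bind_rows(
      rec,
      # a diverged paralog-like off-target so uniqueness varies along the protein
      simulate_ortholog(rec, 0.15, seed = 22, id = "PARA1"),
      simulate_proteome(3, c(60, 80), seed = 21)
    ),
    orthologs = list(mouse = orth)
  )
  raw_cols <- c(
    ig_score_norm = "ig_score", uniqueness_norm = "uniqueness_score",
    conservation_norm = "conservation_overall"
  )
  for (col in names(raw_cols)) {
    v <- rep$rows[[col]]
    raw <- rep$rows[[raw_cols[[col]]]]
    expect_true(all(v >= 0 & v <= 1))
    if (max(raw) > min(raw)) {
      expect_equal(max(v), 1) # brightest tile sits at the track maximum
      expect_equal(which.max(v), which.max(raw))
    } else {
      expect_true(all(v == 0)) # constant tracks render dark
    }
  }
  # this fixture is built to vary on every track
  expect_gt(max(rep$rows$uniqueness_score), min(rep$rows$uniqueness_score))
  expect_gt(max(rep$rows$conservation_overall), min(rep$rows$conservation_overall))
  expect_equal(
    rep$normalization$track,
    c("ig_score", "uniqueness_score", "conservation_overall")
  )
  expect_equal(
    rep$normalization$max[1], max(rep$rows$ig_score)
  )
})

test_that("TSV output follows the documented format contract", {
  rec <- simulate_protein(60, 9)
  rep <- run_design(rec, design_params(12))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(rep, path)
  lines <- readLines(path)
  expect_length(lines, 1 + (60 - 12 + 1))

  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  # constant column count across all rows
  expect_true(all(lengths(cells) == length(header)))

  tab <- utils::read.delim(path,
    colClasses = "character",
    na.strings = character(0)
  )
  # floats carry 3 decimals; absent tracks are the NA sentinel
  expect_match(tab$ig_score[1], "^\\d+\\.\\d{3}$")
  expect_true(all(tab$uniqueness_score == "NA"))
  # an empty off-target set is an empty cell, not "NA"
  expect_true(all(tab$off_target_ids == ""))
})

test_that("identical inputs produce byte-identical TSV output", {
  make <- function() {
    rec <- simulate_protein(90, 11, id = "T1")
    orth <- simulate_ortholog(rec, 0.1, seed = 12, id = "O1")
    rep <- run_design(
      rec, design_params(15),
      proteome = dplyr::bind_rows(rec, simulate_proteome(3, c(50, 70), seed = 13)),
      orthologs = list(rat = orth)
    )
    path <- tempfile(fileext = ".tsv")
    write_report_tsv(rep, path)
    path
  }
  p1 <- make()
  p2 <- make()
  expect_identical(
    readBin(p1, "raw", file.size(p1)),
    readBin(p2, "raw", file.size(p2))
  )
  file.remove(p1, p2)
})

test_that("JSON output round-trips every row value and the params block", {
  rec <- simulate_protein(50, 15, id = "T9")
  rep <- run_design(
    rec, design_params(10, epitope_length = 5),
    proteome = dplyr::bind_rows(rec, simulate_proteome(2, c(40, 60), seed = 16))
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  back <- jsonlite::fromJSON(path)

  expect_equal(back$schema_version, "1.0")
  expect_equal(back$protein$id, "T9")
  expect_equal(back$protein$length, 50)
  expect_equal(
    back$params[c(
      "peptide_length", "epitope_length", "tail_length", "tail_bonus",
      "high_ig_threshold"
    )],
    list(
      peptide_length = 10L, epitope_length = 5L, tail_length = 60L,
      tail_bonus = 2, high_ig_threshold = 7
    )
  )
  expect_equal(back$rows$ig_score, rep$rows$ig_score, tolerance = 1e-12)
  expect_equal(back$rows$uniqueness_score, rep$rows$uniqueness_score)
  expect_equal(back$rows$start, rep$rows$start)
})

test_that("PTM and transmembrane exclusion switches drop flagged windows", {
  rec <- simulate_protein(100, 25)
  ft <- feature_table(c("MOD_RES", "TRANSMEM"), c(30, 60), c(30, 75))
  full <- run_design(rec, design_params(15), features = ft)
  expect_equal(nrow(full$rows), 86)
  no_ptm <- run_design(rec, design_params(15), features = ft, exclude_ptm = TRUE)
  expect_false(any(no_ptm$rows$ptm_overlap))
  expect_equal(
    nrow(no_ptm$rows),
    sum(!full$rows$ptm_overlap)
  )
  no_tm <- run_design(rec, design_params(15),
    features = ft,
    exclude_transmem = TRUE
  )
  expect_false(any(no_tm$rows$transmem_overlap))
})

test_that("autoplot returns a track-aligned ggplot", {
  rep <- run_design(simulate_protein(60, 29), design_params(12))
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p) # renders without error
  expect_gt(length(built$data), 0)
})

test_that("the CLI runs end-to-end and reports errors with exit code 2", {
  rec <- simulate_protein(80, 33, id = "T1")
  target_fa <- tmp_fasta(rec)
  proteome_fa <- tmp_fasta(dplyr::bind_rows(
    rec, simulate_proteome(3, c(50, 70), seed = 34)
  ))
  mouse_fa <- tmp_fasta(simulate_ortholog(rec, 0.1, seed = 35, id = "M1"))
  rat_fa <- tmp_fasta(simulate_ortholog(rec, 0.3, seed = 36, id = "R1"))
  prefix <- file.path(withr::local_tempdir(), "out")

  status <- suppressMessages(cli_main(c(
    "--target", target_fa, "--peptide-length", "15",
    "--proteome", proteome_fa,
    "--ortholog", paste0("mouse=", mouse_fa),
    "--ortholog", paste0("rat=", rat_fa),
    "--out", prefix, "--format", "both", "--top", "3"
  )))
  expect_equal(status, 0L)
  expect_true(file.exists(paste0(prefix, ".tsv")))
  expect_true(file.exists(paste0(prefix, ".json")))
  tab <- utils::read.delim(paste0(prefix, ".tsv"))
  expect_equal(nrow(tab), 80 - 15 + 1)
  expect_true(all(c("conservation_mouse", "conservation_rat") %in% names(tab)))

  # peptide length beyond the sequence: exit 2, message names both numbers
  expect_message(
    status <- cli_main(c(
      "--target", target_fa, "--peptide-length", "90", "--out", prefix
    )),
    "90.*80"
  )
  expect_equal(status, 2L)

  expect_message(
    status <- cli_main(c("--peptide-length", "10")),
    "required"
  )
  expect_equal(status, 2L)
})

test_that("CLI config files mirror flags, with flags winning", {
  rec <- simulate_protein(60, 37, id = "C1")
  target_fa <- tmp_fasta(rec)
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "run.cfg")
  writeLines(c(
    paste0("target=", target_fa),
    "peptide-length=10",
    "format=json",
    paste0("out=", file.path(dir, "cfg_out"))
  ), cfg)
  status <- suppressMessages(cli_main(c(
    "--config", cfg, "--peptide-length", "12"
  )))
  expect_equal(status, 0L)
  back <- jsonlite::fromJSON(file.path(dir, "cfg_out.json"))
  expect_equal(back$params$peptide_length, 12L) # flag beat the config
})
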