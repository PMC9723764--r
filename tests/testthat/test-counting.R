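test_that("exact reads are assigned with zero mismatches", {
  pan <- generate_panel(10, seed = 1)
  set.seed(1)
  reads <- vapply(pan$barcode_seq, with_prefix, "", USE.NAMES = FALSE)
  res <- match_read(reads, pan)
  expect_true(all(res$status == "assigned"))
  expect_equal(res$lectin_name, pan$lectin_name)
  expect_true(all(res$flank_mismatches == 0L))
  expect_true(all(res$middle_mismatches == 0L))
})

test_that("the mismatch budgets bound assignment exactly", {
  pan <- generate_panel(10, seed = 2)
  lay <- pan$layout
  set.seed(7)
  for (i in c(1, 5, 10)) {
    bc <- pan$barcode_seq[i]
    # at the budget: 2 flank + 1 middle -> assigned to the same lectin
    r_at <- with_prefix(mutate_barcode(bc, lay, 2, 1))
    at <- match_read(r_at, pan)
    expect_equal(as.character(at$status), "assigned")
    expect_equal(at$lectin_name, pan$lectin_name[i])
    expect_equal(at$flank_mismatches, 2L)
    expect_equal(at$middle_mismatches, 1L)
    # one over on either region -> unassigned
    expect_equal(
      as.character(match_read(with_prefix(mutate_barcode(bc, lay, 3, 0)),
                              pan)$status),
      "unassigned")
    expect_equal(
      as.character(match_read(with_prefix(mutate_barcode(bc, lay, 0, 2)),
                              pan)$status),
      "unassigned")
  }
})

test_that("ties within tolerance are ambiguous; N counts as mismatch", {
  lay <- region_layout(12, flank_spans = list(c(0, 4), c(8, 12)),
                       middle_span = c(4, 8))
  # two barcodes differing at two middle positions
  a <- "AAAAAAAAAAAA"
  b <- "AAAACCAAAAAA"
  pan <- lectin_panel(c("A", "B"), c(a, b), layout = lay, prefix_trim = 3)
  # read one middle mismatch from each: equal total -> ambiguous
  read <- paste0("GGG", "AAAACAAAAAAA")
  expect_equal(as.character(match_read(read, pan)$status), "ambiguous")
  # minimal-total-mismatch tie rule: closer candidate wins when totals differ
  read2 <- paste0("GGG", a)
  expect_equal(match_read(read2, pan)$lectin_name, "A")
  # N in the middle region consumes the budget
  readN <- paste0("GGG", "AAAANNAAAAAA")
  expect_equal(as.character(match_read(readN, pan)$status), "unassigned")
  readN1 <- paste0("GGG", "AAAANAAAAAAA")
  gotN <- match_read(readN1, pan)
  expect_equal(gotN$lectin_name, "A")
  expect_equal(gotN$middle_mismatches, 1L)
  # too-short reads are flagged, not matched
  expect_equal(as.character(match_read("ACGT", pan)$status), "too_short")
})

test_that("match_read agrees with the brute-force oracle on random input", {
  set.seed(99)
  n_per_panel <- 250L
  for (panel_seed in 1:4) {
    pan <- generate_panel(8, seed = panel_seed, min_separation = 3)
    lay <- pan$layout
    reads <- character(n_per_panel)
    for (k in seq_len(n_per_panel)) {
      kind <- sample(c("random", "near", "exact", "short"), 1,
                     prob = c(0.3, 0.5, 0.1, 0.1))
      reads[k] <- switch(kind,
        random = random_dna(1, 25),
        near = with_prefix(mutate_barcode(
          pan$barcode_seq[sample.int(8, 1)], lay,
          sample(0:3, 1), sample(0:2, 1))),
        exact = with_prefix(pan$barcode_seq[sample.int(8, 1)]),
        short = random_dna(1, sample(0:24, 1)))
    }
    got <- match_read(reads, pan)
    for (k in seq_len(n_per_panel)) {
      want <- oracle_match(reads[k], pan)
      expect_equal(as.character(got$status[k]), want$status)
      expect_equal(got$lectin_name[k], want$lectin_name)
      expect_equal(got$flank_mismatches[k], want$flank_mismatches)
      expect_equal(got$middle_mismatches[k], want$middle_mismatches)
    }
  }
})

test_that("count_sample reproduces simulation truth at zero noise", {
  pan <- generate_panel(12, seed = 6)
  des <- group_design(pan, groups = c(g1 = 1, g2 = 1))
  sim <- simulate_reads(pan, des, withr::local_tempdir(), depth = 2000,
                        error_rate = 0, contaminant_fraction = 0, seed = 17)
  for (sid in names(sim$fastq)) {
    row <- count_sample(sim$fastq[[sid]], pan)
    expect_equal(row$counts, sim$truth$counts[sid, ])
    expect_equal(unname(row$tallies["n_assigned"]), 2000L)
    expect_equal(unname(row$tallies["n_unassigned"]), 0L)
  }
})

test_that("random reads against a well-separated panel go unassigned", {
  pan <- generate_panel(10, seed = 14)
  set.seed(5)
  f <- write_fastq_records(withr::local_tempfile(fileext = ".fastq"),
                           random_dna(100, 25))
  row <- count_sample(f, pan)
  # tolerance volume is tiny relative to 4^22 sequences
  expect_gte(unname(row$tallies["n_unassigned"]), 95L)
  expect_equal(unname(row$tallies["n_reads_total"]), 100L)
})

test_that("count_sample streams gzipped input identically", {
  pan <- generate_panel(6, seed = 3)
  set.seed(2)
  seqs <- c(vapply(pan$barcode_seq, with_prefix, "", USE.NAMES = FALSE),
            random_dna(20, 25))
  f <- write_fastq_records(withr::local_tempfile(fileext = ".fastq"), seqs)
  fgz <- withr::local_tempfile(fileext = ".fastq.gz")
  con <- gzfile(fgz, "wb"); writeLines(readLines(f), con); close(con)
  expect_identical(count_sample(f, pan), count_sample(fgz, pan))
})

test_that("empty and malformed FASTQ inputs are handled", {
  pan <- generate_panel(4, seed = 1)
  f <- withr::local_tempfile(fileext = ".fastq")
  file.create(f)
  expect_warning(row <- count_sample(f, pan), "empty")
  expect_true(all(row$counts == 0L))
  expect_equal(unname(row$tallies["n_reads_total"]), 0L)
  writeLines(c("@r1", "ACGT", "+", "IIII", "not-a-header", "ACGT", "+",
               "IIII"), f)
  expect_error(count_sample(f, pan), "record 2")
  writeLines(c("@r1", "ACGT", "+"), f)
  expect_error(count_sample(f, pan), "truncated")
})

test_that("widening a budget never shrinks the matched read set", {
  pan <- generate_panel(8, seed = 10, min_separation = 4)
  set.seed(31)
  reads <- c(random_dna(150, 25),
             vapply(seq_len(150), function(i) {
               with_prefix(mutate_barcode(
                 pan$barcode_seq[sample.int(8, 1)], pan$layout,
                 sample(0:4, 1), sample(0:2, 1)))
             }, ""))
  matched <- function(tol) {
    st <- match_read(reads, pan, tol)$status
    sum(st %in% c("assigned", "ambiguous"))
  }
  base <- matched(match_tolerance(2, 1))
  expect_gte(matched(match_tolerance(3, 1)), base)
  expect_gte(matched(match_tolerance(2, 2)), base)
  expect_gte(matched(match_tolerance(4, 3)), matched(match_tolerance(3, 2)))
})

test_that("count_experiment assembles rows in sheet order with tallies", {
  pan <- generate_panel(10, seed = 12)
  des <- group_design(pan, groups = c(pups = 2, adult = 2))
  sim <- simulate_reads(pan, des, withr::local_tempdir(), depth = 800,
                        error_rate = 0.01, contaminant_fraction = 0.05,
                        seed = 23)
  cnt <- count_experiment(sim$sample_sheet, pan)
  expect_equal(rownames(cnt$counts),
               c("pups_1", "pups_2", "adult_1", "adult_2"))
  expect_equal(unname(rowSums(cnt$counts)), cnt$tallies$n_assigned)
  expect_equal(cnt$tallies$n_assigned + cnt$tallies$n_ambiguous +
                 cnt$tallies$n_unassigned + cnt$tallies$n_too_short,
               cnt$tallies$n_reads_total)
  expect_true(all(cnt$tallies$n_reads_total == 800L))

  # permuting the sheet permutes rows identically
  sheet <- read_sample_sheet(sim$sample_sheet)
  perm <- c(3, 1, 4, 2)
  cnt_perm <- count_experiment(sheet[perm, ], pan)
  expect_equal(cnt_perm$counts, cnt$counts[perm, ])

  # sheet errors are raised before counting starts
  bad <- sheet; bad$sample_id <- rep("dup", 4)
  expect_error(count_experiment(bad, pan), "duplicate sample_id")
  bad2 <- sheet; bad2$fastq_path[2] <- "/nonexistent.fastq"
  expect_error(count_experiment(bad2, pan), "not found")
})

test_that("counts and QC round-trip to disk", {
  pan <- generate_panel(5, seed = 9)
  des <- group_design(pan, groups = c(a = 1, b = 1))
  sim <- simulate_reads(pan, des, withr::local_tempdir(), depth = 300,
                        seed = 4)
  cnt <- count_experiment(sim$sample_sheet, pan)
  ctsv <- withr::local_tempfile(fileext = ".tsv")
  qjson <- withr::local_tempfile(fileext = ".json")
  write_counts(cnt, ctsv, qjson)
  back <- utils::read.delim(ctsv, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), cnt$counts, ignore_attr = TRUE)
  qc <- jsonlite::read_json(qjson, simplifyVector = TRUE)
  expect_equal(qc$n_reads_total, cnt$tallies$n_reads_total)
})
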