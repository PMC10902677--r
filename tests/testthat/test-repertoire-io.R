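test_that("MiXCR clone tables load with correct totals and drop rules", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mixcr_fixture(path, readCount = c(10, 5, 1),
                      nSeqCDR3 = c("TGTGCGAGA", "TGTGCGAAA", "TGTGCGACA"),
                      aaSeqCDR3 = c("CAR", "CAK", "CAT"))
  rep <- read_mixcr_clones(path)
  expect_s3_class(rep, "repertoire")
  expect_equal(nrow(rep), 3)
  expect_equal(total_reads(rep), 16)
  expect_equal(rep$aa_seq, c("CAR", "CAK", "CAT"))

  # a row with an empty nucleotide sequence is dropped and accounted for
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_mixcr_fixture(path2, readCount = c(10, 5, 1),
                      nSeqCDR3 = c("TGTGCGAGA", "", "TGTGCGACA"),
                      aaSeqCDR3 = c("CAR", "CAK", "CAT"))
  rep2 <- suppressMessages(read_mixcr_clones(path2))
  expect_equal(nrow(rep2), 2)
  report <- load_report(rep2)
  expect_equal(report$dropped_empty_seq, 1)
  expect_equal(report$kept + report$dropped_empty_seq, report$input_rows)
})

test_that("missing required MiXCR columns raise format errors naming them", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mixcr_fixture(path, readCount = c(2, 3),
                      nSeqCDR3 = c("TGTGCGAGA", "TGTGCGAAA"),
                      aaSeqCDR3 = c("CAR", "CAK"), drop_cols = "aaSeqCDR3")
  expect_error(read_mixcr_clones(path), "aaSeqCDR3 missing",
               class = "repanner_format_error")
  write_mixcr_fixture(path, readCount = c(2, 3),
                      nSeqCDR3 = c("TGTGCGAGA", "TGTGCGAAA"),
                      aaSeqCDR3 = c("CAR", "CAK"), drop_cols = "readCount")
  expect_error(read_mixcr_clones(path), "clone-count column missing",
               class = "repanner_format_error")
})

test_that("unparseable counts are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cloneId\treadCount\treadFraction\tnSeqCDR3\taaSeqCDR3",
               "1\t10\t0.9\tTGTGCGAGA\tCAR",
               "2\tbogus\t0.1\tTGTGCGAAA\tCAK"), path)
  expect_error(read_mixcr_clones(path), "line 3.*bogus",
               class = "repanner_format_error")
})

test_that("AIRR tables normalize fractions and apply the count fallback", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_airr_fixture(path, junction = c("TGTGCGAGA", "TGTGCGAAA"),
                     junction_aa = c("CAR", "CAK"),
                     duplicate_count = c(3, 1))
  rep <- read_airr(path)
  expect_equal(rep$read_fraction, c(0.75, 0.25))
  expect_equal(sum(rep$read_fraction), 1, tolerance = 1e-9)

  # duplicate_count absent: unit counts, uniform fractions, flagged
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_airr_fixture(path2, junction = c("TGTGCGAGA", "TGTGCGAAA"),
                     junction_aa = c("CAR", "CAK"))
  expect_message(rep2 <- read_airr(path2), "duplicate_count absent")
  expect_equal(rep2$read_count, c(1, 1))
  expect_equal(rep2$read_fraction, c(0.5, 0.5))
  expect_match(paste(load_report(rep2)$notes, collapse = " "),
               "duplicate_count absent")

  # missing junction_aa with region CDR3 is a format error
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_airr_fixture(path3, junction = c("TGTGCGAGA"),
                     junction_aa = c("CAR"), duplicate_count = 2,
                     drop_cols = "junction_aa")
  expect_error(read_airr(path3), "junction_aa missing",
               class = "repanner_format_error")
})

test_that("binding tables parse numerics, keep NA cells, reject duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("aa_seq,antigen_A", "CARGY,0.8", "CAKWY,0.2"), path)
  bt <- read_binding_table(path)
  expect_s3_class(bt, "binding_table")
  expect_equal(nrow(bt), 2)
  expect_equal(bt$antigen_A, c(0.8, 0.2))

  writeLines(c("aa_seq,antigen_A", "CARGY,NA", "CAKWY,0.2"), path)
  bt2 <- read_binding_table(path)
  expect_true(is.na(bt2$antigen_A[1]))
  expect_equal(nrow(bt2), 2)

  writeLines(c("aa_seq,antigen_A", "CARGY,0.8", "CARGY,0.2"), path)
  expect_error(read_binding_table(path), "duplicated sequence key",
               class = "repanner_format_error")
  writeLines(c("aa_seq", "CARGY"), path)
  expect_error(read_binding_table(path), "antigen",
               class = "repanner_format_error")
})

test_that("experiment sets concatenate repertoires and reject name clashes", {
  reps <- lapply(1:3, function(i) {
    make_rep(random_aa(5), counts = 1:5, sample = paste0("r", i))
  })
  set <- build_experiment(reps)
  expect_equal(nrow(set$master), 15)
  expect_equal(names(set$repertoires), c("r1", "r2", "r3"))

  expect_error(build_experiment(list(reps[[1]], reps[[1]])),
               "duplicate sample name")

  single <- build_experiment(reps[1])
  expect_equal(single$master$aa_seq, reps[[1]]$aa_seq)
  expect_equal(single$master$read_count, reps[[1]]$read_count)
})

test_that("master table round-trips exactly, including unicode names", {
  reps <- list(make_rep(random_aa(5), counts = c(3, 9, 2, 7, 5),
                        sample = "round_0"),
               make_rep(random_aa(4), counts = c(11, 1, 2, 3),
                        sample = "runde_å5"))
  set <- build_experiment(reps)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_master_table(set, path)
  back <- read_master_table(path)
  expect_identical(back$sample_name, set$master$sample_name)
  expect_identical(back$clone_id, set$master$clone_id)
  expect_identical(back$aa_seq, set$master$aa_seq)
  expect_equal(back$read_fraction, set$master$read_fraction,
               tolerance = 1e-9)
  expect_true("runde_å5" %in% back$sample_name)

  # rebuild an experiment set from the master table
  set2 <- experiment_from_master(back)
  expect_equal(names(set2$repertoires), names(set$repertoires))
  expect_equal(set2$master$read_count, set$master$read_count)

  # empty set writes a header-only file
  empty <- build_experiment(list())
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_master_table(empty, path2)
  expect_equal(length(readLines(path2)), 1)
})
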