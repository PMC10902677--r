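test_that("simulated rounds are reader-compatible and survive trimming cleanly", {
  dir <- withr::local_tempdir()
  sim <- simulate_panning(n_clones = 120, n_rounds = 2,
                          reads_per_round = 6000, seed = 101,
                          out_dir = dir)
  expect_equal(length(sim$rounds), 3)
  for (f in grep("round_", sim$files, value = TRUE)) {
    rep <- read_mixcr_clones(f)
    expect_s3_class(rep, "repertoire")
    expect_equal(load_report(rep)$dropped_empty_seq, 0)
    res <- apply_default_trimming(rep)
    # in-frame reverse translation: nothing removed for frame or length
    expect_equal(res$report$not_div3, 0)
    expect_equal(res$report$short_nt, 0)
    expect_equal(nchar(rep$nt_seq), 3 * nchar(rep$aa_seq))
  }
  expect_equal(sum(sim$rounds$round_0$readCount), 6000)
  expect_equal(sum(sim$rounds$round_0$readFraction), 1, tolerance = 1e-9)
})

test_that("simulations are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_panning(n_clones = 60, n_rounds = 2, reads_per_round = 2000,
                   seed = 55, plant_neighbor = TRUE, out_dir = d1)
  simulate_panning(n_clones = 60, n_rounds = 2, reads_per_round = 2000,
                   seed = 55, plant_neighbor = TRUE, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # a different seed gives different libraries
  alt <- simulate_panning(n_clones = 60, n_rounds = 2,
                          reads_per_round = 2000, seed = 56)
  base <- simulate_panning(n_clones = 60, n_rounds = 2,
                           reads_per_round = 2000, seed = 55)
  expect_false(identical(alt$truth$aa_seq, base$truth$aa_seq))
})

test_that("neutral selection keeps expected frequencies flat; strong selection sweeps", {
  # neutral limit: no coefficient, frequencies constant in expectation
  neutral_drift <- vapply(1:15, function(i) {
    seed <- 1000 + i
    sim <- simulate_panning(n_clones = 40, n_rounds = 2,
                            reads_per_round = 4000, seed = seed,
                            selection_sd = 0, n_strong = 0)
    top0 <- sim$rounds$round_0$readFraction[1]
    id0 <- sim$rounds$round_0$cloneId[1]
    last <- sim$rounds$round_2
    fin <- last$readFraction[match(id0, last$cloneId)]
    fin - top0
  }, numeric(1))
  expect_lt(abs(mean(neutral_drift)), 0.02)

  # one strongly selected clone: its mean fraction rises every round
  deltas <- sapply(1:20, function(i) {
    sim <- simulate_panning(n_clones = 100, n_rounds = 3,
                            reads_per_round = 5000, seed = 7000 + i,
                            selection_sd = 0.3, n_strong = 1,
                            strong_coef = 3)
    strong_id <- sim$truth$clone_id[which.max(sim$truth$coefficient)]
    vapply(sim$rounds, function(tab) {
      f <- tab$readFraction[match(strong_id, tab$cloneId)]
      if (is.na(f)) 0 else f
    }, numeric(1))
  })
  mean_frac <- rowMeans(deltas)
  expect_true(all(diff(mean_frac) > 0))
})

test_that("binding labels follow the coefficients and respect the labeled fraction", {
  sim <- simulate_panning(n_clones = 80, n_rounds = 1,
                          reads_per_round = 2000, seed = 77)
  bt <- simulate_binding(sim$truth, fraction_labeled = 0.5, noise_sd = 0,
                         seed = 78)
  expect_s3_class(bt, "binding_table")
  expect_equal(nrow(bt), 40)
  # noise-free binding preserves the coefficient rank order
  coefs <- sim$truth$coefficient[match(bt$aa_seq, sim$truth$aa_seq)]
  expect_equal(order(bt$antigen_A), order(coefs))
  # the top-coefficient clone is always assayed
  top_aa <- sim$truth$aa_seq[which.max(sim$truth$coefficient)]
  expect_true(top_aa %in% bt$aa_seq)

  none <- simulate_binding(sim$truth, fraction_labeled = 0, seed = 79,
                           out_path = file.path(withr::local_tempdir(),
                                                "b.csv"))
  expect_equal(nrow(none), 0)

  # round-trip through the CSV reader
  path <- withr::local_tempfile(fileext = ".csv")
  simulate_binding(sim$truth, fraction_labeled = 0.25, seed = 80,
                   out_path = path)
  back <- read_binding_table(path)
  expect_equal(nrow(back), 20)
})

test_that("planted 1-edit neighbors of the top binder are recovered end to end", {
  hits <- vapply(1:5, function(i) {
    sim <- simulate_panning(n_clones = 100, n_rounds = 2,
                            reads_per_round = 5000, seed = 300 + i,
                            plant_neighbor = TRUE)
    bt <- simulate_binding(sim$truth, fraction_labeled = 0.4,
                           noise_sd = 0.01, seed = 400 + i)
    final <- sim$rounds[[length(sim$rounds)]]
    cand <- nearest_labeled_neighbors(final$aaSeqCDR3, bt, ld_cutoff = 1,
                                      min_binding = 0.5)
    planted <- sim$truth$aa_seq[sim$truth$planted]
    planted %in% cand$sequence
  }, logical(1))
  expect_true(all(hits))
})

test_that("diversity falls and adjacent rounds stay most similar under selection", {
  res <- lapply(1:20, function(i) {
    sim <- simulate_panning(n_clones = 100, n_rounds = 3,
                            reads_per_round = 5000, seed = 9000 + i,
                            selection_sd = 0.5, n_strong = 3,
                            strong_coef = 3)
    reps <- lapply(names(sim$rounds), function(nm) {
      tab <- sim$rounds[[nm]]
      repertoire(tab$cloneId, tab$readCount, tab$nSeqCDR3, tab$aaSeqCDR3,
                 sample_name = nm)
    })
    shannon <- vapply(reps, shannon_index, numeric(1))
    adjacent <- mean(c(morisita_horn(reps[[1]], reps[[2]]),
                       morisita_horn(reps[[2]], reps[[3]]),
                       morisita_horn(reps[[3]], reps[[4]])))
    ends <- morisita_horn(reps[[1]], reps[[4]])
    list(dH = diff(shannon), adjacent = adjacent, ends = ends)
  })
  mean_dH <- rowMeans(sapply(res, `[[`, "dH"))
  expect_true(all(mean_dH < 0))
  expect_gt(mean(sapply(res, `[[`, "adjacent")),
            mean(sapply(res, `[[`, "ends")))
})
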