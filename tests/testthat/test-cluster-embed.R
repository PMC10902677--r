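test_that("edit distances reproduce worked examples and base cases", {
  expect_equal(levenshtein("CAT", "BAD"), 2L)
  expect_equal(levenshtein("CAT", "CATS"), 1L)
  expect_equal(levenshtein("kitten", "sitting"), 3L)
  expect_equal(levenshtein("CARGYW", "CARGYW"), 0L)
  expect_equal(levenshtein("CARGYW", ""), 6L)
  expect_equal(levenshtein("", ""), 0L)
  expect_error(levenshtein(NA, "A"), class = "repanner_parameter_error")
})

test_that("the DP agrees with a plain-R recursion and with utils::adist", {
  withr::with_seed(41, {
    a <- random_aa(40, c(0, 5))
    b <- random_aa(40, c(0, 5))
    expect_equal(levenshtein(a, b),
                 mapply(ld_rec_r, a, b, USE.NAMES = FALSE))
    a2 <- random_aa(30, c(5, 15))
    b2 <- random_aa(30, c(5, 15))
    expect_equal(levenshtein(a2, b2),
                 as.integer(diag(utils::adist(a2, b2))))
  })
})

test_that("edit distance satisfies the metric axioms on random sequences", {
  withr::with_seed(42, {
    s <- random_aa(25, c(4, 12))
    d <- unclass(ld_matrix(s, top_n = Inf))
    expect_equal(unname(diag(d)), rep(0L, 25))
    expect_equal(d, t(d))
    for (k in 1:200) {
      ijk <- sample(25, 3)
      expect_lte(d[ijk[1], ijk[3]], d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]])
    }
  })
})

test_that("distance matrices apply the top-N-by-count cap with lexicographic ties", {
  expect_error(ld_matrix("CAT"), "at least two",
               class = "repanner_parameter_error")
  mat <- ld_matrix(c("CAT", "BAD", "CATS"))
  expect_equal(mat["CAT", "BAD"], 2L)
  expect_equal(mat["CAT", "CATS"], 1L)
  expect_equal(mat["BAD", "CATS"], 3L)

  dup <- ld_matrix(c("CAT", "CAT", "DOG"))
  expect_equal(dup[1, 2], 0L)

  rep <- make_rep(c("AAAA", "CCCC", "DDDD", "EEEE"),
                  counts = c(5, 9, 2, 5))
  capped <- suppressMessages(ld_matrix(rep, top_n = 2))
  # CCCC has the highest count; the 5/5 tie breaks lexicographically to AAAA
  expect_setequal(rownames(capped), c("CCCC", "AAAA"))
})

test_that("dendrograms merge at hand-computed UPGMA heights", {
  two <- ld_matrix(c("CAT", "BAD"))
  tree <- ld_dendrogram(two)
  expect_equal(tree$height, 2)

  # collinear triple: d(a,b)=1, d(b,c)=1, d(a,c)=2 -> merges at 1 then 1.5
  tri <- ld_matrix(c("CAT", "CATS", "CATSS"))
  tree3 <- ld_dendrogram(tri, linkage = "average")
  expect_equal(tree3$height, c(1, 1.5))

  dup <- ld_matrix(c("CAT", "CAT", "CATSS"))
  expect_equal(ld_dendrogram(dup)$height[1], 0)

  nwk <- dendrogram_newick(tree3)
  expect_match(nwk, "^\\(")
  expect_true(all(vapply(c("CAT", "CATS", "CATSS"), grepl, logical(1), nwk,
                         fixed = TRUE)))
})

test_that("cutoff graphs connect the right pairs and coarsen monotonically", {
  g <- ld_graph(c("CAT", "CATS", "DOG"), cutoff = 1)
  expect_equal(nrow(graph_edges(g)), 1)
  expect_setequal(unlist(graph_edges(g)[1, c("from", "to")]),
                  c("CAT", "CATS"))
  expect_equal(max(graph_nodes(g)$component), 2)

  # cutoff >= max distance: complete graph, one component
  seqs <- c("CAT", "CATS", "DOG")
  gmax <- ld_graph(seqs, cutoff = 10)
  expect_equal(nrow(graph_edges(gmax)), 3)
  expect_equal(max(graph_nodes(gmax)$component), 1)

  far <- c("AAAAAAAA", "CCCCCCCC", "DDDDDDDD")
  g0 <- ld_graph(far, cutoff = 1)
  expect_equal(nrow(graph_edges(g0)), 0)
  expect_equal(max(graph_nodes(g0)$component), 3)

  expect_error(ld_graph(seqs, cutoff = 0), class = "repanner_parameter_error")

  # components at cutoff k are nested within components at k+1
  withr::with_seed(43, s <- random_aa(30, c(4, 8)))
  for (k in 1:3) {
    ck <- graph_nodes(ld_graph(s, cutoff = k))$component
    ck1 <- graph_nodes(ld_graph(s, cutoff = k + 1))$component
    # same component at k implies same component at k+1
    for (comp in unique(ck)) {
      members <- which(ck == comp)
      expect_equal(length(unique(ck1[members])), 1)
    }
  }
})

test_that("SGT features match direct evaluation of the transform", {
  e <- sgt_embed("AB", alphabet = c("A", "B"))
  expect_equal(e["AB", "A>B"], exp(-1), tolerance = 1e-12)
  expect_equal(sum(e), exp(-1), tolerance = 1e-12)  # all other features 0

  # single-symbol sequence: only the (A,A) feature is populated
  e2 <- sgt_embed("AAAA", alphabet = c("A", "B"))
  nonzero <- colnames(e2)[e2["AAAA", ] > 0]
  expect_equal(nonzero, "A>A")
  expect_equal(e2["AAAA", "A>A"],
               (exp(-1) * 3 + exp(-2) * 2 + exp(-3)) / 4, tolerance = 1e-12)

  # identical sequences embed identically; feature is 0 iff v never follows u
  e3 <- sgt_embed(c("CARGYW", "CARGYW", "WYGRAC"))
  expect_equal(e3[1, ], e3[2, ])
  expect_gt(e3[1, "C>A"], 0)
  expect_equal(e3[1, "A>C"], 0)

  # kappa halves/doubles: a single adjacent pair never gains weight
  k1 <- sgt_embed("AB", alphabet = c("A", "B"), kappa = 1)["AB", "A>B"]
  k2 <- sgt_embed("AB", alphabet = c("A", "B"), kappa = 2)["AB", "A>B"]
  expect_lte(k2, k1 + 1e-12)

  expect_error(sgt_embed("AB", kappa = 0), class = "repanner_parameter_error")
  expect_warning(sgt_embed("AB*C"), "dropped")
})

test_that("2-D projection is deterministic and keeps duplicates together", {
  # clonal families: a few parents plus single-substitution variants, with
  # one exact duplicate pair appended
  withr::with_seed(44, {
    mut <- function(s) {
      ch <- strsplit(s, "")[[1]]
      p <- sample(length(ch), 1)
      ch[p] <- sample(aa_alphabet(), 1)
      paste(ch, collapse = "")
    }
    parents <- random_aa(8, c(12, 12))
    seqs <- unlist(lapply(parents, function(p) c(p, replicate(4, mut(p)))))
    seqs <- c(seqs, seqs[1])
  })
  vecs <- sgt_embed(seqs)
  c1 <- suppressWarnings(reduce_to_2d(vecs, perplexity = 8, seed = 9))
  c2 <- suppressWarnings(reduce_to_2d(vecs, perplexity = 8, seed = 9))
  expect_identical(c1, c2)
  expect_equal(dim(c1), c(41, 2))

  # the duplicated input vectors end up nearly coincident
  dmat <- as.matrix(stats::dist(c1))
  dup_d <- dmat[1, 41]
  expect_lte(dup_d, stats::quantile(dmat[upper.tri(dmat)], 0.01))

  expect_error(reduce_to_2d(vecs[1:3, ]), class = "repanner_parameter_error")
  expect_warning(reduce_to_2d(vecs[1:10, ], perplexity = 30, seed = 1),
                 "perplexity")
})

test_that("binding overlays annotate points and report unmatched rows", {
  pts <- tibble::tibble(aa_seq = c("CARGYW", "CAKWYD", "CANNNN"),
                        x = 1:3, y = 3:1)
  bt <- structure(tibble::tibble(aa_seq = c("CARGYW", "ZZZZZZ"),
                                 antigen_A = c(0.9, 0.4)),
                  class = c("binding_table", class(tibble::tibble())))
  out <- suppressMessages(overlay_binding(pts, bt))
  expect_equal(out$binding, c(0.9, NA, NA))
  expect_equal(attr(out, "n_unmatched"), 1)
  expect_error(overlay_binding(pts, bt, antigen = "nope"),
               "unknown antigen", class = "repanner_parameter_error")

  # matrix input with sequence rownames is accepted
  m <- matrix(0, 2, 2, dimnames = list(c("CARGYW", "CAKWYD"), c("x", "y")))
  out2 <- suppressMessages(overlay_binding(m, bt))
  expect_equal(out2$binding, c(0.9, NA))
})

test_that("candidate nomination finds unlabeled neighbors of strong binders", {
  bt <- structure(tibble::tibble(aa_seq = c("CAT", "DOG"),
                                 antigen_A = c(0.9, 0.3)),
                  class = c("binding_table", class(tibble::tibble())))
  cand <- nearest_labeled_neighbors(c("CAT", "CATS", "WXYZ"), bt,
                                    ld_cutoff = 1, min_binding = 0.5)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$sequence, "CATS")
  expect_equal(cand$neighbor, "CAT")
  expect_equal(cand$ld, 1L)
  expect_equal(cand$neighbor_binding, 0.9)

  # cutoff 0 admits only exact duplicates of labeled sequences
  cand0 <- nearest_labeled_neighbors(c("CATS", "WXYZ"), bt, ld_cutoff = 0,
                                     min_binding = 0.5)
  expect_equal(nrow(cand0), 0)

  # everything labeled: empty result, not an error
  call <- nearest_labeled_neighbors(c("CAT", "DOG"), bt, ld_cutoff = 2,
                                    min_binding = 0.2)
  expect_equal(nrow(call), 0)

  expect_error(nearest_labeled_neighbors("CATS", bt, min_binding = 0.99),
               class = "repanner_parameter_error")

  # sorted by ascending distance, then descending neighbor binding
  bt2 <- structure(tibble::tibble(aa_seq = c("AAAA", "CCCC"),
                                  antigen_A = c(0.6, 0.9)),
                   class = c("binding_table", class(tibble::tibble())))
  cand2 <- nearest_labeled_neighbors(c("AAAC", "CCCC", "AACC"), bt2,
                                     ld_cutoff = 2, min_binding = 0.5)
  expect_equal(cand2$sequence, c("AAAC", "AACC"))
  expect_equal(cand2$ld, c(1L, 2L))
})
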