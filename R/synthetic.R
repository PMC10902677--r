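# inverse genetic code: standard codons per amino acid (stop codons
# excluded), used for reverse translation with random synonymous codons
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))[aa_alphabet()]
}

random_aa_seqs <- function(n, length_range) {
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
  }, character(1))
}

reverse_translate <- function(aa_seqs, codon_table = codons_by_aa()) {
  vapply(aa_seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    paste(vapply(chars, function(a) {
      cods <- codon_table[[a]]
      cods[sample.int(length(cods), 1)]
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# one substitution at a random position, guaranteed to differ from the
# parent and from every sequence in `avoid`
mutate_one_position <- function(aa, avoid = character()) {
  chars <- strsplit(aa, "")[[1]]
  repeat {
    p <- sample.int(length(chars), 1)
    alt <- sample(setdiff(aa_alphabet(), chars[p]), 1)
    out <- chars
    out[p] <- alt
    out <- paste(out, collapse = "")
    if (!out %in% avoid) return(out)
  }
}

#' Simulate a phage-display panning campaign
#'
#' Generates clonotype tables emulating the selection dynamics of
#' biopanning: round 0 is a diverse naive library whose clone abundances
#' are drawn from a flat Dirichlet prior and sampled multinomially at the
#' sequencing depth; in each subsequent round clone frequencies are
#' multiplied by `exp(selection coefficient)` and resampled multinomially,
#' so strongly selected clones sweep the population while the library
#' collapses toward a few enriched binders. Amino-acid CDR3 sequences are
#' distinct, drawn uniformly over the 20 standard residues with lengths
#' uniform in `cdr3_length_range`, and reverse-translated with random
#' synonymous codons, so every generated record is in frame and at least
#' 18 nt long under the default length range.
#'
#' Selection coefficients are Normal(0, `selection_sd`) with `n_strong`
#' randomly chosen clones spiked to `strong_coef`, producing both neutral
#' and enriched regimes. With `plant_neighbor = TRUE` an extra clone one
#' substitution away from the strongest binder is added to the final round
#' at a small fixed frequency and flagged in the truth table; it is skipped
#' by [simulate_binding()], which makes it a ground-truth target for
#' [nearest_labeled_neighbors()].
#'
#' @param n_clones Clones in the naive library (default 5000).
#' @param n_rounds Number of selection rounds after round 0 (default 3;
#'   rounds 0..`n_rounds` are produced).
#' @param reads_per_round Sequencing depth per round (default 100000).
#' @param cdr3_length_range Amino-acid CDR3 length range, within
#'   `[6, 30]` (default `c(8, 20)`).
#' @param dirichlet_conc Dirichlet concentration for round-0 abundances
#'   (default 1, flat).
#' @param selection_sd Standard deviation of the per-clone selection
#'   coefficients (default 0.5).
#' @param n_strong Number of clones spiked to `strong_coef` (default 5).
#' @param strong_coef Selection coefficient of the spiked clones
#'   (default 3).
#' @param plant_neighbor Add an unlabeled 1-edit neighbor of the top
#'   binder to the final round (default `FALSE`).
#' @param seed Integer seed; the whole simulation is deterministic given
#'   it.
#' @param out_dir Optional directory; when given, each round is written as
#'   `round_<t>.tsv` in MiXCR-export dialect plus `truth.tsv`.
#' @return A list: `rounds` (named list of round tibbles with columns
#'   `cloneId`, `readCount`, `readFraction`, `nSeqCDR3`, `aaSeqCDR3`),
#'   `truth` (tibble `clone_id`, `aa_seq`, `nt_seq`, `coefficient`,
#'   `planted`), `files` (paths written, or `NULL`), and `params`.
#' @export
simulate_panning <- function(n_clones = 5000, n_rounds = 3,
                             reads_per_round = 100000,
                             cdr3_length_range = c(8, 20),
                             dirichlet_conc = 1, selection_sd = 0.5,
                             n_strong = 5, strong_coef = 3,
                             plant_neighbor = FALSE, seed,
                             out_dir = NULL) {
  if (missing(seed)) param_error("an explicit seed is required")
  if (n_clones < 1 || n_rounds < 1 || reads_per_round < 1) {
    param_error("n_clones, n_rounds and reads_per_round must be positive")
  }
  if (cdr3_length_range[1] < 6 || cdr3_length_range[2] > 30 ||
      cdr3_length_range[1] > cdr3_length_range[2]) {
    param_error("cdr3_length_range must be increasing and within [6, 30]")
  }
  if (n_strong > n_clones) param_error("n_strong cannot exceed n_clones")

  sim <- withr::with_seed(seed, {
    aa <- unique(random_aa_seqs(n_clones, cdr3_length_range))
    while (length(aa) < n_clones) {
      aa <- unique(c(aa, random_aa_seqs(n_clones - length(aa),
                                        cdr3_length_range)))
    }
    nt <- reverse_translate(aa)
    coef <- rnorm(n_clones, 0, selection_sd)
    if (n_strong > 0) coef[sample.int(n_clones, n_strong)] <- strong_coef
    p <- rgamma(n_clones, shape = dirichlet_conc)
    p <- p / sum(p)
    counts <- list(drop(rmultinom(1, reads_per_round, p)))
    freq <- p
    for (t in seq_len(n_rounds)) {
      freq <- freq * exp(coef)
      freq <- freq / sum(freq)
      counts[[t + 1]] <- drop(rmultinom(1, reads_per_round, freq))
    }
    planted <- NULL
    if (plant_neighbor) {
      parent <- which.max(coef)
      planted_aa <- mutate_one_position(aa[parent], avoid = aa)
      planted <- list(aa = planted_aa, nt = reverse_translate(planted_aa),
                      parent = parent,
                      count = max(3, round(0.002 * reads_per_round)))
    }
    list(aa = aa, nt = nt, coef = coef, counts = counts, planted = planted)
  })

  clone_ids <- sprintf("C%0*d", nchar(n_clones), seq_len(n_clones))
  truth <- tibble::tibble(clone_id = clone_ids, aa_seq = sim$aa,
                          nt_seq = sim$nt, coefficient = sim$coef,
                          planted = FALSE)
  rounds <- vector("list", n_rounds + 1)
  names(rounds) <- paste0("round_", 0:n_rounds)
  for (t in 0:n_rounds) {
    cnt <- sim$counts[[t + 1]]
    keep <- cnt > 0
    tab <- tibble::tibble(cloneId = clone_ids[keep], readCount = cnt[keep],
                          nSeqCDR3 = sim$nt[keep], aaSeqCDR3 = sim$aa[keep])
    if (t == n_rounds && !is.null(sim$planted)) {
      tab <- dplyr::bind_rows(tab, tibble::tibble(
        cloneId = "Cplanted", readCount = sim$planted$count,
        nSeqCDR3 = sim$planted$nt, aaSeqCDR3 = sim$planted$aa))
    }
    tab$readFraction <- tab$readCount / sum(tab$readCount)
    tab <- tab[order(-tab$readCount, tab$cloneId),
               c("cloneId", "readCount", "readFraction",
                 "nSeqCDR3", "aaSeqCDR3")]
    rounds[[t + 1]] <- tab
  }
  if (!is.null(sim$planted)) {
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      clone_id = "Cplanted", aa_seq = sim$planted$aa,
      nt_seq = sim$planted$nt,
      coefficient = sim$coef[sim$planted$parent], planted = TRUE))
  }

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    for (nm in names(rounds)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      readr::write_tsv(rounds[[nm]], f, progress = FALSE)
      files <- c(files, f)
    }
    truth_file <- file.path(out_dir, "truth.tsv")
    readr::write_tsv(truth, truth_file, progress = FALSE)
    files <- c(files, truth_file)
  }

  list(rounds = rounds, truth = truth, files = files,
       params = list(n_clones = n_clones, n_rounds = n_rounds,
                     reads_per_round = reads_per_round,
                     cdr3_length_range = cdr3_length_range,
                     dirichlet_conc = dirichlet_conc,
                     selection_sd = selection_sd, n_strong = n_strong,
                     strong_coef = strong_coef,
                     plant_neighbor = plant_neighbor, seed = seed))
}

#' Simulate immunoassay binding labels
#'
#' Assigns ground-truth binding values to a labeled subset of simulated
#' clones: the value is the logistic transform of the clone's selection
#' coefficient plus Gaussian noise, so with zero noise the binding rank
#' order equals the selection-coefficient rank order. Only
#' `fraction_labeled` of the eligible (non-planted) clones receive labels;
#' the top-coefficient clone is always among them, mirroring campaigns
#' where the most enriched clone is invariably assayed. Planted neighbor
#' clones are never labeled.
#'
#' @param truth Truth tibble from [simulate_panning()].
#' @param fraction_labeled Fraction of eligible clones labeled, in
#'   `[0, 1]` (default 0.5).
#' @param noise_sd Gaussian noise on the binding value (default 0.05).
#' @param antigen Name of the antigen column (default `"antigen_A"`).
#' @param seed Integer seed.
#' @param out_path Optional CSV path compatible with
#'   [read_binding_table()].
#' @return A `binding_table` (tibble `aa_seq` + one antigen column);
#'   header-only when `fraction_labeled = 0`.
#' @export
simulate_binding <- function(truth, fraction_labeled = 0.5, noise_sd = 0.05,
                             antigen = "antigen_A", seed, out_path = NULL) {
  if (missing(seed)) param_error("an explicit seed is required")
  if (fraction_labeled < 0 || fraction_labeled > 1) {
    param_error("fraction_labeled must lie in [0, 1]")
  }
  eligible <- truth[!truth$planted, , drop = FALSE]
  if (nrow(eligible) == 0) param_error("no eligible clones to label")
  out <- withr::with_seed(seed, {
    n_lab <- round(fraction_labeled * nrow(eligible))
    if (n_lab == 0) {
      tibble::tibble(aa_seq = character(), !!antigen := numeric())
    } else {
      top <- which.max(eligible$coefficient)
      pool <- setdiff(seq_len(nrow(eligible)), top)
      extra <- if (n_lab > 1) sample(pool, n_lab - 1) else integer(0)
      idx <- sort(c(top, extra))
      value <- plogis(eligible$coefficient[idx]) +
        rnorm(length(idx), 0, noise_sd)
      tibble::tibble(aa_seq = eligible$aa_seq[idx], !!antigen := value)
    }
  })
  class(out) <- c("binding_table", class(tibble::tibble()))
  if (!is.null(out_path)) {
    readr::write_csv(out, out_path, progress = FALSE)
  }
  out
}
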