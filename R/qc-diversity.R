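#' Per-sample read accounting
#'
#' Summarizes, for every sample, how many reads were sequenced, how many
#' were successfully aligned upstream, and how many survive the clonotype
#' table that was actually loaded (post-trimming). Totals from upstream
#' aligner logs can be supplied; when absent, total and aligned both default
#' to the summed read count of the loaded table, so the summary degrades
#' gracefully to a depth report. Underrepresented samples show up as rows
#' with a low total, heavy upstream losses as aligned << total.
#'
#' @param set An `experiment_set`.
#' @param upstream_totals Optional named list, one entry per sample, each a
#'   numeric vector `c(total = ..., aligned = ...)`. Names must be sample
#'   names present in `set`.
#' @return A tibble (`sample_name`, `total_reads`, `aligned_reads`,
#'   `retained_after_trim`), one row per sample in set order.
#' @export
alignment_summary <- function(set, upstream_totals = NULL) {
  stopifnot(inherits(set, "experiment_set"))
  samples <- names(set$repertoires)
  if (!is.null(upstream_totals)) {
    unknown <- setdiff(names(upstream_totals), samples)
    if (length(unknown) > 0) {
      param_error(sprintf("upstream totals refer to unknown sample(s): %s",
                          paste(unknown, collapse = ", ")))
    }
  }
  rows <- lapply(samples, function(nm) {
    retained <- total_reads(set$repertoires[[nm]])
    up <- upstream_totals[[nm]]
    total <- if (!is.null(up)) unname(up[["total"]]) else retained
    aligned <- if (!is.null(up)) unname(up[["aligned"]]) else retained
    tibble::tibble(sample_name = nm, total_reads = total,
                   aligned_reads = aligned, retained_after_trim = retained)
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$retained_after_trim > out$aligned_reads |
          out$aligned_reads > out$total_reads)) {
    warn("alignment summary: retained > aligned or aligned > total for some sample")
  }
  out
}

#' Rarefaction curve for one sample
#'
#' Assesses whether sequencing depth suffices to cover the sample's
#' sequence diversity: the reads are randomly divided into `n_bins` bins and
#' the number of unique amino-acid sequences is counted additively bin by
#' bin, yielding `n_bins` points of cumulative depth versus cumulative
#' unique sequences. A curve that is still rising linearly at the last bin
#' indicates insufficient depth; a plateau indicates saturation.
#'
#' Under the default `by_read` weighting each clone contributes
#' `read_count` reads to the shuffled pool; `by_clone` instead shuffles each
#' distinct sequence once, which probes clonal richness irrespective of
#' abundance. Bin sizes differ by at most one read.
#'
#' @param rep A non-empty [repertoire()].
#' @param n_bins Number of bins (default 100).
#' @param seed Integer seed for the shuffle; when `NULL` one is drawn and
#'   reported via a message so the curve can be reproduced.
#' @param weighting `"by_read"` (default) or `"by_clone"`.
#' @return A `rarefaction_curve`: tibble (`bin`, `depth`, `unique`) with
#'   attributes `sample_name`, `n_bins`, `seed`, `weighting`.
#' @export
rarefaction_curve <- function(rep, n_bins = 100, seed = NULL,
                              weighting = c("by_read", "by_clone")) {
  stopifnot(inherits(rep, "repertoire"))
  weighting <- match.arg(weighting)
  if (nrow(rep) == 0) {
    param_error(sprintf("sample '%s' is empty", sample_name(rep)))
  }
  if (n_bins < 1) param_error("n_bins must be >= 1")
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
    message("rarefaction_curve: using generated seed ", seed)
  }
  pool <- if (weighting == "by_read") {
    rep.int(rep$aa_seq, times = as.integer(round(rep$read_count)))
  } else {
    unique(rep$aa_seq)
  }
  n <- length(pool)
  if (n_bins > n) {
    param_error(sprintf(
      "n_bins (%d) exceeds the number of available reads (%d); lower n_bins",
      n_bins, n))
  }
  shuffled <- withr::with_seed(seed, sample(pool, n))
  base_size <- n %/% n_bins
  sizes <- rep.int(base_size, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  depths <- cumsum(sizes)
  cum_new <- cumsum(!duplicated(shuffled))
  out <- tibble::tibble(bin = seq_len(n_bins), depth = depths,
                        unique = cum_new[depths])
  structure(out, sample_name = sample_name(rep), n_bins = n_bins,
            seed = seed, weighting = weighting,
            class = c("rarefaction_curve", class(tibble::tibble())))
}

# shared guts of the diversity indices: a clone-probability vector from a
# repertoire, dropping zero-count records
clone_probabilities <- function(rep, normalize = TRUE) {
  stopifnot(inherits(rep, "repertoire"))
  if (nrow(rep) == 0) {
    param_error(sprintf("sample '%s' is empty", sample_name(rep)))
  }
  if (normalize) {
    counts <- rep$read_count[rep$read_count > 0]
    if (length(counts) == 0) {
      param_error(sprintf("sample '%s' has zero total reads", sample_name(rep)))
    }
    counts / sum(counts)
  } else {
    p <- rep$read_fraction[rep$read_fraction > 0]
    if (abs(sum(p) - 1) > 1e-6) {
      warn(sprintf(
        "stored read fractions of sample '%s' sum to %.6f, not 1; consider recompute_fractions()",
        sample_name(rep), sum(p)))
    }
    p
  }
}

#' Shannon diversity of a sample
#'
#' Computes the Shannon index `H = -sum(p_i * log(p_i))` where `p_i` is the
#' clone fraction of each sequence. By default probabilities are
#' renormalized from read counts over the analyzed records so they form a
#' proper distribution after trimming or aggregation; set
#' `normalize = FALSE` to use the stored fractions verbatim. Natural
#' logarithms (nats) are used unless another `base` is given.
#'
#' @param rep A non-empty [repertoire()].
#' @param base Logarithm base; default `exp(1)` (nats), use 2 for bits.
#' @param normalize Recompute probabilities from read counts (default).
#' @return Non-negative scalar; 0 for a single clone, `log(n, base)` for
#'   `n` uniform clones.
#' @export
shannon_index <- function(rep, base = exp(1), normalize = TRUE) {
  p <- clone_probabilities(rep, normalize)
  -sum(p * log(p)) / log(base)
}

#' Inverse Simpson diversity of a sample
#'
#' Computes `D = 1 / sum(p_i^2)` with `p_i` the clone fractions, i.e. the
#' effective number of equally abundant clones; `D = n` for `n` uniform
#' clones and 1 for a monoclonal sample.
#'
#' @inheritParams shannon_index
#' @return Scalar in `[1, n_clones]`.
#' @export
inverse_simpson <- function(rep, normalize = TRUE) {
  p <- clone_probabilities(rep, normalize)
  1 / sum(p^2)
}

#' Diversity per sample
#'
#' Applies [shannon_index()] or [inverse_simpson()] to every sample of an
#' experiment set; typically drawn as a barplot across panning rounds, where
#' falling diversity in successive rounds signals enrichment of particular
#' sequences.
#'
#' @param set An `experiment_set`.
#' @param metric `"shannon"` or `"inverse_simpson"`.
#' @param ... Passed to the per-sample index function.
#' @return A tibble (`sample_name`, `diversity`) in set order.
#' @export
diversity_table <- function(set, metric = c("shannon", "inverse_simpson"),
                            ...) {
  stopifnot(inherits(set, "experiment_set"))
  metric <- match.arg(metric)
  fn <- switch(metric, shannon = shannon_index,
               inverse_simpson = inverse_simpson)
  vals <- vapply(set$repertoires, function(rep) fn(rep, ...), numeric(1))
  tibble::tibble(sample_name = names(set$repertoires),
                 diversity = unname(vals))
}
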