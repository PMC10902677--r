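# distinct amino-acid sequences / aggregated counts used by the overlap
# indices
aa_set <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  if (nrow(rep) == 0) {
    param_error(sprintf("sample '%s' is empty", sample_name(rep)))
  }
  unique(rep$aa_seq)
}

aa_counts <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  if (nrow(rep) == 0 || sum(rep$read_count) <= 0) {
    param_error(sprintf("sample '%s' is empty or has zero total reads",
                        sample_name(rep)))
  }
  counts <- tapply(rep$read_count, rep$aa_seq, sum)
  stats::setNames(as.numeric(counts), names(counts))
}

#' Pairwise sample-overlap indices
#'
#' Four indices quantify how similar two sequenced samples are, all in
#' `[0, 1]` with 1 for identical and 0 for disjoint repertoires. The three
#' presence/absence indices compare the sets of distinct amino-acid
#' sequences `A` and `B`:
#'
#' * `jaccard()`: `|A∩B| / |A∪B|`
#' * `sorensen_dice()`: `2|A∩B| / (|A| + |B|)`
#' * `relative_overlap()`: `|A∩B| / min(|A|, |B|)` — the count-free
#'   "relative" index (overlap coefficient), which ignores how often each
#'   sequence occurs and saturates at 1 when one repertoire is contained in
#'   the other.
#'
#' `morisita_horn()` additionally weights by abundance: with counts `x_i`,
#' `y_i` over the union of sequences and totals `X`, `Y`,
#' `MH = 2 * sum(x_i y_i) / ((sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) * X * Y)`.
#' It is invariant to rescaling either sample's counts by a positive
#' constant, so differing sequencing depths do not distort it.
#'
#' For every pair the ordering `jaccard <= sorensen_dice <=
#' relative_overlap` holds, since `|A∪B| >= (|A|+|B|)/2 >= min(|A|, |B|)`.
#'
#' @param a,b Non-empty [repertoire()] objects.
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' r1 <- repertoire(c("1", "2"), c(2, 2), c("NNN", "NNN"), c("CAR", "CAK"))
#' r2 <- repertoire(c("1", "2"), c(1, 3), c("NNN", "NNN"), c("CAR", "CAK"))
#' morisita_horn(r1, r2)
jaccard <- function(a, b) {
  A <- aa_set(a); B <- aa_set(b)
  length(intersect(A, B)) / length(union(A, B))
}

#' @rdname jaccard
#' @export
sorensen_dice <- function(a, b) {
  A <- aa_set(a); B <- aa_set(b)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

#' @rdname jaccard
#' @export
relative_overlap <- function(a, b) {
  A <- aa_set(a); B <- aa_set(b)
  length(intersect(A, B)) / min(length(A), length(B))
}

#' @rdname jaccard
#' @export
morisita_horn <- function(a, b) {
  xa <- aa_counts(a); xb <- aa_counts(b)
  seqs <- union(names(xa), names(xb))
  x <- ifelse(seqs %in% names(xa), xa[seqs], 0)
  y <- ifelse(seqs %in% names(xb), xb[seqs], 0)
  X <- sum(x); Y <- sum(y)
  2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}

similarity_methods <- function() {
  c("morisita_horn", "relative", "jaccard", "sorensen_dice")
}

#' Sample-to-sample similarity matrix
#'
#' Computes the chosen overlap index for every pair of samples, producing
#' the symmetric matrix behind a similarity heatmap across panning rounds.
#' The diagonal is exactly 1.
#'
#' @param set An `experiment_set` with at least two samples.
#' @param method One of `"morisita_horn"` (default), `"relative"`,
#'   `"jaccard"`, `"sorensen_dice"`.
#' @return A `similarity_matrix`: numeric matrix with sample names as
#'   dimnames and attribute `method`.
#' @export
pairwise_matrix <- function(set, method = similarity_methods()) {
  stopifnot(inherits(set, "experiment_set"))
  method <- match.arg(method)
  samples <- names(set$repertoires)
  if (length(samples) < 2) param_error("need at least two samples")
  for (nm in samples) {
    if (nrow(set$repertoires[[nm]]) == 0) {
      param_error(sprintf("sample '%s' is empty", nm))
    }
  }
  fn <- switch(method, morisita_horn = morisita_horn,
               relative = relative_overlap, jaccard = jaccard,
               sorensen_dice = sorensen_dice)
  n <- length(samples)
  values <- diag(1, n)
  dimnames(values) <- list(samples, samples)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      v <- fn(set$repertoires[[i]], set$repertoires[[j]])
      values[i, j] <- v
      values[j, i] <- v
    }
  }
  structure(values, method = method,
            class = c("similarity_matrix", "matrix", "array"))
}

#' Similarity matrix exports
#'
#' `similarity_long()` flattens a similarity matrix into a
#' (`sample_a`, `sample_b`, `value`) tibble over unordered pairs;
#' `write_similarity_matrix()` writes the square matrix as TSV with a
#' leading `sample` column.
#'
#' @param mat A `similarity_matrix` from [pairwise_matrix()].
#' @param path Output TSV path.
#' @export
similarity_long <- function(mat) {
  stopifnot(inherits(mat, "similarity_matrix"))
  samples <- rownames(mat)
  idx <- which(upper.tri(mat, diag = FALSE), arr.ind = TRUE)
  tibble::tibble(sample_a = samples[idx[, 1]], sample_b = samples[idx[, 2]],
                 value = mat[idx])
}

#' @rdname similarity_long
#' @export
write_similarity_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "similarity_matrix"))
  out <- dplyr::bind_cols(tibble::tibble(sample = rownames(mat)),
                          tibble::as_tibble(unclass(mat)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
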