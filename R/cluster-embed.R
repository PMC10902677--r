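#' Levenshtein distance between strings
#'
#' Minimum number of single-character substitutions, insertions and
#' deletions turning one string into the other, computed by the standard
#' dynamic program (unit costs). For example `"CAT"` and `"BAD"` are 2
#' edits apart (change C and T) while `"CAT"` and `"CATS"` are 1 edit apart
#' (append S). Arguments are recycled to a common length.
#'
#' @param a,b Character vectors (recycled).
#' @return Integer vector of distances.
#' @export
#' @examples
#' levenshtein("CAT", c("BAD", "CATS"))
levenshtein <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (anyNA(a) || anyNA(b)) param_error("sequences must not be NA")
  n <- max(length(a), length(b))
  if (length(a) == 0 || length(b) == 0) return(integer(0))
  .ld_pairs_cpp(rep_len(a, n), rep_len(b, n))
}

# select the sequences entering all-pairs analyses: top N by count, ties
# broken lexicographically
select_top_sequences <- function(seqs, counts, top_n) {
  if (is.null(counts)) counts <- rep_len(1, length(seqs))
  if (length(seqs) <= top_n) {
    return(seq_along(seqs))
  }
  order(-counts, seqs)[seq_len(top_n)]
}

# normalize the `x` argument of the clustering functions to sequences (+
# counts/samples when available)
sequence_input <- function(x) {
  if (inherits(x, "repertoire")) {
    agg <- aggregate_by_aa(x)
    list(seqs = agg$aa_seq, counts = agg$read_count,
         samples = rep_len(sample_name(x), nrow(agg)))
  } else if (inherits(x, "experiment_set")) {
    pooled <- x$master |>
      dplyr::group_by(.data$aa_seq) |>
      dplyr::summarise(
        count = sum(.data$read_count),
        sample = .data$sample_name[which.max(.data$read_count)],
        .groups = "drop")
    list(seqs = pooled$aa_seq, counts = pooled$count, samples = pooled$sample)
  } else {
    list(seqs = as.character(x), counts = NULL,
         samples = rep_len(NA_character_, length(x)))
  }
}

#' All-pairs Levenshtein distance matrix
#'
#' Computes the symmetric matrix of Levenshtein distances between
#' amino-acid sequences. Because the computation is quadratic in the number
#' of sequences, inputs larger than `top_n` are capped to the `top_n`
#' sequences with the highest read counts (ties broken lexicographically);
#' pass `top_n = Inf` to disable the cap. Repertoires and experiment sets
#' are aggregated to distinct amino-acid sequences first; plain character
#' vectors are used as given (duplicates yield off-diagonal zeros).
#'
#' @param x A [repertoire()], `experiment_set`, or character vector.
#' @param top_n Cap on the number of sequences (default 200).
#' @return An `ld_matrix`: symmetric integer matrix with the sequences as
#'   dimnames and attribute `metric = "levenshtein"`.
#' @export
ld_matrix <- function(x, top_n = 200) {
  inp <- sequence_input(x)
  keep <- select_top_sequences(inp$seqs, inp$counts, top_n)
  seqs <- inp$seqs[keep]
  if (length(seqs) < 2) {
    param_error("need at least two sequences for a distance matrix")
  }
  if (length(keep) < length(inp$seqs)) {
    message(sprintf("ld_matrix: capped %d sequences to top %d by read count",
                    length(inp$seqs), length(keep)))
  }
  values <- .ld_matrix_cpp(seqs)
  dimnames(values) <- list(seqs, seqs)
  structure(values, metric = "levenshtein",
            counts = if (!is.null(inp$counts)) inp$counts[keep] else NULL,
            samples = inp$samples[keep],
            class = c("ld_matrix", "matrix", "array"))
}

#' Hierarchical clustering of sequences by edit distance
#'
#' Clusters the sequences of a Levenshtein distance matrix into a rooted
#' dendrogram. Average linkage (UPGMA) is the default; single and complete
#' linkage are available. Merge heights are in edit-distance units.
#'
#' @param mat An `ld_matrix`.
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return An [stats::hclust] tree with the sequences as labels.
#' @export
ld_dendrogram <- function(mat, linkage = c("average", "single", "complete")) {
  stopifnot(inherits(mat, "ld_matrix"))
  linkage <- match.arg(linkage)
  stats::hclust(stats::as.dist(unclass(mat)), method = linkage)
}

#' Export a dendrogram as Newick
#'
#' Converts the merge tree to a phylogeny (branch lengths derived from the
#' merge heights) and serializes it in Newick format.
#'
#' @param tree An [stats::hclust] tree from [ld_dendrogram()].
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Sequence network at an edit-distance cutoff
#'
#' Builds the undirected graph whose nodes are sequences and whose edges
#' connect pairs at Levenshtein distance at most `cutoff`. Connected
#' components are labeled on the nodes; node attributes carry sample, read
#' count and, when a binding table is supplied, the binding value. Raising
#' the cutoff only merges components, never splits them.
#'
#' @param x A [repertoire()], `experiment_set`, or character vector.
#' @param cutoff Maximum edit distance for an edge (>= 1).
#' @param binding Optional `binding_table` from [read_binding_table()].
#' @param antigen Antigen column of `binding` to annotate with; defaults to
#'   its first antigen column.
#' @param top_n Cap on the number of sequences (see [ld_matrix()]).
#' @return An [igraph::graph] with vertex attributes `name`, `sample`,
#'   `count`, `component` and optionally `binding`; edge attribute `ld`.
#' @export
ld_graph <- function(x, cutoff, binding = NULL, antigen = NULL, top_n = 200) {
  if (cutoff < 1) param_error("cutoff must be >= 1")
  mat <- ld_matrix(x, top_n = top_n)
  seqs <- rownames(mat)
  counts <- attr(mat, "counts") %||% rep_len(NA_real_, length(seqs))
  samples <- attr(mat, "samples")
  nodes <- tibble::tibble(name = seqs, sample = samples, count = counts)
  if (!is.null(binding)) {
    nodes$binding <- binding_values(binding, antigen)[seqs]
  }
  idx <- which(upper.tri(mat) & unclass(mat) <= cutoff, arr.ind = TRUE)
  edges <- tibble::tibble(from = seqs[idx[, 1]], to = seqs[idx[, 2]],
                          ld = unclass(mat)[idx])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)
  igraph::V(g)$component <- comp$membership
  g
}

#' Node and edge tables of a sequence network
#'
#' @param g A graph from [ld_graph()].
#' @return Tibbles suitable for TSV export: `graph_nodes()` one row per
#'   sequence (with component label), `graph_edges()` one row per edge with
#'   its edit distance.
#' @export
graph_nodes <- function(g) {
  tibble::as_tibble(igraph::as_data_frame(g, what = "vertices"))
}

#' @rdname graph_nodes
#' @export
graph_edges <- function(g) {
  tibble::as_tibble(igraph::as_data_frame(g, what = "edges"))
}

#' Sequence graph transform embedding
#'
#' Embeds each sequence into a fixed-length vector that captures the
#' characteristic relative positions of symbol pairs, allowing sequences of
#' different lengths to be compared. For every ordered alphabet pair
#' `(u, v)` the feature is
#' `psi(u, v) = (sum over positions l < m with s_l = u, s_m = v of
#' exp(-kappa * (m - l)) / Z)^(1/kappa)`,
#' where `Z` is the number of occurrences of `u` (length-insensitive
#' default) or that count times the sequence length (`length_sensitive`).
#' Pairs that never occur get feature 0, so the vector has dimension
#' `|alphabet|^2` (400 for the 20 amino acids). Larger `kappa` makes the
#' features more local.
#'
#' @param seqs Character vector of sequences (or a [repertoire()], which is
#'   aggregated to distinct amino-acid sequences).
#' @param kappa Decay rate, > 0 (default 1).
#' @param alphabet Symbol set (default the 20 standard amino acids);
#'   symbols outside it are dropped with a warning.
#' @param length_sensitive Use the length-normalized variant.
#' @return Numeric matrix, one row per input sequence (rownames = the
#'   sequences), columns named `u>v`.
#' @export
#' @examples
#' sgt_embed("AB", alphabet = c("A", "B"))["AB", "A>B"]  # exp(-1)
sgt_embed <- function(seqs, kappa = 1, alphabet = aa_alphabet(),
                      length_sensitive = FALSE) {
  if (inherits(seqs, "repertoire")) seqs <- aggregate_by_aa(seqs)$aa_seq
  seqs <- as.character(seqs)
  if (kappa <= 0) param_error("kappa must be > 0")
  pairs <- expand.grid(v = alphabet, u = alphabet, stringsAsFactors = FALSE)
  cols <- paste0(pairs$u, ">", pairs$v)
  out <- matrix(0, nrow = length(seqs), ncol = length(cols),
                dimnames = list(seqs, cols))
  dropped_any <- FALSE
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    if (nzchar(s) && !is.null(cache[[s]])) {
      out[i, ] <- cache[[s]]
      next
    }
    chars <- strsplit(s, "")[[1]]
    inside <- chars %in% alphabet
    if (any(!inside)) dropped_any <- TRUE
    chars <- chars[inside]
    L <- length(chars)
    v <- numeric(length(cols))
    names(v) <- cols
    if (L >= 2) {
      pos <- split(seq_len(L), chars)
      for (u in names(pos)) {
        Z <- if (length_sensitive) length(pos[[u]]) * L else length(pos[[u]])
        for (w in names(pos)) {
          d <- outer(pos[[w]], pos[[u]], `-`)
          d <- d[d > 0]
          if (length(d) > 0) {
            v[paste0(u, ">", w)] <- (sum(exp(-kappa * d)) / Z)^(1 / kappa)
          }
        }
      }
    }
    out[i, ] <- v
    if (nzchar(s)) cache[[s]] <- v
  }
  if (dropped_any) {
    warn("sgt_embed: symbols outside the alphabet were dropped")
  }
  structure(out, kappa = kappa, alphabet = alphabet,
            length_sensitive = length_sensitive)
}

#' Project embedding vectors to two dimensions
#'
#' Standardizes the embedding vectors, reduces them with PCA to at most
#' `pca_dims` components, then runs t-SNE on the principal-component scores
#' to obtain 2-D coordinates for visual cluster inspection. The run is
#' fully deterministic given `seed`. A perplexity too large for the number
#' of distinct points is lowered automatically with a warning (it must
#' stay below `(n - 1) / 3`). Exactly duplicated input vectors are
#' collapsed before the projection and share one output coordinate, so
#' identical sequences always land on the same point.
#'
#' @param vectors Numeric matrix, one row per sequence (e.g. from
#'   [sgt_embed()]).
#' @param pca_dims Maximum number of principal components (default 50).
#' @param perplexity t-SNE perplexity (default 30).
#' @param seed Integer seed for the t-SNE initialization.
#' @param max_iter t-SNE gradient-descent iterations (default 500).
#' @return Numeric matrix `n x 2` with columns `x`, `y` and the input
#'   rownames.
#' @export
reduce_to_2d <- function(vectors, pca_dims = 50, perplexity = 30, seed = 42,
                         max_iter = 500) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < 4) param_error("need at least 4 points for a 2-D projection")
  # exactly duplicated vectors are collapsed before the projection and
  # share coordinates afterwards: identical inputs must stay coincident,
  # and the Gaussian-kernel calibration is better behaved without
  # zero-distance pairs
  key <- apply(vectors, 1, paste, collapse = "\r")
  uniq <- !duplicated(key)
  nu <- sum(uniq)
  if (perplexity >= (nu - 1) / 3) {
    perplexity <- max(1, (nu - 1) / 3 - 1e-6)
    warn(sprintf("perplexity too large for %d distinct points; lowered to %.2f",
                 nu, perplexity))
  }
  V <- vectors[uniq, , drop = FALSE]
  keep <- apply(V, 2, stats::sd) > 0
  X <- if (any(keep)) scale(V[, keep, drop = FALSE]) else V * 0
  rank <- min(pca_dims, ncol(X), nu - 1)
  scores <- if (rank >= 1 && any(keep)) {
    stats::prcomp(X, center = FALSE, rank. = rank)$x
  } else {
    matrix(0, nu, 1)
  }
  coords_u <- tsne_exact(scores, perplexity = perplexity, seed = seed,
                         max_iter = max_iter)
  coords <- coords_u[match(key, key[uniq]), , drop = FALSE]
  dimnames(coords) <- list(rownames(vectors), c("x", "y"))
  coords
}

# Exact (O(n^2)) t-SNE: Gaussian input kernel calibrated per point to the
# target perplexity by binary search, Student-t output kernel, gradient
# descent with early exaggeration, momentum switch, and per-parameter
# gains. Suited to the capped problem sizes used here (hundreds of
# points).
tsne_exact <- function(X, perplexity = 30, seed = 42, max_iter = 500,
                       eta = 200, exaggeration = 12, exag_iter = 100,
                       momentum_switch = 250) {
  n <- nrow(X)
  P <- tsne_joint_probabilities(X, perplexity)
  Y <- withr::with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (iter in seq_len(max_iter)) {
    sum_Y <- rowSums(Y^2)
    num <- 1 / (1 + outer(sum_Y, sum_Y, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    mult <- if (iter <= exag_iter) exaggeration else 1
    PQ <- (P * mult - Q) * num
    grad <- 4 * (diag(rowSums(PQ)) %*% Y - PQ %*% Y)
    momentum <- if (iter < momentum_switch) 0.5 else 0.8
    gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8),
                  0.01)
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

tsne_joint_probabilities <- function(X, perplexity, tol = 1e-5) {
  n <- nrow(X)
  sum_X <- rowSums(X^2)
  D2 <- pmax(outer(sum_X, sum_X, `+`) - 2 * tcrossprod(X), 0)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    beta_min <- -Inf
    beta_max <- Inf
    for (step in seq_len(50)) {
      p <- exp(-di * beta)
      sum_p <- sum(p)
      if (sum_p == 0) {
        H <- 0
        p <- rep_len(1 / length(di), length(di))
      } else {
        H <- log(sum_p) + beta * sum(di * p) / sum_p
        p <- p / sum_p
      }
      if (abs(H - target) < tol) break
      if (H > target) {
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

# pull one antigen column of a binding table as a named numeric vector
binding_values <- function(binding, antigen = NULL) {
  stopifnot(inherits(binding, "binding_table"))
  antigens <- setdiff(names(binding), "aa_seq")
  antigen <- antigen %||% antigens[1]
  if (!antigen %in% antigens) {
    param_error(sprintf("unknown antigen column '%s' (available: %s)",
                        antigen, paste(antigens, collapse = ", ")))
  }
  stats::setNames(binding[[antigen]], binding$aa_seq)
}

#' Overlay binding data on embedded or clustered sequences
#'
#' Joins immunoassay binding values onto a per-sequence table (embedding
#' coordinates, graph nodes, ...) by amino-acid sequence. Sequences without
#' a measurement get `NA`; binding-table rows that match no sequence are
#' reported via a message and the `n_unmatched` attribute, not an error,
#' since assays typically cover only a subset of the repertoire.
#'
#' @param points A tibble/data frame with an `aa_seq` column, or a matrix
#'   whose rownames are sequences (e.g. from [reduce_to_2d()]).
#' @param binding A `binding_table`.
#' @param antigen Antigen column name; defaults to the first.
#' @return A tibble: `points` plus a `binding` column.
#' @export
overlay_binding <- function(points, binding, antigen = NULL) {
  vals <- binding_values(binding, antigen)
  if (is.matrix(points)) {
    points <- dplyr::bind_cols(tibble::tibble(aa_seq = rownames(points)),
                               tibble::as_tibble(points))
  }
  points <- tibble::as_tibble(points)
  if (!"aa_seq" %in% names(points)) {
    param_error("points must have an 'aa_seq' column or sequence rownames")
  }
  out <- points
  out$binding <- unname(vals[out$aa_seq])
  unmatched <- sum(!names(vals)[!is.na(vals)] %in% out$aa_seq)
  if (unmatched > 0) {
    message(sprintf(
      "overlay_binding: %d labeled sequence(s) not present among the points",
      unmatched))
  }
  attr(out, "n_unmatched") <- unmatched
  out
}

#' Nominate untested sequences near high-affinity binders
#'
#' Scans unlabeled sequences (no binding measurement) for those within
#' `ld_cutoff` edits of any labeled sequence whose binding value is at
#' least `min_binding`. Each candidate is reported with its closest
#' qualifying labeled neighbor (ties resolved toward the higher-binding
#' neighbor, then lexicographically), the edit distance, and that
#' neighbor's binding value, sorted by ascending distance then descending
#' neighbor binding. With `ld_cutoff = 0` only exact duplicates of labeled
#' sequences qualify.
#'
#' @param seqs Character vector of sequences (or a [repertoire()]).
#' @param binding A `binding_table`.
#' @param antigen Antigen column name; defaults to the first.
#' @param ld_cutoff Maximum edit distance to a qualifying binder
#'   (default 2).
#' @param min_binding Minimum binding value for a labeled sequence to seed
#'   candidates.
#' @return A tibble (`sequence`, `neighbor`, `ld`, `neighbor_binding`);
#'   zero rows when every sequence already has a label.
#' @export
nearest_labeled_neighbors <- function(seqs, binding, antigen = NULL,
                                      ld_cutoff = 2, min_binding = 0) {
  if (inherits(seqs, "repertoire")) seqs <- unique(seqs$aa_seq)
  seqs <- unique(as.character(seqs))
  if (ld_cutoff < 0) param_error("ld_cutoff must be >= 0")
  vals <- binding_values(binding, antigen)
  vals <- vals[!is.na(vals)]
  qualifying <- vals[vals >= min_binding]
  if (length(qualifying) == 0) {
    param_error(sprintf("no labeled sequence with binding >= %g", min_binding))
  }
  unlabeled <- setdiff(seqs, names(vals))
  if (length(unlabeled) == 0) {
    return(tibble::tibble(sequence = character(), neighbor = character(),
                          ld = integer(), neighbor_binding = numeric()))
  }
  labs <- names(qualifying)
  rows <- lapply(unlabeled, function(s) {
    d <- levenshtein(rep_len(s, length(labs)), labs)
    dmin <- min(d)
    if (dmin > ld_cutoff) return(NULL)
    best <- which(d == dmin)
    best <- best[order(-qualifying[best], labs[best])][1]
    tibble::tibble(sequence = s, neighbor = labs[best], ld = dmin,
                   neighbor_binding = unname(qualifying[best]))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(sequence = character(), neighbor = character(),
                          ld = integer(), neighbor_binding = numeric()))
  }
  out[order(out$ld, -out$neighbor_binding, out$sequence), ]
}
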