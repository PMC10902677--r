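#' CDR length distribution
#'
#' Tabulates sequence lengths for one sample, either over distinct
#' sequences (`unique`, each distinct sequence counted once) or over reads
#' (`read_weighted`, each length weighted by its summed read count). The
#' unit can be amino acids or nucleotides; after default trimming every
#' nucleotide length is divisible by 3.
#'
#' @param rep A non-empty [repertoire()].
#' @param unit `"aa"` (default) or `"nt"`.
#' @param weighting `"unique"` (default) or `"read_weighted"`.
#' @return A `length_distribution`: tibble (`length`, `count`) sorted by
#'   length, with attributes `sample_name`, `unit`, `weighting`. Counts sum
#'   to the number of distinct sequences (`unique`) or total reads
#'   (`read_weighted`).
#' @export
length_distribution <- function(rep, unit = c("aa", "nt"),
                                weighting = c("unique", "read_weighted")) {
  stopifnot(inherits(rep, "repertoire"))
  unit <- match.arg(unit)
  weighting <- match.arg(weighting)
  if (nrow(rep) == 0) {
    param_error(sprintf("sample '%s' is empty", sample_name(rep)))
  }
  seqs <- if (unit == "aa") rep$aa_seq else rep$nt_seq
  if (weighting == "unique") {
    len <- nchar(unique(seqs))
    tab <- table(len)
  } else {
    len <- nchar(seqs)
    tab <- tapply(rep$read_count, len, sum)
  }
  out <- tibble::tibble(length = as.integer(names(tab)),
                        count = as.numeric(tab)) |>
    dplyr::arrange(.data$length)
  structure(out, sample_name = sample_name(rep), unit = unit,
            weighting = weighting,
            class = c("length_distribution", class(tibble::tibble())))
}

#' Positional amino-acid composition at a fixed length
#'
#' Builds the 20 x L matrix of per-position amino-acid fractions among the
#' sample's sequences of exactly length `L`, the input for sequence-logo and
#' stacked-bar views. Restricting to a single length is essential for CDR
#' loops: their ends are conserved while lengths vary, so mixing lengths
#' systematically overrepresents end-position residues of shorter
#' sequences.
#'
#' Sequences containing symbols outside the 20 standard amino acids
#' (translation artifacts such as `*`, `_`, `X`) are excluded and their
#' number is recorded in the `n_excluded` attribute. Every column of the
#' result sums to 1.
#'
#' @param rep A [repertoire()].
#' @param length Sequence length `L` to select (amino acids).
#' @param weighting `"unique"` (default; each distinct sequence once) or
#'   `"read_weighted"` (sequences weighted by read count). The unweighted
#'   default prevents a single enriched clone from dominating a logo.
#' @return A `positional_aa_matrix`: 20 x L numeric matrix (rows = amino
#'   acids, columns = positions) with attributes `length`, `weighting`,
#'   `n_sequences`, `n_excluded`.
#' @export
positional_aa_matrix <- function(rep, length,
                                 weighting = c("unique", "read_weighted")) {
  stopifnot(inherits(rep, "repertoire"))
  weighting <- match.arg(weighting)
  if (nrow(rep) == 0) {
    param_error(sprintf("sample '%s' is empty", sample_name(rep)))
  }
  if (weighting == "unique") {
    agg <- tibble::tibble(aa_seq = unique(rep$aa_seq), weight = 1)
  } else {
    counts <- aa_counts(rep)
    agg <- tibble::tibble(aa_seq = names(counts), weight = unname(counts))
  }
  agg <- agg[nchar(agg$aa_seq) == length, , drop = FALSE]
  if (nrow(agg) == 0) {
    avail <- sort(unique(nchar(unique(rep$aa_seq))))
    param_error(sprintf(
      "no sequence of length %d in sample '%s'; available lengths: %s",
      length, sample_name(rep), paste(avail, collapse = ", ")))
  }
  letters20 <- aa_alphabet()
  standard <- !grepl(paste0("[^", paste(letters20, collapse = ""), "]"),
                     agg$aa_seq)
  n_excluded <- sum(!standard)
  agg <- agg[standard, , drop = FALSE]
  if (nrow(agg) == 0) {
    param_error(sprintf(
      "all length-%d sequences in sample '%s' contain non-standard symbols",
      length, sample_name(rep)))
  }
  chars <- matrix(unlist(strsplit(agg$aa_seq, "")), nrow = nrow(agg),
                  byrow = TRUE)
  mat <- matrix(0, nrow = base::length(letters20), ncol = length,
                dimnames = list(letters20, paste0("p", seq_len(length))))
  total <- sum(agg$weight)
  for (p in seq_len(length)) {
    w <- tapply(agg$weight, factor(chars[, p], levels = letters20), sum)
    w[is.na(w)] <- 0
    mat[, p] <- w / total
  }
  structure(mat, length = length, weighting = weighting,
            n_sequences = nrow(agg), n_excluded = n_excluded,
            class = c("positional_aa_matrix", "matrix", "array"))
}

#' Per-position information content
#'
#' Converts a positional composition matrix into the information content
#' used for logo letter heights: `IC_p = log2(20) - H_p` with
#' `H_p = -sum_a f[a,p] * log2(f[a,p])`. A fully conserved position carries
#' `log2(20) ~ 4.32` bits, a uniform position 0 bits. No small-sample
#' correction is applied.
#'
#' @param mat A `positional_aa_matrix`.
#' @return Numeric vector of bits per position, named `p1..pL`.
#' @seealso [logo_heights()] for the per-letter heights `f[a,p] * IC_p`.
#' @export
information_content <- function(mat) {
  stopifnot(inherits(mat, "positional_aa_matrix"))
  apply(mat, 2, function(f) {
    f <- f[f > 0]
    log2(nrow(mat)) + sum(f * log2(f))
  })
}

#' @rdname information_content
#' @export
logo_heights <- function(mat) {
  stopifnot(inherits(mat, "positional_aa_matrix"))
  sweep(unclass(mat), 2, information_content(mat), `*`)
}
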