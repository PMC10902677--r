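#' Default clonotype trimming
#'
#' Applies the two-stage trimming used after upstream alignment: a record is
#' kept only if its nucleotide sequence length is divisible by 3 (in frame),
#' its read count is at least `min_count`, and its nucleotide sequence is at
#' least `min_nt_len` long. Defaults (count >= 3, length >= 18 nt, frame
#' required) match the pipeline's standard settings and can all be changed.
#'
#' Removal reporting attributes each removed record to the first failing
#' rule in the fixed order frame (div3), count, length, so reports are
#' deterministic even when a record violates several rules; the keep/remove
#' decision itself is order-independent. Record order is preserved and read
#' fractions are left untouched (see [recompute_fractions()]).
#'
#' @param rep A [repertoire()] whose records all carry a nucleotide
#'   sequence.
#' @param min_count Minimum read count (default 3).
#' @param min_nt_len Minimum nucleotide length (default 18).
#' @param require_div3 Require nucleotide length divisible by 3 (default
#'   `TRUE`).
#' @return A list with elements `repertoire` (trimmed) and `report` (a
#'   `filter_report`: `input_rows`, `output_rows`, `not_div3`, `low_count`,
#'   `short_nt`).
#' @export
#' @examples
#' rep <- repertoire(c("a", "b"), c(100, 5),
#'                   nt_seq = c("TGTGCGAGAGGTCACTA", "TGTGCGAGAGGTCACTACTGG"),
#'                   aa_seq = c("XXXXX", "CARGHYW"))
#' apply_default_trimming(rep)$report
apply_default_trimming <- function(rep, min_count = 3, min_nt_len = 18,
                                   require_div3 = TRUE) {
  stopifnot(inherits(rep, "repertoire"))
  if (min_count < 0 || min_nt_len < 0) {
    param_error("min_count and min_nt_len must be non-negative")
  }
  if (nrow(rep) > 0 && (anyNA(rep$nt_seq) || any(!nzchar(rep$nt_seq)))) {
    param_error("trimming requires a nucleotide sequence for every record")
  }
  len <- nchar(rep$nt_seq)
  fail_div3 <- if (require_div3) (len %% 3L) != 0L else logical(nrow(rep))
  fail_count <- rep$read_count < min_count
  fail_len <- len < min_nt_len
  keep <- !(fail_div3 | fail_count | fail_len)

  report <- structure(list(
    input_rows = nrow(rep),
    output_rows = sum(keep),
    not_div3 = sum(fail_div3),
    low_count = sum(!fail_div3 & fail_count),
    short_nt = sum(!fail_div3 & !fail_count & fail_len)
  ), class = "filter_report")

  trimmed <- rebuild_repertoire(tibble::as_tibble(rep)[keep, , drop = FALSE], rep)
  list(repertoire = trimmed, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "<filter_report> %d -> %d rows (not_div3 %d, low_count %d, short_nt %d)\n",
    x$input_rows, x$output_rows, x$not_div3, x$low_count, x$short_nt))
  invisible(x)
}

filter_report_tibble <- function(reports) {
  dplyr::bind_rows(lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    tibble::tibble(sample_name = nm, input_rows = r$input_rows,
                   output_rows = r$output_rows, not_div3 = r$not_div3,
                   low_count = r$low_count, short_nt = r$short_nt)
  }))
}

#' Renormalize read fractions
#'
#' Recomputes each record's read fraction as its read count divided by the
#' sample total, so that fractions form a probability distribution over the
#' currently retained records. Diversity indices interpret fractions as
#' clone probabilities, so this is applied after trimming or aggregation.
#'
#' @param rep A non-empty [repertoire()] with positive total reads.
#' @return The repertoire with fractions summing to 1 (within 1e-9).
#' @export
recompute_fractions <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  if (nrow(rep) == 0) {
    param_error(sprintf("sample '%s' is empty", sample_name(rep)))
  }
  tot <- sum(rep$read_count)
  if (tot <= 0) {
    param_error(sprintf("sample '%s' has zero total reads", sample_name(rep)))
  }
  records <- tibble::as_tibble(rep)
  records$read_fraction <- records$read_count / tot
  rebuild_repertoire(records, rep)
}

#' Collapse clonotypes by amino-acid sequence
#'
#' Multiple nucleotide clones frequently translate to the same amino-acid
#' sequence. For amino-acid-level analyses (diversity, overlap, clustering)
#' records are collapsed to one per distinct `aa_seq`: read counts are
#' summed, the clone id is the lexicographically smallest contributing id,
#' the nucleotide sequence is taken from that record, and fractions are
#' recomputed. Output order follows first appearance. Total reads are
#' conserved.
#'
#' @param rep A [repertoire()].
#' @return A [repertoire()] with one record per distinct amino-acid
#'   sequence.
#' @export
aggregate_by_aa <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  if (nrow(rep) == 0) return(rep)
  records <- tibble::as_tibble(rep)
  records$.order <- seq_len(nrow(records))
  agg <- records |>
    dplyr::group_by(.data$aa_seq) |>
    dplyr::summarise(
      read_count = sum(.data$read_count),
      nt_seq = .data$nt_seq[order(.data$clone_id)[1]],
      clone_id = min(.data$clone_id),
      region = .data$region[1],
      .order = min(.data$.order),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$.order)
  out <- tibble::tibble(
    clone_id = agg$clone_id,
    read_count = agg$read_count,
    read_fraction = agg$read_count / sum(agg$read_count),
    nt_seq = agg$nt_seq,
    aa_seq = agg$aa_seq,
    region = agg$region
  )
  rebuild_repertoire(out, rep)
}
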