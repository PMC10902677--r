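#' Construct a repertoire from clonotype vectors
#'
#' A repertoire is one sequenced sample: an ordered collection of clonotype
#' records, each carrying a clone identifier, read count, read fraction and
#' the nucleotide / amino-acid sequence of the selected region. It is stored
#' as a tibble subclass with the sample name, free-form metadata and the load
#' report kept as attributes.
#'
#' @param clone_id Character vector of unique clone identifiers.
#' @param read_count Non-negative integer read counts, one per clone.
#' @param nt_seq Nucleotide sequences (A/C/G/T/N) of the selected region.
#' @param aa_seq Amino-acid sequences of the selected region; `*` and `_`
#'   are tolerated as translation artifacts.
#' @param read_fraction Read fractions in `[0, 1]`; when `NULL` they are
#'   computed as `read_count / sum(read_count)`.
#' @param region Which region the sequences cover: `"CDR3"` (default),
#'   `"CDR1"`, `"CDR2"` or `"full"`.
#' @param sample_name Non-empty sample name.
#' @param metadata Optional named list (e.g. panning round).
#'
#' @return A `repertoire` object (tibble with columns `clone_id`,
#'   `read_count`, `read_fraction`, `nt_seq`, `aa_seq`, `region`).
#' @export
#' @examples
#' rep <- repertoire(
#'   clone_id = c("c1", "c2"),
#'   read_count = c(3L, 1L),
#'   nt_seq = c("TGTGCGAGA", "TGTGCGAAA"),
#'   aa_seq = c("CAR", "CAK"),
#'   sample_name = "round_1"
#' )
#' total_reads(rep)
repertoire <- function(clone_id, read_count, nt_seq, aa_seq,
                       read_fraction = NULL, region = "CDR3",
                       sample_name = "sample", metadata = list()) {
  region <- match_region(region)
  n <- length(clone_id)
  if (is.null(read_fraction)) {
    tot <- sum(read_count)
    read_fraction <- if (n == 0) numeric(0) else if (tot > 0) read_count / tot else rep(0, n)
  }
  records <- tibble::tibble(
    clone_id = as.character(clone_id),
    read_count = as.numeric(read_count),
    read_fraction = as.numeric(read_fraction),
    nt_seq = toupper(as.character(nt_seq)),
    aa_seq = toupper(as.character(aa_seq)),
    region = region
  )
  new_repertoire(records, sample_name = sample_name, metadata = metadata)
}

# internal constructor + invariant checks; `records` must already have the
# canonical columns
new_repertoire <- function(records, sample_name, metadata = list(),
                           load_report = NULL) {
  stopifnot(is.data.frame(records))
  required <- c("clone_id", "read_count", "read_fraction",
                "nt_seq", "aa_seq", "region")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort(paste0("repertoire records lack column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!is.character(sample_name) || length(sample_name) != 1 ||
      is.na(sample_name) || !nzchar(sample_name)) {
    param_error("sample_name must be a single non-empty string")
  }
  records <- tibble::as_tibble(records[required])
  if (anyNA(records$read_count) || any(records$read_count < 0)) {
    format_error("read_count must be non-negative for every record")
  }
  fr <- records$read_fraction
  if (any(!is.na(fr) & (fr < 0 | fr > 1))) {
    format_error("read_fraction must lie in [0, 1]")
  }
  if (sum(fr, na.rm = TRUE) > 1 + 1e-6) {
    format_error(sprintf(
      "read fractions in sample '%s' sum to %.6f > 1", sample_name,
      sum(fr, na.rm = TRUE)))
  }
  if (anyDuplicated(records$clone_id)) {
    dup <- records$clone_id[duplicated(records$clone_id)][1]
    format_error(sprintf("duplicate clone_id '%s' in sample '%s'",
                         dup, sample_name))
  }
  structure(
    records,
    sample_name = sample_name,
    metadata = metadata,
    load_report = load_report,
    class = c("repertoire", class(tibble::tibble()))
  )
}

# rebuild a repertoire from a plain tibble, inheriting attributes from a
# template repertoire (dplyr verbs strip subclass attributes)
rebuild_repertoire <- function(records, template, load_report = NULL) {
  new_repertoire(
    records,
    sample_name = attr(template, "sample_name"),
    metadata = attr(template, "metadata") %||% list(),
    load_report = load_report %||% attr(template, "load_report")
  )
}

#' Repertoire accessors
#'
#' @param rep A [repertoire()].
#' @return `sample_name()` the sample name; `total_reads()` the summed read
#'   count; `load_report()` the ingest report recorded by the readers (or
#'   `NULL` for constructed repertoires).
#' @export
sample_name <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  attr(rep, "sample_name")
}

#' @rdname sample_name
#' @export
total_reads <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  sum(rep$read_count)
}

#' @rdname sample_name
#' @export
load_report <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  attr(rep, "load_report")
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> sample '%s': %d clones, %s reads (%s)\n",
              attr(x, "sample_name"), nrow(x),
              format(total_reads(x), big.mark = ","),
              if (nrow(x) > 0) x$region[1] else "empty"))
  NextMethod()
}
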