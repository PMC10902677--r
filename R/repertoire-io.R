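# Column alias tables for the two clonotype-table dialects. Matching is
# case-sensitive: the dialects differ only in naming, so loose matching
# would mask format errors.
mixcr_aliases <- list(
  clone_id = c("cloneId", "clone_id"),
  read_count = c("readCount", "cloneCount", "read_count"),
  read_fraction = c("readFraction", "cloneFraction", "read_fraction")
)

airr_aliases <- list(
  clone_id = c("sequence_id", "clone_id"),
  read_count = c("duplicate_count"),
  read_fraction = c("duplicate_frequency")
)

mixcr_region_columns <- function(region) {
  switch(region,
    CDR1 = list(nt = "nSeqCDR1", aa = "aaSeqCDR1"),
    CDR2 = list(nt = "nSeqCDR2", aa = "aaSeqCDR2"),
    CDR3 = list(nt = "nSeqCDR3", aa = "aaSeqCDR3"),
    full = list(nt = c("nSeqVDJRegion", "targetSequences"),
                aa = c("aaSeqVDJRegion"))
  )
}

airr_region_columns <- function(region) {
  switch(region,
    CDR1 = list(nt = "cdr1", aa = "cdr1_aa"),
    CDR2 = list(nt = "cdr2", aa = "cdr2_aa"),
    CDR3 = list(nt = c("junction", "cdr3"), aa = c("junction_aa", "cdr3_aa")),
    full = list(nt = "sequence", aa = "sequence_aa")
  )
}

find_column <- function(header, candidates) {
  hit <- candidates[candidates %in% header]
  if (length(hit) == 0) NA_character_ else hit[1]
}

read_clone_tsv <- function(path) {
  if (!file.exists(path)) {
    param_error(sprintf("file not found: %s", path))
  }
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  quote = "", na = character(), progress = FALSE)
}

parse_counts <- function(raw, column) {
  x <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(x) & nzchar(trimws(raw)))
  if (length(bad) > 0) {
    format_error(sprintf("line %d: unparseable %s value '%s'",
                         bad[1] + 1L, column, raw[bad[1]]))
  }
  x[is.na(x)] <- 0
  x
}

default_sample_name <- function(path) {
  sub("\\.(tsv|txt|csv)(\\.gz)?$", "", basename(path))
}

clean_nt <- function(x) chartr("u", "T", toupper(x))

#' Read a MiXCR-style clonotype export
#'
#' Parses a tab-separated clone table as written by MiXCR `exportClones`
#' (columns such as `cloneId`, `readCount`, `readFraction`, `nSeqCDR3`,
#' `aaSeqCDR3`). One record is produced per row; rows whose nucleotide or
#' amino-acid sequence for the requested region is empty are dropped and
#' counted in the load report. Sequences are upper-cased on ingest and `U`
#' is mapped to `T` in nucleotide columns.
#'
#' Read fractions are taken verbatim from the file by default, because the
#' upstream tool computed them on its own (pre-trimming) totals; set
#' `recompute_fractions = TRUE` to renormalize over the loaded records.
#'
#' @param path Path to the TSV file.
#' @param region Region to extract: `"CDR3"` (default), `"CDR1"`, `"CDR2"`
#'   or `"full"`.
#' @param sample_name Sample name; defaults to the file name without
#'   extension.
#' @param recompute_fractions Renormalize read fractions over loaded rows.
#' @param metadata Optional named list attached to the repertoire.
#'
#' @return A [repertoire()]; `load_report()` holds row accounting
#'   (`input_rows`, `kept`, `dropped_empty_seq`, `notes`).
#' @export
read_mixcr_clones <- function(path, region = "CDR3", sample_name = NULL,
                              recompute_fractions = FALSE, metadata = list()) {
  region <- match_region(region)
  tab <- read_clone_tsv(path)
  header <- names(tab)
  notes <- character()

  count_col <- find_column(header, mixcr_aliases$read_count)
  if (is.na(count_col)) {
    format_error(sprintf("clone-count column missing (expected one of %s)",
                         paste(mixcr_aliases$read_count, collapse = ", ")))
  }
  frac_col <- find_column(header, mixcr_aliases$read_fraction)
  if (is.na(frac_col)) {
    format_error(sprintf("read-fraction column missing (expected one of %s)",
                         paste(mixcr_aliases$read_fraction, collapse = ", ")))
  }
  rcols <- mixcr_region_columns(region)
  nt_col <- find_column(header, rcols$nt)
  if (is.na(nt_col)) {
    format_error(sprintf("%s missing from %s", rcols$nt[1], basename(path)))
  }
  aa_col <- find_column(header, rcols$aa)
  if (is.na(aa_col)) {
    format_error(sprintf("%s missing from %s", rcols$aa[1], basename(path)))
  }
  id_col <- find_column(header, mixcr_aliases$clone_id)

  read_count <- parse_counts(tab[[count_col]], count_col)
  read_fraction <- suppressWarnings(as.numeric(tab[[frac_col]]))
  clone_id <- if (is.na(id_col)) as.character(seq_len(nrow(tab))) else tab[[id_col]]

  assemble_repertoire(
    clone_id = clone_id, read_count = read_count,
    read_fraction = read_fraction,
    nt_seq = clean_nt(tab[[nt_col]]), aa_seq = toupper(tab[[aa_col]]),
    region = region,
    sample_name = sample_name %||% default_sample_name(path),
    recompute_fractions = recompute_fractions,
    metadata = metadata, notes = notes
  )
}

#' Read an AIRR Rearrangement table
#'
#' Parses a tab-separated file following the AIRR Rearrangement schema
#' (`sequence_id`, `duplicate_count`, `junction`, `junction_aa`, ...).
#' `duplicate_count` is used as the read count; read fractions are
#' recomputed as `duplicate_count / sum(duplicate_count)` since the schema
#' carries no fraction column. When `duplicate_count` is absent entirely,
#' every row receives a read count of 1 and uniform fractions, and the load
#' report flags the assumption.
#'
#' For `region = "CDR3"` the `junction`/`junction_aa` columns are preferred,
#' falling back to `cdr3`/`cdr3_aa`.
#'
#' @inheritParams read_mixcr_clones
#' @return A [repertoire()].
#' @export
read_airr <- function(path, region = "CDR3", sample_name = NULL,
                      metadata = list()) {
  region <- match_region(region)
  tab <- read_clone_tsv(path)
  header <- names(tab)
  notes <- character()

  rcols <- airr_region_columns(region)
  nt_col <- find_column(header, rcols$nt)
  if (is.na(nt_col)) {
    format_error(sprintf("%s missing from %s", rcols$nt[1], basename(path)))
  }
  aa_col <- find_column(header, rcols$aa)
  if (is.na(aa_col)) {
    format_error(sprintf("%s missing from %s", rcols$aa[1], basename(path)))
  }

  count_col <- find_column(header, airr_aliases$read_count)
  if (is.na(count_col)) {
    read_count <- rep(1, nrow(tab))
    notes <- c(notes,
               "duplicate_count absent: assumed read_count = 1 per row")
  } else {
    read_count <- parse_counts(tab[[count_col]], count_col)
  }
  tot <- sum(read_count)
  read_fraction <- if (tot > 0) read_count / tot else rep(0, nrow(tab))

  id_col <- find_column(header, airr_aliases$clone_id)
  clone_id <- if (is.na(id_col)) as.character(seq_len(nrow(tab))) else tab[[id_col]]

  assemble_repertoire(
    clone_id = clone_id, read_count = read_count,
    read_fraction = read_fraction,
    nt_seq = clean_nt(tab[[nt_col]]), aa_seq = toupper(tab[[aa_col]]),
    region = region,
    sample_name = sample_name %||% default_sample_name(path),
    recompute_fractions = TRUE,
    metadata = metadata, notes = notes
  )
}

# shared tail of both readers: drop empty-sequence rows, optionally
# renormalize fractions, attach the load report
assemble_repertoire <- function(clone_id, read_count, read_fraction,
                                nt_seq, aa_seq, region, sample_name,
                                recompute_fractions, metadata, notes) {
  input_rows <- length(clone_id)
  empty <- !nzchar(trimws(nt_seq)) | !nzchar(trimws(aa_seq)) |
    is.na(nt_seq) | is.na(aa_seq)
  keep <- !empty
  dropped <- sum(empty)
  if (dropped > 0) {
    notes <- c(notes, sprintf("%d row(s) dropped: empty %s sequence",
                              dropped, region))
  }
  read_count <- read_count[keep]
  read_fraction <- read_fraction[keep]
  if (recompute_fractions) {
    tot <- sum(read_count)
    read_fraction <- if (tot > 0) read_count / tot else rep(0, sum(keep))
  }
  report <- list(input_rows = input_rows, kept = sum(keep),
                 dropped_empty_seq = dropped, notes = notes)
  for (note in notes) message("load report [", sample_name, "]: ", note)
  records <- tibble::tibble(
    clone_id = as.character(clone_id[keep]),
    read_count = read_count,
    read_fraction = read_fraction,
    nt_seq = nt_seq[keep],
    aa_seq = aa_seq[keep],
    region = region
  )
  new_repertoire(records, sample_name = sample_name, metadata = metadata,
                 load_report = report)
}

#' Read a binding / affinity table
#'
#' Reads a comma-separated file whose first column holds amino-acid
#' sequences and whose remaining columns hold numeric binding or affinity
#' values, one column per antigen. Non-numeric cells become missing values;
#' duplicated sequence keys are an error.
#'
#' @param path Path to the CSV file.
#' @return A `binding_table`: a tibble with column `aa_seq` plus one numeric
#'   column per antigen.
#' @export
read_binding_table <- function(path) {
  if (!file.exists(path)) {
    param_error(sprintf("file not found: %s", path))
  }
  tab <- readr::read_csv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  if (ncol(tab) < 2) {
    format_error("binding table needs a sequence column plus >=1 antigen column")
  }
  keys <- toupper(tab[[1]])
  if (anyDuplicated(keys)) {
    format_error(sprintf("duplicated sequence key '%s' in binding table",
                         keys[duplicated(keys)][1]))
  }
  antigens <- lapply(tab[-1], function(col) suppressWarnings(as.numeric(col)))
  out <- tibble::tibble(aa_seq = keys, !!!antigens)
  class(out) <- c("binding_table", class(tibble::tibble()))
  out
}

#' Assemble an experiment set from repertoires
#'
#' An experiment set is a named, ordered collection of repertoires (one per
#' sample) plus the unified "master table" with one row per (sample, clone)
#' that downstream analyses and exports operate on.
#'
#' @param repertoires List of [repertoire()] objects with unique sample
#'   names.
#' @return An `experiment_set` with elements `repertoires` (named list) and
#'   `master` (tibble with columns `sample_name`, `clone_id`, `read_count`,
#'   `read_fraction`, `nt_seq`, `aa_seq`, `region`).
#' @export
build_experiment <- function(repertoires) {
  stopifnot(is.list(repertoires))
  for (rep in repertoires) {
    if (!inherits(rep, "repertoire")) {
      param_error("build_experiment() expects a list of repertoire objects")
    }
  }
  names(repertoires) <- vapply(repertoires, sample_name, character(1))
  if (anyDuplicated(names(repertoires))) {
    dup <- names(repertoires)[duplicated(names(repertoires))][1]
    param_error(sprintf("duplicate sample name '%s'", dup))
  }
  master <- dplyr::bind_rows(lapply(repertoires, function(rep) {
    dplyr::bind_cols(tibble::tibble(sample_name = sample_name(rep)),
                     tibble::as_tibble(rep))
  }))
  if (nrow(master) == 0) {
    master <- tibble::tibble(sample_name = character(), clone_id = character(),
                             read_count = numeric(), read_fraction = numeric(),
                             nt_seq = character(), aa_seq = character(),
                             region = character())
  }
  structure(list(repertoires = repertoires, master = master),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat(sprintf("<experiment_set> %d sample(s), %d master-table row(s)\n",
              length(x$repertoires), nrow(x$master)))
  for (nm in names(x$repertoires)) {
    cat(sprintf("  %s: %d clones, %s reads\n", nm, nrow(x$repertoires[[nm]]),
                format(total_reads(x$repertoires[[nm]]), big.mark = ",")))
  }
  invisible(x)
}

#' Write and re-read the master table
#'
#' The master table is persisted as UTF-8, tab-delimited text with `.` as
#' decimal separator and no quoting, matching the conventions of both input
#' dialects. The round trip is lossless: strings and integers are exact and
#' read fractions survive to better than 1e-9 (readr writes shortest
#' round-trippable doubles).
#'
#' @param set An `experiment_set` from [build_experiment()].
#' @param path Output TSV path.
#' @return `write_master_table()` returns `path` invisibly;
#'   `read_master_table()` returns the master tibble;
#'   `experiment_from_master()` rebuilds an `experiment_set` from a master
#'   table (samples in order of first appearance).
#' @export
write_master_table <- function(set, path) {
  stopifnot(inherits(set, "experiment_set"))
  readr::write_tsv(set$master, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_master_table
#' @export
read_master_table <- function(path) {
  if (!file.exists(path)) {
    param_error(sprintf("file not found: %s", path))
  }
  readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_name = readr::col_character(),
      clone_id = readr::col_character(),
      read_count = readr::col_double(),
      read_fraction = readr::col_double(),
      nt_seq = readr::col_character(),
      aa_seq = readr::col_character(),
      region = readr::col_character()
    ),
    quote = "", progress = FALSE
  )
}

#' @rdname write_master_table
#' @param master A master tibble as returned by [read_master_table()].
#' @export
experiment_from_master <- function(master) {
  required <- c("sample_name", "clone_id", "read_count", "read_fraction",
                "nt_seq", "aa_seq", "region")
  missing <- setdiff(required, names(master))
  if (length(missing) > 0) {
    format_error(paste0("master table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  samples <- unique(master$sample_name)
  reps <- lapply(samples, function(nm) {
    rows <- master[master$sample_name == nm, setdiff(required, "sample_name")]
    new_repertoire(rows, sample_name = nm)
  })
  build_experiment(reps)
}
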