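#' Assemble a run configuration
#'
#' Collects every input path and tunable parameter of the full workflow
#' into a plain list with validated defaults. Configurations can also be
#' read from a flat `key = value` text file with [read_run_config()]
#' (numeric-looking values are coerced, `true`/`false` become logicals,
#' comma-separated values become vectors); command-line flags override file
#' values.
#'
#' @param inputs Character vector of clonotype-table paths (one sample
#'   each).
#' @param out_dir Output directory.
#' @param dialect `"mixcr"` or `"airr"`.
#' @param region Region to analyze (default `"CDR3"`).
#' @param binding Optional binding CSV path.
#' @param antigen Optional antigen column (default: first column of the
#'   binding table).
#' @param min_count,min_nt_len,require_div3 Trimming parameters (see
#'   [apply_default_trimming()]).
#' @param n_bins Rarefaction bins (default 100).
#' @param top_n Sequence cap for clustering/embedding (default 200).
#' @param ld_cutoff Edit-distance cutoff for the sequence network
#'   (default 2).
#' @param linkage Dendrogram linkage (default `"average"`).
#' @param kappa SGT decay rate (default 1).
#' @param pca_dims,perplexity Projection parameters (see
#'   [reduce_to_2d()]).
#' @param min_binding Minimum neighbor binding for candidate nomination
#'   (default 0.5).
#' @param seed Master seed; per-stage seeds are derived from it and logged
#'   in the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(inputs, out_dir, dialect = c("mixcr", "airr"),
                       region = "CDR3", binding = NULL, antigen = NULL,
                       min_count = 3, min_nt_len = 18, require_div3 = TRUE,
                       n_bins = 100, top_n = 200, ld_cutoff = 2,
                       linkage = "average", kappa = 1, pca_dims = 50,
                       perplexity = 30, min_binding = 0.5, seed = 42) {
  dialect <- match.arg(dialect)
  region <- match_region(region)
  if (length(inputs) < 1) param_error("at least one input file is required")
  structure(list(
    inputs = inputs, out_dir = out_dir, dialect = dialect, region = region,
    binding = binding, antigen = antigen, min_count = min_count,
    min_nt_len = min_nt_len, require_div3 = require_div3, n_bins = n_bins,
    top_n = top_n, ld_cutoff = ld_cutoff, linkage = linkage, kappa = kappa,
    pca_dims = pca_dims, perplexity = perplexity,
    min_binding = min_binding, seed = seed
  ), class = "run_config")
}

#' @rdname run_config
#' @param path Path to a `key = value` configuration file; `#` starts a
#'   comment.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) param_error(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) format_error(sprintf("config line without '=': %s", ln))
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    parsed <- suppressWarnings(as.numeric(parts))
    out <- if (!anyNA(parsed)) {
      parsed
    } else if (all(tolower(parts) %in% c("true", "false"))) {
      tolower(parts) == "true"
    } else {
      parts
    }
    kv[[key]] <- out
  }
  do.call(run_config, kv)
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage %s: %s", stage, conditionMessage(e)),
          class = "repanner_stage_error", parent = e)
  })
}

#' Run the full analysis workflow
#'
#' Executes the complete pipeline on a [run_config()]: load each clonotype
#' table, trim, collapse to amino-acid clones, renormalize fractions, then
#' compute the read-accounting summary, per-sample rarefaction curves,
#' Shannon and inverse Simpson diversity, all four sample-overlap matrices,
#' length distributions, the positional composition matrix at each
#' sample's modal CDR length, the edit-distance dendrogram and cutoff
#' network, and the SGT + PCA + t-SNE embedding; when a binding CSV is
#' configured, binding values are overlaid on the embedding and untested
#' neighbors of strong binders are nominated. Every result is written as
#' TSV (plus Newick for the dendrogram) into `out_dir`, and
#' `manifest.json` records inputs, parameters, derived seeds, and the
#' generating stage and row count of every output file. Given identical
#' inputs and seed the directory contents are byte-identical across runs.
#'
#' @param config A `run_config` (or path to a config file).
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(inputs = as.list(config$inputs),
                   parameters = config[setdiff(names(config),
                                               c("inputs", "out_dir"))],
                   seeds = list(master = config$seed),
                   outputs = list())
  outputs <- list()
  emit <- function(file, stage, object, n_rows, params = NULL) {
    outputs[[length(outputs) + 1]] <<- list(
      file = file, stage = stage, n_rows = n_rows,
      params = params %||% list())
  }
  write_tbl <- function(tbl, name, stage, params = NULL) {
    f <- file.path(config$out_dir, name)
    readr::write_tsv(tibble::as_tibble(tbl), f, progress = FALSE)
    emit(name, stage, tbl, nrow(tbl), params)
    f
  }
  reader <- switch(config$dialect, mixcr = read_mixcr_clones,
                   airr = read_airr)

  # load + trim + aggregate
  reports <- list()
  reps <- stage_try("load", lapply(config$inputs, function(path) {
    reader(path, region = config$region)
  }))
  trimmed <- stage_try("trim", lapply(reps, function(rep) {
    res <- apply_default_trimming(rep, min_count = config$min_count,
                                  min_nt_len = config$min_nt_len,
                                  require_div3 = config$require_div3)
    reports[[sample_name(rep)]] <<- res$report
    res$repertoire
  }))
  analyzed <- stage_try("aggregate", lapply(trimmed, function(rep) {
    recompute_fractions(aggregate_by_aa(rep))
  }))
  set <- stage_try("master_table", build_experiment(analyzed))
  write_tbl(set$master, "master_table.tsv", "master_table")
  write_tbl(filter_report_tibble(reports), "filter_report.tsv", "trim",
            list(min_count = config$min_count,
                 min_nt_len = config$min_nt_len,
                 require_div3 = config$require_div3))

  # QC + diversity
  write_tbl(alignment_summary(set), "alignment_summary.tsv", "qc")
  raref_all <- stage_try("rarefaction", {
    rows <- lapply(seq_along(set$repertoires), function(i) {
      rep <- set$repertoires[[i]]
      seed_i <- config$seed + i
      manifest$seeds[[paste0("rarefaction_", sample_name(rep))]] <<- seed_i
      curve <- rarefaction_curve(rep,
                                 n_bins = min(config$n_bins,
                                              total_reads(rep)),
                                 seed = seed_i)
      dplyr::bind_cols(tibble::tibble(sample_name = sample_name(rep)),
                       tibble::as_tibble(curve))
    })
    dplyr::bind_rows(rows)
  })
  write_tbl(raref_all, "rarefaction.tsv", "rarefaction",
            list(n_bins = config$n_bins))
  div <- stage_try("diversity", {
    sh <- diversity_table(set, "shannon")
    is <- diversity_table(set, "inverse_simpson")
    tibble::tibble(sample_name = sh$sample_name, shannon = sh$diversity,
                   inverse_simpson = is$diversity)
  })
  write_tbl(div, "diversity.tsv", "diversity")

  # similarity heatmap inputs
  if (length(set$repertoires) >= 2) {
    stage_try("similarity", for (m in similarity_methods()) {
      mat <- pairwise_matrix(set, m)
      f <- paste0("similarity_", m, ".tsv")
      write_similarity_matrix(mat, file.path(config$out_dir, f))
      emit(f, "similarity", mat, nrow(mat), list(method = m))
    })
  }

  # composition
  lengths_all <- stage_try("lengths", dplyr::bind_rows(
    lapply(set$repertoires, function(rep) {
      ld <- length_distribution(rep, unit = "aa", weighting = "unique")
      dplyr::bind_cols(tibble::tibble(sample_name = sample_name(rep)),
                       tibble::as_tibble(ld))
    })))
  write_tbl(lengths_all, "length_distribution.tsv", "lengths",
            list(unit = "aa", weighting = "unique"))
  stage_try("aa_matrix", for (rep in set$repertoires) {
    ld <- length_distribution(rep, unit = "aa", weighting = "unique")
    modal <- ld$length[order(-ld$count, ld$length)][1]
    mat <- positional_aa_matrix(rep, modal)
    out <- dplyr::bind_cols(tibble::tibble(aa = rownames(mat)),
                            tibble::as_tibble(unclass(mat)))
    f <- sprintf("aa_matrix_%s_L%d.tsv", sample_name(rep), modal)
    readr::write_tsv(out, file.path(config$out_dir, f), progress = FALSE)
    emit(f, "aa_matrix", out, nrow(out),
         list(length = modal, sample = sample_name(rep)))
  })

  # clustering + embedding on the pooled top sequences
  binding <- NULL
  if (!is.null(config$binding)) {
    binding <- stage_try("binding", read_binding_table(config$binding))
  }
  stage_try("cluster", {
    mat <- ld_matrix(set, top_n = config$top_n)
    tree <- ld_dendrogram(mat, linkage = config$linkage)
    dendrogram_newick(tree, file.path(config$out_dir, "dendrogram.nwk"))
    emit("dendrogram.nwk", "cluster", tree, length(tree$labels),
         list(linkage = config$linkage, top_n = config$top_n))
    g <- ld_graph(set, cutoff = config$ld_cutoff, binding = binding,
                  antigen = config$antigen, top_n = config$top_n)
    write_tbl(graph_nodes(g), "ld_nodes.tsv", "cluster",
              list(cutoff = config$ld_cutoff))
    write_tbl(graph_edges(g), "ld_edges.tsv", "cluster",
              list(cutoff = config$ld_cutoff))
  })
  stage_try("embed", {
    inp <- sequence_input(set)
    keep <- select_top_sequences(inp$seqs, inp$counts, config$top_n)
    seqs <- inp$seqs[keep]
    vectors <- sgt_embed(seqs, kappa = config$kappa)
    embed_seed <- config$seed + 1000L
    manifest$seeds$embedding <- embed_seed
    coords <- reduce_to_2d(vectors, pca_dims = config$pca_dims,
                           perplexity = config$perplexity,
                           seed = embed_seed)
    emb <- tibble::tibble(aa_seq = seqs, x = coords[, "x"],
                          y = coords[, "y"], count = inp$counts[keep],
                          sample = inp$samples[keep])
    if (!is.null(binding)) {
      emb <- overlay_binding(emb, binding, config$antigen)
    }
    write_tbl(emb, "embedding.tsv", "embed",
              list(kappa = config$kappa, pca_dims = config$pca_dims,
                   perplexity = config$perplexity, seed = embed_seed))
  })
  if (!is.null(binding)) {
    stage_try("candidates", {
      cand <- nearest_labeled_neighbors(
        unique(set$master$aa_seq), binding, antigen = config$antigen,
        ld_cutoff = config$ld_cutoff, min_binding = config$min_binding)
      write_tbl(cand, "candidates.tsv", "candidates",
                list(ld_cutoff = config$ld_cutoff,
                     min_binding = config$min_binding))
    })
  } else {
    manifest$binding <- "absent"
  }

  manifest$outputs <- outputs
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
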