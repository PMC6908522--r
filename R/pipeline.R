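## End-to-end orchestration: normalization -> SAM -> consensus ->
## enrichment -> coexpression networks -> CCPs -> survival, from a single
## config with one root seed, writing deterministic TSV/SIF artifacts and
## a JSON manifest of file hashes, seeds and stage timings.

#' Build and validate a pipeline configuration
#'
#' Studies come either from TSV paths (`studies` as a list of
#' `list(matrix, annotation, disease_class)`) or from the synthetic
#' generator (`synthetic` as a list of [sim_config()] arguments). At
#' least one LC study is required.
#'
#' @param studies list of per-study file entries, or `NULL`.
#' @param synthetic list of [sim_config()] arguments, or `NULL`.
#' @param q_threshold,fdr_ceiling,permutations SAM settings.
#' @param min_total,min_lc consensus winner rule.
#' @param grid,window,min_edges network threshold selection.
#' @param network_study id of the study used for the reference (LC)
#'   network; defaults to the first LC study.
#' @param tf_genes extra genes (TF candidates) added to the network gene
#'   set.
#' @param gmt_paths named character vector of GMT files for enrichment.
#' @param probe_map_path optional probe map TSV.
#' @param survival_n,censor_rate synthetic survival cohort settings (the
#'   planted hazard ratio comes from the synthetic config's `true_hr`).
#' @param survival_genes genes to report survival for; `"hubs"` uses the
#'   top 3 hubs of the reference network.
#' @param seed root seed; all stage seeds are derived with
#'   [child_seed()].
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(studies = NULL, synthetic = list(),
                            q_threshold = 0.01, fdr_ceiling = 0.15,
                            permutations = 200,
                            min_total = 7, min_lc = 5,
                            grid = seq(0.50, 0.99, by = 0.01),
                            window = 5, min_edges = 10,
                            network_study = NULL, tf_genes = character(0),
                            gmt_paths = character(0),
                            probe_map_path = NULL,
                            survival_n = 300, censor_rate = 0.2,
                            survival_genes = "hubs", seed = 42L) {
  if (is.null(studies) && is.null(synthetic))
    stop_config("either 'studies' or 'synthetic' must be given")
  if (q_threshold <= 0 || q_threshold >= 1)
    stop_config("q_threshold must lie in (0, 1)")
  if (fdr_ceiling <= 0 || fdr_ceiling > 1)
    stop_config("fdr_ceiling must lie in (0, 1]")
  if (permutations < 50) stop_config("permutations must be >= 50")
  cfg <- as.list(environment())
  if (!is.null(synthetic)) {
    cfg$sim <- do.call(sim_config, c(synthetic, list(seed = as.integer(seed))))
    if (cfg$sim$n_lc_studies < 1) stop_config("need at least one LC study")
  } else {
    cls <- vapply(studies, function(s) s$disease_class %||% "LC", character(1))
    if (!any(cls == "LC")) stop_config("need at least one LC study")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full meta-analysis pipeline
#'
#' Stages: load or generate studies; QC + variance-stabilizing
#' normalization; per-study SAM; optional probe collapse; consensus
#' direction matrix and winner genes; enrichment of winners against the
#' supplied GMT collections; coexpression network of the reference LC
#' study (restricted to winners plus TF candidates) and one network per
#' LD study; one CCP per (reference LC, LD) pair; survival reports for
#' the requested genes. Every output is written under `out_dir` and
#' listed, with its MD5 hash, in `manifest.json`. All stage outputs are
#' pure functions of (inputs, config, root seed).
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly a list with `files` (named MD5
#'   hashes), `winners`, `consensus`, `networks`, `ccps`, `survival`,
#'   `truth` (when synthetic), `timings`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config"))
    stop_config("config must be a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  paths <- character(0)
  emit <- function(path) paths <<- c(paths, path)

  ## --- stage 1: studies ---------------------------------------------------
  truth <- NULL
  if (!is.null(config$sim)) {
    gen <- gen_study_collection(config$sim)
    studies <- lapply(gen, `[[`, "study")
    truth <- lapply(gen, `[[`, "truth")
    names(truth) <- vapply(studies, `[[`, character(1), "study_id")
  } else {
    studies <- lapply(seq_along(config$studies), function(i) {
      s <- config$studies[[i]]
      read_expression_tsv(s$matrix, s$annotation,
                          study_id = s$id %||% sprintf("S%d", i))
    })
    for (i in seq_along(studies))
      studies[[i]]$disease_class <- config$studies[[i]]$disease_class %||% "LC"
  }
  ids <- vapply(studies, `[[`, character(1), "study_id")
  tick("load")

  ## --- stage 2: normalization --------------------------------------------
  norm <- lapply(studies, function(s) suppressMessages(normalize_study(s)))
  for (i in seq_along(norm)) {
    p <- file.path(out_dir, sprintf("norm_%s.tsv", ids[i]))
    write_expression_tsv(norm[[i]], p,
                         file.path(out_dir, sprintf("samples_%s.tsv", ids[i])))
    emit(p)
    emit(file.path(out_dir, sprintf("samples_%s.tsv", ids[i])))
  }
  tick("normalize")

  ## --- stage 3: SAM per study ---------------------------------------------
  probe_map <- if (!is.null(config$probe_map_path))
    read_probe_map(config$probe_map_path)
  sams <- lapply(seq_along(norm), function(i) {
    res <- suppressWarnings(sam_analysis(
      norm[[i]], q_threshold = config$q_threshold,
      fdr_ceiling = config$fdr_ceiling, B = config$permutations,
      seed = child_seed(config$seed, 1000L + i)))
    if (!is.null(probe_map)) res <- collapse_to_genes(res, probe_map)
    res$null_abs_d <- NULL
    p <- file.path(out_dir, sprintf("degs_%s.tsv", ids[i]))
    write_results_tsv(res$table, p)
    emit(p)
    res
  })
  tick("sam")

  ## --- stage 4: consensus -------------------------------------------------
  cons <- direction_matrix(sams, q_threshold = config$q_threshold)
  win <- winner_genes(cons, min_total = config$min_total,
                      min_lc = config$min_lc)
  dir_df <- data.frame(gene = rownames(cons$directions),
                       cons$directions, check.names = FALSE)
  p <- file.path(out_dir, "consensus_directions.tsv")
  write_results_tsv(dir_df, p); emit(p)
  p <- file.path(out_dir, "winners.tsv")
  write_results_tsv(win$support, p); emit(p)
  tick("consensus")

  ## --- stage 5: enrichment ------------------------------------------------
  enrich <- list()
  if (length(config$gmt_paths)) {
    universe <- rownames(cons$directions)
    for (gi in seq_along(config$gmt_paths)) {
      gmt <- read_gmt(config$gmt_paths[[gi]])
      nm <- names(config$gmt_paths)[gi] %||% sprintf("gmt%d", gi)
      for (dirn in c("up", "down")) {
        gl <- intersect(win[[dirn]], universe)
        if (!length(gl)) next
        tab <- enrich_collection(gl, gmt, universe)
        key <- sprintf("enrich_%s_%s", nm, dirn)
        p <- file.path(out_dir, paste0(key, ".tsv"))
        write_results_tsv(tab, p); emit(p)
        enrich[[key]] <- tab
      }
    }
  }
  tick("enrich")

  ## --- stage 6: networks + CCPs -------------------------------------------
  lc_ids <- ids[vapply(studies, `[[`, character(1), "disease_class") == "LC"]
  ld_ids <- setdiff(ids, lc_ids)
  ref_id <- config$network_study %||% lc_ids[1]
  net_genes <- unique(c(win$up, win$down, config$tf_genes))
  networks <- list()
  build_for <- function(id) {
    st <- norm[[match(id, ids)]]
    sim <- suppressWarnings(similarity_matrix(st, gene_subset = net_genes))
    scan <- threshold_scan(sim, grid = config$grid)
    tau <- select_threshold(scan, window = config$window,
                            min_edges = config$min_edges)
    net <- build_network(sim, tau)
    p <- file.path(out_dir, sprintf("network_%s.sif", id))
    write_graph_file(net, p, "sif"); emit(p)
    p <- file.path(out_dir, sprintf("network_%s_edges.tsv", id))
    write_graph_file(net, p, "edge_tsv"); emit(p)
    p <- file.path(out_dir, sprintf("threshold_scan_%s.tsv", id))
    write_results_tsv(as.data.frame(scan), p); emit(p)
    list(network = net, scan = scan, tau = tau)
  }
  ccps <- list()
  if (length(net_genes) >= 3) {
    networks[[ref_id]] <- build_for(ref_id)
    for (id in ld_ids) networks[[id]] <- build_for(id)
    ccp_counts <- list()
    for (id in ld_ids) {
      ccp <- ccp_intersection(networks[[ref_id]]$network, networks[[id]]$network)
      key <- sprintf("ccp_%s_vs_%s", ref_id, id)
      p <- file.path(out_dir, paste0(key, ".sif"))
      write_graph_file(ccp, p, "sif"); emit(p)
      ccps[[key]] <- ccp
      ccp_counts[[key]] <- data.frame(
        pair = key, n_nodes = length(ccp$nodes), n_edges = nrow(ccp$edges),
        n_components = length(unique(attr(ccp, "components"))))
    }
    if (length(ccp_counts)) {
      p <- file.path(out_dir, "ccp_counts.tsv")
      write_results_tsv(do.call(rbind, ccp_counts), p); emit(p)
    }
  }
  tick("network")

  ## --- stage 7: survival --------------------------------------------------
  surv_reports <- list()
  genes <- config$survival_genes
  if (identical(genes, "hubs") && length(networks))
    genes <- head(hub_rank(networks[[ref_id]]$network, 3)$gene, 3)
  if (is.character(genes) && length(genes) && !identical(genes, "hubs")) {
    hr_true <- if (!is.null(config$sim)) config$sim$true_hr else 2
    for (gi in seq_along(genes)) {
      cohort <- gen_survival_cohort(config$survival_n, true_hr = hr_true,
                                    censor_rate = config$censor_rate,
                                    seed = child_seed(config$seed, 2000L + gi))
      rep <- gene_survival_report(cohort$expression, cohort, gene = genes[gi])
      surv_reports[[genes[gi]]] <- rep
    }
    surv_df <- do.call(rbind, lapply(surv_reports, function(r)
      data.frame(gene = r$gene, hr = r$hr, ci_lower = r$ci_lower,
                 ci_upper = r$ci_upper, logrank_p = r$logrank_p,
                 n_high = r$n_high, n_low = r$n_low)))
    if (!is.null(surv_df)) {
      p <- file.path(out_dir, "survival_reports.tsv")
      write_results_tsv(surv_df, p); emit(p)
    }
  }
  tick("survival")

  ## --- manifest -------------------------------------------------------------
  hashes <- tools::md5sum(paths)
  names(hashes) <- basename(names(hashes))
  manifest <- list(
    package = "coexmeta",
    seed = config$seed,
    settings = list(q_threshold = config$q_threshold,
                    fdr_ceiling = config$fdr_ceiling,
                    permutations = config$permutations,
                    min_total = config$min_total, min_lc = config$min_lc,
                    window = config$window, min_edges = config$min_edges),
    studies = ids,
    files = as.list(hashes),
    timings = timings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(files = hashes, manifest = manifest, consensus = cons,
                 winners = win, networks = networks, ccps = ccps,
                 enrichment = enrich, survival = surv_reports,
                 sams = sams, truth = truth))
}
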