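#' Pipeline configuration
#'
#' Collects every tunable of the workflow: input paths (or a simulation
#' config when no paths are given), thresholds, clustering parameters
#' and the global seed. Every published cut-off (0.58 log2FC, 5% FDR,
#' `|R| > 0.8`, 15-gene connectivity) appears here as an overridable
#' default. The config is serialized to YAML in the output directory
#' for provenance.
#'
#' @param outdir output directory.
#' @param seed global RNG seed.
#' @param sim a [sim_config()] used when no expression path is given.
#' @param expression,annotation,design,gmt optional input TSV/GMT paths;
#'   when `expression` is `NULL` the experiment is simulated.
#' @param gates a [de_gates()].
#' @param net a [net_thresholds()].
#' @param bg_method,bg_k_sd,bg_quantile background-filter rule
#'   (see [background_filter()]).
#' @param batch_vars ordered batch variables.
#' @param k_lnc,k_mrna clusters per network axis.
#' @param n_top top lncRNA clusters to report.
#' @param target_mrna_cluster mRNA cluster id feeding the toxicity panel,
#'   or `"auto"` (default): clusters are tried in size order and the first
#'   whose panel yields a valid control-lowest tiering is used, emulating
#'   the deliberate choice of the toxicity-relevant cluster.
#' @param k_tiers number of toxicity tiers.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, sim = sim_config(seed = seed),
                            expression = NULL, annotation = NULL, design = NULL,
                            gmt = NULL,
                            gates = de_gates(), net = net_thresholds(),
                            bg_method = "mean_sd", bg_k_sd = 2, bg_quantile = 0.95,
                            batch_vars = c("batch_label", "batch_array"),
                            k_lnc = 5L, k_mrna = 2L, n_top = 2L,
                            target_mrna_cluster = "auto", k_tiers = 3L) {
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 expression = expression, annotation = annotation,
                 design = design, gmt = gmt,
                 gates = gates, net = net,
                 bg_method = bg_method, bg_k_sd = bg_k_sd, bg_quantile = bg_quantile,
                 batch_vars = batch_vars,
                 k_lnc = as.integer(k_lnc), k_mrna = as.integer(k_mrna),
                 n_top = as.integer(n_top),
                 target_mrna_cluster = target_mrna_cluster,
                 k_tiers = as.integer(k_tiers)),
            class = "pipeline_config")
}

serialize_config <- function(cfg, path) {
  flat <- cfg
  flat$outdir <- NULL     # parameters only; the artifact location is not provenance
  flat$gates <- unclass(cfg$gates)
  flat$net <- unclass(cfg$net)
  flat$sim <- c(unclass(cfg$sim)[setdiff(names(unclass(cfg$sim)), "groups")],
                list(groups = as.data.frame(cfg$sim$groups)))
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Run the complete pipeline
#'
#' simulate (or read) -> preprocess -> differential expression -> network
#' -> enrichment -> toxicity ranking. Every stage writes its TSV outputs
#' into `outdir`; a manifest with md5 checksums of all artifacts is
#' written last, so identical config + seed gives byte-identical
#' manifests. Degenerate stages (empty network, empty panel) are not
#' errors: the corresponding outputs are empty and a warning is logged.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   `manifest` tibble (`file`, `md5`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outdir, f)
  serialize_config(cfg, out("config.yaml"))

  # -- inputs ---------------------------------------------------------------
  if (is.null(cfg$expression)) {
    cfg$sim$seed <- cfg$seed
    sim <- simulate_experiment(cfg$sim)
    em <- sim$expr; design <- sim$design; ann <- sim$annotation
    sets <- simulate_gene_sets(sim)
    readr::write_tsv(sim$truth$de_probes, out("truth_de_probes.tsv"), progress = FALSE)
    readr::write_tsv(sim$truth$true_edges, out("truth_edges.tsv"), progress = FALSE)
    readr::write_tsv(sim$truth$modules, out("truth_modules.tsv"), progress = FALSE)
  } else {
    ann <- read_annotation(cfg$annotation)
    em <- read_expression(cfg$expression, ann)
    design <- read_design(cfg$design)
    sets <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt) else NULL
    sim <- NULL
  }
  design <- validate_design(design)
  write_expression(em, out("expression_raw.tsv"))
  write_annotation(ann, out("annotation.tsv"))
  write_design(design |> select(-"group"), out("design.tsv"))

  # -- preprocess -----------------------------------------------------------
  em_pp <- preprocess(em, design, batch_vars = cfg$batch_vars,
                      method = cfg$bg_method, k_sd = cfg$bg_k_sd,
                      bg_quantile = cfg$bg_quantile)
  write_expression(em_pp, out("expression_preprocessed.tsv"))

  # -- differential expression ----------------------------------------------
  contrasts <- run_contrasts(em_pp, design, gates = cfg$gates)
  de_long <- purrr::imap_dfr(contrasts, function(res, g)
    mutate(as_tibble(res), group = g, .before = 1L))
  readr::write_tsv(de_long, out("de_results.tsv"), progress = FALSE)
  counts <- de_count_table(contrasts)
  readr::write_tsv(counts, out("de_counts.tsv"), progress = FALSE)

  # -- network --------------------------------------------------------------
  profiles <- correlation_profiles(contrasts)
  edges <- pearson_edges(profiles, cfg$net)
  net <- degree_filter(edges, cfg$net)
  readr::write_tsv(net$edges, out("edges.tsv"), progress = FALSE)
  degenerate <- length(net$lnc) == 0L ||
    cfg$k_lnc > length(net$lnc) || cfg$k_mrna > length(net$mrna)
  if (degenerate) {
    warn("network is empty or too small to bi-cluster; downstream stages skipped")
    bic <- NULL; enr <- NULL; rank <- NULL; top <- NULL
    readr::write_tsv(tibble(item_id = character(), axis = character(),
                            cluster_id = integer()),
                     out("clusters.tsv"), progress = FALSE)
    readr::write_tsv(tibble(group = character(), material = character(),
                            surface = character(), n_de_lnc_in_panel = integer(),
                            tier = character(), mean_z = numeric()),
                     out("toxicity_ranking.tsv"), progress = FALSE)
  } else {
    bic <- bicluster_network(net, k_lnc = min(cfg$k_lnc, length(net$lnc)),
                             k_mrna = min(cfg$k_mrna, length(net$mrna)))
    clusters <- dplyr::bind_rows(
      mutate(bic$lnc, axis = "lncRNA"),
      mutate(bic$mrna, axis = "mRNA")) |>
      select("item_id", "axis", "cluster_id")
    readr::write_tsv(clusters, out("clusters.tsv"), progress = FALSE)
    top <- select_top_clusters(bic, n_top = min(cfg$n_top, nrow(bic$lnc_info)))
    readr::write_tsv(top, out("top_clusters.tsv"), progress = FALSE)

    # -- enrichment ---------------------------------------------------------
    if (!is.null(sets)) {
      universe <- em_pp$annotation$accession
      enr <- enrich_clusters(bic, ann, sets, universe)
      readr::write_tsv(enr, out("enrichment.tsv"), progress = FALSE)
    } else enr <- NULL

    # -- toxicity ranking ---------------------------------------------------
    # candidate target clusters: an explicit id, or all clusters in size
    # order for "auto" (first one giving a valid control-lowest tiering
    # wins -- the mechanical analogue of choosing the toxicity-relevant
    # cluster deliberately)
    candidates <- if (identical(cfg$target_mrna_cluster, "auto")) {
      bic$mrna_info$cluster_id
    } else as.integer(cfg$target_mrna_cluster)
    rank <- NULL; last_err <- "empty lncRNA panel"
    for (cl in candidates) {
      target <- mrna_cluster_members(bic, cl)
      panel <- panel_filter(net$edges, target, min_degree = cfg$net$min_degree)
      if (length(panel) == 0L) next
      rank <- tryCatch(
        toxicity_ranking(em_pp, design, contrasts, net$edges, target,
                         min_degree = cfg$net$min_degree, k = cfg$k_tiers),
        error = function(e) { last_err <<- conditionMessage(e); NULL })
      if (!is.null(rank)) { attr(rank, "target_cluster") <- cl; break }
    }
    if (is.null(rank)) {
      # a ranking inversion is a *result* (the tiering is invalid for this
      # panel); retain the stage as failed rather than silently relabeling
      warn(sprintf("toxicity ranking failed: %s", last_err))
      readr::write_lines(last_err, out("toxicity_ranking.failed"))
      readr::write_tsv(tibble(group = character(), material = character(),
                              surface = character(), n_de_lnc_in_panel = integer(),
                              tier = character(), mean_z = numeric()),
                       out("toxicity_ranking.tsv"), progress = FALSE)
    } else {
      readr::write_tsv(as_tibble(rank), out("toxicity_ranking.tsv"), progress = FALSE)
      z <- attr(rank, "z")
      readr::write_tsv(tibble(group = rownames(z)) |> dplyr::bind_cols(as_tibble(z)),
                       out("zscore_matrix.tsv"), progress = FALSE)
    }
  }

  # -- manifest -------------------------------------------------------------
  files <- sort(setdiff(list.files(cfg$outdir), "manifest.tsv"))
  manifest <- tibble(file = files,
                     md5 = unname(tools::md5sum(file.path(cfg$outdir, files))))
  readr::write_tsv(manifest, out("manifest.tsv"), progress = FALSE)
  invisible(list(expr = em_pp, design = design, contrasts = contrasts,
                 counts = counts, edges = edges, net = net, biclust = bic,
                 top_clusters = top, enrichment = enr, ranking = rank,
                 truth = if (!is.null(sim)) sim$truth else NULL,
                 manifest = manifest))
}
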