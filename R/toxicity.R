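#' Filter the lncRNA panel by connectivity to a target mRNA cluster
#'
#' Keeps every lncRNA with at least `min_degree` surviving correlation
#' edges into the target mRNA cluster (edges elsewhere do not count).
#'
#' @param edges edge tibble (post [degree_filter()] or raw
#'   [pearson_edges()] output).
#' @param target_mrna character vector of mRNA ids forming the target
#'   cluster.
#' @param min_degree minimum within-cluster connectivity.
#' @return Character vector of panel lncRNA ids.
#' @export
panel_filter <- function(edges, target_mrna, min_degree = 15L) {
  assert_cols(edges, c("lnc_id", "mrna_id"), "edge table")
  if (length(target_mrna) == 0L) abort("target mRNA cluster is empty")
  deg <- edges |>
    filter(.data$mrna_id %in% target_mrna) |>
    count(.data$lnc_id)
  sort(deg$lnc_id[deg$n >= min_degree])
}

#' Per-group mean Z-scores of a lncRNA panel
#'
#' Each panel probe's log2 intensities are Z-scored across all samples
#' (mean 0, SD 1), then averaged within each exposure group (controls
#' included). Constant probes have undefined Z and are dropped with a
#' warning.
#'
#' @param em log2-scale [expr_matrix].
#' @param design validated design tibble.
#' @param panel character vector of panel probe ids.
#' @return groups x panel numeric matrix of mean Z-scores.
#' @export
zscore_group_matrix <- function(em, design, panel) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "log2") abort("zscore_group_matrix expects a log2-scale matrix")
  design <- validate_design(design)
  validate_dataset(em, design)
  missing <- setdiff(panel, rownames(em$values))
  if (length(missing) > 0L) {
    abort(sprintf("panel probe(s) absent from matrix: %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  x <- em$values[panel, , drop = FALSE]
  sds <- apply(x, 1L, sd)
  if (any(sds == 0)) {
    warn(sprintf("%d constant panel probe(s) dropped (Z undefined)", sum(sds == 0)))
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) == 0L) abort("every panel probe is constant; Z-score matrix undefined")
  }
  z <- (x - rowMeans(x)) / apply(x, 1L, sd)
  design <- design[match(colnames(z), design$sample_id), ]
  groups <- sort(unique(design$group))
  out <- t(vapply(groups, function(g)
    rowMeans(z[, design$group == g, drop = FALSE]), numeric(nrow(z))))
  rownames(out) <- groups
  out
}

#' Cluster exposure groups into toxicity tiers
#'
#' Hierarchically clusters the group rows of the panel Z-score matrix
#' (Euclidean distance, average linkage), cuts the tree into `k`
#' clusters, and orders clusters by mean panel expression ascending.
#' Tier validity is a result, not an assumption: if the cluster holding
#' the control groups is not the lowest-expression cluster, the run
#' errors flagging a ranking inversion. With `k = 3` the tiers are
#' labeled `control_low`, `medium`, `high`.
#'
#' @param z groups x panel matrix from [zscore_group_matrix()].
#' @param k number of tiers.
#' @return Tibble of class `tox_tiers`: `group`, `tier` (ordered
#'   factor), `mean_z`; attribute `hclust`.
#' @export
tier_exposures <- function(z, k = 3L) {
  if (!is.matrix(z) || is.null(rownames(z))) abort("z must be a matrix with group rownames")
  groups <- rownames(z)
  controls <- groups[startsWith(groups, "control")]
  mean_z <- rowMeans(z)
  d <- dist(z)
  labels_for <- function(kk) {
    if (kk == 3L) c("control_low", "medium", "high") else paste0("tier_", seq_len(kk))
  }
  if (k == 1L || nrow(z) == 1L) {
    memb <- rep(1L, nrow(z)); kk <- 1L
  } else if (max(d) == 0) {
    warn("all exposure groups have identical panel profiles; single degenerate tier")
    memb <- rep(1L, nrow(z)); kk <- 1L
  } else {
    if (k > nrow(z)) abort("k exceeds the number of exposure groups")
    hc <- hclust(d, method = "average")
    memb <- cutree(hc, k = k); kk <- k
  }
  cl_mean <- vapply(seq_len(kk), function(cl) mean(mean_z[memb == cl]), 0)
  ord <- order(cl_mean)                      # ascending mean panel expression
  tier_of <- integer(kk); tier_of[ord] <- seq_len(kk)
  tiers <- labels_for(kk)[tier_of[memb]]
  if (length(controls) > 0L && kk > 1L) {
    ctrl_tiers <- tier_of[memb[match(controls, groups)]]
    if (any(ctrl_tiers != 1L)) {
      abort("ranking inversion: control group(s) do not fall in the lowest-expression tier")
    }
  }
  out <- tibble(group = groups,
                tier = factor(tiers, levels = labels_for(kk), ordered = TRUE),
                mean_z = unname(mean_z)) |>
    arrange(.data$tier, .data$mean_z)
  structure(out, class = c("tox_tiers", class(out)),
            hclust = if (exists("hc", inherits = FALSE)) hc else NULL, k = kk)
}

#' Count panel lncRNAs that are DE per exposure group
#'
#' @param contrasts named list of gated contrast tibbles.
#' @param panel character vector of panel lncRNA ids.
#' @return Tibble `group`, `n_de_lnc_in_panel`.
#' @export
panel_de_counts <- function(contrasts, panel) {
  purrr::imap_dfr(contrasts, function(res, g) {
    part <- de_partition(res)
    tibble(group = g, n_de_lnc_in_panel = length(intersect(part$lnc, panel)))
  })
}

#' Full toxicity ranking of exposure groups
#'
#' Combines [panel_filter()], [zscore_group_matrix()],
#' [tier_exposures()] and [panel_de_counts()] into the final ranking
#' table.
#'
#' @param em preprocessed log2-scale [expr_matrix].
#' @param design validated design tibble.
#' @param contrasts named list of gated contrast tibbles.
#' @param edges edge tibble.
#' @param target_mrna mRNA ids of the target cluster.
#' @param min_degree panel connectivity threshold.
#' @param k number of tiers.
#' @return Tibble of class `tox_ranking`: `group`, `material`,
#'   `surface`, `n_de_lnc_in_panel`, `tier`, `mean_z`; attributes
#'   `panel` and `z` (the group x panel matrix).
#' @export
toxicity_ranking <- function(em, design, contrasts, edges, target_mrna,
                             min_degree = 15L, k = 3L) {
  design <- validate_design(design)
  panel <- panel_filter(edges, target_mrna, min_degree = min_degree)
  if (length(panel) == 0L) abort("empty lncRNA panel; no ranking possible")
  z <- zscore_group_matrix(em, design, panel)
  tiers <- tier_exposures(z, k = k)
  counts <- panel_de_counts(contrasts, panel)
  meta <- design |> distinct(.data$group, .data$material, .data$surface)
  out <- tiers |>
    left_join(counts, by = "group") |>
    left_join(meta, by = "group") |>
    mutate(n_de_lnc_in_panel = dplyr::coalesce(.data$n_de_lnc_in_panel, 0L)) |>
    select("group", "material", "surface", "n_de_lnc_in_panel", "tier", "mean_z")
  structure(out, class = c("tox_ranking", class(out)),
            panel = panel, z = z, hclust = attr(tiers, "hclust"))
}
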