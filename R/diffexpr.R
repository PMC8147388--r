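#' Differential-expression gates
#'
#' The fold-change and FDR cut-offs used throughout: a minimum absolute
#' log2 difference of 0.58 (a 1.5-fold change) and a Benjamini-Hochberg
#' FDR of at most 5 percent, both inclusive.
#'
#' @param min_abs_log2fc minimum absolute log2 fold change.
#' @param max_q maximum BH-adjusted FDR.
#' @return A named list of class `de_gates`.
#' @export
de_gates <- function(min_abs_log2fc = 0.58, max_q = 0.05) {
  if (min_abs_log2fc <= 0 || max_q <= 0) abort("gates must be positive")
  structure(list(min_abs_log2fc = min_abs_log2fc, max_q = max_q), class = "de_gates")
}

match_control_group <- function(design, group) {
  design <- validate_design(design)
  rows <- design[design$group == group, ]
  if (nrow(rows) == 0L) abort(sprintf("unknown exposure group '%s'", group))
  disp <- unique(rows$dispersant)
  paste0("control_", disp[1L])
}

#' Moderated two-group differential expression for one exposure contrast
#'
#' Per probe: an ordinary two-group fit (exposed minus dispersant-matched
#' control), pooled residual variance, then empirical-Bayes shrinkage of
#' the residual variances toward a common prior (method-of-moments fit of
#' a scaled inverse-chi-square prior with d0 degrees of freedom and scale
#' s0^2, via [limma::squeezeVar()]). The moderated t is the log2FC over
#' its posterior standard error, with d0 + residual degrees of freedom;
#' p-values are two-sided; q is BH-adjusted within the contrast.
#'
#' @param em log2-scale [expr_matrix] (preprocessed).
#' @param design validated design tibble.
#' @param group exposure group label (e.g. `"CuO-Core"`).
#' @param d0_override optionally force the prior degrees of freedom:
#'   `0` gives the ordinary unmoderated pooled-variance t, `Inf` full
#'   shrinkage to the common variance. Default `NULL` (estimated).
#' @return A tibble of class `lnc_de` with `probe_id`, `accession`,
#'   `biotype`, `log2fc`, `t_mod`, `p`, `q`; attributes `group`,
#'   `df_prior`, `s2_prior`, `df_residual`.
#' @export
moderated_de <- function(em, design, group, d0_override = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "log2") abort("moderated_de expects a log2-scale matrix")
  design <- validate_design(design)
  validate_dataset(em, design)
  ctrl <- match_control_group(design, group)
  exp_ids <- design$sample_id[design$group == group]
  ctl_ids <- design$sample_id[design$group == ctrl]
  n1 <- length(exp_ids); n2 <- length(ctl_ids)
  if (n1 < 2L || n2 < 2L) {
    abort(sprintf("contrast %s vs %s needs >= 2 replicates per side (got %d, %d)",
                  group, ctrl, n1, n2))
  }
  x1 <- em$values[, exp_ids, drop = FALSE]
  x2 <- em$values[, ctl_ids, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  df_res <- n1 + n2 - 2L
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s2 <- ss / df_res
  if (all(s2 == 0)) abort("zero residual variance in every probe; cannot moderate")
  sq <- limma::squeezeVar(s2, df = df_res)
  d0 <- sq$df.prior
  s02 <- sq$var.prior
  if (!is.null(d0_override)) {
    d0 <- d0_override
    s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
      (d0 * s02 + df_res * s2) / (d0 + df_res)
  } else {
    s2_post <- sq$var.post
  }
  lfc <- m1 - m2
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, lfc / se, 0)
  # degrees of freedom d0 + residual, capped at the pooled total as in limma
  df_total <- min(d0 + df_res, length(s2) * df_res)
  p <- 2 * pt(-abs(t_mod), df = df_total)
  res <- tibble(probe_id = rownames(em$values),
                accession = em$annotation$accession,
                biotype = em$annotation$biotype,
                log2fc = unname(lfc),
                t_mod = unname(t_mod),
                p = unname(p),
                q = bh_adjust(unname(p)))
  structure(res, class = c("lnc_de", class(res)),
            group = group, control = ctrl,
            df_prior = d0, s2_prior = s02, df_residual = df_res)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_i = min_{j >= rank(i)} m * p_(j) / j`, clipped at 1 and
#' order-preserving in p. Thin, validated wrapper over
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Apply fold-change and FDR gates to a contrast result
#'
#' A probe passes iff `|log2fc| >= min_abs_log2fc` and `q <= max_q`
#' (inclusive bounds on both).
#'
#' @param results contrast tibble from [moderated_de()].
#' @param gates a [de_gates()].
#' @return The input with a logical `passes_gate` column.
#' @export
gate_de <- function(results, gates = de_gates()) {
  assert_cols(results, c("log2fc", "q"), "contrast result")
  results$passes_gate <- abs(results$log2fc) >= gates$min_abs_log2fc &
    results$q <= gates$max_q
  results
}

#' Partition gated probes into lncRNA and mRNA sets
#'
#' @param gated gated contrast tibble (see [gate_de()]).
#' @param collapse logical; if `TRUE`, probes mapping to one accession
#'   are collapsed to the probe with maximum `|t_mod|` before counting
#'   unique transcripts.
#' @return List with character vectors `lnc` and `mrna` of passing probe ids.
#' @export
de_partition <- function(gated, collapse = FALSE) {
  assert_cols(gated, c("probe_id", "biotype", "passes_gate"), "gated result")
  hits <- gated |> filter(.data$passes_gate)
  if (collapse) {
    hits <- hits |>
      group_by(.data$accession) |>
      dplyr::slice_max(abs(.data$t_mod), n = 1L, with_ties = FALSE) |>
      ungroup()
  }
  list(lnc = hits$probe_id[hits$biotype == "lncRNA"],
       mrna = hits$probe_id[hits$biotype == "mRNA"])
}

#' Run every exposure-vs-control contrast
#'
#' @param em preprocessed log2-scale [expr_matrix].
#' @param design validated design tibble.
#' @param gates a [de_gates()]; gating columns are added to each result.
#' @return Named list of gated contrast tibbles, one per exposure group.
#' @export
run_contrasts <- function(em, design, gates = de_gates()) {
  design <- validate_design(design)
  groups <- design |> filter(.data$material != "control") |>
    distinct(.data$group) |> pull(.data$group)
  purrr::map(setNames(groups, groups),
             function(g) gate_de(moderated_de(em, design, g), gates))
}

#' Per-group counts of differentially expressed transcripts
#'
#' @param contrasts named list of gated contrast tibbles
#'   (see [run_contrasts()]).
#' @param collapse collapse probes to unique accessions (see
#'   [de_partition()]).
#' @return Tibble `group`, `n_lnc`, `n_mrna`.
#' @export
de_count_table <- function(contrasts, collapse = FALSE) {
  purrr::imap_dfr(contrasts, function(res, g) {
    part <- de_partition(res, collapse = collapse)
    tibble(group = g, n_lnc = length(part$lnc), n_mrna = length(part$mrna))
  })
}
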