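#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a moderated differential-expression result
#'
#' @param x an `lnc_de` tibble from [moderated_de()].
#' @param ... unused.
#' @return A plain tibble of per-probe statistics.
#' @method tidy lnc_de
#' @export
tidy.lnc_de <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a moderated DE contrast
#'
#' @param x an `lnc_de` tibble.
#' @param gates a [de_gates()] used for the pass counts.
#' @param ... unused.
#' @return Tibble with the contrast, shrinkage hyperparameters and pass
#'   counts.
#' @method glance lnc_de
#' @export
glance.lnc_de <- function(x, gates = de_gates(), ...) {
  gated <- gate_de(x, gates)
  part <- de_partition(gated)
  tibble(group = attr(x, "group"), control = attr(x, "control"),
         n_probes = nrow(x),
         df_prior = attr(x, "df_prior"), s2_prior = attr(x, "s2_prior"),
         df_residual = attr(x, "df_residual"),
         n_de_lnc = length(part$lnc), n_de_mrna = length(part$mrna))
}

#' Tidy a toxicity ranking
#'
#' @param x a `tox_ranking` from [toxicity_ranking()].
#' @param ... unused.
#' @return A plain tibble.
#' @method tidy tox_ranking
#' @export
tidy.tox_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a toxicity ranking
#'
#' @param x a `tox_ranking`.
#' @param ... unused.
#' @return Tibble with panel size and per-tier group counts.
#' @method glance tox_ranking
#' @export
glance.tox_ranking <- function(x, ...) {
  tiers <- table(x$tier)
  out <- tibble(panel_size = length(attr(x, "panel")), n_groups = nrow(x))
  for (nm in names(tiers)) out[[paste0("n_", nm)]] <- as.integer(tiers[[nm]])
  out
}

#' Tidy a bi-clustered network
#'
#' @param x a `conet_biclust`.
#' @param ... unused.
#' @return Tibble `item_id`, `axis`, `cluster_id`.
#' @method tidy conet_biclust
#' @export
tidy.conet_biclust <- function(x, ...) {
  dplyr::bind_rows(mutate(x$lnc, axis = "lncRNA"),
                   mutate(x$mrna, axis = "mRNA")) |>
    select("item_id", "axis", "cluster_id")
}

#' One-row summary of a bi-clustered network
#'
#' @param x a `conet_biclust`.
#' @param ... unused.
#' @return Tibble with axis sizes, cluster counts and the share of
#'   lncRNAs in the top two clusters.
#' @method glance conet_biclust
#' @export
glance.conet_biclust <- function(x, ...) {
  top <- select_top_clusters(x, n_top = min(2L, nrow(x$lnc_info)))
  tibble(n_lnc = nrow(x$r_matrix), n_mrna = ncol(x$r_matrix),
         k_lnc = nrow(x$lnc_info), k_mrna = nrow(x$mrna_info),
         top2_lnc_fraction = top$fraction[nrow(top)])
}
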