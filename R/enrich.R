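#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail test per gene set: with a universe of size N, a
#' set of size K (after intersection with the universe) and a query of
#' size n, the p-value is `P[X >= overlap]` for
#' `X ~ Hypergeometric(N, K, n)`. q-values are BH-adjusted across all
#' tested sets; results are sorted by q.
#'
#' @param query character vector of accessions; must be a subset of
#'   `universe`.
#' @param sets gene-set tibble (see [read_gmt()]).
#' @param universe character vector of accessions defining the testable
#'   universe (typically: all accessions on the filtered array).
#' @return Tibble `set_id`, `set_name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `q`.
#' @export
hypergeom_enrich <- function(query, sets, universe) {
  query <- unique(query); universe <- unique(universe)
  if (length(query) == 0L) abort("empty query")
  if (length(universe) == 0L) abort("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    abort(sprintf("query contains accession(s) outside the universe: %s",
                  paste(head(outside, 5L), collapse = ", ")))
  }
  assert_cols(sets, c("set_id", "set_name", "members"), "gene-set collection")
  N <- length(universe); n <- length(query)
  res <- purrr::map_dfr(seq_len(nrow(sets)), function(i) {
    members <- intersect(sets$members[[i]], universe)
    K <- length(members)
    ov <- length(intersect(query, members))
    p <- if (K == 0L) 1 else phyper(ov - 1L, K, N - K, n, lower.tail = FALSE)
    tibble(set_id = sets$set_id[i], set_name = sets$set_name[i],
           overlap = ov, set_size = K, query_size = n, universe_size = N,
           p = min(p, 1))
  })
  res$q <- bh_adjust(res$p)
  res |> arrange(.data$q, .data$p, .data$set_id)
}

#' Enrichment of every mRNA cluster
#'
#' Runs [hypergeom_enrich()] once per mRNA cluster of a bi-clustered
#' network, mapping probe ids to accessions first; sets with
#' `q <= sig_q` are flagged significant.
#'
#' @param bic a [bicluster_network()] result (or a tibble `item_id`,
#'   `cluster_id` of mRNA probe ids).
#' @param annotation probe annotation tibble (probe_id -> accession).
#' @param sets gene-set tibble.
#' @param universe character vector of accessions.
#' @param sig_q significance threshold on q.
#' @return Tibble of per-cluster results with `cluster_id` and
#'   `significant` columns.
#' @export
enrich_clusters <- function(bic, annotation, sets, universe, sig_q = 0.05) {
  assignment <- if (inherits(bic, "conet_biclust")) bic$mrna else bic
  assert_cols(assignment, c("item_id", "cluster_id"), "mRNA cluster assignment")
  if (nrow(assignment) == 0L) abort("empty mRNA cluster assignment; nothing to enrich")
  acc_of <- setNames(annotation$accession, annotation$probe_id)
  purrr::map_dfr(sort(unique(assignment$cluster_id)), function(cl) {
    ids <- assignment$item_id[assignment$cluster_id == cl]
    if (length(ids) == 0L) abort(sprintf("mRNA cluster %s is empty", cl))
    query <- unname(acc_of[ids])
    if (anyNA(query)) abort("mRNA cluster member missing from annotation")
    hypergeom_enrich(query, sets, universe) |>
      mutate(cluster_id = cl, significant = .data$q <= sig_q, .before = 1L)
  })
}
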