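#' Network thresholds for guilt-by-association edges
#'
#' Defaults follow the published rule: Pearson `|R| > 0.8` with raw
#' `p < 0.05` (both strict), and a lncRNA is retained only if connected
#' to at least 15 mRNAs.
#'
#' @param min_abs_r minimum absolute Pearson correlation (strict).
#' @param max_p maximum two-sided p-value (strict).
#' @param min_degree minimum mRNA connectivity per lncRNA.
#' @return Named list of class `net_thresholds`.
#' @export
net_thresholds <- function(min_abs_r = 0.8, max_p = 0.05, min_degree = 15L) {
  if (min_abs_r <= 0 || min_abs_r > 1) abort("min_abs_r must lie in (0, 1]")
  if (min_degree < 1L) abort("min_degree must be >= 1")
  structure(list(min_abs_r = min_abs_r, max_p = max_p,
                 min_degree = as.integer(min_degree)),
            class = "net_thresholds")
}

#' Cross-contrast log2FC profiles of DE transcripts
#'
#' The correlation substrate: for every transcript differentially
#' expressed (passing the gates) in at least one contrast, the vector of
#' its log2 fold changes across all exposure contrasts. Profiles use the
#' log2FC from every contrast, significant or not, so vectors are
#' complete.
#'
#' @param contrasts named list of gated contrast tibbles
#'   (see [run_contrasts()]); at least 3 contrasts are required for
#'   Pearson p-values to be meaningful.
#' @return List with matrices `lnc` and `mrna` (transcripts x contrasts).
#' @export
correlation_profiles <- function(contrasts) {
  if (length(contrasts) < 3L) abort("need >= 3 contrasts to build correlation profiles")
  first <- contrasts[[1L]]
  assert_cols(first, c("probe_id", "biotype", "log2fc", "passes_gate"), "contrast result")
  lfc <- vapply(contrasts, function(x) x$log2fc[match(first$probe_id, x$probe_id)],
                numeric(nrow(first)))
  rownames(lfc) <- first$probe_id
  hit <- Reduce(`|`, lapply(contrasts, function(x)
    x$passes_gate[match(first$probe_id, x$probe_id)]))
  list(lnc = lfc[hit & first$biotype == "lncRNA", , drop = FALSE],
       mrna = lfc[hit & first$biotype == "mRNA", , drop = FALSE])
}

#' Thresholded lncRNA-mRNA Pearson edges
#'
#' Pearson correlation of every DE lncRNA profile against every DE mRNA
#' profile; two-sided p from `t = r * sqrt((n - 2) / (1 - r^2))` with
#' `n - 2` degrees of freedom. An edge survives iff `|r| > min_abs_r`
#' and `p < max_p`, both strict. Zero-variance profiles contribute no
#' edges and are skipped with a warning.
#'
#' @param profiles result of [correlation_profiles()].
#' @param th a [net_thresholds()].
#' @return Edge tibble `lnc_id`, `mrna_id`, `r`, `p`, `n`.
#' @export
pearson_edges <- function(profiles, th = net_thresholds()) {
  lnc <- profiles$lnc; mrna <- profiles$mrna
  n <- ncol(lnc)
  if (n < 3L) abort("profiles must span >= 3 contrasts")
  drop_const <- function(m, what) {
    const <- apply(m, 1L, function(x) sd(x) == 0)
    if (any(const)) {
      warn(sprintf("%d constant %s profile(s) skipped (zero variance): %s",
                   sum(const), what, paste(head(rownames(m)[const], 3L), collapse = ", ")))
    }
    m[!const, , drop = FALSE]
  }
  lnc <- drop_const(lnc, "lncRNA"); mrna <- drop_const(mrna, "mRNA")
  empty <- tibble(lnc_id = character(), mrna_id = character(),
                  r = numeric(), p = numeric(), n = integer())
  if (nrow(lnc) == 0L || nrow(mrna) == 0L) return(empty)
  r <- cor(t(lnc), t(mrna))
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  keep <- abs(r) > th$min_abs_r & p < th$max_p
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  tibble(lnc_id = rownames(r)[idx[, 1L]],
         mrna_id = colnames(r)[idx[, 2L]],
         r = r[idx], p = p[idx], n = n) |>
    arrange(.data$lnc_id, .data$mrna_id)
}

#' Connectivity (degree) filter
#'
#' Retains lncRNAs connected to at least `min_degree` mRNAs, then mRNAs
#' with at least one edge to a retained lncRNA, and restricts the edge
#' table accordingly.
#'
#' @param edges edge tibble from [pearson_edges()].
#' @param th a [net_thresholds()].
#' @return List `lnc` (kept lncRNA ids), `mrna` (kept mRNA ids), `edges`.
#' @export
degree_filter <- function(edges, th = net_thresholds()) {
  assert_cols(edges, c("lnc_id", "mrna_id"), "edge table")
  deg <- edges |> count(.data$lnc_id)
  kept_lnc <- deg$lnc_id[deg$n >= th$min_degree]
  edges <- edges |> filter(.data$lnc_id %in% kept_lnc)
  kept_mrna <- unique(edges$mrna_id)
  list(lnc = sort(kept_lnc), mrna = sort(kept_mrna), edges = edges)
}

cluster_heights <- function(hc, assignment, k) {
  # height at which each cutree cluster is fully formed (0 for singletons)
  heights <- setNames(rep(0, k), seq_len(k))
  if (length(hc$height) == 0L) return(heights)
  memb <- cutree(hc, k = k)
  n <- length(memb)
  merge_members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    get_side <- function(v) if (v < 0) -v else merge_members[[v]]
    merge_members[[i]] <- c(get_side(hc$merge[i, 1L]), get_side(hc$merge[i, 2L]))
    cl <- unique(memb[merge_members[[i]]])
    if (length(cl) == 1L) heights[as.character(cl)] <- max(heights[as.character(cl)], hc$height[i])
  }
  heights
}

relabel_by_size <- function(memb, heights) {
  sizes <- table(memb)
  info <- tibble(old = as.integer(names(sizes)), size = as.integer(sizes),
                 height = unname(heights[names(sizes)]))
  info <- info |> arrange(desc(.data$size), .data$height, .data$old)
  map <- setNames(seq_len(nrow(info)), info$old)
  list(memb = unname(map[as.character(memb)]), info = info |>
         mutate(cluster_id = seq_len(nrow(info))) |>
         select("cluster_id", "size", "height"))
}

#' Bi-cluster the lncRNA x mRNA correlation matrix
#'
#' Builds the kept-lncRNA by kept-mRNA matrix of Pearson coefficients
#' (0 where no surviving edge), then hierarchically clusters each axis
#' (Euclidean distance, average linkage) and cuts the trees into `k_lnc`
#' and `k_mrna` clusters. Cluster ids are ordered by size descending;
#' ties broken by lower dendrogram formation height. An optional k-means
#' pre-partitioning (Perseus-style) can coarsen an axis before the
#' hierarchical step.
#'
#' @param net result of [degree_filter()].
#' @param k_lnc,k_mrna number of clusters per axis.
#' @param kmeans_k optional integer: pre-partition each axis into this
#'   many k-means cells and cluster the cell centroids instead.
#' @return Object of class `conet_biclust`: `r_matrix`, tibbles
#'   `lnc`/`mrna` (`item_id`, `cluster_id`), summaries `lnc_info` /
#'   `mrna_info` (`cluster_id`, `size`, `height`), and the two `hclust`
#'   trees.
#' @export
bicluster_network <- function(net, k_lnc = 5L, k_mrna = 2L, kmeans_k = NULL) {
  edges <- net$edges
  if (length(net$lnc) == 0L || length(net$mrna) == 0L) {
    abort("empty network: no lncRNAs or mRNAs survive the degree filter")
  }
  if (k_lnc > length(net$lnc) || k_mrna > length(net$mrna)) {
    abort("k exceeds the number of items on an axis")
  }
  r_mat <- matrix(0, nrow = length(net$lnc), ncol = length(net$mrna),
                  dimnames = list(net$lnc, net$mrna))
  r_mat[cbind(match(edges$lnc_id, net$lnc), match(edges$mrna_id, net$mrna))] <- edges$r

  cluster_axis <- function(m, k) {
    ids <- rownames(m)
    if (!is.null(kmeans_k) && kmeans_k < nrow(m) && kmeans_k > k) {
      km <- kmeans(m, centers = kmeans_k, nstart = 5L)
      hc <- hclust(dist(km$centers), method = "average")
      cell_cl <- cutree(hc, k = k)
      memb <- unname(cell_cl[km$cluster])
      heights <- cluster_heights(hc, NULL, k)
    } else {
      hc <- hclust(dist(m), method = "average")
      memb <- unname(cutree(hc, k = k))
      heights <- cluster_heights(hc, NULL, k)
    }
    rl <- relabel_by_size(memb, heights)
    list(tbl = tibble(item_id = ids, cluster_id = rl$memb), info = rl$info, hc = hc)
  }
  lncc <- cluster_axis(r_mat, k_lnc)
  mrnc <- cluster_axis(t(r_mat), k_mrna)
  structure(list(r_matrix = r_mat,
                 lnc = lncc$tbl, mrna = mrnc$tbl,
                 lnc_info = lncc$info, mrna_info = mrnc$info,
                 hc_lnc = lncc$hc, hc_mrna = mrnc$hc),
            class = "conet_biclust")
}

#' @export
print.conet_biclust <- function(x, ...) {
  cat(sprintf("<conet_biclust> %d lncRNAs x %d mRNAs; %d / %d clusters\n",
              nrow(x$r_matrix), ncol(x$r_matrix),
              nrow(x$lnc_info), nrow(x$mrna_info)))
  invisible(x)
}

#' Members of one mRNA cluster
#'
#' @param bic a [bicluster_network()] result.
#' @param cluster_id mRNA cluster id.
#' @return Character vector of mRNA ids.
#' @export
mrna_cluster_members <- function(bic, cluster_id) {
  stopifnot(inherits(bic, "conet_biclust"))
  bic$mrna$item_id[bic$mrna$cluster_id == cluster_id]
}

#' Select the largest clusters on the lncRNA axis
#'
#' Clusters are ranked by member count (ties broken by lower dendrogram
#' formation height, then id). For a `conet_biclust` input each selected
#' lncRNA cluster is linked to the mRNA cluster it correlates with most
#' strongly (largest mean `|r|`). The returned fraction is cumulative:
#' members of the top clusters so far over all clustered items.
#'
#' @param x a `conet_biclust`, or a tibble with `item_id`, `cluster_id`.
#' @param n_top number of clusters to return.
#' @param heights optional named vector (cluster id -> formation height)
#'   for tie-breaking when `x` is a plain tibble.
#' @return Tibble `cluster_id`, `size`, `fraction` (cumulative share of
#'   all items), plus `linked_mrna_cluster` for biclustered input.
#' @export
select_top_clusters <- function(x, n_top = 2L, heights = NULL) {
  if (inherits(x, "conet_biclust")) {
    info <- x$lnc_info
    linked <- vapply(info$cluster_id, function(cl) {
      rows <- x$lnc$item_id[x$lnc$cluster_id == cl]
      by_col <- vapply(sort(unique(x$mrna$cluster_id)), function(mc) {
        cols <- x$mrna$item_id[x$mrna$cluster_id == mc]
        mean(abs(x$r_matrix[rows, cols, drop = FALSE]))
      }, 0)
      sort(unique(x$mrna$cluster_id))[which.max(by_col)]
    }, 0L)
    info$linked_mrna_cluster <- linked
  } else {
    assert_cols(x, c("item_id", "cluster_id"), "cluster assignment")
    sizes <- x |> count(.data$cluster_id, name = "size")
    h <- if (is.null(heights)) setNames(rep(0, nrow(sizes)), sizes$cluster_id) else heights
    info <- sizes |>
      mutate(height = unname(h[as.character(.data$cluster_id)])) |>
      arrange(desc(.data$size), .data$height, .data$cluster_id)
  }
  total <- sum(info$size)
  if (nrow(info) < n_top) {
    warn(sprintf("only %d cluster(s) available; requested top %d", nrow(info), n_top))
    n_top <- nrow(info)
  }
  out <- info[seq_len(n_top), , drop = FALSE]
  out$fraction <- cumsum(out$size) / total
  out |> select(-dplyr::any_of("height"))
}
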