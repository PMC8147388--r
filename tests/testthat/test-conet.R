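# build a fake gated-contrast list directly from a profile matrix
contrasts_from_profiles <- function(lnc, mrna, de_lnc = rownames(lnc),
                                    de_mrna = rownames(mrna)) {
  all_ids <- c(rownames(lnc), rownames(mrna))
  bt <- c(rep("lncRNA", nrow(lnc)), rep("mRNA", nrow(mrna)))
  lapply(setNames(seq_len(ncol(lnc)), paste0("g", seq_len(ncol(lnc)))), function(j) {
    tibble::tibble(probe_id = all_ids, biotype = bt,
                   log2fc = c(lnc[, j], mrna[, j]),
                   passes_gate = all_ids %in% c(de_lnc, de_mrna))
  })
}

test_that("profiles span all contrasts and keep only DE transcripts", {
  set.seed(20)
  lnc <- matrix(rnorm(5 * 16), nrow = 5, dimnames = list(paste0("l", 1:5), NULL))
  mrna <- matrix(rnorm(8 * 16), nrow = 8, dimnames = list(paste0("m", 1:8), NULL))
  ct <- contrasts_from_profiles(lnc, mrna, de_lnc = paste0("l", 1:3),
                                de_mrna = paste0("m", 1:6))
  prof <- correlation_profiles(ct)
  expect_equal(ncol(prof$lnc), 16L)
  expect_setequal(rownames(prof$lnc), paste0("l", 1:3))
  expect_setequal(rownames(prof$mrna), paste0("m", 1:6))
  expect_error(correlation_profiles(ct[1:2]), ">= 3 contrasts")
})

test_that("edge thresholds are strict and the t-transform p is exact", {
  set.seed(21)
  v81 <- vectors_with_r(0.81)
  lnc <- rbind(l_sig = v81$x, l_self = v81$x, l_neg = v81$x)
  mrna <- rbind(m_sig = v81$y, m_self = v81$x, m_neg = -v81$x)
  ct <- contrasts_from_profiles(lnc, mrna)
  edges <- pearson_edges(correlation_profiles(ct))
  key <- paste(edges$lnc_id, edges$mrna_id)
  expect_true("l_self m_self" %in% key)     # r = +1 kept
  expect_true("l_neg m_neg" %in% key)       # r = -1 kept (absolute-value rule)
  expect_true("l_sig m_sig" %in% key)       # r = 0.81 -> p ~ 1.5e-4 < 0.05
  e <- edges[key == "l_sig m_sig", ]
  expect_equal(e$r, 0.81, tolerance = 1e-12)
  expect_lt(abs(e$p - 1.5e-4), 1e-5)
  expect_equal(e$p, cor.test(v81$x, v81$y)$p.value, tolerance = 1e-12)

  # the thresholds are strict: an edge sitting exactly on |r| = min_abs_r
  # (to the last bit) is excluded
  rr <- cor(v81$x, v81$y)
  at_cut <- pearson_edges(correlation_profiles(ct),
                          net_thresholds(min_abs_r = rr, max_p = 0.05))
  expect_false("l_sig m_sig" %in% paste(at_cut$lnc_id, at_cut$mrna_id))
  expect_true("l_self m_self" %in% paste(at_cut$lnc_id, at_cut$mrna_id))
})

test_that("edges agree with an O(n^2) brute-force computation", {
  set.seed(22)
  lnc <- matrix(rnorm(20 * 10), nrow = 20, dimnames = list(paste0("l", 1:20), NULL))
  mrna <- matrix(rnorm(30 * 10), nrow = 30, dimnames = list(paste0("m", 1:30), NULL))
  # plant some strong pairs
  for (i in 1:6) mrna[i, ] <- lnc[i, ] * c(1, -1)[i %% 2 + 1] + rnorm(10, 0, 0.05)
  th <- net_thresholds(min_abs_r = 0.3, max_p = 0.05)
  edges <- pearson_edges(list(lnc = lnc, mrna = mrna), th)
  brute <- list()
  for (i in rownames(lnc)) for (j in rownames(mrna)) {
    r <- pearson_brute(lnc[i, ], mrna[j, ])
    p <- cor.test(lnc[i, ], mrna[j, ])$p.value
    if (abs(r) > th$min_abs_r && p < th$max_p) {
      brute[[paste(i, j)]] <- c(r = r, p = p)
    }
  }
  expect_setequal(paste(edges$lnc_id, edges$mrna_id), names(brute))
  for (k in seq_len(nrow(edges))) {
    b <- brute[[paste(edges$lnc_id[k], edges$mrna_id[k])]]
    expect_lt(abs(edges$r[k] - b["r"]), 1e-12)
    expect_lt(abs(edges$p[k] - b["p"]), 1e-12)
  }
})

test_that("zero-variance profiles contribute no edges, with a warning", {
  lnc <- rbind(l1 = rep(1, 8), l2 = rnorm(8))
  mrna <- rbind(m1 = rnorm(8))
  expect_warning(edges <- pearson_edges(list(lnc = lnc, mrna = mrna)), "constant")
  expect_false("l1" %in% edges$lnc_id)
})

test_that("degree filter applies the 15-edge rule with mRNA cascade, monotonically", {
  edges <- dplyr::bind_rows(
    tibble::tibble(lnc_id = "keep", mrna_id = sprintf("m%02d", 1:15), r = 0.9, p = 1e-4, n = 16L),
    tibble::tibble(lnc_id = "drop", mrna_id = sprintf("x%02d", 1:14), r = 0.9, p = 1e-4, n = 16L))
  net <- degree_filter(edges)
  expect_equal(net$lnc, "keep")
  expect_setequal(net$mrna, sprintf("m%02d", 1:15))   # x* cascade away with "drop"
  kept <- vapply(1:20, function(k)
    length(degree_filter(edges, net_thresholds(min_degree = k))$lnc), 0L)
  expect_true(all(diff(kept) <= 0))
})

test_that("average-linkage merges match a hand-rolled agglomeration", {
  set.seed(23)
  r4 <- matrix(runif(16, -1, 1), nrow = 4,
               dimnames = list(paste0("l", 1:4), paste0("m", 1:4)))
  edges <- tibble::tibble(lnc_id = rep(rownames(r4), 4),
                          mrna_id = rep(colnames(r4), each = 4),
                          r = as.vector(r4), p = 1e-6, n = 16L)
  net <- list(lnc = rownames(r4), mrna = colnames(r4), edges = edges)
  bic <- bicluster_network(net, k_lnc = 2, k_mrna = 2)
  expect_equal(sort(bic$hc_lnc$height),
               sort(avg_linkage_heights(dist(r4))), tolerance = 1e-12)
  expect_equal(sort(bic$hc_mrna$height),
               sort(avg_linkage_heights(dist(t(r4)))), tolerance = 1e-12)
})

test_that("anti-correlated planted modules split into opposing clusters", {
  lnc_ids <- paste0("l", 1:10); mrna_ids <- paste0("m", 1:40)
  edges <- dplyr::bind_rows(
    tidyr::expand_grid(lnc_id = lnc_ids[1:5], mrna_id = mrna_ids[1:20]) |>
      dplyr::mutate(r = 0.95, p = 1e-6, n = 16L),
    tidyr::expand_grid(lnc_id = lnc_ids[6:10], mrna_id = mrna_ids[21:40]) |>
      dplyr::mutate(r = -0.95, p = 1e-6, n = 16L))
  net <- degree_filter(edges)
  bic <- bicluster_network(net, k_lnc = 2, k_mrna = 2)
  m1 <- mrna_cluster_members(bic, 1)
  cl_of <- function(l) bic$lnc$cluster_id[bic$lnc$item_id == l]
  expect_equal(length(unique(vapply(lnc_ids[1:5], cl_of, 0L))), 1L)
  expect_equal(length(unique(vapply(lnc_ids[6:10], cl_of, 0L))), 1L)
  expect_false(cl_of("l1") == cl_of("l6"))
  mean_r <- function(lcl, mcl) {
    rows <- bic$lnc$item_id[bic$lnc$cluster_id == lcl]
    cols <- bic$mrna$item_id[bic$mrna$cluster_id == mcl]
    mean(bic$r_matrix[rows, cols])
  }
  expect_true(sign(mean_r(cl_of("l1"), 1)) != sign(mean_r(cl_of("l6"), 1)))
})

test_that("top-cluster selection ranks by size with height tie-break", {
  asg <- tibble::tibble(
    item_id = paste0("t", 1:336),
    cluster_id = rep(c(1L, 2L, 3L), times = c(205L, 121L, 10L)))
  top <- select_top_clusters(asg, n_top = 2)
  expect_equal(top$cluster_id, c(1L, 2L))
  expect_equal(top$size, c(205L, 121L))
  expect_equal(top$fraction[2], (205 + 121) / 336)

  tie <- tibble::tibble(item_id = paste0("t", 1:20),
                        cluster_id = rep(c(1L, 2L), each = 10L))
  top_tie <- select_top_clusters(tie, n_top = 1,
                                 heights = c("1" = 2.0, "2" = 0.5))
  expect_equal(top_tie$cluster_id, 2L)   # lower dendrogram height wins

  single <- tibble::tibble(item_id = paste0("t", 1:5), cluster_id = 1L)
  expect_warning(one <- select_top_clusters(single, n_top = 2), "only 1")
  expect_equal(nrow(one), 1L)
})

test_that("two dominant planted modules dominate the top-two lncRNA clusters", {
  # tuned scenario: two large modules plus a small residual of independent
  # responders; the lncRNA tree is cut into 3 clusters (two dominant + rest)
  fr <- vapply(1:3, function(s) {
    sim <- simulate_experiment(small_cfg(seed = 400 + s, n_lnc = 500L,
                                         n_mrna = 2000L, n_negctrl = 100L,
                                         module_n_lnc = 20, module_n_mrna = 40,
                                         frac_de = 0.02))
    em <- preprocess(sim$expr, sim$design)
    ct <- run_contrasts(em, sim$design)
    net <- degree_filter(suppressWarnings(pearson_edges(correlation_profiles(ct))))
    bic <- bicluster_network(net, k_lnc = min(3L, length(net$lnc)), k_mrna = 2L)
    glance(bic)$top2_lnc_fraction
  }, numeric(1))
  expect_gt(mean(fr), 0.9)
})
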