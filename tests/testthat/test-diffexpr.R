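make_two_group_em <- function(n = 50, seed = 1, sd = 0.4) {
  set.seed(seed)
  d <- toy_design()
  m <- matrix(rnorm(n * 6, 8, sd), nrow = n,
              dimnames = list(sprintf("p%03d", seq_len(n)), d$sample_id))
  list(em = toy_em(m), design = d, values = m)
}

test_that("a probe with identical values in both groups gives lfc 0, t 0, p 1", {
  fx <- make_two_group_em()
  fx$values["p001", ] <- 5
  em <- toy_em(fx$values)
  res <- suppressWarnings(moderated_de(em, fx$design, "CuO-Core"))
  row <- res[res$probe_id == "p001", ]
  expect_equal(row$log2fc, 0)
  expect_equal(row$t_mod, 0)
  expect_equal(row$p, 1)
})

test_that("with d0 = 0 the moderated t reduces to the ordinary pooled t", {
  fx <- make_two_group_em(seed = 2)
  res <- moderated_de(fx$em, fx$design, "CuO-Core", d0_override = 0)
  x1 <- fx$values[, 1:3]; x2 <- fx$values[, 4:6]
  s2 <- (rowSums((x1 - rowMeans(x1))^2) + rowSums((x2 - rowMeans(x2))^2)) / 4
  t_ord <- (rowMeans(x1) - rowMeans(x2)) / sqrt(s2 * (2 / 3))
  expect_equal(res$t_mod, unname(t_ord), tolerance = 1e-10)
  expect_equal(res$p, unname(2 * pt(-abs(t_ord), df = 4)), tolerance = 1e-10)
})

test_that("moderated t ordering interpolates between ordinary t and fold change", {
  fx <- make_two_group_em(seed = 3, n = 200)
  t0 <- moderated_de(fx$em, fx$design, "CuO-Core", d0_override = 0)
  tinf <- moderated_de(fx$em, fx$design, "CuO-Core", d0_override = Inf)
  x1 <- fx$values[, 1:3]; x2 <- fx$values[, 4:6]
  s2 <- (rowSums((x1 - rowMeans(x1))^2) + rowSums((x2 - rowMeans(x2))^2)) / 4
  t_ord <- (rowMeans(x1) - rowMeans(x2)) / sqrt(s2 * (2 / 3))
  expect_equal(cor(abs(t0$t_mod), abs(t_ord), method = "spearman"), 1)
  expect_equal(cor(abs(tinf$t_mod), abs(tinf$log2fc), method = "spearman"), 1)
})

test_that("moderated statistics agree with an independent limma fit", {
  fx <- make_two_group_em(seed = 4, n = 300)
  res <- moderated_de(fx$em, fx$design, "CuO-Core")
  grp <- factor(c(rep("exp", 3), rep("ctl", 3)), levels = c("ctl", "exp"))
  fit <- limma::eBayes(limma::lmFit(fx$values, model.matrix(~grp)))
  expect_equal(res$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(res$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(attr(res, "df_prior"), fit$df.prior, tolerance = 1e-8)
})

test_that("contrast invariants hold: q >= p and sign(t) == sign(lfc)", {
  sim <- simulate_experiment(small_cfg(seed = 6))
  em <- quantile_normalize(background_filter(log2_transform(sim$expr)))
  res <- moderated_de(em, sim$design, "CuO-COOH")
  expect_true(all(res$q >= res$p - 1e-15))
  nz <- res$log2fc != 0
  expect_true(all(sign(res$t_mod[nz]) == sign(res$log2fc[nz])))
  expect_error(moderated_de(em, sim$design, "not-a-group"), "unknown exposure group")
})

test_that("BH adjustment matches definition and validates input", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))
    expect_equal(bh_adjust(p), bh_bruteforce(p))
  }
})

test_that("gates are inclusive at the printed cut-offs", {
  res <- tibble::tibble(probe_id = paste0("p", 1:4),
                        biotype = c("lncRNA", "mRNA", "lncRNA", "mRNA"),
                        accession = paste0("A", 1:4),
                        t_mod = c(3, 3, -3, 3),
                        log2fc = c(0.58, 0.57, -0.58, 0.41),
                        q = c(0.05, 0.01, 0.05, 0.01))
  gated <- gate_de(res)
  expect_equal(gated$passes_gate, c(TRUE, FALSE, TRUE, FALSE))
  part <- de_partition(gated)
  expect_equal(part$lnc, c("p1", "p3"))
  expect_equal(part$mrna, character(0))
})

test_that("per-group DE counts recover planted sharing structure", {
  # two exposure groups sharing 5 planted probes, plus 5 unique to the first
  set.seed(12)
  d <- dplyr::bind_rows(
    toy_design(),
    dplyr::mutate(toy_design()[1:3, ], material = "TiO2p",
                  sample_id = paste0("t", 1:3)))
  n <- 60
  m <- matrix(rnorm(n * 9, 8, 0.1), nrow = n,
              dimnames = list(sprintf("p%03d", 1:n), d$sample_id))
  shared <- 1:5; only_a <- 6:10
  m[c(shared, only_a), d$material == "CuO"] <- m[c(shared, only_a), d$material == "CuO"] + 2
  m[shared, d$material == "TiO2p"] <- m[shared, d$material == "TiO2p"] + 2
  ann <- toy_ann(rownames(m), biotype = rep(c("lncRNA", "mRNA"), length.out = n))
  em <- expr_matrix(m, ann, scale = "log2")
  ct <- run_contrasts(em, d)
  hits <- lapply(ct, function(x) x$probe_id[x$passes_gate])
  expect_setequal(intersect(hits[["CuO-Core"]], hits[["TiO2p-Core"]]),
                  sprintf("p%03d", shared))
  expect_setequal(hits[["CuO-Core"]], sprintf("p%03d", c(shared, only_a)))
  counts <- de_count_table(ct)
  expect_equal(counts$n_lnc + counts$n_mrna, c(10L, 5L))
})
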