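test_that("log2 transform matches printed threshold arithmetic", {
  m <- matrix(c(8, 1, 3, 8, 1, 2), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  em <- log2_transform(toy_em(m, scale = "raw"))
  expect_equal(em$values["a", "s1"], 3)
  expect_equal(em$values["b", "s1"], 0)
  # a 1.5-fold ratio is a log2 difference of 0.58 (2 dp)
  expect_equal(round(em$values["c", "s1"] - em$values["c", "s2"], 2), 0.58)
  expect_equal(em$scale, "log2")

  m["a", "s1"] <- 0
  expect_error(log2_transform(toy_em(m, scale = "raw")), "'a'.*'s1'")
})

test_that("background filter retains probes above threshold in at least half the samples", {
  # 20 negative controls at constant 4 -> per-sample threshold = 4 (sd = 0)
  neg <- matrix(4, nrow = 20, ncol = 4,
                dimnames = list(sprintf("neg%02d", 1:20), paste0("s", 1:4)))
  probes <- rbind(all_above = c(5, 5, 5, 5),
                  half_above = c(5, 5, 3, 3),     # exactly half on even n
                  below_half = c(5, 3, 3, 3),
                  none_above = c(3, 3, 3, 3))
  colnames(probes) <- paste0("s", 1:4)
  ann <- dplyr::bind_rows(toy_ann(rownames(probes)),
                          toy_ann(rownames(neg), biotype = "negative_control"))
  em <- expr_matrix(rbind(probes, neg), ann, scale = "log2")
  out <- background_filter(em)
  expect_setequal(rownames(out$values), c("all_above", "half_above"))
  expect_false(any(out$annotation$biotype == "negative_control"))

  no_neg <- expr_matrix(probes, toy_ann(rownames(probes)), scale = "log2")
  expect_error(background_filter(no_neg), "negative-control")
})

test_that("raising the background quantile never retains more probes", {
  sim <- simulate_experiment(small_cfg(seed = 4))
  em <- log2_transform(sim$expr)
  kept <- vapply(c(0.5, 0.8, 0.95, 0.99), function(q)
    nrow(background_filter(em, method = "quantile", bg_quantile = q)$values), 0L)
  expect_true(all(diff(kept) <= 0))
})

test_that("quantile normalization matches the rank-mean oracle and preserves ranks", {
  # hand oracle: sorted-column means are (1+2)/2, (3+4)/2, (5+6)/2
  m <- matrix(c(1, 3, 5, 2, 4, 6), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  qn <- quantile_normalize(toy_em(m))
  expect_equal(unname(qn$values[, "s1"]), c(1.5, 3.5, 5.5))
  expect_equal(unname(qn$values[, "s2"]), c(1.5, 3.5, 5.5))

  # already-identical columns are a fixed point
  same <- matrix(c(2, 7, 4), nrow = 3, ncol = 3,
                 dimnames = list(c("a", "b", "c"), paste0("s", 1:3)))
  expect_equal(quantile_normalize(toy_em(same))$values, same)

  # definitional postcondition + rank preservation on random input
  set.seed(9)
  r <- matrix(rnorm(200), nrow = 20,
              dimnames = list(sprintf("p%02d", 1:20), sprintf("s%02d", 1:10)))
  qr_ <- quantile_normalize(toy_em(r))$values
  for (j in 2:ncol(qr_)) expect_equal(unname(sort(qr_[, j])), unname(sort(qr_[, 1])))
  for (j in seq_len(ncol(qr_))) expect_equal(rank(qr_[, j]), rank(r[, j]))
})

test_that("batch adjustment removes a planted shift but preserves group differences", {
  set.seed(31)
  n <- 200
  d <- toy_design(n_exp = 6, n_ctl = 6, two_batches = TRUE)
  base <- matrix(rnorm(n * 12, 8, 0.3), nrow = n,
                 dimnames = list(sprintf("p%03d", 1:n), d$sample_id))
  de_rows <- 1:40
  base[de_rows, d$material == "CuO"] <- base[de_rows, d$material == "CuO"] + 2
  shifted <- base
  shifted[, d$batch_label == "L2"] <- shifted[, d$batch_label == "L2"] + 1
  adj <- adjust_batch(toy_em(shifted), d, "batch_label")$values

  batch_diff <- rowMeans(adj[, d$batch_label == "L2"]) - rowMeans(adj[, d$batch_label == "L1"])
  expect_lt(abs(mean(batch_diff)), 0.1)   # systematic shift removed on average

  grp_diff <- rowMeans(adj[de_rows, d$material == "CuO"]) -
    rowMeans(adj[de_rows, d$material == "control"])
  expect_equal(mean(grp_diff), 2, tolerance = 0.1)

  # near-idempotence within EB shrinkage
  twice <- adjust_batch(expr_matrix(adj, toy_ann(rownames(adj)), scale = "log2"),
                        d, "batch_label")$values
  expect_lt(mean(abs(twice - adj)), 0.1)
})

test_that("degenerate batch layouts are caught", {
  d <- toy_design(n_exp = 3, n_ctl = 3)
  m <- matrix(rnorm(60, 8), nrow = 10,
              dimnames = list(sprintf("p%02d", 1:10), d$sample_id))
  # single level: unchanged
  expect_equal(suppressMessages(adjust_batch(toy_em(m), d, "batch_label"))$values, m)
  # batch confounded 1:1 with exposure group
  d2 <- d; d2$batch_label <- ifelse(d2$material == "CuO", "L1", "L2")
  expect_error(adjust_batch(toy_em(m), d2, "batch_label"), "confounded")
  # singleton batch level
  d3 <- d; d3$batch_label <- c("L1", rep("L2", 5))
  expect_error(adjust_batch(toy_em(m), d3, "batch_label"), "singleton")
})
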