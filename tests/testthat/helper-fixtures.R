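# Shared fixtures and independent oracles. Everything is built in code;
# oracles are deliberately naive (brute force / enumeration) and never
# call the code paths they check.

small_cfg <- function(seed, ...) {
  args <- list(n_lnc = 200L, n_mrna = 800L, n_negctrl = 50L,
               module_n_lnc = 5L, module_n_mrna = 20L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

toy_ann <- function(ids, biotype = "mRNA") {
  tibble::tibble(probe_id = ids, accession = paste0("ACC_", ids),
                 biotype = rep_len(biotype, length(ids)))
}

# one exposed group (CuO-Core) vs its PBS control
toy_design <- function(n_exp = 3L, n_ctl = 3L, two_batches = FALSE) {
  n <- n_exp + n_ctl
  tibble::tibble(
    sample_id = c(paste0("e", seq_len(n_exp)), paste0("c", seq_len(n_ctl))),
    material = c(rep("CuO", n_exp), rep("control", n_ctl)),
    surface = c(rep("Core", n_exp), rep("none", n_ctl)),
    dispersant = "PBS",
    batch_label = if (two_batches) rep(c("L1", "L2"), length.out = n) else "L1",
    batch_array = "A1",
    replicate = c(seq_len(n_exp), seq_len(n_ctl)))
}

toy_em <- function(values, biotype = "mRNA", scale = "log2") {
  expr_matrix(values, toy_ann(rownames(values), biotype), scale = scale)
}

# --- independent oracles ----------------------------------------------------

# BH step-up by direct definition: q_i = min_{j >= rank(i)} m p_(j) / j
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    cand <- vapply(rank_i:m, function(j) m * p[ord[j]] / j, 0)
    q[i] <- min(1, min(cand))
  }
  q
}

# Pearson r from raw sums, no stats:: shortcuts
pearson_brute <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# hypergeometric upper tail P[X >= ov] by exhaustive enumeration of all
# size-n draws from a universe of size N whose first K elements are the set
hyper_tail_enum <- function(N, K, n, ov) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= ov)
}

# naive average-linkage agglomeration returning sorted merge heights
avg_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# centered orthogonal pair -> vectors with exact correlation r
vectors_with_r <- function(r, n = 16L) {
  x <- scale(seq_len(n))[, 1L]
  e <- stats::residuals(stats::lm(stats::rnorm(n) ~ x))
  e <- e / sqrt(sum(e^2)); x <- x / sqrt(sum(x^2))
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}
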