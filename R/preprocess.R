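#' Log2-transform raw intensities
#'
#' @param em raw-scale [expr_matrix] with strictly positive values.
#' @return log2-scale [expr_matrix].
#' @export
log2_transform <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "raw") abort("log2_transform expects a raw-scale matrix")
  if (any(em$values <= 0)) {
    bad <- which(em$values <= 0, arr.ind = TRUE)[1L, ]
    abort(sprintf("nonpositive intensity at probe '%s', sample '%s'",
                  rownames(em$values)[bad[1L]], colnames(em$values)[bad[2L]]))
  }
  expr_matrix(log2(em$values), em$annotation, scale = "log2")
}

#' Filter probes against negative-control background
#'
#' The per-sample background threshold is estimated from the
#' negative-control probes of that sample (default: mean + `k_sd` SD of
#' their log2 intensities; alternatively an upper quantile). A probe is
#' retained iff its intensity exceeds the threshold in at least half of
#' the samples (`ceiling(n/2)`, so "exactly half" passes on even n).
#' Negative-control probes are removed from the output.
#'
#' @param em log2-scale [expr_matrix] containing negative-control probes.
#' @param method `"mean_sd"` (default) or `"quantile"`.
#' @param k_sd multiplier on the negative-control SD (mean_sd method).
#' @param bg_quantile upper quantile of negative controls (quantile method).
#' @return Filtered [expr_matrix] without negative-control probes.
#' @export
background_filter <- function(em, method = c("mean_sd", "quantile"),
                              k_sd = 2, bg_quantile = 0.95) {
  stopifnot(inherits(em, "expr_matrix"))
  method <- match.arg(method)
  if (em$scale != "log2") abort("background_filter expects a log2-scale matrix")
  is_neg <- em$annotation$biotype == "negative_control"
  if (!any(is_neg)) abort("no negative-control probes present; background undefined")
  neg <- em$values[is_neg, , drop = FALSE]
  thresh <- switch(method,
                   mean_sd = colMeans(neg) + k_sd * apply(neg, 2L, sd),
                   quantile = apply(neg, 2L, quantile, probs = bg_quantile, names = FALSE))
  true_vals <- em$values[!is_neg, , drop = FALSE]
  n_above <- rowSums(sweep(true_vals, 2L, thresh, ">"))
  keep <- n_above >= ceiling(ncol(true_vals) / 2)
  kept_ids <- rownames(true_vals)[keep]
  if (length(kept_ids) == 0L) abort("background filter removed every probe")
  expr_matrix(true_vals[keep, , drop = FALSE],
              em$annotation[!is_neg & em$annotation$probe_id %in% kept_ids, ],
              scale = "log2")
}

#' Quantile-normalize samples
#'
#' Forces every sample (column) onto the identical intensity distribution,
#' the row-wise mean of the sorted columns; ties within a column receive
#' the mean of the quantile values they span. Delegates to
#' [limma::normalizeQuantiles()] with tie averaging.
#'
#' @param em log2-scale [expr_matrix] with at least 2 samples.
#' @return Quantile-normalized [expr_matrix].
#' @export
quantile_normalize <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "log2") abort("quantile_normalize expects a log2-scale matrix")
  if (ncol(em$values) < 2L) abort("quantile normalization needs >= 2 samples")
  norm <- limma::normalizeQuantiles(em$values, ties = TRUE)
  dimnames(norm) <- dimnames(em$values)
  expr_matrix(norm, em$annotation, scale = "log2")
}

#' Empirical-Bayes batch adjustment (ComBat), preserving exposure group
#'
#' Parametric ComBat location/scale adjustment of one batch variable,
#' protecting the biological covariate (exposure group) by including it
#' in the model matrix. A single batch level leaves the data unchanged;
#' a singleton batch or a batch confounded 1:1 with the preserved
#' covariate is an error.
#'
#' @param em log2-scale [expr_matrix].
#' @param design validated design tibble covering the matrix samples.
#' @param batch_var design column naming the batch variable.
#' @param preserve design column to protect (default `"group"`).
#' @return Batch-adjusted [expr_matrix].
#' @export
adjust_batch <- function(em, design, batch_var, preserve = "group") {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$scale != "log2") abort("adjust_batch expects a log2-scale matrix")
  design <- validate_design(design)
  validate_dataset(em, design)
  design <- design[match(colnames(em$values), design$sample_id), ]
  assert_cols(design, c(batch_var, preserve), "design")
  batch <- factor(design[[batch_var]])
  if (nlevels(batch) == 1L) {
    inform(sprintf("'%s' has a single level; nothing to adjust", batch_var))
    return(em)
  }
  sizes <- table(batch)
  if (any(sizes < 2L)) {
    abort(sprintf("singleton batch level(s) in '%s': %s", batch_var,
                  paste(names(sizes)[sizes < 2L], collapse = ", ")))
  }
  grp <- factor(design[[preserve]])
  mod <- model.matrix(~grp)
  X <- cbind(model.matrix(~0 + batch), mod[, -1L, drop = FALSE])
  if (qr(X)$rank < ncol(X)) {
    abort(sprintf("batch variable '%s' is confounded with '%s'; adjustment is unidentifiable",
                  batch_var, preserve))
  }
  log <- utils::capture.output(
    adj <- suppressMessages(sva::ComBat(dat = em$values, batch = batch, mod = mod,
                                        par.prior = TRUE, prior.plots = FALSE)))
  expr_matrix(adj, em$annotation, scale = "log2")
}

#' Adjust several batch variables sequentially
#'
#' Runs [adjust_batch()] once per batch variable in the order given
#' (labeling first, then array, for the default design), each pass
#' preserving the exposure group.
#'
#' @inheritParams adjust_batch
#' @param batch_vars ordered character vector of design columns.
#' @return Batch-adjusted [expr_matrix].
#' @export
adjust_batches <- function(em, design, batch_vars = c("batch_label", "batch_array"),
                           preserve = "group") {
  for (bv in batch_vars) em <- adjust_batch(em, design, bv, preserve = preserve)
  em
}

#' Run the full preprocessing chain
#'
#' log2 transform, background filter, quantile normalization, then
#' sequential batch adjustment.
#'
#' @param em raw-scale [expr_matrix].
#' @param design design tibble.
#' @param batch_vars ordered batch variables (see [adjust_batches()]).
#' @param ... passed to [background_filter()].
#' @return Preprocessed log2-scale [expr_matrix].
#' @export
preprocess <- function(em, design, batch_vars = c("batch_label", "batch_array"), ...) {
  em |>
    log2_transform() |>
    background_filter(...) |>
    quantile_normalize() |>
    adjust_batches(design, batch_vars = batch_vars)
}
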