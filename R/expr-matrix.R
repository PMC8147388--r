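#' Probe-level expression matrix with biotype-aware annotation
#'
#' The container every pipeline stage transforms: a probes x samples
#' numeric matrix plus a probe annotation table and a scale flag that
#' records whether values are raw foreground intensities or log2.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids). No `NA` permitted.
#' @param annotation tibble with columns `probe_id`, `accession`,
#'   `biotype` (one of `"lncRNA"`, `"mRNA"`, `"negative_control"`).
#'   Every probe in `values` must have exactly one annotation row.
#' @param scale `"raw"` or `"log2"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, annotation, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry probe rownames and sample colnames")
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    abort(sprintf("NA intensity at probe '%s', sample '%s'; missing values are not permitted",
                  rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (anyDuplicated(rownames(values))) abort("duplicate probe ids in expression matrix")
  if (anyDuplicated(colnames(values))) abort("duplicate sample ids in expression matrix")
  annotation <- validate_annotation(annotation)
  unknown <- setdiff(rownames(values), annotation$probe_id)
  if (length(unknown) > 0L) {
    abort(sprintf("probe(s) with no annotation: %s",
                  paste(head(unknown, 5L), collapse = ", ")))
  }
  annotation <- annotation[match(rownames(values), annotation$probe_id), ]
  structure(list(values = values, annotation = annotation, scale = scale),
            class = "expr_matrix")
}

#' Validate a probe annotation table
#'
#' @param annotation data frame with `probe_id`, `accession`, `biotype`.
#' @return The annotation as a tibble, invisibly checked.
#' @export
validate_annotation <- function(annotation) {
  assert_cols(annotation, c("probe_id", "accession", "biotype"), "annotation")
  annotation <- as_tibble(annotation)
  if (anyDuplicated(annotation$probe_id)) abort("duplicate probe_id in annotation")
  bad <- setdiff(unique(annotation$biotype), BIOTYPES)
  if (length(bad) > 0L) {
    abort(sprintf("unknown biotype(s): %s (expected %s)",
                  paste(bad, collapse = ", "), paste(BIOTYPES, collapse = ", ")))
  }
  annotation
}

#' @export
print.expr_matrix <- function(x, ...) {
  bt <- table(x$annotation$biotype)
  cat(sprintf("<expr_matrix> %d probes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("  biotypes:", paste(sprintf("%s=%d", names(bt), bt), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Long-format view of an expression matrix
#'
#' @param x an [expr_matrix].
#' @param ... unused.
#' @return Tibble with `probe_id`, `accession`, `biotype`, `sample_id`, `value`.
#' @method as_tibble expr_matrix
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble(
    probe_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  ) |>
    left_join(x$annotation, by = "probe_id") |>
    select("probe_id", "accession", "biotype", "sample_id", "value")
}

#' Subset an expression matrix by probe and/or sample ids
#'
#' @param x an [expr_matrix].
#' @param probes,samples character vectors of ids to keep (default all).
#' @return An [expr_matrix].
#' @export
em_subset <- function(x, probes = rownames(x$values), samples = colnames(x$values)) {
  missing_p <- setdiff(probes, rownames(x$values))
  if (length(missing_p) > 0L) abort(sprintf("unknown probe(s): %s", paste(head(missing_p, 5L), collapse = ", ")))
  missing_s <- setdiff(samples, colnames(x$values))
  if (length(missing_s) > 0L) abort(sprintf("unknown sample(s): %s", paste(head(missing_s, 5L), collapse = ", ")))
  expr_matrix(x$values[probes, samples, drop = FALSE],
              x$annotation[x$annotation$probe_id %in% probes, ],
              scale = x$scale)
}
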