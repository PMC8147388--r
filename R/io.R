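#' Read a probe-level expression TSV
#'
#' Expects a tab-separated file: header row of sample ids, first column
#' `probe_id`, numeric body. Missing values and non-numeric cells are hard
#' errors (the platform reports an intensity for every feature; this
#' workflow has no imputation step).
#'
#' @param path file path.
#' @param annotation probe annotation tibble (see [validate_annotation()]);
#'   every probe in the file must be annotated.
#' @param scale `"raw"` (default) or `"log2"`.
#' @return An [expr_matrix].
#' @export
read_expression <- function(path, annotation, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (names(df)[1L] != "probe_id") abort("first column of expression TSV must be 'probe_id'")
  probe_id <- df$probe_id
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(probe_id, colnames(body))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-numeric or missing cell at probe '%s', sample '%s' (cell value '%s')",
                  probe_id[bad[1L]], colnames(num)[bad[2L]], body[bad[1L], bad[2L]]))
  }
  expr_matrix(num, annotation, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' @param em an [expr_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  df <- tibble(probe_id = rownames(em$values)) |>
    dplyr::bind_cols(as_tibble(em$values))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write a probe annotation TSV (probe_id, accession, biotype)
#'
#' @param path file path.
#' @return Annotation tibble.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @param annotation annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(validate_annotation(annotation), path, progress = FALSE)
  invisible(path)
}

#' Read / write a sample design TSV
#'
#' Columns: `sample_id`, `material`, `surface`, `dispersant`,
#' `batch_label`, `batch_array`, `replicate`. A derived `group` column
#' (`material_surface`, or `control_<dispersant>` for controls) is added
#' on read.
#'
#' @param path file path.
#' @return Design tibble.
#' @export
read_design <- function(path) {
  design <- readr::read_tsv(path, col_types = readr::cols(replicate = "i", .default = "c"),
                            progress = FALSE)
  validate_design(design)
}

#' @rdname read_design
#' @param design design tibble.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(validate_design(design), path, progress = FALSE)
  invisible(path)
}

#' Validate a design table and derive exposure group labels
#'
#' Checks id uniqueness, enum levels, that every exposed group has a
#' dispersant-matched control group, and that every group carries at
#' least 2 replicates (required downstream for differential expression).
#'
#' @param design design tibble.
#' @return The design tibble with a `group` column.
#' @export
validate_design <- function(design) {
  assert_cols(design,
              c("sample_id", "material", "surface", "dispersant",
                "batch_label", "batch_array", "replicate"),
              "design")
  design <- as_tibble(design)
  if (anyDuplicated(design$sample_id)) abort("duplicate sample_id in design")
  for (chk in list(c("material", paste(MATERIALS, collapse = "|")),
                   c("surface", paste(SURFACES, collapse = "|")),
                   c("dispersant", paste(DISPERSANTS, collapse = "|")))) {
    allowed <- strsplit(chk[2L], "|", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(design[[chk[1L]]]), allowed)
    if (length(bad) > 0L) {
      abort(sprintf("invalid %s level(s): %s", chk[1L], paste(bad, collapse = ", ")))
    }
  }
  if (any(design$replicate < 1L)) abort("replicate must be >= 1")
  design <- design |>
    mutate(group = ifelse(.data$material == "control",
                          paste0("control_", .data$dispersant),
                          paste(.data$material, .data$surface, sep = "-")))
  tab <- design |> count(.data$group)
  if (any(tab$n < 2L)) {
    abort(sprintf("group(s) with fewer than 2 replicates: %s",
                  paste(tab$group[tab$n < 2L], collapse = ", ")))
  }
  exposed <- design |> filter(.data$material != "control") |>
    distinct(.data$group, .data$dispersant)
  ctrl_disp <- design |> filter(.data$material == "control") |> pull(.data$dispersant) |> unique()
  unmatched <- exposed$group[!exposed$dispersant %in% ctrl_disp]
  if (length(unmatched) > 0L) {
    abort(sprintf("exposed group(s) without a dispersant-matched control: %s",
                  paste(unmatched, collapse = ", ")))
  }
  design
}

#' Cross-validate an expression matrix against a design table
#'
#' @param em an [expr_matrix].
#' @param design validated design tibble.
#' @return `TRUE` invisibly; errors on any mismatch.
#' @export
validate_dataset <- function(em, design) {
  design <- validate_design(design)
  extra <- setdiff(colnames(em$values), design$sample_id)
  missing <- setdiff(design$sample_id, colnames(em$values))
  if (length(extra) > 0L || length(missing) > 0L) {
    abort(sprintf("sample id mismatch between expression and design (extra: %s; missing: %s)",
                  paste(extra, collapse = ", "), paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a GMT gene-set file
#'
#' Standard dialect: one set per line, `set_id TAB description TAB member...`.
#' Duplicate members within a set are dropped; set order is preserved.
#'
#' @param path file path.
#' @return Tibble with `set_id`, `set_name` and a `members` list-column.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0L) {
    abort(sprintf("GMT line %d has fewer than 3 fields", short[1L]))
  }
  tibble(
    set_id = vapply(fields, `[[`, "", 1L),
    set_name = vapply(fields, `[[`, "", 2L),
    members = lapply(fields, function(f) unique(f[-(1:2)]))
  )
}

#' @rdname read_gmt
#' @param sets gene-set tibble as returned by [read_gmt()].
#' @export
write_gmt <- function(sets, path) {
  assert_cols(sets, c("set_id", "set_name", "members"), "gene-set collection")
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_id[i], sets$set_name[i], sets$members[[i]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}
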