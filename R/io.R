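# Plain-text readers/writers for the pipeline's stage artifacts.
# Expression matrices and sample metadata travel as TSV, physiology as CSV,
# so any stage can be re-run on user data in place of the simulator.

#' Write / read a log2 expression matrix as TSV
#'
#' First column `gene` holds gene ids; remaining columns are sample ids.
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path file path.
#' @return `read_expression_matrix` returns the matrix;
#'   `write_expression_matrix` returns `path` invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  # full double precision so persisted stages re-run bit-identically
  fmt <- apply(mat, 2L, function(x) sprintf("%.17g", x))
  df <- data.frame(gene = rownames(mat), fmt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  storage.mode(mat) <- "double"
  mat
}

#' Write / read sample metadata as TSV
#'
#' Columns: `sample_id, class, tissue, stage, replicate`.
#'
#' @param meta data.frame of sample metadata.
#' @param path file path.
#' @return `read_sample_metadata` returns the data.frame.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "tissue", "stage", "replicate")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("sample metadata is missing columns: ", paste(missing, collapse = ", "))
  }
  meta
}

#' Write / read a per-berry physiology table as CSV
#'
#' Columns: `berry_id, plant, cluster, class, day, brix, L, h, C, elasticity`.
#'
#' @param table physiology data.frame.
#' @param path file path.
#' @return `read_physiology` returns the data.frame.
#' @export
write_physiology <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1L)) & names(table) != "day"
  table[num] <- lapply(table[num], function(x) sprintf("%.17g", x))
  utils::write.csv(table, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_physiology
#' @export
read_physiology <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("berry_id", "plant", "cluster", "class", "day", "brix",
            "L", "h", "C", "elasticity")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("physiology table is missing columns: ", paste(missing, collapse = ", "))
  }
  tab
}

#' Write a stage artifact as TSV
#' @noRd
write_stage_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset expression columns by metadata condition, in metadata order
#' @noRd
select_samples <- function(meta, tissue = NULL, stage = NULL, class = NULL) {
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(tissue)) keep <- keep & meta$tissue == tissue
  if (!is.null(stage)) keep <- keep & meta$stage == stage
  if (!is.null(class)) keep <- keep & meta$class == class
  meta[keep, , drop = FALSE]
}

#' Per-gene class means over replicates for one tissue/stage block
#' @noRd
class_stage_means <- function(mat, meta, tissue, stage, classes) {
  out <- matrix(NA_real_, nrow(mat), length(classes),
                dimnames = list(rownames(mat), classes))
  for (k in seq_along(classes)) {
    sel <- select_samples(meta, tissue = tissue, stage = stage,
                          class = classes[k])
    if (nrow(sel) == 0L) {
      stop(sprintf("no samples for class '%s' at stage '%s' in tissue '%s'",
                   classes[k], stage, tissue))
    }
    out[, k] <- rowMeans(mat[, sel$sample_id, drop = FALSE])
  }
  out
}
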