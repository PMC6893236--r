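#' Write a log2 expression matrix as TSV
#'
#' First column \code{gene}, remaining columns samples; missing values as NA.
#'
#' @param mat Numeric matrix, genes x samples, with dimnames.
#' @param path Output file.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression TSV written by \code{\link{write_expression_tsv}}
#' @param path Input file.
#' @return Numeric matrix genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read a sample metadata table
#' @param meta data.frame with sample_id, study_id, platform_id, disease,
#'   phase, sex, batch.
#' @param path File path.
#' @export
write_sample_table <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors (term -> member genes).
#' @param path Output file.
#' @param descriptions Optional named character vector of term descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' One expression TSV per study, a combined sample table, ground-truth
#' proportion and regulated-gene tables, and the marker sets as GMT.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in cohort$studies) {
    write_expression_tsv(b$expr,
                         file.path(dir, paste0("expr_", b$design$study_id,
                                               ".tsv")))
  }
  write_sample_table(cohort_sample_table(cohort),
                     file.path(dir, "samples.tsv"))
  P <- cohort_true_proportions(cohort)
  utils::write.table(data.frame(sample_id = rownames(P), P,
                                check.names = FALSE),
                     file.path(dir, "true_proportions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$regulated)) {
    utils::write.table(cohort$regulated,
                       file.path(dir, "regulated_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_gmt(cohort$profiles$markers, file.path(dir, "markers.gmt"))
  utils::write.table(cohort$profiles$sex_genes,
                     file.path(dir, "sex_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
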