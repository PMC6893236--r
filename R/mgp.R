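#' Remove between-study variation gene-wise
#'
#' For every gene, each study's values are centred to the gene's grand mean
#' (study-mean removal). Genes missing in a study remain missing there.
#'
#' @param matrix Genes x samples matrix.
#' @param studies Study label per sample.
#' @return Corrected matrix of the same shape.
#' @export
correct_study_effects <- function(matrix, studies) {
  if (length(studies) != ncol(matrix)) {
    stop("one study label per sample is required")
  }
  tab <- table(studies)
  if (any(tab < 2)) stop("every study needs at least 2 samples")
  grand <- rowMeans(matrix, na.rm = TRUE)
  out <- matrix
  for (s in names(tab)) {
    idx <- which(studies == s)
    sub <- matrix[, idx, drop = FALSE]
    m_s <- rowMeans(sub, na.rm = TRUE)
    out[, idx] <- sub - m_s + grand
  }
  out
}

#' Estimate marker gene profiles (MGPs)
#'
#' Per cell type, the rows of its marker genes are z-scored across samples
#' and the samples' scores on the first principal component form the raw MGP,
#' a surrogate for the cell type's relative abundance. The sign is fixed so
#' the score correlates positively with the mean standardized marker
#' expression, and scores are min-max scaled to [0, 1] within the analysis
#' set (so scores are comparable only within one run). Markers missing in any
#' sample are dropped for that cell type; a cell type with no usable markers
#' is skipped with a warning; with one marker the score degenerates to that
#' marker's standardized expression.
#'
#' @param matrix Study-corrected genes x samples matrix (see
#'   \code{\link{correct_study_effects}}).
#' @param markers Named list, cell type -> marker gene symbols. No gene may
#'   mark two cell types.
#' @return Object of class \code{mgp_table}: list with \code{scores}
#'   (samples x cell types, unit scaled), \code{raw}, \code{var_explained},
#'   \code{markers_used}, \code{skipped}.
#' @export
estimate_mgp <- function(matrix, markers) {
  all_mk <- unlist(markers, use.names = FALSE)
  if (anyDuplicated(all_mk)) {
    stop("a gene may be a marker of at most one cell type")
  }
  n <- ncol(matrix)
  types <- names(markers)
  raw <- matrix(NA_real_, n, length(types),
                dimnames = list(colnames(matrix), types))
  varexp <- stats::setNames(rep(NA_real_, length(types)), types)
  used <- stats::setNames(vector("list", length(types)), types)
  skipped <- character(0)
  for (ct in types) {
    mk <- intersect(markers[[ct]], rownames(matrix))
    if (length(mk)) {
      sub <- matrix[mk, , drop = FALSE]
      mk <- mk[rowSums(is.na(sub)) == 0]
    }
    if (length(mk)) {
      sub <- matrix[mk, , drop = FALSE]
      sds <- apply(sub, 1, stats::sd)
      mk <- mk[sds > 0]
    }
    if (length(mk) == 0) {
      warning(sprintf("cell type %s has no usable markers; skipped", ct))
      skipped <- c(skipped, ct)
      next
    }
    z <- t(scale(t(matrix[mk, , drop = FALSE])))  # z-score per gene
    S <- t(z)                                     # samples x markers
    if (ncol(S) == 1) {
      score <- S[, 1]
      varexp[ct] <- 1
    } else {
      sv <- svd(S)
      score <- sv$u[, 1] * sv$d[1]
      varexp[ct] <- sv$d[1]^2 / sum(sv$d^2)
    }
    if (stats::cor(score, rowMeans(S)) < 0) score <- -score
    raw[, ct] <- score
    used[[ct]] <- mk
  }
  keep <- setdiff(types, skipped)
  raw <- raw[, keep, drop = FALSE]
  if (ncol(raw) == 0) {
    return(structure(list(scores = raw, raw = raw,
                          var_explained = varexp[keep],
                          markers_used = used[keep], skipped = skipped),
                     class = "mgp_table"))
  }
  rng <- apply(raw, 2, range)
  unit <- sweep(raw, 2, rng[1, ], "-")
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  unit <- sweep(unit, 2, span, "/")
  structure(list(scores = unit, raw = raw,
                 var_explained = varexp[keep],
                 markers_used = used[keep], skipped = skipped),
            class = "mgp_table")
}

#' @export
print.mgp_table <- function(x, ...) {
  cat(sprintf("mgp_table: %d samples x %d cell types (unit scores in [0,1])\n",
              nrow(x$scores), ncol(x$scores)))
  if (length(x$skipped)) {
    cat("skipped:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Test case-control differences in MGPs per cell type
#'
#' Two-sided Wilcoxon rank-sum test of case versus control unit scores per
#' cell type, exact for small groups without ties (both groups at most 10),
#' normal approximation with continuity and tie correction otherwise;
#' Benjamini-Hochberg adjustment across the tested cell types.
#'
#' @param mgp An \code{mgp_table}.
#' @param meta Sample table with \code{sample_id} and \code{disease}
#'   (\code{control}/\code{case}).
#' @return data.frame: celltype, n_case, n_control, direction (sign of the
#'   case-control median difference), p, fdr.
#' @export
test_mgp_difference <- function(mgp, meta) {
  scores <- mgp$scores
  disease <- meta$disease[match(rownames(scores), meta$sample_id)]
  if (anyNA(disease)) stop("metadata missing for some samples")
  if (sum(disease == "case") < 2 || sum(disease == "control") < 2) {
    stop("need at least 2 samples per group")
  }
  res <- lapply(colnames(scores), function(ct) {
    x <- scores[disease == "case", ct]
    y <- scores[disease == "control", ct]
    exact <- max(length(x), length(y)) <= 10 &&
      !anyDuplicated(c(x, y))
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
    data.frame(celltype = ct, n_case = length(x), n_control = length(y),
               direction = ifelse(stats::median(x) >= stats::median(y),
                                  "up", "down"),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p)
  out
}
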