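#' Collapse probes to genes by highest median expression
#'
#' Probes mapping to no gene or to several genes are discarded; when several
#' probes remain for one gene, the probe with the highest median expression
#' across samples represents the gene. Ties are broken by keeping the
#' lexicographically smallest probe id, which is deterministic and
#' platform-independent.
#'
#' @param probe_matrix Numeric matrix, probes x samples, no missing values.
#' @param probemap data.frame with columns \code{probe} and \code{gene}; a
#'   probe mapping to several genes appears in several rows.
#' @return Numeric matrix, genes x samples.
#' @export
collapse_probes <- function(probe_matrix, probemap) {
  if (anyNA(probe_matrix)) {
    stop("probe matrix must not contain missing values")
  }
  stopifnot(all(c("probe", "gene") %in% names(probemap)))
  n_genes <- tapply(probemap$gene, probemap$probe,
                    function(g) length(unique(g)))
  usable <- names(n_genes)[n_genes == 1]
  usable <- intersect(usable, rownames(probe_matrix))
  map <- unique(probemap[probemap$probe %in% usable, c("probe", "gene")])
  if (nrow(map) == 0) stop("no usable probes after collapsing")
  med <- apply(probe_matrix[map$probe, , drop = FALSE], 1, stats::median)
  ord <- order(map$gene, -med, map$probe)
  map <- map[ord, ]
  keep <- map[!duplicated(map$gene), ]
  out <- probe_matrix[keep$probe, , drop = FALSE]
  rownames(out) <- keep$gene
  out[order(rownames(out)), , drop = FALSE]
}

#' Flag outlier samples by mean inter-sample correlation
#'
#' For each sample the mean Pearson correlation with all other samples is
#' computed; samples whose mean correlation deviates from the grand mean of
#' these per-sample means by more than \code{k} standard deviations (of the
#' per-sample means) are flagged. Single pass, no re-iteration. Samples with
#' zero expression variance (undefined correlation) are reported separately.
#'
#' @param matrix Numeric matrix genes x samples, no missing values within the
#'   study (all-missing genes, i.e. platform absences, are dropped first).
#' @param k Number of standard deviations; default 2.
#' @return List with \code{outliers}, \code{constant} (sample ids) and
#'   \code{mean_correlation} (named vector).
#' @export
detect_outliers <- function(matrix, k = 2) {
  matrix <- matrix[rowSums(!is.na(matrix)) > 0, , drop = FALSE]
  if (anyNA(matrix)) stop("missing values within the study are not allowed")
  if (ncol(matrix) < 3) stop("need at least 3 samples")
  sds <- apply(matrix, 2, stats::sd)
  constant <- colnames(matrix)[sds == 0]
  ok <- sds > 0
  m <- matrix[, ok, drop = FALSE]
  cm <- stats::cor(m)
  diag(cm) <- NA
  mc <- rowMeans(cm, na.rm = TRUE)
  s <- stats::sd(mc)
  thr <- k * s
  flagged <- if (!is.finite(thr) || s == 0) {
    character(0)
  } else {
    names(mc)[abs(mc - mean(mc)) > thr]
  }
  list(outliers = flagged, constant = constant, mean_correlation = mc)
}

#' Per-batch location-scale adjustment
#'
#' For each gene, each batch's values are centred to the gene's overall mean
#' and rescaled to the gene's overall standard deviation. Batches with zero
#' within-batch variance for a gene are centred only. With fewer than two
#' batches, or any batch smaller than two samples, the matrix is returned
#' unchanged with a warning. This is the non-Bayesian location-scale core of
#' batch correction; no empirical-Bayes shrinkage is applied.
#'
#' @param matrix Numeric matrix genes x samples.
#' @param batches Batch label per sample (no missing labels).
#' @return Adjusted matrix of the same shape.
#' @export
batch_adjust <- function(matrix, batches) {
  if (length(batches) != ncol(matrix)) {
    stop("one batch label per sample is required")
  }
  if (anyNA(batches)) stop("batch label missing for at least one sample")
  batches <- as.character(batches)
  tab <- table(batches)
  if (length(tab) < 2 || any(tab < 2)) {
    warning("fewer than 2 batches with >=2 samples; no batch adjustment")
    return(matrix)
  }
  mu <- rowMeans(matrix, na.rm = TRUE)
  sd_all <- apply(matrix, 1, stats::sd, na.rm = TRUE)
  out <- matrix
  for (b in names(tab)) {
    idx <- which(batches == b)
    sub <- matrix[, idx, drop = FALSE]
    m_b <- rowMeans(sub, na.rm = TRUE)
    s_b <- apply(sub, 1, stats::sd, na.rm = TRUE)
    scale <- ifelse(is.na(s_b) | s_b == 0 | sd_all == 0, 1, sd_all / s_b)
    out[, idx] <- (sub - m_b) * scale + mu
  }
  out
}

#' Select genes measured on enough platforms
#'
#' Keeps genes measured (at least one non-missing value) in at least
#' \code{ceiling(fraction * n_platforms)} distinct platforms. Platforms, not
#' studies, are the counting unit: studies sharing a platform count once.
#'
#' @param matrices List of genes x samples matrices, one per study.
#' @param platforms Platform id per matrix; defaults to
#'   \code{names(matrices)}.
#' @param fraction Required fraction of platforms; default 2/3.
#' @return Character vector of gene ids.
#' @export
select_shared_genes <- function(matrices, platforms = names(matrices),
                                fraction = 2 / 3) {
  if (length(matrices) < 2) stop("need at least 2 matrices")
  if (is.null(platforms) || length(platforms) != length(matrices)) {
    stop("one platform id per matrix is required")
  }
  pids <- unique(platforms)
  per_platform <- lapply(pids, function(p) {
    genes <- unlist(lapply(matrices[platforms == p], function(m) {
      rownames(m)[rowSums(!is.na(m)) > 0]
    }))
    unique(genes)
  })
  counts <- table(unlist(per_platform))
  need <- ceiling(fraction * length(pids))
  keep <- names(counts)[counts >= need]
  if (length(keep) == 0) stop("no gene is shared by enough platforms")
  sort(keep)
}

# Quantile-normalize one complete matrix: every column gets the mean sorted
# profile; ties within a column receive interpolated (averaged) values.
.qn_reference <- function(mat) {
  rowMeans(apply(mat, 2, sort))
}

.qn_map_column <- function(v, ref_probs, ref) {
  obs <- which(!is.na(v))
  x <- v[obs]
  n <- length(x)
  if (n == 1) {
    v[obs] <- stats::approx(ref_probs, ref, xout = 0.5, rule = 2)$y
    return(v)
  }
  r <- rank(x, ties.method = "average")
  q <- (r - 1) / (n - 1)
  v[obs] <- stats::approx(ref_probs, ref, xout = q, rule = 2)$y
  v
}

#' Quantile normalization of a complete matrix
#'
#' All samples are forced onto the mean empirical distribution; within-sample
#' ranks are preserved and ties receive equal values.
#'
#' @param matrix Numeric matrix genes x samples without missing values.
#' @return Normalized matrix.
#' @export
quantile_normalize <- function(matrix) {
  if (anyNA(matrix)) stop("quantile_normalize expects a complete matrix")
  if (ncol(matrix) == 1) return(matrix)
  ref <- .qn_reference(matrix)
  n <- nrow(matrix)
  probs <- if (n == 1) 0.5 else (seq_len(n) - 1) / (n - 1)
  out <- apply(matrix, 2, .qn_map_column, ref_probs = probs, ref = ref)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Column-bind studies on shared genes and quantile normalize jointly
#'
#' Matrices are combined on \code{shared_genes} (missing where a platform
#' lacks a gene) and quantile normalized across all samples jointly. The
#' reference distribution is computed from complete genes (genes observed in
#' every sample); samples with missing genes are mapped by interpolating the
#' reference at their observed ranks. After normalization all samples without
#' missing genes share an identical sorted value vector.
#'
#' @param matrices List of genes x samples matrices.
#' @param shared_genes Genes to keep (non-empty).
#' @return Combined normalized matrix, \code{shared_genes} x all samples.
#' @export
combine_and_normalize <- function(matrices, shared_genes) {
  if (length(shared_genes) == 0) stop("shared_genes must be non-empty")
  blocks <- lapply(matrices, function(m) {
    out <- matrix(NA_real_, length(shared_genes), ncol(m),
                  dimnames = list(shared_genes, colnames(m)))
    common <- intersect(shared_genes, rownames(m))
    out[common, ] <- m[common, , drop = FALSE]
    out
  })
  comb <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(comb))) stop("duplicate sample ids across studies")
  if (ncol(comb) == 1) return(comb)
  complete <- rowSums(is.na(comb)) == 0
  if (sum(complete) < 2) stop("fewer than 2 complete genes; cannot normalize")
  ref <- .qn_reference(comb[complete, , drop = FALSE])
  k <- length(ref)
  probs <- (seq_len(k) - 1) / (k - 1)
  out <- apply(comb, 2, .qn_map_column, ref_probs = probs, ref = ref)
  dimnames(out) <- dimnames(comb)
  out
}

#' Background expression level from sex-specific genes
#'
#' The signal of sex-specific genes in the non-expressing sex (e.g. Y-linked
#' genes in females) indicates the array background. Returns the median of
#' those values plus \code{margin}; with the default margin of 0.8 a
#' background median of 5.2 yields the filtering threshold 6.0.
#'
#' @param matrix Integrated genes x samples matrix.
#' @param meta Sample table with a \code{sex} column (\code{M}/\code{F}).
#' @param sex_genes data.frame with \code{gene} and \code{expressed_sex}.
#' @param margin Added to the background median; default 0.8.
#' @return List with \code{threshold} and \code{background_median}.
#' @export
background_threshold <- function(matrix, meta, sex_genes, margin = 0.8) {
  stopifnot(all(c("gene", "expressed_sex") %in% names(sex_genes)))
  sex <- meta$sex[match(colnames(matrix), meta$sample_id)]
  if (!all(c("M", "F") %in% sex)) {
    stop("need at least one sample of each sex")
  }
  present <- sex_genes[sex_genes$gene %in% rownames(matrix), , drop = FALSE]
  if (nrow(present) == 0) stop("no sex-specific genes present in matrix")
  vals <- unlist(lapply(seq_len(nrow(present)), function(i) {
    non_expr <- sex != present$expressed_sex[i]
    v <- matrix[present$gene[i], non_expr]
    v[!is.na(v)]
  }))
  if (length(vals) == 0) stop("no background values available")
  bg <- stats::median(vals)
  list(threshold = bg + margin, background_median = bg)
}

#' Filter non-expressed genes
#'
#' Keeps genes whose median expression across non-missing samples is at or
#' above the threshold. The gene median is used as the summary statistic.
#'
#' @param matrix Genes x samples matrix.
#' @param threshold Finite expression threshold (log2 scale).
#' @return Filtered matrix.
#' @export
filter_expressed <- function(matrix, threshold) {
  if (!is.finite(threshold) && threshold != -Inf) {
    stop("threshold must be finite (or -Inf for no filtering)")
  }
  med <- apply(matrix, 1, stats::median, na.rm = TRUE)
  keep <- !is.na(med) & med >= threshold
  if (!any(keep)) stop("expression filter removed every gene")
  matrix[keep, , drop = FALSE]
}

#' Remove blacklisted genes
#'
#' Genes measured by transgene-contaminated probes (e.g. Thy1 in models with
#' Thy1-driven constructs) are removed. Blacklist entries absent from the
#' matrix are reported, not errors.
#'
#' @param matrix Genes x samples matrix.
#' @param blacklist Character vector of genes to drop.
#' @return Matrix without the listed genes.
#' @export
exclude_genes <- function(matrix, blacklist) {
  if (length(blacklist) == 0) return(matrix)
  absent <- setdiff(blacklist, rownames(matrix))
  if (length(absent)) {
    message("blacklist entries not present: ", paste(absent, collapse = ", "))
  }
  matrix[setdiff(rownames(matrix), blacklist), , drop = FALSE]
}

#' Integrate a multi-study cohort into one expression matrix
#'
#' Fixed pipeline: per-study quantile normalization, outlier removal, batch
#' adjustment, shared-gene selection across platforms, joint combine +
#' quantile normalization, background-guided expression filter, blacklist
#' exclusion. Every removed sample or gene and every threshold is recorded in
#' the returned provenance.
#'
#' @param studies List of per-study bundles (\code{expr}, \code{meta}) as
#'   produced by \code{\link{generate_cohort}}, or equivalent.
#' @param sex_genes Sex-specific gene table for the background estimate.
#' @param outlier_k Outlier threshold in standard deviations; default 2.
#' @param fraction Platform fraction for shared-gene selection; default 2/3.
#' @param margin Background margin; default 0.8.
#' @param blacklist Genes removed last; default \code{"Thy1"}.
#' @param filter Apply the background expression filter; default TRUE.
#' @return List with \code{expr} (integrated matrix), \code{meta} (samples
#'   kept), \code{threshold} and \code{provenance}.
#' @export
integrate_cohort <- function(studies, sex_genes = default_sex_genes(),
                             outlier_k = 2, fraction = 2 / 3, margin = 0.8,
                             blacklist = "Thy1", filter = TRUE) {
  prov <- list(order = c("per-study QN", "outlier removal", "batch adjust",
                         "shared-gene selection", "combine+QN",
                         "background filter", "blacklist"),
               outlier_k = outlier_k, fraction = fraction, margin = margin,
               outliers = list(), constant = list())
  processed <- list()
  metas <- list()
  platforms <- character(0)
  for (b in studies) {
    sid <- b$meta$study_id[1]
    m <- b$expr
    measured <- rowSums(!is.na(m)) > 0
    m_obs <- quantile_normalize(m[measured, , drop = FALSE])

    flag <- detect_outliers(m_obs, k = outlier_k)
    bad <- union(flag$outliers, flag$constant)
    if (length(bad) > 0.5 * ncol(m_obs)) {
      stop(sprintf("study %s: outlier rule would remove %d of %d samples",
                   sid, length(bad), ncol(m_obs)))
    }
    prov$outliers[[sid]] <- flag$outliers
    prov$constant[[sid]] <- flag$constant
    keep <- setdiff(colnames(m_obs), bad)
    m_obs <- m_obs[, keep, drop = FALSE]
    meta <- b$meta[b$meta$sample_id %in% keep, , drop = FALSE]

    m_obs <- batch_adjust(m_obs, meta$batch[match(colnames(m_obs),
                                                  meta$sample_id)])
    full <- matrix(NA_real_, nrow(m), ncol(m_obs),
                   dimnames = list(rownames(m), colnames(m_obs)))
    full[rownames(m_obs), ] <- m_obs
    processed[[sid]] <- full
    metas[[sid]] <- meta
    platforms[sid] <- meta$platform_id[1]
  }

  shared <- select_shared_genes(processed, platforms = platforms,
                                fraction = fraction)
  prov$n_shared_genes <- length(shared)
  combined <- combine_and_normalize(processed, shared)
  meta <- do.call(rbind, c(metas, make.row.names = FALSE))

  if (filter) {
    bt <- background_threshold(combined, meta, sex_genes, margin = margin)
    prov$background_median <- bt$background_median
    prov$threshold <- bt$threshold
    before <- nrow(combined)
    combined <- filter_expressed(combined, bt$threshold)
    prov$genes_filtered <- before - nrow(combined)
    threshold <- bt$threshold
  } else {
    threshold <- -Inf
  }
  prov$blacklist_removed <- intersect(blacklist, rownames(combined))
  combined <- exclude_genes(combined, blacklist)

  list(expr = combined, meta = meta, threshold = threshold,
       provenance = prov)
}
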