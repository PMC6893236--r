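#' Benjamini-Hochberg false discovery rates
#'
#' Standard step-up adjustment (sorted ascending, adjusted value
#' \eqn{\min_{j \ge i} p_j m / j}, capped at 1, returned in input order).
#' Missing p-values propagate and are excluded from the number of tests m.
#'
#' @param pvalues Numeric vector of p-values in [0, 1] (NA/NaN allowed).
#' @return Adjusted values in input order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- pvalues
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Directional gene ranking by ascending p-value
#'
#' Genes are split by the sign of the disease coefficient; within each
#' direction, rank 1 is the smallest p-value, ties broken by larger absolute
#' effect, then gene id. Genes with a coefficient of exactly zero (or
#' unconverged fits) get no direction and no rank.
#'
#' @param stats data.frame with columns \code{gene}, \code{beta}, \code{p}.
#' @return The input with \code{direction} (\code{up}/\code{down}/NA) and
#'   \code{rank} columns added.
#' @export
rank_genes <- function(stats) {
  stopifnot(all(c("gene", "beta", "p") %in% names(stats)))
  direction <- rep(NA_character_, nrow(stats))
  usable <- !is.na(stats$beta) & !is.na(stats$p)
  direction[usable & stats$beta > 0] <- "up"
  direction[usable & stats$beta < 0] <- "down"
  if (any(usable & stats$beta == 0)) {
    message(sum(usable & stats$beta == 0),
            " gene(s) with zero effect assigned to neither direction")
  }
  rank_out <- rep(NA_real_, nrow(stats))
  for (d in c("up", "down")) {
    idx <- which(!is.na(direction) & direction == d)
    if (length(idx) == 0) next
    ord <- idx[order(stats$p[idx], -abs(stats$beta[idx]), stats$gene[idx])]
    rank_out[ord] <- seq_along(ord)
  }
  stats$direction <- direction
  stats$rank <- rank_out
  stats
}

#' Leave-one-study-out jackknife gene ranking
#'
#' Refits the per-gene models once with every study withheld plus once on all
#' studies, producing one directional ranking per replicate. The aggregated
#' rank of a gene is the mean of its per-replicate ranks (replicates where
#' the gene loses all observations, or fails to fit, are treated as missing),
#' so a gene whose signal collapses when one study is withheld is penalized;
#' ties are broken by the all-study p-value, then gene id. The direction
#' consistency flag is true iff the disease coefficient has the same sign in
#' every replicate in which it was estimable. With fewer than
#' \code{min_studies} studies the jackknife is skipped and the all-study
#' ranking returned with a warning.
#'
#' @param expr Integrated genes x samples matrix.
#' @param meta Sample table.
#' @param mgps Optional \code{mgp_table} (MGP-corrected variant). Scores are
#'   estimated once on the full set and row-subset per replicate.
#' @param variant Label for the output (see \code{\link{fit_all_genes}}).
#' @param min_studies Minimum number of studies for the jackknife; default 3.
#' @return data.frame: all-study statistics plus \code{agg_rank} (mean
#'   replicate rank), \code{jackknife_rank} (1..n within direction after
#'   aggregation), \code{direction_consistent}, \code{n_replicates}.
#' @export
jackknife_rank <- function(expr, meta, mgps = NULL, variant = NULL,
                           min_studies = 3) {
  studies <- unique(meta$study_id)
  all_fit <- fit_all_genes(expr, meta, mgps = mgps, variant = variant)
  if (length(studies) < min_studies) {
    warning("fewer than ", min_studies,
            " studies; jackknife skipped, all-study ranking returned")
    all_fit$agg_rank <- all_fit$rank
    all_fit$jackknife_rank <- all_fit$rank
    all_fit$direction_consistent <- TRUE
    all_fit$n_replicates <- 1L
    return(all_fit)
  }
  scores <- if (inherits(mgps, "mgp_table")) mgps$scores else mgps
  reps <- lapply(studies, function(s) {
    keep <- meta$sample_id[meta$study_id != s]
    fit_all_genes(expr[, keep, drop = FALSE],
                  meta[meta$study_id != s, , drop = FALSE],
                  mgps = if (is.null(scores)) NULL else
                    scores[intersect(rownames(scores), keep), , drop = FALSE],
                  variant = variant)
  })
  reps <- c(list(all_fit), reps)
  genes <- all_fit$gene
  rank_mat <- vapply(reps, function(r) r$rank[match(genes, r$gene)],
                     numeric(length(genes)))
  beta_mat <- vapply(reps, function(r) r$beta[match(genes, r$gene)],
                     numeric(length(genes)))
  agg <- rowMeans(rank_mat, na.rm = TRUE)
  agg[is.nan(agg)] <- NA
  consistent <- apply(beta_mat, 1, function(b) {
    b <- b[!is.na(b)]
    length(b) > 0 && (all(b > 0) || all(b < 0))
  })
  out <- all_fit
  out$agg_rank <- agg
  out$direction_consistent <- consistent
  out$n_replicates <- length(reps)
  out$jackknife_rank <- NA_real_
  for (d in c("up", "down")) {
    idx <- which(!is.na(out$direction) & out$direction == d & !is.na(agg))
    if (length(idx) == 0) next
    ord <- idx[order(agg[idx], out$p[idx], out$gene[idx])]
    out$jackknife_rank[ord] <- seq_along(ord)
  }
  out
}

#' Spearman correlation between two directional rankings
#'
#' Each ranking is converted to a signed score (up-regulated genes positive,
#' most significant largest; down-regulated negative, most significant most
#' negative) and the Spearman rank correlation is computed over the genes
#' ranked in both.
#'
#' @param r1,r2 data.frames as returned by \code{\link{fit_all_genes}} or
#'   \code{\link{jackknife_rank}} (columns gene, direction, rank).
#' @param rank_col Which rank column to use; default \code{"rank"}.
#' @return Spearman correlation coefficient.
#' @export
compare_rankings <- function(r1, r2, rank_col = "rank") {
  s1 <- .signed_scores(r1, rank_col)
  s2 <- .signed_scores(r2, rank_col)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0) stop("no genes in common between rankings")
  stats::cor(s1[common], s2[common], method = "spearman")
}

.signed_scores <- function(r, rank_col = "rank") {
  ok <- !is.na(r$direction) & !is.na(r[[rank_col]])
  r <- r[ok, , drop = FALSE]
  n_up <- sum(r$direction == "up")
  n_down <- sum(r$direction == "down")
  s <- ifelse(r$direction == "up",
              n_up + 1 - r[[rank_col]],
              -(n_down + 1 - r[[rank_col]]))
  stats::setNames(s, r$gene)
}

#' Ordered gene list from a directional ranking
#'
#' Flattens a directional ranking into a single ordered list for threshold-
#' free enrichment: most significant up-regulated gene first, down-regulated
#' genes at the bottom (most significant last), undirected genes in between.
#' With \code{direction = "down"} the list is reversed.
#'
#' @param stats Ranked data.frame (gene, direction, rank columns).
#' @param direction Which end of the ranking goes on top.
#' @param rank_col Rank column to order by; default \code{"rank"}.
#' @return Character vector of gene ids.
#' @export
signed_ranking <- function(stats, direction = c("up", "down"),
                           rank_col = "rank") {
  direction <- match.arg(direction)
  s <- .signed_scores(stats, rank_col)
  undirected <- setdiff(stats$gene, names(s))
  up <- names(sort(s[s > 0], decreasing = TRUE))
  down <- names(sort(s[s < 0], decreasing = TRUE))
  ordered <- c(up, undirected, down)
  if (direction == "down") ordered <- rev(ordered)
  ordered
}
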