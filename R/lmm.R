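# Random-intercept Gaussian mixed model, maximum likelihood.
#
# y = X beta + u_study + e,  u ~ N(0, s2_u), e ~ N(0, s2_e).
# With lambda = s2_u / s2_e, V0 = I + lambda Z Z' has the closed-form inverse
# within group j of size n_j:  V0^-1 = I - lambda/(1 + n_j lambda) 1 1'.
# beta and s2_e are profiled out analytically; only lambda is searched.

.lmm_structure <- function(X, g) {
  ng <- tabulate(g)
  list(X = X, g = g, ng = ng,
       GX = rowsum(X, g, reorder = TRUE),
       n = nrow(X), p = ncol(X))
}

.lmm_profile <- function(lambda, y, st, Gy) {
  cj <- lambda / (1 + lambda * st$ng)
  Wy <- y - cj[st$g] * Gy[st$g]
  WX <- st$X - cj[st$g] * st$GX[st$g, , drop = FALSE]
  XtWX <- crossprod(st$X, WX)
  XtWy <- crossprod(st$X, Wy)
  beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
  if (is.null(beta)) return(list(ll = -Inf))
  rss <- sum(y * Wy) - sum(beta * XtWy)
  if (!is.finite(rss) || rss <= 0) return(list(ll = -Inf))
  sigma2 <- rss / st$n
  ll <- -0.5 * (st$n * log(2 * pi * sigma2) + st$n +
                  sum(log1p(lambda * st$ng)))
  list(ll = ll, beta = beta, sigma2 = sigma2, XtWX = XtWX)
}

.lmm_lambda_grid <- function() c(0, 10^seq(-4, 3, length.out = 36))

.lmm_fit <- function(y, X, g) {
  st <- .lmm_structure(X, g)
  Gy <- rowsum(y, g, reorder = TRUE)[, 1]
  grid <- .lmm_lambda_grid()
  lls <- vapply(grid, function(l) .lmm_profile(l, y, st, Gy)$ll, 0)
  if (all(!is.finite(lls))) {
    return(list(converged = FALSE))
  }
  i <- which.max(lls)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  lambda <- grid[i]
  if (hi > lo) {
    opt <- stats::optimize(function(l) .lmm_profile(l, y, st, Gy)$ll,
                           interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-9)
    if (opt$objective > lls[i]) lambda <- opt$maximum
  }
  best <- .lmm_profile(lambda, y, st, Gy)
  at_zero <- .lmm_profile(0, y, st, Gy)
  if (is.finite(at_zero$ll) && at_zero$ll >= best$ll) {
    lambda <- 0
    best <- at_zero
  }
  beta <- best$beta[, 1]
  names(beta) <- colnames(X)
  vcov_beta <- tryCatch(solve(best$XtWX) * best$sigma2,
                        error = function(e) NULL)
  list(converged = TRUE, beta = beta, lambda = lambda,
       sigma2_resid = best$sigma2, sigma2_study = lambda * best$sigma2,
       loglik = best$ll, vcov = vcov_beta, n = st$n)
}

#' Fit a random-study-intercept mixed model for one gene
#'
#' Maximizes the marginal Gaussian likelihood of
#' \eqn{y = X\beta + u_{study} + \epsilon} by profile likelihood over the
#' variance ratio \eqn{\sigma^2_{study}/\sigma^2_{resid}} (bounded scalar
#' search over a grid plus golden-section refinement), with a GLS solve for
#' \eqn{\beta} at each step. The boundary estimate
#' \eqn{\sigma^2_{study} = 0} is permitted. X holds an intercept, the disease
#' indicator (control = 0, case = 1) and, when \code{mgps} is supplied, the
#' per-cell-type unit scores. With fewer than two studies the model degrades
#' to a fixed-intercept fit with a warning.
#'
#' @param y Named numeric vector of log2 expression, one value per sample;
#'   missing values are excluded.
#' @param meta Sample table (\code{sample_id}, \code{study_id},
#'   \code{disease}).
#' @param mgps Optional \code{mgp_table} (or a samples x celltypes matrix of
#'   unit scores) entering as fixed covariates.
#' @param include_disease Set FALSE to fit the reduced model without the
#'   disease term (the null model of \code{\link{lrt_disease}}).
#' @return Object of class \code{lmm_fit}: coefficients, \code{beta_disease},
#'   \code{se_disease}, \code{wald_z}, variance components, \code{loglik}
#'   (ML), \code{n_obs}, \code{samples}, \code{converged}.
#' @export
fit_gene_lmm <- function(y, meta, mgps = NULL, include_disease = TRUE) {
  if (is.null(names(y))) stop("y must be named by sample id")
  obs <- names(y)[is.finite(y)]
  if (length(obs) < 4) stop("too few observed samples")
  yy <- y[obs]
  if (stats::sd(yy) == 0) stop("zero residual variance: y is constant")
  idx <- match(obs, meta$sample_id)
  if (anyNA(idx)) stop("metadata missing for some samples")
  disease <- as.integer(meta$disease[idx] == "case")
  if (include_disease && length(unique(disease)) < 2) {
    stop("disease status does not vary among observed samples")
  }
  studies <- meta$study_id[idx]
  single_study <- length(unique(studies)) < 2
  if (single_study) {
    warning("fewer than 2 studies with data; fitting fixed-intercept model")
  }
  X <- cbind(`(Intercept)` = rep(1, length(obs)))
  if (include_disease) X <- cbind(X, disease = disease)
  if (!is.null(mgps)) {
    scores <- if (inherits(mgps, "mgp_table")) mgps$scores else mgps
    midx <- match(obs, rownames(scores))
    if (anyNA(midx)) stop("MGP scores missing for some samples")
    X <- cbind(X, scores[midx, , drop = FALSE])
  }
  keep <- c(TRUE, vapply(seq_len(ncol(X))[-1],
                         function(j) stats::sd(X[, j]) > 0, TRUE))
  X <- X[, keep, drop = FALSE]
  if (include_disease && !"disease" %in% colnames(X)) {
    stop("disease status does not vary among observed samples")
  }
  g <- as.integer(factor(studies))
  fit <- if (single_study) {
    st <- .lmm_structure(X, g)
    Gy <- rowsum(yy, g, reorder = TRUE)[, 1]
    b <- .lmm_profile(0, yy, st, Gy)
    if (!is.finite(b$ll)) list(converged = FALSE) else {
      beta <- b$beta[, 1]; names(beta) <- colnames(X)
      list(converged = TRUE, beta = beta, lambda = 0,
           sigma2_resid = b$sigma2, sigma2_study = 0, loglik = b$ll,
           vcov = tryCatch(solve(b$XtWX) * b$sigma2,
                           error = function(e) NULL),
           n = st$n)
    }
  } else {
    .lmm_fit(yy, X, g)
  }
  if (!fit$converged) {
    return(structure(list(converged = FALSE, n_obs = length(obs),
                          samples = obs), class = "lmm_fit"))
  }
  se <- if (!is.null(fit$vcov)) sqrt(diag(fit$vcov)) else
    rep(NA_real_, ncol(X))
  names(se) <- colnames(X)
  structure(list(coefficients = fit$beta,
                 beta_disease = unname(fit$beta["disease"]),
                 se_disease = unname(se["disease"]),
                 wald_z = unname(fit$beta["disease"] / se["disease"]),
                 sigma2_study = fit$sigma2_study,
                 sigma2_resid = fit$sigma2_resid,
                 lambda = fit$lambda,
                 loglik = fit$loglik, n_obs = fit$n,
                 samples = obs, converged = TRUE),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("lmm_fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "lmm_fit: n=%d, beta_disease=%.4f, s2_study=%.4g, s2_resid=%.4g, logLik=%.3f\n",
    x$n_obs, x$beta_disease, x$sigma2_study, x$sigma2_resid, x$loglik))
  invisible(x)
}

#' Likelihood-ratio test for the disease effect
#'
#' Compares nested ML fits (full with disease term, reduced without) on
#' identical samples. The statistic \eqn{\Lambda = 2(ll_f - ll_r)}, clipped
#' at zero, is referred to a chi-square distribution with one degree of
#' freedom. With a boundary estimate of the study variance the test is
#' conservative.
#'
#' @param full,reduced \code{lmm_fit} objects on the same samples.
#' @return The p-value, with the statistic as attribute \code{statistic}.
#' @export
lrt_disease <- function(full, reduced) {
  if (!full$converged || !reduced$converged) {
    stop("both fits must have converged")
  }
  if (!setequal(full$samples, reduced$samples)) {
    stop("full and reduced fits use different sample sets")
  }
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  attr(p, "statistic") <- stat
  p
}

# One fit pair (full/reduced) for a gene; design structures are cached by
# missingness pattern in `cache` (an environment) across genes.
.fit_gene_pair <- function(y, meta, scores, cache) {
  obs <- names(y)[is.finite(y)]
  if (length(obs) < 4) return(NULL)
  yy <- y[obs]
  if (stats::sd(yy) == 0) return(NULL)
  key <- paste(obs, collapse = "\r")
  ds <- cache[[key]]
  if (is.null(ds)) {
    idx <- match(obs, meta$sample_id)
    disease <- as.integer(meta$disease[idx] == "case")
    if (length(unique(disease)) < 2) return(NULL)
    g <- as.integer(factor(meta$study_id[idx]))
    Xr <- cbind(`(Intercept)` = rep(1, length(obs)))
    if (!is.null(scores)) {
      midx <- match(obs, rownames(scores))
      if (anyNA(midx)) return(NULL)
      sc <- scores[midx, , drop = FALSE]
      sc <- sc[, apply(sc, 2, stats::sd) > 0, drop = FALSE]
      Xr <- cbind(Xr, sc)
    }
    Xf <- cbind(Xr[, 1, drop = FALSE], disease = disease,
                Xr[, -1, drop = FALSE])
    ds <- list(st_f = .lmm_structure(Xf, g), st_r = .lmm_structure(Xr, g),
               g = g)
    cache[[key]] <- ds
  }
  full <- .lmm_fit_st(yy, ds$st_f, ds$g)
  red <- .lmm_fit_st(yy, ds$st_r, ds$g)
  if (!full$converged || !red$converged) return(NULL)
  stat <- max(0, 2 * (full$loglik - red$loglik))
  se <- if (!is.null(full$vcov)) sqrt(full$vcov["disease", "disease"]) else NA
  list(beta = unname(full$beta["disease"]), se = se,
       p = stats::pchisq(stat, 1, lower.tail = FALSE),
       n_obs = length(obs),
       sigma2_study = full$sigma2_study, sigma2_resid = full$sigma2_resid)
}

# .lmm_fit with a precomputed structure (avoids rebuilding rowsums of X)
.lmm_fit_st <- function(y, st, g) {
  Gy <- rowsum(y, g, reorder = TRUE)[, 1]
  grid <- .lmm_lambda_grid()
  lls <- vapply(grid, function(l) .lmm_profile(l, y, st, Gy)$ll, 0)
  if (all(!is.finite(lls))) return(list(converged = FALSE))
  i <- which.max(lls)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  lambda <- grid[i]
  if (hi > lo) {
    opt <- stats::optimize(function(l) .lmm_profile(l, y, st, Gy)$ll,
                           interval = c(lo, hi), maximum = TRUE, tol = 1e-9)
    if (opt$objective > lls[i]) lambda <- opt$maximum
  }
  best <- .lmm_profile(lambda, y, st, Gy)
  at_zero <- .lmm_profile(0, y, st, Gy)
  if (is.finite(at_zero$ll) && at_zero$ll >= best$ll) {
    lambda <- 0
    best <- at_zero
  }
  beta <- best$beta[, 1]
  names(beta) <- colnames(st$X)
  list(converged = TRUE, beta = beta, lambda = lambda,
       sigma2_resid = best$sigma2, sigma2_study = lambda * best$sigma2,
       loglik = best$ll,
       vcov = tryCatch({
         v <- solve(best$XtWX) * best$sigma2
         dimnames(v) <- list(colnames(st$X), colnames(st$X))
         v
       }, error = function(e) NULL))
}

#' Per-gene differential expression across all genes
#'
#' Fits the full (with disease) and reduced (without) random-study-intercept
#' models per gene by maximum likelihood, computes the likelihood-ratio
#' p-value for the disease effect, Benjamini-Hochberg FDR across genes, the
#' direction of change, and directional ranks. Genes with too few
#' observations, constant values, or non-varying disease status are reported
#' unconverged and excluded from ranking.
#'
#' @param expr Integrated genes x samples log2 matrix.
#' @param meta Sample table.
#' @param mgps Optional \code{mgp_table} used as covariates
#'   (the MGP-corrected model variant).
#' @param variant Label recorded in the output: \code{"uncorrected"} or
#'   \code{"mgp_corrected"}; inferred from \code{mgps} when missing.
#' @return data.frame: gene, beta, se, wald_z (secondary Wald statistic for
#'   comparison with the LRT), p, fdr, direction, rank, n_obs, sigma2_study,
#'   sigma2_resid, converged, model_variant.
#' @export
fit_all_genes <- function(expr, meta, mgps = NULL, variant = NULL) {
  if (is.null(variant)) {
    variant <- if (is.null(mgps)) "uncorrected" else "mgp_corrected"
  }
  scores <- if (inherits(mgps, "mgp_table")) mgps$scores else mgps
  cache <- new.env(parent = emptyenv())
  genes <- rownames(expr)
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    r <- .fit_gene_pair(expr[i, ], meta, scores, cache)
    rows[[i]] <- if (is.null(r)) {
      data.frame(gene = genes[i], beta = NA_real_, se = NA_real_,
                 p = NA_real_, n_obs = sum(is.finite(expr[i, ])),
                 sigma2_study = NA_real_, sigma2_resid = NA_real_,
                 converged = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(gene = genes[i], beta = r$beta, se = r$se, p = r$p,
                 n_obs = r$n_obs, sigma2_study = r$sigma2_study,
                 sigma2_resid = r$sigma2_resid, converged = TRUE,
                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$wald_z <- out$beta / out$se
  out$fdr <- bh_fdr(out$p)
  out$model_variant <- variant
  rank_genes(out)
}
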