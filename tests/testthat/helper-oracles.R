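# Independent oracles used by the tests. Each re-derives the expected
# quantity by a route separate from the package implementation (dense matrix
# algebra, exhaustive enumeration, direct formulas).

# Benjamini-Hochberg step-up, direct formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact two-sided Wilcoxon rank-sum p by exhaustive enumeration of all
# C(n, m) group labelings (no ties assumed)
oracle_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(m)])
  ws <- apply(utils::combn(n, m), 2, function(ii) sum(r[ii]))
  min(1, 2 * min(mean(ws <= obs), mean(ws >= obs)))
}

# ML log-likelihood of the random-intercept model by dense grid search over
# the variance ratio, using explicit covariance matrices
oracle_lmm_grid_ll <- function(y, X, g,
                               lambdas = c(0, exp(seq(log(1e-4), log(1e3),
                                                      length.out = 800)))) {
  n <- length(y)
  Z <- outer(g, sort(unique(g)), `==`) * 1
  ZZt <- tcrossprod(Z)
  best <- -Inf
  for (l in lambdas) {
    V <- diag(n) + l * ZZt
    Vi <- solve(V)
    XtVi <- crossprod(X, Vi)
    beta <- solve(XtVi %*% X, XtVi %*% y)
    r <- y - X %*% beta
    rss <- as.numeric(crossprod(r, Vi %*% r))
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + n +
                    as.numeric(determinant(V)$modulus))
    if (ll > best) best <- ll
  }
  best
}

# Same grid oracle for many genes sharing one design: V is inverted once per
# lambda, the per-gene GLS is then cheap
oracle_lmm_grid_ll_many <- function(Y, X, g,
                                    lambdas = c(0, exp(seq(log(1e-4),
                                                           log(1e3),
                                                           length.out = 800)))) {
  n <- ncol(Y)
  Z <- outer(g, sort(unique(g)), `==`) * 1
  ZZt <- tcrossprod(Z)
  best <- rep(-Inf, nrow(Y))
  for (l in lambdas) {
    V <- diag(n) + l * ZZt
    Vi <- solve(V)
    ldet <- as.numeric(determinant(V)$modulus)
    XtVi <- crossprod(X, Vi)
    A <- solve(XtVi %*% X)
    for (i in seq_len(nrow(Y))) {
      y <- Y[i, ]
      beta <- A %*% (XtVi %*% y)
      r <- y - X %*% beta
      rss <- as.numeric(crossprod(r, Vi %*% r))
      ll <- -0.5 * (n * log(2 * pi * rss / n) + n + ldet)
      if (ll > best[i]) best[i] <- ll
    }
  }
  best
}

# Average precision of a member set at given ranking positions, direct loop
oracle_average_precision <- function(positions) {
  pos <- sort(positions)
  prec <- numeric(length(pos))
  for (i in seq_along(pos)) prec[i] <- i / pos[i]
  mean(prec)
}

# Noise-free bulk mixture evaluated gene by gene, sample by sample
oracle_mixture_log2 <- function(base_expr, P, delta, case) {
  G <- nrow(base_expr)
  n <- nrow(P)
  K <- ncol(base_expr)
  out <- matrix(NA_real_, G, n, dimnames = list(rownames(base_expr), NULL))
  for (i in seq_len(n)) {
    for (g in seq_len(G)) {
      s <- 0
      for (k in seq_len(K)) {
        s <- s + P[i, k] * base_expr[g, k] * 2^(delta[g, k] * case[i])
      }
      out[g, i] <- log2(s)
    }
  }
  out
}

# Small helpers to build fixtures
make_meta <- function(study, disease, phase = "late", sex = NULL,
                      batch = NULL) {
  n <- length(study)
  data.frame(sample_id = sprintf("s%03d", seq_len(n)), study_id = study,
             platform_id = study, disease = disease, phase = phase,
             sex = if (is.null(sex)) rep(c("M", "F"), length.out = n) else sex,
             batch = if (is.null(batch)) paste0(study, "_b1") else batch,
             stringsAsFactors = FALSE)
}

make_mgp_table <- function(values, sample_ids, celltype = "ct1") {
  scores <- matrix(values, ncol = 1, dimnames = list(sample_ids, celltype))
  structure(list(scores = scores, raw = scores,
                 var_explained = stats::setNames(1, celltype),
                 markers_used = stats::setNames(list("m1"), celltype),
                 skipped = character(0)),
            class = "mgp_table")
}
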