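test_that("probe collapse keeps the highest-median probe per gene", {
  m <- rbind(p1 = c(7, 7, 7), p2 = c(9, 9, 9), p3 = c(8, 8, 8))
  colnames(m) <- paste0("s", 1:3)
  pm <- data.frame(probe = c("p1", "p2", "p3", "p3"),
                   gene = c("A", "A", "A", "B"), stringsAsFactors = FALSE)
  out <- collapse_probes(m, pm)
  expect_identical(rownames(out), "A")
  expect_equal(unname(out["A", ]), c(9, 9, 9))  # p3 multi-gene, discarded

  # single usable probe per gene: identity minus unmapped
  m2 <- rbind(p1 = 1:3, p2 = 4:6, px = 7:9)
  colnames(m2) <- paste0("s", 1:3)
  pm2 <- data.frame(probe = c("p1", "p2"), gene = c("A", "B"))
  out2 <- collapse_probes(m2, pm2)
  expect_equal(unname(out2), unname(m2[c("p1", "p2"), ]))

  # ties broken by lexicographically smallest probe id
  m3 <- rbind(pB = c(1, 2), pA = c(2, 1))
  colnames(m3) <- c("s1", "s2")
  pm3 <- data.frame(probe = c("pA", "pB"), gene = "G")
  expect_equal(unname(collapse_probes(m3, pm3)["G", ]), c(2, 1))

  expect_error(collapse_probes(m3, data.frame(probe = "pz", gene = "G")),
               "no usable probes")
  m3[1, 1] <- NA
  expect_error(collapse_probes(m3, pm3), "missing")
})

test_that("probe collapse matches a brute-force argmax-of-median oracle", {
  set.seed(1)
  probes <- sprintf("p%02d", 1:50)
  genes <- sprintf("G%02d", 1:10)
  m <- matrix(rnorm(50 * 12, 8, 2), 50, 12,
              dimnames = list(probes, sprintf("s%02d", 1:12)))
  pm <- data.frame(probe = probes, gene = sample(genes, 50, replace = TRUE))
  out <- collapse_probes(m, pm)
  for (g in unique(pm$gene)) {
    cand <- pm$probe[pm$gene == g]
    med <- apply(m[cand, , drop = FALSE], 1, median)
    best <- sort(cand[med == max(med)])[1]
    expect_equal(out[g, ], m[best, ], ignore_attr = TRUE)
  }
})

test_that("outlier detection flags deviant and constant samples", {
  set.seed(2)
  base <- rnorm(200, 8, 2)
  m <- sapply(1:5, function(i) base + rnorm(200, 0, 0.05))
  flipped <- mean(base) - (base - mean(base)) + rnorm(200, 0, 0.05)
  m <- cbind(m, flipped)
  colnames(m) <- paste0("s", 1:6)
  res <- detect_outliers(m, k = 2)
  expect_identical(res$outliers, "s6")
  # direct recomputation of the rule
  cm <- cor(m); diag(cm) <- NA
  mc <- rowMeans(cm, na.rm = TRUE)
  expect_identical(sort(res$outliers),
                   sort(names(mc)[abs(mc - mean(mc)) > 2 * sd(mc)]))

  expect_identical(detect_outliers(m, k = Inf)$outliers, character(0))

  m_const <- cbind(m[, 1:4], s5 = rep(5, 200))
  res2 <- detect_outliers(m_const, k = 2)
  expect_identical(res2$constant, "s5")

  expect_error(detect_outliers(m[, 1:2]), "3 samples")
  m_na <- m; m_na[1, 1] <- NA
  expect_error(detect_outliers(m_na), "missing")
})

test_that("near-identical samples produce no outliers", {
  set.seed(3)
  base <- rnorm(100, 8, 2)
  m <- sapply(1:8, function(i) base + rnorm(100, 0, 1e-4))
  colnames(m) <- paste0("s", 1:8)
  # all mean correlations essentially 1; nothing beyond 2 sd of a ~0 spread
  res <- detect_outliers(m, k = 2)
  expect_true(all(res$mean_correlation > 0.999))
})

test_that("batch adjustment centres and rescales each batch per gene", {
  set.seed(4)
  m <- matrix(rnorm(40 * 8, 8), 40, 8,
              dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:8)))
  batches <- rep(c("b1", "b2"), each = 4)

  expect_warning(out1 <- batch_adjust(m, rep("b1", 8)), "no batch adjustment")
  expect_identical(out1, m)

  off <- rnorm(40, 0, 2)
  m2 <- m
  m2[, 5:8] <- m2[, 5:8] + off
  adj <- batch_adjust(m2, batches)
  for (b in c("b1", "b2")) {
    expect_equal(unname(rowMeans(adj[, batches == b])),
                 unname(rowMeans(m2)), tolerance = 1e-10)
  }
  # per-batch sd equals the gene's overall sd (direct recomputation)
  sd_all <- apply(m2, 1, sd)
  for (b in c("b1", "b2")) {
    expect_equal(unname(apply(adj[, batches == b], 1, sd)), unname(sd_all),
                 tolerance = 1e-10)
  }

  expect_error(batch_adjust(m2, c(batches[-1], NA)), "missing")
  expect_error(batch_adjust(m2, "b1"), "one batch label per sample")
})

test_that("zero-variance batches are centred only", {
  m <- rbind(g1 = c(5, 5, 7, 9), g2 = c(1, 2, 3, 4))
  colnames(m) <- paste0("s", 1:4)
  adj <- batch_adjust(m, c("b1", "b1", "b2", "b2"))
  # g1 batch b1 has zero variance: values centred to the overall mean
  expect_equal(unname(adj["g1", 1:2]), rep(mean(m["g1", ]), 2))
})

test_that("shared-gene selection counts platforms, not studies", {
  mk <- function(genes, samples = 3) {
    matrix(1, length(genes), samples,
           dimnames = list(genes, sprintf("%s%d", paste(genes, collapse = ""),
                                          seq_len(samples))))
  }
  m1 <- mk(c("A", "B", "C")); colnames(m1) <- paste0("x", 1:3)
  m2 <- mk(c("A", "B")); colnames(m2) <- paste0("y", 1:3)
  m3 <- mk(c("A", "D")); colnames(m3) <- paste0("z", 1:3)
  shared <- select_shared_genes(list(m1, m2, m3),
                                platforms = c("P1", "P2", "P3"))
  expect_setequal(shared, c("A", "B"))  # B on 2/3 kept, C and D on 1/3 dropped

  # two studies on one platform count once: P1 = {A,B,C}, P2 = {A,D},
  # 2 platforms need ceil(2/3 * 2) = 2, so only A survives
  shared2 <- select_shared_genes(list(m1, m2, m3),
                                 platforms = c("P1", "P1", "P2"))
  expect_identical(shared2, "A")
})

test_that("shared-gene selection equals a counting oracle on random masks", {
  set.seed(5)
  genes <- sprintf("G%02d", 1:40)
  mats <- lapply(1:4, function(i) {
    keep <- sample(genes, 25)
    m <- matrix(rnorm(25 * 3), 25, 3,
                dimnames = list(keep, sprintf("s%d_%d", i, 1:3)))
    m
  })
  platforms <- paste0("P", 1:4)
  shared <- select_shared_genes(mats, platforms = platforms)
  counts <- table(unlist(lapply(mats, rownames)))
  oracle <- sort(names(counts)[counts >= ceiling(2 / 3 * 4)])
  expect_identical(shared, oracle)
  expect_error(select_shared_genes(mats[1], platforms = "P1"), "at least 2")
})

test_that("joint quantile normalization matches the hand-computable case", {
  m1 <- matrix(c(1, 3), 2, 1, dimnames = list(c("A", "B"), "s1"))
  m2 <- matrix(c(2, 4), 2, 1, dimnames = list(c("A", "B"), "s2"))
  out <- combine_and_normalize(list(m1, m2), c("A", "B"))
  expect_equal(unname(out[, "s1"]), c(1.5, 3.5))
  expect_equal(unname(out[, "s2"]), c(1.5, 3.5))
})

test_that("complete samples share identical sorted vectors after QN", {
  set.seed(6)
  genes <- sprintf("G%02d", 1:30)
  m1 <- matrix(rnorm(30 * 4, 8), 30, 4,
               dimnames = list(genes, paste0("a", 1:4)))
  m2 <- matrix(rnorm(25 * 5, 10, 2), 25, 5,
               dimnames = list(genes[1:25], paste0("b", 1:5)))
  out <- combine_and_normalize(list(m1, m2), genes)
  sorted <- apply(out[, 1:4], 2, sort)  # the complete samples
  for (j in 2:4) expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
})

test_that("quantile normalization agrees with limma on complete matrices", {
  set.seed(7)
  m <- matrix(rnorm(50 * 6, 8, 2), 50, 6,
              dimnames = list(sprintf("G%02d", 1:50), paste0("s", 1:6)))
  ours <- quantile_normalize(m)
  ref <- limma::normalizeQuantiles(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
  expect_error(combine_and_normalize(list(m[1:2, 1, drop = FALSE],
                                          m[3:4, 2, drop = FALSE]),
                                     c("G01", "G03")), "complete genes")
})

test_that("rank order within each sample survives joint normalization", {
  set.seed(8)
  genes <- sprintf("G%02d", 1:40)
  m1 <- matrix(rnorm(40 * 3, 8), 40, 3, dimnames = list(genes, paste0("a", 1:3)))
  m2 <- matrix(rnorm(30 * 3, 11, 3), 30, 3,
               dimnames = list(genes[1:30], paste0("b", 1:3)))
  out <- combine_and_normalize(list(m1, m2), genes)
  orig <- cbind(rbind(m1, matrix(NA, 0, 3)),
                rbind(m2, matrix(NA, 10, 3,
                                 dimnames = list(genes[31:40], NULL))))
  for (s in colnames(out)) {
    obs <- !is.na(out[, s])
    expect_equal(cor(orig[obs, s], out[obs, s], method = "spearman"), 1)
  }
})

test_that("background threshold reproduces the sex-gene rule", {
  genes <- c("Ddx3y", "Xist", "g1")
  m <- rbind(Ddx3y = c(9.1, 9.0, 5.0, 5.4), Xist = c(5.2, 5.3, 9.2, 9.3),
             g1 = c(7, 7, 7, 7))
  colnames(m) <- paste0("s", 1:4)
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     sex = c("M", "M", "F", "F"))
  sg <- data.frame(gene = c("Ddx3y", "Xist"), expressed_sex = c("M", "F"))
  bt <- background_threshold(m, meta, sg, margin = 0.8)
  # background values: Ddx3y in F (5.0, 5.4), Xist in M (5.2, 5.3)
  expect_equal(bt$background_median, median(c(5.0, 5.4, 5.2, 5.3)))
  expect_equal(bt$threshold, bt$background_median + 0.8)
  # a background median of 5.2 yields the expression threshold 6.0
  m2 <- m; m2["Ddx3y", 3:4] <- c(5.2, 5.2); m2["Xist", 1:2] <- c(5.2, 5.2)
  expect_equal(background_threshold(m2, meta, sg)$threshold, 6.0)
  expect_equal(background_threshold(m2, meta, sg, margin = 0)$threshold, 5.2)
  expect_error(background_threshold(m[3, , drop = FALSE], meta, sg),
               "no sex-specific genes")
  expect_error(background_threshold(m, transform(meta, sex = "M"), sg),
               "each sex")
})

test_that("expression filtering keeps genes with median above threshold", {
  set.seed(9)
  m <- matrix(rnorm(30 * 5, 6, 2), 30, 5,
              dimnames = list(sprintf("G%02d", 1:30), paste0("s", 1:5)))
  expect_identical(filter_expressed(m, -Inf), m)
  out <- filter_expressed(m, 6)
  med <- apply(m, 1, median)
  expect_setequal(rownames(out), rownames(m)[med >= 6])
  m["G01", ] <- 5
  expect_false("G01" %in% rownames(filter_expressed(m, 6)))
  expect_error(filter_expressed(m, 100), "every gene")
})

test_that("blacklisted genes are excluded, absent entries tolerated", {
  m <- matrix(1, 10, 2, dimnames = list(sprintf("G%02d", 1:10),
                                        c("s1", "s2")))
  expect_false("G01" %in% rownames(exclude_genes(m, "G01")))
  expect_identical(exclude_genes(m, character(0)), m)
  expect_equal(nrow(exclude_genes(m, c("G01", "G02", "G03"))), 7)
  expect_message(out <- exclude_genes(m, "Thy1"), "not present")
  expect_identical(out, m)
})

test_that("cohort integration runs the fixed pipeline and logs provenance", {
  cfg <- cohort_config(n_genes = 200, n_markers_per_type = 8,
                       n_control = 5, n_case = 5)
  coh <- generate_cohort(cfg, seed = 3)
  res <- integrate_cohort(coh$studies)
  expect_identical(res$provenance$order,
                   c("per-study QN", "outlier removal", "batch adjust",
                     "shared-gene selection", "combine+QN",
                     "background filter", "blacklist"))
  expect_false("Thy1" %in% rownames(res$expr))
  expect_identical(res$provenance$blacklist_removed, "Thy1")
  expect_true(res$provenance$n_shared_genes <= length(coh$profiles$gene_ids))
  expect_true(all(colnames(res$expr) %in% res$meta$sample_id))
  expect_true(res$threshold > res$provenance$background_median)
  # genes kept have median expression above the threshold
  med <- apply(res$expr, 1, median, na.rm = TRUE)
  expect_true(all(med >= res$threshold))
})

test_that("integration aborts when the outlier rule removes too many samples", {
  cfg <- cohort_config(n_genes = 150, n_markers_per_type = 5,
                       n_control = 4, n_case = 4)
  coh <- generate_cohort(cfg, seed = 4)
  expect_error(integrate_cohort(coh$studies, outlier_k = 0.1),
               "outlier rule")
})
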