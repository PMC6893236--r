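test_that("cell profiles honour marker invariants and are deterministic", {
  p1 <- generate_cell_profiles(600, 20, 8, seed = 11)
  p2 <- generate_cell_profiles(600, 20, 8, seed = 11)
  expect_identical(p1, p2)

  mk <- unlist(p1$markers, use.names = FALSE)
  expect_length(mk, 120)
  expect_equal(anyDuplicated(mk), 0L)
  expect_true(all(p1$base_expr > 0))

  # exhaustive scan: every marker at least 8-fold enriched in its own type
  B <- p1$base_expr
  for (ct in names(p1$markers)) {
    own <- B[p1$markers[[ct]], ct]
    off <- apply(B[p1$markers[[ct]], setdiff(colnames(B), ct), drop = FALSE],
                 1, max)
    expect_true(all(own / off >= 8))
  }

  expect_error(generate_cell_profiles(-5), "positive")
  expect_error(generate_cell_profiles(600, fold_enrichment = 1), "exceed 1")
  expect_error(generate_cell_profiles(60, 20, 8), "exceeds n_genes")
})

test_that("noise-free bulk generation equals the mixture formula", {
  prof <- generate_cell_profiles(120, 5, 8, seed = 3)
  des <- study_design("S1", 4, 4, study_bias_sd = 0, batch_sd = 0,
                      noise_sd = 0)
  set.seed(42)
  K <- length(prof$celltypes)
  P <- matrix(rgamma(8 * K, 2), 8)
  P <- P / rowSums(P)
  reg <- data.frame(gene = c("g0001", "g0002"),
                    celltype = c("astrocyte", "pyramidal"),
                    log2fc = c(1, -0.5), stringsAsFactors = FALSE)
  b <- generate_study(prof, des,
                      truth_params = list(fixed_proportions = P,
                                          regulated = reg),
                      seed = 5)
  D <- matrix(0, nrow(prof$base_expr), K,
              dimnames = list(prof$gene_ids, prof$celltypes))
  D[cbind(reg$gene, reg$celltype)] <- reg$log2fc
  expected <- oracle_mixture_log2(prof$base_expr, P, D,
                                  b$meta$disease == "case")
  regular <- setdiff(prof$gene_ids, c(prof$sex_genes$gene, "Thy1"))
  expect_equal(unname(b$expr[regular, ]), unname(expected[regular, ]),
               tolerance = 1e-12)
  # Thy1 is the mixture plus the transgene inflation in case samples
  expect_equal(unname(b$expr["Thy1", ]),
               unname(expected["Thy1", ] + 2 * (b$meta$disease == "case")),
               tolerance = 1e-12)
})

test_that("degenerate mixture with one cell type collapses to its profile", {
  prof <- generate_cell_profiles(60, 5, 8, seed = 9)
  des <- study_design("S1", 3, 3, study_bias_sd = 0, batch_sd = 0,
                      noise_sd = 0)
  P <- matrix(0, 6, 6)
  P[, 3] <- 1
  b <- generate_study(prof, des,
                      truth_params = list(fixed_proportions = P), seed = 2)
  regular <- setdiff(prof$gene_ids, c(prof$sex_genes$gene, "Thy1"))
  for (i in 1:6) {
    expect_equal(unname(b$expr[regular, i]),
                 unname(log2(prof$base_expr[regular, 3])), tolerance = 1e-12)
  }
})

test_that("realized proportions sum to one and are recorded in truth", {
  prof <- generate_cell_profiles(150, 5, 8, seed = 4)
  des <- study_design("S1", 6, 6)
  b <- generate_study(prof, des, seed = 7)
  expect_equal(unname(rowSums(b$truth$proportions)), rep(1, 12),
               tolerance = 1e-12)
  expect_true(all(b$truth$proportions >= 0 & b$truth$proportions <= 1))
  expect_identical(rownames(b$truth$proportions), b$meta$sample_id)
})

test_that("no-effect generation yields exchangeable groups", {
  prof <- generate_cell_profiles(400, 10, 8, seed = 21)
  shift1 <- stats::setNames(rep(1, 6), prof$celltypes)
  des <- study_design("S1", 12, 12, phase = "early")
  b <- generate_study(prof, des,
                      truth_params = list(composition_shift = shift1),
                      seed = 31)
  regular <- setdiff(prof$gene_ids, c(prof$sex_genes$gene, "Thy1"))
  case <- b$meta$disease == "case"
  tt <- apply(b$expr[regular, ], 1, function(v) {
    stats::t.test(v[case], v[!case])$statistic
  })
  expect_lt(mean(abs(tt)), 1.1)
  expect_lt(mean(abs(tt) > 3), 0.02)
})

test_that("invalid designs and parameters are rejected", {
  prof <- generate_cell_profiles(60, 5, 8, seed = 1)
  expect_error(study_design("S1", 1, 4), "two biological replicates")
  des <- study_design("S1", 3, 3)
  expect_error(generate_study(prof, des,
                              truth_params = list(conc = c(-1, 1, 1, 1, 1, 1))),
               "positive")
  expect_error(study_design("S1", 3, 3, platform_genes = character(0)),
               "non-empty")
})

test_that("cohorts are reproducible and order-invariant per study", {
  cfg <- cohort_config(n_genes = 200, n_markers_per_type = 8,
                       n_control = 3, n_case = 3, phase = "early")
  c1 <- generate_cohort(cfg, seed = 5)
  c2 <- generate_cohort(cfg, seed = 5)
  expect_identical(c1$studies, c2$studies)

  cfg_perm <- cfg
  cfg_perm$studies <- cfg$studies[c(3, 1, 2)]
  c3 <- generate_cohort(cfg_perm, seed = 5)
  for (sid in names(c1$studies)) {
    expect_identical(c1$studies[[sid]]$expr, c3$studies[[sid]]$expr)
    expect_identical(c1$studies[[sid]]$meta, c3$studies[[sid]]$meta)
  }
})

test_that("platform masks control the shared gene universe", {
  cfg_full <- cohort_config(n_genes = 150, n_markers_per_type = 5,
                            n_control = 3, n_case = 3,
                            platform_drop_frac = 0)
  coh <- generate_cohort(cfg_full, seed = 2)
  for (pg in coh$platform_genes) {
    expect_setequal(pg, coh$profiles$gene_ids)
  }
  # dropping all regular genes leaves only the always-measured specials
  coh2 <- generate_cohort(cohort_config(n_genes = 150, n_markers_per_type = 5,
                                        n_control = 3, n_case = 3,
                                        platform_drop_frac = 1), seed = 2)
  for (pg in coh2$platform_genes) {
    expect_setequal(pg, c(coh2$profiles$sex_genes$gene, "Thy1"))
  }
})

test_that("regulated genes are drawn from universally measured non-markers", {
  cfg <- cohort_config(n_genes = 300, n_markers_per_type = 10,
                       n_control = 3, n_case = 3, phase = "early",
                       regulated = list(n = 15, celltype = "pyramidal",
                                        log2fc = 1))
  coh <- generate_cohort(cfg, seed = 8)
  expect_equal(nrow(coh$regulated), 15)
  expect_false(any(coh$regulated$gene %in% unlist(coh$profiles$markers)))
  everywhere <- Reduce(intersect, coh$platform_genes)
  expect_true(all(coh$regulated$gene %in% everywhere))
})

test_that("larger microglia shifts raise expected case expression of its markers", {
  prof <- generate_cell_profiles(200, 10, 8, seed = 13)
  ct <- prof$celltypes
  means_for_shift <- function(mult) {
    shift <- stats::setNames(rep(1, 6), ct)
    shift["microglia"] <- mult
    des <- study_design("S1", 2, 200, study_bias_sd = 0, batch_sd = 0,
                        noise_sd = 0)
    b <- generate_study(prof, des,
                        truth_params = list(composition_shift = shift),
                        seed = 99)
    case <- b$meta$disease == "case"
    rowMeans(b$expr[prof$markers$microglia, case])
  }
  m1 <- means_for_shift(1)
  m2 <- means_for_shift(1.8)
  m3 <- means_for_shift(3)
  expect_true(all(m2 > m1))
  expect_true(all(m3 > m2))
})
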