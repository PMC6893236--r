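#' Cell types modelled in the hippocampal mixture
#'
#' Three neuronal and three glial cell types, the composition the bulk
#' generator mixes and the MGP module estimates.
#'
#' @return Character vector of cell-type names.
#' @export
hippocampal_celltypes <- function() {
  c("pyramidal", "dentate_granule", "gabaergic",
    "astrocyte", "microglia", "oligodendrocyte")
}

#' Default Dirichlet concentrations for hippocampal composition
#'
#' Baseline concentration parameters of the Dirichlet distribution from which
#' per-sample cell-type proportions are drawn. Neuron-dominated, reflecting
#' the cellular makeup of hippocampal tissue. These are generator defaults,
#' tunable via \code{\link{cohort_config}}.
#'
#' @return Named numeric vector, one concentration per cell type.
#' @export
default_dirichlet_conc <- function() {
  c(pyramidal = 30, dentate_granule = 20, gabaergic = 8,
    astrocyte = 10, microglia = 6, oligodendrocyte = 6)
}

#' Default disease effect on mixing weights by phase
#'
#' Multiplicative effect of disease on the Dirichlet concentrations of case
#' samples. The late-phase default encodes neurodegeneration with gliosis:
#' neurons down, astrocytes and microglia up. Early phase has no
#' composition change.
#'
#' @param phase \code{"late"} or \code{"early"}.
#' @return Named numeric vector of per-cell-type multipliers.
#' @export
default_composition_shift <- function(phase = c("late", "early")) {
  phase <- match.arg(phase)
  ct <- hippocampal_celltypes()
  if (phase == "early") return(stats::setNames(rep(1, length(ct)), ct))
  stats::setNames(c(0.7, 0.7, 0.7, 1.6, 1.8, 1.0), ct)
}

#' Default sex-specific genes
#'
#' Genes expressed in only one sex (Y-linked genes and Xist), used by the
#' integration module to estimate the array background level from the
#' non-expressing sex.
#'
#' @return data.frame with columns \code{gene} and \code{expressed_sex}.
#' @export
default_sex_genes <- function() {
  data.frame(gene = c("Ddx3y", "Uty", "Kdm5d", "Eif2s3y", "Xist"),
             expressed_sex = c("M", "M", "M", "M", "F"),
             stringsAsFactors = FALSE)
}

# Deterministic sub-seed from a master seed and a string key, so per-study
# streams are independent of study order. Kept below 2^31 - 1.
derive_seed <- function(seed, key) {
  h <- 0
  for (x in utf8ToInt(key)) h <- (h * 131 + x) %% 1048573
  as.integer((as.numeric(seed) %% 2097143) * 1021 + h %% 1021)
}

rdirichlet <- function(n, alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("Dirichlet concentration parameters must be positive")
  }
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

#' Generate cell-type expression profiles with built-in markers
#'
#' Draws per-gene per-cell-type mean expression on the linear scale and
#' designates \code{n_markers_per_type} marker genes per cell type. Every
#' marker is expressed in its own cell type at least \code{fold_enrichment}
#' times higher than in any other type, and no gene marks two types. A small
#' set of sex-specific genes and (optionally) a Thy1 transgene-artifact gene
#' are appended to the universe.
#'
#' @param n_genes Number of regular genes (markers included; special genes
#'   such as sex genes come on top).
#' @param n_markers_per_type Markers per cell type.
#' @param fold_enrichment Minimum own-type / other-type expression ratio of a
#'   marker, linear scale. Must exceed 1.
#' @param celltypes Cell-type names.
#' @param sex_genes data.frame of sex-specific genes
#'   (see \code{\link{default_sex_genes}}).
#' @param thy1_artifact Add a "Thy1" gene whose case-sample values are
#'   inflated by the transgene construct.
#' @param seed Integer seed; same seed gives bit-identical profiles.
#' @return An object of class \code{cell_profiles}: list with
#'   \code{celltypes}, \code{gene_ids}, \code{base_expr} (genes x types,
#'   linear scale), \code{markers} (named list), \code{sex_genes},
#'   \code{thy1_artifact}, \code{fold_enrichment}.
#' @export
generate_cell_profiles <- function(n_genes, n_markers_per_type = 20,
                                   fold_enrichment = 8,
                                   celltypes = hippocampal_celltypes(),
                                   sex_genes = default_sex_genes(),
                                   thy1_artifact = TRUE,
                                   seed = 1L) {
  if (length(n_genes) != 1 || !is.finite(n_genes) || n_genes <= 0) {
    stop("n_genes must be a positive integer")
  }
  if (n_markers_per_type <= 0) stop("n_markers_per_type must be positive")
  if (fold_enrichment <= 1) stop("fold_enrichment must exceed 1")
  K <- length(celltypes)
  n_marker_total <- n_markers_per_type * K
  if (n_marker_total > n_genes) {
    stop("n_markers_per_type x number of cell types exceeds n_genes")
  }
  set.seed(seed)

  abbrev <- c(pyramidal = "Pyr", dentate_granule = "Dg", gabaergic = "Gaba",
              astrocyte = "Astro", microglia = "Micro",
              oligodendrocyte = "Oligo")[celltypes]
  abbrev[is.na(abbrev)] <- abbreviate(celltypes[is.na(abbrev)], 5)
  marker_ids <- unlist(lapply(seq_len(K), function(k) {
    sprintf("%s_mk%02d", abbrev[k], seq_len(n_markers_per_type))
  }))
  filler_ids <- if (n_genes > n_marker_total) {
    sprintf("g%04d", seq_len(n_genes - n_marker_total))
  } else character(0)
  special <- c(sex_genes$gene, if (thy1_artifact) "Thy1")
  gene_ids <- c(marker_ids, filler_ids, special)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in universe")
  G <- length(gene_ids)

  # log2 means: gene-level level + type-specific deviation
  L <- matrix(stats::rnorm(G * K, 0, 0.5), G, K,
              dimnames = list(gene_ids, celltypes))
  L <- L + stats::rnorm(G, mean = 9, sd = 1.2)
  # markers: high in own type, suppressed beyond fold_enrichment elsewhere
  for (k in seq_len(K)) {
    rows <- (k - 1) * n_markers_per_type + seq_len(n_markers_per_type)
    own <- stats::rnorm(length(rows), 10, 0.5)
    L[rows, k] <- own
    for (j in setdiff(seq_len(K), k)) {
      L[rows, j] <- own - log2(fold_enrichment) - 0.3 -
        abs(stats::rnorm(length(rows), 0, 0.75))
    }
  }
  # sex genes are overridden sample-wise at study generation; placeholder
  if (nrow(sex_genes)) L[sex_genes$gene, ] <- 5.2

  markers <- stats::setNames(
    lapply(seq_len(K), function(k) {
      marker_ids[(k - 1) * n_markers_per_type + seq_len(n_markers_per_type)]
    }), celltypes)

  structure(list(celltypes = celltypes, gene_ids = gene_ids,
                 base_expr = 2^L, markers = markers,
                 sex_genes = sex_genes, thy1_artifact = thy1_artifact,
                 fold_enrichment = fold_enrichment),
            class = "cell_profiles")
}

#' @export
print.cell_profiles <- function(x, ...) {
  cat(sprintf("cell_profiles: %d genes x %d cell types, %d markers/type\n",
              length(x$gene_ids), length(x$celltypes),
              length(x$markers[[1]])))
  invisible(x)
}

#' Describe one synthetic study
#'
#' @param study_id Study identifier.
#' @param n_control,n_case Sample counts; each must be at least 2.
#' @param phase \code{"late"} or \code{"early"} disease phase.
#' @param platform_id Platform identifier (several studies may share one).
#' @param platform_genes Genes measured by the platform (NULL = all).
#' @param n_batches Number of processing batches.
#' @param sex_ratio_male Fraction of male animals.
#' @param study_bias_sd SD of the log2-normal per-gene study bias.
#' @param batch_sd SD of additive per-gene per-batch log2 offsets.
#' @param noise_sd SD of residual log2 noise.
#' @return A \code{study_design} list.
#' @export
study_design <- function(study_id, n_control, n_case,
                         phase = c("late", "early"),
                         platform_id = study_id, platform_genes = NULL,
                         n_batches = 2, sex_ratio_male = 0.5,
                         study_bias_sd = 0.2, batch_sd = 0.15,
                         noise_sd = 0.3) {
  phase <- match.arg(phase)
  if (n_control < 2 || n_case < 2) {
    stop("designs require at least two biological replicates per condition")
  }
  if (!is.null(platform_genes) && length(platform_genes) == 0) {
    stop("platform_genes must be non-empty when given")
  }
  structure(list(study_id = study_id, platform_id = platform_id,
                 platform_genes = platform_genes,
                 n_control = n_control, n_case = n_case, phase = phase,
                 n_batches = n_batches, sex_ratio_male = sex_ratio_male,
                 study_bias_sd = study_bias_sd, batch_sd = batch_sd,
                 noise_sd = noise_sd),
            class = "study_design")
}

#' Generate one bulk expression study from cell profiles
#'
#' Bulk linear expression of sample i at gene g is the proportion-weighted
#' mixture \eqn{\sum_c p_{ic} \cdot base[g,c] \cdot 2^{\delta_{gc} case_i}}
#' times a per-gene study bias; the mixture is formed on the linear scale,
#' log2-transformed, and additive batch offsets plus Gaussian log2 noise are
#' applied. Case-sample proportions are drawn from a Dirichlet whose
#' concentrations are multiplied by the composition shift. Genes outside the
#' platform mask are returned missing.
#'
#' @param profiles A \code{cell_profiles} object.
#' @param design A \code{study_design}.
#' @param truth_params Optional list: \code{conc} (Dirichlet concentrations),
#'   \code{composition_shift} (per-type multipliers for case samples),
#'   \code{regulated} (data.frame gene/celltype/log2fc of within-cell-type
#'   regulatory effects), \code{fixed_proportions} (samples x types matrix
#'   overriding the Dirichlet draw), sex-gene level parameters
#'   (\code{sex_background_mean} etc.) and \code{thy1_inflation}.
#' @param seed Integer seed.
#' @return List with \code{expr} (log2 genes x samples matrix, NA outside
#'   the platform mask), \code{meta} (sample table) and \code{truth}
#'   (realized proportions, regulated genes, composition shift).
#' @export
generate_study <- function(profiles, design, truth_params = list(),
                           seed = 1L) {
  stopifnot(inherits(profiles, "cell_profiles"),
            inherits(design, "study_design"))
  ct <- profiles$celltypes
  K <- length(ct)
  tp <- utils::modifyList(
    list(conc = default_dirichlet_conc()[ct],
         composition_shift = default_composition_shift(design$phase)[ct],
         regulated = NULL, fixed_proportions = NULL,
         sex_background_mean = 5.2, sex_background_sd = 0.25,
         sex_expressed_mean = 9, sex_expressed_sd = 0.4,
         thy1_inflation = 2),
    truth_params)
  conc <- tp$conc
  shift <- tp$composition_shift
  if (length(conc) != K || any(!is.finite(conc)) || any(conc <= 0)) {
    stop("Dirichlet concentration parameters must be positive")
  }
  if (length(shift) != K || any(shift <= 0)) {
    stop("composition_shift must be positive, one value per cell type")
  }
  set.seed(seed)

  n0 <- design$n_control; n1 <- design$n_case; n <- n0 + n1
  disease <- c(rep("control", n0), rep("case", n1))
  sample_ids <- sprintf("%s_s%02d", design$study_id, seq_len(n))

  if (!is.null(tp$fixed_proportions)) {
    P <- tp$fixed_proportions
    if (nrow(P) != n || ncol(P) != K) stop("fixed_proportions has wrong shape")
  } else {
    P <- rbind(rdirichlet(n0, conc), rdirichlet(n1, conc * shift))
  }
  dimnames(P) <- list(sample_ids, ct)

  gene_ids <- profiles$gene_ids
  G <- length(gene_ids)
  D <- matrix(0, G, K, dimnames = list(gene_ids, ct))
  if (!is.null(tp$regulated) && nrow(tp$regulated)) {
    reg <- tp$regulated
    if (!all(reg$gene %in% gene_ids)) stop("regulated genes not in universe")
    if (!all(reg$celltype %in% ct)) stop("regulated cell types unknown")
    D[cbind(match(reg$gene, gene_ids), match(reg$celltype, ct))] <- reg$log2fc
  }

  B <- profiles$base_expr
  lin <- cbind(B %*% t(P[disease == "control", , drop = FALSE]),
               (B * 2^D) %*% t(P[disease == "case", , drop = FALSE]))
  bias <- 2^stats::rnorm(G, 0, design$study_bias_sd)
  M <- log2(lin * bias)

  # balanced batch assignment within disease groups
  batch <- integer(n)
  batch[disease == "control"] <- rep_len(seq_len(design$n_batches), n0)
  batch[disease == "case"] <- rep_len(seq_len(design$n_batches), n1)
  batch_off <- matrix(stats::rnorm(G * design$n_batches, 0, design$batch_sd),
                      G, design$n_batches)
  M <- M + batch_off[, batch, drop = FALSE]
  M <- M + matrix(stats::rnorm(G * n, 0, design$noise_sd), G, n)

  # sex assignment, balanced within disease groups
  sex <- character(n)
  for (d in c("control", "case")) {
    idx <- which(disease == d)
    nm <- round(design$sex_ratio_male * length(idx))
    s <- c(rep("M", nm), rep("F", length(idx) - nm))
    sex[idx] <- sample(s)
  }
  sg <- profiles$sex_genes
  if (nrow(sg)) {
    for (i in seq_len(nrow(sg))) {
      expressed <- sex == sg$expressed_sex[i]
      M[sg$gene[i], expressed] <-
        stats::rnorm(sum(expressed), tp$sex_expressed_mean, tp$sex_expressed_sd)
      M[sg$gene[i], !expressed] <-
        stats::rnorm(sum(!expressed), tp$sex_background_mean, tp$sex_background_sd)
    }
  }
  if (profiles$thy1_artifact && "Thy1" %in% gene_ids) {
    M["Thy1", disease == "case"] <- M["Thy1", disease == "case"] +
      tp$thy1_inflation
  }

  if (!is.null(design$platform_genes)) {
    absent <- setdiff(gene_ids, design$platform_genes)
    M[absent, ] <- NA_real_
  }
  colnames(M) <- sample_ids

  meta <- data.frame(sample_id = sample_ids, study_id = design$study_id,
                     platform_id = design$platform_id, disease = disease,
                     phase = design$phase, sex = sex,
                     batch = sprintf("%s_b%d", design$study_id, batch),
                     stringsAsFactors = FALSE)
  truth <- list(proportions = P,
                regulated = tp$regulated,
                composition_shift = shift,
                conc = conc)
  list(expr = M, meta = meta, truth = truth, design = design)
}

#' Configuration of a synthetic multi-study cohort
#'
#' @param n_genes,n_markers_per_type,fold_enrichment Passed to
#'   \code{\link{generate_cell_profiles}}.
#' @param celltypes Cell-type names.
#' @param conc Baseline Dirichlet concentrations.
#' @param phase Disease phase of the cohort (sets the default composition
#'   shift).
#' @param n_studies,n_control,n_case Study layout when \code{studies} is not
#'   given explicitly.
#' @param composition_shift Per-type case multipliers; NULL = phase default.
#' @param regulated Either NULL, a data.frame (gene, celltype, log2fc), or a
#'   list \code{list(n=, celltype=, log2fc=)} asking the generator to pick
#'   \code{n} non-marker genes present on all platforms.
#' @param platform_drop_frac Fraction of regular genes absent from each
#'   platform (sex genes and Thy1 are always measured).
#' @param noise_sd,study_bias_sd,batch_sd,n_batches,sex_ratio_male Study-level
#'   defaults.
#' @param studies Optional explicit list of \code{\link{study_design}}
#'   argument lists, overriding the regular layout.
#' @return A \code{cohort_config} list.
#' @export
cohort_config <- function(n_genes = 600, n_markers_per_type = 20,
                          fold_enrichment = 8,
                          celltypes = hippocampal_celltypes(),
                          conc = default_dirichlet_conc(),
                          phase = c("late", "early"),
                          n_studies = 3, n_control = 10, n_case = 10,
                          composition_shift = NULL, regulated = NULL,
                          platform_drop_frac = 0.1,
                          noise_sd = 0.3, study_bias_sd = 0.2,
                          batch_sd = 0.15, n_batches = 2,
                          sex_ratio_male = 0.5, studies = NULL) {
  phase <- match.arg(phase)
  if (is.null(composition_shift)) {
    composition_shift <- default_composition_shift(phase)[celltypes]
  }
  if (is.null(studies)) {
    studies <- lapply(seq_len(n_studies), function(i) {
      list(study_id = sprintf("S%d", i), platform_id = sprintf("P%d", i),
           n_control = n_control, n_case = n_case, phase = phase,
           n_batches = n_batches, sex_ratio_male = sex_ratio_male,
           study_bias_sd = study_bias_sd, batch_sd = batch_sd,
           noise_sd = noise_sd)
    })
  }
  if (length(studies) < 2) stop("a cohort needs at least 2 studies")
  structure(list(n_genes = n_genes, n_markers_per_type = n_markers_per_type,
                 fold_enrichment = fold_enrichment, celltypes = celltypes,
                 conc = conc, phase = phase,
                 composition_shift = composition_shift, regulated = regulated,
                 platform_drop_frac = platform_drop_frac, studies = studies),
            class = "cohort_config")
}

#' Generate a synthetic multi-study cohort with ground truth
#'
#' Studies share one simulated gene universe but are measured on platforms
#' with overlapping, unequal gene sets. Per-study random streams are derived
#' deterministically from the master seed and the study id, so regenerating a
#' permuted study list yields identical per-study data.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param seed Master integer seed.
#' @return Object of class \code{synthetic_cohort}: list with
#'   \code{profiles}, \code{studies} (list of per-study bundles),
#'   \code{regulated}, \code{platform_genes}, \code{config}.
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  profiles <- generate_cell_profiles(
    n_genes = config$n_genes,
    n_markers_per_type = config$n_markers_per_type,
    fold_enrichment = config$fold_enrichment,
    celltypes = config$celltypes,
    seed = derive_seed(seed, "profiles"))

  regular <- setdiff(profiles$gene_ids,
                     c(profiles$sex_genes$gene,
                       if (profiles$thy1_artifact) "Thy1"))
  pids <- unique(vapply(config$studies, `[[`, "", "platform_id"))
  platform_genes <- stats::setNames(lapply(pids, function(pid) {
    set.seed(derive_seed(seed, paste0("platform:", pid)))
    n_drop <- round(config$platform_drop_frac * length(regular))
    dropped <- if (n_drop > 0) sample(regular, n_drop) else character(0)
    setdiff(profiles$gene_ids, dropped)
  }), pids)

  n_pl <- length(pids)
  need <- ceiling(2 / 3 * n_pl)
  counts <- table(unlist(platform_genes))
  if (!any(counts >= need)) {
    stop("no gene is present in at least 2/3 of the platforms")
  }

  regulated <- config$regulated
  if (is.list(regulated) && !is.data.frame(regulated)) {
    set.seed(derive_seed(seed, "regulated"))
    everywhere <- Reduce(intersect, platform_genes)
    candidates <- setdiff(intersect(regular, everywhere),
                          unlist(profiles$markers))
    if (regulated$n > length(candidates)) {
      stop("not enough universally measured non-marker genes to regulate")
    }
    regulated <- data.frame(gene = sample(candidates, regulated$n),
                            celltype = regulated$celltype,
                            log2fc = regulated$log2fc,
                            stringsAsFactors = FALSE)
  }

  studies <- lapply(config$studies, function(sd_args) {
    des <- do.call(study_design, utils::modifyList(
      sd_args, list(platform_genes = platform_genes[[sd_args$platform_id]])))
    generate_study(profiles, des,
                   truth_params = list(conc = config$conc[config$celltypes],
                                       composition_shift =
                                         config$composition_shift,
                                       regulated = regulated),
                   seed = derive_seed(seed, paste0("study:", des$study_id)))
  })
  names(studies) <- vapply(studies, function(b) b$design$study_id, "")

  structure(list(profiles = profiles, studies = studies,
                 regulated = regulated, platform_genes = platform_genes,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  ns <- vapply(x$studies, function(b) ncol(b$expr), 0L)
  cat(sprintf("synthetic_cohort: %d studies (%s samples), %d genes, phase %s\n",
              length(x$studies), paste(ns, collapse = "+"),
              length(x$profiles$gene_ids), x$config$phase))
  invisible(x)
}

#' Combined sample table of a cohort
#' @param cohort A \code{synthetic_cohort}.
#' @return data.frame of all studies' sample metadata.
#' @export
cohort_sample_table <- function(cohort) {
  do.call(rbind, c(lapply(cohort$studies, `[[`, "meta"),
                   make.row.names = FALSE))
}

#' True per-sample cell-type proportions of a cohort
#' @param cohort A \code{synthetic_cohort}.
#' @return Matrix samples x cell types.
#' @export
cohort_true_proportions <- function(cohort) {
  do.call(rbind, lapply(cohort$studies, function(b) b$truth$proportions))
}
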