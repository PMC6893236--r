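#' Load gene sets from a GMT file
#'
#' Each line: term id, description, then tab-separated member genes.
#' Duplicate members within a term are de-duplicated; genes unknown to any
#' particular analysis are retained until universe intersection.
#'
#' @param path GMT file path.
#' @return Object of class \code{gene_set_collection}: list with \code{sets}
#'   (named list of member vectors) and \code{descriptions}.
#' @export
load_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 3)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %d: fewer than 3 fields", bad[1]))
  }
  ids <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(ids)) stop("duplicate term ids in GMT file")
  sets <- stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids)
  descriptions <- stats::setNames(vapply(parts, `[[`, "", 2), ids)
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms (sizes %d-%d)\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

# Average precision of set members along a ranking: mean precision at each
# member's position.
.average_precision <- function(positions) {
  pos <- sort(positions)
  mean(seq_along(pos) / pos)
}

#' Threshold-free precision-recall gene-set enrichment
#'
#' For each term, the ranking is walked and the precision at each member
#' gene's position is recorded; the score is the mean of those precisions
#' (average precision, the area under the precision-recall curve of members
#' along the ranking). The null distribution places a same-size set at
#' uniformly random ranks (\code{n_perm} draws, shared across equal-size
#' terms); the permutation p-value uses the add-one estimator, so it is never
#' exactly zero. FDR is Benjamini-Hochberg across terms. No gene
#' multifunctionality adjustment is applied.
#'
#' @param ranking Ordered character vector of gene ids (best first) covering
#'   the analyzed gene universe.
#' @param sets A \code{gene_set_collection} or named list of member vectors.
#' @param n_perm Number of permutations (at least 100).
#' @param seed Integer seed for the permutation null.
#' @param min_size,max_size Term size limits after universe intersection;
#'   terms outside are skipped. Defaults 5 and 200.
#' @return data.frame: term, size, auprc, p, fdr; ordered by p.
#' @export
pr_enrichment <- function(ranking, sets, n_perm = 1000, seed = 1L,
                          min_size = 5, max_size = 200) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (anyDuplicated(ranking)) stop("ranking contains duplicate genes")
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  N <- length(ranking)
  members <- lapply(sets, function(g) which(ranking %in% g))
  sizes <- lengths(members)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) stop("no term within the configured size limits")
  members <- members[keep]
  sizes <- sizes[keep]

  set.seed(seed)
  null_by_size <- lapply(sort(unique(sizes)), function(m) {
    vapply(seq_len(n_perm), function(i) {
      .average_precision(sample.int(N, m))
    }, 0)
  })
  names(null_by_size) <- as.character(sort(unique(sizes)))

  ap <- vapply(members, .average_precision, 0)
  p <- vapply(seq_along(ap), function(i) {
    null <- null_by_size[[as.character(sizes[i])]]
    (1 + sum(null >= ap[i])) / (1 + n_perm)
  }, 0)
  out <- data.frame(term = names(members), size = as.integer(sizes),
                    auprc = ap, p = p, fdr = bh_fdr(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, -out$auprc), , drop = FALSE]
}
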