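#' Overlap of two top-fraction gene lists
#'
#' Percentage of the training top-`frac_train` genes that also appear in
#' the validation top-`frac_valid` list. Scores are ranked decreasingly
#' (use the negated statistic for p-value-type scores); ties are broken by
#' gene id for determinism. Under independent scores the expected overlap
#' equals `frac_valid`.
#'
#' @param train,valid Named (gene id) numeric score vectors over the same
#'   genes; larger = stronger.
#' @param frac_train,frac_valid Top fractions in (0, 1\].
#' @return List with `overlap_percent`, `train_top`, `valid_top`.
#' @export
top_overlap <- function(train, valid, frac_train = 0.05,
                        frac_valid = 0.05) {
  stopifnot(length(train) == length(valid),
            !is.null(names(train)), setequal(names(train), names(valid)))
  valid <- valid[names(train)]
  pick <- function(s, frac) {
    ktop <- max(1L, floor(frac * length(s)))
    names(s)[order(-s, names(s))][seq_len(ktop)]
  }
  tt <- pick(train, frac_train)
  vt <- pick(valid, frac_valid)
  list(overlap_percent = 100 * length(intersect(tt, vt)) / length(tt),
       train_top = tt, valid_top = vt)
}

# larger-is-stronger score vector from either score table
dc_score_vector <- function(scores) {
  s <- if (inherits(scores, "dcglob_scores")) -scores$p else scores$d
  names(s) <- scores$gene_id
  s
}

#' Cross-validation reproducibility of differential-correlation lists
#'
#' Draws disjoint training and validation condition pairs of `n_per_group`
#' samples per group from two pooled single-condition cohorts, scores both
#' pairs with the chosen algorithm, and reports how many of the training
#' top-fraction genes are recovered in the validation top fraction,
#' together with the Spearman rank correlation of the two score vectors.
#'
#' @param pooled_a,pooled_b Genes x samples matrices holding all available
#'   samples of condition A resp. B (both at least `2 * n_per_group`
#'   columns).
#' @param n_per_group Samples per group in each of training and validation.
#' @param method `"dcloc"` or `"dcglob"`.
#' @param top_frac_train,top_frac_valid Top fractions compared.
#' @param seed Seed for the sample draws.
#' @param ... Passed to the scoring function (e.g. `k`).
#' @return Object of class `dc_crossval`: `n_per_group`, `method`,
#'   `overlap_percent`, `rank_correlation`, `scores` (`data.frame` of
#'   per-gene train/valid scores).
#' @export
crossval_reproducibility <- function(pooled_a, pooled_b, n_per_group,
                                     method = c("dcloc", "dcglob"),
                                     top_frac_train = 0.05,
                                     top_frac_valid = 0.05, seed = 1, ...) {
  method <- match.arg(method)
  validate_expression_matrix(pooled_a, "pooled condition A")
  validate_expression_matrix(pooled_b, "pooled condition B")
  if (!identical(rownames(pooled_a), rownames(pooled_b)))
    stop("pooled cohorts must share the same gene set")
  if (2 * n_per_group > min(ncol(pooled_a), ncol(pooled_b)))
    stop("pooled cohorts too small for disjoint training and validation ",
         "draws of ", n_per_group, " samples per group")
  idx <- with_seed(seed, list(a = sample.int(ncol(pooled_a)),
                              b = sample.int(ncol(pooled_b))))
  take <- function(m, ii) m[, ii, drop = FALSE]
  tr <- condition_pair(take(pooled_a, idx$a[seq_len(n_per_group)]),
                       take(pooled_b, idx$b[seq_len(n_per_group)]))
  va <- condition_pair(take(pooled_a, idx$a[n_per_group + seq_len(n_per_group)]),
                       take(pooled_b, idx$b[n_per_group + seq_len(n_per_group)]))
  scorer <- if (method == "dcglob") dcglob_scores else dcloc_scores
  s_tr <- dc_score_vector(scorer(tr, ...))
  s_va <- dc_score_vector(scorer(va, ...))[names(s_tr)]
  ov <- top_overlap(s_tr, s_va, top_frac_train, top_frac_valid)
  structure(
    list(n_per_group = n_per_group, method = method,
         top_frac_train = top_frac_train, top_frac_valid = top_frac_valid,
         overlap_percent = ov$overlap_percent,
         rank_correlation = stats::cor(s_tr, s_va, method = "spearman"),
         scores = data.frame(gene_id = names(s_tr), train = unname(s_tr),
                             valid = unname(s_va),
                             stringsAsFactors = FALSE)),
    class = "dc_crossval"
  )
}

#' @export
print.dc_crossval <- function(x, ...) {
  cat("dc_crossval (", x$method, ", n = ", x$n_per_group, "/group): ",
      round(x$overlap_percent, 1), "% of the top ",
      100 * x$top_frac_train, "% reproduced in the top ",
      100 * x$top_frac_valid, "%; Spearman R = ",
      round(x$rank_correlation, 2), "\n", sep = "")
  invisible(x)
}

#' Welch's t-test per gene with Benjamini-Hochberg correction
#'
#' The standard differential-expression counterpart to the
#' differential-correlation analysis: unequal-variance t statistic per
#' gene (Welch-Satterthwaite degrees of freedom), two-sided p-values, and
#' BH step-up adjustment across all genes. Genes that are constant in both
#' groups get t = 0 and p = 1 with a warning.
#'
#' @param pair A [condition_pair()] (at least 2 samples per group).
#' @param alpha FDR level for the significance flag (default 0.05).
#' @return `data.frame` with `gene_id`, `t`, `df`, `p`, `p_adj`,
#'   `significant`, in the input gene order.
#' @export
welch_bh_de <- function(pair, alpha = 0.05) {
  stopifnot(inherits(pair, "condition_pair"))
  if (pair$n_a < 2 || pair$n_b < 2)
    stop("Welch's test needs at least 2 samples per group")
  n1 <- pair$n_a; n2 <- pair$n_b
  m1 <- rowMeans(pair$a); m2 <- rowMeans(pair$b)
  v1 <- apply(pair$a, 1, stats::var); v2 <- apply(pair$b, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  degenerate <- se2 == 0
  if (any(degenerate))
    warning("gene(s) constant in both groups: ",
            paste(pair$gene_ids[degenerate], collapse = ", "))
  tstat <- ifelse(degenerate, 0, (m1 - m2) / sqrt(se2))
  df <- ifelse(degenerate, NA_real_,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tstat), df))
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = pair$gene_ids, t = tstat, df = df, p = p,
             p_adj = p_adj, significant = p_adj < alpha,
             stringsAsFactors = FALSE)
}

#' Average-linkage clusters from a correlation matrix
#'
#' Agglomerative clustering of genes with distance 1 - c (c = Pearson
#' correlation, recovered as tanh(z) if a Fisher-z matrix is given),
#' average linkage, with the tree cut at height 1 - `corr_cutoff` so that
#' clusters are groups of genes correlated above the cutoff. Cluster ids
#' are relabeled in decreasing size order (ties by first occurrence).
#'
#' @param x A `fisher_z_matrix` (possibly restricted to a gene list) or a
#'   correlation matrix with gene dimnames.
#' @param corr_cutoff Pearson correlation at which the tree is cut
#'   (default 0.4).
#' @return Named integer vector of cluster ids, with the `hclust` tree as
#'   attribute `tree`.
#' @export
cluster_genes <- function(x, corr_cutoff = 0.4) {
  cmat <- if (inherits(x, "fisher_z_matrix")) {
    cc <- tanh(x$z)
    diag(cc) <- 1
    cc
  } else {
    stopifnot(is.matrix(x), isSymmetric(unname(x)))
    x
  }
  if (nrow(cmat) < 2) stop("need at least 2 genes to cluster")
  tree <- stats::hclust(stats::as.dist(1 - cmat), method = "average")
  cl <- stats::cutree(tree, h = 1 - corr_cutoff)
  sizes <- as.vector(table(cl))
  first <- as.vector(tapply(seq_along(cl), cl, min))
  ord <- order(-sizes, first) # old ids, largest cluster first
  new_id <- integer(length(ord))
  new_id[ord] <- seq_along(ord)
  relabeled <- new_id[cl]
  names(relabeled) <- names(cl)
  attr(relabeled, "tree") <- tree
  relabeled
}

#' Standardize expression rows to mean 0, standard deviation 1
#'
#' Row-wise centering and scaling, the conventional preprocessing before
#' heatmap display of an expression block.
#'
#' @param m Numeric matrix (genes x samples).
#' @return Matrix of the same shape.
#' @export
standardize_rows <- function(m) {
  s <- apply(m, 1, stats::sd)
  if (any(s == 0)) stop("constant row(s): ",
                        paste(rownames(m)[s == 0], collapse = ", "))
  (m - rowMeans(m)) / s
}
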