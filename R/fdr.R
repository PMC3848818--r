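#' Draw one null condition pair from a pooled cohort
#'
#' Samples two disjoint groups of the requested sizes uniformly without
#' replacement from all samples of the pooled expression matrix, ignoring
#' any group labels. Because the two groups are random subsets of one
#' population, any differential correlation between them is a false
#' discovery, which is what makes repeated draws a null distribution.
#'
#' @param pooled Numeric genes x samples matrix with row and column names.
#' @param n_a,n_b Group sizes; `n_a + n_b` must not exceed the cohort size.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A [condition_pair()].
#' @export
draw_null_pair <- function(pooled, n_a, n_b, seed) {
  validate_expression_matrix(pooled, "pooled cohort")
  if (n_a + n_b > ncol(pooled))
    stop("pooled cohort has ", ncol(pooled), " samples; cannot draw ",
         n_a + n_b)
  idx <- with_seed(seed, sample.int(ncol(pooled), n_a + n_b))
  suppressWarnings(
    condition_pair(pooled[, idx[seq_len(n_a)], drop = FALSE],
                   pooled[, idx[n_a + seq_len(n_b)], drop = FALSE],
                   allow_unequal = n_a != n_b))
}

#' Score repeated null subsamples
#'
#' Runs the chosen algorithm on `B` independent null pairs drawn by
#' [draw_null_pair()] (null pair b uses seed `base_seed + b`). The
#' per-subsample score tables are returned so that detection counts can be
#' thresholded at any cutoff without recomputation, and can optionally be
#' cached to disk as TSV.
#'
#' @param pooled Pooled genes x samples matrix.
#' @param method `"dcglob"` or `"dcloc"`.
#' @param n_a,n_b Subsample group sizes.
#' @param B Number of subsample pairs (default 100).
#' @param base_seed Base seed for the subsample series.
#' @param cache_dir Optional directory; per-subsample score tables are
#'   written there as `null_scores_<b>.tsv`.
#' @param ... Passed to [dcglob_scores()] / [dcloc_scores()] (e.g. `k`,
#'   `z_max`).
#' @return List of `B` score tables, with attributes `method`, `B`,
#'   `base_seed`.
#' @export
null_scores <- function(pooled, method = c("dcloc", "dcglob"), n_a, n_b,
                        B = 100, base_seed = 1, cache_dir = NULL, ...) {
  method <- match.arg(method)
  scorer <- if (method == "dcglob") dcglob_scores else dcloc_scores
  dots <- list(...)
  # every subsample must be scored on one common grid, or detection counts
  # are not comparable; default its upper end to the pooled-cohort maximum
  if (is.null(dots$z_max) && is.null(dots$grid))
    dots$z_max <- pooled_z_max(pooled)
  out <- lapply(seq_len(B), function(b) {
    s <- do.call(scorer, c(
      list(draw_null_pair(pooled, n_a, n_b, seed = base_seed + b)), dots))
    if (!is.null(cache_dir)) {
      if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
      write_scores(s, file.path(cache_dir, sprintf("null_scores_%d.tsv", b)),
                   extra = c(subsample = b, seed = base_seed + b))
    }
    s
  })
  attr(out, "method") <- method
  attr(out, "B") <- B
  attr(out, "base_seed") <- base_seed
  out
}

#' Grid upper end implied by a pooled cohort
#'
#' Maximal off-diagonal |z| of the Fisher-transformed correlation matrix of
#' the full cohort; the common grid end used for observed and null runs in
#' an FDR analysis.
#'
#' @param pooled Genes x samples matrix.
#' @return Positive scalar in Fisher-z units.
#' @export
pooled_z_max <- function(pooled) {
  z <- fisher_transform(stats::cor(t(pooled)))
  diag(z) <- 0
  max(abs(z))
}

# number of genes called differentially correlated at a cutoff
count_detected <- function(scores, cutoff) {
  if (inherits(scores, "dcglob_scores")) sum(scores$p < cutoff)
  else if (inherits(scores, "dcloc_scores")) sum(scores$d > cutoff)
  else stop("scores must come from dcglob_scores() or dcloc_scores()")
}

#' Null distribution of detection counts under subsampling
#'
#' Counts, for each of `B` null subsample pairs, how many genes the chosen
#' algorithm calls differentially correlated at the given cutoff, and
#' summarizes the counts by their mean, standard error and 5%/95%
#' percentiles (linear-interpolation quantiles, type 7).
#'
#' @inheritParams null_scores
#' @param cutoff Detection cutoff: p-value cutoff for `"dcglob"` (p <
#'   cutoff), dissimilarity cutoff for `"dcloc"` (d > cutoff).
#' @param scores Optional precomputed [null_scores()] list; when supplied,
#'   `pooled`, `n_a`, `n_b`, `B` and `base_seed` are taken from it.
#' @return Object of class `dc_null` with `counts`, `mean`, `se` (NA for B
#'   = 1), `ci_5`, `ci_95`, `method`, `cutoff`, `B`, `base_seed`.
#' @export
null_counts <- function(pooled, method = c("dcloc", "dcglob"), cutoff,
                        n_a, n_b, B = 100, base_seed = 1, scores = NULL,
                        ...) {
  if (is.null(scores))
    scores <- null_scores(pooled, method, n_a = n_a, n_b = n_b, B = B,
                          base_seed = base_seed, ...)
  counts <- vapply(scores, count_detected, 0L, cutoff = cutoff)
  B <- length(counts)
  qs <- stats::quantile(counts, c(0.05, 0.95), type = 7, names = FALSE)
  structure(
    list(counts = counts, mean = mean(counts),
         se = if (B > 1) stats::sd(counts) / sqrt(B) else NA_real_,
         ci_5 = qs[1], ci_95 = qs[2],
         method = attr(scores, "method"), cutoff = cutoff, B = B,
         base_seed = attr(scores, "base_seed")),
    class = "dc_null"
  )
}

#' @export
print.dc_null <- function(x, ...) {
  cat("dc_null (", x$method, ", cutoff ", x$cutoff, "): n0 = ",
      signif(x$mean, 4), " +/- ", signif(x$se, 3), " (B = ", x$B,
      "; 5-95% [", x$ci_5, ", ", x$ci_95, "])\n", sep = "")
  invisible(x)
}

#' Subsampling estimate of the false discovery rate
#'
#' FDR = pi0 * mean(n0) / n_AB: the expected number of genes detected
#' between random subsamples of one population (false positives), divided
#' by the number detected between the real groups. pi0, the proportion of
#' genes that are not differentially correlated, is set to 1 by default,
#' which slightly overestimates the FDR when true signal is present.
#'
#' @param n_ab Observed number of differentially correlated genes at the
#'   cutoff.
#' @param null A [null_counts()] object, or directly the mean null count.
#' @param pi0 Proportion of null genes (default 1).
#' @return Object of class `fdr_estimate` with `n_ab`, `n0_mean`, `pi0`,
#'   `fdr` (NA when `n_ab` = 0) and `exceeds_one`.
#' @examples
#' estimate_fdr(185, 10)$fdr * 100 # 5.4%
#' @export
estimate_fdr <- function(n_ab, null, pi0 = 1) {
  if (!is.numeric(n_ab) || length(n_ab) != 1 || n_ab < 0)
    stop("n_ab must be a single nonnegative count")
  n0 <- if (inherits(null, "dc_null")) null$mean else as.numeric(null)
  fdr <- if (n_ab == 0) NA_real_ else pi0 * n0 / n_ab
  if (!is.na(fdr) && fdr > 1)
    warning("estimated FDR exceeds 1 (", signif(fdr, 3),
            "); no evidence of signal at this cutoff")
  structure(list(n_ab = n_ab, n0_mean = n0, pi0 = pi0, fdr = fdr,
                 exceeds_one = isTRUE(fdr > 1)),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat("FDR = ", if (is.na(x$fdr)) "NA (no detections)" else
    paste0(round(100 * x$fdr, 1), "%"),
    "  (n_AB = ", x$n_ab, ", mean n0 = ", signif(x$n0_mean, 4),
    ", pi0 = ", x$pi0, ")\n", sep = "")
  invisible(x)
}

#' FDR as a function of the detection cutoff
#'
#' Scores the observed pair once and the `B` null subsamples once, then
#' thresholds both at every cutoff of the grid, yielding the number of
#' detected genes, the null mean with its 5-95% band, and the FDR per
#' cutoff (the score-once-threshold-many layout of an FDR-vs-count curve).
#'
#' @inheritParams null_scores
#' @param pair The observed [condition_pair()] (same group sizes as the
#'   null subsamples).
#' @param cutoffs Ordered vector of cutoffs (p cutoffs for dcglob, d
#'   cutoffs for dcloc).
#' @return `data.frame` with columns `cutoff`, `n_ab`, `n0_mean`, `n0_se`,
#'   `ci_5`, `ci_95`, `fdr`.
#' @export
fdr_curve <- function(pooled, pair, method = c("dcloc", "dcglob"), cutoffs,
                      B = 100, base_seed = 1, pi0 = 1, ...) {
  method <- match.arg(method)
  stopifnot(inherits(pair, "condition_pair"))
  if (is.unsorted(cutoffs) && is.unsorted(rev(cutoffs)))
    stop("cutoffs must be ordered")
  scorer <- if (method == "dcglob") dcglob_scores else dcloc_scores
  dots <- list(...)
  if (is.null(dots$z_max) && is.null(dots$grid))
    dots$z_max <- pooled_z_max(pooled) # one grid for observed and null runs
  obs <- do.call(scorer, c(list(pair), dots))
  ns <- do.call(null_scores, c(
    list(pooled, method, n_a = pair$n_a, n_b = pair$n_b, B = B,
         base_seed = base_seed), dots))
  rows <- lapply(cutoffs, function(cf) {
    nl <- null_counts(scores = ns, cutoff = cf)
    n_ab <- count_detected(obs, cf)
    est <- suppressWarnings(estimate_fdr(n_ab, nl, pi0 = pi0))
    data.frame(cutoff = cf, n_ab = n_ab, n0_mean = nl$mean, n0_se = nl$se,
               ci_5 = nl$ci_5, ci_95 = nl$ci_95, fdr = est$fdr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "method") <- method
  out
}
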