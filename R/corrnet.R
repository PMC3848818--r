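#' Fisher z-transform of Pearson correlations
#'
#' Computes z = atanh(c) = 0.5 * log((1 + c) / (1 - c)) after clipping the
#' correlation to +/-(1 - eps), so that perfectly correlated gene pairs
#' (e.g. duplicated genes) map to a large finite value instead of infinity.
#' The transform is odd and strictly increasing; on the Fisher scale the
#' sampling standard deviation of a correlation estimated from n samples is
#' approximately 1/sqrt(n - 3), which is what makes an equidistant threshold
#' grid on this scale comparable across the correlation range.
#'
#' @param c Numeric vector or matrix of correlations in \[-1, 1\].
#' @param eps Clipping margin (default 1e-6).
#' @return Object of the same shape in Fisher-z units.
#' @examples
#' fisher_transform(0.985) # about 2.44
#' @export
fisher_transform <- function(c, eps = 1e-6) {
  if (!is.numeric(c)) stop("correlations must be numeric")
  if (any(!is.finite(c))) stop("correlations must be finite")
  atanh(pmin(pmax(c, -1 + eps), 1 - eps))
}

validate_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) stop(what, " must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " needs gene row names and sample column names")
  if (anyDuplicated(rownames(x))) stop(what, ": duplicated gene identifiers")
  if (anyDuplicated(colnames(x))) stop(what, ": duplicated sample identifiers")
  if (any(!is.finite(x)))
    stop(what, ": non-finite values are not supported (missing values must be ",
         "imputed or the genes removed upstream)")
  invisible(x)
}

#' Pair of expression matrices for two conditions
#'
#' Bundles the genes x samples matrices of two disease conditions A and B
#' over a shared, identically ordered gene set. The two algorithms compare
#' correlation structure between the two members of the pair. Equal sample
#' counts are enforced by default: unequal group sizes change the sampling
#' variability of correlations per condition and inflate apparent
#' differential correlation.
#'
#' @param a,b Numeric matrices (genes x samples, log2 scale) with gene row
#'   names and sample column names. Sample id sets must be disjoint. If the
#'   gene sets are equal but ordered differently, `b` is reordered to match
#'   `a`.
#' @param allow_unequal Permit `ncol(a) != ncol(b)` (with a warning).
#' @return An object of class `condition_pair` with elements `a`, `b`,
#'   `n_a`, `n_b`, `gene_ids`.
#' @export
condition_pair <- function(a, b, allow_unequal = FALSE) {
  validate_expression_matrix(a, "condition A")
  validate_expression_matrix(b, "condition B")
  if (!identical(rownames(a), rownames(b))) {
    if (setequal(rownames(a), rownames(b))) {
      b <- b[rownames(a), , drop = FALSE]
    } else {
      stop("conditions A and B must share the same gene set")
    }
  }
  if (length(intersect(colnames(a), colnames(b))))
    stop("sample identifiers of the two conditions must be disjoint")
  if (ncol(a) != ncol(b)) {
    if (!allow_unequal)
      stop("unequal group sizes (", ncol(a), " vs ", ncol(b), "); ",
           "use allow_unequal = TRUE only if you accept the resulting ",
           "false-positive risk")
    warning("unequal group sizes: differential-correlation calls may be ",
            "biased towards the smaller group")
  }
  structure(
    list(a = a, b = b, n_a = ncol(a), n_b = ncol(b), gene_ids = rownames(a)),
    class = "condition_pair"
  )
}

#' @export
print.condition_pair <- function(x, ...) {
  cat("condition_pair:", length(x$gene_ids), "genes;",
      x$n_a, "samples (A) vs", x$n_b, "samples (B)\n")
  invisible(x)
}

new_fisher_z_matrix <- function(z, n) {
  structure(list(z = z, n = n, gene_ids = rownames(z)),
            class = "fisher_z_matrix")
}

#' @export
print.fisher_z_matrix <- function(x, ...) {
  cat("fisher_z_matrix:", nrow(x$z), "genes, n =", x$n, "samples\n")
  invisible(x)
}

#' Per-condition Fisher-transformed correlation matrices
#'
#' Computes the Pearson correlation of every gene pair within each
#' condition and applies [fisher_transform()]. The diagonal is set to 0 and
#' is excluded from all downstream use (a gene is never its own neighbor).
#'
#' @param pair A [condition_pair()].
#' @param eps Clipping margin passed to [fisher_transform()].
#' @return List with elements `A` and `B`, each a `fisher_z_matrix` holding
#'   the symmetric z matrix and the sample count.
#' @export
correlation_matrices <- function(pair, eps = 1e-6) {
  stopifnot(inherits(pair, "condition_pair"))
  one <- function(m, label) {
    if (ncol(m) < 4)
      stop("condition ", label, ": at least 4 samples are required")
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0))
      stop("condition ", label, ": constant expression for gene(s) ",
           paste(rownames(m)[sds == 0], collapse = ", "),
           " (correlation undefined)")
    z <- fisher_transform(stats::cor(t(m)), eps = eps)
    diag(z) <- 0
    new_fisher_z_matrix(z, ncol(m))
  }
  list(A = one(pair$a, "A"), B = one(pair$b, "B"))
}

#' Equidistant threshold grid on the Fisher-z scale
#'
#' The grid t_m = m * z_max / k for m = 1..k: k equidistant values with the
#' upper end included and 0 excluded (a threshold of 0 would connect every
#' positively correlated pair into a near-complete, uninformative graph).
#'
#' @param k Number of thresholds (>= 2). Defaults used by the two
#'   algorithms are 200 (global) and 100 (local).
#' @param z_max Upper end of the grid in Fisher-z units (> 0); typically
#'   the maximal off-diagonal |z| in the data, see [default_z_max()].
#' @return Object of class `threshold_grid` with `thresholds`, `k`,
#'   `z_max`, `delta`.
#' @export
threshold_grid <- function(k, z_max) {
  if (!is.numeric(k) || length(k) != 1 || k < 2 || k != round(k))
    stop("k must be an integer >= 2")
  if (!is.numeric(z_max) || length(z_max) != 1 || !is.finite(z_max) ||
      z_max <= 0)
    stop("z_max must be a positive finite number")
  k <- as.integer(k)
  structure(
    list(thresholds = seq_len(k) * (z_max / k), k = k, z_max = z_max,
         delta = z_max / k),
    class = "threshold_grid"
  )
}

#' @export
print.threshold_grid <- function(x, ...) {
  cat("threshold_grid: k =", x$k, "values in (0,", x$z_max, "], spacing",
      signif(x$delta, 4), "\n")
  invisible(x)
}

#' Default grid upper end: maximal off-diagonal |z| over both conditions
#'
#' Mirrors fixing the grid end at the Fisher transform of the strongest
#' observed correlation, so that the grid covers the full range of
#' correlations present in the data.
#'
#' @param fz_a,fz_b `fisher_z_matrix` objects for the two conditions.
#' @return A positive scalar in Fisher-z units.
#' @export
default_z_max <- function(fz_a, fz_b) {
  off <- upper.tri(fz_a$z)
  m <- max(abs(fz_a$z[off]), abs(fz_b$z[off]))
  if (m <= 0) stop("all correlations are zero; no usable threshold range")
  m
}

#' Correlation network at a single threshold
#'
#' Two genes are joined by an edge whenever their Fisher-transformed
#' correlation strictly exceeds the threshold (z > t). Negative
#' correlations never produce edges under this (default, signed) rule; set
#' `absolute = TRUE` to threshold |z| instead.
#'
#' @param fz A `fisher_z_matrix`.
#' @param t Threshold in Fisher-z units (> 0).
#' @param absolute Threshold on |z| instead of signed z.
#' @return Object of class `threshold_network` with a logical adjacency
#'   matrix `adj` (diagonal FALSE), `gene_ids` and `t`.
#' @export
network_at <- function(fz, t, absolute = FALSE) {
  stopifnot(inherits(fz, "fisher_z_matrix"))
  if (!is.numeric(t) || length(t) != 1 || t <= 0)
    stop("threshold must be a positive scalar")
  z <- if (absolute) abs(fz$z) else fz$z
  adj <- z > t
  diag(adj) <- FALSE
  structure(list(adj = adj, gene_ids = fz$gene_ids, t = t),
            class = "threshold_network")
}

#' @export
print.threshold_network <- function(x, ...) {
  cat("threshold_network: t =", signif(x$t, 4), ";", length(x$gene_ids),
      "genes,", sum(x$adj) / 2, "edges\n")
  invisible(x)
}

#' Connected components with at least three genes
#'
#' Decomposes the network into connected components and keeps those of size
#' >= 3, the smallest size at which component topology is non-trivial;
#' isolated genes and pairs are discarded.
#'
#' @param net A [network_at()] result.
#' @return List of character vectors (gene ids per component), class
#'   `component_decomposition`.
#' @export
components_min3 <- function(net) {
  stopifnot(inherits(net, "threshold_network"))
  g <- igraph::graph_from_adjacency_matrix(net$adj, mode = "undirected",
                                           diag = FALSE)
  cm <- igraph::components(g)
  keep <- which(cm$csize >= 3)
  comps <- lapply(keep, function(cc) net$gene_ids[cm$membership == cc])
  structure(comps, class = "component_decomposition", t = net$t)
}

# counts[i, m] = #(j != i : z[i, j] > t_m), for all grid thresholds at once.
# Strict inequality via findInterval(..., left.open = TRUE), which returns
# the number of grid points strictly below each value.
row_threshold_counts <- function(z, grid) {
  th <- grid$thresholds
  k <- grid$k
  G <- nrow(z)
  diag(z) <- -Inf
  out <- matrix(0L, G, k)
  for (i in seq_len(G)) {
    gi <- findInterval(z[i, ], th, left.open = TRUE)
    tab <- tabulate(gi[gi > 0L], nbins = k)
    out[i, ] <- rev(cumsum(rev(tab)))
  }
  out
}
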