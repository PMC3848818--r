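#' Topological dissimilarity of two neighborhoods
#'
#' One minus the Jaccard similarity of a gene's neighbor sets in the two
#' condition networks: 1 - |V_A n V_B| / |V_A u V_B|. When the union holds
#' fewer than 3 genes the value is defined as 0, restricting attention to
#' changes that involve correlation clusters of at least 3 genes.
#'
#' @param v_a,v_b Neighbor sets (vectors of gene ids), excluding the gene
#'   itself.
#' @return Dissimilarity in \[0, 1\].
#' @examples
#' local_dissimilarity(c("a", "b", "c"), c("b", "c", "d")) # 0.5
#' @export
local_dissimilarity <- function(v_a, v_b) {
  u <- union(v_a, v_b)
  if (length(u) < 3) return(0)
  1 - length(intersect(v_a, v_b)) / length(u)
}

# Vectorized core over the whole grid: per-gene neighbor counts at every
# threshold, for A, B, their intersection (pairwise min of z) and union
# (pairwise max). Neighborhoods are open (diagonal excluded).
dcloc_from_z <- function(z_a, z_b, grid) {
  n_ngb_a <- row_threshold_counts(z_a, grid)
  n_ngb_b <- row_threshold_counts(z_b, grid)
  inter <- row_threshold_counts(pmin(z_a, z_b), grid)
  uni <- row_threshold_counts(pmax(z_a, z_b), grid)
  d_mat <- 1 - inter / uni
  d_mat[uni < 3L] <- 0 # includes the empty union (0/0)
  sgn <- sign(n_ngb_a - n_ngb_b)
  list(
    d = rowMeans(d_mat),
    signed_sum = rowSums(d_mat * sgn),
    mean_neighbors_a = rowMeans(n_ngb_a),
    mean_neighbors_b = rowMeans(n_ngb_b)
  )
}

#' Local-topology differential correlation scores
#'
#' For every gene, the neighborhood dissimilarity between the two condition
#' networks ([local_dissimilarity()]) is computed at each threshold of the
#' grid and averaged: d_i = (1/k) * sum_m d_i(t_m), a value in \[0, 1\]
#' where larger d means stronger differential correlation. A signed
#' companion statistic sums the per-threshold dissimilarities weighted by
#' the sign of the neighborhood-size difference |V_A| - |V_B|; its sign
#' defines the direction (condition with the larger neighborhoods).
#'
#' @param pair A [condition_pair()].
#' @param grid A [threshold_grid()]; defaults to k = 100 thresholds up to
#'   the maximal |z| in the data.
#' @param k,z_max Grid parameters used when `grid` is NULL.
#' @return A `data.frame` of class `dcloc_scores` with columns `gene_id`,
#'   `d`, `signed_sum`, `mean_neighbors_a`, `mean_neighbors_b`,
#'   `direction`, sorted by decreasing `d` (ties by gene id).
#' @export
dcloc_scores <- function(pair, grid = NULL, k = 100, z_max = NULL) {
  stopifnot(inherits(pair, "condition_pair"))
  fz <- correlation_matrices(pair)
  if (is.null(grid))
    grid <- threshold_grid(k, z_max %||% default_z_max(fz$A, fz$B))
  res <- dcloc_from_z(fz$A$z, fz$B$z, grid)
  out <- data.frame(
    gene_id = pair$gene_ids,
    d = res$d,
    signed_sum = res$signed_sum,
    mean_neighbors_a = res$mean_neighbors_a,
    mean_neighbors_b = res$mean_neighbors_b,
    direction = c("B", "none", "A")[sign(res$signed_sum) + 2],
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$d, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grid") <- grid
  attr(out, "method") <- "dcloc"
  class(out) <- c("dcloc_scores", "data.frame")
  out
}

#' Differentially correlated gene lists at a score cutoff
#'
#' Splits the genes with mean dissimilarity d strictly above the cutoff by
#' the direction of the change.
#'
#' @param scores A [dcloc_scores()] table.
#' @param cutoff Cutoff s with 0 <= s < 1; genes with d > s are reported.
#' @return List with character vectors `A`, `B`, `none`.
#' @export
dc_gene_list <- function(scores, cutoff) {
  stopifnot(inherits(scores, "dcloc_scores"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0 || cutoff >= 1)
    stop("cutoff must satisfy 0 <= s < 1")
  hit <- scores[scores$d > cutoff, , drop = FALSE]
  list(A = hit$gene_id[hit$direction == "A"],
       B = hit$gene_id[hit$direction == "B"],
       none = hit$gene_id[hit$direction == "none"])
}
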