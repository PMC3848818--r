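#' Genes exclusively clustered in one condition at a threshold
#'
#' The core set algebra of the global-topology algorithm at a single
#' threshold. Genes belonging to a >= 3-gene connected component in *both*
#' condition networks are removed from the gene universe; the two networks
#' are then restricted (induced) to the remaining genes and their >= 3-gene
#' components recomputed. Genes clustered in the induced A network are
#' considered differentially correlated towards A at this threshold
#' (`a_tilde`), and likewise for B. The two sets are provably disjoint.
#'
#' The induced recomputation is conservative: a gene that was clustered in
#' A only through partners that are themselves shared with B loses its
#' component and is not called.
#'
#' @param net_a,net_b [network_at()] results over the same gene set.
#' @return List with `t`, `removed`, `a_tilde`, `b_tilde` (character
#'   vectors of gene ids).
#' @export
exclusive_component_genes <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "threshold_network"),
            inherits(net_b, "threshold_network"))
  if (!identical(net_a$gene_ids, net_b$gene_ids))
    stop("the two networks must be over the same (identically ordered) gene set")
  ids <- net_a$gene_ids
  in_a <- comp3_flags(net_a$adj)
  in_b <- comp3_flags(net_b$adj)
  removed <- in_a & in_b
  keep <- !removed
  a_tilde <- b_tilde <- character(0)
  if (any(in_a & keep)) {
    fl <- comp3_flags(net_a$adj[keep, keep, drop = FALSE])
    a_tilde <- ids[keep][fl]
  }
  if (any(in_b & keep)) {
    fl <- comp3_flags(net_b$adj[keep, keep, drop = FALSE])
    b_tilde <- ids[keep][fl]
  }
  list(t = net_a$t, removed = ids[removed], a_tilde = a_tilde,
       b_tilde = b_tilde)
}

# logical flag per vertex: member of a connected component of size >= 3
comp3_flags <- function(adj) {
  if (!nrow(adj)) return(logical(0))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  cm <- igraph::components(g)
  cm$csize[cm$membership] >= 3
}

# Same flags from an integer edge list (i, j), vertices 1..G; used by the
# threshold sweep where building adjacency matrices per threshold would be
# wasteful.
comp3_flags_edges <- function(i, j, G) {
  if (!length(i)) return(logical(G))
  g <- igraph::make_undirected_graph(as.vector(rbind(i, j)), n = G)
  cm <- igraph::components(g)
  cm$csize[cm$membership] >= 3
}

# Threshold sweep for the global algorithm. Edges of each condition are
# binned against the grid once (edge {i,j} is present at thresholds
# m = 1..#(t_m < z_ij)), sorted by their last active threshold, and each
# grid point reuses the prefix of that order. Returns logical indicator
# matrices I_A, I_B (genes x k): I_A[g, m] is TRUE iff gene g is in a
# >= 3-component of the induced A network but removed-free at t_m.
dcglob_sweep <- function(z_a, z_b, grid) {
  G <- nrow(z_a)
  k <- grid$k
  iu <- which(upper.tri(z_a))
  prep <- function(z) {
    lvl <- findInterval(z[iu], grid$thresholds, left.open = TRUE)
    keep <- which(lvl > 0L)
    lvl <- lvl[keep]
    idx <- iu[keep]
    o <- order(lvl, decreasing = TRUE)
    lvl <- lvl[o]
    idx <- idx[o]
    cnt <- rev(cumsum(rev(tabulate(lvl, nbins = k)))) # edges active at t_m
    list(i = ((idx - 1L) %% G) + 1L, j = ((idx - 1L) %/% G) + 1L, cnt = cnt)
  }
  ea <- prep(z_a)
  eb <- prep(z_b)
  I_A <- matrix(FALSE, G, k)
  I_B <- matrix(FALSE, G, k)
  for (m in seq_len(k)) {
    na <- ea$cnt[m]
    nb <- eb$cnt[m]
    if (na == 0L && nb == 0L) next
    ia <- ea$i[seq_len(na)]; ja <- ea$j[seq_len(na)]
    ib <- eb$i[seq_len(nb)]; jb <- eb$j[seq_len(nb)]
    in_a <- comp3_flags_edges(ia, ja, G)
    in_b <- comp3_flags_edges(ib, jb, G)
    removed <- in_a & in_b
    if (any(in_a & !removed)) {
      ka <- !(removed[ia] | removed[ja])
      I_A[, m] <- comp3_flags_edges(ia[ka], ja[ka], G) & !removed
    }
    if (any(in_b & !removed)) {
      kb <- !(removed[ib] | removed[jb])
      I_B[, m] <- comp3_flags_edges(ib[kb], jb[kb], G) & !removed
    }
  }
  stopifnot(!any(I_A & I_B))
  list(I_A = I_A, I_B = I_B)
}

#' Per-gene exclusivity indicator profiles over the threshold grid
#'
#' For every gene and every grid threshold, records whether the gene is
#' exclusively clustered in condition A (`I_A`) or in condition B (`I_B`),
#' as defined by [exclusive_component_genes()]. The two indicators are
#' never simultaneously 1.
#'
#' @param pair A [condition_pair()].
#' @param grid A [threshold_grid()]; defaults to k = 200 thresholds up to
#'   the maximal |z| in the data.
#' @param k,z_max Grid parameters used when `grid` is NULL.
#' @return List with logical matrices `I_A`, `I_B` (genes x k, rownames =
#'   gene ids) and the `grid`.
#' @export
indicator_profiles <- function(pair, grid = NULL, k = 200, z_max = NULL) {
  stopifnot(inherits(pair, "condition_pair"))
  fz <- correlation_matrices(pair)
  if (is.null(grid))
    grid <- threshold_grid(k, z_max %||% default_z_max(fz$A, fz$B))
  prof <- dcglob_sweep(fz$A$z, fz$B$z, grid)
  rownames(prof$I_A) <- rownames(prof$I_B) <- pair$gene_ids
  prof$grid <- grid
  prof
}

#' Longest exclusivity run of one gene
#'
#' Scans one gene's indicator profiles for the longest run of consecutive
#' thresholds with indicator 1, separately in A and in B, and returns the
#' longer of the two together with its condition label. The run interval
#' \[a, b\] is reported in Fisher-z units (grid values of the first and last
#' threshold of the run), so a single-threshold run has length 0. Ties
#' (between equal-length runs within a profile, or between the A run and
#' the B run) are broken towards the run with the higher mean threshold
#' (stronger correlations), then towards A.
#'
#' @param i_a,i_b Logical vectors over the grid (exclusivity in A resp. B).
#' @param grid The [threshold_grid()] the profiles were computed on.
#' @return List with `direction` ("A", "B" or "none"), `run_start`,
#'   `run_end`, `run_length` (all NA for "none") and `run_points` (number
#'   of grid points in the run, 0 for "none").
#' @export
max_run <- function(i_a, i_b, grid) {
  stopifnot(length(i_a) == grid$k, length(i_b) == grid$k)
  th <- grid$thresholds
  best <- function(x) {
    r <- rle(as.logical(x))
    if (!any(r$values)) return(NULL)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values)
    lens <- r$lengths[ok]
    cand <- ok[lens == max(lens)]
    # equal-length runs: later run = higher mean threshold
    pick <- cand[length(cand)]
    list(start = starts[pick], end = ends[pick], points = r$lengths[pick])
  }
  ra <- best(i_a)
  rb <- best(i_b)
  pick_a <- if (is.null(ra)) FALSE
    else if (is.null(rb)) TRUE
    else if (ra$points != rb$points) ra$points > rb$points
    else if (mean(th[ra$start:ra$end]) != mean(th[rb$start:rb$end]))
      mean(th[ra$start:ra$end]) > mean(th[rb$start:rb$end])
    else TRUE
  if (is.null(ra) && is.null(rb))
    return(list(direction = "none", run_start = NA_real_, run_end = NA_real_,
                run_length = NA_real_, run_points = 0L))
  r <- if (pick_a) ra else rb
  list(direction = if (pick_a) "A" else "B",
       run_start = th[r$start], run_end = th[r$end],
       run_length = th[r$end] - th[r$start], run_points = r$points)
}

#' Convert an exclusivity run length to a p-value (Steiger's test)
#'
#' A run of length b - a on the Fisher-z scale is the range of thresholds
#' over which a gene's correlation environment differs between the two
#' conditions. Under the null hypothesis of equal correlation, the
#' difference of two independent Fisher-z values has standard error
#' sqrt(1/(n_A - 3) + 1/(n_B - 3)); the run length is referred to that
#' scale and converted to a one-sided upper-tail standard-normal p-value
#' (run lengths are nonnegative by construction). A gene with no run at any
#' threshold gets p = 1 ("no evidence", ranking below an observed
#' zero-length run with p = 0.5).
#'
#' @param run_length Nonnegative run length(s) in Fisher-z units; NA means
#'   no run observed.
#' @param n_a,n_b Per-condition sample counts (both > 3).
#' @return p-value(s) in (0, 1\].
#' @examples
#' interval_to_pvalue(0.2, 208, 208) # about 0.021
#' @export
interval_to_pvalue <- function(run_length, n_a, n_b) {
  if (n_a <= 3 || n_b <= 3)
    stop("Steiger's test requires more than 3 samples per condition")
  if (any(run_length < 0, na.rm = TRUE)) stop("run_length must be >= 0")
  se <- sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
  p <- stats::pnorm(run_length / se, lower.tail = FALSE)
  p[is.na(run_length)] <- 1
  p
}

#' Global-topology differential correlation scores
#'
#' Runs the full global algorithm: per-condition Fisher-z correlation
#' matrices, the exclusivity indicator sweep over the threshold grid,
#' longest-run extraction per gene, and conversion of run lengths to
#' p-values. Smaller p means stronger differential correlation. The
#' computation is fully deterministic.
#'
#' @inheritParams indicator_profiles
#' @return A `data.frame` of class `dcglob_scores` with columns `gene_id`,
#'   `direction` (condition with the exclusive run), `run_start`,
#'   `run_end`, `run_length`, `p`, sorted by increasing `p` (ties by gene
#'   id). The grid is attached as attribute `grid`.
#' @export
dcglob_scores <- function(pair, grid = NULL, k = 200, z_max = NULL) {
  prof <- indicator_profiles(pair, grid = grid, k = k, z_max = z_max)
  grid <- prof$grid
  runs <- lapply(seq_along(pair$gene_ids), function(g)
    max_run(prof$I_A[g, ], prof$I_B[g, ], grid))
  out <- data.frame(
    gene_id = pair$gene_ids,
    direction = vapply(runs, `[[`, "", "direction"),
    run_start = vapply(runs, `[[`, 0, "run_start"),
    run_end = vapply(runs, `[[`, 0, "run_end"),
    run_length = vapply(runs, `[[`, 0, "run_length"),
    stringsAsFactors = FALSE
  )
  out$p <- interval_to_pvalue(out$run_length, pair$n_a, pair$n_b)
  out <- out[order(out$p, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grid") <- grid
  attr(out, "method") <- "dcglob"
  class(out) <- c("dcglob_scores", "data.frame")
  out
}
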