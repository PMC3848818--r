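# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths: components by BFS flood fill, Pearson
# correlation by the two-pass covariance formula, and both scoring
# algorithms by literal per-threshold set manipulation.

# BFS flood-fill connected components of a logical adjacency matrix
bfs_components <- function(adj) {
  n <- nrow(adj)
  membership <- integer(n)
  comp <- 0L
  for (v in seq_len(n)) {
    if (membership[v] > 0L) next
    comp <- comp + 1L
    queue <- v
    membership[v] <- comp
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[u, ] & membership == 0L)
      membership[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  membership
}

# two-pass Pearson correlation of two vectors
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

clip_z <- function(c, eps = 1e-6) atanh(pmin(pmax(c, -1 + eps), 1 - eps))

pair_z <- function(pair) {
  za <- clip_z(cor(t(pair$a)))
  zb <- clip_z(cor(t(pair$b)))
  diag(za) <- diag(zb) <- 0
  list(a = za, b = zb)
}

# literal per-threshold global algorithm: adjacency matrices, BFS
# components, the removal/induction set algebra, exhaustive run scan
naive_dcglob <- function(pair, grid) {
  z <- pair_z(pair)
  G <- nrow(z$a)
  th <- grid$thresholds
  ids <- rownames(pair$a)
  flags3 <- function(adj) {
    m <- bfs_components(adj)
    tab <- tabulate(m)
    tab[m] >= 3
  }
  IA <- IB <- matrix(FALSE, G, grid$k)
  for (m in seq_along(th)) {
    adj_a <- z$a > th[m]; diag(adj_a) <- FALSE
    adj_b <- z$b > th[m]; diag(adj_b) <- FALSE
    in_a <- flags3(adj_a)
    in_b <- flags3(adj_b)
    removed <- in_a & in_b
    keep <- which(!removed)
    if (length(keep) >= 3) {
      fa <- flags3(adj_a[keep, keep, drop = FALSE])
      fb <- flags3(adj_b[keep, keep, drop = FALSE])
      IA[keep[fa], m] <- TRUE
      IB[keep[fb], m] <- TRUE
    }
  }
  # exhaustive scan over all candidate run intervals
  longest <- function(x) {
    best <- NULL
    for (i in seq_along(x)) for (j in i:length(x)) {
      if (all(x[i:j])) {
        if (is.null(best) || (j - i) > (best[2] - best[1]) ||
            ((j - i) == (best[2] - best[1]) &&
             mean(th[i:j]) > mean(th[best[1]:best[2]])))
          best <- c(i, j)
      }
    }
    best
  }
  se <- sqrt(1 / (ncol(pair$a) - 3) + 1 / (ncol(pair$b) - 3))
  res <- lapply(seq_len(G), function(g) {
    ra <- longest(IA[g, ])
    rb <- longest(IB[g, ])
    if (is.null(ra) && is.null(rb))
      return(data.frame(gene_id = ids[g], direction = "none",
                        run_length = NA_real_, p = 1))
    pick_a <- if (is.null(rb)) TRUE else if (is.null(ra)) FALSE else {
      la <- th[ra[2]] - th[ra[1]]
      lb <- th[rb[2]] - th[rb[1]]
      if (la != lb) la > lb
      else if (mean(th[ra[1]:ra[2]]) != mean(th[rb[1]:rb[2]]))
        mean(th[ra[1]:ra[2]]) > mean(th[rb[1]:rb[2]])
      else TRUE
    }
    r <- if (pick_a) ra else rb
    len <- th[r[2]] - th[r[1]]
    data.frame(gene_id = ids[g], direction = if (pick_a) "A" else "B",
               run_length = len,
               p = pnorm(len / se, lower.tail = FALSE))
  })
  do.call(rbind, res)
}

# literal per-threshold local algorithm with explicit neighbor sets
naive_dcloc <- function(pair, grid) {
  z <- pair_z(pair)
  G <- nrow(z$a)
  ids <- rownames(pair$a)
  d <- signed <- numeric(G)
  na_mean <- nb_mean <- numeric(G)
  for (g in seq_len(G)) {
    dts <- sts <- numeric(grid$k)
    nas <- nbs <- numeric(grid$k)
    for (m in seq_len(grid$k)) {
      va <- setdiff(which(z$a[g, ] > grid$thresholds[m]), g)
      vb <- setdiff(which(z$b[g, ] > grid$thresholds[m]), g)
      u <- union(va, vb)
      dt <- if (length(u) < 3) 0 else 1 - length(intersect(va, vb)) / length(u)
      dts[m] <- dt
      sts[m] <- dt * sign(length(va) - length(vb))
      nas[m] <- length(va)
      nbs[m] <- length(vb)
    }
    d[g] <- mean(dts)
    signed[g] <- sum(sts)
    na_mean[g] <- mean(nas)
    nb_mean[g] <- mean(nbs)
  }
  data.frame(gene_id = ids, d = d, signed_sum = signed,
             mean_neighbors_a = na_mean, mean_neighbors_b = nb_mean,
             stringsAsFactors = FALSE)
}

# Benjamini-Hochberg significance set by the literal step-up rule:
# reject the k smallest p-values for the largest k with p_(k) <= k*alpha/m
naive_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * alpha / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# type-7 percentile by the sort-and-interpolate definition
naive_quantile7 <- function(x, prob) {
  xs <- sort(x)
  h <- (length(x) - 1) * prob + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# symmetric random z-like matrix (zero diagonal) for structural tests
random_z <- function(G, seed, sd = 0.5) {
  set.seed(seed)
  m <- matrix(0, G, G)
  m[upper.tri(m)] <- rnorm(G * (G - 1) / 2, sd = sd)
  m <- m + t(m)
  dimnames(m) <- list(sprintf("g%03d", 1:G), sprintf("g%03d", 1:G))
  m
}

fz_from_z <- function(z, n = 50) dctopo:::new_fisher_z_matrix(z, n)

# z matrix from an explicit weighted edge list
z_from_edges <- function(G, i, j, z, ids = sprintf("g%02d", seq_len(G))) {
  m <- matrix(0, G, G, dimnames = list(ids, ids))
  for (e in seq_along(i)) m[i[e], j[e]] <- m[j[e], i[e]] <- z[e]
  m
}

# small planted-module condition pair for cross-checks
planted_pair <- function(n_genes = 30, module = 6, rho_a = 0.8, rho_b = 0,
                         n = 20, seed = 1) {
  synth_generate(synth_spec(
    n_genes, n,
    modules = data.frame(size = module, rho_a = rho_a, rho_b = rho_b),
    seed = seed))
}
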