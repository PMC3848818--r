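#' Specification of a synthetic two-condition expression data set
#'
#' Describes a latent-factor simulation with planted
#' differential-correlation modules over a background of independent
#' genes. Each module m is governed by one shared factor per condition:
#' module genes are generated as x_g = sqrt(rho_q) * f_m + sqrt(1 - rho_q)
#' * eps_g with f_m and eps_g independent standard normals per sample, so
#' that the expected Pearson correlation between two genes of the module
#' in condition q is exactly rho_q. A module with rho_a != rho_b is
#' differentially correlated (its genes carry the DC truth flag); an
#' optional per-module `de_shift` additionally offsets the module mean in
#' condition B, giving differential expression without touching
#' correlation.
#'
#' @param n_genes Total number of genes.
#' @param n_per_group Samples per condition (>= 4).
#' @param modules `data.frame` with columns `size`, `rho_a`, `rho_b` and
#'   optionally `de_shift`; module sizes must sum to at most `n_genes`.
#'   NULL for a background-only data set.
#' @param background_rho Baseline correlation shared by all background
#'   genes (one global factor; default 0 = independent background).
#' @param noise_sd Overall scale of the generated values.
#' @param seed Integer seed; generation is bitwise reproducible.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(n_genes, n_per_group, modules = NULL,
                       background_rho = 0, noise_sd = 1, seed = 1) {
  if (n_per_group < 4) stop("need at least 4 samples per group")
  if (!is.null(modules)) {
    stopifnot(is.data.frame(modules),
              all(c("size", "rho_a", "rho_b") %in% names(modules)))
    if (is.null(modules$de_shift)) modules$de_shift <- 0
    rhos <- c(modules$rho_a, modules$rho_b)
    if (any(rhos < 0 | rhos >= 1)) stop("module rho must lie in [0, 1)")
    if (sum(modules$size) > n_genes)
      stop("module sizes exceed the number of genes")
  }
  if (background_rho < 0 || background_rho >= 1)
    stop("background_rho must lie in [0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group), modules = modules,
                 background_rho = background_rho, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic condition pair with planted modules
#'
#' Realizes a [synth_spec()]: module genes load on their module's latent
#' factor with condition-specific strength, background genes are
#' independent noise (or share one weak global factor when
#' `background_rho` > 0). Gene ids are `g0001`, ..., module genes first;
#' sample ids are `A_s1`, ... and `B_s1`, ....
#'
#' @param spec A [synth_spec()].
#' @return List with `pair` (a [condition_pair()]) and `truth`
#'   (`data.frame` with `gene_id`, `module` (0 = background), `dc`
#'   (logical: module has rho_a != rho_b)).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  G <- spec$n_genes
  n <- spec$n_per_group
  ids <- sprintf("g%04d", seq_len(G))
  module_of <- integer(G)
  if (!is.null(spec$modules)) {
    module_of[seq_len(sum(spec$modules$size))] <-
      rep(seq_len(nrow(spec$modules)), spec$modules$size)
  }
  gen_condition <- function(which_rho, shift_cond) {
    x <- matrix(stats::rnorm(G * n), G, n)
    if (spec$background_rho > 0) {
      bg <- module_of == 0L
      f0 <- stats::rnorm(n)
      x[bg, ] <- sqrt(spec$background_rho) * rep(f0, each = sum(bg)) +
        sqrt(1 - spec$background_rho) * x[bg, ]
    }
    if (!is.null(spec$modules)) {
      for (m in seq_len(nrow(spec$modules))) {
        rho <- spec$modules[[which_rho]][m]
        rows <- which(module_of == m)
        f <- stats::rnorm(n)
        x[rows, ] <- sqrt(rho) * rep(f, each = length(rows)) +
          sqrt(1 - rho) * x[rows, ]
        if (shift_cond)
          x[rows, ] <- x[rows, ] + spec$modules$de_shift[m]
      }
    }
    x * spec$noise_sd
  }
  res <- with_seed(spec$seed, {
    a <- gen_condition("rho_a", shift_cond = FALSE)
    b <- gen_condition("rho_b", shift_cond = TRUE)
    list(a = a, b = b)
  })
  dimnames(res$a) <- list(ids, paste0("A_s", seq_len(n)))
  dimnames(res$b) <- list(ids, paste0("B_s", seq_len(n)))
  truth <- data.frame(
    gene_id = ids, module = module_of,
    dc = if (is.null(spec$modules)) rep(FALSE, G) else
      module_of > 0L &
        spec$modules$rho_a[pmax(module_of, 1L)] !=
        spec$modules$rho_b[pmax(module_of, 1L)],
    stringsAsFactors = FALSE
  )
  list(pair = condition_pair(res$a, res$b), truth = truth)
}

#' Expression matrix with an exactly prescribed sample correlation
#'
#' Deterministically constructs a genes x samples matrix whose sample
#' Pearson correlation matrix equals `R` to machine precision: the rows of
#' an orthonormal mean-zero basis (normalized Helmert contrasts) are mixed
#' by the Cholesky factor of `R`. Requires `nrow(R) <= n - 1` and `R`
#' positive definite. Used to build small fixtures whose per-threshold
#' networks are known by construction.
#'
#' @param R Target correlation matrix (symmetric positive definite, unit
#'   diagonal).
#' @param n Number of samples.
#' @param gene_ids,sample_ids Optional dimnames.
#' @param center,scale Affine transform applied to every row (does not
#'   change correlations).
#' @return Numeric matrix with `cor(t(.))` equal to `R`.
#' @export
expression_from_correlation <- function(R, n, gene_ids = NULL,
                                        sample_ids = NULL, center = 0,
                                        scale = 1) {
  p <- nrow(R)
  if (p > n - 1) stop("need n >= nrow(R) + 1 samples")
  H <- stats::contr.helmert(n) # n x (n-1), orthogonal, columns sum to 0
  H <- sweep(H, 2, sqrt(colSums(H^2)), "/")
  X <- t(chol(R)) %*% t(H[, seq_len(p), drop = FALSE])
  X <- center + scale * X
  dimnames(X) <- list(gene_ids %||% sprintf("g%02d", seq_len(p)),
                      sample_ids %||% sprintf("s%02d", seq_len(n)))
  X
}

# correlation matrix with equicorrelated blocks on an identity background
block_correlation <- function(p, blocks) {
  R <- diag(p)
  for (b in blocks) R[b$rows, b$rows] <- b$c
  diag(R) <- 1
  R
}

#' Hand-built toy condition pairs with known network structure
#'
#' Small deterministic fixtures (built via
#' [expression_from_correlation()], so pairwise correlations are exact)
#' whose per-threshold networks can be enumerated by hand. All fixtures
#' are meant to be analyzed with `threshold_grid(10, 1.0)`; the planted
#' Fisher-z edge values sit at least 0.04 away from every grid point so
#' that the strict edge rule is numerically unambiguous.
#'
#' * `"identical"`: 5 genes, 8 samples; condition B is a value-identical
#'   copy of A (samples renamed). Genes 1-3 are equicorrelated at c = 0.6.
#'   Every differential-correlation score is null.
#' * `"one_module_flip"`: 7 genes, 10 samples; genes 1-4 equicorrelated at
#'   c = 0.6 (z = 0.693) in A only, B fully uncorrelated. At thresholds
#'   0.1-0.6 the exclusive A set is exactly genes 1-4; at 0.7-1.0 it is
#'   empty.
#' * `"tie_case"`: 6 genes `g, x, y, u, v, w`, 10 samples. In A, `{g, x,
#'   y}` form a triangle at z = 0.95 and `{g, u, v}` a triangle at z =
#'   0.35; in B, `{x, y, w}` form a triangle at z = 0.65. Gene `g` is
#'   exclusively A-clustered at thresholds 0.1-0.3 (via u, v, after x, y
#'   are removed as shared) and again at 0.7-0.9 (via x, y, once the B
#'   triangle has dissolved), but not at 0.4-0.6 where x and y are removed
#'   and u, v are disconnected: two equal-length runs in the same
#'   profile, resolved towards the higher-threshold run \[0.7, 0.9\].
#'
#' @param name Fixture name.
#' @return A [condition_pair()].
#' @export
toy_fixture <- function(name = c("identical", "one_module_flip",
                                 "tie_case")) {
  name <- match.arg(name)
  if (name == "identical") {
    R <- block_correlation(5, list(list(rows = 1:3, c = 0.6)))
    a <- expression_from_correlation(R, 8, sample_ids = paste0("a", 1:8))
    b <- a
    colnames(b) <- paste0("b", 1:8)
    return(condition_pair(a, b))
  }
  if (name == "one_module_flip") {
    RA <- block_correlation(7, list(list(rows = 1:4, c = 0.6)))
    RB <- diag(7)
    a <- expression_from_correlation(RA, 10, sample_ids = paste0("a", 1:10))
    b <- expression_from_correlation(RB, 10, sample_ids = paste0("b", 1:10))
    return(condition_pair(a, b))
  }
  # tie_case
  ids <- c("g", "x", "y", "u", "v", "w")
  RA <- diag(6)
  hi <- tanh(0.95)
  lo <- tanh(0.35)
  RA[1, 2] <- RA[2, 1] <- hi # g-x
  RA[1, 3] <- RA[3, 1] <- hi # g-y
  RA[2, 3] <- RA[3, 2] <- hi # x-y
  RA[1, 4] <- RA[4, 1] <- lo # g-u
  RA[1, 5] <- RA[5, 1] <- lo # g-v
  RA[4, 5] <- RA[5, 4] <- lo # u-v
  RB <- diag(6)
  md <- tanh(0.65)
  RB[2, 3] <- RB[3, 2] <- md # x-y
  RB[2, 6] <- RB[6, 2] <- md # x-w
  RB[3, 6] <- RB[6, 3] <- md # y-w
  a <- expression_from_correlation(RA, 10, gene_ids = ids,
                                   sample_ids = paste0("a", 1:10))
  b <- expression_from_correlation(RB, 10, gene_ids = ids,
                                   sample_ids = paste0("b", 1:10))
  condition_pair(a, b)
}
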