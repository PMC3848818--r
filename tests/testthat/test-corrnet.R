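test_that("fisher transform is the clipped atanh", {
  expect_identical(fisher_transform(0), 0)
  expect_equal(fisher_transform(0.985), 0.5 * log(1.985 / 0.015),
               tolerance = 1e-12)
  expect_equal(round(fisher_transform(0.985), 4), 2.4427)
  cc <- seq(-0.99, 0.99, by = 0.07)
  expect_equal(fisher_transform(-cc), -fisher_transform(cc))
  # strictly increasing, clipping keeps +/-1 finite
  expect_true(all(diff(fisher_transform(cc)) > 0))
  expect_true(is.finite(fisher_transform(1)))
  expect_equal(fisher_transform(1), atanh(1 - 1e-6))
  expect_error(fisher_transform(NA_real_), "finite")
  expect_error(fisher_transform(Inf), "finite")
  # round trip with tanh inside the clipping range
  z <- seq(-7, 7, by = 0.25)
  expect_equal(fisher_transform(tanh(z)), z, tolerance = 1e-9)
})

test_that("correlation matrices match a two-pass Pearson oracle", {
  x <- matrix(c(1.2, 2.4, 3.1, 0.5, 1.9,
                4.0, 3.2, 5.1, 4.4, 2.8,
                0.1, 0.9, 0.4, 1.3, 0.6), 3, 5, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("a", 1:5)))
  y <- matrix(c(2.2, 1.4, 0.1, 3.5, 2.9,
                1.0, 1.2, 2.1, 1.4, 0.8,
                5.1, 4.9, 5.4, 4.3, 5.6), 3, 5, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("b", 1:5)))
  fz <- correlation_matrices(condition_pair(x, y))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(fz$A$z[i, j], clip_z(naive_pearson(x[i, ], x[j, ])),
                 tolerance = 1e-12)
    expect_equal(fz$B$z[i, j], clip_z(naive_pearson(y[i, ], y[j, ])),
                 tolerance = 1e-12)
  }
  expect_true(isSymmetric(fz$A$z))
  expect_equal(fz$A$n, 5)
})

test_that("duplicated genes clip to the finite z ceiling", {
  set.seed(4)
  a <- matrix(rnorm(4 * 8), 4, 8,
              dimnames = list(paste0("g", 1:4), paste0("a", 1:8)))
  a[2, ] <- a[1, ] # duplicate
  b <- matrix(rnorm(4 * 8), 4, 8,
              dimnames = list(paste0("g", 1:4), paste0("b", 1:8)))
  fz <- correlation_matrices(condition_pair(a, b))
  expect_equal(fz$A$z[1, 2], atanh(1 - 1e-6))
})

test_that("correlations are invariant to joint sample permutation", {
  sim <- planted_pair(seed = 8)
  fz1 <- correlation_matrices(sim$pair)
  perm <- sample(ncol(sim$pair$a))
  p2 <- condition_pair(sim$pair$a[, perm], sim$pair$b[, perm])
  fz2 <- correlation_matrices(p2)
  expect_equal(fz1$A$z, fz2$A$z)
  expect_equal(fz1$B$z, fz2$B$z)
})

test_that("value-identical conditions give identical z matrices", {
  pair <- toy_fixture("identical")
  fz <- correlation_matrices(pair)
  expect_identical(fz$A$z, fz$B$z)
})

test_that("constant genes are rejected by name", {
  a <- matrix(rnorm(3 * 6), 3, 6,
              dimnames = list(c("g1", "flatgene", "g3"), paste0("a", 1:6)))
  a[2, ] <- 7
  b <- matrix(rnorm(3 * 6), 3, 6,
              dimnames = list(c("g1", "flatgene", "g3"), paste0("b", 1:6)))
  expect_error(correlation_matrices(condition_pair(a, b)), "flatgene")
})

test_that("condition pair validation enforces its invariants", {
  a <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("g1", "g2"), paste0("a", 1:3)))
  b <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("g1", "g2"), paste0("b", 1:3)))
  expect_s3_class(condition_pair(a, b), "condition_pair")
  expect_error(condition_pair(a, a), "disjoint")
  b_bad <- b; rownames(b_bad) <- c("g1", "other")
  expect_error(condition_pair(a, b_bad), "gene set")
  expect_error(condition_pair(a, b[, 1:2]), "unequal")
  expect_warning(condition_pair(a, b[, 1:2], allow_unequal = TRUE),
                 "unequal")
  a_na <- a; a_na[1, 1] <- NA
  expect_error(condition_pair(a_na, b), "non-finite")
  # reordered but set-equal gene ids are harmonized
  b_perm <- b[c("g2", "g1"), ]
  pp <- condition_pair(a, b_perm)
  expect_identical(rownames(pp$b), rownames(a))
})

test_that("threshold grid is equidistant, endpoint-inclusive, zero-free", {
  g <- threshold_grid(200, 2.5)
  expect_length(g$thresholds, 200)
  expect_equal(g$delta, 0.0125)
  expect_equal(g$thresholds[1], 0.0125)
  expect_equal(g$thresholds[200], 2.5)
  expect_equal(unique(round(diff(g$thresholds), 12)), 0.0125)
  expect_equal(threshold_grid(4, 1.0)$thresholds, c(0.25, 0.5, 0.75, 1.0))
  expect_error(threshold_grid(1, 2.5), "k")
  expect_error(threshold_grid(10, 0), "z_max")
  expect_error(threshold_grid(10, -1), "z_max")
})

test_that("network edges follow the strict signed threshold rule", {
  z <- z_from_edges(3, c(1, 1, 2), c(2, 3, 3), c(0.6, 0.2, 0.5))
  fz <- fz_from_z(z)
  net <- network_at(fz, 0.4)
  expect_equal(sum(net$adj) / 2, 2)
  expect_true(net$adj[1, 2] && net$adj[2, 3])
  expect_false(net$adj[1, 3])
  # above the maximum: empty
  expect_equal(sum(network_at(fz, 0.7)$adj), 0)
  # exact equality is not an edge (strict rule)
  expect_false(network_at(fz, 0.6)$adj[1, 2])
  # negative correlations never connect under the signed rule
  zn <- z_from_edges(3, 1, 2, -2.5)
  expect_equal(sum(network_at(fz_from_z(zn), 0.5)$adj), 0)
  expect_equal(sum(network_at(fz_from_z(zn), 0.5, absolute = TRUE)$adj) / 2, 1)
})

test_that("edge sets are nested across the threshold grid", {
  for (seed in 1:5) {
    fz <- fz_from_z(random_z(25, seed))
    grid <- threshold_grid(12, 1.2)
    prev <- NULL
    for (t in grid$thresholds) {
      adj <- network_at(fz, t)$adj
      if (!is.null(prev)) expect_true(all(prev | !adj)) # adj subset of prev
      prev <- adj
    }
  }
})

test_that("size-3 component filter matches a BFS flood-fill oracle", {
  # triangle plus isolated pair
  z <- z_from_edges(5, c(1, 1, 2, 4), c(2, 3, 3, 5), rep(0.9, 4),
                    ids = c("a", "b", "c", "d", "e"))
  comps <- components_min3(network_at(fz_from_z(z), 0.5))
  expect_length(comps, 1)
  expect_setequal(comps[[1]], c("a", "b", "c"))
  # empty graph
  expect_length(components_min3(network_at(fz_from_z(z), 1.0)), 0)
  # random graphs against the oracle
  for (seed in 1:100) {
    G <- sample(5:60, 1)
    net <- network_at(fz_from_z(random_z(G, seed + 1000, sd = 0.3)), 0.35)
    got <- components_min3(net)
    memb <- bfs_components(net$adj)
    sizes <- tabulate(memb)
    want <- lapply(which(sizes >= 3), function(cc)
      net$gene_ids[memb == cc])
    expect_equal(length(got), length(want))
    got_sets <- lapply(got, sort)
    want_sets <- lapply(want, sort)
    expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                    vapply(want_sets, paste, "", collapse = ","))
  }
})
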