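test_that("exclusive component sets follow the removal/induction algebra", {
  # identical networks: everything clustered is removed, nothing exclusive
  z <- z_from_edges(6, c(1, 1, 2), c(2, 3, 3), rep(0.9, 3))
  na <- network_at(fz_from_z(z), 0.5)
  ex <- exclusive_component_genes(na, na)
  expect_setequal(ex$removed, c("g01", "g02", "g03"))
  expect_length(ex$a_tilde, 0)
  expect_length(ex$b_tilde, 0)

  # A has two triangles, B shares one of them
  za <- z_from_edges(6, c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6), rep(0.9, 6))
  zb <- z_from_edges(6, c(1, 1, 2), c(2, 3, 3), rep(0.9, 3))
  ex <- exclusive_component_genes(network_at(fz_from_z(za), 0.5),
                                  network_at(fz_from_z(zb), 0.5))
  expect_setequal(ex$removed, c("g01", "g02", "g03"))
  expect_setequal(ex$a_tilde, c("g04", "g05", "g06"))
  expect_length(ex$b_tilde, 0)

  # conservative induction: shared genes tear both leftovers below size 3
  za <- z_from_edges(5, c(1, 2, 3), c(2, 3, 4), rep(0.9, 3)) # path 1-2-3-4
  zb <- z_from_edges(5, c(3, 4), c(4, 5), rep(0.9, 2))       # path 3-4-5
  ex <- exclusive_component_genes(network_at(fz_from_z(za), 0.5),
                                  network_at(fz_from_z(zb), 0.5))
  expect_setequal(ex$removed, c("g03", "g04"))
  expect_length(ex$a_tilde, 0)
  expect_length(ex$b_tilde, 0)

  # mismatched gene sets are rejected
  z5 <- z_from_edges(5, 1, 2, 0.9)
  expect_error(
    exclusive_component_genes(network_at(fz_from_z(z), 0.5),
                              network_at(fz_from_z(z5), 0.5)),
    "gene set")
})

test_that("indicator profiles vanish for identical conditions", {
  prof <- indicator_profiles(toy_fixture("identical"), k = 20)
  expect_false(any(prof$I_A))
  expect_false(any(prof$I_B))
})

test_that("indicator profiles match the documented module flip", {
  grid <- threshold_grid(10, 1.0)
  prof <- indicator_profiles(toy_fixture("one_module_flip"), grid = grid)
  module <- paste0("g0", 1:4)
  # module correlated at z = 0.693 in A only: exclusive at t = 0.1..0.6
  for (m in 1:6) expect_setequal(rownames(prof$I_A)[prof$I_A[, m]], module)
  for (m in 7:10) expect_false(any(prof$I_A[, m]))
  expect_false(any(prof$I_B))
})

test_that("indicator columns equal a single-threshold recomputation", {
  sim <- planted_pair(seed = 21)
  grid <- threshold_grid(8, 1.0)
  prof <- indicator_profiles(sim$pair, grid = grid)
  fz <- correlation_matrices(sim$pair)
  for (m in c(1, 4, 8)) {
    ex <- exclusive_component_genes(network_at(fz$A, grid$thresholds[m]),
                                    network_at(fz$B, grid$thresholds[m]))
    expect_setequal(rownames(prof$I_A)[prof$I_A[, m]], ex$a_tilde)
    expect_setequal(rownames(prof$I_B)[prof$I_B[, m]], ex$b_tilde)
  }
})

test_that("max_run finds the longest run with documented tie-breaks", {
  grid <- threshold_grid(20, 2.0)
  all_on <- rep(TRUE, 20)
  none <- rep(FALSE, 20)
  r <- max_run(all_on, none, grid)
  expect_equal(r$direction, "A")
  expect_equal(r$run_start, grid$thresholds[1])
  expect_equal(r$run_end, grid$thresholds[20])
  expect_equal(r$run_length, grid$z_max - grid$thresholds[1])

  # runs of grid-length 3 and 5: the 5-run wins, length 4 * delta
  ia <- none
  ia[2:4] <- TRUE
  ia[10:14] <- TRUE
  r <- max_run(ia, none, grid)
  expect_equal(r$run_points, 5)
  expect_equal(r$run_length, 4 * grid$delta)
  expect_equal(r$run_start, grid$thresholds[10])

  # A-vs-B tie on length: higher mean threshold wins, then A
  ia2 <- none; ia2[2:4] <- TRUE
  ib2 <- none; ib2[6:8] <- TRUE
  expect_equal(max_run(ia2, ib2, grid)$direction, "B")
  expect_equal(max_run(ib2, ia2, grid)$direction, "A")
  expect_equal(max_run(ia2, ia2, grid)$direction, "A")

  # both empty
  r <- max_run(none, none, grid)
  expect_equal(r$direction, "none")
  expect_true(is.na(r$run_length))

  # exhaustive-scan oracle on random profiles
  set.seed(33)
  for (rep in 1:50) {
    x <- runif(20) < 0.45
    r <- max_run(x, none, grid)
    best_len <- 0L
    found <- FALSE
    for (i in 1:20) for (j in i:20) if (all(x[i:j])) {
      found <- TRUE
      best_len <- max(best_len, j - i + 1L)
    }
    if (found) {
      expect_equal(r$run_points, best_len)
    } else {
      expect_equal(r$direction, "none")
    }
  }
})

test_that("run lengths convert to one-sided Steiger p-values", {
  expect_equal(interval_to_pvalue(0, 208, 208), 0.5)
  expect_equal(round(interval_to_pvalue(0.2, 208, 208), 4), 0.0214)
  # detection boundary at n = 208: p < 0.05 iff length > 1.6449*sqrt(2/205)
  expect_lt(interval_to_pvalue(0.163, 208, 208), 0.05)
  expect_gt(interval_to_pvalue(0.162, 208, 208), 0.05)
  # no run at all: p = 1
  expect_equal(interval_to_pvalue(NA_real_, 208, 208), 1)
  expect_error(interval_to_pvalue(0.2, 3, 208), "3 samples")
  expect_error(interval_to_pvalue(-0.1, 10, 10), ">= 0")
  # monotone non-increasing in run length, p in (0, 1]
  lens <- seq(0, 2, by = 0.1)
  ps <- interval_to_pvalue(lens, 30, 30)
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("global scores are null for identical conditions", {
  s <- dcglob_scores(toy_fixture("identical"), k = 25)
  expect_true(all(s$p == 1))
  expect_true(all(s$direction == "none"))
})

test_that("global scores match the literal per-threshold oracle", {
  for (seed in c(5, 17)) {
    sim <- planted_pair(n_genes = 25, module = 5, n = 12, seed = seed)
    grid <- threshold_grid(15, 1.4)
    got <- dcglob_scores(sim$pair, grid = grid)
    want <- naive_dcglob(sim$pair, grid)
    got <- got[order(got$gene_id), ]
    want <- want[order(want$gene_id), ]
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_equal(got$direction, want$direction)
    expect_equal(got$run_length, want$run_length, tolerance = 1e-12)
  }
})

test_that("global scoring is deterministic and sorted by p", {
  sim <- planted_pair(seed = 9)
  s1 <- dcglob_scores(sim$pair, k = 30)
  s2 <- dcglob_scores(sim$pair, k = 30)
  expect_identical(s1, s2)
  expect_true(!is.unsorted(s1$p))
})

test_that("exclusivity indicators for A and B are mutually exclusive", {
  for (seed in 1:4) {
    sim <- planted_pair(n_genes = 20, module = 5, n = 10, seed = seed)
    prof <- indicator_profiles(sim$pair, k = 12)
    expect_false(any(prof$I_A & prof$I_B))
  }
})

test_that("equal-length runs within a profile resolve to higher thresholds", {
  grid <- threshold_grid(10, 1.0)
  s <- dcglob_scores(toy_fixture("tie_case"), grid = grid)
  g <- s[s$gene_id == "g", ]
  expect_equal(g$direction, "A")
  expect_equal(g$run_start, 0.7)
  expect_equal(g$run_end, 0.9)
  # and the profile really has the two documented runs
  prof <- indicator_profiles(toy_fixture("tie_case"), grid = grid)
  expect_equal(unname(which(prof$I_A["g", ])), c(1:3, 7:9))
})

test_that("planted module genes dominate the global ranking", {
  sim <- planted_pair(n_genes = 100, module = 10, rho_a = 0.8, n = 50,
                      seed = 2)
  s <- dcglob_scores(sim$pair)
  module <- sim$truth$gene_id[sim$truth$dc]
  expect_lte(median(match(module, s$gene_id)), 15)
})
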