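## a synthetic one-mode spectrum built from an explicit displacement
fake_spectrum <- function(v, value = 1) {
  v <- v / sqrt(sum(v^2))
  structure(list(values = value, vectors = matrix(v, ncol = 1),
                 n_null = 6, n_mainchain = length(v) / 3, M = 1L),
            class = "mode_spectrum")
}

test_that("rigid pair motions produce exactly zero strain", {
  st <- random_cloud_structure(6, seed = 4)
  n <- 6
  ## pure translation
  sp <- fake_spectrum(rep(c(1, 0, 0), n))
  expect_equal(pair_strain(sp, st, 1, 2), 0)
  ## pure linearized rotation about the centroid: (w x d) . d = 0
  xyz <- sweep(as.matrix(st$residues[, c("x", "y", "z")]), 2,
               colMeans(as.matrix(st$residues[, c("x", "y", "z")])))
  w <- c(0.3, -0.2, 0.9)
  rot <- as.vector(t(cbind(w[2] * xyz[, 3] - w[3] * xyz[, 2],
                           w[3] * xyz[, 1] - w[1] * xyz[, 3],
                           w[1] * xyz[, 2] - w[2] * xyz[, 1])))
  sp <- fake_spectrum(rot)
  for (j in 2:6) expect_equal(pair_strain(sp, st, 1, j), 0, tolerance = 1e-12)
})

test_that("pair strain is symmetric, nonnegative, and matches the field matrix", {
  hinge <- make_hinge_toy()
  sp <- compute_modes(hinge$network, n_modes = 6, method = "dense")
  f <- strain_field(sp, hinge$structure)
  for (i in 1:5) for (j in (i + 1):6) {
    sij <- pair_strain(sp, hinge$structure, i, j)
    expect_gte(sij, 0)
    expect_equal(sij, pair_strain(sp, hinge$structure, j, i))
    expect_equal(sij, f$S[i, j], tolerance = 1e-12)
  }
})

test_that("hinge toy: intra-triangle strain is negligible, cross-hinge is not", {
  hinge <- make_hinge_toy()
  sp <- compute_modes(hinge$network, n_modes = 6, method = "dense")
  intra <- pair_strain(sp, hinge$structure, 1, 2)
  cross <- pair_strain(sp, hinge$structure, 1, 4)
  expect_gt(cross, 10 * intra)
  ## and already in the lowest nonzero mode alone
  sp1 <- truncate_spectrum(sp, 1)
  expect_gt(pair_strain(sp1, hinge$structure, 1, 4),
            10 * pair_strain(sp1, hinge$structure, 1, 2))
})

test_that("partition strain sums intra-domain pairs only", {
  hinge <- make_hinge_toy()
  sp <- compute_modes(hinge$network, n_modes = 6, method = "dense")
  f <- strain_field(sp, hinge$structure)
  ## all singletons -> zero
  expect_equal(partition_strain(1:6, f)$total, 0)
  ## Q = 1 -> full pairwise sum
  expect_equal(partition_strain(rep(1, 6), f)$total, sum(f$S) / 2)
  ## total = sum of per-domain strains
  ps <- partition_strain(hinge$planted, f)
  expect_equal(ps$total, sum(ps$per_domain), tolerance = 1e-12)
})

test_that("the planted hinge 2-partition beats every other 2-partition", {
  hinge <- make_hinge_toy()
  sp <- compute_modes(hinge$network, n_modes = 6, method = "dense")
  f <- strain_field(sp, hinge$structure)
  planted <- partition_strain(hinge$planted, f)$total
  best_other <- Inf
  for (code in 1:31) {                 # all 2-subsets up to complement
    lab <- as.integer(intToBits(code))[1:6] + 1L
    if (length(unique(lab)) < 2) next
    if (match_score(lab, hinge$planted) == 1) next
    best_other <- min(best_other, partition_strain(lab, f)$total)
  }
  expect_lt(planted, best_other)
})

test_that("coincident residues are rejected", {
  df <- data.frame(chain = "A", protein = "A", resno = 1:2, ins = "",
                   resid = "ALA", x = c(1, 1), y = 1, z = 1)
  st <- capsid_structure(df)
  sp <- fake_spectrum(rep(c(1, 0, 0), 2))
  expect_error(pair_strain(sp, st, 1, 2), "coincident")
  expect_error(strain_field(sp, st), "coincident")
})

test_that("pair_cutoff masks distant pairs and flags the approximation", {
  ring <- fixture("ring", make_ring_assembly(4, 8, seed = 7))
  sp <- compute_modes(ring$network, n_modes = 18, method = "dense")
  f0 <- strain_field(sp, ring$structure)
  f1 <- strain_field(sp, ring$structure, pair_cutoff = 4)
  expect_true(f1$approximate)
  d <- as.matrix(dist(f1$coords))
  expect_true(all(f1$S[d > 4] == 0))
  expect_equal(f1$S[d <= 4], f0$S[d <= 4])
})
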