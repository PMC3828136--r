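test_that("a connected network yields exactly 6 discarded null modes", {
  for (toy in list(make_hinge_toy(),
                   fixture("ring", make_ring_assembly(4, 8, seed = 7)))) {
    sp <- compute_modes(toy$network, n_modes = 5, method = "dense")
    expect_equal(sp$n_null, 6)
    expect_true(all(diff(sp$values) >= 0))
    expect_true(all(sp$values > 0))
  }
})

test_that("shift-invert Arnoldi matches dense diagonalization", {
  ## ~100-residue planted assembly (300 degrees of freedom)
  toy <- fixture("ring5", make_ring_assembly(5, 20, seed = 21))
  spD <- compute_modes(toy$network, n_modes = 30, method = "dense")
  spA <- compute_modes(toy$network, n_modes = 30, method = "arpack")
  expect_equal(spA$n_null, 6)
  expect_lt(max(abs(spA$values - spD$values) / spD$values), 1e-8)
  ## eigenvectors agree up to sign within degenerate clusters:
  ## compare the projectors mode by mode where eigenvalues are simple
  gaps <- c(Inf, diff(spD$values)) > 1e-6 & c(diff(spD$values), Inf) > 1e-6
  for (l in which(gaps))
    expect_gt(abs(sum(spA$vectors[, l] * spD$vectors[, l])), 1 - 1e-6)
})

test_that("mode vectors are orthonormal and orthogonal to rigid motions", {
  toy <- fixture("ring", make_ring_assembly(4, 8, seed = 7))
  sp <- compute_modes(toy$network, n_modes = 18, method = "dense")
  G <- crossprod(sp$vectors)
  expect_lt(max(abs(G - diag(18))), 1e-8)
  tr <- rep(c(1, 0, 0), 32) / sqrt(32)
  expect_lt(max(abs(crossprod(sp$vectors, tr))), 1e-8)
})

test_that("two point masses joined by one spring have eigenvalue 2k", {
  for (k in c(1, 3.5)) {
    net <- elastic_network(rbind(c(0, 0, 0), c(2, 0, 0)),
                           data.frame(i = 1, j = 2, k = k))
    sp <- compute_modes(net, n_modes = 1, method = "dense")
    expect_equal(sp$values, 2 * k, tolerance = 1e-12)
  }
})

test_that("the spectrum is invariant under rigid rotation of the input", {
  toy <- make_ring_assembly(3, 6, seed = 9)
  sp1 <- compute_modes(toy$network, n_modes = 12, method = "dense")
  th <- 0.7; ax <- c(1, 2, 3) / sqrt(14)
  Kx <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
  net2 <- elastic_network(toy$network$coords %*% t(R), toy$network$edges)
  sp2 <- compute_modes(net2, n_modes = 12, method = "dense")
  expect_lt(max(abs(sp1$values - sp2$values) / sp1$values), 1e-8)
})

test_that("doubling all spring strengths doubles every eigenvalue", {
  toy <- make_ring_assembly(3, 6, seed = 9)
  e2 <- toy$network$edges; e2$k <- 2 * e2$k
  net2 <- elastic_network(toy$network$coords, e2)
  sp1 <- compute_modes(toy$network, n_modes = 10, method = "dense")
  sp2 <- compute_modes(net2, n_modes = 10, method = "dense")
  expect_equal(sp2$values, 2 * sp1$values, tolerance = 1e-10)
})

test_that("select_mode_count counts capsid modes below the protein threshold", {
  fake <- function(vals) structure(list(values = vals), class = "mode_spectrum")
  expect_equal(select_mode_count(fake(c(0.1, 0.5, 1.9, 2.0, 2.5)),
                                 fake(c(.2, .4, .6, .8, 2.0)), floor = 1), 3)
  expect_warning(
    M <- select_mode_count(fake(seq(2, 30)), fake(c(.2, .4, .6, .8, 1.0)),
                           floor = 10),
    "floor")
  expect_equal(M, 10)
  expect_error(select_mode_count(fake(1:10), fake(c(1, 2))), "fewer than 5")
})

test_that("a planted-block assembly retains at least its soft inter-block modes", {
  toy <- fixture("ring", make_ring_assembly(4, 8, seed = 7))
  sp <- compute_modes(toy$network, n_modes = 40, method = "dense")
  psub <- capsidomains:::.subnetwork(toy$network,
                                     toy$structure$proteins[[1]])
  pspec <- compute_modes(psub, n_modes = 5, method = "dense")
  M <- select_mode_count(sp, pspec)
  ## 4 quasi-rigid blocks -> 6*4 - 6 = 18 soft relative modes
  expect_gte(M, 18)
})
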