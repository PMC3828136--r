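test_that("two residues 5 A apart with cutoff 7.5 yield the expected couplings", {
  st <- capsid_structure(data.frame(
    chain = "A", protein = "A", resno = 1:2, ins = "", resid = "ALA",
    x = c(0, 5), y = 0, z = 0))
  net <- build_beta_gaussian(st, cutoff = 7.5)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$n_mainchain, 2)
})

test_that("glycine contributes no side centroid to the network", {
  path <- tempfile(fileext = ".pdb")
  write_mini_pdb(path, c(gly_atoms(0, "A", 1, 0), gly_atoms(5, "A", 2, 3)))
  st <- suppressMessages(load_structure(path))
  net <- build_beta_gaussian(st, cutoff = 7.5)
  expect_equal(nrow(net$coords), 2)        # main-chain centroids only
  expect_equal(nrow(net$edges), 1)
})

test_that("cell-list neighbour search matches the brute-force pair scan", {
  for (seed in 1:3) {
    st <- random_cloud_structure(20, seed = seed)
    cutoff <- 2.5
    net <- suppressWarnings(build_beta_gaussian(st, cutoff = cutoff))
    coords <- net$coords
    brute <- brute_pairs_within(coords, cutoff)
    ## backbone springs beyond the cutoff are extra edges
    d_bb <- sqrt(rowSums((coords[-1, ] - coords[-20, ])^2))
    expect_equal(nrow(net$edges), brute + sum(d_bb > cutoff))
  }
})

test_that("backbone_bonus rescales consecutive main-chain springs only", {
  st <- peptide_structure(6)
  net <- build_beta_gaussian(st, cutoff = 7.5, backbone_bonus = 5)
  e <- net$edges
  consec <- abs(e$i - e$j) == 1 & e$i <= 6 & e$j <= 6
  expect_true(all(e$k[consec] == 5))
  expect_true(all(e$k[!consec] == 1))
})

test_that("a disconnected network triggers a component report", {
  st <- capsid_structure(data.frame(
    chain = rep(c("A", "B"), each = 2), protein = rep(c("A", "B"), each = 2),
    resno = c(1, 2, 1, 2), ins = "", resid = "ALA",
    x = c(0, 3, 100, 103), y = 0, z = 0))
  expect_warning(build_beta_gaussian(st, cutoff = 7.5), "2 components")
})

test_that("with no side centroids the effective matrix is the main-chain Hessian", {
  ring <- fixture("ring", make_ring_assembly(4, 8, seed = 7))
  K <- effective_mainchain_matrix(ring$network)
  expect_equal(dim(K), c(96, 96))
  expect_equal(as.matrix(K),
               as.matrix(capsidomains:::.network_hessian(ring$network)),
               tolerance = 1e-12)
})

test_that("side-chain elimination equals the dense Schur-complement oracle", {
  st <- peptide_structure(5)
  net <- build_beta_gaussian(st, cutoff = 7.5)
  expect_gt(nrow(net$coords), 5)          # side centroids present
  Keff <- as.matrix(effective_mainchain_matrix(net))
  Kfull <- capsidomains:::.network_hessian(net)
  expect_equal(Keff, unname(dense_schur(Kfull, 15)), tolerance = 1e-10)
})

test_that("the effective matrix annihilates global rigid motions", {
  st <- peptide_structure(8, seed = 2)
  net <- build_beta_gaussian(st, cutoff = 7.5)
  K <- effective_mainchain_matrix(net)
  n <- 8
  for (a in 1:3) {
    tr <- rep(0, 3 * n); tr[seq(a, 3 * n, by = 3)] <- 1
    expect_lt(max(abs(K %*% tr)), 1e-10)
  }
  ## linearized rotations about the centroid
  xyz <- sweep(as.matrix(st$residues[, c("x", "y", "z")]), 2,
               colMeans(as.matrix(st$residues[, c("x", "y", "z")])))
  for (axis in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    rot <- as.vector(t(xyz %*% rbind(c(0, axis[3], -axis[2]),
                                     c(-axis[3], 0, axis[1]),
                                     c(axis[2], -axis[1], 0))))
    rot <- rot / sqrt(sum(rot^2))
    expect_lt(max(abs(K %*% rot)), 1e-8)
  }
})

test_that("an isolated side centroid is reported by residue", {
  coords <- rbind(c(0, 0, 0), c(3, 0, 0), c(50, 50, 50))
  edges <- data.frame(i = 1, j = 2, k = 1)
  net <- suppressWarnings(elastic_network(coords, edges, n_mainchain = 2,
                                          owner = c(1, 2, 2)))
  expect_error(effective_mainchain_matrix(net), "side-chain centroid")
})

test_that("zero-coupling and invalid networks are rejected", {
  expect_error(elastic_network(diag(3), data.frame(i = integer(),
                                                   j = integer(),
                                                   k = numeric())),
               "zero couplings")
  expect_error(elastic_network(diag(3), data.frame(i = 1, j = 2, k = -1)),
               "positive")
})
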