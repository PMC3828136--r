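## a toy bookkeeping structure: 4 proteins of 10 residues each
op_structure <- function() fixture("op_structure", {
  capsid_structure(data.frame(
    chain = rep(c("A", "B", "C", "D"), each = 10),
    protein = rep(c("A", "B", "C", "D"), each = 10),
    resno = rep(1:10, 4), ins = "", resid = "ALA",
    x = seq_len(40), y = rep(1:4, each = 10), z = 0))
})

test_that("integrity is 1 for protein-respecting partitions, 0.5 for half-splits", {
  st <- op_structure()
  grouping <- protein_grouping(st)
  whole <- rep(1:4, each = 10)
  expect_equal(integrity_score(whole, grouping), 1)
  halves <- rep(rep(1:8), each = 5)
  expect_equal(integrity_score(halves, grouping), 0.5)
  expect_error(integrity_score(whole, list(A = integer())), "empty group")
})

test_that("tile types cluster domain sizes by single linkage", {
  ## all equal -> one type
  expect_equal(tile_types(rep(1:4, each = 10))$n_types, 1)
  ## two clear size clusters: 12 domains of 300, 20 of 500
  labels <- rep(seq_len(32), times = c(rep(300, 12), rep(500, 20)))
  tt <- tile_types(labels)
  expect_equal(tt$n_types, 2)
  expect_equal(unname(table(tt$type)), array(c(12L, 20L)))
  ## type count bounded by Q, invariant under uniform size rescaling
  lab2 <- rep(seq_len(32), times = 3 * c(rep(300, 12), rep(500, 20)))
  expect_equal(tile_types(lab2)$n_types, 2)
  expect_lte(tile_types(sample(1:5, 100, replace = TRUE))$n_types, 5)
})

test_that("near-equal sizes within the 3% band share a type", {
  ## sizes 100 and 102: mean 101, band 3.03 -> one type
  expect_equal(tile_types(rep(1:2, times = c(100, 102)))$n_types, 1)
  ## sizes 100 and 110: band 3.15 -> two types
  expect_equal(tile_types(rep(1:2, times = c(100, 110)))$n_types, 2)
})

test_that("interlocking counts terminal residues outside the dominant domain", {
  st <- op_structure()
  whole <- rep(1:4, each = 10)
  expect_equal(suppressMessages(interlocking(whole, st)), 0)
  ## every protein's last 3 residues sit in the next protein's domain
  swapped <- whole
  for (p in 1:4) swapped[(p - 1) * 10 + 8:10] <- (p %% 4) + 1
  expect_equal(suppressMessages(interlocking(swapped, st,
                                             terminal_length = 3)), 3)
  ## asymmetric termini: N-average 1, C-average 3 -> max rule gives 3
  asym <- whole
  for (p in 1:4) {
    asym[(p - 1) * 10 + 1] <- (p %% 4) + 1
    asym[(p - 1) * 10 + 8:10] <- (p %% 4) + 1
  }
  expect_equal(suppressMessages(interlocking(asym, st, terminal_length = 3)), 3)
  ## terminal_length clipping for short proteins is announced
  expect_message(interlocking(whole, st, terminal_length = 20), "clipped")
})

test_that("integrity 1 and interlocking 0 coincide on protein-respecting partitions", {
  st <- op_structure()
  grouping <- protein_grouping(st)
  ## with terminal_length 5 the two termini cover each 10-residue
  ## protein entirely, so the equivalence is exact both ways
  set.seed(8)
  for (rep_i in 1:25) {
    labels <- sample(1:3, 40, replace = TRUE)
    integ <- integrity_score(labels, grouping)
    lock <- suppressMessages(interlocking(labels, st, terminal_length = 5))
    expect_equal(integ == 1, lock == 0)
  }
  ## and the protein-respecting case explicitly
  expect_equal(integrity_score(rep(1:4, each = 10), grouping), 1)
  expect_equal(suppressMessages(interlocking(rep(1:4, each = 10), st,
                                             terminal_length = 5)), 0)
})

test_that("select_optimal ranks integrity peaks with few tile types", {
  rep_df <- function(Q, integrity, types)
    data.frame(Q = Q, integrity = integrity, n_tile_types = types)
  ## unique peak with 2 types ranks first
  r <- rep_df(2:6, c(.6, .7, .9, .7, .6), c(1, 2, 2, 4, 5))
  expect_equal(select_optimal(r)$Q[1], 4)
  ## two equal-integrity peaks -> larger Q first
  r <- rep_df(2:8, c(.5, .9, .5, .5, .9, .5, .4), c(1, 2, 2, 2, 2, 2, 2))
  expect_equal(select_optimal(r)$Q[1:2], c(6, 3))
  ## peaks failing the tile-type filter are dropped
  r <- rep_df(2:6, c(.6, .7, .9, .7, .6), c(1, 2, 9, 4, 5))
  expect_warning(out <- select_optimal(r), "no interior integrity peak")
  expect_equal(nrow(out), 0)
  ## monotone-decreasing profile has no interior peak
  r <- rep_df(2:6, c(.9, .8, .7, .6, .5), rep(1, 5))
  expect_warning(out <- select_optimal(r), "no interior")
  expect_equal(nrow(out), 0)
})
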