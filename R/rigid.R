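## Rigid-motion projection: how much of the capsid motion is captured
## by treating the domains as strictly rigid bodies.

#' Orthonormal basis of per-domain rigid motions
#'
#' For every domain, spans its three translations and three rotations
#' linearized about the (unweighted) domain centroid, embedded in the
#' full 3N space with zeros outside the domain.  A rank-revealing SVD
#' (tolerance 1e-10) drops degenerate directions, so collinear domains
#' yield 5 vectors and singletons 3.
#'
#' @param structure a `capsid_structure` (only the main-chain
#'   coordinates are used)
#' @param partition a `capsid_partition` or bare label vector
#' @return an object of class `rigid_basis`: a list with one element
#'   per domain holding `idx` (residue indices) and `basis`
#'   (3*length(idx) x r orthonormal matrix, r <= 6)
#' @export
build_rigid_basis <- function(structure, partition) {
  labels <- .partition_labels(partition)
  xyz <- .main_coords(structure)
  stopifnot(length(labels) == nrow(xyz))
  doms <- sort(unique(labels))
  basis <- lapply(doms, function(d) {
    ii <- which(labels == d)
    nd <- length(ii)
    ctr <- colMeans(xyz[ii, , drop = FALSE])
    rel <- sweep(xyz[ii, , drop = FALSE], 2, ctr)
    B <- matrix(0, 3 * nd, 6)
    sel <- function(a) seq(a, 3 * nd, by = 3)
    B[sel(1), 1] <- 1; B[sel(2), 2] <- 1; B[sel(3), 3] <- 1
    ## rotations about x, y, z axes: v_i = a x r_i
    B[sel(2), 4] <- -rel[, 3]; B[sel(3), 4] <- rel[, 2]
    B[sel(1), 5] <- rel[, 3];  B[sel(3), 5] <- -rel[, 1]
    B[sel(1), 6] <- -rel[, 2]; B[sel(2), 6] <- rel[, 1]
    sv <- svd(B)
    keep <- sv$d > 1e-10 * sv$d[1]
    list(idx = ii, basis = sv$u[, keep, drop = FALSE])
  })
  structure(list(domains = basis, n = nrow(xyz)), class = "rigid_basis")
}

#' Fraction of capsid motion captured by rigid domain movement
#'
#' Each retained mode splits orthogonally into per-domain rigid
#' translations/rotations plus internal fluctuations.  The captured
#' fraction weights the squared rigid component of each mode by its
#' inverse eigenvalue (the mode's share of the mean-square
#' fluctuation):
#' \deqn{f = \frac{\sum_l \|P v_l\|^2 / \lambda_l}{\sum_l 1/\lambda_l}}
#' where P projects onto the union of the domain rigid subspaces.
#' Bounded in \[0, 1\]; ~0 when the whole capsid is one domain
#' (nonzero modes are orthogonal to global rigid motions) and exactly
#' 1 for all-singleton partitions.
#'
#' @param spectrum a `mode_spectrum`
#' @param basis a [build_rigid_basis()] result over the same residues
#' @return fraction in \[0, 1\]
#' @export
captured_fraction <- function(spectrum, basis) {
  stopifnot(basis$n == spectrum$n_mainchain)
  w <- 1 / spectrum$values
  num <- 0
  for (d in basis$domains) {
    rows <- as.vector(rbind(3 * (d$idx - 1) + 1,
                            3 * (d$idx - 1) + 2,
                            3 * (d$idx - 1) + 3))
    Vd <- spectrum$vectors[rows, , drop = FALSE]
    cf <- crossprod(d$basis, Vd)          # r x M
    num <- num + as.numeric(w %*% colSums(cf^2))
  }
  f <- num / sum(w)
  if (f < -1e-9 || f > 1 + 1e-9)
    stop("captured fraction out of bounds: ", f)
  min(max(f, 0), 1)
}
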