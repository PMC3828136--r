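## Distance-fluctuation strain.
##
## For a residue pair (i, j) the geometric strain accumulates, over
## the M retained modes, the 1/lambda-weighted squared fluctuation of
## the pair distance: the relative mode displacement projected on the
## native separation direction.  Pairs that co-move rigidly in every
## retained mode (including rigid rotations, for which the relative
## displacement is perpendicular to the separation) have zero strain.

#' Geometric strain of one residue pair
#'
#' @param spectrum a `mode_spectrum` over the structure's main-chain
#'   degrees of freedom
#' @param structure the matching `capsid_structure`
#' @param i,j distinct residue indices (1-based)
#' @return nonnegative strain, symmetric in `(i, j)`
#' @export
pair_strain <- function(spectrum, structure, i, j) {
  stopifnot(i != j)
  xyz <- .main_coords(structure)
  d <- xyz[j, ] - xyz[i, ]
  r <- sqrt(sum(d^2))
  if (r == 0) stop("residues ", i, " and ", j, " have coincident positions")
  e <- d / r
  vi <- spectrum$vectors[3 * (i - 1) + 1:3, , drop = FALSE]
  vj <- spectrum$vectors[3 * (j - 1) + 1:3, , drop = FALSE]
  proj <- as.numeric(e %*% (vi - vj))
  sum(proj^2 / spectrum$values)
}

#' Precompute the pairwise strain field
#'
#' Evaluates the pair strain for all residue pairs (dense n x n
#' matrix), the quantity whose intra-domain sum the decomposition
#' minimizes.  For very large assemblies `pair_cutoff` restricts the
#' sum to pairs within a native distance cutoff; the result is then an
#' approximation and is flagged as such in reports.
#'
#' @param spectrum a `mode_spectrum`
#' @param structure the matching `capsid_structure`
#' @param pair_cutoff optional native-distance cutoff (Angstrom) beyond
#'   which pair strains are dropped from the objective
#' @return an object of class `strain_field` wrapping the strain
#'   matrix and the native coordinates
#' @export
strain_field <- function(spectrum, structure, pair_cutoff = NULL) {
  xyz <- .main_coords(structure)
  n <- nrow(xyz)
  if (n != spectrum$n_mainchain)
    stop("spectrum covers ", spectrum$n_mainchain,
         " residues but the structure has ", n)
  dx <- outer(xyz[, 1], xyz[, 1], "-")
  dy <- outer(xyz[, 2], xyz[, 2], "-")
  dz <- outer(xyz[, 3], xyz[, 3], "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(r[upper.tri(r)] == 0))
    stop("coincident native positions between distinct residues")
  diag(r) <- 1
  ex <- dx / r; ey <- dy / r; ez <- dz / r
  S <- matrix(0, n, n)
  ix <- seq(1, 3 * n, by = 3)
  for (l in seq_along(spectrum$values)) {
    v <- spectrum$vectors[, l]
    ux <- v[ix]; uy <- v[ix + 1]; uz <- v[ix + 2]
    p <- ex * outer(ux, ux, "-") + ey * outer(uy, uy, "-") +
      ez * outer(uz, uz, "-")
    S <- S + p * p / spectrum$values[l]
  }
  diag(S) <- 0
  approx <- FALSE
  if (!is.null(pair_cutoff)) {
    S[r > pair_cutoff] <- 0
    approx <- TRUE
  }
  structure(list(S = S, coords = xyz, n = n, M = spectrum$M,
                 pair_cutoff = if (approx) pair_cutoff else NA_real_,
                 approximate = approx),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("Strain field: %d residues, %d modes%s\n", x$n, x$M,
              if (x$approximate)
                sprintf(", pair cutoff %g A (approximate)", x$pair_cutoff)
              else ""))
  invisible(x)
}

#' Total and per-domain strain of a partition
#'
#' The strain of a domain is the sum of pair strains over all its
#' unordered residue pairs (singletons contribute zero); the total is
#' the sum over domains.
#'
#' @param labels integer domain labels (one per residue) or a
#'   `capsid_partition`
#' @param field a `strain_field`
#' @return list with `total` and named vector `per_domain`
#' @export
partition_strain <- function(labels, field) {
  labels <- .partition_labels(labels)
  stopifnot(length(labels) == field$n)
  doms <- sort(unique(labels))
  per <- vapply(doms, function(d) {
    ii <- which(labels == d)
    if (length(ii) < 2) return(0)
    sum(field$S[ii, ii]) / 2
  }, numeric(1))
  names(per) <- doms
  list(total = sum(per), per_domain = per)
}
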