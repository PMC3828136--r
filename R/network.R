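## Elastic network construction.
##
## The free energy is the quadratic form (1/2) dx' K dx around the
## native coordinates.  Centroid pairs (main-main, main-side,
## side-side) closer than the cutoff are joined by Hookean springs
## acting along the native separation, so each pair contributes the
## familiar anisotropic block  -k e e'  to the off-diagonal of K.

#' Construct an elastic network from explicit centroids and springs
#'
#' Low-level constructor, used by [build_beta_gaussian()] and by the
#' synthetic toys (which plant stiff/soft spring patterns directly).
#'
#' @param coords numeric matrix (K x 3) of centroid coordinates, all
#'   main-chain centroids first.
#' @param edges data frame with columns `i`, `j` (1-based centroid
#'   indices) and `k` (spring strength > 0).
#' @param n_mainchain number of main-chain centroids (leading rows of
#'   `coords`); the remaining rows are side-chain centroids.
#' @param owner integer vector mapping each centroid to its residue
#'   index (used in error messages); defaults to `1:K` for main-chain
#'   rows.
#' @param cutoff the interaction cutoff (Angstrom) the network was
#'   built with, for bookkeeping.
#' @return an object of class `elastic_network`
#' @export
elastic_network <- function(coords, edges, n_mainchain = nrow(coords),
                            owner = NULL, cutoff = NA_real_) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)))
  if (!nrow(edges)) stop("elastic network has zero couplings")
  if (any(edges$k <= 0)) stop("spring strengths must be positive")
  if (any(edges$i == edges$j)) stop("self-couplings are not allowed")
  ## store i < j
  swap <- edges$i > edges$j
  tmp <- edges$i[swap]; edges$i[swap] <- edges$j[swap]; edges$j[swap] <- tmp
  edges <- edges[!duplicated(edges[, c("i", "j")]), , drop = FALSE]
  if (is.null(owner)) owner <- seq_len(nrow(coords))
  net <- structure(list(coords = coords, edges = edges,
                        n_mainchain = as.integer(n_mainchain),
                        owner = as.integer(owner), cutoff = cutoff),
                   class = "elastic_network")
  deg <- tabulate(c(edges$i, edges$j), nbins = nrow(coords))
  if (any(deg == 0))
    warning(sum(deg == 0), " centroid(s) participate in no coupling")
  net
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("Elastic network: %d centroids (%d main-chain), %d couplings, cutoff %s A\n",
              nrow(x$coords), x$n_mainchain, nrow(x$edges),
              format(x$cutoff)))
  invisible(x)
}

## all pairs within `cutoff`, by cell-list binning (exact; validated
## against the O(n^2) scan in the tests)
.pairs_within <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n < 2) return(data.frame(i = integer(), j = integer()))
  cell <- floor(sweep(coords, 2, apply(coords, 2, min)) / cutoff)
  dims <- apply(cell, 2, max) + 1L
  id <- cell[, 1] + dims[1] * (cell[, 2] + dims[2] * cell[, 3])
  buckets <- split(seq_len(n), id)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ## half-space of offsets (plus self) to visit each cell pair once
  offs <- offs[offs[, 1] + 3 * offs[, 2] + 9 * offs[, 3] >= 0, , drop = FALSE]
  out_i <- list(); out_j <- list(); nb <- 0L
  key <- function(cx, cy, cz) cx + dims[1] * (cy + dims[2] * cz)
  cell_of <- vapply(buckets, function(ii) id[ii[1]], numeric(1))
  lookup <- new.env(hash = TRUE)
  for (b in seq_along(buckets)) assign(as.character(cell_of[b]), b, envir = lookup)
  for (b in seq_along(buckets)) {
    ii <- buckets[[b]]
    cc <- cell[ii[1], ]
    for (o in seq_len(nrow(offs))) {
      cx <- cc[1] + offs[o, 1]; cy <- cc[2] + offs[o, 2]; cz <- cc[3] + offs[o, 3]
      if (cx < 0 || cy < 0 || cz < 0 ||
          cx >= dims[1] || cy >= dims[2] || cz >= dims[3]) next
      b2 <- mget(as.character(key(cx, cy, cz)), envir = lookup,
                 ifnotfound = list(NULL))[[1]]
      if (is.null(b2)) next
      jj <- buckets[[b2]]
      if (b2 == b) {
        if (length(ii) < 2) next
        pr <- which(upper.tri(matrix(0, length(ii), length(ii))), arr.ind = TRUE)
        pi <- ii[pr[, 1]]; pj <- ii[pr[, 2]]
      } else if (identical(offs[o, ], c(dx = 0, dy = 0, dz = 0))) {
        next
      } else {
        pr <- expand.grid(a = seq_along(ii), b = seq_along(jj))
        pi <- ii[pr$a]; pj <- jj[pr$b]
      }
      d2 <- rowSums((coords[pi, , drop = FALSE] - coords[pj, , drop = FALSE])^2)
      keep <- d2 <= cutoff^2 & d2 > 0
      if (any(keep)) {
        nb <- nb + 1L
        out_i[[nb]] <- pi[keep]; out_j[[nb]] <- pj[keep]
      }
    }
  }
  data.frame(i = unlist(out_i), j = unlist(out_j))
}

#' Build the two-centroid (beta-Gaussian) elastic network
#'
#' Places one interaction centre on each residue's main chain (CA) and
#' one on its side-chain centroid (omitted for glycine and residues
#' without side-chain heavy atoms), and joins every centroid pair
#' within `cutoff` by a spring of uniform strength.  Consecutive
#' main-chain centroids of the same chain are always coupled,
#' with strength multiplied by `backbone_bonus`.
#'
#' On a decimated structure (no side-chain centroids) this reduces to
#' the single-centroid anisotropic network backend.
#'
#' @param structure a `capsid_structure`
#' @param cutoff interaction range in Angstrom (default 7.5; use 15
#'   with [decimate_structure()] factor 2)
#' @param backbone_bonus strength multiplier for consecutive main-chain
#'   pairs (default 1, i.e. no special treatment)
#' @param spring uniform spring strength (arbitrary energy/A^2 units;
#'   all downstream decision quantities are scale-free)
#' @return an `elastic_network`
#' @export
build_beta_gaussian <- function(structure, cutoff = 7.5, backbone_bonus = 1,
                                spring = 1) {
  stopifnot(cutoff > 0, backbone_bonus > 0, spring > 0)
  n <- n_residues(structure)
  if (n < 2) stop("need at least 2 residues")
  res <- structure$residues
  has_side <- is.finite(res$sx)
  coords <- rbind(.main_coords(structure),
                  as.matrix(res[has_side, c("sx", "sy", "sz")]))
  owner <- c(seq_len(n), which(has_side))
  pairs <- .pairs_within(coords, cutoff)
  k <- rep(spring, nrow(pairs))

  ## chain-connectivity springs (always present)
  same_chain <- res$chain[-n] == res$chain[-1] &
    res$protein[-n] == res$protein[-1]
  bi <- which(same_chain); bj <- bi + 1L
  if (length(bi)) {
    key <- paste(pmin(pairs$i, pairs$j), pmax(pairs$i, pairs$j))
    bkey <- paste(bi, bj)
    hit <- key %in% bkey
    k[hit] <- spring * backbone_bonus
    add <- !(bkey %in% key)
    pairs <- rbind(pairs, data.frame(i = bi[add], j = bj[add]))
    k <- c(k, rep(spring * backbone_bonus, sum(add)))
  }
  if (!nrow(pairs))
    stop("zero couplings: cutoff ", cutoff, " A leaves the network empty")
  net <- elastic_network(coords, data.frame(i = pairs$i, j = pairs$j, k = k),
                         n_mainchain = n, owner = owner, cutoff = cutoff)
  .check_connected(net)
  net
}

.check_connected <- function(net) {
  g <- igraph::graph_from_edgelist(cbind(net$edges$i, net$edges$j),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(net$coords) - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no > 1)
    warning("elastic network is disconnected: ", comp$no,
            " components with sizes ",
            paste(sort(comp$csize, decreasing = TRUE), collapse = ", "))
  invisible(comp$no)
}

## sparse Hessian (3K x 3K) of the full quadratic form
.network_hessian <- function(net) {
  e <- net$edges
  d <- net$coords[e$j, , drop = FALSE] - net$coords[e$i, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  if (any(r == 0)) stop("coincident centroids in a coupling")
  u <- d / r
  ne <- nrow(e)
  ## 3x3 block for each edge: B = k * u u'
  bl <- array(0, c(ne, 3, 3))
  for (a in 1:3) for (b in 1:3) bl[, a, b] <- e$k * u[, a] * u[, b]
  ia <- rep((e$i - 1L) * 3L, each = 9L) + rep(rep(1:3, 3), ne)
  ja <- rep((e$i - 1L) * 3L, each = 9L) + rep(rep(1:3, each = 3), ne)
  ib <- rep((e$j - 1L) * 3L, each = 9L) + rep(rep(1:3, 3), ne)
  jb <- rep((e$j - 1L) * 3L, each = 9L) + rep(rep(1:3, each = 3), ne)
  v <- as.numeric(aperm(bl, c(2, 3, 1)))   # 9 values per edge, row-fastest
  K <- Matrix::sparseMatrix(
    i = c(ia, ib, ia, ib),
    j = c(ja, jb, jb, ja),
    x = c(v, v, -v, -v),
    dims = c(3 * nrow(net$coords), 3 * nrow(net$coords)))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Effective main-chain interaction matrix
#'
#' Forms the full two-centroid Hessian and eliminates the side-chain
#' coordinates analytically (Schur complement), returning the
#' symmetric positive semi-definite operator over the 3N main-chain
#' degrees of freedom.  Its null space contains the six global rigid
#' motions.  With no side-chain centroids the main-chain Hessian is
#' returned unchanged.
#'
#' @param network an `elastic_network`
#' @return a sparse symmetric matrix (class `dsCMatrix`), 3N x 3N
#' @export
effective_mainchain_matrix <- function(network) {
  K <- .network_hessian(network)
  nm <- network$n_mainchain
  ntot <- nrow(network$coords)
  if (ntot == nm) return(K)
  mi <- seq_len(3L * nm)
  si <- (3L * nm + 1L):(3L * ntot)
  Kss <- K[si, si, drop = FALSE]
  ## a side centroid with too few independent couplings makes the
  ## side-chain block singular
  deg <- tabulate(c(network$edges$i, network$edges$j), nbins = ntot)
  lone <- which(deg[(nm + 1L):ntot] == 0)
  if (length(lone))
    stop("isolated side-chain centroid for residue(s) ",
         paste(network$owner[nm + lone], collapse = ", "))
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kss), perm = TRUE),
                 error = function(e)
                   stop("singular side-chain block (under-coupled side ",
                        "centroid); residues with fewest couplings: ",
                        paste(network$owner[nm + order(deg[(nm + 1L):ntot])[1:3]],
                              collapse = ", ")))
  Ksm <- K[si, mi, drop = FALSE]
  X <- Matrix::solve(ch, Ksm)
  Keff <- K[mi, mi, drop = FALSE] - Matrix::t(Ksm) %*% X
  Matrix::forceSymmetric((Keff + Matrix::t(Keff)) / 2)
}
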