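## Normal modes of the effective main-chain matrix.
##
## The low-energy spectrum is obtained either by dense symmetric
## diagonalization (small systems) or by the shift-invert Arnoldi
## method: ARPACK is run on (K + sigma I)^{-1} through a sparse
## Cholesky factorization, so its largest-magnitude Ritz values map to
## the smallest eigenvalues of K.  The six global rigid motions come
## out as numerically null modes and are discarded by a relative
## tolerance.

#' Compute the lowest nonzero normal modes of an elastic network
#'
#' @param network an `elastic_network`, or a precomputed effective
#'   matrix from [effective_mainchain_matrix()] (then `n_mainchain`
#'   must be inferable from its size).
#' @param n_modes number of nonzero modes to return (1 <= n_modes <
#'   3N - 6).
#' @param method `"auto"` (dense up to 1000 degrees of freedom, else
#'   Arnoldi), `"dense"`, or `"arpack"`.
#' @param null_tol relative tolerance below which an eigenvalue is a
#'   discarded rigid-motion (null) mode: eigenvalue < `null_tol` x
#'   largest computed eigenvalue.
#' @return an object of class `mode_spectrum` with fields `values`
#'   (ascending positive eigenvalues), `vectors` (3N x M orthonormal
#'   columns, sign-fixed so the largest-magnitude entry is positive),
#'   `n_null` (discarded near-zero modes; 6 for a connected assembly)
#'   and `n_mainchain`.
#' @export
compute_modes <- function(network, n_modes,
                          method = c("auto", "dense", "arpack"),
                          null_tol = 1e-8) {
  method <- match.arg(method)
  if (inherits(network, "elastic_network")) {
    K <- effective_mainchain_matrix(network)
    nm <- network$n_mainchain
  } else {
    K <- network
    nm <- nrow(K) / 3L
  }
  dim3 <- 3L * nm
  stopifnot(n_modes >= 1)
  if (n_modes > dim3 - 1)
    stop("n_modes must be below 3N = ", dim3)
  if (method == "auto") method <- if (dim3 <= 1000) "dense" else "arpack"

  if (method == "dense") {
    e <- eigen(as.matrix(K), symmetric = TRUE)
    values <- rev(e$values)
    vectors <- e$vectors[, rev(seq_len(dim3)), drop = FALSE]
  } else {
    got <- .arpack_smallest(K, nev = min(dim3 - 2L, n_modes + 12L))
    if (sum(got$values >= null_tol * max(got$values)) < n_modes) {
      nev2 <- min(dim3 - 2L, 2L * (n_modes + 12L))
      if (nev2 > length(got$values)) got <- .arpack_smallest(K, nev = nev2)
    }
    values <- got$values
    vectors <- got$vectors
  }
  tol <- null_tol * max(values)
  null <- values < tol
  n_null <- sum(null)
  values <- values[!null]
  vectors <- vectors[, !null, drop = FALSE]
  if (length(values) < n_modes) {
    warning("only ", length(values), " nonzero modes available (",
            n_modes, " requested)")
    n_modes <- length(values)
  }
  values <- values[seq_len(n_modes)]
  vectors <- vectors[, seq_len(n_modes), drop = FALSE]
  ## fix sign: largest-magnitude component positive
  for (l in seq_len(ncol(vectors))) {
    s <- vectors[which.max(abs(vectors[, l])), l]
    if (s < 0) vectors[, l] <- -vectors[, l]
  }
  structure(list(values = values, vectors = vectors, n_null = n_null,
                 n_mainchain = nm, M = n_modes),
            class = "mode_spectrum")
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat(sprintf("Mode spectrum: %d modes over %d residues (%d null discarded)\n",
              x$M, x$n_mainchain, x$n_null))
  cat("  eigenvalues: ", paste(format(head(x$values, 5), digits = 4),
                               collapse = ", "),
      if (x$M > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

## shift-invert Arnoldi: largest eigenpairs of (K + sigma I)^{-1}
.arpack_smallest <- function(K, nev) {
  dim3 <- nrow(K)
  sigma <- 1e-4 * mean(Matrix::diag(K))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(K) +
                           sigma * Matrix::Diagonal(dim3), perm = TRUE)
  fn <- function(x, extra) as.numeric(Matrix::solve(ch, x))
  res <- igraph::arpack(fn, sym = TRUE,
                        options = list(n = dim3, nev = nev,
                                       ncv = min(dim3, max(2L * nev + 2L, 40L)),
                                       which = "LM", maxiter = 3000))
  mu <- res$values
  lambda <- 1 / mu - sigma
  ord <- order(lambda)
  vec <- res$vectors[, ord, drop = FALSE]
  ## Ritz vectors of the shifted inverse are eigenvectors of K itself;
  ## re-orthonormalize to tighten degenerate clusters
  qr_ <- qr(vec)
  list(values = lambda[ord], vectors = qr.Q(qr_))
}

#' Number of modes to retain, from a single-protein reference spectrum
#'
#' Retains every capsid mode with energy strictly below the fifth
#' nonzero eigenvalue of a single coat protein modelled with the same
#' network settings, with a configurable lower floor.
#'
#' @param capsid_spectrum `mode_spectrum` of the full assembly
#' @param protein_spectrum `mode_spectrum` of one coat protein (needs
#'   at least 5 nonzero eigenvalues)
#' @param floor minimum retained count (default 10)
#' @return integer M
#' @export
select_mode_count <- function(capsid_spectrum, protein_spectrum, floor = 10) {
  if (length(protein_spectrum$values) < 5)
    stop("protein spectrum has fewer than 5 nonzero eigenvalues")
  thr <- protein_spectrum$values[5]
  M <- sum(capsid_spectrum$values < thr)
  if (M < floor) {
    M <- min(floor, length(capsid_spectrum$values))
    warning("fewer modes below the protein threshold than the floor; ",
            "retaining ", M)
  }
  as.integer(M)
}

#' Truncate a mode spectrum to its first M modes
#' @param spectrum a `mode_spectrum`
#' @param M retained mode count (<= number of computed modes)
#' @return a `mode_spectrum`
#' @export
truncate_spectrum <- function(spectrum, M) {
  stopifnot(M >= 1, M <= length(spectrum$values))
  spectrum$values <- spectrum$values[seq_len(M)]
  spectrum$vectors <- spectrum$vectors[, seq_len(M), drop = FALSE]
  spectrum$M <- as.integer(M)
  spectrum
}
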