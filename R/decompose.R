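## Strain minimization over partitions at fixed Q, and the sweep over Q.

.new_partition <- function(labels, field, seed = NA_integer_,
                           restarts = 1L, trace = NULL) {
  ps <- partition_strain(labels, field)
  structure(list(labels = as.integer(labels), Q = length(unique(labels)),
                 per_domain_strain = ps$per_domain, total_strain = ps$total,
                 seed = seed, restarts = restarts, trace = trace),
            class = "capsid_partition")
}

#' @export
print.capsid_partition <- function(x, ...) {
  cat(sprintf("Partition: Q = %d, total strain = %.6g (seed %s, %d restart(s))\n",
              x$Q, x$total_strain, format(x$seed), x$restarts))
  invisible(x)
}

## random labelling with every domain nonempty
.random_labels <- function(n, Q) {
  stopifnot(Q <= n)
  sample(c(seq_len(Q), sample.int(Q, n - Q, replace = TRUE)))
}

#' Greedy strain minimization at fixed Q
#'
#' Starting from a uniform-random labelling into Q nonempty domains
#' (or from `init`), repeatedly proposes moving a random residue to a
#' random other domain and accepts only strict strain decreases that
#' do not empty a domain.  The chain stops when consecutive rejections
#' reach the residue count, after which deterministic best-move sweeps
#' bring the labelling to one-move local optimality.  Fully
#' reproducible from `seed`.
#'
#' @param field a [strain_field()]
#' @param Q number of domains (2 <= Q <= residues)
#' @param seed integer RNG seed (optional; current RNG state used if
#'   missing)
#' @param init optional integer initial labelling (values 1..Q, all
#'   domains nonempty)
#' @param stall consecutive-rejection count that ends the stochastic
#'   phase; default = number of residues
#' @param polish run the deterministic local-optimality sweeps?
#' @return a `capsid_partition` with labels, per-domain and total
#'   strain, and the accepted-move strain trace in `$trace`
#' @export
greedy_minimize <- function(field, Q, seed = NULL, init = NULL,
                            stall = NULL, polish = TRUE) {
  n <- field$n
  if (Q < 2 || Q > n) stop("Q must be between 2 and ", n)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- .random_labels(n, Q)
  stopifnot(length(init) == n, all(init %in% seq_len(Q)),
            length(unique(init)) == Q)
  if (is.null(stall)) stall <- n
  res <- .greedy_cpp(field$S, as.integer(init) - 1L, as.integer(Q),
                     as.integer(stall), polish, TRUE)
  .new_partition(res$labels + 1L, field,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 trace = res$trace)
}

#' Split/join refinement of a partition
#'
#' Counters asymmetric local minima: while some domain's strain
#' exceeds the mean by more than `outlier_k` standard deviations, the
#' two lowest-strain domains are merged, the highest-strain domain is
#' split in two by the plane through its centroid normal to its
#' principal spatial axis, and the greedy pass is rerun from that
#' labelling.  Q is preserved at every step; iteration stops at
#' homogeneity, non-improvement, or `max_iter`.
#'
#' @param partition a `capsid_partition` (typically from
#'   [greedy_minimize()])
#' @param field the `strain_field` it was optimized on
#' @param outlier_k heterogeneity threshold in standard deviations
#'   (default 2)
#' @param max_iter maximum refinement rounds (default 10)
#' @return a `capsid_partition` with strain <= the input strain
#' @export
refine_split_join <- function(partition, field, outlier_k = 2, max_iter = 10) {
  best <- partition
  for (iter in seq_len(max_iter)) {
    s <- best$per_domain_strain
    if (length(s) < 3) break
    if (max(s) <= mean(s) + outlier_k * sd(s)) break
    doms <- as.integer(names(s))
    lows <- doms[order(s)[1:2]]
    high <- doms[which.max(s)]
    labels <- best$labels
    ## join the two lowest-strain domains ...
    labels[labels == lows[2]] <- lows[1]
    ## ... and split the highest-strain one by spatial bisection
    ii <- which(labels == high)
    ctr <- colMeans(field$coords[ii, , drop = FALSE])
    pc <- prcomp(field$coords[ii, , drop = FALSE], center = TRUE)
    proj <- as.numeric(sweep(field$coords[ii, , drop = FALSE], 2, ctr) %*%
                         pc$rotation[, 1])
    side <- proj > 0
    if (all(side) || !any(side)) side <- proj > stats::median(proj)
    if (all(side) || !any(side)) side <- seq_along(ii) <= length(ii) / 2
    labels[ii[side]] <- lows[2]
    cand <- greedy_minimize(field, Q = best$Q, init = .relabel(labels),
                            polish = TRUE)
    if (cand$total_strain < best$total_strain) {
      cand$seed <- best$seed
      best <- cand
    } else break
  }
  best$restarts <- partition$restarts
  best
}

## compress arbitrary labels to 1..Q preserving first appearance
.relabel <- function(labels) match(labels, unique(labels))

#' Sweep the decomposition over a range of Q
#'
#' For each Q, runs `restarts` independent greedy + split/join chains
#' with seeds derived from the master seed and keeps the
#' minimum-strain partition.
#'
#' @param field a [strain_field()]
#' @param q_values integer vector of Q values to explore (e.g.
#'   `2:180`); may be any grid
#' @param restarts independent chains per Q (default 5)
#' @param seed master RNG seed (mandatory, recorded in the result)
#' @param outlier_k,max_iter passed to [refine_split_join()]
#' @return an object of class `strain_profile`: a list with `table`
#'   (data frame of Q and minimized strain) and `partitions` (best
#'   `capsid_partition` per Q, named by Q)
#' @export
sweep_partitions <- function(field, q_values, restarts = 5, seed,
                             outlier_k = 2, max_iter = 10) {
  q_values <- sort(unique(as.integer(q_values)))
  stopifnot(all(q_values >= 2), all(q_values <= field$n), restarts >= 1)
  set.seed(seed)
  chain_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   length(q_values) * restarts),
                        nrow = length(q_values))
  parts <- vector("list", length(q_values))
  for (qi in seq_along(q_values)) {
    best <- NULL
    for (r in seq_len(restarts)) {
      p <- greedy_minimize(field, q_values[qi], seed = chain_seeds[qi, r])
      p <- refine_split_join(p, field, outlier_k = outlier_k,
                             max_iter = max_iter)
      if (is.null(best) || p$total_strain < best$total_strain) best <- p
    }
    best$restarts <- restarts
    parts[[qi]] <- best
  }
  names(parts) <- q_values
  structure(list(table = data.frame(Q = q_values,
                                    strain = vapply(parts, function(p)
                                      p$total_strain, numeric(1))),
                 partitions = parts, seed = seed, restarts = restarts),
            class = "strain_profile")
}

#' @export
print.strain_profile <- function(x, ...) {
  cat(sprintf("Strain profile over Q = %d..%d (%d values, %d restarts, seed %d)\n",
              min(x$table$Q), max(x$table$Q), nrow(x$table), x$restarts,
              x$seed))
  invisible(x)
}

#' Locate the kink of a minimized-strain profile
#'
#' The minimized strain decreases with Q; at the innate number of
#' quasi-rigid units the slope changes and the profile shows a kink.
#' This helper returns the interior Q maximizing the discrete
#' curvature (second difference) of the strain profile.
#'
#' @param profile a `strain_profile` (or its `table` data frame)
#' @return the Q at the kink
#' @export
strain_kink <- function(profile) {
  tab <- if (inherits(profile, "strain_profile")) profile$table else profile
  stopifnot(nrow(tab) >= 3)
  s <- tab$strain
  curv <- s[-c(1, length(s))] * NA
  for (k in 2:(length(s) - 1))
    curv[k - 1] <- (s[k - 1] - s[k]) / max(tab$Q[k] - tab$Q[k - 1], 1) -
      (s[k] - s[k + 1]) / max(tab$Q[k + 1] - tab$Q[k], 1)
  tab$Q[which.max(curv) + 1]
}
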