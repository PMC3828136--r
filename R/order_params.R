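## Order parameters used to select the optimal subdivision: protein
## (or subdomain) integrity, tile types by size, and terminal
## interlocking.

#' Protein (or subdomain) integrity of a partition
#'
#' For each group (protein, or structural subdomain) the integrity is
#' the largest fraction of its residues assigned to a single domain;
#' the capsid score is the unweighted mean over groups.  1.0 means
#' every group sits wholly inside one quasi-rigid domain.
#'
#' @param partition a `capsid_partition` or bare label vector
#' @param grouping named list of residue index vectors, e.g.
#'   [protein_grouping()] or a structure's `subdomains`; groups may
#'   cover a subset of residues (uncovered residues are simply not
#'   scored)
#' @return score in \[0, 1\]
#' @export
integrity_score <- function(partition, grouping) {
  labels <- .partition_labels(partition)
  if (!length(grouping)) stop("empty grouping")
  per <- vapply(grouping, function(ii) {
    if (!length(ii)) stop("empty group in grouping")
    max(tabulate(factor(labels[ii]))) / length(ii)
  }, numeric(1))
  mean(per)
}

#' Tile types: domain equivalence classes by size
#'
#' Domain size is its residue count.  Two domains share a type when
#' they are connected by a chain of domains whose consecutive size
#' differences are each at most `tolerance` times the mean domain size
#' (single-linkage clustering on sizes).
#'
#' @param partition a `capsid_partition` or bare label vector
#' @param tolerance relative size tolerance (default 0.03, i.e. ~3%
#'   of the average size)
#' @return list with `n_types` and `type` (named integer vector,
#'   domain id -> type, types numbered by increasing size)
#' @export
tile_types <- function(partition, tolerance = 0.03) {
  labels <- .partition_labels(partition)
  sizes <- table(labels)
  if (length(sizes) == 1)
    return(list(n_types = 1L,
                type = setNames(1L, names(sizes))))
  band <- tolerance * mean(sizes)
  ord <- order(sizes)
  sorted <- as.numeric(sizes)[ord]
  ## single linkage on the sorted sizes: new type at each gap > band
  type_sorted <- cumsum(c(1, diff(sorted) > band))
  type <- integer(length(sizes))
  type[ord] <- type_sorted
  list(n_types = max(type_sorted),
       type = setNames(as.integer(type), names(sizes)))
}

#' Terminal interlocking of a partition
#'
#' For each protein, the dominant domain is the one holding most of
#' its residues; the parameter counts how many of the first
#' (N-terminal) and last (C-terminal) `terminal_length` residues are
#' assigned elsewhere.  The two termini are averaged separately over
#' proteins and the larger average is returned: an interlocking of 10
#' means that on average a protein has 10 terminal residues assigned
#' to a different domain than its core.
#'
#' @param partition a `capsid_partition` or bare label vector
#' @param structure the matching `capsid_structure`
#' @param terminal_length residues per terminus (default 20); clipped
#'   to half the protein length for short proteins, with a message.
#' @return nonnegative average interlocked-residue count
#' @export
interlocking <- function(partition, structure, terminal_length = 20) {
  labels <- .partition_labels(partition)
  grouping <- protein_grouping(structure)
  clipped <- FALSE
  per_term <- vapply(grouping, function(ii) {
    L <- terminal_length
    if (2 * L > length(ii)) {
      L <- length(ii) %/% 2
      clipped <<- TRUE
    }
    lab <- labels[ii]
    dominant <- as.integer(names(which.max(table(lab))))
    c(nterm = sum(lab[seq_len(L)] != dominant),
      cterm = sum(lab[seq.int(length(ii) - L + 1L, length.out = L)] != dominant))
  }, numeric(2))
  if (clipped)
    message("terminal_length clipped to half the protein length for short proteins")
  max(rowMeans(per_term))
}

#' Rank candidate optimal subdivisions
#'
#' Candidates are the interior local maxima of the integrity profile
#' whose tile-type count does not exceed `max_types`; they are ranked
#' by integrity and, at equal integrity, by larger Q (the smallest
#' basic units).  The ranking is advisory: the full report is kept so
#' the profiles can be inspected.
#'
#' @param report a `decomposition_report` data frame (from
#'   [assess_partitions()]) with columns `Q`, `integrity`,
#'   `n_tile_types`
#' @param max_types maximum tile-type count for a viable subdivision
#'   (default 3)
#' @return data frame of ranked candidates (possibly empty, with a
#'   warning)
#' @export
select_optimal <- function(report, max_types = 3) {
  stopifnot(nrow(report) >= 3)
  report <- report[order(report$Q), , drop = FALSE]
  g <- report$integrity
  n <- length(g)
  is_peak <- logical(n)
  for (k in 2:(n - 1))
    is_peak[k] <- g[k] >= g[k - 1] && g[k] >= g[k + 1] &&
      (g[k] > g[k - 1] || g[k] > g[k + 1])
  cand <- report[is_peak & report$n_tile_types <= max_types, , drop = FALSE]
  if (!nrow(cand)) {
    warning("no interior integrity peak with at most ", max_types,
            " tile types; inspect the profiles")
    return(cand)
  }
  cand[order(-cand$integrity, -cand$Q), , drop = FALSE]
}
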