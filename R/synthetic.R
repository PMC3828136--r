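## Synthetic assemblies with planted quasi-rigid structure.
##
## Toys carry main-chain-only pseudo-residues and an explicit spring
## network: all pairs inside a planted block are stiff, couplings
## between blocks are soft, so the low-energy modes are (nearly) rigid
## relative motions of the blocks and the planted partition is the
## strain optimum.  Block membership doubles as the "protein"
## bookkeeping, so integrity and interlocking are testable without
## sequence data.

.toy_assembly <- function(kind, coords, block, edges, contrast,
                          block_prefix = "B") {
  ord <- order(block)
  coords <- coords[ord, , drop = FALSE]
  block <- block[ord]
  pos <- match(seq_along(block), ord)
  edges$i <- pos[edges$i]; edges$j <- pos[edges$j]
  ## single-character chain ids so toys survive a PDB round trip
  stopifnot(max(block) <= 62)
  chains <- c(LETTERS, letters, as.character(0:9))[block]
  labels <- sprintf("%s%02d", block_prefix, block)
  res <- data.frame(chain = chains, protein = labels,
                    resno = stats::ave(block, block, FUN = seq_along),
                    ins = "", resid = "ALA",
                    x = coords[, 1], y = coords[, 2], z = coords[, 3])
  st <- capsid_structure(res)
  net <- elastic_network(coords, edges, n_mainchain = nrow(coords))
  structure(list(structure = st, network = net, planted = block,
                 stiffness_contrast = contrast, kind = kind),
            class = "toy_assembly")
}

#' @export
print.toy_assembly <- function(x, ...) {
  cat(sprintf("Toy assembly '%s': %d points, %d planted blocks, contrast %g\n",
              x$kind, length(x$planted), length(unique(x$planted)),
              x$stiffness_contrast))
  invisible(x)
}

## uniform points in a ball
.ball <- function(n, r) {
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  u * r * runif(n)^(1 / 3)
}

.all_pairs <- function(idx) {
  pr <- which(upper.tri(diag(length(idx))), arr.ind = TRUE)
  data.frame(i = idx[pr[, 1]], j = idx[pr[, 2]])
}

.cross_pairs <- function(ii, jj) expand.grid(i = ii, j = jj)

#' Two rigid triangles joined by a soft hinge
#'
#' Six points: two stiff triangles whose nine cross pairs are coupled
#' by soft springs, so the lowest nonzero modes are relative rigid
#' motions of the triangles.  Intra-triangle distances barely
#' fluctuate while cross-hinge distances do, making the two triangles
#' the planted 2-domain partition.  Deterministic (no RNG).
#'
#' @param contrast stiff/soft spring strength ratio (default 100)
#' @return a `toy_assembly` with planted Q = 2
#' @export
make_hinge_toy <- function(contrast = 100) {
  stopifnot(contrast > 1)
  coords <- rbind(c(0, 0, 0), c(0, 0, 2), c(-1.8, 0.3, 1),
                  c(0.8, 0, 0), c(0.8, 0, 2), c(2.6, -0.4, 1.2))
  block <- rep(1:2, each = 3)
  edges <- rbind(cbind(.all_pairs(1:3), k = contrast),
                 cbind(.all_pairs(4:6), k = contrast),
                 cbind(.cross_pairs(1:3, 4:6), k = 1))
  .toy_assembly("hinge", coords, block, edges, contrast)
}

#' Ring of K planted rigid blocks
#'
#' K jittered point clusters on a circle; all pairs inside a cluster
#' are stiff, all pairs between ring-adjacent clusters are soft.
#'
#' @param K number of blocks (>= 2)
#' @param n points per block (>= 3)
#' @param contrast stiff/soft ratio (default 100)
#' @param seed RNG seed (toys are reproducible bit-exactly from it)
#' @param cluster_radius radius of each point cluster
#' @return a `toy_assembly` with planted Q = K
#' @export
make_ring_assembly <- function(K, n, contrast = 100, seed = 1,
                               cluster_radius = 1) {
  stopifnot(K >= 2, n >= 3, contrast > 1)
  set.seed(seed)
  R <- max(2.5, 3 * K / (2 * pi))
  ang <- 2 * pi * (seq_len(K) - 1) / K
  centers <- cbind(R * cos(ang), R * sin(ang), 0)
  coords <- do.call(rbind, lapply(seq_len(K), function(k)
    sweep(.ball(n, cluster_radius), 2, centers[k, ], "+")))
  block <- rep(seq_len(K), each = n)
  idx <- split(seq_len(K * n), block)
  intra <- do.call(rbind, lapply(idx, .all_pairs))
  inter <- do.call(rbind, lapply(seq_len(K), function(k) {
    k2 <- if (k == K) 1L else k + 1L
    if (K == 2 && k == 2) return(NULL)
    .cross_pairs(idx[[k]], idx[[k2]])
  }))
  edges <- rbind(cbind(intra, k = contrast), cbind(inter, k = 1))
  .toy_assembly("ring", coords, block, edges, contrast)
}

## --- icosahedral rotation group -------------------------------------

## Rodrigues rotation about unit axis u by angle theta
.rotation_about <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  Kx <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * Kx + (1 - cos(theta)) * Kx %*% Kx
}

## the 60 rotations of the icosahedral group, by closure of a 5-fold
## and a 3-fold generator; element 2 is the 3-fold rotation about the
## reference face axis (used for trimer cosets)
.icosahedral_group <- function() {
  phi <- (1 + sqrt(5)) / 2
  v1 <- c(0, 1, phi)
  face <- (c(0, 1, phi) + c(0, -1, phi) + c(phi, 0, 1)) / 3
  r5 <- .rotation_about(v1, 2 * pi / 5)
  r3 <- .rotation_about(face, 2 * pi / 3)
  key <- function(m) paste(round(m, 8), collapse = ",")
  els <- list(diag(3), r3)
  seen <- c(key(els[[1]]), key(els[[2]]))
  gens <- list(r5, r3)
  repeat {
    added <- FALSE
    for (g in seq_along(els)) {
      for (h in gens) {
        m <- els[[g]] %*% h
        k <- key(m)
        if (!(k %in% seen)) {
          els[[length(els) + 1L]] <- m
          seen <- c(seen, k)
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  stopifnot(length(els) == 60)
  attr(els, "face_axis") <- face
  attr(els, "vertex") <- v1
  els
}

#' Icosahedral toy capsid of 60 identical units
#'
#' One random asymmetric point cluster is replicated by the 60
#' rotations of the icosahedral group on a sphere.  All pairs within a
#' unit are stiff; point pairs between neighbouring units (unit
#' centroids closer than 1.1x the connectivity threshold of the
#' unit-adjacency graph) are soft.  With `fuse = "trimer"` the
#' inter-unit couplings inside each triple of units around a 3-fold
#' axis are made stiff as well, so the planted blocks (and the toy's
#' "proteins") become the 20 trimers.
#'
#' @param points_per_unit points in the asymmetric unit (>= 3)
#' @param contrast stiff/soft ratio (default 100)
#' @param seed RNG seed
#' @param fuse `"none"` (60 planted units) or `"trimer"` (20 planted
#'   trimers)
#' @param radius capsid radius (default 10)
#' @param unit_radius radius of the unit point cluster (default 1.2)
#' @return a `toy_assembly` with planted Q = 60 (or 20)
#' @export
make_icosahedral_toy <- function(points_per_unit = 4, contrast = 100,
                                 seed = 1, fuse = c("none", "trimer"),
                                 radius = 10, unit_radius = 1.2) {
  fuse <- match.arg(fuse)
  stopifnot(points_per_unit >= 3, contrast > 1)
  set.seed(seed)
  G <- .icosahedral_group()
  face <- attr(G, "face_axis"); vert <- attr(G, "vertex")
  anchor_dir <- 0.8 * face / sqrt(sum(face^2)) + 0.2 * vert / sqrt(sum(vert^2))
  anchor <- radius * anchor_dir / sqrt(sum(anchor_dir^2))
  cloud <- sweep(.ball(points_per_unit, unit_radius), 2, anchor, "+")
  coords <- do.call(rbind, lapply(G, function(g) cloud %*% t(g)))
  n <- points_per_unit
  unit <- rep(seq_len(60), each = n)

  ## trimer cosets of the 3-fold subgroup generated by element 2
  key <- function(m) paste(round(m, 8), collapse = ",")
  keys <- vapply(G, key, character(1))
  r3 <- G[[2]]
  mate1 <- match(vapply(G, function(g) key(g %*% r3), character(1)), keys)
  mate2 <- match(vapply(G, function(g) key(g %*% r3 %*% r3), character(1)), keys)
  trimer <- integer(60); tid <- 0L
  for (g in seq_len(60)) if (!trimer[g]) {
    tid <- tid + 1L
    trimer[c(g, mate1[g], mate2[g])] <- tid
  }

  ## unit adjacency from centroids: neighbours within 1.1x the
  ## threshold that first makes the adjacency graph connected
  cent <- t(vapply(seq_len(60), function(u)
    colMeans(coords[unit == u, , drop = FALSE]), numeric(3)))
  D <- as.matrix(dist(cent))
  g_full <- igraph::graph_from_adjacency_matrix(D < Inf, mode = "undirected",
                                                diag = FALSE)
  igraph::E(g_full)$weight <- D[igraph::as_edgelist(g_full)]
  tstar <- max(igraph::E(igraph::mst(g_full))$weight)
  adj <- which(D <= 1.1 * tstar & upper.tri(D), arr.ind = TRUE)

  idx <- split(seq_len(60 * n), unit)
  intra <- cbind(do.call(rbind, lapply(idx, .all_pairs)), k = contrast)
  inter <- do.call(rbind, lapply(seq_len(nrow(adj)), function(e) {
    u <- adj[e, 1]; v <- adj[e, 2]
    stiff <- fuse == "trimer" && trimer[u] == trimer[v]
    cbind(.cross_pairs(idx[[u]], idx[[v]]), k = if (stiff) contrast else 1)
  }))
  edges <- rbind(intra, inter)
  block <- if (fuse == "trimer") trimer[unit] else unit
  .toy_assembly(if (fuse == "trimer") "icosahedral-trimer" else "icosahedral",
                coords, block, edges, contrast,
                block_prefix = if (fuse == "trimer") "T" else "U")
}

#' Agreement between a partition and planted labels
#'
#' Maximum fraction of residues whose labels agree under an injective
#' mapping between the two label sets: solved exactly by assignment
#' when the smaller label set has at most 12 labels, greedily above.
#'
#' @param partition a `capsid_partition` or label vector
#' @param planted reference labels (same length)
#' @return agreement fraction in \[0, 1\]
#' @export
match_score <- function(partition, planted) {
  labels <- .partition_labels(partition)
  stopifnot(length(labels) == length(planted))
  tab <- table(labels, planted)
  if (nrow(tab) > ncol(tab)) tab <- t(tab)   # rows = smaller side
  m <- nrow(tab); cn <- ncol(tab)
  matched <- if (m <= 12) .assign_exact(tab) else .assign_greedy(tab)
  matched / length(labels)
}

## exact max-weight assignment by subset DP over the smaller side
.assign_exact <- function(tab) {
  m <- nrow(tab)
  dp <- rep(-Inf, 2^m); dp[1] <- 0
  for (j in seq_len(ncol(tab))) {
    new <- dp
    for (S in which(is.finite(dp)) - 1L) {
      for (i in seq_len(m)) {
        bit <- bitwShiftL(1L, i - 1L)
        if (!bitwAnd(S, bit)) {
          S2 <- bitwOr(S, bit) + 1L
          cand <- dp[S + 1L] + tab[i, j]
          if (cand > new[S2]) new[S2] <- cand
        }
      }
    }
    dp <- new
  }
  max(dp)
}

.assign_greedy <- function(tab) {
  total <- 0
  while (nrow(tab) && ncol(tab)) {
    best <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    total <- total + tab[best[1], best[2]]
    tab <- tab[-best[1], -best[2], drop = FALSE]
  }
  total
}
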