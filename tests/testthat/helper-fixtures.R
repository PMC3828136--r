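## Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- expr
  .fixtures[[name]]
}

## a random connected point-cloud structure (no side chains)
random_cloud_structure <- function(n, seed, spread = 6) {
  set.seed(seed)
  xyz <- matrix(runif(3 * n, 0, spread), n, 3)
  capsid_structure(data.frame(chain = "A", protein = "A",
                              resno = seq_len(n), ins = "", resid = "ALA",
                              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

## a small peptide structure with side-chain centroids placed off the
## backbone (synthetic geometry, not a real conformation)
peptide_structure <- function(n, seed = 1, gly_at = integer()) {
  set.seed(seed)
  t <- seq_len(n)
  xyz <- cbind(3.8 * t, 2 * sin(t), 2 * cos(t)) + matrix(rnorm(3 * n, 0, .2), n)
  side <- xyz + cbind(rnorm(n, 0, .5), 1.5 + rnorm(n, 0, .3), rnorm(n, 0, .5))
  side[gly_at, ] <- NA_real_
  capsid_structure(data.frame(chain = "A", protein = "A",
                              resno = t, ins = "",
                              resid = ifelse(t %in% gly_at, "GLY", "ALA"),
                              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                              sx = side[, 1], sy = side[, 2], sz = side[, 3]))
}

## brute-force O(n^2) neighbour scan (oracle for the cell-list search)
brute_pairs_within <- function(coords, cutoff) {
  n <- nrow(coords)
  cnt <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (sum((coords[i, ] - coords[j, ])^2) <= cutoff^2) cnt <- cnt + 1L
  cnt
}

## dense oracle for the side-chain Schur complement
dense_schur <- function(K, main_dofs) {
  K <- as.matrix(K)
  mi <- seq_len(main_dofs)
  si <- setdiff(seq_len(nrow(K)), mi)
  K[mi, mi] - K[mi, si] %*% solve(K[si, si], K[si, mi])
}

## exhaustive minimum strain over all labelings into exactly Q
## nonempty domains (oracle for greedy + refine)
exhaustive_min_strain <- function(S, Q) {
  n <- nrow(S)
  labs <- as.matrix(expand.grid(rep(list(seq_len(Q)), n)))
  keep <- apply(labs, 1, function(l) length(unique(l)) == Q)
  labs <- labs[keep, , drop = FALSE]
  total <- numeric(nrow(labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    total <- total + S[i, j] * (labs[, i] == labs[, j])
  list(min = min(total), labels = labs[which.min(total), ])
}

## write a minimal PDB file from atom records (list of lists)
write_mini_pdb <- function(path, atoms, remarks = character()) {
  fmt <- function(a)
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$type, a$no, ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
            "", a$resid, a$chain, a$resno, "", a$x, a$y, a$z, 1, 0, a$elem)
  writeLines(c(remarks, vapply(atoms, fmt, character(1)), "END"), path)
}

ala_atoms <- function(no0, chain, resno, x0) {
  list(
    list(type = "ATOM", no = no0 + 1, name = "N",  resid = "ALA", chain = chain,
         resno = resno, x = x0, y = 0, z = 0, elem = "N"),
    list(type = "ATOM", no = no0 + 2, name = "CA", resid = "ALA", chain = chain,
         resno = resno, x = x0 + 1.5, y = 0, z = 0, elem = "C"),
    list(type = "ATOM", no = no0 + 3, name = "C",  resid = "ALA", chain = chain,
         resno = resno, x = x0 + 2.5, y = 1.2, z = 0, elem = "C"),
    list(type = "ATOM", no = no0 + 4, name = "O",  resid = "ALA", chain = chain,
         resno = resno, x = x0 + 2.2, y = 2.3, z = 0, elem = "O"),
    list(type = "ATOM", no = no0 + 5, name = "CB", resid = "ALA", chain = chain,
         resno = resno, x = x0 + 2.0, y = -0.9, z = 1.2, elem = "C"))
}

gly_atoms <- function(no0, chain, resno, x0) {
  list(
    list(type = "ATOM", no = no0 + 1, name = "N",  resid = "GLY", chain = chain,
         resno = resno, x = x0, y = 0, z = 0, elem = "N"),
    list(type = "ATOM", no = no0 + 2, name = "CA", resid = "GLY", chain = chain,
         resno = resno, x = x0 + 1.5, y = 0, z = 0, elem = "C"),
    list(type = "ATOM", no = no0 + 3, name = "C",  resid = "GLY", chain = chain,
         resno = resno, x = x0 + 2.5, y = 1.2, z = 0, elem = "C"),
    list(type = "ATOM", no = no0 + 4, name = "O",  resid = "GLY", chain = chain,
         resno = resno, x = x0 + 2.2, y = 2.3, z = 0, elem = "O"))
}

## BIOMT remark lines for rotations about z by 360/k degrees
biomt_remarks <- function(k, chains = "A", radius_shift = 0) {
  out <- c("REMARK 350 BIOMOLECULE: 1",
           paste0("REMARK 350 APPLY THE FOLLOWING TO CHAINS: ",
                  paste(chains, collapse = ", ")))
  for (m in seq_len(k)) {
    th <- 2 * pi * (m - 1) / k
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    for (r in 1:3)
      out <- c(out, sprintf(
        "REMARK 350   BIOMT%d %3d %9.6f %9.6f %9.6f %14.5f",
        r, m, R[r, 1], R[r, 2], R[r, 3], radius_shift * (r == 1)))
  }
  out
}
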