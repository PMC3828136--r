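## Structure container and PDB/mmCIF input.
##
## A capsid structure is a residue-level view of an assembled protein
## shell: one record per amino acid carrying the main-chain centroid
## (the CA atom) and, when the residue has side-chain heavy atoms, the
## unweighted centroid of those atoms.  Chains are grouped into
## "proteins" (the coat-protein bookkeeping used by the integrity and
## interlocking order parameters).

#' Construct a capsid structure from a residue table
#'
#' Low-level constructor used by [load_structure()] and by the
#' synthetic-assembly generators.  Most users will not call it directly.
#'
#' @param residues data frame with columns `chain`, `protein`, `resno`,
#'   `ins`, `resid`, `x`, `y`, `z` and optionally `sx`, `sy`, `sz`
#'   (side-chain centroid; `NA` when the residue has no side-chain
#'   heavy atoms).  One row per residue, in sequence order within each
#'   protein.
#' @param subdomains optional named list mapping `"protein:subdomain"`
#'   labels to residue index vectors (1-based, into `residues`).
#' @return an object of class `capsid_structure`: the residue table
#'   plus a `proteins` list mapping protein id to residue indices.
#' @export
capsid_structure <- function(residues, subdomains = NULL) {
  need <- c("chain", "protein", "resno", "ins", "resid", "x", "y", "z")
  miss <- setdiff(need, names(residues))
  if (length(miss))
    stop("residue table lacks columns: ", paste(miss, collapse = ", "))
  if (!nrow(residues)) stop("empty structure: no residues")
  for (cc in c("sx", "sy", "sz"))
    if (is.null(residues[[cc]])) residues[[cc]] <- NA_real_
  xyz <- as.matrix(residues[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite main-chain coordinates")
  side <- as.matrix(residues[, c("sx", "sy", "sz")])
  bad <- rowSums(is.finite(side)) %in% c(1L, 2L)
  if (any(bad))
    stop("side-chain centroid partially defined for residue(s) ",
         paste(which(bad), collapse = ", "))
  residues$protein <- as.character(residues$protein)
  residues$chain <- as.character(residues$chain)
  proteins <- split(seq_len(nrow(residues)),
                    factor(residues$protein, levels = unique(residues$protein)))
  structure(list(residues = residues, proteins = proteins,
                 subdomains = subdomains),
            class = "capsid_structure")
}

#' @export
print.capsid_structure <- function(x, ...) {
  n <- nrow(x$residues)
  cat(sprintf("Capsid structure: %d residues, %d protein(s), %d with side-chain centroid\n",
              n, length(x$proteins), sum(is.finite(x$residues$sx))))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure a `capsid_structure`
#' @return integer residue count
#' @export
n_residues <- function(structure) nrow(structure$residues)

#' Residue-index grouping by protein
#'
#' @param structure a `capsid_structure`
#' @return named list of residue index vectors, one per protein, in
#'   first-appearance order; the grouping consumed by
#'   [integrity_score()].
#' @export
protein_grouping <- function(structure) structure$proteins

## backbone atoms never counted into the side-chain centroid
.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

#' Read an assembly structure from PDB or mmCIF
#'
#' Parses a coordinate file, keeps one record per amino-acid residue
#' (identified by the presence of a carbon CA atom, so HETATM amino
#' acids such as MSE are retained while waters, ions, ligands and
#' nucleic acids are ignored), and optionally expands the biological
#' assembly from REMARK 350 BIOMT transforms.  Each generated copy
#' receives a distinct protein id (`<chain>.<copy>`).
#'
#' If expansion is requested but the file carries no transforms (or a
#' single identity transform), the file is assumed to be a pre-expanded
#' full assembly (VIPERdb dialect) and a notice is emitted.  mmCIF
#' files are always treated as pre-expanded.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param expand_assembly expand REMARK 350 transforms? Default `TRUE`.
#' @param protein_map optional named character vector mapping chain ids
#'   to protein ids, for capsids whose coat protein spans several
#'   chains/segments.  Default: protein id = chain id.
#' @return a [capsid_structure()]
#' @export
load_structure <- function(path, expand_assembly = TRUE, protein_map = NULL) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- if (is_cif) bio3d::read.cif(path) else
    tryCatch(bio3d::read.pdb(path),
             error = function(e) stop("parse error in ", path, ": ",
                                      conditionMessage(e)))
  res <- .residues_from_atoms(pdb$atom)
  if (!nrow(res$residues)) stop("empty structure: no amino-acid residues in ", path)

  transforms <- if (!is_cif) .biomt_transforms(pdb) else NULL
  if (expand_assembly) {
    if (is.null(transforms) || length(transforms$mat) <= 1L) {
      message("no (non-trivial) assembly transforms found; ",
              "assuming the file is a pre-expanded full assembly")
    } else {
      res$residues <- .expand_assembly(res$residues, transforms)
    }
  }
  if (!is.null(protein_map)) {
    hit <- res$residues$chain %in% names(protein_map)
    res$residues$protein[hit] <- unname(protein_map[res$residues$chain[hit]])
  }
  capsid_structure(res$residues)
}

## residue table from a bio3d atom data frame
.residues_from_atoms <- function(atom) {
  atom <- atom[!(atom$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!nrow(atom))
    return(list(residues = data.frame()))
  atom$ins <- ifelse(is.na(atom$insert) | atom$insert == "", "", atom$insert)
  key <- paste(atom$chain, atom$resno, atom$ins, sep = "|")
  grp <- split(seq_len(nrow(atom)), factor(key, levels = unique(key)))
  rows <- lapply(grp, function(ii) {
    a <- atom[ii, , drop = FALSE]
    ca <- which(a$elety == "CA" & (is.na(a$elesy) | a$elesy %in% c("C", "")))
    if (!length(ca)) {
      ## amino acid (recognized 3-letter code) without CA -> warn + drop
      if (a$resid[1] %in% rownames(bio3d::aa.table))
        warning("dropping residue ", a$resid[1], " ", a$chain[1], a$resno[1],
                ": no CA atom", call. = FALSE)
      return(NULL)
    }
    ca <- ca[1]
    sc <- which(!(a$elety %in% .backbone_atoms) &
                  !(a$elesy %in% c("H", "D")) &
                  !grepl("^[0-9]*[HD]", a$elety))
    side <- if (length(sc)) colMeans(a[sc, c("x", "y", "z")]) else
      c(NA_real_, NA_real_, NA_real_)
    data.frame(chain = a$chain[ca], protein = a$chain[ca],
               resno = a$resno[ca], ins = a$ins[ca], resid = a$resid[ca],
               x = a$x[ca], y = a$y[ca], z = a$z[ca],
               sx = side[1], sy = side[2], sz = side[3],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  list(residues = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

## REMARK 350 transforms of the first biomolecule, as a list of 3x4
## matrices plus the chains they apply to
.biomt_transforms <- function(pdb) {
  bm <- pdb$remark$biomat
  if (is.null(bm)) return(NULL)
  mats <- bm$mat[[1]]
  chains <- bm$chain[[1]]
  for (m in mats) {
    d <- det(m[, 1:3])
    if (abs(d - 1) > 1e-6)
      stop("assembly transform is not a proper rotation (det = ",
           format(d), ")")
  }
  list(mat = mats, chains = chains)
}

.expand_assembly <- function(residues, transforms) {
  apply_to <- residues$chain %in% transforms$chains
  base <- residues[apply_to, , drop = FALSE]
  rest <- residues[!apply_to, , drop = FALSE]
  copies <- lapply(seq_along(transforms$mat), function(k) {
    m <- transforms$mat[[k]]
    out <- base
    xyz <- as.matrix(base[, c("x", "y", "z")]) %*% t(m[, 1:3])
    out$x <- xyz[, 1] + m[1, 4]
    out$y <- xyz[, 2] + m[2, 4]
    out$z <- xyz[, 3] + m[3, 4]
    has_side <- is.finite(base$sx)
    if (any(has_side)) {
      sxyz <- as.matrix(base[has_side, c("sx", "sy", "sz")]) %*% t(m[, 1:3])
      out$sx[has_side] <- sxyz[, 1] + m[1, 4]
      out$sy[has_side] <- sxyz[, 2] + m[2, 4]
      out$sz[has_side] <- sxyz[, 3] + m[3, 4]
    }
    out$protein <- paste0(base$protein, ".", k)
    out
  })
  do.call(rbind, c(copies, list(rest), list(make.row.names = FALSE)))
}

#' Structural coarse-graining: retain every k-th residue
#'
#' Keeps, within each protein in sequence order, the residues at
#' positions 1, 1+k, 1+2k, ...; side-chain centroids are dropped, so
#' the decimated structure is meant for the single-centroid network
#' backend (with the interaction cutoff rescaled accordingly, e.g.
#' 15 Angstrom at factor 2).
#'
#' @param structure a `capsid_structure`
#' @param factor positive integer decimation factor; 1 returns the
#'   structure unchanged.
#' @return a `capsid_structure`
#' @export
decimate_structure <- function(structure, factor) {
  stopifnot(length(factor) == 1L, factor >= 1, factor == round(factor))
  if (factor == 1) return(structure)
  lens <- lengths(structure$proteins)
  if (factor > min(lens))
    stop("decimation factor (", factor, ") exceeds the shortest chain (",
         min(lens), " residues)")
  keep <- sort(unlist(lapply(structure$proteins, function(ii)
    ii[seq(1L, length(ii), by = factor)]), use.names = FALSE))
  res <- structure$residues[keep, , drop = FALSE]
  res$sx <- res$sy <- res$sz <- NA_real_
  capsid_structure(res)
}

#' Extract one protein as a standalone structure
#'
#' Used to build the single-coat-protein reference spectrum for
#' [select_mode_count()].
#'
#' @param structure a `capsid_structure`
#' @param protein protein id; default the first protein.
#' @return a `capsid_structure` holding only that protein's residues
#' @export
extract_protein <- function(structure, protein = NULL) {
  if (is.null(protein)) protein <- names(structure$proteins)[1]
  ii <- structure$proteins[[protein]]
  if (is.null(ii)) stop("no such protein: ", protein)
  capsid_structure(structure$residues[ii, , drop = FALSE])
}

## main-chain coordinate matrix (n x 3)
.main_coords <- function(structure)
  as.matrix(structure$residues[, c("x", "y", "z")])
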