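## Partition input/output: TSV, PDB-with-B-factor-labels, JSON.

#' Write a partition to disk
#'
#' @param structure the `capsid_structure` the partition refers to
#' @param partition a `capsid_partition` (from [greedy_minimize()] or
#'   [sweep_partitions()]) or a bare integer label vector
#' @param path output file
#' @param format `"tsv"` (one row per residue: chain, residue number +
#'   insertion code, protein id, domain id), `"pdb-bfactor"` (CA-trace
#'   PDB with the domain id in the B-factor column) or `"json"` (full
#'   record including strains)
#' @return `path`, invisibly
#' @export
write_partition <- function(structure, partition, path,
                            format = c("tsv", "pdb-bfactor", "json")) {
  format <- match.arg(format)
  labels <- .partition_labels(partition)
  n <- n_residues(structure)
  if (length(labels) != n)
    stop("partition has ", length(labels), " labels but the structure has ",
         n, " residues")
  res <- structure$residues
  if (format == "tsv") {
    df <- data.frame(chain = res$chain,
                     resno = paste0(res$resno, res$ins),
                     protein = res$protein,
                     domain = labels)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "pdb-bfactor") {
    xyz <- as.numeric(t(.main_coords(structure)))
    chain <- substr(res$chain, 1, 1)
    bio3d::write.pdb(file = path, xyz = xyz, resno = res$resno,
                     chain = chain, insert = ifelse(res$ins == "", NA, res$ins),
                     resid = res$resid, elety = rep("CA", n),
                     b = as.numeric(labels), o = rep(1, n))
  } else {
    rec <- list(domain = labels,
                chain = res$chain,
                resno = paste0(res$resno, res$ins),
                protein = res$protein)
    if (inherits(partition, "capsid_partition"))
      rec <- c(rec, list(Q = partition$Q,
                         total_strain = partition$total_strain,
                         per_domain_strain = partition$per_domain_strain,
                         seed = partition$seed,
                         restarts = partition$restarts))
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a partition written by [write_partition()]
#'
#' TSV rows may appear in any order: they are matched to the structure
#' by (protein id, residue number + insertion code).
#'
#' @param path a TSV or JSON file produced by [write_partition()] (or
#'   matching its TSV schema)
#' @param structure the `capsid_structure` the labels refer to
#' @return integer label vector aligned to the structure's residue order
#' @export
read_partition <- function(path, structure) {
  res <- structure$residues
  skey <- paste(res$protein, paste0(res$resno, res$ins), sep = "|")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::read_json(path, simplifyVector = TRUE)
    fkey <- paste(rec$protein, rec$resno, sep = "|")
    labels <- rec$domain
  } else {
    df <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = c("character", "character", "character",
                                    "integer"))
    fkey <- paste(df$protein, df$resno, sep = "|")
    labels <- df$domain
  }
  pos <- match(skey, fkey)
  if (anyNA(pos))
    stop("residues not found in partition file: ",
         paste(head(skey[is.na(pos)], 10), collapse = ", "),
         if (sum(is.na(pos)) > 10) " ...")
  as.integer(labels[pos])
}

## label vector from a partition object or bare vector
.partition_labels <- function(partition) {
  if (inherits(partition, "capsid_partition")) partition$labels
  else as.integer(partition)
}
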