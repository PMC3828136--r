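## Per-Q profiling and the one-stop decomposition pipeline.

#' Profile a sweep with the selection order parameters
#'
#' For every Q in a [sweep_partitions()] profile, computes the total
#' strain, protein integrity (and subdomain integrity when the
#' structure defines subdomains), tile-type count, interlocking and
#' captured-motion fraction.
#'
#' @param profile a `strain_profile`
#' @param spectrum the `mode_spectrum` (truncated to the retained M)
#'   the sweep was based on
#' @param structure the matching `capsid_structure`
#' @param tile_tolerance relative size tolerance for [tile_types()]
#' @param terminal_length residues per terminus for [interlocking()]
#' @return a `decomposition_report`: a data frame with one row per Q
#'   and the best partitions attached as attribute `"partitions"`
#' @export
assess_partitions <- function(profile, spectrum, structure,
                              tile_tolerance = 0.03, terminal_length = 20) {
  parts <- profile$partitions
  grouping <- protein_grouping(structure)
  rows <- lapply(parts, function(p) {
    basis <- build_rigid_basis(structure, p)
    rec <- data.frame(
      Q = p$Q,
      strain = p$total_strain,
      integrity = integrity_score(p, grouping),
      n_tile_types = tile_types(p, tolerance = tile_tolerance)$n_types,
      interlocking = interlocking(p, structure,
                                  terminal_length = terminal_length),
      captured = captured_fraction(spectrum, basis),
      seed = p$seed,
      restarts = p$restarts)
    if (!is.null(structure$subdomains))
      rec$subdomain_integrity <- integrity_score(p, structure$subdomains)
    rec
  })
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(report, "partitions") <- parts
  class(report) <- c("decomposition_report", "data.frame")
  report
}

#' Full quasi-rigid domain decomposition pipeline
#'
#' Runs all three stages on a structure or synthetic toy: elastic
#' network and low-energy modes, retained-mode selection against a
#' single-protein reference spectrum, strain-field construction, sweep
#' over Q with greedy + split/join minimization, per-Q order
#' parameters, and ranking of candidate optimal subdivisions.
#'
#' @param x a `capsid_structure` (a beta-Gaussian network is built
#'   with `cutoff`/`backbone_bonus`) or a `toy_assembly` (its planted
#'   network is used directly)
#' @param seed master RNG seed (mandatory; recorded in the report)
#' @param q_values Q grid; default `2:(number of proteins)`
#' @param n_modes cap on computed capsid modes (default 100)
#' @param M retained mode count; default `NULL` selects it with
#'   [select_mode_count()] from the reference protein
#' @param cutoff,backbone_bonus network parameters (structures only)
#' @param reference_protein protein id for the reference spectrum
#'   (default: first protein)
#' @param mode_floor floor passed to [select_mode_count()]
#' @param restarts,outlier_k,max_iter sweep/refinement controls
#' @param pair_cutoff optional strain-pair distance cutoff
#'   (approximation for very large capsids, flagged in the result)
#' @param tile_tolerance,terminal_length,max_types selection controls
#' @param method eigensolver method, see [compute_modes()]
#' @return an object of class `capsid_decomposition`: list with
#'   `report`, `candidates`, `profile`, `spectrum`, `M`, `params`
#' @export
decompose_capsid <- function(x, seed, q_values = NULL, n_modes = 100,
                             M = NULL, cutoff = 7.5, backbone_bonus = 1,
                             reference_protein = NULL, mode_floor = 10,
                             restarts = 5, outlier_k = 2, max_iter = 10,
                             pair_cutoff = NULL, tile_tolerance = 0.03,
                             terminal_length = 20, max_types = 3,
                             method = "auto") {
  if (inherits(x, "toy_assembly")) {
    structure <- x$structure
    network <- x$network
  } else if (inherits(x, "capsid_structure")) {
    structure <- x
    network <- build_beta_gaussian(structure, cutoff = cutoff,
                                   backbone_bonus = backbone_bonus)
  } else stop("x must be a capsid_structure or toy_assembly")

  n <- n_residues(structure)
  navail <- 3L * n - 7L
  spec <- compute_modes(network, n_modes = min(n_modes, navail),
                        method = method)
  if (is.null(M)) {
    ref <- .reference_network(x, structure, network, reference_protein,
                              cutoff, backbone_bonus)
    np <- ref$n_mainchain
    pspec <- compute_modes(ref, n_modes = min(20L, 3L * np - 7L),
                           method = method)
    M <- select_mode_count(spec, pspec, floor = mode_floor)
  }
  spec <- truncate_spectrum(spec, min(M, length(spec$values)))

  field <- strain_field(spec, structure, pair_cutoff = pair_cutoff)
  if (is.null(q_values)) q_values <- 2:length(structure$proteins)
  profile <- sweep_partitions(field, q_values, restarts = restarts,
                              seed = seed, outlier_k = outlier_k,
                              max_iter = max_iter)
  report <- assess_partitions(profile, spec, structure,
                              tile_tolerance = tile_tolerance,
                              terminal_length = terminal_length)
  candidates <- if (nrow(report) >= 3)
    withCallingHandlers(select_optimal(report, max_types = max_types),
                        warning = function(w) invokeRestart("muffleWarning"))
  else report[0, , drop = FALSE]
  structure(list(report = report, candidates = candidates,
                 profile = profile, spectrum = spec, M = spec$M,
                 params = list(seed = seed, restarts = restarts,
                               cutoff = cutoff,
                               backbone_bonus = backbone_bonus,
                               pair_cutoff = pair_cutoff,
                               tile_tolerance = tile_tolerance,
                               terminal_length = terminal_length,
                               max_types = max_types,
                               approximate = !is.null(pair_cutoff))),
            class = "capsid_decomposition")
}

## reference single-protein network: extracted from the toy network or
## rebuilt from the structure
.reference_network <- function(x, structure, network, reference_protein,
                               cutoff, backbone_bonus) {
  if (inherits(x, "toy_assembly")) {
    if (is.null(reference_protein))
      reference_protein <- names(structure$proteins)[1]
    .subnetwork(network, structure$proteins[[reference_protein]])
  } else {
    build_beta_gaussian(extract_protein(structure, reference_protein),
                        cutoff = cutoff, backbone_bonus = backbone_bonus)
  }
}

## restriction of a main-chain-only network to a residue subset
.subnetwork <- function(net, idx) {
  stopifnot(net$n_mainchain == nrow(net$coords))
  pos <- match(seq_len(nrow(net$coords)), idx)
  e <- net$edges
  keep <- !is.na(pos[e$i]) & !is.na(pos[e$j])
  elastic_network(net$coords[idx, , drop = FALSE],
                  data.frame(i = pos[e$i[keep]], j = pos[e$j[keep]],
                             k = e$k[keep]),
                  n_mainchain = length(idx), cutoff = net$cutoff)
}

#' @export
print.capsid_decomposition <- function(x, ...) {
  cat(sprintf("Quasi-rigid decomposition: %d Q values swept, M = %d modes retained\n",
              nrow(x$report), x$M))
  if (nrow(x$candidates)) {
    cat("Ranked candidate subdivisions:\n")
    print(utils::head(as.data.frame(
      x$candidates[, c("Q", "integrity", "n_tile_types", "interlocking",
                       "captured")]), 5))
  } else cat("No interior integrity peak passed the tile-type filter.\n")
  invisible(x)
}

#' Export a decomposition report
#'
#' @param x a `capsid_decomposition` or `decomposition_report`
#' @param path output file
#' @param format `"json"` (per-Q records plus ranked candidates) or
#'   `"csv"` (per-Q profile table)
#' @return `path`, invisibly
#' @export
write_report <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (inherits(x, "capsid_decomposition")) {
    report <- x$report; cand <- x$candidates; params <- x$params
  } else {
    report <- x; cand <- NULL; params <- NULL
  }
  tab <- as.data.frame(report)
  if (format == "csv") {
    write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(list(profile = tab,
                              candidates = if (!is.null(cand))
                                as.data.frame(cand),
                              params = params),
                         path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
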