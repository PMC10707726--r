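#' Run the standard TsaBgl loop analysis on local coordinate files
#'
#' Convenience wrapper assembling the canonical analysis of the
#' *T. saccharolyticum* beta-glucosidase study system: the four deposited
#' crystal forms (PDB entries 8WFT and 8WFU, triclinic, four molecules per
#' asymmetric unit; 8WFV and 8WFW, orthorhombic, one molecule), the
#' [tsabgl_loops] definitions, chain A of the first entry as the folded
#' reference, and both per-loop r.m.s.d. modes. Files must already be on
#' disk (e.g. fetched from the PDB beforehand); nothing is downloaded.
#'
#' @param paths character vector of coordinate file paths (PDB format).
#' @param chains optional list, parallel to `paths`, of chain-id vectors
#'   (default: all chains of each file).
#' @param reference `list(structure = <id>, chain = <id>)`; defaults to
#'   chain A of the first file.
#' @param ... further arguments to [analysis_config] (loops, cutoffs,
#'   thresholds).
#' @return An `analysis_report` (see [run_analysis]).
#' @export
tsabgl_analysis <- function(paths, chains = NULL, reference = NULL, ...) {
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("coordinate file(s) not found: ", paste(missing, collapse = ", "),
         "\nfetch the deposited entries (8WFT, 8WFU, 8WFV, 8WFW) first")
  }
  structures <- lapply(seq_along(paths), function(i) {
    list(structure = paths[i],
         chains = if (is.null(chains)) NULL else chains[[i]])
  })
  if (is.null(reference)) {
    id <- tools::file_path_sans_ext(basename(paths[1]))
    reference <- list(structure = id, chain = "A")
  }
  run_analysis(analysis_config(structures = structures,
                               reference = reference, ...))
}
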