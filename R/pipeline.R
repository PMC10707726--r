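#' Configure a full loop analysis
#'
#' Bundles the inputs and parameters of [run_analysis]: the structures
#' (paths or in-memory [loop_structure] objects) with the chains to use,
#' the loop definitions, the reference conformer, and every geometric
#' cutoff, so a report is reproducible from its configuration alone.
#'
#' @param structures list of entries, each `list(structure = <path or
#'   loop_structure>, chains = <chain ids or NULL for all>)`.
#' @param loops list of [region_spec] loops (default [tsabgl_loops]).
#' @param reference `list(structure = <index or id>, chain = <id>)`
#'   naming the reference conformer; default the first chain of the first
#'   structure.
#' @param reference_label conformer label of the reference (default
#'   `"folded"`); subjects exceeding the displacement threshold get
#'   `alternate_label`.
#' @param alternate_label default `"straight"`.
#' @param modes per-loop r.m.s.d. modes to run.
#' @param conformer_region sub-region used for conformer classification
#'   (default residues 301-311, the flexible N-terminal part of L3).
#' @param conformer_threshold angstrom (default 3).
#' @param hbond_dmax,phobic_dmax,seq_sep_min contact cutoffs.
#' @param flex_threshold region-flexibility label threshold.
#' @param scope B-factor normalization scope.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(structures,
                            loops = tsabgl_loops(),
                            reference = NULL,
                            reference_label = "folded",
                            alternate_label = "straight",
                            modes = c("core-frame", "loop-local"),
                            conformer_region = region_spec("L3n", 301, 311),
                            conformer_threshold = 3.0,
                            hbond_dmax = 3.5,
                            phobic_dmax = 4.5,
                            seq_sep_min = 2,
                            flex_threshold = 0.5,
                            scope = "chain") {
  structure(list(structures = structures, loops = loops,
                 reference = reference, reference_label = reference_label,
                 alternate_label = alternate_label, modes = modes,
                 conformer_region = conformer_region,
                 conformer_threshold = conformer_threshold,
                 hbond_dmax = hbond_dmax, phobic_dmax = phobic_dmax,
                 seq_sep_min = seq_sep_min, flex_threshold = flex_threshold,
                 scope = scope),
            class = "analysis_config")
}

#' Run the full loop-conformation analysis
#'
#' Orchestrates every stage over an ensemble of chains: per-loop pairwise
#' r.m.s.d. (in each requested mode), normalized B-factor flexibility per
#' chain and region, conformer classification of every chain against the
#' declared reference, per-loop contact counts, pocket-entrance geometry
#' and loop formal charges. Chains that fail a stage are reported
#' per-item; the run only aborts if no chain is usable.
#'
#' @param config an [analysis_config].
#' @return An object of class `analysis_report`: a named list that
#'   serializes to JSON via [write_report], containing `inputs`,
#'   `parameters`, `chains`, `per_loop_rmsd`, `flexibility`, `conformers`,
#'   `contacts`, `pocket`, `charges`, `failures` and `provenance`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  failures <- list()
  note_failure <- function(stage, item, e) {
    failures[[length(failures) + 1]] <<- list(stage = stage, item = item,
                                              error = conditionMessage(e))
  }
  # resolve structures and chain list
  structs <- lapply(config$structures, function(entry) {
    s <- entry$structure
    if (is.character(s)) {
      s <- tryCatch(read_structure(s), error = function(e) {
        note_failure("parse", s, e)
        NULL
      })
    }
    if (is.null(s)) return(NULL)
    list(structure = s, chains = entry$chains %||% chain_ids(s))
  })
  structs <- Filter(Negate(is.null), structs)
  chains <- list()
  for (st in structs) {
    for (ch in st$chains) {
      chains[[length(chains) + 1]] <- list(structure = st$structure,
                                           chain = ch,
                                           label = paste0(st$structure$id,
                                                          ":", ch))
    }
  }
  if (length(chains) == 0) {
    stop("no valid chains; per-file diagnostics: ",
         paste(vapply(failures, function(f) paste0(f$item, " (", f$error, ")"),
                      ""), collapse = "; "))
  }
  labels <- vapply(chains, `[[`, "", "label")
  # reference chain
  ref_idx <- 1L
  if (!is.null(config$reference)) {
    want <- paste0(config$reference$structure, ":", config$reference$chain)
    hit <- which(labels == want)
    if (length(hit) == 0) {
      hit <- which(vapply(chains, function(cr) {
        cr$chain == config$reference$chain
      }, TRUE))
    }
    if (length(hit) > 0) ref_idx <- hit[1]
  }
  loops <- config$loops

  # per-loop pairwise r.m.s.d., each declared mode
  rmsd_out <- list()
  if (length(chains) >= 2) {
    for (mode in config$modes) {
      rmsd_out[[mode]] <- tryCatch(
        per_loop_rmsd(chains, loops, mode = mode),
        error = function(e) {
          note_failure("per_loop_rmsd", mode, e)
          NULL
        })
    }
  }

  # flexibility per chain
  flex_out <- lapply(chains, function(cr) {
    tryCatch({
      prof <- normalize_bfactors(cr$structure, scope = config$scope,
                                 chains = cr$chain)
      regs <- lapply(loops, function(r) {
        region_flexibility(prof, r, threshold = config$flex_threshold)
      })
      list(chain = cr$label,
           regions = do.call(rbind, lapply(regs, as.data.frame)))
    }, error = function(e) {
      note_failure("flexibility", cr$label, e)
      NULL
    })
  })
  names(flex_out) <- labels

  # conformer classification against the reference
  ref <- chains[[ref_idx]]
  conf_out <- lapply(seq_along(chains), function(i) {
    cr <- chains[[i]]
    if (i == ref_idx) {
      return(data.frame(chain = cr$label, label = config$reference_label,
                        max_disp = 0, reference = TRUE,
                        stringsAsFactors = FALSE))
    }
    tryCatch({
      prof <- displacement_profile(ref$structure, cr$structure,
                                   ref$chain, cr$chain, exclude = loops)
      cl <- classify_conformer(prof, region = config$conformer_region,
                               threshold = config$conformer_threshold,
                               alternate_label = config$alternate_label)
      lab <- if (cl$label == "reference-equal") config$reference_label
             else cl$label
      data.frame(chain = cr$label, label = lab, max_disp = cl$max_disp,
                 reference = FALSE, stringsAsFactors = FALSE)
    }, error = function(e) {
      note_failure("conformer", cr$label, e)
      NULL
    })
  })
  conf_out <- do.call(rbind, Filter(Negate(is.null), conf_out))

  # contacts and pocket geometry and charges, per chain
  contact_out <- lapply(chains, function(cr) {
    tryCatch(
      loop_contact_report(cr$structure, cr$chain, loops,
                          hbond_dmax = config$hbond_dmax,
                          phobic_dmax = config$phobic_dmax,
                          seq_sep_min = config$seq_sep_min)$counts,
      error = function(e) {
        note_failure("contacts", cr$label, e)
        NULL
      })
  })
  names(contact_out) <- labels
  pocket_out <- lapply(chains, function(cr) {
    tryCatch({
      pg <- pocket_geometry(cr$structure, cr$chain, l2 = loops$L2,
                            l3 = loops$L3, l1 = loops$L1, l4 = loops$L4)
      data.frame(chain = cr$label, min_l2_l3 = pg$min_l2_l3,
                 entrance_width = pg$entrance_width,
                 definition = pg$definition, stringsAsFactors = FALSE)
    }, error = function(e) {
      note_failure("pocket", cr$label, e)
      NULL
    })
  })
  pocket_out <- do.call(rbind, Filter(Negate(is.null), pocket_out))
  charge_out <- lapply(chains, function(cr) {
    tryCatch({
      data.frame(chain = cr$label,
                 loop = vapply(loops, function(r) r$name, ""),
                 net_charge = vapply(loops, function(r) {
                   loop_charge(cr$structure, r, chain = cr$chain)
                 }, 0L), stringsAsFactors = FALSE, row.names = NULL)
    }, error = function(e) {
      note_failure("charge", cr$label, e)
      NULL
    })
  })
  charge_out <- do.call(rbind, Filter(Negate(is.null), charge_out))

  report <- structure(list(
    schema_version = "1.0",
    inputs = vapply(structs, function(st) st$structure$id, ""),
    parameters = config[setdiff(names(config), "structures")],
    chains = labels,
    reference = labels[ref_idx],
    per_loop_rmsd = lapply(rmsd_out, function(x) {
      if (is.null(x)) NULL else list(mode = x$mode, summary = x$summary,
                                     matrices = x$matrices)
    }),
    flexibility = Filter(Negate(is.null), flex_out),
    conformers = conf_out,
    contacts = contact_out,
    pocket = pocket_out,
    charges = charge_out,
    failures = failures,
    provenance = list(
      package = "loopscape",
      version = as.character(utils::packageVersion("loopscape")))
  ), class = "analysis_report")
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> chains:", paste(x$chains, collapse = ", "), "\n")
  cat(" reference:", x$reference, "\n")
  for (mode in names(x$per_loop_rmsd)) {
    cat(" per-loop rmsd (", mode, "):\n", sep = "")
    print(x$per_loop_rmsd[[mode]]$summary, digits = 3)
  }
  if (!is.null(x$conformers)) {
    cat(" conformers:\n")
    print(x$conformers, digits = 3)
  }
  if (length(x$failures) > 0) {
    cat(" failures:", length(x$failures), "(see $failures)\n")
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' @param report an `analysis_report` from [run_analysis].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  plain <- rapply(unclass(report), function(x) {
    if (inherits(x, "region_spec")) format(x) else x
  }, classes = "ANY", how = "replace")
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
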