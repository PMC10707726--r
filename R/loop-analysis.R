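#' Per-loop pairwise r.m.s.d. across an ensemble of chains
#'
#' For every pair of chains in the ensemble and every loop, computes the
#' C-alpha r.m.s.d. of the loop in one of two declared modes:
#'
#' * `"loop-local"` — the rigid fit is made on the loop's own C-alpha
#'   atoms; measures internal loop-shape agreement.
#' * `"core-frame"` — the fit is made on the core (all shared residues
#'   minus every loop, or an explicit `core` region set) and the loop
#'   r.m.s.d. is measured in that frame; measures loop placement relative
#'   to the rigid fold.
#'
#' The mode is always recorded in the output because the two can differ
#' substantially for a loop that moves as a rigid body.
#'
#' @param chains list of chain references, each `list(structure =
#'   <loop_structure>, chain = <id>, label = <optional name>)`.
#' @param loops list of [region_spec] loops, resolvable in every chain.
#' @param mode `"core-frame"` or `"loop-local"`.
#' @param core optional region list overriding the default core
#'   (everything minus the loops) in `"core-frame"` mode.
#' @return list of class `loop_rmsd`: per-loop symmetric zero-diagonal
#'   matrices (`matrices`), a summary data frame (`summary`: loop, min,
#'   max over off-diagonal entries) and the `mode`.
#' @export
per_loop_rmsd <- function(chains, loops,
                          mode = c("core-frame", "loop-local"), core = NULL) {
  mode <- match.arg(mode)
  if (inherits(loops, "region_spec")) loops <- list(loops)
  names(loops) <- vapply(loops, function(r) r$name, "")
  if (length(chains) < 2) stop("need at least 2 chains")
  labels <- vapply(seq_along(chains), function(i) {
    chains[[i]]$label %||% paste0(chains[[i]]$structure$id, ":",
                                  chains[[i]]$chain)
  }, "")
  cas <- lapply(chains, function(cr) {
    ca <- tryCatch(chain_ca(cr$structure, cr$chain), error = function(e) {
      stop("chain ", cr$chain, " of ", cr$structure$id, ": ",
           conditionMessage(e), call. = FALSE)
    })
    for (r in loops) {
      hit <- ca$resno >= r$start & ca$resno <= r$end
      if (!any(hit)) {
        stop(sprintf("loop %s (%d-%d) unresolvable in chain %s of %s",
                     r$name, r$start, r$end, cr$chain, cr$structure$id))
      }
    }
    ca
  })
  n <- length(chains)
  mats <- lapply(loops, function(r) {
    m <- matrix(0, n, n, dimnames = list(labels, labels))
    m
  })
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      shared <- intersect(cas[[i]]$resno, cas[[j]]$resno)
      a <- cas[[i]][match(shared, cas[[i]]$resno), , drop = FALSE]
      b <- cas[[j]][match(shared, cas[[j]]$resno), , drop = FALSE]
      if (mode == "core-frame") {
        in_core <- if (is.null(core)) {
          !regions_mask(data.frame(chain = a$chain, resno = shared),
                        wildcard_regions(loops))
        } else {
          regions_mask(data.frame(chain = a$chain, resno = shared),
                       wildcard_regions(core))
        }
        fit <- kabsch_fit(coords_of(b)[in_core, , drop = FALSE],
                          coords_of(a)[in_core, , drop = FALSE])
        moved <- apply_superposition(fit, coords_of(b))
        for (k in names(loops)) {
          r <- loops[[k]]
          in_loop <- shared >= r$start & shared <= r$end
          mats[[k]][i, j] <- mats[[k]][j, i] <-
            rmsd(moved[in_loop, , drop = FALSE],
                 coords_of(a)[in_loop, , drop = FALSE])
        }
      } else {
        for (k in names(loops)) {
          r <- loops[[k]]
          in_loop <- shared >= r$start & shared <= r$end
          mats[[k]][i, j] <- mats[[k]][j, i] <-
            rmsd(coords_of(b)[in_loop, , drop = FALSE],
                 coords_of(a)[in_loop, , drop = FALSE], superpose = TRUE)
        }
      }
    }
  }
  off <- function(m) m[upper.tri(m)]
  summary <- data.frame(
    loop = names(loops),
    min = vapply(mats, function(m) min(off(m)), 0),
    max = vapply(mats, function(m) max(off(m)), 0),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  structure(list(matrices = mats, summary = summary, mode = mode),
            class = "loop_rmsd")
}

#' @export
print.loop_rmsd <- function(x, ...) {
  cat("<loop_rmsd> mode:", x$mode, "\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Classify a conformer from a displacement profile
#'
#' Labels a subject conformer relative to the reference used to build the
#' [displacement_profile]: `"reference-equal"` if the maximum C-alpha
#' displacement over the classification region stays below `threshold`,
#' otherwise the alternate label. The default region is the flexible
#' N-terminal sub-span of the L3 loop (residues 301-311), where the
#' folded/straight bimodality of the study system is localized; the
#' default threshold of 3 angstrom sits well below the ~5-9 angstrom
#' swings of a genuine conformer change and well above coordinate noise.
#'
#' @param profile a `displacement_profile`.
#' @param region [region_spec] over which the maximum displacement is
#'   taken; default residues 301-311.
#' @param threshold angstrom, default 3.0.
#' @param alternate_label label used when the threshold is exceeded
#'   (default `"alternate"`; e.g. `"straight"` when the reference is the
#'   folded conformer).
#' @return list of class `conformer_label`: `label`, `max_disp`,
#'   `max_residue` (author number at the maximum), `region`, `threshold`.
#' @export
classify_conformer <- function(profile, region = region_spec("L3n", 301, 311),
                               threshold = 3.0,
                               alternate_label = "alternate") {
  stopifnot(inherits(profile, "displacement_profile"),
            inherits(region, "region_spec"), threshold > 0)
  m <- region_mask(profile, region)
  if (!any(m)) {
    stop(sprintf("region %s (%d-%d) absent from displacement profile",
                 region$name, region$start, region$end))
  }
  sub <- profile[m, , drop = FALSE]
  i <- which.max(sub$displacement)
  label <- if (sub$displacement[i] < threshold) "reference-equal"
           else alternate_label
  structure(list(label = label, max_disp = sub$displacement[i],
                 max_residue = sub$resno[i], region = region,
                 threshold = threshold),
            class = "conformer_label")
}

#' @export
print.conformer_label <- function(x, ...) {
  cat(sprintf("<conformer> %s (max C-alpha displacement %.2f A at residue %d; threshold %.1f A over %s)\n",
              x$label, x$max_disp, x$max_residue, x$threshold,
              format(x$region)))
  invisible(x)
}

#' Pocket-entrance geometry
#'
#' Two simple rim metrics of the substrate-binding pocket entrance:
#'
#' * `min_l2_l3` — minimum heavy-atom distance between the L2 and L3 loop
#'   residue sets (the "proximate distance" closing or opening the gap
#'   between the two loops);
#' * `entrance_width` — maximum C-alpha/C-alpha distance across the rim,
#'   either over an explicit list of residue pairs (`rim_pairs`) or, by
#'   default, between the L1+L2 rim set and the L3+L4 rim set.
#'
#' The width metric has no canonical definition in the literature; the
#' definition actually used is recorded in the output so reports are
#' self-describing.
#'
#' @param s a [loop_structure].
#' @param chain chain id.
#' @param l2,l3 [region_spec] of the two gap-forming loops.
#' @param rim_pairs optional 2-column matrix/data frame of author residue
#'   number pairs for the width metric.
#' @param l1,l4 optional [region_spec]s for the default rim sets; if
#'   omitted, the width falls back to the maximum C-alpha distance between
#'   the L2 and L3 sets.
#' @return list of class `pocket_geometry`: `min_l2_l3`,
#'   `entrance_width`, `definition`.
#' @export
pocket_geometry <- function(s, chain, l2, l3, rim_pairs = NULL, l1 = NULL,
                            l4 = NULL) {
  heavy <- function(region) {
    at <- chain_atoms(s, chain)
    at <- at[region_mask(at, region) & at$elesy != "H", , drop = FALSE]
    if (nrow(at) == 0) {
      stop(sprintf("region %s (%d-%d) has no atoms in chain %s",
                   region$name, region$start, region$end, chain))
    }
    as.matrix(at[, c("x", "y", "z")])
  }
  ca_xyz <- function(regions) {
    sel <- do.call(rbind, lapply(regions, function(r) {
      select_atoms(s, r, atom_names = "CA", chain = chain)
    }))
    coords_of(sel)
  }
  min_l2_l3 <- min_cross_dist(heavy(l2), heavy(l3))
  if (!is.null(rim_pairs)) {
    rim_pairs <- as.matrix(rim_pairs)
    w <- apply(rim_pairs, 1, function(p) {
      a <- ca_xyz(list(region_spec("rimA", p[1], p[1], chain)))
      b <- ca_xyz(list(region_spec("rimB", p[2], p[2], chain)))
      sqrt(sum((a[1, ] - b[1, ])^2))
    })
    width <- max(w)
    def <- "max CA-CA distance over explicit rim pairs"
  } else if (!is.null(l1) && !is.null(l4)) {
    width <- max_cross_dist(ca_xyz(list(l1, l2)), ca_xyz(list(l3, l4)))
    def <- "max CA-CA distance, L1+L2 rim vs L3+L4 rim"
  } else {
    width <- max_cross_dist(ca_xyz(list(l2)), ca_xyz(list(l3)))
    def <- "max CA-CA distance, L2 vs L3"
  }
  structure(list(min_l2_l3 = min_l2_l3, entrance_width = width,
                 definition = def),
            class = "pocket_geometry")
}

#' @export
print.pocket_geometry <- function(x, ...) {
  cat(sprintf("<pocket> min L2-L3 distance %.2f A; entrance width %.2f A (%s)\n",
              x$min_l2_l3, x$entrance_width, x$definition))
  invisible(x)
}

min_cross_dist <- function(A, B) {
  sqrt(min(cross_dist2(A, B)))
}

max_cross_dist <- function(A, B) {
  sqrt(max(cross_dist2(A, B)))
}

cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  pmax(d2, 0)
}

# formal charge convention at physiological pH: Asp/Glu -1, Lys/Arg +1,
# His treated neutral
CHARGE_TABLE <- c(ASP = -1L, GLU = -1L, LYS = 1L, ARG = 1L, HIS = 0L,
                  D = -1L, E = -1L, K = 1L, R = 1L, H = 0L)

#' Net formal charge of a loop region
#'
#' Counts Asp/Glu as -1 and Lys/Arg as +1 (His neutral); a coarse,
#' discrete stand-in for the surface-charge character of a loop. Accepts
#' either a structure plus region or a plain amino-acid string.
#'
#' @param x a [loop_structure], or a one-letter amino-acid string.
#' @param region [region_spec] (required for a structure).
#' @param chain chain id (required for a multi-chain structure unless the
#'   region names one).
#' @return integer net charge. Unknown residue types count 0 and are
#'   reported via a warning.
#' @export
loop_charge <- function(x, region = NULL, chain = NULL) {
  if (inherits(x, "loop_structure")) {
    stopifnot(inherits(region, "region_spec"))
    at <- x$atoms
    at <- at[at$type == "ATOM", , drop = FALSE]
    if (!is.null(chain)) at <- at[at$chain == chain, , drop = FALSE]
    at <- at[region_mask(at, region), , drop = FALSE]
    if (nrow(at) == 0) {
      stop(sprintf("region %s (%d-%d) resolves to no residues",
                   region$name, region$start, region$end))
    }
    res <- at$resid[!duplicated(paste(at$chain, at$resno, at$insert))]
    known <- bio3d::aa321(res)
    if (any(is.na(known))) {
      warning(sum(is.na(known)), " residue(s) of unknown type counted as 0")
    }
  } else {
    res <- strsplit(toupper(as.character(x)[1]), "")[[1]]
  }
  sum(CHARGE_TABLE[res], na.rm = TRUE)
}
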