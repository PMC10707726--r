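# Contact geometry. Crystal structures at typical resolution carry no
# hydrogens, so hydrogen bonds are called on heavy-atom donor/acceptor
# distance alone (no angle term) — the standard fallback criterion.

MAINCHAIN_ATOMS <- c("N", "CA", "C", "O", "OXT")

# apolar residues and the side-chain carbons counted for each; Tyr counts
# ring carbons only (the hydroxyl end is polar)
APOLAR_SET <- list(
  ALA = c("CB"),
  VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  MET = c("CB", "CG", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  PRO = c("CB", "CG", "CD"),
  CYS = c("CB"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
)

#' Detect hydrogen bonds by donor/acceptor distance
#'
#' All pairs of nitrogen/oxygen heavy atoms (optionally sulfur) within
#' `d_max` of each other are reported as candidate hydrogen bonds. Pairs
#' within the same residue are excluded, and pairs in which both atoms are
#' main-chain atoms must be at least `seq_sep_min` residues apart (the
#' near-covalent N(i)...O(i-1) geometry of the peptide plane is not a
#' bond). Pairs are stored once, in canonical order by residue key.
#'
#' @param s a [loop_structure].
#' @param chain chain id, or a character vector of chains (inter-chain
#'   pairs are then reported regardless of sequence separation).
#' @param d_max heavy-atom distance cutoff in angstrom (default 3.5).
#' @param seq_sep_min minimum residue separation for main-chain/main-chain
#'   pairs (default 2).
#' @param include_s also treat sulfur as donor/acceptor.
#' @param include_het include HETATM records.
#' @return data frame of class `contact_table`: `kind`, `chain_a`,
#'   `resno_a`, `resid_a`, `atom_a`, `chain_b`, `resno_b`, `resid_b`,
#'   `atom_b`, `distance`.
#' @export
detect_hbonds <- function(s, chain, d_max = 3.5, seq_sep_min = 2,
                          include_s = FALSE, include_het = FALSE) {
  at <- chain_atoms(s, chain, include_het)
  elems <- c("N", "O", if (include_s) "S")
  polar <- at[at$elesy %in% elems, , drop = FALSE]
  if (nrow(polar) < 2) return(empty_contacts())
  pairs <- close_pairs(polar, d_max)
  if (nrow(pairs) == 0) return(empty_contacts())
  a <- polar[pairs$i, ]
  b <- polar[pairs$j, ]
  same_res <- a$chain == b$chain & a$resno == b$resno & a$insert == b$insert
  mc <- a$elety %in% MAINCHAIN_ATOMS & b$elety %in% MAINCHAIN_ATOMS
  sep_ok <- a$chain != b$chain | abs(a$resno - b$resno) >= seq_sep_min
  keep <- !same_res & (!mc | sep_ok)
  build_contacts("hbond", a[keep, ], b[keep, ], pairs$d[keep])
}

#' Detect hydrophobic contacts between apolar side chains
#'
#' Pairs of side-chain carbon atoms from apolar residues (Ala, Val, Leu,
#' Ile, Met, Phe, Trp, Pro, Cys and the Tyr ring) within `d_max` are
#' grouped per residue pair; each pair is reported once with its minimum
#' carbon-carbon distance.
#'
#' @inheritParams detect_hbonds
#' @param d_max side-chain carbon-carbon cutoff in angstrom (default 4.5).
#' @return A `contact_table` (see [detect_hbonds]) with `kind`
#'   `"hydrophobic"`, one row per residue pair at the minimum distance.
#' @export
detect_hydrophobic <- function(s, chain, d_max = 4.5, include_het = FALSE) {
  at <- chain_atoms(s, chain, include_het)
  keep <- rep(FALSE, nrow(at))
  for (resid in names(APOLAR_SET)) {
    keep <- keep | (at$resid == resid & at$elety %in% APOLAR_SET[[resid]])
  }
  apol <- at[keep & at$elesy == "C", , drop = FALSE]
  if (nrow(apol) < 2) return(empty_contacts())
  pairs <- close_pairs(apol, d_max)
  if (nrow(pairs) == 0) return(empty_contacts())
  a <- apol[pairs$i, ]
  b <- apol[pairs$j, ]
  same_res <- a$chain == b$chain & a$resno == b$resno & a$insert == b$insert
  cont <- build_contacts("hydrophobic", a[!same_res, ], b[!same_res, ],
                         pairs$d[!same_res])
  if (nrow(cont) == 0) return(cont)
  # one row per residue pair, minimum C-C distance
  key <- paste(cont$chain_a, cont$resno_a, cont$chain_b, cont$resno_b,
               sep = "\r")
  cont <- cont[order(key, cont$distance), , drop = FALSE]
  cont <- cont[!duplicated(paste(cont$chain_a, cont$resno_a, cont$chain_b,
                                 cont$resno_b, sep = "\r")), , drop = FALSE]
  rownames(cont) <- NULL
  cont
}

#' Per-loop contact report
#'
#' Runs both contact detectors and, for each loop region, tabulates the
#' contacts with at least one endpoint inside the loop (reported with the
#' loop residue as the `a` side). Loop regions must be disjoint.
#'
#' @param s a [loop_structure].
#' @param chain chain id.
#' @param loops list of disjoint [region_spec] objects.
#' @param hbond_dmax,phobic_dmax distance cutoffs passed to the detectors.
#' @param seq_sep_min passed to [detect_hbonds].
#' @return list with `per_loop` (named list of `contact_table`s) and
#'   `counts` (data frame: loop, n_hbond, n_hydrophobic).
#' @export
loop_contact_report <- function(s, chain, loops, hbond_dmax = 3.5,
                                phobic_dmax = 4.5, seq_sep_min = 2) {
  if (inherits(loops, "region_spec")) loops <- list(loops)
  nm <- vapply(loops, function(r) r$name, "")
  names(loops) <- nm
  spans <- unlist(lapply(loops, function(r) seq(r$start, r$end)))
  if (anyDuplicated(spans)) stop("loop regions overlap; spans must be disjoint")
  hb <- detect_hbonds(s, chain, d_max = hbond_dmax, seq_sep_min = seq_sep_min)
  ph <- detect_hydrophobic(s, chain, d_max = phobic_dmax)
  all_contacts <- rbind(hb, ph)
  per_loop <- lapply(loops, function(r) {
    in_a <- all_contacts$resno_a >= r$start & all_contacts$resno_a <= r$end
    in_b <- all_contacts$resno_b >= r$start & all_contacts$resno_b <= r$end
    sel <- all_contacts[in_a | in_b, , drop = FALSE]
    # orient so the loop residue is on the a side
    flip <- !(sel$resno_a >= r$start & sel$resno_a <= r$end)
    if (any(flip)) {
      tmp <- sel[flip, c("chain_b", "resno_b", "resid_b", "atom_b",
                         "chain_a", "resno_a", "resid_a", "atom_a")]
      sel[flip, c("chain_a", "resno_a", "resid_a", "atom_a",
                  "chain_b", "resno_b", "resid_b", "atom_b")] <- tmp
    }
    rownames(sel) <- NULL
    sel
  })
  counts <- data.frame(
    loop = nm,
    n_hbond = vapply(per_loop, function(x) sum(x$kind == "hbond"), 0L),
    n_hydrophobic = vapply(per_loop,
                           function(x) sum(x$kind == "hydrophobic"), 0L),
    stringsAsFactors = FALSE
  )
  rownames(counts) <- NULL
  list(per_loop = per_loop, counts = counts)
}

# ---- internals ----

chain_atoms <- function(s, chain, include_het = FALSE) {
  stopifnot(inherits(s, "loop_structure"))
  at <- s$atoms
  if (!include_het) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms in chain ", paste(chain, collapse = ","))
  # collapse altlocs for geometry
  at <- at[order(at$chain, at$resno, at$insert, at$elety, -at$o, at$alt), ,
           drop = FALSE]
  at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")), ,
     drop = FALSE]
}

# all index pairs (i < j) within d_max, grid-free distance matrix approach
close_pairs <- function(at, d_max) {
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  d[lower.tri(d, diag = TRUE)] <- Inf
  idx <- which(d <= d_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  }
  data.frame(i = idx[, 1], j = idx[, 2], d = d[idx])
}

res_key <- function(df) paste(df$chain, sprintf("%06d", df$resno), df$insert)

build_contacts <- function(kind, a, b, d) {
  if (nrow(a) == 0) return(empty_contacts())
  # canonical order: smaller residue key first (atom name as tiebreak)
  swap <- res_key(a) > res_key(b) |
    (res_key(a) == res_key(b) & a$elety > b$elety)
  a2 <- a; b2 <- b
  a2[swap, ] <- b[swap, ]
  b2[swap, ] <- a[swap, ]
  out <- data.frame(
    kind = kind,
    chain_a = a2$chain, resno_a = a2$resno, resid_a = a2$resid,
    atom_a = a2$elety,
    chain_b = b2$chain, resno_b = b2$resno, resid_b = b2$resid,
    atom_b = b2$elety,
    distance = d, stringsAsFactors = FALSE
  )
  out <- out[!duplicated(out[, c("chain_a", "resno_a", "atom_a",
                                 "chain_b", "resno_b", "atom_b")]), ,
             drop = FALSE]
  out <- out[order(out$chain_a, out$resno_a, out$atom_a, out$chain_b,
                   out$resno_b, out$atom_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_table", "data.frame")
  out
}

empty_contacts <- function() {
  out <- data.frame(
    kind = character(0), chain_a = character(0), resno_a = integer(0),
    resid_a = character(0), atom_a = character(0), chain_b = character(0),
    resno_b = integer(0), resid_b = character(0), atom_b = character(0),
    distance = numeric(0), stringsAsFactors = FALSE
  )
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Does a contact table contain a given residue pair?
#'
#' Convenience membership test (order-insensitive) for qualitative checks
#' such as "Glu317 contacts Lys370".
#'
#' @param contacts a `contact_table`.
#' @param resno_a,resno_b author residue numbers of the pair.
#' @return `TRUE` if any contact joins the two residues.
#' @export
has_contact <- function(contacts, resno_a, resno_b) {
  any((contacts$resno_a == resno_a & contacts$resno_b == resno_b) |
      (contacts$resno_a == resno_b & contacts$resno_b == resno_a))
}
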