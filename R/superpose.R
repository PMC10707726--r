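#' Optimal rigid-body (Kabsch) superposition
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' root-mean-square deviation of `R P + t` onto `Q` over all rigid
#' transforms, by singular value decomposition of the cross-covariance
#' matrix with the determinant correction that excludes reflections.
#'
#' @param P,Q numeric `n x 3` coordinate matrices of paired points
#'   (`n >= 3`, not all collinear).
#' @return An object of class `superposition`: list with `rotation`
#'   (3x3 proper rotation), `translation` (length-3 vector), `rmsd`
#'   (angstrom over kept pairs), `kept_mask` (logical per pair, here all
#'   `TRUE`) and `n_cycles_run` (0 for a plain fit).
#' @export
kabsch_fit <- function(P, Q) {
  P <- as_coord_matrix(P)
  Q <- as_coord_matrix(Q)
  if (nrow(P) != nrow(Q)) {
    stop("pairing error: ", nrow(P), " vs ", nrow(Q), " points")
  }
  n <- nrow(P)
  if (n < 3) stop("fit error: need at least 3 paired points, got ", n)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp)
  Q0 <- sweep(Q, 2, cq)
  if (is_collinear(P0) || is_collinear(Q0)) {
    stop("fit error: degenerate (collinear) point set")
  }
  H <- crossprod(P0, Q0)               # sum_i p0_i q0_i^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- as.vector(cq - R %*% cp)
  moved <- P %*% t(R)
  moved <- sweep(moved, 2, tvec, "+")
  rms <- sqrt(sum((moved - Q)^2) / n)
  structure(
    list(rotation = R, translation = tvec, rmsd = rms,
         kept_mask = rep(TRUE, n), n_cycles_run = 0L),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf(
    "<superposition> rmsd %.4f A over %d/%d pairs (%d refinement cycle%s)\n",
    x$rmsd, sum(x$kept_mask), length(x$kept_mask), x$n_cycles_run,
    if (x$n_cycles_run == 1) "" else "s"))
  invisible(x)
}

as_coord_matrix <- function(X) {
  if (is.data.frame(X)) X <- coords_of(X)
  X <- as.matrix(X)
  if (ncol(X) != 3) stop("coordinates must be an n x 3 matrix")
  storage.mode(X) <- "double"
  X
}

is_collinear <- function(X0, tol = 1e-9) {
  if (nrow(X0) < 3) return(TRUE)
  sv <- svd(X0, nu = 0, nv = 0)$d
  sv[2] <= tol * max(sv[1], 1)
}

#' Apply a superposition to coordinates
#'
#' @param sup a `superposition` from [kabsch_fit] or
#'   [refine_superposition].
#' @param X `n x 3` coordinate matrix (or [select_atoms] data frame).
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(sup, X) {
  stopifnot(inherits(sup, "superposition"))
  X <- as_coord_matrix(X)
  sweep(X %*% t(sup$rotation), 2, sup$translation, "+")
}

#' Superposition with iterative outlier rejection
#'
#' Repeats \{fit on the kept pairs; drop kept pairs whose residual exceeds
#' `reject_sigma` times the root-mean-square residual of the kept pairs\}
#' until no pair is dropped or `max_cycles` is reached. The r.m.s. residual
#' is the natural scale here: residual norms of well-fitted pairs follow a
#' Maxwell distribution, whose r.m.s. bounds the bulk of the distribution,
#' so a multiplier of 2 removes only genuine outliers instead of eroding
#' the kept set cycle after cycle. This is the standard route to a
#' core r.m.s.d. that is not dominated by a few residues in an alternate
#' conformation: a whole-molecule fit between a folded- and a straight-loop
#' conformer reports the agreement of the rigid body, with the swung loop
#' residues excluded by the rejection cycles.
#'
#' @inheritParams kabsch_fit
#' @param max_cycles maximum number of fit cycles (default 5).
#' @param reject_sigma rejection multiplier on the r.m.s. residual
#'   (default 2.0).
#' @return A `superposition`; `kept_mask` records survivors, `rmsd` is over
#'   kept pairs only, `n_cycles_run` counts fits performed.
#' @export
refine_superposition <- function(P, Q, max_cycles = 5, reject_sigma = 2.0) {
  P <- as_coord_matrix(P)
  Q <- as_coord_matrix(Q)
  if (nrow(P) != nrow(Q)) {
    stop("pairing error: ", nrow(P), " vs ", nrow(Q), " points")
  }
  if (max_cycles < 0) stop("max_cycles must be >= 0")
  kept <- rep(TRUE, nrow(P))
  fit <- NULL
  cycles <- 0L
  trace <- integer(0)
  repeat {
    fit <- kabsch_fit(P[kept, , drop = FALSE], Q[kept, , drop = FALSE])
    cycles <- cycles + 1L
    trace <- c(trace, sum(kept))
    if (cycles > max_cycles) break
    resid <- sqrt(rowSums((apply_superposition(fit, P) - Q)^2))
    s <- sqrt(mean(resid[kept]^2))
    # stop once residual scatter is below coordinate precision: further
    # cycles would chase numerical noise
    if (!is.finite(s) || s < 1e-6) break
    drop <- kept & resid > reject_sigma * s
    if (!any(drop)) break
    if (sum(kept & !drop) < 3) {
      stop("refinement failure: fewer than 3 pairs would remain; ",
           "kept-pair trace: ", paste(trace, collapse = " -> "))
    }
    kept <- kept & !drop
  }
  fit$kept_mask <- kept
  fit$n_cycles_run <- cycles
  fit
}

#' Root-mean-square deviation between paired coordinates
#'
#' @inheritParams kabsch_fit
#' @param superpose if `TRUE`, fit the optimal rigid transform first
#'   ([kabsch_fit]); if `FALSE` (default) compute the plain
#'   `sqrt(mean(|p_i - q_i|^2))` of the coordinates as given.
#' @return r.m.s.d. in angstrom.
#' @export
rmsd <- function(P, Q, superpose = FALSE) {
  P <- as_coord_matrix(P)
  Q <- as_coord_matrix(Q)
  if (nrow(P) != nrow(Q)) {
    stop("pairing error: ", nrow(P), " vs ", nrow(Q), " points")
  }
  if (nrow(P) < 1) stop("need at least one pair")
  if (superpose) return(kabsch_fit(P, Q)$rmsd)
  sqrt(sum((P - Q)^2) / nrow(P))
}

#' Per-residue C-alpha displacement between two conformers
#'
#' Fits the rigid transform on the *core* C-alpha atoms only, applies it to
#' the whole chain, and reports the per-residue C-alpha distance for every
#' residue shared (by author number) between the two chains. Loop motion
#' then shows up as large displacements against a near-zero core baseline.
#'
#' @param sa,sb two [loop_structure] objects (reference and subject).
#' @param chain_a,chain_b chain ids to compare.
#' @param core region(s) ([region_spec] or list thereof) whose C-alpha
#'   atoms define the fitted frame; `NULL` means all shared residues.
#' @param exclude region(s) removed from the core (e.g. the loops, to fit
#'   on the rigid fold only).
#' @param refine if `TRUE`, use [refine_superposition] for the core fit.
#' @param ... passed to [refine_superposition].
#' @return An object of class `displacement_profile`: data frame with
#'   columns `chain`, `resno`, `resid`, `displacement` (angstrom), with the
#'   fitted `superposition` in attribute `"fit"` and unpaired residue
#'   numbers in attribute `"unpaired"`.
#' @export
displacement_profile <- function(sa, sb, chain_a, chain_b, core = NULL,
                                 exclude = NULL, refine = FALSE, ...) {
  ca_a <- chain_ca(sa, chain_a)
  ca_b <- chain_ca(sb, chain_b)
  shared <- intersect(ca_a$resno, ca_b$resno)
  unpaired <- c(setdiff(ca_a$resno, shared), setdiff(ca_b$resno, shared))
  if (length(unpaired) > 0) {
    message(length(unpaired), " unpaired residue(s) omitted from profile")
  }
  a <- ca_a[match(shared, ca_a$resno), , drop = FALSE]
  b <- ca_b[match(shared, ca_b$resno), , drop = FALSE]
  core_idx <- rep(TRUE, length(shared))
  if (!is.null(core)) {
    core_idx <- regions_mask(data.frame(chain = a$chain, resno = shared),
                             wildcard_regions(core))
  }
  if (!is.null(exclude)) {
    core_idx <- core_idx & !regions_mask(
      data.frame(chain = a$chain, resno = shared), wildcard_regions(exclude))
  }
  if (sum(core_idx) < 3) {
    stop("fit error: fewer than 3 shared core residues")
  }
  Pc <- coords_of(b)[core_idx, , drop = FALSE]
  Qc <- coords_of(a)[core_idx, , drop = FALSE]
  fit <- if (refine) refine_superposition(Pc, Qc, ...) else kabsch_fit(Pc, Qc)
  moved <- apply_superposition(fit, coords_of(b))
  disp <- sqrt(rowSums((moved - coords_of(a))^2))
  out <- data.frame(chain = a$chain, resno = shared, resid = a$resid,
                    displacement = disp, stringsAsFactors = FALSE)
  class(out) <- c("displacement_profile", "data.frame")
  attr(out, "fit") <- fit
  attr(out, "unpaired") <- unpaired
  out
}

# regions with chain forced to wildcard (pairing is by author number)
wildcard_regions <- function(regions) {
  if (inherits(regions, "region_spec")) regions <- list(regions)
  lapply(regions, function(r) region_spec(r$name, r$start, r$end, "*"))
}

chain_ca <- function(s, chain) {
  at <- s$atoms
  at <- at[at$type == "ATOM" & at$chain == chain & at$elety == "CA", ,
           drop = FALSE]
  if (nrow(at) == 0) stop("no C-alpha atoms in chain ", chain)
  whole <- region_spec("all", min(at$resno), max(at$resno), chain)
  select_atoms(s, whole, atom_names = "CA")
}
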