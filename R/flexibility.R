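#' Normalized B-factor profile
#'
#' Per-residue C-alpha B-factors converted to z-scores,
#' `z = (B - mean(B)) / sd(B)` with the population standard deviation
#' (denominator `n`), over a normalization population of either
#' each chain separately (default) or the whole structure. Per-chain
#' normalization is the default because absolute B-factors are not
#' comparable between chains refined against different datasets (overall
#' protein B can differ by a factor of two between crystals of the same
#' protein); the z-scale makes "more mobile than this molecule's average"
#' a transferable statement. If the population standard deviation is zero
#' all z-scores are defined as 0.
#'
#' @param s a [loop_structure].
#' @param scope `"chain"` (normalize each chain over itself) or
#'   `"structure"` (one population over all selected chains).
#' @param chains chain ids to include; default all protein chains.
#' @return An object of class `bfactor_profile`: data frame with columns
#'   `chain`, `resno`, `resid`, `raw_b` (angstrom^2) and `z`
#'   (dimensionless), attribute `"scope"` recording the population used.
#'   Residues without a C-alpha are omitted and listed in attribute
#'   `"gaps"`.
#' @export
normalize_bfactors <- function(s, scope = c("chain", "structure"),
                               chains = NULL) {
  stopifnot(inherits(s, "loop_structure"))
  scope <- match.arg(scope)
  if (is.null(chains)) chains <- chain_ids(s)
  at <- s$atoms
  prot <- at[at$type == "ATOM" & at$chain %in% chains, , drop = FALSE]
  if (nrow(prot) == 0) stop("empty scope: no protein atoms in chains ",
                            paste(chains, collapse = ", "))
  res_all <- prot[!duplicated(paste(prot$chain, prot$resno, prot$insert)), ,
                  drop = FALSE]
  ca <- prot[prot$elety == "CA", , drop = FALSE]
  # altloc collapse as in select_atoms: highest occupancy, then letter
  ca <- ca[order(ca$chain, ca$resno, ca$insert, -ca$o, ca$alt), , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$insert)), , drop = FALSE]
  gaps <- setdiff(paste(res_all$chain, res_all$resno, sep = ":"),
                  paste(ca$chain, ca$resno, sep = ":"))
  out <- data.frame(chain = ca$chain, resno = ca$resno, resid = ca$resid,
                    raw_b = ca$b, z = NA_real_, stringsAsFactors = FALSE)
  zscore <- function(b) {
    s <- sqrt(mean((b - mean(b))^2))   # population sd
    if (!is.finite(s) || s == 0) return(rep(0, length(b)))
    (b - mean(b)) / s
  }
  if (scope == "structure") {
    out$z <- zscore(out$raw_b)
  } else {
    for (ch in unique(out$chain)) {
      i <- out$chain == ch
      out$z[i] <- zscore(out$raw_b[i])
    }
  }
  class(out) <- c("bfactor_profile", "data.frame")
  attr(out, "scope") <- scope
  attr(out, "gaps") <- gaps
  out
}

#' Region-level flexibility call from a B-factor profile
#'
#' Mean z-score of a region and a three-way label: `"flexible"` if
#' `mean_z > threshold`, `"rigid"` if `mean_z < -threshold`, else
#' `"average"`. The default threshold of 0.5 (half a population standard
#' deviation) is a labelling convention, not a fitted value; the mean z
#' itself is the quantitative result.
#'
#' @param profile a `bfactor_profile` from [normalize_bfactors].
#' @param region a [region_spec].
#' @param threshold label threshold on `|mean_z|`, default 0.5.
#' @return list with `region`, `n` (residues used), `mean_z` and `label`.
#' @export
region_flexibility <- function(profile, region, threshold = 0.5) {
  stopifnot(inherits(profile, "bfactor_profile"),
            inherits(region, "region_spec"))
  m <- region_mask(profile, region)
  if (!any(m)) {
    stop(sprintf("region %s (%d-%d, chain %s) has no residues in profile",
                 region$name, region$start, region$end, region$chain))
  }
  mz <- mean(profile$z[m])
  label <- if (mz > threshold) "flexible" else if (mz < -threshold) "rigid"
           else "average"
  list(region = region$name, n = sum(m), mean_z = mz, label = label)
}
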