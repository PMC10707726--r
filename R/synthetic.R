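# Seeded synthetic structures with known ground truth. The generator lays
# residues on a smooth helical curve with the canonical ~3.8 A C-alpha
# spacing — realistic enough for superposition, B-factor, contact and
# pocket-geometry tests without a forcefield — and plants exactly the
# statistical features the analysis assumes: a rigid scaffold, rigid
# loops, one flexible loop with a discrete two-state swing, inflated
# B-factors in the flexible span, optional rigid-body transforms,
# outliers and hydrogen-bond pairs.

#' Specification for a synthetic structure
#'
#' Defaults mirror the TsaBgl study system: a 420-residue chain with the
#' four author-numbered loop spans of [tsabgl_loops], L3 flexible with a
#' 6-angstrom two-state swing, 0.1-angstrom per-axis coordinate noise
#' (typical positional uncertainty of a well-refined 1.5-2 angstrom
#' structure), background B-factors of 20 +/- 5 angstrom^2 and a
#' +10 angstrom^2 (two standard deviation) B-factor shift in the flexible
#' span.
#'
#' @param n_residues scaffold length.
#' @param loop_spans named list of [region_spec] loops (>= 1, disjoint,
#'   within `[1, n_residues]`).
#' @param flexible_loop name of the flexible span (must be in
#'   `loop_spans`).
#' @param swing_amplitude angstrom; peak displacement of the planted
#'   conformer swing.
#' @param noise_sigma per-axis Gaussian coordinate noise, angstrom.
#' @param loop_noise_sigma extra per-axis noise inside the flexible span.
#' @param b_background_mean,b_background_sd background per-residue
#'   B-factor distribution, angstrom^2.
#' @param b_flex_shift B-factor increment inside the flexible span.
#' @param rigid_transform optional `list(rotation = 3x3, translation =
#'   length-3)` applied to the finished structure.
#' @param outliers optional data frame (`resno`, `displacement`) of
#'   residues displaced radially by the stated amount.
#' @param planted_hbonds optional 2-column matrix/data frame of residue
#'   number pairs to bridge with a 2.9-angstrom side-chain O...O contact.
#' @param atoms `"ca"` (C-alpha trace, default) or `"cb"` (adds a
#'   C-beta).
#' @param sequence optional residue names (3-letter, recycled); default
#'   `"ALA"`.
#' @param seed integer seed; identical (spec, seed) gives identical
#'   output.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues = 420,
                           loop_spans = tsabgl_loops(),
                           flexible_loop = "L3",
                           swing_amplitude = 6,
                           noise_sigma = 0.1,
                           loop_noise_sigma = 0,
                           b_background_mean = 20,
                           b_background_sd = 5,
                           b_flex_shift = 10,
                           rigid_transform = NULL,
                           outliers = NULL,
                           planted_hbonds = NULL,
                           atoms = c("ca", "cb"),
                           sequence = "ALA",
                           seed = 1L) {
  atoms <- match.arg(atoms)
  stopifnot(n_residues >= 10, swing_amplitude >= 0, noise_sigma >= 0,
            loop_noise_sigma >= 0, b_background_sd >= 0)
  if (!flexible_loop %in% names(loop_spans)) {
    stop("flexible_loop '", flexible_loop, "' not among loop_spans")
  }
  spans <- unlist(lapply(loop_spans, function(r) seq(r$start, r$end)))
  if (anyDuplicated(spans)) stop("spec error: loop spans overlap")
  if (min(spans) < 1 || max(spans) > n_residues) {
    stop("spec error: loop spans outside [1, n_residues]")
  }
  structure(list(
    n_residues = as.integer(n_residues), loop_spans = loop_spans,
    flexible_loop = flexible_loop, swing_amplitude = swing_amplitude,
    noise_sigma = noise_sigma, loop_noise_sigma = loop_noise_sigma,
    b_background_mean = b_background_mean, b_background_sd = b_background_sd,
    b_flex_shift = b_flex_shift, rigid_transform = rigid_transform,
    outliers = outliers, planted_hbonds = planted_hbonds, atoms = atoms,
    sequence = sequence, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# deterministic template curve: helix with ~3.8 A CA-CA spacing
template_ca <- function(n) {
  i <- seq_len(n)
  theta <- i * (100 * pi / 180)
  cbind(x = 2.3 * cos(theta), y = 2.3 * sin(theta), z = 1.5 * i)
}

# radial unit vectors of the template (swing/outlier/side-chain direction)
radial_dir <- function(n) {
  i <- seq_len(n)
  theta <- i * (100 * pi / 180)
  cbind(cos(theta), sin(theta), 0)
}

# smooth arc window over the flexible span: 0 at the span edges' neighbors,
# peak = amplitude near the span centre
swing_profile <- function(spec) {
  d <- numeric(spec$n_residues)
  if (spec$swing_amplitude > 0) {
    r <- spec$loop_spans[[spec$flexible_loop]]
    k <- seq(r$start, r$end) - r$start + 1L
    L <- r$end - r$start + 1L
    d[seq(r$start, r$end)] <- spec$swing_amplitude * sin(pi * k / (L + 1))
  }
  d
}

#' Generate a synthetic structure with ground truth
#'
#' Builds one chain on the template curve, applies (in order) the planted
#' conformer swing (if `swing_amplitude > 0`), outlier displacements,
#' coordinate noise, B-factors and the rigid transform, all under one
#' seeded RNG stream.
#'
#' @param spec a [synthetic_spec].
#' @param id structure identifier.
#' @param chain chain id.
#' @param swung apply the conformer swing (default: yes whenever
#'   `swing_amplitude > 0`).
#' @return list with `structure` (a [loop_structure]) and `truth`
#'   (ground truth: `template` C-alpha coordinates, `planted_displacement`
#'   per residue, `flexible_loop`, `true_transform`, `planted_hbonds`,
#'   `seed`).
#' @export
generate_structure <- function(spec, id = "synthetic", chain = "A",
                               swung = spec$swing_amplitude > 0) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    build_synthetic(spec, id, chain, swung)
  })
}

build_synthetic <- function(spec, id, chain, swung) {
  n <- spec$n_residues
  ca <- template_ca(n)
  u <- radial_dir(n)
  planted <- if (swung) swing_profile(spec) else numeric(n)
  if (!is.null(spec$outliers)) {
    ol <- as.data.frame(spec$outliers)
    planted[ol$resno] <- planted[ol$resno] + ol$displacement
  }
  ca_true <- ca + u * planted
  sigma <- rep(spec$noise_sigma, n)
  flex <- spec$loop_spans[[spec$flexible_loop]]
  in_flex <- seq_len(n) >= flex$start & seq_len(n) <= flex$end
  sigma[in_flex] <- sqrt(sigma[in_flex]^2 + spec$loop_noise_sigma^2)
  ca_noisy <- ca_true + matrix(rnorm(3 * n), n, 3) * sigma
  b <- rnorm(n, spec$b_background_mean, spec$b_background_sd)
  b[in_flex] <- b[in_flex] + spec$b_flex_shift
  b <- pmax(b, 0.01)
  resid <- rep(bio3d::aa123(bio3d::aa321(spec$sequence)), length.out = n)
  # atom table: CA (+ optional CB), then planted side-chain oxygens
  rows <- list(atom_rows("CA", "C", ca_noisy, resid, b, chain))
  if (spec$atoms == "cb") {
    cb <- ca_noisy + 1.5 * u
    rows <- c(rows, list(atom_rows("CB", "C", cb, resid, b, chain)))
  }
  hb_pairs <- NULL
  if (!is.null(spec$planted_hbonds)) {
    hb <- as.matrix(spec$planted_hbonds)
    resid[c(hb)] <- "SER"
    for (r in seq_len(nrow(hb))) {
      ia <- hb[r, 1]
      ib <- hb[r, 2]
      og_a <- ca_noisy[ia, ] + 1.4 * u[ia, ]
      dir <- ca_noisy[ib, ] - og_a
      dir <- dir / sqrt(sum(dir^2))
      og_b <- og_a + 2.9 * dir
      rows <- c(rows, list(
        atom_rows("OG", "O", rbind(og_a), resid[ia], b[ia], chain,
                  resno = ia),
        atom_rows("OG", "O", rbind(og_b), resid[ib], b[ib], chain,
                  resno = ib)
      ))
    }
    hb_pairs <- hb
  }
  atoms <- do.call(rbind, rows)
  atoms$resid <- resid[atoms$resno]
  atoms <- atoms[order(atoms$resno, match(atoms$elety, c("N", "CA", "C", "O",
                                                         "CB", "OG"))), ]
  atoms$eleno <- seq_len(nrow(atoms))
  transform <- spec$rigid_transform
  if (!is.null(transform)) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    xyz <- sweep(xyz %*% t(transform$rotation), 2, transform$translation, "+")
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  rownames(atoms) <- NULL
  s <- loop_structure(id, atoms,
                      metadata = list(generator = "loopscape-synthetic",
                                      seed = spec$seed))
  truth <- list(template = ca, planted_displacement = planted,
                flexible_loop = spec$flexible_loop,
                true_transform = transform, planted_hbonds = hb_pairs,
                seed = spec$seed)
  list(structure = s, truth = truth)
}

atom_rows <- function(elety, elesy, xyz, resid, b, chain, resno = NULL) {
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  data.frame(
    type = "ATOM", eleno = 0L, elety = elety, alt = "",
    resid = rep(resid, length.out = n), chain = chain, resno = resno,
    insert = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1,
    b = rep(b, length.out = n), elesy = elesy, stringsAsFactors = FALSE
  )
}

#' Generate a folded/straight conformer pair
#'
#' Twin structures identical outside the flexible span (one shared noise
#' draw); inside the span, the "straight" twin is displaced along the
#' smooth swing arc with peak `swing_amplitude`. B-factors are shared and
#' inflated in the span on both twins, so flexibility profiling sees the
#' same planted signal in each.
#'
#' @param spec a [synthetic_spec].
#' @param chain chain id for both twins.
#' @return list with `folded`, `straight` (both [loop_structure]) and
#'   `truth` (as in [generate_structure]; `planted_displacement` is the
#'   exact per-residue C-alpha displacement between the twins).
#' @export
generate_conformer_pair <- function(spec, chain = "A") {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    folded <- build_synthetic(spec, "folded", chain, swung = FALSE)
    st <- folded$structure
    planted <- swing_profile(spec)
    u <- radial_dir(spec$n_residues)
    at <- st$atoms
    shift <- u[at$resno, , drop = FALSE] * planted[at$resno]
    at$x <- at$x + shift[, 1]
    at$y <- at$y + shift[, 2]
    at$z <- at$z + shift[, 3]
    straight <- loop_structure("straight", at, st$metadata)
    truth <- folded$truth
    truth$planted_displacement <- planted
    list(folded = folded$structure, straight = straight, truth = truth)
  })
}

#' Generate a synthetic homolog family with planted loop variation
#'
#' Builds a reference sequence with defined loop spans, then mutated
#' homologs with planted insertions/deletions inside named loops and
#' planted invariant columns, together with the truth table the
#' sequence-comparison stage should recover.
#'
#' @param n_species number of homologs (including the reference).
#' @param n_residues reference sequence length.
#' @param loops named list of [region_spec] loops on the reference
#'   numbering; default four short loops.
#' @param loop_offsets named list, one entry per non-reference species,
#'   each a named numeric vector of per-loop length offsets (positive =
#'   insertion at the loop midpoint, negative = deletion).
#' @param invariant_columns reference positions never mutated in any
#'   homolog.
#' @param mutation_rate per-position substitution probability outside
#'   invariant columns.
#' @param seed integer seed.
#' @return list with `seqs` (named character vector; first element is the
#'   reference `REF`), `loops`, `truth` (data frame: species, loop,
#'   expected_length), `invariant_columns`, `seed`.
#' @export
generate_family <- function(n_species = 6, n_residues = 160,
                            loops = list(
                              L1 = region_spec("L1", 20, 33),
                              L2 = region_spec("L2", 60, 68),
                              L3 = region_spec("L3", 95, 120),
                              L4 = region_spec("L4", 135, 153)),
                            loop_offsets = NULL,
                            invariant_columns = integer(0),
                            mutation_rate = 0.1,
                            seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  spans <- unlist(lapply(loops, function(r) seq(r$start, r$end)))
  if (anyDuplicated(spans) || max(spans) > n_residues) {
    stop("spec error: loop spans overlap or exceed sequence length")
  }
  for (off in loop_offsets) {
    for (nm in names(off)) {
      r <- loops[[nm]]
      if ((r$end - r$start + 1) + off[[nm]] < 0) {
        stop("spec error: offset makes loop ", nm, " negative-length")
      }
    }
  }
  with_seed(seed, {
    ref <- sample(aa, n_residues, replace = TRUE)
    species <- c("REF", paste0("SP", seq_len(max(0, n_species - 1))))
    seqs <- list(REF = paste(ref, collapse = ""))
    truth <- list()
    for (sp in species) {
      offs <- if (sp == "REF") NULL else loop_offsets[[sp]]
      offset_of <- function(nm) {
        k <- suppressWarnings(as.integer(offs[nm]))
        if (length(k) == 0 || is.na(k)) 0L else k
      }
      for (nm in names(loops)) {
        r <- loops[[nm]]
        len <- r$end - r$start + 1L
        truth[[length(truth) + 1]] <- data.frame(
          species = sp, loop = nm,
          expected_length = len + offset_of(nm),
          stringsAsFactors = FALSE)
      }
      if (sp == "REF") next
      sv <- ref
      mut <- runif(n_residues) < mutation_rate
      mut[invariant_columns] <- FALSE
      sv[mut] <- vapply(which(mut), function(i) sample(setdiff(aa, sv[i]), 1),
                        "")
      # apply indels loop by loop, from the C-terminal side so earlier
      # coordinates stay valid
      ord <- order(vapply(loops, function(r) r$start, 0), decreasing = TRUE)
      for (nm in names(loops)[ord]) {
        k <- offset_of(nm)
        if (k == 0) next
        r <- loops[[nm]]
        mid <- floor((r$start + r$end) / 2)
        if (k > 0) {
          ins <- sample(aa, k, replace = TRUE)
          sv <- append(sv, ins, after = mid)
        } else {
          drop <- seq(mid, mid - k - 1)
          sv <- sv[-drop]
        }
      }
      seqs[[sp]] <- paste(sv, collapse = "")
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(seqs = unlist(seqs), loops = loops, truth = truth,
         invariant_columns = invariant_columns, seed = seed)
  })
}
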