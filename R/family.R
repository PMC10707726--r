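# Sequence-level loop comparison across homologs. The aligner is a plain
# affine-gap Needleman-Wunsch: the loop-mapping task is strictly pairwise
# (reference -> target), so no multiple-alignment engine is needed.

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 table (as distributed with Biostrings), used as
#' the default scoring matrix for [global_align].
#'
#' @return integer matrix with amino-acid single-letter row/column names.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment under an affine gap model in which a
#' gap of length `L` costs `gap_open + L * gap_extend`. Traceback ties are
#' broken deterministically, preferring diagonal over up (gap in `b`) over
#' left (gap in `a`).
#'
#' @param a,b amino-acid strings over the 20-letter alphabet plus `X`.
#' @param matrix substitution matrix (default [blosum62]).
#' @param gap_open,gap_extend gap penalties (positive numbers);
#'   `gap_open >= gap_extend >= 0`.
#' @return An object of class `alignment_result`: list with `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `score`, and
#'   `identity_pct` (identities over aligned columns, excluding columns
#'   that are gaps in both, times 100).
#' @export
global_align <- function(a, b, matrix = blosum62(), gap_open = 10,
                         gap_extend = 0.5) {
  if (gap_open < gap_extend || gap_extend < 0) {
    stop("need gap_open >= gap_extend >= 0")
  }
  av <- split_seq(a)
  bv <- split_seq(b)
  bad <- setdiff(c(av, bv), rownames(matrix))
  if (length(bad) > 0) {
    stop("illegal character(s) for substitution matrix: ",
         paste(unique(bad), collapse = ", "))
  }
  n <- length(av)
  m <- length(bv)
  if (n == 0 && m == 0) {
    return(new_alignment("", "", 0))
  }
  if (n == 0 || m == 0) {
    gaps <- strrep("-", max(n, m))
    sc <- -(gap_open + max(n, m) * gap_extend)
    if (n == 0) return(new_alignment(gaps, paste(bv, collapse = ""), sc))
    return(new_alignment(paste(av, collapse = ""), gaps, sc))
  }
  NEG <- -.Machine$double.xmax / 4
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  # pointer codes: 1 = from M, 2 = from Ix, 3 = from Iy
  pM <- pIx <- pIy <- matrix(0L, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    Ix[i + 1, 1] <- -(gap_open + i * gap_extend)
    pIx[i + 1, 1] <- 2L
  }
  pIx[2, 1] <- 1L
  for (j in seq_len(m)) {
    Iy[1, j + 1] <- -(gap_open + j * gap_extend)
    pIy[1, j + 1] <- 3L
  }
  pIy[1, 2] <- 1L
  open_cost <- gap_open + gap_extend
  for (i in seq_len(n)) {
    srow <- matrix[av[i], bv]
    for (j in seq_len(m)) {
      # match state: best predecessor, ties prefer M > Ix > Iy
      cand <- c(M[i, j], Ix[i, j], Iy[i, j])
      k <- which.max(cand)
      M[i + 1, j + 1] <- cand[k] + srow[j]
      pM[i + 1, j + 1] <- k
      # gap in b (consume a_i)
      cand <- c(M[i, j + 1] - open_cost, Ix[i, j + 1] - gap_extend,
                Iy[i, j + 1] - open_cost)
      k <- which.max(cand)
      Ix[i + 1, j + 1] <- cand[k]
      pIx[i + 1, j + 1] <- k
      # gap in a (consume b_j)
      cand <- c(M[i + 1, j] - open_cost, Ix[i + 1, j] - open_cost,
                Iy[i + 1, j] - gap_extend)
      k <- which.max(cand)
      Iy[i + 1, j + 1] <- cand[k]
      pIy[i + 1, j + 1] <- k
    }
  }
  finals <- c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  state <- which.max(finals)
  score <- finals[state]
  # traceback
  ga <- character(0)
  gb <- character(0)
  i <- n
  j <- m
  while (i > 0 || j > 0) {
    if (state == 1) {
      prev <- pM[i + 1, j + 1]
      ga <- c(av[i], ga); gb <- c(bv[j], gb)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      prev <- pIx[i + 1, j + 1]
      ga <- c(av[i], ga); gb <- c("-", gb)
      i <- i - 1
    } else {
      prev <- pIy[i + 1, j + 1]
      ga <- c("-", ga); gb <- c(bv[j], gb)
      j <- j - 1
    }
    state <- prev
  }
  new_alignment(paste(ga, collapse = ""), paste(gb, collapse = ""), score)
}

new_alignment <- function(aligned_a, aligned_b, score) {
  ca <- split_seq(aligned_a)
  cb <- split_seq(aligned_b)
  cols <- !(ca == "-" & cb == "-")
  ident <- if (any(cols)) {
    100 * sum(ca[cols] == cb[cols] & ca[cols] != "-") / sum(cols)
  } else {
    NA_real_
  }
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = score, identity_pct = ident),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment> score", format(x$score), "identity",
      sprintf("%.1f%%", x$identity_pct), "\n")
  cat(" a:", x$aligned_a, "\n b:", x$aligned_b, "\n")
  invisible(x)
}

split_seq <- function(s) {
  s <- toupper(as.character(s)[1])
  if (nchar(s) == 0) return(character(0))
  strsplit(s, "")[[1]]
}

#' Map reference loop regions onto a target sequence
#'
#' Projects each reference loop's aligned column interval onto the target
#' sequence of a pairwise alignment and tabulates the mapped span, length
#' and net formal charge per loop — the machinery behind loop-length
#' comparison across a homolog family.
#'
#' @param reference_seq reference amino-acid string.
#' @param reference_loops list of [region_spec] loops in reference author
#'   numbering.
#' @param target_seq target amino-acid string.
#' @param aln optional precomputed [global_align] result for
#'   (reference, target); computed if omitted.
#' @param ref_start author number of the first residue of
#'   `reference_seq` (default 1).
#' @param target_start author number of the first residue of the target
#'   (default 1).
#' @param species_tag label for the target rows.
#' @param ... passed to [global_align].
#' @return data frame with one row per loop: `species_tag`, `loop`,
#'   `start`, `end` (mapped target author numbers, `NA` if unmappable),
#'   `length` (non-gap target positions in the loop interval; 0 =
#'   unmappable), `net_charge`, `mappable`.
#' @export
map_loops <- function(reference_seq, reference_loops, target_seq, aln = NULL,
                      ref_start = 1, target_start = 1,
                      species_tag = "target", ...) {
  if (inherits(reference_loops, "region_spec")) {
    reference_loops <- list(reference_loops)
  }
  if (is.null(aln)) aln <- global_align(reference_seq, target_seq, ...)
  ra <- split_seq(aln$aligned_a)
  ta <- split_seq(aln$aligned_b)
  stopifnot(length(ra) == length(ta))
  # author number of the reference residue at each column (NA at gaps)
  ref_no <- ifelse(ra == "-", NA_integer_,
                   cumsum(ra != "-") + ref_start - 1L)
  tgt_no <- ifelse(ta == "-", NA_integer_,
                   cumsum(ta != "-") + target_start - 1L)
  rows <- lapply(reference_loops, function(r) {
    cols <- which(!is.na(ref_no) & ref_no >= r$start & ref_no <= r$end)
    if (length(cols) == 0) {
      stop(sprintf("loop %s (%d-%d) outside reference numbering",
                   r$name, r$start, r$end))
    }
    interval <- seq(min(cols), max(cols))
    tgt_in <- tgt_no[interval]
    tgt_in <- tgt_in[!is.na(tgt_in)]
    if (length(tgt_in) == 0) {
      return(data.frame(species_tag = species_tag, loop = r$name,
                        start = NA_integer_, end = NA_integer_, length = 0L,
                        net_charge = 0L, mappable = FALSE,
                        stringsAsFactors = FALSE))
    }
    sub <- paste(ta[interval][ta[interval] != "-"], collapse = "")
    data.frame(species_tag = species_tag, loop = r$name,
               start = min(tgt_in), end = max(tgt_in),
               length = length(tgt_in),
               net_charge = loop_charge(sub), mappable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan sequences for a positional motif
#'
#' Matches a pattern of fixed residues and `x` wildcards (e.g. the
#' conserved L4 signature `WxxxDNxEWxxGxxxxFG`, which fixes 8 of its 18
#' positions) against each sequence at every offset. A sequence matches if
#' some window satisfies every fixed position; otherwise the best window
#' (fewest mismatches, leftmost) is reported with its mismatching fixed
#' positions.
#'
#' @param seqs named character vector of amino-acid strings.
#' @param pattern pattern string over residue letters and `x`.
#' @return data frame: `name`, `match` (logical), `offset` (1-based start
#'   of the matched/best window, `NA` if the pattern does not fit),
#'   `n_mismatch`, `mismatch_positions` (comma-separated pattern
#'   positions), `reason` for non-matches.
#' @export
motif_scan <- function(seqs, pattern) {
  pat <- split_seq(pattern)
  fixed <- which(pat != "X")
  n_fixed <- length(fixed)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  rows <- lapply(names(seqs), function(nm) {
    sv <- split_seq(seqs[[nm]])
    L <- length(sv)
    if (L < length(pat)) {
      return(data.frame(name = nm, match = FALSE, offset = NA_integer_,
                        n_mismatch = NA_integer_,
                        mismatch_positions = "",
                        reason = "pattern longer than sequence",
                        stringsAsFactors = FALSE))
    }
    best <- NULL
    for (off in seq_len(L - length(pat) + 1)) {
      win <- sv[off + fixed - 1]
      mm <- fixed[win != pat[fixed]]
      if (is.null(best) || length(mm) < length(best$mm)) {
        best <- list(off = off, mm = mm)
        if (length(mm) == 0) break
      }
    }
    data.frame(name = nm, match = length(best$mm) == 0, offset = best$off,
               n_mismatch = length(best$mm),
               mismatch_positions = paste(best$mm, collapse = ","),
               reason = if (length(best$mm) == 0) "" else "fixed-position mismatch",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-column conservation of an aligned set
#'
#' Fraction of sequences carrying the most common non-gap residue in each
#' column of an equal-length (aligned) set.
#'
#' @param seqs character vector of equal-length (gapped) sequences.
#' @return numeric vector, one fraction per column (0 for all-gap
#'   columns).
#' @export
conservation_profile <- function(seqs) {
  if (length(seqs) == 0) stop("empty sequence set")
  if (length(unique(nchar(seqs))) != 1) {
    stop("sequences must be aligned to equal length")
  }
  mat <- do.call(rbind, lapply(seqs, split_seq))
  apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return(0)
    max(table(col)) / nrow(mat)
  })
}

#' Read / write FASTA sequence sets
#'
#' Thin wrappers over Biostrings returning/accepting plain named character
#' vectors, the sequence representation used throughout this package.
#'
#' @param path FASTA file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
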