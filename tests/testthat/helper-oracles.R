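# Independent oracles used to freeze expected values. These deliberately do
# not share code with the package implementations they check.

# -- rotation-grid oracle ----------------------------------------------------

# n uniformly distributed proper rotations via random unit quaternions
random_rotations <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # rows of the 3x3 rotation, flattened row-major per rotation
  cbind(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  )
}

# minimum rmsd of R %*% P + t onto Q over a set of sampled rotations, with
# the translation handled in closed form (centroid matching). Uses
# |Q0 - R P0|^2 = |P0|^2 + |Q0|^2 - 2 tr(R H), H = t(P0) Q0.
grid_min_rmsd <- function(P, Q, rot_flat) {
  n <- nrow(P)
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  H <- crossprod(P0, Q0)
  const <- sum(P0^2) + sum(Q0^2)
  # tr(R H) = sum over entries of R * t(H); R stored row-major
  tr <- rot_flat %*% as.vector(t(H))
  sqrt(pmax(const - 2 * max(tr), 0) / n)
}

# a random proper rotation matrix
random_rotation_matrix <- function() {
  matrix(random_rotations(1), 3, 3, byrow = TRUE)
}

# -- alignment enumeration oracle --------------------------------------------

# score of a fully gapped alignment under gap(L) = open + L * ext
score_gapped <- function(ga, gb, mat, open, ext) {
  s <- 0
  in_gap_a <- FALSE
  in_gap_b <- FALSE
  for (k in seq_along(ga)) {
    if (ga[k] == "-") {
      s <- s - ext - (!in_gap_a) * open
      in_gap_a <- TRUE
      in_gap_b <- FALSE
    } else if (gb[k] == "-") {
      s <- s - ext - (!in_gap_b) * open
      in_gap_b <- TRUE
      in_gap_a <- FALSE
    } else {
      s <- s + mat[ga[k], gb[k]]
      in_gap_a <- FALSE
      in_gap_b <- FALSE
    }
  }
  s
}

# maximum score over all global alignments, by exhaustive enumeration of
# every monotone path (no dynamic programming)
enum_best_score <- function(a, b, mat, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, ga, gb) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score_gapped(ga, gb, mat, open, ext))
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, c(ga, av[i]), c(gb, bv[j]))
    }
    if (i <= length(av)) rec(i + 1, j, c(ga, av[i]), c(gb, "-"))
    if (j <= length(bv)) rec(i, j + 1, c(ga, "-"), c(gb, bv[j]))
  }
  rec(1, 1, character(0), character(0))
  best
}

# -- small structure builders ------------------------------------------------

# a loop_structure from explicit atom rows; defaults give a protein atom
make_atoms <- function(elety, x, y, z, resno, resid = "GLY", chain = "A",
                       elesy = substr(elety, 1, 1), b = 10, o = 1,
                       alt = "", insert = "", type = "ATOM") {
  n <- length(x)
  data.frame(type = rep(type, length.out = n), eleno = seq_len(n),
             elety = rep(elety, length.out = n),
             alt = rep(alt, length.out = n),
             resid = rep(resid, length.out = n),
             chain = rep(chain, length.out = n),
             resno = rep(resno, length.out = n),
             insert = rep(insert, length.out = n),
             x = x, y = y, z = z, o = rep(o, length.out = n),
             b = rep(b, length.out = n),
             elesy = rep(elesy, length.out = n), stringsAsFactors = FALSE)
}

make_structure <- function(..., id = "test") {
  atoms <- do.call(rbind, list(...))
  atoms$eleno <- seq_len(nrow(atoms))
  loop_structure(id, atoms)
}

# C-alpha coordinates of a chain as a plain matrix
ca_coords <- function(s, chain = "A") {
  at <- s$atoms
  at <- at[at$type == "ATOM" & at$chain == chain & at$elety == "CA", ]
  as.matrix(at[order(at$resno), c("x", "y", "z")])
}
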