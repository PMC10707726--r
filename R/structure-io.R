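#' Read a coordinate file into the hierarchical model
#'
#' Parses a PDB (or mmCIF) file into a [loop_structure]. All ATOM and
#' HETATM records are retained, including alternate locations; altlocs are
#' collapsed only at selection time ([select_atoms]), so the parsed model
#' preserves file fidelity. Format parsing is delegated to bio3d.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param id entry identifier; defaults to the file name without extension.
#' @return A [loop_structure].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read '", path, "': no such file")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, cif = "cif", mmcif = "cif", pdb = "pdb", ent = "pdb",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  raw <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("failed to parse '", path, "' as ", format, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- raw$atom
  atoms <- data.frame(
    type = at$type, eleno = at$eleno, elety = at$elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    resid = at$resid, chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    elesy = ifelse(is.na(at$elesy), guess_element(at$elety), at$elesy),
    stringsAsFactors = FALSE
  )
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  loop_structure(id, atoms, metadata = list(source = path, format = format))
}

guess_element <- function(elety) {
  sub("^([A-Za-z]).*$", "\\1", trimws(elety))
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM/HETATM records that re-parse to an equal model
#' (coordinates to 3 decimals, B-factors and occupancies to 2, the fixed
#' precision of the format).
#'
#' @param s a [loop_structure].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "loop_structure"))
  at <- s$atoms
  if (nrow(at) == 0) {
    ok <- tryCatch({writeLines("END", path); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop("cannot write '", path, "'")
    return(invisible(path))
  }
  tryCatch(
    bio3d::write.pdb(
      pdb = NULL, file = path,
      xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
      type = at$type, resno = at$resno, resid = at$resid,
      eleno = at$eleno, elety = at$elety, chain = at$chain,
      insert = ifelse(at$insert == "", NA, at$insert),
      alt = ifelse(at$alt == "", NA, at$alt),
      o = at$o, b = at$b, elesy = at$elesy
    ),
    error = function(e) stop("cannot write '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' Select atoms by region and atom name
#'
#' Resolves a [region_spec] against a structure and returns one row per
#' (residue, requested atom name) present, in residue order. Alternate
#' locations are collapsed deterministically: the highest-occupancy altloc
#' wins, ties broken by altloc letter order. Heteroatom (HETATM) records
#' are excluded unless `include_het = TRUE`.
#'
#' @param s a [loop_structure].
#' @param region a [region_spec]; its chain field (or `chain` below)
#'   selects the chain.
#' @param atom_names character vector of atom labels, default `"CA"`.
#' @param chain optional chain id overriding `region$chain`.
#' @param include_het include HETATM records.
#' @return data frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety`, `x`, `y`, `z`, `b`, `o`. Residues in the span lacking a
#'   requested atom are skipped and reported via a warning.
#' @export
select_atoms <- function(s, region, atom_names = "CA", chain = NULL,
                         include_het = FALSE) {
  stopifnot(inherits(s, "loop_structure"), inherits(region, "region_spec"))
  at <- s$atoms
  if (!include_het) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) {
    region <- region_spec(region$name, region$start, region$end, chain)
  }
  m <- region_mask(at, region)
  sel <- at[m & at$elety %in% atom_names, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop(sprintf("empty selection: region %s (%d-%d) on chain %s",
                 region$name, region$start, region$end, region$chain))
  }
  # collapse altlocs: per (chain, resno, insert, elety) keep highest
  # occupancy, ties by altloc letter order ("" sorts first)
  key <- paste(sel$chain, sel$resno, sel$insert, sel$elety, sep = "\r")
  ord <- order(match(key, unique(key)), -sel$o, sel$alt)
  sel <- sel[ord, , drop = FALSE]
  sel <- sel[!duplicated(paste(sel$chain, sel$resno, sel$insert, sel$elety,
                               sep = "\r")), , drop = FALSE]
  # restore residue order, insertion codes alphabetical after bare number
  sel <- sel[order(sel$chain, sel$resno, sel$insert,
                   match(sel$elety, atom_names)), , drop = FALSE]
  # report residues present in span but lacking a requested atom
  span <- at[m, , drop = FALSE]
  have <- unique(paste(sel$chain, sel$resno, sel$insert, sep = "\r"))
  all_res <- unique(paste(span$chain, span$resno, span$insert, sep = "\r"))
  missed <- setdiff(all_res, have)
  if (length(missed) > 0) {
    warning(length(missed), " residue(s) in region ", region$name,
            " lack requested atom(s) and were skipped: ",
            paste(gsub("\r", ":", head(missed, 5)), collapse = ", "),
            if (length(missed) > 5) ", ..." else "")
  }
  rownames(sel) <- NULL
  sel[, c("chain", "resno", "insert", "resid", "elety", "x", "y", "z",
          "b", "o")]
}

# coordinate matrix (n x 3) from a select_atoms result
coords_of <- function(sel) {
  as.matrix(sel[, c("x", "y", "z"), drop = FALSE])
}

#' One-letter sequence of a chain
#'
#' @param s a [loop_structure].
#' @param chain chain id.
#' @return named character vector of one-letter codes, names are author
#'   residue numbers. Non-standard residues become `"X"`.
#' @export
chain_sequence <- function(s, chain) {
  at <- s$atoms
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no protein residues in chain ", chain)
  res <- at[!duplicated(paste(at$resno, at$insert)), , drop = FALSE]
  aa <- bio3d::aa321(res$resid)
  aa[is.na(aa) | !aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  setNames(aa, res$resno)
}

#' Summarize a structure's contents
#'
#' @param s a [loop_structure].
#' @return data frame with one row per protein chain: chain id, number of
#'   residues, first and last author residue number, atom count.
#' @export
inspect_structure <- function(s) {
  stopifnot(inherits(s, "loop_structure"))
  prot <- s$atoms[s$atoms$type == "ATOM", , drop = FALSE]
  chains <- chain_ids(s)
  out <- do.call(rbind, lapply(chains, function(ch) {
    res <- prot[prot$chain == ch, , drop = FALSE]
    data.frame(chain = ch,
               n_residues = length(unique(paste(res$resno, res$insert))),
               first = min(res$resno), last = max(res$resno),
               n_atoms = nrow(res), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
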