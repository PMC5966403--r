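# Multi-model PDB input/output for stem-loop ensembles.  The reader is
# a focused fixed-width parser for ATOM/MODEL/ENDMDL records: the
# ensemble contract requires per-model atom-roster validation with
# errors that name the offending model and atom, which generic readers
# do not report.

pdbAtomName <- function(name) {
  # normalise prime dialects: C1* and C1' both mean the ribose C1'
  gsub("\\*", "'", trimws(name))
}

#' Read a (multi-model) PDB file into a HairpinEnsemble
#'
#' Parses `MODEL`/`ENDMDL` blocks (a file without `MODEL` records is
#' read as a single-model ensemble).  Atom-name dialects `C1'` and
#' `C1*` are accepted and normalised to the prime convention.  For
#' atoms with alternate locations, the highest-occupancy altloc is
#' kept.  Hydrogens are retained in the roster (selections decide what
#' to use); chain identifiers are ignored (single-chain convention).
#' All models must share an identical atom roster; a mismatch is an
#' error naming the model and atom.
#'
#' @param path PDB file path.
#' @return a [HairpinEnsemble-class] object.
#' @seealso [writeEnsemblePDB()], [pairwiseBundleRmsd()]
#' @export
readEnsemblePDB <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  isModel <- startsWith(rec, "MODEL")
  isEnd <- startsWith(rec, "ENDMDL")
  isAtom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(isAtom)) stop("no ATOM records in ", path)

  modelId <- cumsum(isModel)
  if (!any(isModel)) modelId <- rep(1L, length(lines))
  atomLines <- lines[isAtom]
  atomModel <- modelId[isAtom]
  models <- split(atomLines, atomModel)

  parseModel <- function(ls) {
    df <- data.frame(
      atom = pdbAtomName(substr(ls, 13, 16)),
      altloc = trimws(substr(ls, 17, 17)),
      resname = trimws(substr(ls, 18, 20)),
      residue = as.integer(substr(ls, 23, 26)),
      x = as.numeric(substr(ls, 31, 38)),
      y = as.numeric(substr(ls, 39, 46)),
      z = as.numeric(substr(ls, 47, 54)),
      occ = suppressWarnings(as.numeric(substr(ls, 55, 60))),
      element = trimws(substr(ls, 77, 78)),
      stringsAsFactors = FALSE
    )
    if (anyNA(df$residue) || anyNA(df$x))
      stop("malformed ATOM record in ", path)
    # altloc: keep highest occupancy per (residue, atom)
    if (any(nzchar(df$altloc))) {
      df$occ[is.na(df$occ)] <- 1
      ord <- order(df$residue, df$atom, -df$occ)
      df <- df[ord, ]
      df <- df[!duplicated(df[, c("residue", "atom")]), ]
      df <- df[order(df$residue, match(df$atom, unique(df$atom))), ]
    }
    if (!all(nzchar(df$element)))
      df$element <- ifelse(nzchar(df$element), df$element,
                           substr(gsub("[^A-Za-z]", "", df$atom), 1, 1))
    df
  }

  parsed <- lapply(models, parseModel)
  ref <- parsed[[1]]
  refKey <- paste(ref$residue, ref$atom)
  for (i in seq_along(parsed)[-1]) {
    key <- paste(parsed[[i]]$residue, parsed[[i]]$atom)
    miss <- setdiff(refKey, key)
    extra <- setdiff(key, refKey)
    if (length(miss) || length(extra))
      stop("inconsistent atom roster in model ", i,
           if (length(miss)) paste0(": missing atom(s) ",
                                    paste(miss, collapse = ", ")),
           if (length(extra)) paste0(": extra atom(s) ",
                                     paste(extra, collapse = ", ")))
    parsed[[i]] <- parsed[[i]][match(refKey, key), ]
  }

  nAtoms <- nrow(ref)
  coords <- array(NA_real_, c(nAtoms, 3, length(parsed)))
  for (i in seq_along(parsed))
    coords[, , i] <- as.matrix(parsed[[i]][, c("x", "y", "z")])

  masses <- ATOM_MASSES[toupper(ref$element)]
  masses[is.na(masses)] <- 1.008  # hydrogens and unknowns
  atoms <- data.frame(residue = ref$residue, resname = ref$resname,
                      atom = ref$atom, element = toupper(ref$element),
                      mass = unname(masses), stringsAsFactors = FALSE)
  # re-base residue numbering at 1 if needed (chain-agnostic contract)
  atoms$residue <- atoms$residue - min(atoms$residue) + 1L
  new("HairpinEnsemble", coords = coords, atoms = atoms,
      metadata = list(source = path))
}

#' Write a HairpinEnsemble as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame; atom names use the prime
#' convention (`C1'`).  Coordinates are written at the standard PDB
#' precision of 0.001 Angstrom.
#'
#' @param ensemble a [HairpinEnsemble-class] object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEnsemblePDB <- function(ensemble, path) {
  stopifnot(methods::is(ensemble, "HairpinEnsemble"))
  a <- ensemble@atoms
  nA <- nrow(a)
  con <- file(path, "w")
  on.exit(close(con))
  atomField <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom),
                      substr(a$atom, 1, 4))
  for (f in seq_len(nFrames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ensemble@coords[, , f]
    writeLines(sprintf(
      "ATOM  %5d %s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nA), atomField, a$resname, a$residue,
      xyz[, 1], xyz[, 2], xyz[, 3], a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
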