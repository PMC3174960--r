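#' @include AllClasses.R
NULL

.BACKBONE <- c("N", "CA", "C", "O")
.AMIDE_H <- c("H", "HN")

.parseHeaderPDB <- function(lines) {
  res <- NA_real_
  rf <- NA_real_
  m <- regmatches(lines, regexec(
    "^REMARK   2 RESOLUTION\\.\\s+([0-9]+\\.?[0-9]*)\\s+ANGSTROM", lines))
  hit <- which(lengths(m) == 2L)
  if (length(hit)) res <- as.numeric(m[[hit[1L]]][2L])
  m <- regmatches(lines, regexec(
    "^REMARK   3   R VALUE\\s+\\(WORKING SET\\)\\s*:\\s*([0-9]+\\.?[0-9]*)", lines))
  hit <- which(lengths(m) == 2L)
  if (length(hit)) rf <- as.numeric(m[[hit[1L]]][2L])
  list(resolution = res, rFactor = rf)
}

.parseHeaderCIF <- function(lines) {
  grab <- function(tag) {
    m <- regmatches(lines, regexec(
      paste0("^", tag, "\\s+([0-9]+\\.?[0-9]*)"), lines))
    hit <- which(lengths(m) == 2L)
    if (length(hit)) as.numeric(m[[hit[1L]]][2L]) else NA_real_
  }
  rf <- grab("_refine\\.ls_R_factor_R_work")
  if (is.na(rf)) rf <- grab("_refine\\.ls_R_factor_obs")
  list(resolution = grab("_refine\\.ls_d_res_high"), rFactor = rf)
}

## Keep the highest-occupancy alternate location per (chain, resno, insert,
## atom name); ties go to the alphabetically first altloc (so 'A' beats 'B').
.resolveAltlocs <- function(at) {
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$occ, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at[order(at$chain, at$resno, at$insert, match(at$elety, c(.BACKBONE, .AMIDE_H),
                                               nomatch = 99L)), , drop = FALSE]
}

#' Read a PDB or mmCIF coordinate file
#'
#' Parses coordinates through bio3d, keeping polymer (ATOM) records of the
#' first model only. Alternate locations are resolved to the
#' highest-occupancy conformer (ties to altloc 'A'), and any residue whose
#' backbone carries an atom with occupancy below 1 is flagged
#' partial-occupancy -- the flag survives resolution so the survey filter can
#' act on it. Header resolution and R-factor are captured when present
#' (REMARK 2 / REMARK 3 for PDB, the _refine category for mmCIF).
#'
#' @param path file path.
#' @param format "pdb", "cif", or "auto" (default; decided by file extension,
#'   falling back to content sniffing).
#' @param entryId entry identifier; defaults to the file name stem.
#' @return a \linkS4class{StructureModel}.
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif"),
                          entryId = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("readStructure: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else if (ext == "pdb") "pdb"
      else if (any(grepl("^data_", readLines(path, n = 5L)))) "cif" else "pdb"
  }
  if (is.null(entryId)) entryId <- tools::file_path_sans_ext(basename(path))
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    } else {
      ## read.cif warns about its beta status and absent helix/sheet records;
      ## neither affects the atom table we consume
      suppressWarnings(
        bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
    },
    error = function(e) stop("readStructure: cannot parse ", path,
                             " as ", format, ": ", conditionMessage(e)))
  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L)
    stop("readStructure: no polymer coordinates in ", path)
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  atoms <- data.frame(
    chain = as.character(at$chain), resno = as.integer(at$resno),
    insert = as.character(at$insert), resid = toupper(at$resid),
    elety = as.character(at$elety), element = as.character(at$elesy),
    x = at$x, y = at$y, z = at$z, b = at$b, occ = at$o,
    alt = as.character(at$alt), stringsAsFactors = FALSE)
  atoms <- .resolveAltlocs(atoms)
  rkey <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  bb <- atoms$elety %in% .BACKBONE
  partial <- tapply(atoms$occ[bb] < 1, rkey[bb], any)
  atoms$partialOcc <- !is.na(partial[rkey]) & partial[rkey]
  hdr <- if (format == "pdb") .parseHeaderPDB(readLines(path, warn = FALSE))
         else .parseHeaderCIF(readLines(path, warn = FALSE))
  StructureModel(atoms, entryId = entryId,
                 resolution = hdr$resolution, rFactor = hdr$rFactor)
}

#' Write a StructureModel as a PDB file
#'
#' Standard ATOM records with 3-decimal coordinates and 2-decimal B-factors,
#' so a write/read round trip reproduces coordinates to 1e-3 Angstrom.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePDB <- function(model, path) {
  a <- atomData(model)
  if (nrow(a) == 0L) stop("writePDB: empty model")
  if (nrow(a) > 99999L || any(a$resno > 9999L))
    stop("writePDB: chain exceeds PDB format limits (99999 atoms / 9999 residues)")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain, insert = a$insert,
                   alt = ifelse(nzchar(a$alt), a$alt, NA),
                   o = a$occ, b = a$b)
  invisible(path)
}

.residueIndex <- function(atoms) {
  unique(atoms[, c("chain", "resno", "insert", "resid")])
}

#' Backbone atoms of one residue
#'
#' Returns the main-chain atoms N, CA, C, O (and the amide hydrogen when the
#' entry resolves it) of the residue identified by chain/resno/insert.
#' Missing atoms are reported, never invented; a backbone name still
#' duplicated after altloc resolution is an error.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param chain chain identifier.
#' @param resno residue number.
#' @param insert insertion code, default "".
#' @return list with \code{atoms} (named list of single-row data.frames, names
#'   among N, CA, C, O, H) and \code{missing} (character vector of absent
#'   backbone names).
#' @export
backboneAtoms <- function(model, chain, resno, insert = "") {
  a <- atomData(model)
  sel <- a$chain == chain & a$resno == resno & a$insert == insert
  res <- a[sel & a$elety %in% c(.BACKBONE, .AMIDE_H), , drop = FALSE]
  out <- list()
  for (nm in .BACKBONE) {
    rows <- res[res$elety == nm, , drop = FALSE]
    if (nrow(rows) > 1L)
      stop(sprintf("backboneAtoms: duplicated %s in %s %s%s after altloc resolution",
                   nm, chain, resno, insert))
    if (nrow(rows) == 1L) out[[nm]] <- rows
  }
  h <- res[res$elety %in% .AMIDE_H, , drop = FALSE]
  if (nrow(h) >= 1L) out[["H"]] <- h[1L, , drop = FALSE]
  list(atoms = out, missing = setdiff(.BACKBONE, names(out)))
}

#' Entry-level selection gate
#'
#' Checks header-derived resolution and R-factor against the survey
#' thresholds. With \code{gateSource = "none"} (the default) every entry
#' passes: the selection is assumed done upstream by the culling service that
#' produced the entry list, as in a PISCES-style workflow.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param config a \linkS4class{FilterConfig}.
#' @return list with \code{pass} (logical) and \code{reasons} (character).
#' @export
entryPassesSelection <- function(model, config = FilterConfig()) {
  if (config@gateSource == "none") return(list(pass = TRUE, reasons = character()))
  reasons <- character()
  res <- resolutionOf(model)
  rf <- rFactorOf(model)
  if (is.na(res) || res > config@minResolution)
    reasons <- c(reasons, "resolution")
  if (is.na(rf) || rf >= config@maxRFactor)
    reasons <- c(reasons, "r_factor")
  list(pass = length(reasons) == 0L, reasons = reasons)
}
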