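## Fixture builders. Everything is generated in code; the only files on disk
## are the tiny tripeptide PDB/mmCIF pair under inst/extdata.

toyPDB <- function() system.file("extdata", "toy_tripeptide.pdb", package = "pepgeom")
toyCIF <- function() system.file("extdata", "toy_tripeptide.cif", package = "pepgeom")

## A clean n-residue poly-Ala chain with uniform geometry.
makeChain <- function(n = 5, phi = -63, psi = 148, dOmega = 0, thC = 0,
                      b = 20, entryId = "chain") {
  omega <- wrapAngle(rep(180 + dOmega, length.out = n - 1))
  omega3 <- wrapAngle(omega + 180 - rep(thC, length.out = n - 1))
  ic <- backboneInternalCoords(rep(phi, n), rep(psi, n), omega, omega3)
  m <- buildBackbone(ic, entryId = entryId)
  a <- atomData(m)
  a$b <- b
  StructureModel(a, entryId = entryId)
}

## Edit atom-table fields of selected residues and rebuild the model.
editResidues <- function(model, resno, field, value, elety = NULL) {
  a <- atomData(model)
  sel <- a$resno %in% resno
  if (!is.null(elety)) sel <- sel & a$elety %in% elety
  a[[field]][sel] <- value
  StructureModel(a, entryId = entryId(model),
                 resolution = resolutionOf(model), rFactor = rFactorOf(model))
}

## Fixed-width PDB ATOM record (columns per the format spec).
atomLine <- function(serial, name, alt, resid, chain, resno, x, y, z, occ, b) {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
          serial, name, alt, resid, chain, resno, x, y, z, occ, b,
          substr(name, 1, 1))
}

## PDB text with a CA in two alternate locations (A occ 0.6 / B occ 0.4).
writeAltlocFixture <- function(path) {
  m <- makeChain(3)
  a <- atomData(m)
  lines <- character()
  serial <- 0L
  for (i in seq_len(nrow(a))) {
    serial <- serial + 1L
    if (a$elety[i] == "CA" && a$resno[i] == 2L) {
      lines <- c(lines,
        atomLine(serial, "CA", "A", "ALA", "A", 2L, a$x[i], a$y[i], a$z[i], 0.60, 20),
        atomLine(serial + 1L, "CA", "B", "ALA", "A", 2L,
                 a$x[i] + 0.3, a$y[i], a$z[i], 0.40, 20))
      serial <- serial + 1L
    } else {
      lines <- c(lines, atomLine(serial, a$elety[i], " ", "ALA", "A",
                                 a$resno[i], a$x[i], a$y[i], a$z[i], 1, 20))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

## Two-model PDB: model 2 is model 1 shifted; only model 1 must be read.
writeTwoModelFixture <- function(path) {
  body <- grep("^ATOM", readLines(toyPDB()), value = TRUE)
  shifted <- vapply(body, function(l) {
    x <- as.numeric(substr(l, 31, 38)) + 5
    paste0(substr(l, 1, 30), sprintf("%8.3f", x), substr(l, 39, nchar(l)))
  }, character(1), USE.NAMES = FALSE)
  writeLines(c("MODEL        1", body, "ENDMDL",
               "MODEL        2", shifted, "ENDMDL", "END"), path)
  path
}

## Synthetic survey records with exact generator values, 'copies' records per
## psi grid center; delta_omega = A sin(3 psi) + offsetFun(psi).
makeRecordGrid <- function(A = 2, copies = 100, phi = -60,
                           psiCenters = seq(-165, 180, by = 15),
                           thetaCFun = function(d) d) {
  d <- rep(A * sin(3 * psiCenters * pi / 180), each = copies)
  data.frame(
    entry_id = "synthetic", chain_id = "A",
    seq_number = seq_along(d), insert = "", residue_name = "ALA",
    phi = rep(phi, length(d)), psi = rep(psiCenters, each = copies),
    omega = wrapAngle(180 + d), omega3 = 0,
    delta_omega = d, theta_C = thetaCFun(d), theta_N = NA_real_,
    b_mainchain = 20, included = TRUE, exclusion_reasons = "",
    stringsAsFactors = FALSE)
}
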