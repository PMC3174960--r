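#' @include AllClasses.R angles.R structure-io.R
NULL

#' Default covalent geometry for backbone synthesis
#'
#' Engh-Huber-style bond lengths and valence angles, the community defaults
#' for protein backbone stereochemistry. All values overridable; torsions are
#' the only degrees of freedom the generator varies.
#'
#' @return named list: bond lengths n_ca, ca_c, c_n, c_o (Angstrom) and
#'   valence angles n_ca_c, ca_c_n, c_n_ca, o_c_n, ca_c_o (degrees).
#' @export
defaultBackboneGeometry <- function() {
  list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
       n_ca_c = 111.0, ca_c_n = 117.2, c_n_ca = 121.7,
       o_c_n = 122.7, ca_c_o = 120.1)
}

#' Place an atom from internal coordinates (NeRF primitive)
#'
#' Given three placed anchor atoms a-b-c, returns the point d with
#' |d - c| = bondLength, angle(b, c, d) = bondAngle and
#' dihedral(a, b, c, d) = torsion.
#'
#' @param a,b,c numeric length-3 anchor coordinates; must not be collinear.
#' @param bondLength Angstrom, > 0.
#' @param bondAngle degrees, in (0, 180).
#' @param torsion degrees.
#' @return numeric length-3 coordinate of the new atom.
#' @export
placeAtom <- function(a, b, c, bondLength, bondAngle, torsion) {
  if (bondLength <= 0) stop("placeAtom: bondLength must be > 0")
  if (bondAngle <= 0 || bondAngle >= 180)
    stop("placeAtom: bondAngle must lie in (0, 180)")
  bc <- c - b
  nbc <- sqrt(sum(bc^2))
  if (nbc < 1e-10) stop("placeAtom: degenerate frame (b and c coincide)")
  bc <- bc / nbc
  n <- .cross3(b - a, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("placeAtom: degenerate frame (a, b, c collinear)")
  n <- n / nn
  m <- .cross3(n, bc)
  th <- .deg2rad(bondAngle)
  tau <- .deg2rad(torsion)
  d2 <- bondLength * c(-cos(th), sin(th) * cos(tau), sin(th) * sin(tau))
  c + bc * d2[1L] + m * d2[2L] + n * d2[3L]
}

## Internal-coordinate chain from backbone torsion vectors.
## phi has length n (phi[1] unused), psi length n (psi[n] orients the
## terminal carbonyl O at psi + 180), omega and omega3 length n - 1.
#' Internal coordinates from backbone torsions
#'
#' Assembles an \linkS4class{InternalCoordinates} chain with fixed covalent
#' geometry and the given torsions. The anchor frame puts N1 at the origin,
#' CA1 on +x and C1 in the xy-plane, which makes unsuperposed displacement
#' comparisons between rebuilds well defined. Peptide-bond i (between
#' residues i and i+1) contributes its omega on the CA(i+1) placement row and
#' its omega3 on the O(i) placement row, so theta-C = omega - omega3 + 180 is
#' set directly by the two torsion vectors.
#'
#' @param phi length-n vector, degrees (first element unused).
#' @param psi length-n vector, degrees (last element orients the terminal O).
#' @param omega length n-1, degrees.
#' @param omega3 length n-1, degrees.
#' @param geometry covalent geometry, see \code{\link{defaultBackboneGeometry}}.
#' @return an \linkS4class{InternalCoordinates}.
#' @export
backboneInternalCoords <- function(phi, psi, omega, omega3,
                                   geometry = defaultBackboneGeometry()) {
  n <- length(phi)
  stopifnot(n >= 2L, length(psi) == n,
            length(omega) == n - 1L, length(omega3) == n - 1L)
  g <- geometry
  anchor <- rbind(
    N = c(0, 0, 0),
    CA = c(g$n_ca, 0, 0),
    C = c(g$n_ca, 0, 0) +
      g$ca_c * c(cos(.deg2rad(180 - g$n_ca_c)), sin(.deg2rad(180 - g$n_ca_c)), 0))
  rows <- list()
  add <- function(resno, atom, len, ang, tor) {
    rows[[length(rows) + 1L]] <<- data.frame(
      resno = resno, atom = atom, length = len, angle = ang,
      torsion = wrapAngle(tor), stringsAsFactors = FALSE)
  }
  for (i in 2:n) {
    add(i, "N", g$c_n, g$ca_c_n, psi[i - 1L])
    add(i, "CA", g$n_ca, g$c_n_ca, omega[i - 1L])
    add(i - 1L, "O", g$c_o, g$o_c_n, omega3[i - 1L])
    add(i, "C", g$ca_c, g$n_ca_c, phi[i])
  }
  add(n, "O", g$c_o, g$ca_c_o, psi[n] + 180)
  new("InternalCoordinates", anchor = anchor,
      ic = do.call(rbind, rows), nres = as.integer(n))
}

#' Rebuild Cartesian coordinates from internal coordinates
#'
#' Deterministic sequential placement (NeRF): every row of the internal
#' coordinate table is placed against its three already-built anchor atoms,
#' starting from the stored Cartesian anchor (N1, CA1, C1). Exact inverse of
#' \code{\link{extractInternal}}.
#'
#' @param ic an \linkS4class{InternalCoordinates}.
#' @param chainId chain identifier for the output model. Default "A".
#' @param entryId entry identifier. Default "built".
#' @return a \linkS4class{StructureModel} of poly-alanine backbone
#'   (N, CA, C, O per residue).
#' @export
buildBackbone <- function(ic, chainId = "A", entryId = "built") {
  stopifnot(is(ic, "InternalCoordinates"))
  validObject(ic)
  n <- ic@nres
  coords <- new.env(parent = emptyenv())
  key <- function(atom, resno) paste0(atom, ".", resno)
  assign(key("N", 1L), ic@anchor["N", ], envir = coords)
  assign(key("CA", 1L), ic@anchor["CA", ], envir = coords)
  assign(key("C", 1L), ic@anchor["C", ], envir = coords)
  getc <- function(atom, resno) get(key(atom, resno), envir = coords)
  tab <- ic@ic
  for (r in seq_len(nrow(tab))) {
    atom <- tab$atom[r]; i <- tab$resno[r]
    anchors <- switch(atom,
      N = list(getc("N", i - 1L), getc("CA", i - 1L), getc("C", i - 1L)),
      CA = list(getc("CA", i - 1L), getc("C", i - 1L), getc("N", i)),
      C = list(getc("C", i - 1L), getc("N", i), getc("CA", i)),
      O = if (i < n) list(getc("CA", i + 1L), getc("N", i + 1L), getc("C", i))
          else list(getc("N", i), getc("CA", i), getc("C", i)),
      stop("buildBackbone: unknown atom name ", atom))
    assign(key(atom, i),
           placeAtom(anchors[[1L]], anchors[[2L]], anchors[[3L]],
                     tab$length[r], tab$angle[r], tab$torsion[r]),
           envir = coords)
  }
  recs <- list()
  for (i in seq_len(n)) for (atom in c("N", "CA", "C", "O")) {
    p <- getc(atom, i)
    recs[[length(recs) + 1L]] <- data.frame(
      chain = chainId, resno = i, insert = "", resid = "ALA", elety = atom,
      element = substr(atom, 1L, 1L), x = p[1L], y = p[2L], z = p[3L],
      b = 20, occ = 1, alt = "", partialOcc = FALSE, stringsAsFactors = FALSE)
  }
  StructureModel(do.call(rbind, recs), entryId = entryId)
}

#' Extract internal coordinates from a backbone
#'
#' Measures the (bond length, bond angle, torsion) triplet of every backbone
#' atom beyond the anchored first three, in the same build order
#' \code{\link{buildBackbone}} consumes, so the two functions are exact
#' inverses up to floating point. Requires a single unbroken chain with a
#' complete N, CA, C, O backbone.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param chain chain to use; defaults to the only chain (error if several).
#' @param breakDistance C-N distance (Angstrom) above which the chain is
#'   considered broken. Default 1.8.
#' @return an \linkS4class{InternalCoordinates}.
#' @export
extractInternal <- function(model, chain = NULL, breakDistance = 1.8) {
  a <- atomData(model)
  if (is.null(chain)) {
    ch <- unique(a$chain)
    if (length(ch) != 1L)
      stop("extractInternal: several chains present; pick one with 'chain'")
    chain <- ch
  }
  a <- a[a$chain == chain, , drop = FALSE]
  a <- a[order(a$resno, a$insert), , drop = FALSE]
  resix <- unique(a[, c("resno", "insert")])
  n <- nrow(resix)
  if (n < 2L) stop("extractInternal: need at least 2 residues")
  P <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- a[a$resno == resix$resno[i] & a$insert == resix$insert[i], , drop = FALSE]
    lst <- list()
    for (nm in c("N", "CA", "C", "O")) {
      hit <- which(rows$elety == nm)
      if (!length(hit))
        stop(sprintf("extractInternal: residue %s%s is missing backbone atom %s",
                     chain, resix$resno[i], nm))
      lst[[nm]] <- .xyz(rows[hit[1L], ])
    }
    P[[i]] <- lst
  }
  for (i in seq_len(n - 1L)) {
    d <- sqrt(sum((P[[i]]$C - P[[i + 1L]]$N)^2))
    if (d > breakDistance)
      stop(sprintf("extractInternal: chain break between residues %d and %d (C-N %.2f A)",
                   resix$resno[i], resix$resno[i + 1L], d))
  }
  len <- function(p, q) sqrt(sum((p - q)^2))
  ang <- function(p, q, r) {
    u <- p - q; v <- r - q
    .rad2deg(acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))))
  }
  rows <- list()
  add <- function(resno, atom, l, an, tor) {
    rows[[length(rows) + 1L]] <<- data.frame(
      resno = resno, atom = atom, length = l, angle = an, torsion = tor,
      stringsAsFactors = FALSE)
  }
  for (i in 2:n) {
    p <- P[[i - 1L]]; q <- P[[i]]
    add(i, "N", len(p$C, q$N), ang(p$CA, p$C, q$N),
        dihedralAngle(p$N, p$CA, p$C, q$N))
    add(i, "CA", len(q$N, q$CA), ang(p$C, q$N, q$CA),
        dihedralAngle(p$CA, p$C, q$N, q$CA))
    add(i - 1L, "O", len(p$C, p$O), ang(q$N, p$C, p$O),
        dihedralAngle(q$CA, q$N, p$C, p$O))
    add(i, "C", len(q$CA, q$C), ang(q$N, q$CA, q$C),
        dihedralAngle(p$C, q$N, q$CA, q$C))
  }
  q <- P[[n]]
  add(n, "O", len(q$C, q$O), ang(q$CA, q$C, q$O),
      dihedralAngle(q$N, q$CA, q$C, q$O))
  new("InternalCoordinates",
      anchor = rbind(N = P[[1L]]$N, CA = P[[1L]]$CA, C = P[[1L]]$C),
      ic = do.call(rbind, rows), nres = as.integer(n))
}

.samplePhiPsi <- function(sampler, n) {
  if (sampler$type == "fixed")
    return(list(phi = rep(sampler$phi, n), psi = rep(sampler$psi, n)))
  b <- sampler$basins
  ix <- sample.int(nrow(b), n, replace = TRUE, prob = b$weight / sum(b$weight))
  list(phi = wrapAngle(stats::rnorm(n, b$phi[ix], b$sd[ix])),
       psi = wrapAngle(stats::rnorm(n, b$psi[ix], b$sd[ix])))
}

#' Synthesize a backbone ensemble with prescribed geometry statistics
#'
#' For every residue, (phi, psi) are drawn from the supplied
#' \linkS4class{EnsembleSpec}'s sampler; for every
#' peptide bond i the generator sets
#' \deqn{\Delta\omega_i = A \sin(3 (\psi_i - phase)) + N(0, \sigma_\omega)}
#' \deqn{\theta_{C,i} = slope \cdot \Delta\omega_i + intercept + N(0, \sigma_\theta)}
#' and derives omega = 180 + delta-omega and
#' omega3 = omega + 180 - theta-C (wrapped), then builds Cartesian chains.
#' Fully reproducible under the stored seed.
#'
#' @param spec an \linkS4class{EnsembleSpec}.
#' @return list with \code{models} (list of \linkS4class{StructureModel}) and
#'   \code{truth} (data.frame of generating values per peptide bond:
#'   entry_id, resno, phi, psi, delta_omega, theta_C, omega, omega3).
#' @export
synthesizeEnsemble <- function(spec) {
  stopifnot(is(spec, "EnsembleSpec"))
  validObject(spec)
  set.seed(spec@seed)
  L <- spec@chainLength
  models <- vector("list", spec@nChains)
  truth <- list()
  for (k in seq_len(spec@nChains)) {
    ps <- .samplePhiPsi(spec@sampler, L)
    psiB <- ps$psi[seq_len(L - 1L)]
    dOm <- spec@amplitude * sin(.deg2rad(3 * (psiB - spec@phase))) +
      stats::rnorm(L - 1L, 0, spec@noiseOmegaSd)
    thC <- spec@thetaCSlope * dOm + spec@thetaCIntercept +
      stats::rnorm(L - 1L, 0, spec@noiseThetaCSd)
    omega <- wrapAngle(180 + dOm)
    omega3 <- wrapAngle(omega + 180 - thC)
    id <- sprintf("synth%04d", k)
    ic <- backboneInternalCoords(ps$phi, ps$psi, omega, omega3)
    models[[k]] <- buildBackbone(ic, chainId = "A", entryId = id)
    truth[[k]] <- data.frame(
      entry_id = id, resno = seq_len(L - 1L), phi = ps$phi[seq_len(L - 1L)],
      psi = psiB, delta_omega = wrapAngle(dOm), theta_C = wrapAngle(thC),
      omega = omega, omega3 = omega3, stringsAsFactors = FALSE)
  }
  list(models = models, truth = do.call(rbind, truth))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid-body alignment of paired point sets via SVD of the
#' covariance matrix, with the determinant correction that guarantees a
#' proper rotation (no reflection).
#'
#' @param P,Q n x 3 matrices of paired points, n >= 3.
#' @return list with \code{rotation} (3x3, det +1), \code{translation}
#'   (length 3; the map is \code{x -> rotation \%*\% x + translation} applied
#'   to rows of P), and \code{rmsd} (Angstrom).
#' @export
kabschSuperpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("kabschSuperpose: point sets differ in size")
  if (nrow(P) < 3L) stop("kabschSuperpose: need at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rot <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((rot - Qc)^2)))
  list(rotation = R, translation = as.numeric(cq - R %*% cp), rmsd = rmsd)
}

#' C-alpha coordinates of a model
#'
#' @param model a \linkS4class{StructureModel}.
#' @param chain optional chain filter.
#' @return n x 3 matrix of C-alpha coordinates in residue order.
#' @export
caTrace <- function(model, chain = NULL) {
  a <- atomData(model)
  if (!is.null(chain)) a <- a[a$chain == chain, , drop = FALSE]
  a <- a[a$elety == "CA", , drop = FALSE]
  a <- a[order(a$chain, a$resno, a$insert), , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Idealize all trans omega angles to 180 degrees
#'
#' Extracts the chain's internal coordinates, replaces the omega torsion of
#' every trans peptide bond by exactly 180 degrees (cis bonds are left
#' untouched), keeps every other internal coordinate, and rebuilds from the
#' same anchored first three atoms. Because the anchor is shared, the
#' per-residue C-alpha displacements are directly comparable without
#' superposition; the report also carries the Kabsch RMSD after optimal
#' superposition, which bounds the unsuperposed RMS from below. Small
#' planarity deviations accumulate along the chain, so even a few degrees of
#' scatter in omega can move distal residues by several Angstrom.
#'
#' @param model a \linkS4class{StructureModel} (single unbroken chain, or
#'   pick one with \code{chain}).
#' @param chain chain identifier, optional.
#' @return list with \code{model} (the idealized
#'   \linkS4class{StructureModel}) and \code{report}
#'   (a \linkS4class{DistortionReport} over the C-alpha trace).
#' @export
idealizeOmega <- function(model, chain = NULL) {
  ic <- extractInternal(model, chain = chain)
  tab <- ic@ic
  isOmega <- tab$atom == "CA" & tab$resno >= 2L
  tor <- tab$torsion
  trans <- isOmega & abs(wrapAngle(tor - 180)) <= 90
  tab$torsion[trans] <- 180
  icIdeal <- new("InternalCoordinates", anchor = ic@anchor, ic = tab,
                 nres = ic@nres)
  ideal <- buildBackbone(icIdeal, chainId = if (is.null(chain)) "A" else chain,
                         entryId = paste0(entryId(model), "_ideal"))
  ca0 <- caTrace(model, chain = chain)
  ca1 <- caTrace(ideal)
  disp <- unname(sqrt(rowSums((ca0 - ca1)^2)))
  rep <- new("DistortionReport", perResidueDisplacement = disp,
             meanDisplacement = mean(disp), maxDisplacement = max(disp),
             kabschRmsd = kabschSuperpose(ca0, ca1)$rmsd,
             nAtoms = nrow(ca0))
  list(model = ideal, report = rep)
}
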