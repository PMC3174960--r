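## Independent numeric oracles, deliberately coded on different formulas than
## the package: a Gram-Schmidt-frame atom placement, a chain rebuild driven by
## it, and a brute-force rigid superposition minimizer.

## Place atom d with |d-c| = len, angle(b,c,d) = ang, dihedral(a,b,c,d) = tor,
## using an orthonormal frame built by Gram-Schmidt projection (the package
## uses a cross-product frame instead).
oraclePlaceAtom <- function(a, b, c, len, ang, tor) {
  ez <- (c - b) / sqrt(sum((c - b)^2))
  ab <- a - b
  ex <- ab - sum(ab * ez) * ez
  ex <- ex / sqrt(sum(ex^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  th <- ang * pi / 180
  ta <- tor * pi / 180
  c + len * (-cos(th) * ez + sin(th) * (cos(ta) * ex + sin(ta) * ey))
}

## Rebuild a backbone from an InternalCoordinates object using the oracle
## placement kernel; returns the n x 3 C-alpha matrix and full coords.
oracleRebuild <- function(ic) {
  tab <- icTable(ic)
  n <- nResidues(ic)
  anc <- anchorCoords(ic)
  env <- new.env(parent = emptyenv())
  key <- function(atom, i) paste0(atom, ".", i)
  assign(key("N", 1), anc["N", ], envir = env)
  assign(key("CA", 1), anc["CA", ], envir = env)
  assign(key("C", 1), anc["C", ], envir = env)
  g <- function(atom, i) get(key(atom, i), envir = env)
  for (r in seq_len(nrow(tab))) {
    atom <- tab$atom[r]; i <- tab$resno[r]
    anch <- switch(atom,
      N = list(g("N", i - 1), g("CA", i - 1), g("C", i - 1)),
      CA = list(g("CA", i - 1), g("C", i - 1), g("N", i)),
      C = list(g("C", i - 1), g("N", i), g("CA", i)),
      O = if (i < n) list(g("CA", i + 1), g("N", i + 1), g("C", i))
          else list(g("N", i), g("CA", i), g("C", i)))
    assign(key(atom, i),
           oraclePlaceAtom(anch[[1]], anch[[2]], anch[[3]],
                           tab$length[r], tab$angle[r], tab$torsion[r]),
           envir = env)
  }
  ca <- t(vapply(seq_len(n), function(i) g("CA", i), numeric(3)))
  all <- do.call(rbind, lapply(seq_len(n), function(i)
    rbind(g("N", i), g("CA", i), g("C", i), g("O", i))))
  list(ca = ca, coords = all)
}

## Brute-force best rigid superposition of P onto Q: minimize RMSD over
## Euler angles + translation with multi-start BFGS.
oracleSuperposeRmsd <- function(P, Q) {
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  obj <- function(par) {
    R <- rotmat(par[1:3])
    moved <- P %*% t(R)
    moved <- sweep(moved, 2, -par[4:6])
    sqrt(mean(rowSums((moved - Q)^2)))
  }
  best <- Inf
  set.seed(42)
  for (s in 1:8) {
    start <- c(runif(3, -pi, pi), colMeans(Q) - colMeans(P))
    fit <- optim(start, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}
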