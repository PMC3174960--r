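test_that("placeAtom reproduces hand-verifiable planar constructions", {
  expect_equal(placeAtom(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), 1, 90, 180),
               c(2, 1, 0), tolerance = 1e-9)
  expect_equal(placeAtom(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), 1, 90, 0),
               c(0, 1, 0), tolerance = 1e-9)
  expect_error(placeAtom(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), 1, 90, 0),
               "collinear")
  expect_error(placeAtom(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), -1, 90, 0), "> 0")
  expect_error(placeAtom(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), 1, 181, 0),
               "\\(0, 180\\)")
})

test_that("placeAtom satisfies its three defining constraints on random
           frames and agrees with the independent placement oracle", {
  set.seed(7)
  for (i in 1:50) {
    repeat {
      a <- runif(3, -5, 5); b <- runif(3, -5, 5); c_ <- runif(3, -5, 5)
      n <- sqrt(sum((c_ - b)^2))
      if (n > 0.5 && sqrt(sum((b - a)^2)) > 0.5) break
    }
    len <- runif(1, 0.8, 2)
    ang <- runif(1, 30, 150)
    tor <- runif(1, -179, 180)
    d <- placeAtom(a, b, c_, len, ang, tor)
    expect_equal(sqrt(sum((d - c_)^2)), len, tolerance = 1e-9)
    cosang <- sum((b - c_) * (d - c_)) /
      (sqrt(sum((b - c_)^2)) * sqrt(sum((d - c_)^2)))
    expect_equal(acos(cosang) * 180 / pi, ang, tolerance = 1e-9)
    expect_equal(dihedralAngle(a, b, c_, d), tor, tolerance = 1e-9)
    expect_equal(d, oraclePlaceAtom(a, b, c_, len, ang, tor), tolerance = 1e-9)
  }
})

test_that("buildBackbone and extractInternal are exact inverses", {
  # fixed helix-like chain
  ic <- backboneInternalCoords(rep(-60, 10), rep(-45, 10), rep(180, 9),
                               rep(0, 9))
  m <- buildBackbone(ic)
  ic2 <- extractInternal(m)
  expect_equal(anchorCoords(ic2), anchorCoords(ic), tolerance = 1e-9)
  expect_lt(max(abs(wrapAngle(icTable(ic2)$torsion - icTable(ic)$torsion))),
            1e-6)
  expect_lt(max(abs(icTable(ic2)$angle - icTable(ic)$angle)), 1e-6)
  expect_lt(max(abs(icTable(ic2)$length - icTable(ic)$length)), 1e-9)
  # re-measured survey angles equal the construction torsions
  recs <- extractRecords(m, FilterConfig(bFactorRatio = 1e9))
  ok <- recs$included
  expect_equal(recs$phi[ok], rep(-60, sum(ok)), tolerance = 1e-6)
  expect_equal(recs$psi[ok], rep(-45, sum(ok)), tolerance = 1e-6)
  expect_equal(abs(recs$omega[ok]), rep(180, sum(ok)), tolerance = 1e-6)
  # randomized chains rebuild to identical coordinates
  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    icr <- backboneInternalCoords(
      runif(n, -180, 180), runif(n, -180, 180),
      wrapAngle(180 + rnorm(n - 1, 0, 8)), wrapAngle(rnorm(n - 1, 0, 8)))
    mr <- buildBackbone(icr)
    icr2 <- extractInternal(mr)
    expect_lt(max(abs(wrapAngle(icTable(icr2)$torsion - icTable(icr)$torsion))),
              1e-6)
    mr2 <- buildBackbone(icr2)
    expect_lt(max(abs(as.matrix(atomData(mr)[, c("x", "y", "z")]) -
                      as.matrix(atomData(mr2)[, c("x", "y", "z")]))), 1e-6)
  }
})

test_that("a single peptide unit built at omega 170 re-measures delta-omega -10", {
  ic <- backboneInternalCoords(rep(-60, 2), rep(150, 2), 170, wrapAngle(170 + 180))
  recs <- extractRecords(buildBackbone(ic), FilterConfig(bFactorRatio = 1e9))
  expect_equal(recs$delta_omega[1], -10, tolerance = 1e-6)
  expect_equal(recs$theta_C[1], 0, tolerance = 1e-6)
})

test_that("the generator hits its prescribed geometry exactly when noiseless", {
  spec0 <- EnsembleSpec(nChains = 2L, chainLength = 8L, amplitude = 0,
                        noiseOmegaSd = 0, thetaCSlope = 0,
                        thetaCIntercept = 1.5, noiseThetaCSd = 0, seed = 3L)
  ens <- synthesizeEnsemble(spec0)
  expect_true(all(abs(ens$truth$omega) == 180))
  expect_equal(ens$truth$theta_C, rep(1.5, nrow(ens$truth)))
  recs <- do.call(rbind, lapply(ens$models, function(m)
    extractRecords(m, FilterConfig(bFactorRatio = 1e9))))
  ok <- recs$included
  expect_equal(recs$theta_C[ok], rep(1.5, sum(ok)), tolerance = 1e-6)

  # fixed sampler at psi = 30: delta-omega = 2 sin(90 deg) = 2
  specF <- EnsembleSpec(nChains = 1L, chainLength = 6L,
                        sampler = list(type = "fixed", phi = -60, psi = 30),
                        amplitude = 2, phase = 0, noiseOmegaSd = 0,
                        noiseThetaCSd = 0, seed = 4L)
  ensF <- synthesizeEnsemble(specF)
  expect_equal(ensF$truth$delta_omega, rep(2, 5), tolerance = 1e-12)
})

test_that("the generator is reproducible under a fixed seed", {
  s <- EnsembleSpec(nChains = 2L, chainLength = 6L, seed = 99L)
  e1 <- synthesizeEnsemble(s)
  e2 <- synthesizeEnsemble(s)
  expect_identical(e1$truth, e2$truth)
  expect_equal(atomData(e1$models[[2]]), atomData(e2$models[[2]]))
})

test_that("kabschSuperpose finds the optimal proper rotation", {
  set.seed(19)
  P <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabschSuperpose(P, P)$rmsd, 0, tolerance = 1e-9)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Q <- P %*% t(R) + matrix(rep(c(1, -2, 3), each = 10), ncol = 3)
  res <- kabschSuperpose(P, Q)
  expect_equal(res$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(res$rotation), 1, tolerance = 1e-9)
  # the returned transform actually maps P onto Q
  moved <- sweep(P %*% t(res$rotation), 2, -res$translation)
  expect_equal(moved, Q, tolerance = 1e-9)
  # one displaced point: agreement with brute-force numeric minimization
  Q2 <- P
  Q2[4, ] <- Q2[4, ] + c(1, 0, 0)
  expect_equal(kabschSuperpose(P, Q2)$rmsd, oracleSuperposeRmsd(P, Q2),
               tolerance = 1e-5)
  expect_error(kabschSuperpose(P, P[1:5, ]), "size")
})

test_that("kabsch rmsd agrees with the bio3d reference superposition", {
  set.seed(37)
  P <- matrix(rnorm(45), ncol = 3)
  Q <- P + matrix(rnorm(45, 0, 0.3), ncol = 3)
  ref <- bio3d::rmsd(as.numeric(t(P)), as.numeric(t(Q)), fit = TRUE)
  expect_equal(kabschSuperpose(P, Q)$rmsd, ref, tolerance = 1e-3)
})

test_that("omega idealization is a fixed point on planar chains and
           idempotent elsewhere", {
  flat <- makeChain(12, dOmega = 0)
  res <- idealizeOmega(flat)
  expect_equal(maxDisplacement(res$report), 0, tolerance = 1e-9)
  perturbed <- makeChain(12, dOmega = rnorm(11, 0, 5))
  once <- idealizeOmega(perturbed)
  twice <- idealizeOmega(once$model)
  expect_equal(maxDisplacement(twice$report), 0, tolerance = 1e-8)
  expect_equal(as.matrix(atomData(once$model)[, c("x", "y", "z")]),
               as.matrix(atomData(twice$model)[, c("x", "y", "z")]),
               tolerance = 1e-8)
})

test_that("cis bonds are left untouched by idealization", {
  dOm <- rep(0, 11)
  m <- makeChain(12, dOmega = dOm)
  ic <- extractInternal(m)
  tab <- icTable(ic)
  # force bond 6 to cis (omega ~ 5 deg) and rebuild
  tab$torsion[tab$atom == "CA" & tab$resno == 7] <- 5
  cisModel <- buildBackbone(new("InternalCoordinates", anchor = anchorCoords(ic),
                                ic = tab, nres = nResidues(ic)))
  ideal <- idealizeOmega(cisModel)
  icI <- extractInternal(ideal$model)
  tabI <- icTable(icI)
  expect_equal(tabI$torsion[tabI$atom == "CA" & tabI$resno == 7], 5,
               tolerance = 1e-6)
  expect_equal(maxDisplacement(ideal$report), 0, tolerance = 1e-8)
})

test_that("a single distorted bond displaces only downstream residues, with
           a lever arm growing along an extended chain and in |delta-omega|", {
  dOm <- rep(0, 19)
  dOm[10] <- -10
  m <- makeChain(20, phi = -179, psi = 179, dOmega = dOm)
  res <- idealizeOmega(m)
  d <- caDisplacements(res$report)
  expect_equal(d[1:10], rep(0, 10), tolerance = 1e-9)
  expect_true(all(diff(d[10:20]) > -1e-9))
  expect_gt(d[20], d[11])
  # terminal displacement nondecreasing in the perturbation magnitude
  term <- vapply(seq(0, 20, by = 2.5), function(mag) {
    dd <- rep(0, 19); dd[10] <- -mag
    mm <- makeChain(20, phi = -179, psi = 179, dOmega = dd)
    caDisplacements(idealizeOmega(mm)$report)[20]
  }, numeric(1))
  expect_true(all(diff(term) > -1e-9))
})

test_that("idealized chains agree with the independently coded rebuild
           oracle to 1e-6 Angstrom", {
  set.seed(67)
  m <- makeChain(40, phi = -100, psi = 130, dOmega = rnorm(39, 0, 6.8))
  ic <- extractInternal(m)
  tab <- icTable(ic)
  sel <- tab$atom == "CA" & tab$resno >= 2
  tab$torsion[sel & abs(wrapAngle(tab$torsion - 180)) <= 90] <- 180
  oracle <- oracleRebuild(new("InternalCoordinates",
                              anchor = anchorCoords(ic), ic = tab,
                              nres = nResidues(ic)))
  ideal <- idealizeOmega(m)$model
  expect_lt(max(abs(caTrace(ideal) - oracle$ca)), 1e-6)
  expect_lt(max(abs(as.matrix(atomData(ideal)[, c("x", "y", "z")]) -
                    oracle$coords)), 1e-6)
})

test_that("kabsch rmsd never exceeds the unsuperposed RMS displacement", {
  set.seed(71)
  for (i in 1:5) {
    m <- makeChain(15, dOmega = rnorm(14, 0, 6))
    rep_ <- idealizeOmega(m)$report
    rms <- sqrt(mean(caDisplacements(rep_)^2))
    expect_lte(kabschRmsd(rep_), rms + 1e-9)
  }
})

test_that("the survey-fit loop recovers the generator parameters across
           seeded replicates", {
  stats <- vapply(1:20, function(s) {
    ens <- synthesizeEnsemble(EnsembleSpec(nChains = 25L, chainLength = 42L,
                                           seed = 1000L + s))
    recs <- do.call(rbind, lapply(ens$models, function(m)
      extractRecords(m, FilterConfig(bFactorRatio = 1e9))))
    recs <- recs[recs$included, ]
    c(amplitude(fitHarmonic(recs$psi, recs$delta_omega)),
      slopeOf(fitLinear(recs$delta_omega, recs$theta_C)))
  }, numeric(2))
  expect_lt(abs(mean(stats[1, ]) - 2) / 2, 0.05)
  expect_lt(abs(mean(stats[2, ]) - 0.6) / 0.6, 0.05)
})
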