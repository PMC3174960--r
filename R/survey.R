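#' @include structure-io.R angles.R
NULL

.xyz <- function(row) c(row$x, row$y, row$z)

.wCircMean <- function(angles, w) {
  rad <- .deg2rad(angles)
  wrapAngle(.rad2deg(atan2(sum(w * sin(rad)), sum(w * cos(rad)))))
}

#' Per-residue survey records with a full filter audit
#'
#' Measures phi, psi and the geometry of the following peptide bond (omega,
#' omega3, delta-omega, theta-C, and theta-N when the next residue's amide
#' hydrogen is present) for every residue of every chain, and annotates each
#' record with the survey exclusion reasons instead of dropping it. The
#' omega-type angles of the bond between residues i and i+1 are attributed to
#' residue i, whose psi shares the N(i+1) atom -- this is the convention that
#' makes the psi-dependence analysis well defined.
#'
#' Exclusion reasons: \code{terminal} (no neighbour residue, phi or psi
#' undefined), \code{chain_break} (neighbour present but C-N distance beyond
#' the cutoff), \code{missing_atoms}, \code{gly_pro}, \code{partial_occupancy},
#' \code{high_b} (residue main-chain B above \code{bFactorRatio} times the
#' pooled main-chain average of the entire entry), \code{cis} (following bond
#' cis while \code{transOnly}). A record is included iff its reason set is
#' empty.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param config a \linkS4class{FilterConfig}.
#' @return data.frame with one row per residue: entry_id, chain_id,
#'   seq_number, insert, residue_name, phi, psi, omega, omega3, delta_omega,
#'   theta_C, theta_N, b_mainchain, included, exclusion_reasons
#'   (semicolon-joined).
#' @export
extractRecords <- function(model, config = FilterConfig()) {
  stopifnot(is(model, "StructureModel"), is(config, "FilterConfig"))
  a <- atomData(model)
  a <- a[order(a$chain, a$resno, a$insert), , drop = FALSE]
  bbsel <- a$elety %in% .BACKBONE
  bProtein <- mean(a$b[bbsel])

  out <- list()
  for (ch in unique(a$chain)) {
    ca <- a[a$chain == ch, , drop = FALSE]
    resix <- unique(ca[, c("resno", "insert", "resid")])
    n <- nrow(resix)
    ## per-residue backbone atom lookup
    atoms <- vector("list", n)
    for (i in seq_len(n)) {
      rsel <- ca$resno == resix$resno[i] & ca$insert == resix$insert[i]
      rows <- ca[rsel, , drop = FALSE]
      lst <- list()
      for (nm in c(.BACKBONE, .AMIDE_H)) {
        hit <- which(rows$elety == nm)
        if (length(hit)) lst[[if (nm %in% .AMIDE_H) "H" else nm]] <-
          .xyz(rows[hit[1L], ])
      }
      lst$partialOcc <- any(rows$partialOcc)
      bsel <- rows$elety %in% .BACKBONE
      lst$bMain <- if (any(bsel)) mean(rows$b[bsel]) else NA_real_
      atoms[[i]] <- lst
    }
    bondedNext <- function(i) {
      if (i >= n) return(FALSE)
      ci <- atoms[[i]]$C; nn <- atoms[[i + 1L]]$N
      if (is.null(ci) || is.null(nn)) return(NA)
      sqrt(sum((ci - nn)^2)) <= config@chainBreakDistance
    }
    dih <- function(p1, p2, p3, p4) {
      if (is.null(p1) || is.null(p2) || is.null(p3) || is.null(p4))
        return(NA_real_)
      dihedralAngle(p1, p2, p3, p4)
    }
    for (i in seq_len(n)) {
      res <- atoms[[i]]
      reasons <- character()
      phi <- psi <- omega <- omega3 <- dOm <- thC <- thN <- NA_real_

      ownMissing <- setdiff(.BACKBONE, names(res))
      if (length(ownMissing)) reasons <- c(reasons, "missing_atoms")

      ## phi needs a bonded predecessor C
      if (i == 1L) reasons <- c(reasons, "terminal")
      else {
        bp <- bondedNext(i - 1L)
        if (is.na(bp)) reasons <- c(reasons, "missing_atoms")
        else if (!bp) reasons <- c(reasons, "chain_break")
        else phi <- dih(atoms[[i - 1L]]$C, res$N, res$CA, res$C)
      }
      ## psi/omega/omega3 need a bonded successor
      if (i == n) reasons <- c(reasons, "terminal")
      else {
        bn <- bondedNext(i)
        if (is.na(bn)) reasons <- c(reasons, "missing_atoms")
        else if (!bn) reasons <- c(reasons, "chain_break")
        else {
          nxt <- atoms[[i + 1L]]
          psi <- dih(res$N, res$CA, res$C, nxt$N)
          omega <- dih(res$CA, res$C, nxt$N, nxt$CA)
          omega3 <- dih(res$O, res$C, nxt$N, nxt$CA)
          if (!is.na(omega)) {
            iso <- classifyIsomer(omega)
            dOm <- deltaOmega(omega, iso)
            if (config@transOnly && iso == "cis") reasons <- c(reasons, "cis")
          }
          if (!is.na(omega) && !is.na(omega3)) thC <- thetaC(omega, omega3)
          if (!is.na(omega) && !is.null(nxt$H))
            thN <- thetaN(dih(res$CA, res$C, nxt$N, nxt$H), omega)
          if (is.na(psi) || is.na(omega) || is.na(omega3))
            reasons <- c(reasons, "missing_atoms")
        }
      }
      if (resix$resid[i] %in% config@excludeResidues)
        reasons <- c(reasons, "gly_pro")
      if (isTRUE(res$partialOcc)) reasons <- c(reasons, "partial_occupancy")
      if (!is.na(res$bMain) && res$bMain > config@bFactorRatio * bProtein)
        reasons <- c(reasons, "high_b")
      reasons <- unique(reasons)
      out[[length(out) + 1L]] <- data.frame(
        entry_id = entryId(model), chain_id = ch,
        seq_number = resix$resno[i], insert = resix$insert[i],
        residue_name = resix$resid[i],
        phi = phi, psi = psi, omega = omega, omega3 = omega3,
        delta_omega = dOm, theta_C = thC, theta_N = thN,
        b_mainchain = res$bMain,
        included = length(reasons) == 0L,
        exclusion_reasons = paste(sort(reasons), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.gridCenter <- function(x, step) wrapAngle(step * floor(x / step + 0.5))

#' Bin survey records on a Ramachandran grid
#'
#' Assigns each included record to the 15x15-degree (by default) cell whose
#' center is nearest -- cells are half-open, [center - step/2, center + step/2)
#' on both axes, with centers on multiples of the step -- and computes per-cell
#' counts and circular means of delta-omega and theta-C. Cells holding fewer
#' than \code{minCount} records are flagged below-threshold; downstream
#' profile and trend computations omit them, following the rule that each
#' reported point averages at least 100 independent values.
#'
#' @param records data.frame from \code{\link{extractRecords}} (only rows with
#'   \code{included == TRUE} are used; a table without the column is taken as
#'   already filtered).
#' @param gridStep grid step in degrees; must divide 360. Default 15.
#' @param minCount minimum records per usable cell. Default 100.
#' @return data.frame with phi_center, psi_center, count, mean_delta_omega,
#'   mean_theta_C, dispersion_delta_omega, dispersion_theta_C,
#'   below_threshold.
#' @export
binRecords <- function(records, gridStep = 15, minCount = 100) {
  if (360 %% gridStep != 0)
    stop("binRecords: gridStep must divide 360")
  if ("included" %in% names(records)) records <- records[records$included, ]
  records <- records[!is.na(records$phi) & !is.na(records$psi), ]
  if (nrow(records) == 0L)
    return(data.frame(phi_center = numeric(), psi_center = numeric(),
                      count = integer(), mean_delta_omega = numeric(),
                      mean_theta_C = numeric(),
                      dispersion_delta_omega = numeric(),
                      dispersion_theta_C = numeric(),
                      below_threshold = logical()))
  pc <- .gridCenter(records$phi, gridStep)
  sc <- .gridCenter(records$psi, gridStep)
  key <- paste(pc, sc, sep = "\r")
  out <- lapply(split(seq_len(nrow(records)), key), function(ix) {
    cmO <- circularMean(records$delta_omega[ix])
    cmT <- circularMean(records$theta_C[ix])
    data.frame(phi_center = pc[ix[1L]], psi_center = sc[ix[1L]],
               count = length(ix), mean_delta_omega = cmO$mean,
               mean_theta_C = cmT$mean, dispersion_delta_omega = cmO$R,
               dispersion_theta_C = cmT$R,
               below_threshold = length(ix) < minCount)
  })
  bins <- do.call(rbind, out)
  rownames(bins) <- NULL
  bins[order(bins$phi_center, bins$psi_center), , drop = FALSE]
}

#' psi-marginal profile of the binned survey
#'
#' Collapses the Ramachandran grid over phi: for each psi column, the
#' count-weighted circular mean of the qualifying (not below-threshold) cells'
#' delta-omega and theta-C means.
#'
#' @param bins data.frame from \code{\link{binRecords}}.
#' @return data.frame with psi_center, mean_delta_omega, mean_theta_C, count,
#'   ordered by psi_center.
#' @export
psiProfile <- function(bins) {
  q <- bins[!bins$below_threshold, , drop = FALSE]
  if (nrow(q) == 0L) stop("psiProfile: no bins reach the count threshold")
  out <- lapply(split(q, q$psi_center), function(g) {
    data.frame(psi_center = g$psi_center[1L],
               mean_delta_omega = .wCircMean(g$mean_delta_omega, g$count),
               mean_theta_C = .wCircMean(g$mean_theta_C, g$count),
               count = sum(g$count))
  })
  prof <- do.call(rbind, out)
  rownames(prof) <- NULL
  prof[order(prof$psi_center), , drop = FALSE]
}
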