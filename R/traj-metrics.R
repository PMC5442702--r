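#' @include AllClasses.R AllGenerics.R utils.R
NULL

.lenFactor <- function(units) {
  switch(match.arg(units, c("angstrom", "nm")), angstrom = 1, nm = 0.1)
}

# Row indices of CA atoms, optionally restricted to a residue set.
.caIndices <- function(atoms, selection = NULL) {
  idx <- which(atoms$name == "CA")
  if (!is.null(selection)) idx <- idx[atoms$resnum[idx] %in% selection]
  idx
}

#' Rigid-body superposition of trajectory frames
#'
#' Least-squares fits every frame onto a reference frame using the
#' selected C-alpha atoms: optimal rotation by the Kabsch/SVD
#' construction after centering, so the per-frame RMSD to the
#' reference over the selection is minimized. The fitted rotation and
#' translation are applied to all atoms of the frame.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param refFrame reference frame index (default 1).
#' @param selection optional residue numbers to fit on (default: all
#'   residues with a CA). At least 3 CA atoms are required.
#' @return A superposed \linkS4class{Trajectory}.
#' @export
superpose <- function(traj, refFrame = 1, selection = NULL) {
  stopifnot(is(traj, "Trajectory"))
  idx <- .caIndices(traj@atoms, selection)
  if (length(idx) < 3)
    stop("underdetermined fit: need >= 3 selected CA atoms, got ",
         length(idx))
  nf <- nFrames(traj)
  stopifnot(refFrame >= 1, refFrame <= nf)
  ref <- traj@coords[refFrame, idx, , drop = TRUE]
  refC <- colMeans(ref)
  refCtr <- sweep(ref, 2, refC)
  out <- traj@coords
  for (i in seq_len(nf)) {
    mob <- traj@coords[i, idx, , drop = TRUE]
    mobC <- colMeans(mob)
    R <- .kabschRotation(sweep(mob, 2, mobC), refCtr)
    all_i <- sweep(traj@coords[i, , , drop = TRUE], 2, mobC)
    out[i, , ] <- sweep(all_i %*% R, 2, refC, `+`)
  }
  new("Trajectory", atoms = traj@atoms, coords = out, dt = traj@dt)
}

#' Per-residue root mean square fluctuation
#'
#' RMSF of each selected C-alpha about its time-averaged position:
#' sqrt of the mean squared deviation over frames. The trajectory
#' should be superposed first (\code{\link{superpose}}) so that rigid
#' body motion does not inflate the fluctuations.
#'
#' @param traj a (superposed) \linkS4class{Trajectory} with >= 2
#'   frames.
#' @param selection optional residue numbers (default all).
#' @param units "angstrom" (default) or "nm".
#' @return data.frame with columns \code{resnum} and \code{rmsf}.
#' @export
rmsf <- function(traj, selection = NULL, units = "angstrom") {
  stopifnot(is(traj, "Trajectory"))
  if (nFrames(traj) < 2)
    stop("RMSF needs at least 2 frames")
  idx <- .caIndices(traj@atoms, selection)
  if (length(idx) == 0) stop("no CA atoms in the selection")
  xyz <- traj@coords[, idx, , drop = FALSE]
  mu <- apply(xyz, c(2, 3), mean)
  dev2 <- sweep(xyz, c(2, 3), mu)^2
  # per atom: mean over frames of |x - xbar|^2
  msd <- apply(dev2, 2, sum) / nFrames(traj)
  data.frame(resnum = traj@atoms$resnum[idx],
             rmsf = sqrt(msd) * .lenFactor(units))
}

#' Minimal inter-residue distance along a trajectory
#'
#' Per frame, the minimum pairwise atom distance between two residues
#' (heavy atoms by default, since hydrogen positions in stripped
#' trajectories are often absent or force-field artifacts), plus a
#' normalized histogram of the series. Used e.g. to characterize the
#' open/closed state of a substrate-binding cleft between a thumb-loop
#' proline and a fingers-domain tryptophan.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param resA,resB author residue numbers of the two residues.
#' @param mode "heavy" (default) or "all" atoms.
#' @param breaks histogram breaks (passed to \code{hist}).
#' @param units "angstrom" (default) or "nm".
#' @return list with \code{times} (ps), \code{values} (distances), and
#'   \code{histogram} (\code{breaks}, \code{mids}, \code{density};
#'   the density integrates to 1).
#' @export
minDistanceSeries <- function(traj, resA, resB, mode = c("heavy", "all"),
                              breaks = "Sturges", units = "angstrom") {
  stopifnot(is(traj, "Trajectory"))
  mode <- match.arg(mode)
  a <- traj@atoms
  ia <- which(a$resnum == resA)
  ib <- which(a$resnum == resB)
  if (length(ia) == 0) stop("residue ", resA, " not in the topology")
  if (length(ib) == 0) stop("residue ", resB, " not in the topology")
  if (mode == "heavy") {
    ia <- ia[a$element[ia] != "H"]
    ib <- ib[a$element[ib] != "H"]
  }
  nf <- nFrames(traj)
  vals <- vapply(seq_len(nf), function(f) {
    pa <- traj@coords[f, ia, , drop = FALSE][1, , , drop = TRUE]
    pb <- traj@coords[f, ib, , drop = FALSE][1, , , drop = TRUE]
    pa <- matrix(pa, ncol = 3)
    pb <- matrix(pb, ncol = 3)
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  vals <- vals * .lenFactor(units)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  list(times = (seq_len(nf) - 1) * traj@dt, values = vals,
       histogram = list(breaks = h$breaks, mids = h$mids,
                        density = h$density))
}

# Shrake-Rupley accessible area per atom for one coordinate frame.
.sasaFrame <- function(xyz, radii, probe, pts) {
  n <- nrow(xyz)
  ext <- radii + probe
  area <- numeric(n)
  npts <- nrow(pts)
  for (i in seq_len(n)) {
    ci <- xyz[i, ]
    d2 <- rowSums(sweep(xyz, 2, ci)^2)
    nb <- which(d2 > 0 & sqrt(d2) < ext[i] + ext)
    nb <- setdiff(nb, i)
    p <- sweep(pts * ext[i], 2, ci, `+`)
    free <- rep(TRUE, npts)
    for (j in nb) {
      if (!any(free)) break
      dj <- sweep(p[free, , drop = FALSE], 2, xyz[j, ])
      free[free] <- rowSums(dj^2) >= ext[j]^2
    }
    area[i] <- 4 * pi * ext[i]^2 * sum(free) / npts
  }
  area
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA: each atom is inflated by the probe radius and
#' covered with a deterministic golden-spiral point mesh; the
#' accessible area is the unoccluded point fraction times the sphere
#' area. Van der Waals radii are the Bondi set, looked up by element
#' (an unknown element raises an error naming it). For a trajectory
#' the per-residue mean and standard deviation over frames are
#' reported.
#'
#' @param x a \linkS4class{StructureModel} or \linkS4class{Trajectory}.
#' @param residues optional author residue numbers to report (default
#'   all); occlusion always considers every atom present.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param nPoints mesh points per atom (default 960).
#' @param units "angstrom" (default, areas in A^2) or "nm" (nm^2).
#' @return data.frame with columns \code{resnum}, \code{meanArea},
#'   \code{sdArea} (0 for a single structure), \code{nFrames}.
#' @export
sasa <- function(x, residues = NULL, probe = 1.4, nPoints = 960,
                 units = "angstrom") {
  stopifnot(probe >= 0, nPoints >= 10)
  f <- .lenFactor(units)^2
  pts <- .spherePoints(nPoints)
  if (is(x, "StructureModel")) {
    atoms <- x@atoms
    frames <- list(as.matrix(atoms[, c("x", "y", "z")]))
  } else if (is(x, "Trajectory")) {
    atoms <- x@atoms
    frames <- lapply(seq_len(nFrames(x)), function(i)
      matrix(x@coords[i, , ], ncol = 3))
  } else stop("x must be a StructureModel or a Trajectory")
  radii <- .vdwRadius(atoms$element)
  want <- if (is.null(residues)) unique(atoms$resnum) else residues
  miss <- setdiff(want, atoms$resnum)
  if (length(miss) > 0)
    stop("residue(s) not in the structure: ", paste(miss, collapse = ", "))
  perRes <- vapply(frames, function(xyz) {
    a <- .sasaFrame(xyz, radii, probe, pts)
    vapply(want, function(r) sum(a[atoms$resnum == r]), numeric(1))
  }, numeric(length(want)))
  perRes <- matrix(perRes, nrow = length(want))
  data.frame(resnum = want,
             meanArea = apply(perRes, 1, mean) * f,
             sdArea = if (ncol(perRes) > 1)
               apply(perRes, 1, stats::sd) * f else 0,
             nFrames = ncol(perRes))
}

#' Geometric hydrogen-bond criteria
#'
#' Donor-acceptor distance and hydrogen-donor-acceptor angle cutoffs.
#' Defaults (3.5 Angstrom, 30 degrees) are the conventional choices of
#' trajectory H-bond tools; both are configurable.
#'
#' @param maxDaDist maximum donor-acceptor distance, Angstrom.
#' @param maxHdaAngle maximum H-donor-acceptor angle, degrees.
#' @return list with the two cutoffs.
#' @export
hbondCriteria <- function(maxDaDist = 3.5, maxHdaAngle = 30) {
  stopifnot(maxDaDist > 0, maxHdaAngle > 0)
  list(maxDaDist = maxDaDist, maxHdaAngle = maxHdaAngle)
}

# Donor table: hydrogens attached (< 1.25 A) to N/O atoms.
.donorTable <- function(atoms, xyz) {
  isH <- atoms$element == "H"
  isDA <- atoms$element %in% c("N", "O")
  hIdx <- which(isH)
  dIdx <- which(isDA)
  if (length(hIdx) == 0 || length(dIdx) == 0)
    return(data.frame(d = integer(0), h = integer(0)))
  out <- lapply(hIdx, function(h) {
    d2 <- rowSums(sweep(xyz[dIdx, , drop = FALSE], 2, xyz[h, ])^2)
    j <- which.min(d2)
    if (d2[j] < 1.25^2) data.frame(d = dIdx[j], h = h) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(d = integer(0), h = integer(0)) else out
}

#' Detect hydrogen bonds in a single structure
#'
#' All D-H...A triples satisfying the geometric criteria: donors are
#' N/O atoms with a covalently attached hydrogen (attachment inferred
#' by distance < 1.25 Angstrom, so explicit hydrogens are required),
#' acceptors are all N/O atoms. A triple is a bond when the
#' donor-acceptor distance and the H-D-A angle are within the cutoffs.
#'
#' @param model a \linkS4class{StructureModel} with hydrogens.
#' @param criteria from \code{\link{hbondCriteria}}.
#' @return data.frame with one row per bond: \code{donorRes},
#'   \code{donorAtom}, \code{hAtom}, \code{acceptorRes},
#'   \code{acceptorAtom}, \code{distance} (Angstrom), \code{angle}
#'   (degrees). Empty when none are found.
#' @export
detectHBonds <- function(model, criteria = hbondCriteria()) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  don <- .donorTable(a, xyz)
  acc <- which(a$element %in% c("N", "O"))
  rows <- list()
  for (k in seq_len(nrow(don))) {
    d <- don$d[k]; h <- don$h[k]
    cand <- acc[acc != d]
    dda <- sqrt(rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[d, ])^2))
    cand <- cand[dda <= criteria$maxDaDist]
    dda <- dda[dda <= criteria$maxDaDist]
    for (m in seq_along(cand)) {
      ang <- .angle3(xyz[h, ], xyz[d, ], xyz[cand[m], ])
      if (ang <= criteria$maxHdaAngle)
        rows[[length(rows) + 1]] <- data.frame(
          donorRes = a$resnum[d], donorAtom = a$name[d],
          hAtom = a$name[h],
          acceptorRes = a$resnum[cand[m]], acceptorAtom = a$name[cand[m]],
          distance = dda[m], angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(donorRes = integer(0), donorAtom = character(0),
                      hAtom = character(0), acceptorRes = integer(0),
                      acceptorAtom = character(0), distance = numeric(0),
                      angle = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Hydrogen-bond occupancy of one donor/acceptor pair
#'
#' Fraction of frames in which the pair satisfies the geometric
#' criteria, plus a per-window occupancy series and a block standard
#' error (one standard error of the per-block occupancy means, the
#' conventional way to put error bars on trajectory H-bond counts).
#'
#' @param traj a \linkS4class{Trajectory} with hydrogens on the donor.
#' @param donorRes,donorAtom residue number and atom name of the donor
#'   heavy atom (N or O).
#' @param acceptorRes,acceptorAtom residue number and atom name of the
#'   acceptor.
#' @param criteria from \code{\link{hbondCriteria}}.
#' @param window averaging window, ps (default span/100, at least one
#'   frame).
#' @param block block length for the standard error, ps (default
#'   span/5).
#' @return list with \code{occupancy}, \code{series} (data.frame
#'   \code{windowStart}, \code{occupancy}, \code{nFrames}),
#'   \code{blockError}, \code{window}, \code{block}.
#' @export
hbondOccupancy <- function(traj, donorRes, donorAtom, acceptorRes,
                           acceptorAtom, criteria = hbondCriteria(),
                           window = NULL, block = NULL) {
  stopifnot(is(traj, "Trajectory"))
  a <- traj@atoms
  d <- which(a$resnum == donorRes & a$name == donorAtom)
  acp <- which(a$resnum == acceptorRes & a$name == acceptorAtom)
  if (length(d) != 1)
    stop("donor atom ", donorAtom, " of residue ", donorRes,
         " not found in the topology")
  if (length(acp) != 1)
    stop("acceptor atom ", acceptorAtom, " of residue ", acceptorRes,
         " not found in the topology")
  nf <- nFrames(traj)
  span <- nf * traj@dt
  window <- window %||% max(traj@dt, span / 100)
  block <- block %||% max(window, span / 5)
  if (window > span)
    stop("window (", window, " ps) exceeds the trajectory span (",
         span, " ps)")
  # hydrogens attached to the donor (topology frame 1)
  xyz1 <- matrix(traj@coords[1, , ], ncol = 3)
  hs <- which(a$element == "H" & a$resnum == donorRes)
  hs <- hs[sqrt(rowSums(sweep(xyz1[hs, , drop = FALSE], 2,
                              xyz1[d, ])^2)) < 1.25]
  if (length(hs) == 0)
    stop("donor ", donorAtom, "/", donorRes, " has no attached hydrogen")
  bonded <- vapply(seq_len(nf), function(f) {
    xyz <- matrix(traj@coords[f, , ], ncol = 3)
    if (.vnorm(xyz[acp, ] - xyz[d, ]) > criteria$maxDaDist) return(FALSE)
    any(vapply(hs, function(h)
      .angle3(xyz[h, ], xyz[d, ], xyz[acp, ]) <= criteria$maxHdaAngle,
      logical(1)))
  }, logical(1))
  tm <- (seq_len(nf) - 1) * traj@dt
  wid <- pmin(floor(tm / window) + 1L, ceiling(span / window))
  series <- data.frame(
    windowStart = (sort(unique(wid)) - 1) * window,
    occupancy = as.numeric(tapply(bonded, wid, mean)),
    nFrames = as.integer(tapply(bonded, wid, length)))
  bid <- pmin(floor(tm / block) + 1L, ceiling(span / block))
  bmeans <- as.numeric(tapply(bonded, bid, mean))
  blockError <- if (length(bmeans) > 1)
    stats::sd(bmeans) / sqrt(length(bmeans)) else 0
  list(occupancy = mean(bonded), series = series,
       blockError = blockError, window = window, block = block)
}

# ---- Secondary structure (simplified Kabsch-Sander) -------------------

# Backbone atom coordinates per residue; NA rows where missing.
.backbone <- function(a, xyz) {
  res <- unique(a$resnum)
  get <- function(nm) {
    out <- matrix(NA_real_, length(res), 3)
    idx <- match(paste(res, nm), paste(a$resnum, a$name))
    ok <- !is.na(idx)
    out[ok, ] <- xyz[idx[ok], , drop = FALSE]
    out
  }
  list(res = res, N = get("N"), CA = get("CA"), C = get("C"),
       O = get("O"), H = get("H"), resname = a$resname[match(res, a$resnum)])
}

# Amide H: use the file's H when present, otherwise construct it 1.0 A
# from N opposite the bisector of the C(i-1)-N and CA-N bonds.
# Residue 1 and prolines have no donor (NA).
.amideH <- function(bb) {
  n <- length(bb$res)
  H <- bb$H
  for (i in seq_len(n)) {
    if (!anyNA(H[i, ])) next
    if (i == 1 || bb$resname[i] == "PRO" ||
        anyNA(bb$C[i - 1, ]) || anyNA(bb$N[i, ]) || anyNA(bb$CA[i, ])) {
      H[i, ] <- NA_real_
      next
    }
    u <- .unit(bb$C[i - 1, ] - bb$N[i, ]) + .unit(bb$CA[i, ] - bb$N[i, ])
    H[i, ] <- bb$N[i, ] - .unit(u) * 1.0
  }
  H
}

# Kabsch-Sander electrostatic H-bond energy matrix, kcal/mol.
# E[i, j]: CO of residue i accepting the NH of residue j.
.ksEnergy <- function(bb, H) {
  n <- length(bb$res)
  E <- matrix(Inf, n, n)
  for (j in seq_len(n)) {           # NH donor
    if (anyNA(H[j, ]) || anyNA(bb$N[j, ])) next
    for (i in seq_len(n)) {         # CO acceptor
      if (abs(i - j) < 2) next
      if (anyNA(bb$C[i, ]) || anyNA(bb$O[i, ])) next
      rON <- .vnorm(bb$O[i, ] - bb$N[j, ])
      rCH <- .vnorm(bb$C[i, ] - H[j, ])
      rOH <- .vnorm(bb$O[i, ] - H[j, ])
      rCN <- .vnorm(bb$C[i, ] - bb$N[j, ])
      if (min(rON, rCH, rOH, rCN) < 0.5) { E[i, j] <- -9.9; next }
      E[i, j] <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    }
  }
  E
}

#' Assign helix/strand/coil secondary structure to one frame
#'
#' Simplified Kabsch-Sander assignment from backbone hydrogen bonds.
#' The electrostatic bond energy
#' E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN) kcal/mol is
#' evaluated for every CO(i)/NH(j) pair (amide hydrogens are
#' constructed when absent); a bond exists when E < -0.5 kcal/mol.
#' Residues covered by two consecutive i -> i+4 bonds are labelled H;
#' residues in parallel or antiparallel bridge patterns are labelled
#' E (helix takes precedence); everything else, including residues
#' with missing backbone atoms (warned about), is C. The 8-class DSSP
#' subtypes are deliberately collapsed to H/E/C.
#'
#' @param model a \linkS4class{StructureModel} with backbone N, CA, C,
#'   O atoms.
#' @return character vector of labels ("H", "E", "C"), named by
#'   residue number.
#' @export
assignSecondaryStructure <- function(model) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  bb <- .backbone(a, xyz)
  n <- length(bb$res)
  incomplete <- apply(cbind(bb$N, bb$CA, bb$C, bb$O), 1, anyNA)
  if (any(incomplete))
    warning(sum(incomplete),
            " residue(s) with missing backbone atoms labelled C")
  H <- .amideH(bb)
  E <- .ksEnergy(bb, H)
  hb <- E < -0.5
  lab <- rep("C", n)
  # helices: two consecutive i -> i+4 bonds cover residues i+1 .. i+4
  if (n >= 6) {
    for (i in seq_len(n - 5)) {
      if (hb[i, i + 4] && hb[i + 1, i + 5]) lab[(i + 1):(i + 4)] <- "H"
    }
  }
  # bridges
  bridge <- rep(FALSE, n)
  if (n >= 6) for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) <= 2) next
      par <- (hb[i - 1, j] && hb[j, i + 1]) ||
             (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
              (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) bridge[c(i, j)] <- TRUE
    }
  }
  lab[bridge & lab != "H"] <- "E"
  lab[incomplete] <- "C"
  stats::setNames(lab, bb$res)
}

#' Secondary-structure propensity along a trajectory
#'
#' Per-residue fraction of frames assigned to each of H, E and C by
#' \code{\link{assignSecondaryStructure}}.
#'
#' @param traj a \linkS4class{Trajectory} (>= 1 frame).
#' @param residues optional residue numbers to report (default all).
#' @return list with \code{labels} (frames x residues character
#'   matrix, columns named by residue) and \code{propensity}
#'   (data.frame \code{resnum}, \code{H}, \code{E}, \code{C}; rows sum
#'   to 1).
#' @export
ssPropensity <- function(traj, residues = NULL) {
  stopifnot(is(traj, "Trajectory"), nFrames(traj) >= 1)
  nf <- nFrames(traj)
  labs <- t(vapply(seq_len(nf), function(i)
    assignSecondaryStructure(trajectoryFrame(traj, i)),
    character(length(unique(traj@atoms$resnum)))))
  res <- as.integer(colnames(labs))
  keep <- if (is.null(residues)) seq_along(res) else match(residues, res)
  if (anyNA(keep)) stop("residue(s) not in the topology")
  prop <- data.frame(
    resnum = res[keep],
    H = colMeans(labs[, keep, drop = FALSE] == "H"),
    E = colMeans(labs[, keep, drop = FALSE] == "E"),
    C = colMeans(labs[, keep, drop = FALSE] == "C"))
  rownames(prop) <- NULL
  list(labels = labs[, keep, drop = FALSE], propensity = prop)
}
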