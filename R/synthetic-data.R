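#' @include AllClasses.R AllGenerics.R utils.R structure-io.R
NULL

# ---- idealized backbone construction ---------------------------------

# Standard backbone internal coordinates (Angstrom / degrees).
.BB <- list(nca = 1.458, cac = 1.525, cn = 1.329, co = 1.231,
            ang_ncac = 111.2, ang_cacn = 116.2, ang_cnca = 121.7,
            ang_caco = 120.8, omega = 180)

# Backbone N/CA/C/O coordinates for n residues at fixed phi/psi.
# Returns a list of n x 3 matrices.
.buildBackbone <- function(n, phi = -57, psi = -47) {
  g <- .BB
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$nca, 0, 0)
  a <- g$ang_ncac * pi / 180
  C[1, ] <- CA[1, ] + g$cac * c(-cos(a), sin(a), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- .placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$cn, g$ang_cacn, psi)
      CA[i, ] <- .placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$nca, g$ang_cnca, g$omega)
      C[i, ] <- .placeAtom(C[i - 1, ], N[i, ], CA[i, ],
                           g$cac, g$ang_ncac, phi)
    }
    # carbonyl O on the psi + 180 side of the peptide plane
    ref <- N[i, ]
    O[i, ] <- .placeAtom(ref, CA[i, ], C[i, ], g$co,
                         g$ang_caco, psi + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

# Assemble a StructureModel from backbone coordinate matrices.
# `extra` is an optional data.frame of additional atoms with columns
# resnum, name, element, x, y, z.
.backboneModel <- function(bb, seq1 = NULL, resnums = NULL,
                           bfactors = NULL, chain = "A",
                           caOnly = FALSE, extra = NULL) {
  n <- nrow(bb$CA)
  resnums <- resnums %||% seq_len(n)
  seq1 <- seq1 %||% paste(rep("G", n), collapse = "")
  bfactors <- bfactors %||% rep(10, n)
  resname <- .aa123(strsplit(seq1, "")[[1]])
  names_per <- if (caOnly) "CA" else c("N", "CA", "C", "O")
  rows <- lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(names_per, function(nm)
      data.frame(name = nm, resname = resname[i], resnum = resnums[i],
                 x = bb[[nm]][i, 1], y = bb[[nm]][i, 2],
                 z = bb[[nm]][i, 3],
                 bfactor = bfactors[i],
                 element = substr(nm, 1, 1),
                 stringsAsFactors = FALSE)))
  })
  a <- do.call(rbind, rows)
  if (!is.null(extra)) {
    extra$resname <- resname[match(extra$resnum, resnums)]
    extra$bfactor <- bfactors[match(extra$resnum, resnums)]
    a <- rbind(a, extra[, names(a)])
  }
  a$serial <- seq_len(nrow(a))
  a$altloc <- " "
  a$chain <- chain
  a$icode <- " "
  a$occupancy <- 1
  a <- a[, .ATOM_COLS]
  new("StructureModel", atoms = .orderAtoms(a), modelId = 1L)
}

# ---- generators -------------------------------------------------------

#' Generate a synthetic target/homolog structure pair
#'
#' Emulates the input of a cross-structure flexibility comparison: two
#' structures of the same fold where the homolog carries a smooth
#' (AR(1)) baseline B-factor profile and the target carries the same
#' profile plus planted normalized-B excesses over chosen segments and
#' optional insertion blocks absent from the homolog. The planted
#' truth is returned alongside, so downstream segment calling can be
#' scored against it.
#'
#' @param nRes residues in the target.
#' @param plantedSegments list of \code{c(start, end, delta)} triples:
#'   target residue ranges whose normalized B-factor is raised by
#'   \code{delta} relative to the homolog.
#' @param gapBlocks list of \code{c(start, len)} pairs: target residue
#'   stretches deleted from the homolog (gap-opposite regions).
#' @param noiseSd standard deviation of the normalized-B noise added
#'   to matched target positions.
#' @param seed integer seed; identical seeds give byte-identical
#'   output files.
#' @param dir optional directory; when given, \code{target.pdb},
#'   \code{homolog.pdb} and \code{truth.tsv} are written there.
#' @return list with \code{target}, \code{homolog}
#'   (\linkS4class{StructureModel}s), \code{truth} (data.frame
#'   \code{start}, \code{end}, \code{delta}, \code{kind}) and
#'   \code{files} (paths or NULL).
#' @export
genStructurePair <- function(nRes = 220,
                             plantedSegments = list(c(207, 210, 1.2)),
                             gapBlocks = list(c(86, 6)),
                             noiseSd = 0.1, seed = 1, dir = NULL) {
  segs <- do.call(rbind, lapply(plantedSegments, function(s)
    data.frame(start = s[1], end = s[2], delta = s[3])))
  gaps <- do.call(rbind, lapply(gapBlocks, function(g)
    data.frame(start = g[1], end = g[1] + g[2] - 1)))
  segPos <- unlist(lapply(seq_len(NROW(segs)), function(i)
    segs$start[i]:segs$end[i]))
  gapPos <- unlist(lapply(seq_len(NROW(gaps)), function(i)
    gaps$start[i]:gaps$end[i]))
  if (anyDuplicated(segPos)) stop("planted segments overlap")
  if (length(intersect(segPos, gapPos)) > 0)
    stop("planted segments overlap gap blocks")
  if (length(c(segPos, gapPos)) > 0 &&
      (max(c(segPos, gapPos)) > nRes || min(c(segPos, gapPos)) < 1))
    stop("planted positions outside 1..nRes")
  .withSeed(seed, {
    aa <- sample(.AA20, nRes, replace = TRUE)
    # make gap placement unambiguous in a global alignment: a deletion
    # block can slide by one at equal score iff its first letter equals
    # the letter after it (or its last equals the one before), so
    # resample those letters to differ
    for (i in seq_len(NROW(gaps))) {
      st <- gaps$start[i]; en <- gaps$end[i]
      if (en + 1 <= nRes && aa[st] == aa[en + 1])
        aa[st] <- sample(setdiff(.AA20, c(aa[en + 1], aa[en])), 1)
      if (st - 1 >= 1 && aa[en] == aa[st - 1])
        aa[en] <- sample(setdiff(.AA20, c(aa[st - 1],
                                          if (en + 1 <= nRes)
                                            aa[en + 1])), 1)
    }
    targetSeq <- paste(aa, collapse = "")
    inHom <- !(seq_len(nRes) %in% gapPos)
    nB <- sum(inHom)
    # homolog baseline: AR(1)-smoothed, standardized, mapped to a
    # positive raw-B scale
    ar <- numeric(nB)
    e <- stats::rnorm(nB)
    for (i in seq_len(nB)) ar[i] <- if (i == 1) e[1]
      else 0.85 * ar[i - 1] + sqrt(1 - 0.85^2) * e[i]
    zB <- as.numeric(scale(ar))
    bB <- pmax(2, 20 + 4 * zB)
    delta <- numeric(nRes)
    for (i in seq_len(NROW(segs)))
      delta[segs$start[i]:segs$end[i]] <- segs$delta[i]
    zA <- numeric(nRes)
    zA[inHom] <- zB + delta[inHom] + stats::rnorm(nB, 0, noiseSd)
    zA[!inHom] <- stats::rnorm(sum(!inHom), 0.8, 0.3)
    bA <- pmax(2, 25 + 6 * zA)
    bbA <- .buildBackbone(nRes, phi = -139, psi = 135)
    target <- .backboneModel(bbA, targetSeq, bfactors = round(bA, 2))
    homSeq <- paste(strsplit(targetSeq, "")[[1]][inHom], collapse = "")
    bbB <- lapply(bbA, function(m) m[inHom, , drop = FALSE])
    homolog <- .backboneModel(bbB, homSeq, resnums = seq_len(nB),
                              bfactors = round(bB, 2), chain = "B")
    truth <- rbind(
      if (NROW(segs) > 0)
        data.frame(start = segs$start, end = segs$end,
                   delta = segs$delta, kind = "matched"),
      if (NROW(gaps) > 0)
        data.frame(start = gaps$start, end = gaps$end, delta = NA_real_,
                   kind = "gap-opposite"))
    if (is.null(truth))
      truth <- data.frame(start = integer(0), end = integer(0),
                          delta = numeric(0), kind = character(0))
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      files <- file.path(dir, c("target.pdb", "homolog.pdb", "truth.tsv"))
      writeStructure(target, files[1])
      writeStructure(homolog, files[2])
      utils::write.table(truth, files[3], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    list(target = target, homolog = homolog, truth = truth, files = files)
  })
}

#' Generate a synthetic aligned protein family (MSA)
#'
#' Produces an ungapped alignment of \code{nSeq} sequences of length
#' \code{refLength} in which chosen reference positions carry exact
#' planted residue counts (frequencies rounded to the nearest count of
#' \code{nSeq}) while all other columns are i.i.d. uniform over the 20
#' amino acids. Record 1 is the reference (\code{refId}); its residue
#' at each planted column is set by \code{refResidues} (default: the
#' most frequent planted residue).
#'
#' @param nSeq number of sequences.
#' @param refLength alignment length (ungapped).
#' @param columns named list: names are reference positions, values
#'   are named frequency vectors, e.g.
#'   \code{list("207" = c(S = 0.31, N = 0.07))}; the planted
#'   frequencies of a column must sum to at most 1.
#' @param refResidues optional named character vector (position ->
#'   residue) giving the reference's own residue at planted columns.
#' @param refSeq optional full reference sequence (length
#'   \code{refLength}); when given, record 1 is exactly this sequence
#'   and its residues at planted columns must carry a planted count.
#' @param refId reference record identifier (default "ref").
#' @param seed integer seed.
#' @param file optional FASTA output path.
#' @return list with \code{msa} (an \linkS4class{Msa}), \code{truth}
#'   (data.frame \code{refPos}, \code{residue}, \code{count},
#'   \code{freq}) and \code{file}.
#' @export
genMsa <- function(nSeq = 100, refLength = 230,
                   columns = list("207" = c(S = 0.31, N = 0.07)),
                   refResidues = NULL, refSeq = NULL, refId = "ref",
                   seed = 1, file = NULL) {
  stopifnot(nSeq >= 1, refLength >= 1)
  if (!is.null(refSeq)) {
    if (nchar(refSeq) != refLength)
      stop("refSeq length must equal refLength")
    if (is.null(refResidues) && length(columns) > 0)
      refResidues <- stats::setNames(
        vapply(as.integer(names(columns)),
               function(p) substr(refSeq, p, p), character(1)),
        names(columns))
  }
  for (nm in names(columns)) {
    f <- columns[[nm]]
    if (is.null(names(f)) || !all(names(f) %in% .AA20))
      stop("invalid frequency spec at position ", nm)
    if (sum(f) > 1 + 1e-9)
      stop("planted frequencies at position ", nm, " exceed 1")
  }
  .withSeed(seed, {
    mat <- matrix(sample(.AA20, nSeq * refLength, replace = TRUE),
                  nrow = nSeq)
    if (!is.null(refSeq)) mat[1, ] <- strsplit(refSeq, "")[[1]]
    truth <- list()
    for (nm in names(columns)) {
      p <- as.integer(nm)
      if (p < 1 || p > refLength) stop("planted position ", p,
                                       " outside the alignment")
      f <- columns[[nm]]
      counts <- round(f * nSeq)
      if (sum(counts) > nSeq) stop("planted counts at ", p, " exceed nSeq")
      refAa <- if (!is.null(refResidues) && nm %in% names(refResidues))
        refResidues[[nm]] else names(f)[which.max(f)]
      if (!refAa %in% names(counts) || counts[refAa] < 1)
        stop("reference residue '", refAa, "' at ", p,
             " has a planted count of zero")
      pool <- rep(names(counts), counts)
      bg <- setdiff(.AA20, names(counts))
      fill <- sample(bg, nSeq - length(pool), replace = TRUE)
      vec <- c(pool, fill)
      # reference takes one of the refAa slots; the rest are shuffled
      vec <- vec[-match(refAa, vec)]
      mat[, p] <- c(refAa, sample(vec))
      truth[[nm]] <- data.frame(refPos = p, residue = names(counts),
                                count = as.integer(counts),
                                freq = as.numeric(counts) / nSeq)
    }
    ids <- c(refId, sprintf("seq_%03d", seq_len(nSeq - 1) + 1))[seq_len(nSeq)]
    seqs <- apply(mat, 1, paste, collapse = "")
    msa <- new("Msa", ids = ids, seqs = unname(seqs))
    truth <- if (length(truth) > 0) do.call(rbind, truth)
             else data.frame(refPos = integer(0), residue = character(0),
                             count = integer(0), freq = numeric(0))
    rownames(truth) <- NULL
    if (!is.null(file)) writeFasta(stats::setNames(seqs, ids), file)
    list(msa = msa, truth = truth, file = file)
  })
}

#' Generate a synthetic trajectory with known statistical truth
#'
#' Three modes, each a toy emulation of an analyzed simulation:
#' \describe{
#'   \item{harmonic}{a C-alpha-only reference chain with i.i.d.
#'     Gaussian per-axis jitter of per-residue standard deviation
#'     \code{sigma}; the true RMSF is \code{sigma * sqrt(3)}.}
#'   \item{hbond_schedule}{a donor/acceptor pair driven inside (2.9
#'     Angstrom, collinear) or outside (5 Angstrom) the geometric
#'     criteria by a logical \code{schedule}; the true occupancy is
#'     \code{mean(schedule)}.}
#'   \item{ss_ideal}{full-backbone frames built from ideal phi/psi
#'     (helix -57/-47, strand -139/135, or an antiparallel
#'     \code{hairpin}); an optional per-frame \code{ssSchedule} of
#'     "H"/"C" alternates helix-built and strand-built frames.}
#' }
#'
#' @param mode one of "harmonic", "hbond_schedule", "ss_ideal".
#' @param nRes residues (harmonic and ss_ideal modes).
#' @param nFrames frames (harmonic mode; the other modes take their
#'   length from \code{schedule} / \code{ssSchedule}).
#' @param sigma per-residue jitter sd in Angstrom (scalar or length
#'   \code{nRes}), harmonic mode.
#' @param schedule logical vector, hbond_schedule mode.
#' @param geometry "helix", "strand" or "hairpin" (ss_ideal mode).
#' @param ssSchedule optional character vector of "H"/"C" per frame
#'   (ss_ideal mode, helix/strand geometries).
#' @param dt ps per frame.
#' @param seed integer seed (harmonic mode randomness).
#' @param file optional multi-model PDB output path.
#' @return list with \code{traj} (a \linkS4class{Trajectory}),
#'   \code{truth} (mode-specific), and \code{file}.
#' @export
genTrajectory <- function(mode = c("harmonic", "hbond_schedule",
                                   "ss_ideal"),
                          nRes = 10, nFrames = 100, sigma = 0.1,
                          schedule = NULL, geometry = "helix",
                          ssSchedule = NULL, dt = 1, seed = 1,
                          file = NULL) {
  mode <- match.arg(mode)
  out <- switch(mode,
    harmonic = {
      if (any(sigma <= 0)) stop("sigma must be positive")
      sig <- rep_len(sigma, nRes)
      bb <- .buildBackbone(nRes, phi = -139, psi = 135)
      ref <- .backboneModel(bb, caOnly = TRUE)
      xyz0 <- as.matrix(ref@atoms[, c("x", "y", "z")])
      coords <- .withSeed(seed, {
        arr <- array(NA_real_, c(nFrames, nRes, 3))
        for (f in seq_len(nFrames))
          arr[f, , ] <- xyz0 + stats::rnorm(nRes * 3) * sig
        arr
      })
      traj <- new("Trajectory", atoms = ref@atoms, coords = coords,
                  dt = dt)
      list(traj = traj,
           truth = data.frame(resnum = seq_len(nRes),
                              rmsf = sig * sqrt(3)))
    },
    hbond_schedule = {
      if (is.null(schedule) || length(schedule) == 0)
        stop("hbond_schedule mode needs a non-empty logical schedule")
      schedule <- as.logical(schedule)
      model <- .hbondPairModel()
      a <- model@atoms
      xyz <- as.matrix(a[, c("x", "y", "z")])
      accRow <- which(a$resnum == 5 & a$name == "O")
      coords <- array(NA_real_, c(length(schedule), nrow(a), 3))
      for (f in seq_along(schedule)) {
        xi <- xyz
        # acceptor O sits on the N-H axis: 2.9 A (bonded) or 5 A (not)
        xi[accRow, ] <- c(0, 0, if (schedule[f]) -2.9 else -5.0)
        coords[f, , ] <- xi
      }
      traj <- new("Trajectory", atoms = a, coords = coords, dt = dt)
      list(traj = traj,
           truth = list(occupancy = mean(schedule),
                        donorRes = 1, donorAtom = "N",
                        acceptorRes = 5, acceptorAtom = "O"))
    },
    ss_ideal = {
      phipsi <- switch(geometry,
        helix = c(-57, -47), strand = c(-139, 135), hairpin = NULL,
        stop("unknown geometry '", geometry, "'"))
      if (identical(geometry, "hairpin")) {
        model <- .hairpinModel(nRes)
        nf <- max(1, nFrames)
        coords <- array(NA_real_, c(nf, nrow(model@atoms), 3))
        xyz <- as.matrix(model@atoms[, c("x", "y", "z")])
        for (f in seq_len(nf)) coords[f, , ] <- xyz
        traj <- new("Trajectory", atoms = model@atoms, coords = coords,
                    dt = dt)
        list(traj = traj, truth = list(geometry = "hairpin"))
      } else {
        ssSchedule <- ssSchedule %||% rep("H", max(1, nFrames))
        if (!all(ssSchedule %in% c("H", "C")))
          stop("ssSchedule must contain only 'H' and 'C'")
        bbH <- .buildBackbone(nRes, phipsi[1], phipsi[2])
        bbC <- .buildBackbone(nRes, -139, 135)
        mH <- .backboneModel(bbH)
        mC <- .backboneModel(bbC)
        coords <- array(NA_real_, c(length(ssSchedule),
                                    nrow(mH@atoms), 3))
        for (f in seq_along(ssSchedule)) {
          m <- if (ssSchedule[f] == "H") mH else mC
          coords[f, , ] <- as.matrix(m@atoms[, c("x", "y", "z")])
        }
        traj <- new("Trajectory", atoms = mH@atoms, coords = coords,
                    dt = dt)
        list(traj = traj,
             truth = list(geometry = geometry, schedule = ssSchedule,
                          helixFraction = mean(ssSchedule == "H")))
      }
    })
  if (!is.null(file)) writeStructure(out$traj, file)
  out$file <- file
  out
}

# Minimal donor/acceptor geometry for scripted H-bond trajectories:
# residue 1 glycine with an amide H pointing down -z, residue 5
# glycine whose carbonyl O is moved along that axis per frame.
.hbondPairModel <- function() {
  mk <- function(resnum, name, element, x, y, z)
    data.frame(name = name, resname = "GLY", resnum = resnum,
               x = x, y = y, z = z, bfactor = 10, element = element,
               stringsAsFactors = FALSE)
  a <- rbind(
    mk(1, "N", "N", 0, 0, 0),
    mk(1, "H", "H", 0, 0, -1.0),
    mk(1, "CA", "C", 1.458, 0, 0),
    mk(1, "C", "C", 2.0, 1.4, 0),
    mk(1, "O", "O", 3.2, 1.5, 0),
    mk(5, "N", "N", 0, 8, -4),
    mk(5, "CA", "C", 1.458, 8, -4),
    mk(5, "C", "C", 0.6, 0.8, -4.0),
    mk(5, "O", "O", 0, 0, -5.0))
  a$serial <- seq_len(nrow(a))
  a$altloc <- " "
  a$chain <- "A"
  a$icode <- " "
  a$occupancy <- 1
  new("StructureModel", atoms = .orderAtoms(a[, .ATOM_COLS]),
      modelId = 1L)
}

# Two-strand antiparallel pair with cross-strand registration: an
# extended strand is canonicalized (axis along x, centered), its
# 180-degree rotation about z becomes the partner, and the partner is
# offset so that cross-strand CO/NH pairs satisfy the Kabsch-Sander
# energy criterion. The offset constants are checked by the
# secondary-structure tests (strand cores label E).
.hairpinModel <- function(nRes = 12) {
  n1 <- ceiling(nRes / 2)
  n2 <- nRes - n1
  stopifnot(n1 >= 3, n2 >= 3, n1 == n2)
  bb <- .buildBackbone(n1, phi = -139, psi = 135)
  ctr <- colMeans(bb$CA)
  u <- stats::prcomp(bb$CA)$rotation[, 1]
  if (u[1] < 0) u <- -u
  v <- .unit(.cross3(u, c(0, 0, 1)))
  w <- .cross3(u, v)
  R <- rbind(u, w, v)
  th <- .HAIRPIN_ROLL
  Rx <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  bb <- lapply(bb[c("N", "CA", "C", "O")],
               function(m) t(Rx %*% R %*% (t(m) - ctr)))
  off <- .HAIRPIN_OFFSET
  rot <- function(m) sweep(m %*% diag(c(-1, -1, 1)), 2, off, `+`)
  bb2 <- lapply(bb, rot)
  bbAll <- list(N = rbind(bb$N, bb2$N), CA = rbind(bb$CA, bb2$CA),
                C = rbind(bb$C, bb2$C), O = rbind(bb$O, bb2$O))
  .backboneModel(bbAll, resnums = seq_len(n1 + n2))
}

# Roll of the canonicalized strand about its axis (radians) and rigid
# offset of the rotated partner strand (x, y, z, Angstrom); chosen so
# the cross-strand Kabsch-Sander energies sit well clear of the
# -0.5 kcal/mol bond threshold on both sides.
.HAIRPIN_ROLL <- -0.5
.HAIRPIN_OFFSET <- c(-4.5, 4.0, 0)

#' Generate synthetic Michaelis-Menten rate data
#'
#' v = Vmax S / (Km + S) times multiplicative Gaussian noise
#' (1 + eps), eps ~ N(0, noiseCv).
#'
#' @param Vmax,Km true parameters (positive).
#' @param conc substrate concentrations (default eight values spanning
#'   0.5 to 5 mg/mL).
#' @param noiseCv coefficient of variation of the noise (0 = exact).
#' @param seed integer seed.
#' @param file optional CSV output path (columns S, v).
#' @return list with \code{data} (data.frame \code{S}, \code{v}),
#'   \code{truth} (list Vmax, Km) and \code{file}.
#' @export
genKinetics <- function(Vmax = 278, Km = 1.5,
                        conc = seq(0.5, 5, length.out = 8),
                        noiseCv = 0, seed = 1, file = NULL) {
  stopifnot(Vmax > 0, Km > 0, all(conc > 0), noiseCv >= 0)
  v0 <- Vmax * conc / (Km + conc)
  v <- if (noiseCv > 0)
    .withSeed(seed, v0 * (1 + stats::rnorm(length(conc), 0, noiseCv)))
  else v0
  d <- data.frame(S = conc, v = v)
  if (!is.null(file))
    utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
  list(data = d, truth = list(Vmax = Vmax, Km = Km), file = file)
}
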