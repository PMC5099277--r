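#' Canonical phi/psi presets for helix classes
#'
#' Backbone torsion presets that land inside the default typing bands and
#' produce the correct exclusive hydrogen-bond ladders when built with
#' \code{\link{makeBackbone}}: alpha (-63, -42) gives an i<-i+4 ladder,
#' 3-10 (-49, -26) i<-i+3, pi (-57, -70) i<-i+5.
#'
#' @param class One of "ALPHA", "G310", "PI".
#' @return Numeric length-2 vector c(phi, psi) in degrees.
#' @export
phiPsiPreset <- function(class = c("ALPHA", "G310", "PI")) {
  class <- match.arg(class)
  switch(class,
         ALPHA = c(phi = -63, psi = -42),
         G310  = c(phi = -49, psi = -26),
         PI    = c(phi = -57, psi = -70))
}

#' Ideal parametric CA helix
#'
#' CA positions of an exact circular helix: point k (k = 0..n-1) at
#' (r cos(k t + phase), r sin(k t + phase), k d) for twist t, rise d and
#' radius r. Every 4-CA window of the result returns exactly (t, d, r) from
#' \code{\link{localStepParams}}, with axis (0, 0, 1).
#'
#' @param n Number of residues (>= 4).
#' @param twist Twist per residue in degrees, in (0, 180).
#' @param rise Rise per residue in Angstrom (> 0).
#' @param radius Helix radius in Angstrom (> 0).
#' @param phase Phase offset in degrees (default 0).
#' @return n x 3 coordinate matrix with rownames 1..n and the generator
#'   parameters in attribute \code{params}.
#' @export
makeParametricCA <- function(n, twist = 100, rise = 1.5, radius = 2.3,
                             phase = 0) {
  if (n < 4L) stop("n must be >= 4")
  if (twist <= 0 || twist >= 180) stop("twist must be in (0, 180) degrees")
  if (rise <= 0) stop("rise must be > 0")
  if (radius <= 0) stop("radius must be > 0")
  k <- 0:(n - 1L)
  th <- (k * twist + phase) * pi / 180
  m <- cbind(radius * cos(th), radius * sin(th), k * rise)
  rownames(m) <- seq_len(n)
  attr(m, "params") <- c(twist = twist, rise = rise, radius = radius)
  m
}

#' Build a full backbone from phi/psi angles
#'
#' Constructs N, CA, C, O (and CB, except for glycine) coordinates for a
#' chain with the given backbone torsions, using ideal geometry: bonds
#' N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 A; angles N-CA-C 111.2,
#' CA-C-N 116.2, C-N-CA 121.7, CA-C-O 120.8 degrees; omega fixed at 180
#' (trans). CB is placed at the ideal tetrahedral position (needed for
#' CB-H...O analyses). phi(1) and psi(n) do not affect the build except that
#' psi(n) orients the final carbonyl. Torsions round-trip through
#' \code{\link{phiPsi}} exactly (to numerical precision).
#'
#' @param phi,psi Numeric vectors of torsions in degrees (length n). A single
#'   value is recycled.
#' @param n Number of residues (default: length of phi/psi).
#' @param sequence Residue names: a character vector of 3-letter codes, a
#'   1-letter string (e.g. "AAPA"), or NULL for poly-alanine.
#' @param chain Chain identifier (default "A").
#' @param seqStart First author residue number (default 1).
#' @return A \linkS4class{ResidueSet}.
#' @export
makeBackbone <- function(phi, psi, n = max(length(phi), length(psi)),
                         sequence = NULL, chain = "A", seqStart = 1L) {
  if (!all(is.finite(phi)) || !all(is.finite(psi)))
    stop("phi/psi must be finite")
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  resnames <- .expandSequence(sequence, n)
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329; bCO <- 1.231; bCACB <- 1.521
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7; aCACO <- 120.8
  N <- matrix(0, n, 3L); CA <- N; C <- N; O <- N
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(bNCA, 0, 0)
  C[1L, ] <- CA[1L, ] + bCAC * c(-cos(aNCAC * pi / 180), sin(aNCAC * pi / 180), 0)
  for (i in seq_len(n)[-1L]) {
    N[i, ] <- placeAtom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ], bCN, aCACN,
                        psi[i - 1L])
    CA[i, ] <- placeAtom(CA[i - 1L, ], C[i - 1L, ], N[i, ], bNCA, aCNCA, 180)
    C[i, ] <- placeAtom(C[i - 1L, ], N[i, ], CA[i, ], bCAC, aNCAC, phi[i])
  }
  for (i in seq_len(n)) {
    ps <- if (i < n) dihedralAngle(N[i, ], CA[i, ], C[i, ], N[i + 1L, ]) else psi[i]
    O[i, ] <- placeAtom(N[i, ], CA[i, ], C[i, ], bCO, aCACO, ps + 180)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    at <- rbind(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ])
    if (resnames[i] != "GLY") {
      ## ideal tetrahedral CB from the backbone frame
      b <- CA[i, ] - N[i, ]; cc <- C[i, ] - CA[i, ]
      a <- cross3(b, cc)
      CB <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + CA[i, ]
      at <- rbind(at, CB = CB)
    }
    rows[[i]] <- data.frame(chain = chain, seqnum = seqStart + i - 1L,
                            icode = "", resname = resnames[i],
                            atom = rownames(at),
                            x = at[, 1L], y = at[, 2L], z = at[, 3L],
                            stringsAsFactors = FALSE)
  }
  ResidueSet(do.call(rbind, rows))
}

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.expandSequence <- function(sequence, n) {
  if (is.null(sequence)) return(rep("ALA", n))
  if (length(sequence) == 1L && nchar(sequence) > 3L) {
    s <- strsplit(sequence, "")[[1L]]
    out <- unname(.aa1to3[toupper(s)])
    if (anyNA(out)) stop("unknown 1-letter code in sequence")
  } else if (length(sequence) == 1L && n > 1L) {
    out <- rep(toupper(sequence), n)
  } else out <- toupper(sequence)
  if (length(out) != n) stop("sequence length ", length(out), " != n = ", n)
  out
}

#' Phi/psi series with an inserted perturbed stretch
#'
#' Convenience builder for perturbed backbones: a base-class torsion series
#' of length n with \code{length} consecutive residues switched to another
#' class's preset starting at \code{at} (1-based). Used to plant pi-bulges
#' and 3-10 runs with known ground truth.
#'
#' @param n Total residues.
#' @param base Base class preset (default "ALPHA").
#' @param insert Inserted class preset (e.g. "PI").
#' @param at Start position of the insertion.
#' @param length Number of inserted residues (default 3).
#' @return List with vectors \code{phi} and \code{psi}.
#' @export
perturbedPhiPsi <- function(n, base = "ALPHA", insert = "PI", at, length = 3L) {
  stopifnot(at >= 1L, at + length - 1L <= n)
  pb <- phiPsiPreset(base)
  pi_ <- phiPsiPreset(insert)
  phi <- rep(pb[["phi"]], n); psi <- rep(pb[["psi"]], n)
  idx <- at:(at + length - 1L)
  phi[idx] <- pi_[["phi"]]; psi[idx] <- pi_[["psi"]]
  list(phi = phi, psi = psi)
}

.kinkCore <- function(coords, caIdx, position, angle, direction) {
  if (!(angle > 0 && angle <= 90))
    stop("kink angle must be in (0, 90] degrees")
  ## local axis from the last fully-upstream window
  w <- max(1L, position - 3L)
  if (position < 4L || position > length(caIdx) - 1L)
    stop("kink position must be interior (>= 4 residues on each side)")
  p <- coords[caIdx, , drop = FALSE]
  st <- localStepParams(p[w, ], p[w + 1L, ], p[w + 2L, ], p[w + 3L, ])
  if (!st$ok) stop("cannot determine local axis at the hinge")
  u <- st$axis
  e <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  k0 <- unitVector(e - sum(e * u) * u)
  k <- rodriguesRotate(k0, u, direction)
  hinge <- p[position, ]
  list(k = k, hinge = hinge)
}

#' Insert a rigid hinge (kink) into a helix
#'
#' Rotates everything downstream of the hinge residue rigidly by \code{angle}
#' degrees about an axis through the hinge CA perpendicular to the local
#' helix axis; upstream coordinates are untouched. \code{direction} spins the
#' hinge axis about the helix axis, selecting the kink direction.
#'
#' @param x CA coordinate matrix, or a \linkS4class{ResidueSet} (all atoms of
#'   residues after the hinge are rotated).
#' @param position Hinge residue: row index for the matrix method, author
#'   seqnum for the ResidueSet method. Must be interior.
#' @param angle Kink angle in degrees, in (0, 90].
#' @param direction Azimuth of the hinge axis in degrees (default 0).
#' @param ... Unused.
#' @return Same type as \code{x}.
#' @export
setMethod("insertKink", "matrix", function(x, position, angle, direction = 0, ...) {
  core <- .kinkCore(x, seq_len(nrow(x)), position, angle, direction)
  out <- x
  for (i in seq_len(nrow(x))) {
    if (i > position)
      out[i, ] <- core$hinge + rodriguesRotate(x[i, ] - core$hinge, core$k, angle)
  }
  out
})

#' @rdname insertKink-matrix-method
#' @export
setMethod("insertKink", "ResidueSet", function(x, position, angle,
                                               direction = 0, chain = NULL, ...) {
  a <- atomTable(x)
  if (is.null(chain)) chain <- a$chain[1L]
  ca <- caTrace(x, chain)
  seqs <- attr(ca, "seqnums")
  pos <- match(position, seqs)
  if (is.na(pos)) stop("hinge residue ", position, " not in chain ", chain)
  core <- .kinkCore(ca, seq_len(nrow(ca)), pos, angle, direction)
  move <- a$chain == chain & a$seqnum > position
  for (i in which(move)) {
    v <- c(a$x[i], a$y[i], a$z[i]) - core$hinge
    v <- core$hinge + rodriguesRotate(v, core$k, angle)
    a$x[i] <- v[1L]; a$y[i] <- v[2L]; a$z[i] <- v[3L]
  }
  ResidueSet(a)
})

#' Smoothly curved CA helix
#'
#' A parametric helix whose axis is bent gradually: each residue is rotated
#' about a fixed perpendicular axis by a small cumulative angle so the total
#' axis turning over the helix equals \code{totalBend} degrees with no local
#' break.
#'
#' @param n Number of residues.
#' @param totalBend Total axis turning in degrees (default 30).
#' @param twist,rise,radius,phase As \code{\link{makeParametricCA}}.
#' @return n x 3 coordinate matrix.
#' @export
makeCurvedCA <- function(n, totalBend = 30, twist = 100, rise = 1.5,
                         radius = 2.3, phase = 0) {
  h <- makeParametricCA(n, twist, rise, radius, phase)
  k <- c(1, 0, 0)
  per <- totalBend / (n - 1L)
  out <- h
  for (i in seq_len(n)[-1L])
    out[i, ] <- out[i - 1L, ] + rodriguesRotate(h[i, ] - h[i - 1L, ], k, per * (i - 1L))
  attr(out, "params") <- attr(h, "params")
  out
}

#' Generate a multi-helix bundle with known ground truth
#'
#' Builds several synthetic helices (CA-parametric or full-backbone, with
#' optional kinks and perturbed stretches), places each at a specified
#' centroid with its axis along a specified direction, and returns the
#' combined structure together with a ground-truth ledger: the planted class
#' per helix, all pairwise planted crossing angles (angles between the
#' placement directions) and the vicinity matrix measured on the placed
#' coordinates. Deterministic for a given spec and seed.
#'
#' @param specs List of per-helix specs; each a list with elements \code{n}
#'   (residues), and optionally \code{class} ("ALPHA"/"G310"/"PI", default
#'   ALPHA), \code{mode} ("ca" or "backbone"), \code{kink} (list(position,
#'   angle)), \code{insert} (list(class, at, length)), \code{sequence},
#'   \code{centroid} (3-vector, default origin), \code{direction} (3-vector,
#'   default +Z), \code{phase} (degrees; random under seed if NULL).
#' @param seed Integer seed for any randomised phases (default 1).
#' @param vicinityCutoff Cutoff for the ledger vicinity matrix (default 8).
#' @return List with \code{structure} (a multi-chain
#'   \linkS4class{ResidueSet}, chains A, B, ...), and \code{ledger}: a list
#'   with \code{helices} (data.frame chain/class/kink angle/hinge),
#'   \code{crossings} (data.frame chainA/chainB/angle) and \code{vicinity}
#'   (data.frame chainA/chainB/in_vicinity).
#' @export
generateBundle <- function(specs, seed = 1L, vicinityCutoff = 8) {
  set.seed(as.integer(seed))
  chains <- LETTERS[seq_along(specs)]
  regimes <- list(ALPHA = c(100, 1.5, 2.3), G310 = c(120, 2.0, 1.9),
                  PI = c(85, 1.2, 2.7))
  parts <- vector("list", length(specs))
  dirs <- matrix(0, length(specs), 3L)
  cas <- vector("list", length(specs))
  hel <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    cls <- if (is.null(sp$class)) "ALPHA" else sp$class
    mode <- if (is.null(sp$mode)) "ca" else sp$mode
    phase <- if (is.null(sp$phase)) stats::runif(1L, 0, 360) else sp$phase
    dir <- if (is.null(sp$direction)) c(0, 0, 1) else unitVector(sp$direction)
    cen <- if (is.null(sp$centroid)) c(0, 0, 0) else sp$centroid
    if (mode == "backbone") {
      if (!is.null(sp$insert)) {
        pp <- perturbedPhiPsi(sp$n, base = cls, insert = sp$insert$class,
                              at = sp$insert$at, length = sp$insert$length)
      } else {
        pr <- phiPsiPreset(cls)
        pp <- list(phi = rep(pr[["phi"]], sp$n), psi = rep(pr[["psi"]], sp$n))
      }
      rs <- makeBackbone(pp$phi, pp$psi, sp$n, sequence = sp$sequence,
                         chain = chains[i])
      if (!is.null(sp$kink))
        rs <- insertKink(rs, sp$kink$position, sp$kink$angle)
      a <- atomTable(rs)
      xyz <- as.matrix(a[, c("x", "y", "z")])
    } else {
      rg <- regimes[[cls]]
      ca <- makeParametricCA(sp$n, rg[1L], rg[2L], rg[3L], phase)
      if (!is.null(sp$kink))
        ca <- insertKink(ca, sp$kink$position, sp$kink$angle)
      resn <- .expandSequence(sp$sequence, sp$n)
      a <- data.frame(chain = chains[i], seqnum = seq_len(sp$n), icode = "",
                      resname = resn, atom = "CA",
                      x = ca[, 1L], y = ca[, 2L], z = ca[, 3L],
                      stringsAsFactors = FALSE)
      xyz <- as.matrix(a[, c("x", "y", "z")])
    }
    ## centre, align +Z onto the placement direction, translate
    caRows <- a$atom == "CA"
    xyz <- sweep(xyz, 2L, colMeans(xyz[caRows, , drop = FALSE]))
    ## current overall axis (mean of interior window axes, N-to-C): aligning
    ## the end-to-end vector instead would tilt the placement by the phase
    ## mismatch of the terminal CAs
    caM <- xyz[caRows, , drop = FALSE]
    cur <- overallAxis(stepSeries(caM))$axis
    R <- rotationBetween(cur, dir)
    xyz <- xyz %*% t(R)
    xyz <- sweep(xyz, 2L, cen, "+")
    a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
    parts[[i]] <- a
    dirs[i, ] <- dir
    cas[[i]] <- xyz[caRows, , drop = FALSE]
    hel[[i]] <- data.frame(
      chain = chains[i], class = cls, mode = mode,
      kink_angle = if (is.null(sp$kink)) NA_real_ else sp$kink$angle,
      kink_position = if (is.null(sp$kink)) NA_integer_ else sp$kink$position,
      stringsAsFactors = FALSE)
  }
  if (length(specs) > 1L) {
    pairs <- utils::combn(seq_along(specs), 2L)
    crossings <- data.frame(
      chainA = chains[pairs[1L, ]], chainB = chains[pairs[2L, ]],
      angle = apply(pairs, 2L, function(p)
        crossingAngle(dirs[p[1L], ], dirs[p[2L], ])),
      stringsAsFactors = FALSE)
    vicinity <- data.frame(
      chainA = chains[pairs[1L, ]], chainB = chains[pairs[2L, ]],
      in_vicinity = apply(pairs, 2L, function(p)
        vicinityCheck(cas[[p[1L]]], cas[[p[2L]]], vicinityCutoff)),
      stringsAsFactors = FALSE)
  } else {
    crossings <- data.frame(chainA = character(0), chainB = character(0),
                            angle = numeric(0), stringsAsFactors = FALSE)
    vicinity <- data.frame(chainA = character(0), chainB = character(0),
                           in_vicinity = logical(0), stringsAsFactors = FALSE)
  }
  list(structure = ResidueSet(do.call(rbind, parts)),
       ledger = list(helices = do.call(rbind, hel),
                     crossings = crossings, vicinity = vicinity))
}
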