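#' Local helix parameters of one 4-CA window
#'
#' Computes twist, rise per residue, virtual torsion, helical radius and the
#' unit helix-axis direction cosines from four consecutive CA positions.
#' Writing B1 = p2-p1, B2 = p3-p2, B3 = p4-p3, the construction uses the angle
#' bisectors V1 (of the angle at p2) and V2 (of the angle at p3): the twist is
#' the angle between V1 and V2, the local axis U is the unit cross product
#' V1 x V2 (sign-fixed so U.B2 >= 0, hence rise >= 0 for N-to-C traversal),
#' the rise is B2.U, and the radius follows from projecting the chord B2 onto
#' the plane normal to U: radius = |B2 - (B2.U)U| / (2 sin(twist/2)).
#'
#' On points sampled from an exact circular helix these recover the generator
#' twist, rise and radius to machine precision.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors: consecutive CA coordinates (Angstrom).
#' @return List with elements \code{twist}, \code{rise}, \code{vtor},
#'   \code{radius} (all numeric), \code{axis} (unit 3-vector), and \code{ok}
#'   (FALSE for degenerate/collinear windows, in which case the numeric
#'   elements are NA).
#' @export
localStepParams <- function(p1, p2, p3, p4) {
  bad <- list(twist = NA_real_, rise = NA_real_, vtor = NA_real_,
              radius = NA_real_, axis = c(NA_real_, NA_real_, NA_real_),
              ok = FALSE)
  B2 <- p3 - p2
  v1a <- p1 - p2; v1b <- p3 - p2
  v2a <- p2 - p3; v2b <- p4 - p3
  n1a <- vecNorm(v1a); n1b <- vecNorm(v1b)
  n2a <- vecNorm(v2a); n2b <- vecNorm(v2b)
  if (min(n1a, n1b, n2a, n2b) < 1e-9) return(bad)
  V1 <- v1a / n1a + v1b / n1b
  V2 <- v2a / n2a + v2b / n2b
  if (vecNorm(V1) < 1e-9 || vecNorm(V2) < 1e-9) return(bad)  # collinear
  V1 <- V1 / vecNorm(V1); V2 <- V2 / vecNorm(V2)
  twist <- clampedAcos(sum(V1 * V2)) * 180 / pi
  U <- cross3(V1, V2)
  nU <- vecNorm(U)
  if (nU < 1e-9 || twist < 1e-6) return(bad)  # parallel bisectors
  U <- U / nU
  if (sum(U * B2) < 0) U <- -U
  rise <- sum(U * B2)
  chord <- B2 - sum(B2 * U) * U
  radius <- vecNorm(chord) / (2 * sin(twist / 2 * pi / 180))
  vtor <- dihedralAngle(p1, p2, p3, p4)
  list(twist = twist, rise = rise, vtor = vtor, radius = radius,
       axis = U, ok = TRUE)
}

#' Per-window helix parameter series along a CA trace
#'
#' Slides a 4-CA window along the trace (N-3 windows for N residues) and
#' evaluates \code{\link{localStepParams}} for each, then fills the local
#' bending-angle column against the window \code{offset} windows downstream.
#' The first and last windows are flagged terminal: their bending angles are
#' boundary artifacts and are excluded from MaxBA searches and from overall
#' axis averaging. A CA-CA distance outside (2.0, 4.5] Angstrom inside the
#' trace is reported as a chain break: the affected windows are flagged
#' \code{ok = FALSE} and a warning names the break.
#'
#' @param x Either an n x 3 CA coordinate matrix or a
#'   \linkS4class{ResidueSet} (in which case \code{chain} selects the trace).
#' @param seqnums Author residue numbers of the trace rows (matrix method
#'   only; defaults to rownames or 1..n).
#' @param offset Window offset for the bend column (default 1: successive
#'   windows).
#' @param chain Chain identifier for the ResidueSet method.
#' @param ... Unused.
#' @return A \linkS4class{HelixSteps} object.
#' @export
setMethod("stepSeries", "matrix", function(x, seqnums = NULL, offset = 1L, ...) {
  n <- nrow(x)
  if (n < 4L) stop("trace length must be >= 4 (got ", n, ")")
  if (is.null(seqnums)) {
    seqnums <- if (!is.null(rownames(x))) as.integer(rownames(x)) else seq_len(n)
  }
  d <- sqrt(rowSums((x[-1L, , drop = FALSE] - x[-n, , drop = FALSE])^2))
  breakAfter <- which(d <= 2.0 | d > 4.5)
  if (length(breakAfter))
    warning("chain break(s) inside trace after residue(s) ",
            paste(seqnums[breakAfter], collapse = ", "),
            "; affected windows flagged")
  nw <- n - 3L
  cols <- matrix(NA_real_, nw, 7L)
  ok <- logical(nw)
  for (i in seq_len(nw)) {
    if (length(breakAfter) && any(breakAfter >= i & breakAfter <= i + 2L)) {
      ok[i] <- FALSE
      next
    }
    s <- localStepParams(x[i, ], x[i + 1L, ], x[i + 2L, ], x[i + 3L, ])
    ok[i] <- s$ok
    if (s$ok) cols[i, ] <- c(s$twist, s$rise, s$vtor, s$radius, s$axis)
  }
  steps <- data.frame(start = seqnums[seq_len(nw)],
                      twist = cols[, 1L], rise = cols[, 2L], vtor = cols[, 3L],
                      bend = NA_real_, radius = cols[, 4L],
                      l = cols[, 5L], m = cols[, 6L], n = cols[, 7L],
                      terminal = seq_len(nw) %in% c(1L, nw), ok = ok)
  obj <- new("HelixSteps", steps = steps, offset = as.integer(offset))
  obj@steps$bend <- bendingAngles(obj, offset = offset)
  obj
})

#' @rdname stepSeries-matrix-method
#' @export
setMethod("stepSeries", "ResidueSet", function(x, chain = NULL, offset = 1L, ...) {
  ca <- caTrace(x, chain = chain)
  stepSeries(ca, seqnums = attr(ca, "seqnums"), offset = offset)
})

#' @rdname accessors
#' @export
setMethod("stepTable", "HelixSteps", function(x, ...) x@steps)

setMethod("show", "HelixSteps", function(object) {
  s <- object@steps
  cat("HelixSteps:", nrow(s), "windows, residues", min(s$start), "-",
      max(s$start) + 3L, "(bend offset ", object@offset, ")\n")
  p <- utils::head(s, 8L)
  p[, c("twist", "rise", "vtor", "bend", "radius")] <-
    round(p[, c("twist", "rise", "vtor", "bend", "radius")], 1)
  print(p[, c("start", "twist", "rise", "vtor", "bend", "radius")],
        row.names = FALSE)
  if (nrow(s) > 8L) cat("  ...", nrow(s) - 8L, "more windows\n")
})

#' Local bending angles between window axes
#'
#' bend(i) is the angle in degrees between the local helix axis of window i
#' and that of window i + \code{offset}; NA where the partner window is absent
#' or either window is degenerate.
#'
#' @param steps A \linkS4class{HelixSteps} object.
#' @param offset Positive integer window offset (default 1).
#' @return Numeric vector, one value per window.
#' @export
bendingAngles <- function(steps, offset = 1L) {
  s <- stepTable(steps)
  offset <- as.integer(offset)
  if (offset < 1L) stop("offset must be >= 1")
  n <- nrow(s)
  ax <- as.matrix(s[, c("l", "m", "n")])
  bend <- rep(NA_real_, n)
  for (i in seq_len(max(0L, n - offset))) {
    if (isTRUE(s$ok[i]) && isTRUE(s$ok[i + offset]))
      bend[i] <- clampedAcos(sum(ax[i, ] * ax[i + offset, ])) * 180 / pi
  }
  bend
}

#' Backbone phi/psi torsion angles
#'
#' Standard IUPAC signed dihedrals: phi(i) = C(i-1)-N(i)-CA(i)-C(i),
#' psi(i) = N(i)-CA(i)-C(i)-N(i+1). Values are NA (absent) at chain termini,
#' where backbone atoms are missing, or across chain breaks (peptide-bond
#' C-N distance > 2.5 Angstrom) -- never zero-filled.
#'
#' @param x A \linkS4class{ResidueSet}.
#' @param chain Optional chain restriction.
#' @return data.frame with columns \code{chain}, \code{seqnum}, \code{phi},
#'   \code{psi} (degrees in (-180, 180]).
#' @export
phiPsi <- function(x, chain = NULL) {
  rt <- residueTable(x)
  if (!is.null(chain)) keep <- rt$chain %in% chain else keep <- rep(TRUE, nrow(rt))
  N <- .atomCoords(x, "N"); CA <- .atomCoords(x, "CA"); C <- .atomCoords(x, "C")
  n <- nrow(rt)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  sameChain <- function(i, j) rt$chain[i] == rt$chain[j]
  bonded <- function(ci, nj) {  # C(i) to N(j) peptide bond sanity
    all(is.finite(ci)) && all(is.finite(nj)) && vecNorm(nj - ci) <= 2.5
  }
  for (i in seq_len(n)) {
    if (!keep[i]) next
    if (i > 1L && sameChain(i - 1L, i) &&
        all(is.finite(c(C[i - 1L, ], N[i, ], CA[i, ], C[i, ]))) &&
        bonded(C[i - 1L, ], N[i, ]))
      phi[i] <- dihedralAngle(C[i - 1L, ], N[i, ], CA[i, ], C[i, ])
    if (i < n && sameChain(i, i + 1L) &&
        all(is.finite(c(N[i, ], CA[i, ], C[i, ], N[i + 1L, ]))) &&
        bonded(C[i, ], N[i + 1L, ]))
      psi[i] <- dihedralAngle(N[i, ], CA[i, ], C[i, ], N[i + 1L, ])
  }
  data.frame(chain = rt$chain, seqnum = rt$seqnum, phi = phi, psi = psi,
             stringsAsFactors = FALSE)[keep, ]
}

#' Write a per-window parameter table
#'
#' Tab-separated output mirroring the classical per-step layout: window start,
#' twist, rise, virtual torsion, bend and radius at one decimal place (the
#' print precision of the reference tables); use \code{digits = NA} for full
#' precision.
#'
#' @param steps A \linkS4class{HelixSteps}.
#' @param path Output path.
#' @param digits Decimal places (default 1; NA = full precision).
#' @return Invisibly, \code{path}.
#' @export
writeStepTable <- function(steps, path, digits = 1) {
  s <- stepTable(steps)
  out <- s[, c("start", "twist", "rise", "vtor", "bend", "radius")]
  if (!is.na(digits))
    out[, -1L] <- round(out[, -1L], digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
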