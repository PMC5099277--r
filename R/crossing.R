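#' Overall axis of a helix
#'
#' The overall direction of a TM helix is the unit mean of its interior local
#' window axes (terminal windows excluded to damp end effects), oriented
#' N-to-C; the centroid is the mean CA position. A best-fit-line alternative
#' (first principal component of the CA cloud, sign-aligned N-to-C) is
#' available via \code{method = "fit"}.
#'
#' @param steps A \linkS4class{HelixSteps} for the helix.
#' @param ca Optional CA coordinate matrix (needed for the centroid and for
#'   \code{method = "fit"}).
#' @param method "mean" (default) or "fit".
#' @return List with \code{axis} (unit 3-vector) and \code{centroid}
#'   (3-vector, NA if \code{ca} not supplied).
#' @export
overallAxis <- function(steps, ca = NULL, method = c("mean", "fit")) {
  method <- match.arg(method)
  s <- stepTable(steps)
  interior <- which(!s$terminal & s$ok)
  if (length(interior) < 3L)
    stop("need at least 3 interior windows to define an overall axis (got ",
         length(interior), ")")
  if (method == "mean") {
    ax <- colMeans(as.matrix(s[interior, c("l", "m", "n"), drop = FALSE]))
    axis <- unitVector(ax)
  } else {
    if (is.null(ca)) stop("method = 'fit' requires the CA matrix")
    cc <- sweep(ca, 2L, colMeans(ca))
    axis <- unitVector(svd(cc, nu = 0L, nv = 1L)$v[, 1L])
    if (sum(axis * (ca[nrow(ca), ] - ca[1L, ])) < 0) axis <- -axis
  }
  centroid <- if (is.null(ca)) c(NA_real_, NA_real_, NA_real_) else colMeans(ca)
  list(axis = axis, centroid = centroid)
}

#' Crossing angle between two helix axes
#'
#' The angle between the N-to-C axis direction cosines of two helices,
#' unfolded to [0, 180] degrees (antiparallel packing therefore reads as
#' obtuse angles rather than being folded below 90).
#'
#' @param a,b Outputs of \code{\link{overallAxis}} (or unit 3-vectors).
#' @return Angle in degrees.
#' @export
crossingAngle <- function(a, b) {
  va <- if (is.list(a)) a$axis else a
  vb <- if (is.list(b)) b$axis else b
  va <- unitVector(va); vb <- unitVector(vb)
  atan2(vecNorm(cross3(va, vb)), sum(va * vb)) * 180 / pi
}

#' Are two helices in each other's vicinity?
#'
#' TRUE when the minimum inter-helix CA-CA distance is at most \code{cutoff}
#' Angstrom (default 8) -- the package's proxy for "interacting" helix pairs.
#'
#' @param caA,caB CA coordinate matrices of the two helices.
#' @param cutoff Distance cutoff in Angstrom.
#' @return Logical.
#' @export
vicinityCheck <- function(caA, caB, cutoff = 8) {
  ## min pairwise distance without forming the full n*m matrix for huge inputs
  mind <- Inf
  for (i in seq_len(nrow(caA))) {
    d2 <- rowSums(sweep(caB, 2L, caA[i, ])^2)
    mind <- min(mind, min(d2))
    if (sqrt(mind) <= cutoff) return(TRUE)
  }
  sqrt(mind) <= cutoff
}

#' Pairwise crossing angles against a reference helix
#'
#' Computes the crossing angle of every TM helix against a chosen reference
#' helix, with a vicinity flag marking pairs whose minimum CA-CA distance is
#' within the cutoff (non-interacting pairs can then be set aside, as in the
#' published matrices).
#'
#' @param x A \linkS4class{ResidueSet} for the whole structure.
#' @param segments data.frame from \code{\link{tmSegments}}.
#' @param reference Label of the reference helix (default: first row).
#' @param cutoff Vicinity cutoff in Angstrom (default 8).
#' @return data.frame with one row per non-reference helix: \code{helix},
#'   \code{angle} (degrees, 1 decimal), \code{in_vicinity}.
#' @export
crossingMatrix <- function(x, segments, reference = segments$label[1L],
                           cutoff = 8) {
  parts <- selectSegments(x, segments)
  axes <- lapply(parts, function(rs) {
    ca <- caTrace(rs)
    overallAxis(stepSeries(ca), ca)
  })
  cas <- lapply(parts, caTrace)
  if (!reference %in% names(parts)) stop("reference helix not found: ", reference)
  others <- setdiff(names(parts), reference)
  data.frame(
    helix = others,
    angle = round(vapply(others, function(h)
      crossingAngle(axes[[reference]], axes[[h]]), numeric(1)), 1),
    in_vicinity = vapply(others, function(h)
      vicinityCheck(cas[[reference]], cas[[h]], cutoff), logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
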