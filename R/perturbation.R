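#' Geometric class of a TM helix: linear, curved or kinked
#'
#' Classifies the overall geometry of one helix from its local bending-angle
#' series. Bends are evaluated between window pairs separated by
#' \code{bracketOffset} windows (default 4): a sharp hinge is only measured in
#' full by pairs whose windows lie on opposite sides of it, and a smooth
#' curve accumulates enough turning over four windows to be distinguishable
#' from noise (successive-window bends underestimate both; see the package
#' vignette). Terminal windows are excluded -- their axes are boundary
#' artifacts.
#'
#' Rules: KINKED when the maximum interior bend reaches \code{kinkThreshold};
#' otherwise CURVED when the mean interior bend reaches \code{curveThreshold}
#' and the bending direction is consistent (angle between the first-quarter
#' and last-quarter mean axes at least \code{axisTurnMin}); otherwise LINEAR.
#' The MaxBA locus is the CA2 residue of the later window of the sharpest
#' successive-window pair.
#'
#' @param steps A \linkS4class{HelixSteps}.
#' @param kinkThreshold Kink threshold in degrees (default 20).
#' @param curveThreshold Mean-bend threshold in degrees (default 6).
#' @param bracketOffset Window offset for the bend series (default 4).
#' @param axisTurnMin Minimum first-to-last-quarter axis angle for CURVED
#'   (default 15 degrees).
#' @return List with \code{class} (LINEAR/CURVED/KINKED, or UNCLASSIFIED with
#'   a \code{reason} when fewer than 6 interior bends exist), \code{maxbaSeq},
#'   \code{maxbaValue}, \code{meanBend}, \code{axisTurn}.
#' @export
geometryClass <- function(steps, kinkThreshold = 20, curveThreshold = 6,
                          bracketOffset = 4L, axisTurnMin = 15) {
  s <- stepTable(steps)
  n <- nrow(s)
  interior <- which(!s$terminal & s$ok)
  bends <- bendingAngles(steps, offset = bracketOffset)
  ## a bend value is interior when both windows of its pair are interior
  use <- intersect(interior, interior - bracketOffset)
  bends <- bends[use]
  bends <- bends[is.finite(bends)]
  if (length(bends) < 6L)
    return(list(class = "UNCLASSIFIED",
                reason = paste0("only ", length(bends),
                                " interior bend values (need >= 6)"),
                maxbaSeq = NA_integer_, maxbaValue = NA_real_,
                meanBend = NA_real_, axisTurn = NA_real_))
  maxba <- max(bends)
  ## locus from the sharpest successive-window pair (CA2 of the later window)
  b1 <- bendingAngles(steps, offset = 1L)
  use1 <- intersect(interior, interior - 1L)
  b1v <- b1[use1]
  locus <- if (length(b1v) && any(is.finite(b1v))) {
    i <- use1[which.max(b1v)]
    as.integer(s$start[i + 1L] + 1L)
  } else NA_integer_
  ## direction consistency: first vs last quarter of interior axes
  ax <- as.matrix(s[interior, c("l", "m", "n"), drop = FALSE])
  q <- max(1L, floor(nrow(ax) / 4))
  a1 <- colMeans(ax[seq_len(q), , drop = FALSE])
  a2 <- colMeans(ax[seq(nrow(ax) - q + 1L, nrow(ax)), , drop = FALSE])
  axisTurn <- vectorAngle(a1, a2)
  cls <- if (maxba >= kinkThreshold) "KINKED"
  else if (mean(bends) >= curveThreshold && axisTurn >= axisTurnMin) "CURVED"
  else "LINEAR"
  list(class = cls, maxbaSeq = locus, maxbaValue = maxba,
       meanBend = mean(bends), axisTurn = axisTurn)
}

#' Perturbation type of a TM helix
#'
#' Combines the segment typing, the geometric class and the sequence into one
#' of the nine perturbation types (or the LINEAR / CURVED references). The
#' priority order mirrors the mutual exclusivity of the perturbation
#' taxonomy: an interspersed pi segment outranks a 3-10 segment, which
#' outranks a kink, then curvature, then linearity. Co-occurring features are
#' resolved by this order.
#'
#' Proline attribution: for a pi or 3-10 segment, the perturbation is
#' proline-mediated when a proline lies within
#' \code{[segment_first - 1, segment_last + prolineWindow]}. For a kink:
#' KINKED_PRO_P1 when a proline sits at MaxBA or MaxBA+1, KINKED_PRO_P2 when
#' a proline lies elsewhere within \code{[MaxBA - 4, MaxBA + 5]}, otherwise
#' KINKED_NONPRO. Curved/linear helices are *_PRO when they contain any
#' proline.
#'
#' @param geometry Output of \code{\link{geometryClass}}.
#' @param segments A \linkS4class{HelixSegments} for the helix.
#' @param prolines Integer vector: author residue numbers of prolines within
#'   the helix (may be empty).
#' @param helixId Label for the helix (e.g. "TM2").
#' @param prolineWindow Window (residues) downstream of a perturbed segment
#'   within which a proline is credited (default 4).
#' @return A \linkS4class{PerturbationRecord}.
#' @export
perturbationType <- function(geometry, segments, prolines = integer(0),
                             helixId = "TM", prolineWindow = 4L) {
  seg <- segmentTable(segments)
  region <- segments@region
  prolines <- as.integer(prolines)
  mk <- function(cls, pro = NA_integer_, segrow = seg[0L, ]) {
    new("PerturbationRecord", helixId = helixId, pertClass = cls,
        maxbaSeq = if (is.null(geometry$maxbaSeq)) NA_integer_ else
          as.integer(geometry$maxbaSeq),
        maxbaValue = if (is.null(geometry$maxbaValue)) NA_real_ else
          as.numeric(geometry$maxbaValue),
        prolineSeq = as.integer(pro), segment = segrow)
  }
  if (identical(geometry$class, "UNCLASSIFIED")) return(mk("UNCLASSIFIED"))
  ## interspersed pi, then 3-10 (interspersed or terminal): a perturbed
  ## segment is any non-alpha segment that does not span the whole region
  pick <- function(cls) {
    rows <- seg[seg$class == cls &
                  !(seg$first <= region[1L] & seg$last >= region[2L]), ,
                drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    rows[which.max(rows$last - rows$first), , drop = FALSE]
  }
  for (cls in c("PI", "G310")) {
    row <- pick(cls)
    if (!is.null(row)) {
      inWin <- prolines[prolines >= row$first - 1L &
                          prolines <= row$last + prolineWindow]
      tag <- if (cls == "PI") "PI" else "G310"
      if (length(inWin)) return(mk(paste0(tag, "_PRO"), inWin[1L], row))
      return(mk(paste0(tag, "_NONPRO"), segrow = row))
    }
  }
  if (geometry$class == "KINKED") {
    mb <- geometry$maxbaSeq
    p1 <- prolines[prolines %in% c(mb, mb + 1L)]
    if (length(p1)) return(mk("KINKED_PRO_P1", p1[1L]))
    p2 <- prolines[prolines >= mb - 4L & prolines <= mb + 5L]
    if (length(p2)) return(mk("KINKED_PRO_P2", p2[1L]))
    return(mk("KINKED_NONPRO"))
  }
  base <- geometry$class  # CURVED or LINEAR
  if (length(prolines)) return(mk(paste0(base, "_PRO"), prolines[1L]))
  mk(base)
}

#' @rdname accessors
#' @export
setMethod("pertClass", "PerturbationRecord", function(x, ...) x@pertClass)

#' @rdname accessors
#' @export
setMethod("maxbaSeq", "PerturbationRecord", function(x, ...) x@maxbaSeq)

#' @rdname accessors
#' @export
setMethod("maxbaValue", "PerturbationRecord", function(x, ...) x@maxbaValue)

#' @rdname accessors
#' @export
setMethod("prolineSeq", "PerturbationRecord", function(x, ...) x@prolineSeq)

setMethod("show", "PerturbationRecord", function(object) {
  cat("PerturbationRecord ", object@helixId, ": ", object@pertClass, sep = "")
  if (!is.na(object@maxbaSeq))
    cat("  MaxBA ", round(object@maxbaValue, 1), "° at ", object@maxbaSeq,
        sep = "")
  if (!is.na(object@prolineSeq)) cat("  Pro", object@prolineSeq, sep = "")
  cat("\n")
  if (nrow(object@segment))
    cat("  perturbed segment: ", object@segment$first, "-",
        object@segment$last, " (", object@segment$class, ")\n", sep = "")
})

#' Anchor-relative phi/psi report
#'
#' Tabulates backbone torsion angles at fixed offsets relative to the
#' perturbation anchor of a helix (the implicated proline when there is one,
#' otherwise the MaxBA residue): the positions whose carbonyls a perturbation
#' typically leaves unpaired (-4, -3) and the perturbation-inducing residue
#' itself (0). Rows whose position falls outside the available torsions are
#' absent.
#'
#' @param record A \linkS4class{PerturbationRecord}.
#' @param torsions data.frame from \code{\link{phiPsi}}.
#' @param offsets Integer offsets to report (default c(-4, -3, 0)).
#' @return data.frame with columns \code{helix}, \code{class}, \code{offset},
#'   \code{seqnum}, \code{phi}, \code{psi}.
#' @export
torsionReport <- function(record, torsions, offsets = c(-4L, -3L, 0L)) {
  anchor <- if (!is.na(record@prolineSeq)) record@prolineSeq else record@maxbaSeq
  empty <- data.frame(helix = character(0), class = character(0),
                      offset = integer(0), seqnum = integer(0),
                      phi = numeric(0), psi = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.na(anchor)) return(empty)
  rows <- lapply(as.integer(offsets), function(off) {
    i <- which(torsions$seqnum == anchor + off)
    if (!length(i) || (is.na(torsions$phi[i[1L]]) && is.na(torsions$psi[i[1L]])))
      return(NULL)
    data.frame(helix = record@helixId, class = record@pertClass, offset = off,
               seqnum = anchor + off, phi = torsions$phi[i[1L]],
               psi = torsions$psi[i[1L]], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
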