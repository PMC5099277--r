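#' @import methods
NULL

#' ResidueSet: protein residues with backbone and side-chain coordinates
#'
#' A flat atom table (one row per atom) grouped by residue. Residues are
#' identified by author chain identifier, author sequence number and insertion
#' code, in file order. Every residue carries at least a CA atom; N, C and O
#' are required only by the hydrogen-bond and torsion operations.
#'
#' @slot atoms data.frame with columns \code{chain}, \code{seqnum} (integer,
#'   author numbering), \code{icode}, \code{resname} (3-letter code),
#'   \code{atom} (PDB atom name), \code{x}, \code{y}, \code{z} (Angstrom).
#' @exportClass ResidueSet
setClass("ResidueSet", representation(atoms = "data.frame"))

setValidity("ResidueSet", function(object) {
  a <- object@atoms
  need <- c("chain", "seqnum", "icode", "resname", "atom", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) && !all(is.finite(c(a$x, a$y, a$z))))
    return("atom coordinates must be finite")
  key <- paste(a$chain, a$seqnum, a$icode)
  hasCA <- tapply(a$atom, key, function(at) "CA" %in% at)
  if (nrow(a) && !all(hasCA))
    return("every residue must contain a CA atom")
  TRUE
})

#' HelixSteps: per-window local helix parameters
#'
#' One row per 4-CA window along a helix: twist (deg), rise per residue (A),
#' virtual CA torsion (deg), local bending angle (deg, against the window
#' \code{offset} windows downstream), helical radius (A) and the unit axis
#' direction cosines (l, m, n). Terminal windows are flagged; degenerate
#' windows carry \code{ok = FALSE} and NA parameters rather than silent zeros.
#'
#' @slot steps data.frame with columns \code{start} (seqnum of CA1),
#'   \code{twist}, \code{rise}, \code{vtor}, \code{bend}, \code{radius},
#'   \code{l}, \code{m}, \code{n}, \code{terminal}, \code{ok}.
#' @slot offset integer, window offset used for the \code{bend} column.
#' @exportClass HelixSteps
setClass("HelixSteps",
         representation(steps = "data.frame", offset = "integer"))

setValidity("HelixSteps", function(object) {
  s <- object@steps
  need <- c("start", "twist", "rise", "vtor", "bend", "radius",
            "l", "m", "n", "terminal", "ok")
  if (!all(need %in% names(s)))
    return(paste("steps table must have columns:", paste(need, collapse = ", ")))
  okRows <- which(s$ok)
  if (length(okRows)) {
    nrm <- sqrt(s$l[okRows]^2 + s$m[okRows]^2 + s$n[okRows]^2)
    if (any(abs(nrm - 1) > 1e-9)) return("axis direction cosines must be unit length")
    if (any(s$twist[okRows] <= 0 | s$twist[okRows] >= 360))
      return("twist must lie in (0, 360)")
    if (any(s$rise[okRows] < 0)) return("rise must be non-negative (axis oriented along B2)")
  }
  TRUE
})

#' HelixSegments: typed helical segments within one TM helix
#'
#' Result of merging per-window type labels into contiguous alpha / 3-10 / pi
#' segments with residue bounds (author numbering) and mean parameters.
#' Segments are ordered and non-overlapping; residues not covered by any
#' segment are unassigned gaps.
#'
#' @slot segments data.frame with columns \code{first}, \code{last},
#'   \code{class} (ALPHA/G310/PI), \code{mean_twist}, \code{mean_rise},
#'   \code{mean_radius}.
#' @slot region integer length-2, residue bounds of the analysed region.
#' @exportClass HelixSegments
setClass("HelixSegments",
         representation(segments = "data.frame", region = "integer"))

setValidity("HelixSegments", function(object) {
  s <- object@segments
  need <- c("first", "last", "class", "mean_twist", "mean_rise", "mean_radius")
  if (!all(need %in% names(s)))
    return(paste("segments table must have columns:", paste(need, collapse = ", ")))
  if (nrow(s) > 1L) {
    if (is.unsorted(s$first)) return("segments must be ordered")
    if (any(s$first[-1L] <= s$last[-nrow(s)])) return("segments must not overlap")
  }
  if (nrow(s) && any(s$last < s$first)) return("segment last must be >= first")
  TRUE
})

#' PerturbationRecord: perturbation class of one TM helix
#'
#' One TM helix labelled with one of the 11 classes (9 perturbation types plus
#' the LINEAR / CURVED references), together with the locus and magnitude of
#' the maximum local bending angle (MaxBA), the proline locus where one drives
#' the perturbation, and the perturbed 3-10/pi segment where one exists.
#'
#' @slot helixId character label (e.g. "TM2").
#' @slot pertClass one of LINEAR, CURVED, LINEAR_PRO, CURVED_PRO,
#'   KINKED_PRO_P1, KINKED_PRO_P2, KINKED_NONPRO, G310_PRO, G310_NONPRO,
#'   PI_PRO, PI_NONPRO (or UNCLASSIFIED when too few windows exist).
#' @slot maxbaSeq integer residue number at MaxBA (NA if undefined).
#' @slot maxbaValue numeric, MaxBA in degrees.
#' @slot prolineSeq integer residue number of the implicated proline (NA
#'   for non-proline classes).
#' @slot segment data.frame, the perturbed segment row (0 rows if none).
#' @exportClass PerturbationRecord
setClass("PerturbationRecord",
         representation(helixId = "character", pertClass = "character",
                        maxbaSeq = "integer", maxbaValue = "numeric",
                        prolineSeq = "integer", segment = "data.frame"))

.pertClasses <- c("LINEAR", "CURVED", "LINEAR_PRO", "CURVED_PRO",
                  "KINKED_PRO_P1", "KINKED_PRO_P2", "KINKED_NONPRO",
                  "G310_PRO", "G310_NONPRO", "PI_PRO", "PI_NONPRO",
                  "UNCLASSIFIED")

setValidity("PerturbationRecord", function(object) {
  if (!object@pertClass %in% .pertClasses)
    return(paste("unknown perturbation class:", object@pertClass))
  pro <- grepl("_PRO", object@pertClass) && object@pertClass != "KINKED_NONPRO"
  if (pro && is.na(object@prolineSeq))
    return("proline-mediated classes require prolineSeq")
  if (object@pertClass %in% c("G310_PRO", "G310_NONPRO", "PI_PRO", "PI_NONPRO") &&
      nrow(object@segment) == 0L)
    return("3-10/pi classes require the perturbed segment")
  TRUE
})
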