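#' Default helix-typing thresholds
#'
#' Per-window parameter bands used to label each 4-CA window as alpha, 3-10 or
#' pi helical. The bands are configuration defaults calibrated on the packaged
#' per-step fixture (the exact cut-offs of the original assignment programs
#' are not published); every threshold is exposed here so an analysis can be
#' pinned and reproduced. \code{radius} is the class-typical helical radius
#' used as a tie-breaker when user-supplied bands overlap. \code{smoothTwist}
#' is the slack (degrees) by which an outlier window's twist may miss a class
#' band and still be absorbed during segment merging.
#'
#' @return Named list of class bands and merging parameters.
#' @export
typingThresholds <- function() {
  list(
    ALPHA = list(twist = c(93, 108), rise = c(1.30, 1.70), radius = 2.3),
    G310  = list(twist = c(108, 130), rise = c(1.70, 2.30), radius = 1.9),
    PI    = list(twist = c(70, 93),  rise = c(0.70, 1.45), radius = 2.7),
    smoothTwist = 8,
    minSpan = c(ALPHA = 4L, G310 = 3L, PI = 5L)
  )
}

.classPriority <- c(PI = 3L, G310 = 2L, ALPHA = 1L)

#' Label each helix window as alpha, 3-10, pi or unassigned
#'
#' A window matches a class when its twist and rise both fall inside the
#' class band; if several classes match (possible when configured bands
#' overlap), the class whose typical radius is closest to the window radius
#' wins. Windows matching no class, and degenerate windows, are UNASSIGNED.
#'
#' @param steps A \linkS4class{HelixSteps} object, or a data.frame with
#'   columns \code{start}, \code{twist}, \code{rise}, \code{radius} (e.g. a
#'   transcribed per-step table read by \code{\link{readStepFixture}}).
#' @param thresholds As from \code{\link{typingThresholds}}.
#' @return data.frame with columns \code{start} and \code{label}
#'   (ALPHA/G310/PI/UNASSIGNED), one row per window.
#' @export
classifySteps <- function(steps, thresholds = typingThresholds()) {
  s <- if (is(steps, "HelixSteps")) stepTable(steps) else steps
  ok <- if ("ok" %in% names(s)) s$ok else rep(TRUE, nrow(s))
  classes <- c("ALPHA", "G310", "PI")
  lab <- rep("UNASSIGNED", nrow(s))
  for (i in seq_len(nrow(s))) {
    if (!isTRUE(ok[i]) || !is.finite(s$twist[i]) || !is.finite(s$rise[i])) next
    hit <- character(0)
    for (cl in classes) {
      b <- thresholds[[cl]]
      ## half-open on the right so abutting bands cannot double-match
      twIn <- s$twist[i] >= b$twist[1L] &&
        (s$twist[i] < b$twist[2L] || (cl == "G310" && s$twist[i] == b$twist[2L]))
      rsIn <- s$rise[i] >= b$rise[1L] && s$rise[i] <= b$rise[2L]
      if (twIn && rsIn) hit <- c(hit, cl)
    }
    if (length(hit) == 1L) lab[i] <- hit
    else if (length(hit) > 1L) {
      dev <- vapply(hit, function(cl)
        abs(s$radius[i] - thresholds[[cl]]$radius), numeric(1))
      lab[i] <- hit[which.min(dev)]
    }
  }
  data.frame(start = s$start, label = lab, stringsAsFactors = FALSE)
}

.twistInBand <- function(twist, band, slack = 0) {
  is.finite(twist) && twist >= band[1L] - slack && twist <= band[2L] + slack
}

#' Merge per-window labels into typed helical segments
#'
#' Turns the window labels from \code{\link{classifySteps}} into ordered,
#' non-overlapping alpha / 3-10 / pi segments with residue bounds. The
#' procedure:
#' \enumerate{
#'   \item \emph{Smoothing}: a single window whose label disagrees with the
#'     nearest classified windows on both sides (which must agree with each
#'     other) is absorbed into that flanking class when its twist lies within
#'     the class band widened by \code{smoothTwist} degrees. Iterated to a
#'     fixed point, this absorbs isolated parameter outliers inside an
#'     otherwise uniform run.
#'   \item \emph{Boundary anchoring}: a segment may not terminate on a window
#'     that is an isolated raw occurrence of its class (no raw same-class
#'     neighbour window); such terminal windows are trimmed back to
#'     unassigned. A perturbed segment therefore needs two consecutive
#'     raw-labelled windows at its boundary, which suppresses spurious
#'     single-window extensions at segment ends while keeping absorbed
#'     interior outliers.
#'   \item \emph{Minimum span}: runs whose residue span falls below the class
#'     minimum (alpha 4, 3-10 3, pi 5 residues) are absorbed into the longer
#'     flanking run when twist-compatible, otherwise unassigned.
#'   \item \emph{Residue claims}: a run of windows i..j claims residues
#'     i..j+3 (a 4-CA window claims all four residues). Where claims of
#'     adjacent segments overlap, the perturbed class wins (PI > G310 >
#'     ALPHA); between equal priorities the later segment's start prevails.
#' }
#'
#' @param labels data.frame from \code{\link{classifySteps}}.
#' @param steps The matching \linkS4class{HelixSteps} or fixture data.frame.
#' @param thresholds As from \code{\link{typingThresholds}}.
#' @param region Optional length-2 residue bounds of the analysed region
#'   (default: first window start to last window start + 3).
#' @return A \linkS4class{HelixSegments} object.
#' @export
mergeSegments <- function(labels, steps, thresholds = typingThresholds(),
                          region = NULL) {
  s <- if (is(steps, "HelixSteps")) stepTable(steps) else steps
  stopifnot(nrow(s) == nrow(labels))
  start <- labels$start
  lab <- labels$label
  rawlab <- lab
  n <- length(lab)
  if (is.null(region)) region <- c(start[1L], start[n] + 3L)
  region <- as.integer(region)

  runsOf <- function(lab) {
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    data.frame(label = r$values, from = ends - r$lengths + 1L, to = ends,
               stringsAsFactors = FALSE)
  }
  nearestClassified <- function(lab, i, dir) {
    j <- i + dir
    while (j >= 1L && j <= n) {
      if (lab[j] != "UNASSIGNED") return(lab[j])
      j <- j + dir
    }
    NA_character_
  }

  ## 1. smoothing to fixed point
  repeat {
    changed <- FALSE
    rr <- runsOf(lab)
    for (k in seq_len(nrow(rr))) {
      if (rr$to[k] != rr$from[k]) next           # singletons only
      i <- rr$from[k]
      if (i == 1L || i == n) next                # interior only
      left <- nearestClassified(lab, i, -1L)
      right <- nearestClassified(lab, i, +1L)
      if (is.na(left) || is.na(right) || left != right) next
      if (lab[i] == left) next
      if (.twistInBand(s$twist[i], thresholds[[left]]$twist,
                       thresholds$smoothTwist)) {
        lab[i] <- left
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  ## 2. boundary anchoring: trim terminal windows that are isolated raw
  ##    occurrences of the run's own class
  isolatedRaw <- function(i, cl) {
    rawlab[i] == cl &&
      !(i > 1L && rawlab[i - 1L] == cl) &&
      !(i < n && rawlab[i + 1L] == cl)
  }
  repeat {
    changed <- FALSE
    rr <- runsOf(lab)
    for (k in seq_len(nrow(rr))) {
      cl <- rr$label[k]
      if (cl == "UNASSIGNED") next
      if (isolatedRaw(rr$from[k], cl)) { lab[rr$from[k]] <- "UNASSIGNED"; changed <- TRUE }
      else if (rr$to[k] != rr$from[k] && isolatedRaw(rr$to[k], cl)) {
        lab[rr$to[k]] <- "UNASSIGNED"; changed <- TRUE
      }
    }
    if (!changed) break
  }

  ## 3. minimum residue span
  minSpan <- thresholds$minSpan
  repeat {
    changed <- FALSE
    rr <- runsOf(lab)
    for (k in seq_len(nrow(rr))) {
      cl <- rr$label[k]
      if (cl == "UNASSIGNED") next
      span <- (start[rr$to[k]] + 3L) - start[rr$from[k]] + 1L
      if (span >= minSpan[[cl]]) next
      ## absorb into the longer twist-compatible neighbouring run
      nb <- c(if (k > 1L) k - 1L, if (k < nrow(rr)) k + 1L)
      nb <- nb[rr$label[nb] != "UNASSIGNED"]
      if (length(nb)) {
        lens <- rr$to[nb] - rr$from[nb] + 1L
        nb <- nb[order(-lens)]
        done <- FALSE
        for (j in nb) {
          cl2 <- rr$label[j]
          if (all(vapply(rr$from[k]:rr$to[k], function(i)
            .twistInBand(s$twist[i], thresholds[[cl2]]$twist,
                         thresholds$smoothTwist), logical(1)))) {
            lab[rr$from[k]:rr$to[k]] <- cl2
            done <- TRUE
            break
          }
        }
        if (!done) lab[rr$from[k]:rr$to[k]] <- "UNASSIGNED"
      } else lab[rr$from[k]:rr$to[k]] <- "UNASSIGNED"
      changed <- TRUE
      break
    }
    if (!changed) break
  }

  ## 4. residue claims and overlap resolution
  rr <- runsOf(lab)
  rr <- rr[rr$label != "UNASSIGNED", , drop = FALSE]
  if (nrow(rr) == 0L)
    return(new("HelixSegments",
               segments = data.frame(first = integer(0), last = integer(0),
                                     class = character(0),
                                     mean_twist = numeric(0),
                                     mean_rise = numeric(0),
                                     mean_radius = numeric(0),
                                     stringsAsFactors = FALSE),
               region = region))
  first <- start[rr$from]
  last <- pmin(start[rr$to] + 3L, region[2L])
  for (k in seq_len(nrow(rr) - 1L)) {
    if (last[k] >= first[k + 1L]) {  # overlapping claims
      pa <- .classPriority[[rr$label[k]]]
      pb <- .classPriority[[rr$label[k + 1L]]]
      if (pa > pb) first[k + 1L] <- last[k] + 1L
      else last[k] <- first[k + 1L] - 1L
    }
  }
  keep <- last >= first
  rr <- rr[keep, , drop = FALSE]; first <- first[keep]; last <- last[keep]
  seg <- data.frame(
    first = first, last = last, class = rr$label,
    mean_twist = vapply(seq_len(nrow(rr)), function(k)
      mean(s$twist[rr$from[k]:rr$to[k]], na.rm = TRUE), numeric(1)),
    mean_rise = vapply(seq_len(nrow(rr)), function(k)
      mean(s$rise[rr$from[k]:rr$to[k]], na.rm = TRUE), numeric(1)),
    mean_radius = vapply(seq_len(nrow(rr)), function(k)
      mean(s$radius[rr$from[k]:rr$to[k]], na.rm = TRUE), numeric(1)),
    stringsAsFactors = FALSE)
  new("HelixSegments", segments = seg, region = region)
}

#' @rdname accessors
#' @export
setMethod("segmentTable", "HelixSegments", function(x, ...) x@segments)

setMethod("show", "HelixSegments", function(object) {
  s <- object@segments
  cat("HelixSegments: region ", object@region[1L], "-", object@region[2L],
      ", ", nrow(s), " segment(s)\n", sep = "")
  if (nrow(s)) {
    lab <- c(ALPHA = "α", G310 = "3₁₀", PI = "π")[s$class]
    cat(" ", paste0(s$first, "-", s$last, "=", lab, collapse = ", "), "\n")
  }
})

#' Read a transcribed per-step parameter fixture
#'
#' Reads a tab-separated per-step table with columns \code{step} (window
#' start residue number), \code{twist}, \code{rise}, \code{vtor}, \code{bend},
#' \code{radius} -- the layout of published per-step listings. The package
#' ships one such fixture, the TM2 region (residues 51-87) of mitochondrial
#' cytochrome-c oxidase chain A (steps 51-86), under
#' \code{system.file("extdata", "1v55A_tm2_assp_steps.tsv", package =
#' "HelixScan")}.
#'
#' @param path File path.
#' @return data.frame with a \code{start} column plus the parameter columns,
#'   directly usable by \code{\link{classifySteps}}.
#' @export
readStepFixture <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  names(d)[names(d) == "step"] <- "start"
  need <- c("start", "twist", "rise", "radius")
  if (!all(need %in% names(d)))
    stop("fixture must have columns: ", paste(need, collapse = ", "))
  d
}

#' Write a segment table
#'
#' One row per segment: \code{first last class mean_twist mean_rise
#' mean_radius}, tab-separated.
#'
#' @param segments A \linkS4class{HelixSegments}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeSegmentTable <- function(segments, path) {
  s <- segmentTable(segments)
  s[, 4:6] <- round(s[, 4:6], 2)
  utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
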