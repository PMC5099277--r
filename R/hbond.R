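#' Default hydrogen-bond detection criteria
#'
#' Geometric criteria for backbone and stabilising interactions. These are
#' configuration defaults in the literature-standard range (the detection
#' criteria of the original non-bonded-interaction software are not
#' published); they are pinned here so results are reproducible.
#'
#' \itemize{
#'   \item \code{noMax}: backbone N...O donor-acceptor distance cutoff (A).
#'   \item \code{nhoMin}: minimum N-H...O angle at the amide hydrogen (deg);
#'     the hydrogen is built geometrically (in the C(i-1)/N/CA plane, N-H
#'     1.0 A, opposite the bisector of C(i-1)-N-CA).
#'   \item \code{smMax}: side-chain donor (N/O) to carbonyl O distance (A).
#'   \item \code{choMax}: CA/CB-H...O heavy-atom C...O distance (A); no
#'     hydrogen placement is needed. Sequence neighbours (|i-j| <= 1) are
#'     excluded as trivially close.
#'   \item \code{proMax}: proline CD/CG to carbonyl O distance (A).
#' }
#'
#' @return Named list of cutoffs.
#' @export
hbondCriteria <- function() {
  list(noMax = 3.5, nhoMin = 120, smMax = 3.5, choMax = 4.0, proMax = 3.8)
}

## Geometric amide hydrogens for all residues with C(i-1), N(i), CA(i);
## proline has no amide H. Returns matrix aligned with residueTable().
amideHydrogens <- function(rs) {
  rt <- residueTable(rs)
  N <- .atomCoords(rs, "N"); CA <- .atomCoords(rs, "CA"); C <- .atomCoords(rs, "C")
  n <- nrow(rt)
  H <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)[-1L]) {
    if (rt$resname[i] == "PRO") next
    if (rt$chain[i] != rt$chain[i - 1L]) next
    if (!all(is.finite(c(C[i - 1L, ], N[i, ], CA[i, ])))) next
    if (vecNorm(N[i, ] - C[i - 1L, ]) > 2.5) next
    dir <- -(unitVector(C[i - 1L, ] - N[i, ]) + unitVector(CA[i, ] - N[i, ]))
    H[i, ] <- N[i, ] + unitVector(dir)
  }
  H
}

#' Backbone N-H...O hydrogen bonds
#'
#' Detects backbone-backbone hydrogen bonds at helical sequence separations:
#' the donor N of residue i+3 (3-10), i+4 (alpha) or i+5 (pi) to the carbonyl
#' O of residue i, within the same chain. A bond requires N...O distance
#' within \code{noMax} and N-H...O angle at the (geometrically built) amide
#' hydrogen of at least \code{nhoMin}. Proline nitrogens are never donors;
#' residues lacking a carbonyl O are skipped. One carbonyl may accept from
#' several donors (bifurcation is allowed).
#'
#' @param rs A \linkS4class{ResidueSet} with backbone N, CA, C, O atoms.
#' @param criteria As from \code{\link{hbondCriteria}}.
#' @return data.frame with one row per bond: \code{chain},
#'   \code{donor_seq}, \code{acceptor_seq}, \code{sep} (sequence separation),
#'   \code{category} (BB_310/BB_ALPHA/BB_PI), \code{distance} (N...O, A),
#'   \code{angle} (N-H...O, deg).
#' @export
backboneHBonds <- function(rs, criteria = hbondCriteria()) {
  rt <- residueTable(rs)
  N <- .atomCoords(rs, "N"); O <- .atomCoords(rs, "O")
  H <- amideHydrogens(rs)
  n <- nrow(rt)
  cats <- c("3" = "BB_310", "4" = "BB_ALPHA", "5" = "BB_PI")
  rows <- vector("list", 0L)
  for (sep in 3:5) {
    if (n <= sep) next
    acc <- seq_len(n - sep)
    don <- acc + sep
    keep <- rt$chain[acc] == rt$chain[don] &
      is.finite(O[acc, 1L]) & is.finite(N[don, 1L]) & is.finite(H[don, 1L])
    acc <- acc[keep]; don <- don[keep]
    if (!length(acc)) next
    d <- sqrt(rowSums((N[don, , drop = FALSE] - O[acc, , drop = FALSE])^2))
    sel <- d <= criteria$noMax
    acc <- acc[sel]; don <- don[sel]; d <- d[sel]
    if (!length(acc)) next
    ang <- vapply(seq_along(acc), function(k) {
      vectorAngle(N[don[k], ] - H[don[k], ], O[acc[k], ] - H[don[k], ])
    }, numeric(1))
    sel <- ang >= criteria$nhoMin
    if (!any(sel)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chain = rt$chain[don[sel]],
      donor_seq = rt$seqnum[don[sel]], acceptor_seq = rt$seqnum[acc[sel]],
      sep = sep, category = unname(cats[as.character(sep)]),
      distance = d[sel], angle = ang[sel], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(chain = character(0), donor_seq = integer(0),
                      acceptor_seq = integer(0), sep = integer(0),
                      category = character(0), distance = numeric(0),
                      angle = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$chain, out$acceptor_seq, out$sep), , drop = FALSE]
}

#' Unpaired backbone carbonyls within a helix
#'
#' A carbonyl O(i) inside the helix is unpaired when no backbone N-H...O bond
#' reaches it from N(i+3), N(i+4) or N(i+5) with the donor residue inside the
#' helix. Residues within four positions of the helix C-terminus are excluded:
#' their canonical alpha acceptor partner N(i+4) lies outside the helix, so a
#' missing bond there is a boundary artifact, not a perturbation signal.
#'
#' @param rs A \linkS4class{ResidueSet} (the helix, or a larger structure).
#' @param hbonds Output of \code{\link{backboneHBonds}} on \code{rs}.
#' @param region Length-2 residue bounds of the helix (author numbering);
#'   default: full range of \code{rs}.
#' @param chain Chain of the helix (default: first chain).
#' @return data.frame with columns \code{chain}, \code{seqnum} (the residue
#'   whose carbonyl is unpaired).
#' @export
unpairedCarbonyls <- function(rs, hbonds = backboneHBonds(rs), region = NULL,
                              chain = NULL) {
  rt <- residueTable(rs)
  if (is.null(chain)) chain <- rt$chain[1L]
  rt <- rt[rt$chain == chain, , drop = FALSE]
  if (is.null(region)) region <- range(rt$seqnum)
  O <- .atomCoords(rs, "O")
  hasO <- residueTable(rs)$chain == chain & is.finite(O[, 1L])
  seqs <- residueTable(rs)$seqnum[hasO]
  seqs <- seqs[seqs >= region[1L] & seqs <= region[2L] - 4L]
  bb <- hbonds[hbonds$chain == chain &
                 hbonds$category %in% c("BB_310", "BB_ALPHA", "BB_PI") &
                 hbonds$donor_seq >= region[1L] & hbonds$donor_seq <= region[2L], ,
               drop = FALSE]
  unpaired <- sort(setdiff(seqs, bb$acceptor_seq))
  data.frame(chain = rep(chain, length(unpaired)), seqnum = unpaired,
             stringsAsFactors = FALSE)
}

.sideChainDonorNames <- function() {
  ## side-chain nitrogen/oxygen atoms able to donate (N-H / O-H)
  c("ND1", "ND2", "NE", "NE1", "NE2", "NH1", "NH2", "NZ",
    "OG", "OG1", "OH")
}

#' Stabilisation of unpaired carbonyls
#'
#' For each unpaired carbonyl, searches the full structure for stabilising
#' interactions: side-chain-to-main-chain (SM) donors (side-chain N/O within
#' \code{smMax} of the O; intra- or inter-helical), CA-H...O and CB-H...O
#' contacts (heavy-atom C...O within \code{choMax}; counted inter-helically
#' only, because within a helix the i+2..i+4 CA/CB atoms sit within 4
#' Angstrom of every carbonyl by construction and carry no signal), and
#' proline CD/CG contacts (within \code{proMax}). Each stabiliser is tagged
#' intra- or inter-helical according to whether the partner residue lies in
#' the same TM segment as the carbonyl (segment membership, not chain
#' identity, decides the scope; without a segment table, chain identity is
#' the fallback).
#'
#' @param unpaired data.frame from \code{\link{unpairedCarbonyls}}.
#' @param rs The full \linkS4class{ResidueSet} (all helices/chains).
#' @param segments Optional data.frame from \code{\link{tmSegments}} defining
#'   TM segment membership for the intra/inter tag.
#' @param criteria As from \code{\link{hbondCriteria}}.
#' @return List with \code{carbonyls} (the input plus a logical
#'   \code{stabilized} column) and \code{stabilizers} (one row per
#'   interaction: carbonyl, partner residue/atom, category SM / CA_H_O /
#'   CB_H_O / PRO_CD_CG, distance, scope intra/inter).
#' @export
stabilization <- function(unpaired, rs, segments = NULL,
                          criteria = hbondCriteria()) {
  a <- atomTable(rs)
  segOf <- function(chain, seqnum) {
    if (is.null(segments)) return(chain)  # fall back to chain identity
    hit <- which(segments$chain == chain & segments$first <= seqnum &
                   segments$last >= seqnum)
    if (length(hit)) segments$label[hit[1L]] else paste0(chain, ":none")
  }
  tagCat <- function(df, cat) { df$category <- rep(cat, nrow(df)); df }
  donors <- rbind(
    tagCat(a[a$atom %in% .sideChainDonorNames(), , drop = FALSE], "SM"),
    tagCat(a[a$atom == "CA", , drop = FALSE], "CA_H_O"),
    tagCat(a[a$atom == "CB", , drop = FALSE], "CB_H_O"),
    tagCat(a[a$resname == "PRO" & a$atom %in% c("CD", "CG"), , drop = FALSE],
           "PRO_CD_CG"))
  cutoffs <- c(SM = criteria$smMax, CA_H_O = criteria$choMax,
               CB_H_O = criteria$choMax, PRO_CD_CG = criteria$proMax)
  Oat <- a[a$atom == "O", , drop = FALSE]
  stab <- vector("list", 0L)
  flag <- logical(nrow(unpaired))
  for (k in seq_len(nrow(unpaired))) {
    o <- Oat[Oat$chain == unpaired$chain[k] & Oat$seqnum == unpaired$seqnum[k], ,
             drop = FALSE]
    if (nrow(o) == 0L) next
    op <- c(o$x[1L], o$y[1L], o$z[1L])
    d <- sqrt((donors$x - op[1L])^2 + (donors$y - op[2L])^2 + (donors$z - op[3L])^2)
    ok <- d <= cutoffs[donors$category]
    same <- donors$chain == o$chain[1L]
    ok <- ok & !(same & donors$seqnum == o$seqnum[1L])  # never self
    if (any(ok)) {
      oseg <- segOf(o$chain[1L], o$seqnum[1L])
      scope <- rep(NA_character_, nrow(donors))
      scope[ok] <- ifelse(vapply(which(ok), function(j)
        segOf(donors$chain[j], donors$seqnum[j]), character(1)) == oseg,
        "intra", "inter")
      ## C-H...O carries signal only across helices
      ok <- ok & !(donors$category %in% c("CA_H_O", "CB_H_O") & scope == "intra")
    }
    if (any(ok)) {
      hit <- donors[ok, , drop = FALSE]
      stab[[length(stab) + 1L]] <- data.frame(
        chain = o$chain[1L], seqnum = o$seqnum[1L],
        partner_chain = hit$chain, partner_seq = hit$seqnum,
        partner_atom = hit$atom, category = hit$category,
        distance = d[ok], scope = scope[ok],
        stringsAsFactors = FALSE)
      flag[k] <- TRUE
    }
  }
  carbonyls <- unpaired
  carbonyls$stabilized <- flag
  list(carbonyls = carbonyls,
       stabilizers = if (length(stab)) do.call(rbind, stab) else
         data.frame(chain = character(0), seqnum = integer(0),
                    partner_chain = character(0), partner_seq = integer(0),
                    partner_atom = character(0), category = character(0),
                    distance = numeric(0), scope = character(0),
                    stringsAsFactors = FALSE))
}

#' Anchor-relative positions of unpaired carbonyls
#'
#' Positions of unpaired carbonyls relative to the perturbation anchor: the
#' proline for proline-mediated classes, otherwise the +2 position of the
#' perturbation (MaxBA + 2). Offsets are differences of author residue
#' numbers, so they are invariant under renumbering shifts.
#'
#' @param unpaired data.frame from \code{\link{unpairedCarbonyls}}.
#' @param record A \linkS4class{PerturbationRecord}.
#' @return Integer vector of offsets (empty when the record has no anchor).
#' @export
anchorOffsets <- function(unpaired, record) {
  anchor <- if (!is.na(record@prolineSeq)) record@prolineSeq
  else if (!is.na(record@maxbaSeq)) record@maxbaSeq + 2L
  else return(integer(0))
  as.integer(unpaired$seqnum - anchor)
}

#' Table-style stabilisation summary
#'
#' Aggregates per-carbonyl stabilisation into one row per perturbation class:
#' number of carbonyls missing a backbone hydrogen bond, number stabilised by
#' intra-/inter-helical interactions, and the percentage (counted
#' per-carbonyl).
#'
#' @param perClass Named list: for each class label, the \code{carbonyls}
#'   data.frame from \code{\link{stabilization}}.
#' @return data.frame with columns \code{class}, \code{n_unpaired},
#'   \code{n_stabilized}, \code{pct}.
#' @export
stabilizationSummary <- function(perClass) {
  rows <- lapply(names(perClass), function(cl) {
    d <- perClass[[cl]]
    nu <- nrow(d)
    ns <- sum(d$stabilized)
    data.frame(class = cl, n_unpaired = nu, n_stabilized = ns,
               pct = if (nu) round(100 * ns / nu, 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
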