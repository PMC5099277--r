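#' Construct a ResidueSet from an atom table
#'
#' @param atoms data.frame with columns \code{chain}, \code{seqnum},
#'   \code{icode}, \code{resname}, \code{atom}, \code{x}, \code{y}, \code{z}.
#' @return A \linkS4class{ResidueSet}.
#' @export
ResidueSet <- function(atoms) {
  atoms$chain <- as.character(atoms$chain)
  atoms$seqnum <- as.integer(atoms$seqnum)
  atoms$icode <- as.character(atoms$icode)
  atoms$resname <- as.character(atoms$resname)
  atoms$atom <- as.character(atoms$atom)
  rownames(atoms) <- NULL
  new("ResidueSet", atoms = atoms)
}

#' @rdname accessors
#' @export
setMethod("atomTable", "ResidueSet", function(x, ...) x@atoms)

#' @describeIn accessors One row per residue: chain, seqnum, icode, resname,
#'   in file order.
#' @export
setMethod("residueTable", "ResidueSet", function(x, ...) {
  a <- x@atoms
  key <- paste(a$chain, a$seqnum, a$icode, sep = "\r")
  first <- !duplicated(key)
  out <- a[first, c("chain", "seqnum", "icode", "resname")]
  rownames(out) <- NULL
  out
})

#' @describeIn accessors CA coordinate matrix (n x 3) for one chain, with the
#'   author residue numbers as rownames and in attribute \code{seqnums};
#'   residue names in attribute \code{resnames}.
#' @param chain Chain identifier; defaults to the first chain present.
#' @export
setMethod("caTrace", "ResidueSet", function(x, chain = NULL, ...) {
  a <- x@atoms
  if (is.null(chain)) chain <- a$chain[1L]
  ca <- a[a$chain == chain & a$atom == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA atoms in chain ", chain)
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$seqnum
  attr(m, "seqnums") <- ca$seqnum
  attr(m, "resnames") <- ca$resname
  m
})

setMethod("show", "ResidueSet", function(object) {
  a <- object@atoms
  rt <- residueTable(object)
  cat("ResidueSet:", nrow(rt), "residues,", nrow(a), "atoms,",
      length(unique(a$chain)), "chain(s)\n")
  if (nrow(rt)) {
    for (ch in unique(rt$chain)) {
      r <- rt[rt$chain == ch, ]
      cat("  chain ", ch, ": residues ", min(r$seqnum), "-", max(r$seqnum),
          " (", nrow(r), ")\n", sep = "")
    }
  }
})

## Coordinates of one named atom per residue, aligned with residueTable();
## rows of NA where the atom is absent.
.atomCoords <- function(rs, name) {
  a <- rs@atoms
  rt <- residueTable(rs)
  key <- paste(rt$chain, rt$seqnum, rt$icode, sep = "\r")
  akey <- paste(a$chain, a$seqnum, a$icode, sep = "\r")
  sel <- a[a$atom == name, , drop = FALSE]
  m <- matrix(NA_real_, nrow(rt), 3L)
  idx <- match(paste(sel$chain, sel$seqnum, sel$icode, sep = "\r"), key)
  m[idx[!is.na(idx)], ] <- as.matrix(sel[!is.na(idx), c("x", "y", "z")])
  m
}

.waterNames <- c("HOH", "WAT", "DOD", "H2O")

#' Read a protein structure from a PDB file
#'
#' Reads ATOM/HETATM records via \pkg{bio3d}, resolves alternate locations
#' (highest occupancy, then alphabetical altloc), drops hydrogens and waters,
#' and keeps every residue that carries a CA atom (so modified amino acids
#' deposited as HETATM are retained). Residues are returned in author order
#' within each chain; author numbering (with insertion codes) is the single
#' numbering used throughout the package.
#'
#' @param path Path to a PDB file.
#' @param model Model index for multi-model files (default 1, the first).
#' @param chains Optional character vector restricting to specific chains.
#' @return A \linkS4class{ResidueSet}.
#' @export
readStructure <- function(path, model = 1L, chains = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  multi <- model > 1L
  pdb <- bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  if (multi) {
    if (model > nrow(pdb$xyz)) stop("model ", model, " not present in ", path)
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
  }
  a$chain[is.na(a$chain)] <- " "
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  ## drop waters and hydrogens/deuteriums
  a <- a[!(a$resid %in% .waterNames), , drop = FALSE]
  elesy <- a$elesy
  elesy[is.na(elesy)] <- ""
  isH <- elesy %in% c("H", "D") |
    (elesy == "" & grepl("^[0-9]*[HD]", a$elety))
  a <- a[!isH, , drop = FALSE]
  ## altloc: for each (chain, resno, insert, atom) keep highest occupancy,
  ## ties broken alphabetically by altloc code
  if (any(a$alt != "")) {
    o <- a$o
    o[is.na(o)] <- 1
    key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
    ord <- order(key, -o, a$alt)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")), ,
           drop = FALSE]
    a <- a[order(match(paste(a$chain, a$resno, a$insert, sep = "\r"),
                       unique(paste(a$chain, a$resno, a$insert, sep = "\r")))), ,
           drop = FALSE]
  }
  ## keep residues that have a CA
  rkey <- paste(a$chain, a$resno, a$insert, sep = "\r")
  hasCA <- rkey %in% rkey[a$elety == "CA"]
  a <- a[hasCA, , drop = FALSE]
  if (nrow(a) == 0L) stop("no CA atoms found in ", path,
                          if (!is.null(chains)) paste0(" (chains ", paste(chains, collapse = ","), ")"))
  ResidueSet(data.frame(chain = a$chain, seqnum = a$resno, icode = a$insert,
                        resname = a$resid, atom = a$elety,
                        x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE))
}

#' Write a ResidueSet to a PDB file
#'
#' Emits plain ATOM records via \pkg{bio3d}. Coordinates round-trip through
#' \code{\link{readStructure}} to the PDB precision of 1e-3 Angstrom.
#'
#' @param x A \linkS4class{ResidueSet}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeStructure <- function(x, path) {
  a <- atomTable(x)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$seqnum, resid = a$resname, chain = a$chain,
                   insert = ifelse(a$icode == "", NA, a$icode),
                   eleno = seq_len(nrow(a)), elety = a$atom)
  invisible(path)
}

#' Define transmembrane segments
#'
#' A small constructor for explicit TM segment tables (the preferred input:
#' published helical-region bounds in author numbering). A segment must span
#' at least 7 residues so that at least four 4-CA windows exist.
#'
#' @param chain Chain identifiers.
#' @param first,last First and last author residue numbers.
#' @param label Segment labels (e.g. "TM2").
#' @return data.frame with columns chain, first, last, label.
#' @export
tmSegments <- function(chain, first, last, label = NULL) {
  if (is.null(label)) label <- paste0("TM", seq_along(first))
  stopifnot(length(chain) == length(first), length(first) == length(last))
  if (any(last < first + 6L))
    stop("TM segments must span at least 7 residues (last >= first + 6)")
  data.frame(chain = as.character(chain), first = as.integer(first),
             last = as.integer(last), label = as.character(label),
             stringsAsFactors = FALSE)
}

#' Read a TM segment table from a tab-separated file
#'
#' Expected columns: \code{chain  first  last  label} (header optional).
#'
#' @param path File path.
#' @return data.frame as from \code{\link{tmSegments}}.
#' @export
readSegmentTable <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  if (!is.numeric(d[[2L]])) {  # header row present
    names(d) <- as.character(unlist(d[1L, ]))
    d <- d[-1L, ]
    d[[2L]] <- as.integer(d[[2L]]); d[[3L]] <- as.integer(d[[3L]])
  }
  names(d)[1:4] <- c("chain", "first", "last", "label")
  tmSegments(d$chain, d$first, d$last, d$label)
}

#' Select transmembrane helical segments from a structure
#'
#' Either returns the residues of explicitly given segment ranges (authoritative
#' when published bounds exist), or, in slab mode, maximal runs of at least
#' \code{minRun} consecutive residues whose CA lies within \code{|z| <=
#' zHalfWidth} -- the membrane-slab convention for structures oriented with the
#' membrane normal along Z. Consecutive residues in a returned segment must
#' have CA-CA distances in (2.0, 4.5) Angstrom; explicit ranges violating this
#' are rejected as chain-broken, slab runs are split at breaks.
#'
#' @param x A \linkS4class{ResidueSet}.
#' @param segments Optional data.frame from \code{\link{tmSegments}}.
#' @param zHalfWidth Half-width of the membrane slab in Angstrom (default 15).
#' @param minRun Minimum run length in slab mode (default 12).
#' @return Named list of \linkS4class{ResidueSet} objects, one per segment.
#' @export
selectSegments <- function(x, segments = NULL, zHalfWidth = 15, minRun = 12L) {
  a <- atomTable(x)
  if (!is.null(segments)) {
    out <- vector("list", nrow(segments))
    names(out) <- segments$label
    for (i in seq_len(nrow(segments))) {
      sg <- segments[i, ]
      want <- sg$first:sg$last
      sel <- a$chain == sg$chain & a$seqnum %in% want
      have <- unique(a$seqnum[sel & a$atom == "CA"])
      missing <- setdiff(want, have)
      if (length(missing))
        stop("segment ", sg$label, " (chain ", sg$chain, "): missing residues ",
             paste(missing, collapse = ", "))
      sub <- ResidueSet(a[sel, , drop = FALSE])
      .checkContinuity(sub, sg$label)
      out[[i]] <- sub
    }
    return(out)
  }
  ## slab mode
  out <- list()
  for (ch in unique(a$chain)) {
    ca <- a[a$chain == ch & a$atom == "CA", , drop = FALSE]
    inSlab <- abs(ca$z) <= zHalfWidth
    ## split runs additionally at chain breaks
    if (nrow(ca) > 1L) {
      d <- sqrt(rowSums((as.matrix(ca[-1L, c("x", "y", "z")]) -
                         as.matrix(ca[-nrow(ca), c("x", "y", "z")]))^2))
      broken <- c(FALSE, d <= 2.0 | d > 4.5)
    } else broken <- FALSE
    grp <- cumsum(!inSlab | broken)
    for (g in unique(grp[inSlab])) {
      idx <- which(grp == g & inSlab)
      if (length(idx) >= minRun) {
        seqs <- ca$seqnum[idx]
        sel <- a$chain == ch & a$seqnum %in% seqs
        out[[paste0(ch, ":", min(seqs), "-", max(seqs))]] <-
          ResidueSet(a[sel, , drop = FALSE])
      }
    }
  }
  out
}

.checkContinuity <- function(rs, label = "segment") {
  ca <- caTrace(rs)
  if (nrow(ca) < 2L) return(invisible(TRUE))
  d <- sqrt(rowSums((ca[-1L, , drop = FALSE] - ca[-nrow(ca), , drop = FALSE])^2))
  bad <- which(d <= 2.0 | d > 4.5)
  if (length(bad))
    stop(label, " rejected as chain-broken: CA-CA distance ",
         round(d[bad[1L]], 2), " A between residues ",
         rownames(ca)[bad[1L]], " and ", rownames(ca)[bad[1L] + 1L])
  invisible(TRUE)
}
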