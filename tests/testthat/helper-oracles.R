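# Independent oracles and small generators used across the test files.

.unit <- function(v) v / sqrt(sum(v * v))
.crs <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])

# Random rigid motion: rotation matrix (QR of a random gaussian matrix,
# determinant fixed to +1) plus translation.
randomRigidMotion <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = rnorm(3, sd = 20))
}

applyRigid <- function(coords, rm) sweep(coords %*% t(rm$R), 2, rm$t, "+")

# Brute-force all-pairs backbone H-bond oracle. Rebuilds the amide hydrogen
# independently and enumerates every residue pair at separations 3-5,
# applying the same geometric criteria as the package defaults.
oracleBackboneHBonds <- function(rs, noMax = 3.5, nhoMin = 120) {
  rt <- residueTable(rs)
  a <- atomTable(rs)
  getAtom <- function(i, name) {
    r <- a[a$chain == rt$chain[i] & a$seqnum == rt$seqnum[i] &
             a$icode == rt$icode[i] & a$atom == name, ]
    if (nrow(r) == 0) return(NULL)
    c(r$x[1], r$y[1], r$z[1])
  }
  n <- nrow(rt)
  out <- NULL
  for (j in seq_len(n)) {
    if (rt$resname[j] == "PRO") next
    if (j == 1 || rt$chain[j] != rt$chain[j - 1]) next
    Nj <- getAtom(j, "N"); CAj <- getAtom(j, "CA"); Cprev <- getAtom(j - 1, "C")
    if (is.null(Nj) || is.null(CAj) || is.null(Cprev)) next
    if (sqrt(sum((Nj - Cprev)^2)) > 2.5) next
    bis <- .unit(Cprev - Nj) + .unit(CAj - Nj)
    H <- Nj - .unit(bis)  # N-H 1.0 A opposite the bisector
    for (i in seq_len(n)) {
      sep <- j - i
      if (!(sep %in% 3:5)) next
      if (rt$chain[i] != rt$chain[j]) next
      Oi <- getAtom(i, "O")
      if (is.null(Oi)) next
      d <- sqrt(sum((Nj - Oi)^2))
      if (d > noMax) next
      ang <- acos(max(-1, min(1, sum(.unit(Nj - H) * .unit(Oi - H))))) * 180 / pi
      if (ang < nhoMin) next
      out <- rbind(out, data.frame(chain = rt$chain[j],
                                   donor_seq = rt$seqnum[j],
                                   acceptor_seq = rt$seqnum[i], sep = sep,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    return(data.frame(chain = character(0), donor_seq = integer(0),
                      acceptor_seq = integer(0), sep = integer(0),
                      stringsAsFactors = FALSE))
  out[order(out$chain, out$acceptor_seq, out$sep), , drop = FALSE]
}

# Canonical bond-set representation for set comparison.
bondKeys <- function(df) sort(paste(df$chain, df$donor_seq, df$acceptor_seq, df$sep))

# Sample one element from a vector without R's scalar-expansion surprise.
pickOne <- function(x) x[sample.int(length(x), 1)]

# A random perturbed backbone: alpha base with one planted feature.
randomPerturbedBackbone <- function(n = 24) {
  kind <- pickOne(c("PI_BULGE", "G310_RUN", "KINK", "NONE"))
  at <- pickOne(8:(n - 10))
  if (kind == "PI_BULGE") {
    pp <- perturbedPhiPsi(n, insert = "PI", at = at, length = pickOne(2:4))
    rs <- makeBackbone(pp$phi, pp$psi, n)
  } else if (kind == "G310_RUN") {
    pp <- perturbedPhiPsi(n, insert = "G310", at = at, length = pickOne(2:4))
    rs <- makeBackbone(pp$phi, pp$psi, n)
  } else {
    pr <- phiPsiPreset("ALPHA")
    rs <- makeBackbone(pr["phi"], pr["psi"], n)
    if (kind == "KINK") rs <- insertKink(rs, at, runif(1, 15, 35))
  }
  list(rs = rs, kind = kind, at = at)
}
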