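# Small 3-vector helpers shared across the package. All angles in degrees.

vecNorm <- function(v) sqrt(sum(v * v))

unitVector <- function(v) {
  n <- vecNorm(v)
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## arccos with the argument clamped to [-1, 1]; mandatory numerical safety for
## dot products of unit vectors.
clampedAcos <- function(x) acos(max(-1, min(1, x)))

## Angle between two vectors, degrees in [0, 180].
vectorAngle <- function(a, b) {
  clampedAcos(sum(unitVector(a) * unitVector(b))) * 180 / pi
}

#' Signed dihedral angle of four points
#'
#' Standard IUPAC convention: the angle is measured looking down the
#' \code{p2 -> p3} bond, positive clockwise, returned in degrees in
#' \code{(-180, 180]}.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (coordinates in Angstrom).
#' @return Dihedral angle in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  ang <- atan2(sum(cross3(n1, n2) * unitVector(b2)), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

## Rodrigues rotation of vector v about unit axis k by theta degrees.
rodriguesRotate <- function(v, k, theta) {
  th <- theta * pi / 180
  v * cos(th) + cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

## 3x3 rotation matrix sending unit vector a onto unit vector b.
rotationBetween <- function(a, b) {
  a <- unitVector(a)
  b <- unitVector(b)
  v <- cross3(a, b)
  c_ <- sum(a * b)
  if (vecNorm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    ## antiparallel: rotate 180 deg about any axis perpendicular to a
    p <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    k <- unitVector(p - sum(p * a) * a)
    K <- matrix(c(0, k[3L], -k[2L], -k[3L], 0, k[1L], k[2L], -k[1L], 0), 3L, 3L)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
  diag(3) + K + K %*% K * (1 / (1 + c_))
}

## Place atom D given reference atoms A, B, C, the bond length |C-D|, the
## angle B-C-D and the torsion A-B-C-D (degrees). Natural-extension
## reference-frame construction used by the backbone builder.
placeAtom <- function(A, B, C, bond, angle, torsion) {
  ar <- angle * pi / 180
  tr <- torsion * pi / 180
  bc <- unitVector(C - B)
  n <- unitVector(cross3(B - A, bc))
  m <- cross3(n, bc)
  d <- bond * c(-cos(ar), sin(ar) * cos(tr), sin(ar) * sin(tr))
  C + d[1L] * bc + d[2L] * m + d[3L] * n
}

## FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used to stamp
## report files with a configuration fingerprint.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    ## xor touches only the low byte (b < 256); keep everything in doubles so
    ## values up to 2^32 never hit bitwXor's 32-bit signed limit
    lowb <- h %% 256
    h <- h - lowb + bitwXor(as.integer(lowb), as.integer(b))
    ## 32-bit multiply by 16777619 without overflow: split into 16-bit halves
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 403) * 65536) %% 4294967296
  }
  ## format as 8 hex digits from the two 16-bit halves (h is a double)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
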