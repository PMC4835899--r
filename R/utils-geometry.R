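# Small vector-geometry helpers shared across modules. All coordinates are
# plain numeric 3-vectors or n x 3 matrices in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

vdist <- function(a, b) vnorm(a - b)

## Rotation matrix for angle theta (radians) about unit axis u (Rodrigues).
rotationAboutAxis <- function(u, theta) {
  u <- unitv(u)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

## Rotation from ZYZ Euler angles; used by the brute-force fitting oracle in
## the test suite as well as by random-transform property tests.
rotationFromEuler <- function(a, b, g) {
  Rz1 <- rotationAboutAxis(c(0, 0, 1), a)
  Ry <- rotationAboutAxis(c(0, 1, 0), b)
  Rz2 <- rotationAboutAxis(c(0, 0, 1), g)
  Rz2 %*% Ry %*% Rz1
}

rotationAngle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ct)))
}

applyRigid <- function(xyz, R = diag(3), t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, t, "+")
}

## Least-squares line direction through points (rows of xyz), oriented from
## the first toward the last point.
fitDirection <- function(xyz) {
  if (nrow(xyz) < 2) stop("need at least two points to fit a direction")
  ctr <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, ctr), nu = 0, nv = 3)
  d <- s$v[, 1]
  if (sum(d * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) d <- -d
  unitv(d)
}

## Least-squares plane through points; returns list(normal, center, rms) where
## rms is the root-mean-square out-of-plane deviation.
fitPlane <- function(xyz) {
  if (nrow(xyz) < 3) stop("need at least three points to fit a plane")
  ctr <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, ctr), nu = 0, nv = 3)
  n <- s$v[, 3]
  dev <- as.numeric(sweep(xyz, 2, ctr) %*% n)
  list(normal = n, center = ctr, rms = sqrt(mean(dev^2)), dev = dev)
}

## Place atom D given positions A, B, C and internal coordinates of D relative
## to them: bond |CD|, angle B-C-D (degrees), dihedral A-B-C-D (degrees).
## Standard natural-extension-of-reference-frame construction.
placeAtom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- -dihedral * pi / 180
  bc <- unitv(c - b)
  n <- unitv(pracmaCross(b - a, bc))
  m <- pracmaCross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
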