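# Small 2D/3D geometry helpers shared by layout, interaction detection and
# placement scoring. All distances in angstrom, all angles in degrees.

vnorm <- function(v) sqrt(sum(v^2))

dist3 <- function(a, b) sqrt(sum((a - b)^2))

dist2 <- function(a, b) sqrt(sum((a - b)^2))

#' Angle at vertex `b` formed by points `a`-`b`-`c`
#'
#' Works for 2- or 3-vectors. Returns the angle in degrees in \[0, 180\].
#' @param a,b,c numeric coordinate vectors of equal length.
#' @return angle in degrees.
#' @keywords internal
angle_at <- function(b, a, c) {
  u <- a - b
  v <- c - b
  cs <- sum(u * v) / (vnorm(u) * vnorm(v))
  cs <- min(1, max(-1, cs))
  acos(cs) * 180 / pi
}

deg2rad <- function(d) d * pi / 180

rot2 <- function(v, deg) {
  th <- deg2rad(deg)
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
}

unit2 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) c(1, 0) else v / n
}

# Proper segment intersection test (shared endpoints do not count).
segments_cross <- function(p1, p2, q1, q2, eps = 1e-9) {
  ends <- list(p1, p2)
  for (e in ends) {
    if (dist2(e, q1) < eps || dist2(e, q2) < eps) return(FALSE)
  }
  d1 <- cross_sign(q1, q2, p1)
  d2 <- cross_sign(q1, q2, p2)
  d3 <- cross_sign(p1, p2, q1)
  d4 <- cross_sign(p1, p2, q2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

cross_sign <- function(a, b, c) {
  v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  if (abs(v) < 1e-12) 0 else sign(v)
}

# Does segment p1-p2 pass through a circle (centre c, radius r)?
segment_hits_circle <- function(p1, p2, centre, r) {
  d <- p2 - p1
  f <- p1 - centre
  a <- sum(d * d)
  if (a < 1e-18) return(vnorm(f) <= r)
  t <- -sum(f * d) / a
  t <- min(1, max(0, t))
  closest <- p1 + t * d
  dist2(closest, centre) <= r
}

# Orthographic projection of 3D coordinates onto their least-squares plane;
# returns an n x 2 matrix. Degenerate (collinear/coincident) inputs fall back
# to the first two principal directions padded with zeros.
project_plane <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 1L) return(matrix(0, 1, 2))
  ctr <- colMeans(xyz)
  m <- sweep(xyz, 2, ctr)
  sv <- svd(m, nu = 0, nv = 2)
  v <- sv$v
  if (ncol(v) < 2) v <- cbind(v, c(0, 0, 0))
  m %*% v
}

# Reflect 2D points across the line through a and b.
reflect_across <- function(pts, a, b) {
  u <- unit2(b - a)
  t(apply(pts, 1L, function(p) {
    w <- p - a
    par <- sum(w * u) * u
    a + 2 * par - w
  }))
}

# Deterministic RNG scope: run `expr` under a seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
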