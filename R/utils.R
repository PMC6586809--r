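# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalize a zero vector")
  v / n
}

# cumulative arclength of a polyline (n x 3)
arclengths <- function(pts) {
  if (nrow(pts) < 2) return(0)
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

# linear interpolation of a polyline (and optional per-point values) at
# target arclengths
interp_polyline <- function(pts, s_targets, values = NULL) {
  s <- arclengths(pts)
  xs <- cbind(
    approx(s, pts[, 1], xout = s_targets, rule = 2)$y,
    approx(s, pts[, 2], xout = s_targets, rule = 2)$y,
    approx(s, pts[, 3], xout = s_targets, rule = 2)$y
  )
  if (is.null(values)) return(xs)
  list(points = xs, values = approx(s, values, xout = s_targets, rule = 2)$y)
}

# run code with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# rotation matrices (degrees)
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# rotate vector v by angle deg about unit axis k (Rodrigues)
rot_about <- function(v, k, deg) {
  a <- deg * pi / 180
  k <- unitize(k)
  v * cos(a) + pracma_cross(k, v) * sin(a) + k * sum(k * v) * (1 - cos(a))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# trapezoidal integral
trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
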