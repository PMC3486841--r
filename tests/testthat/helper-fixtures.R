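# Shared toy builders and independent oracles.

# A minimal 3-residue topology: GLU 105 (OE1/OE2), LYS 109 (NZ), ASP 137 (OD1).
toy_topology <- function() {
  data.frame(
    serial = 1:6,
    name = c("OE1", "OE2", "NZ", "OD1", "CA", "CA"),
    residue_name = c("GLU", "GLU", "LYS", "ASP", "GLY", "GLY"),
    chain = "A",
    residue_seq = c(105L, 105L, 109L, 137L, 1L, 2L),
    stringsAsFactors = FALSE
  )
}

toy_trajectory <- function(frames, dt_ps = 10) {
  # frames: list of 6x3 matrices matching toy_topology()
  coords <- array(unlist(frames), dim = c(6L, 3L, length(frames)))
  new_trajectory(toy_topology(), coords, dt_ps = dt_ps)
}

toy_frame <- function(e105 = c(0, 0, 0), e105b = c(1.2, 0, 0),
                      nz = c(3, 0, 0), d137 = c(10, 0, 0)) {
  rbind(e105, e105b, nz, d137, c(20, 0, 0), c(0, 20, 0))
}

# Independent Pearson oracle: direct product-moment sums, no cor().
pearson_oracle <- function(a, b) {
  am <- a - sum(a) / length(a)
  bm <- b - sum(b) / length(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# Brute-force minimum distance over all atom pairs (double loop).
min_dist_oracle <- function(xa, xb) {
  best <- Inf
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      best <- min(best, sqrt(sum((xa[i, ] - xb[j, ])^2)))
    }
  }
  best
}

rotation_from_angles <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

random_rotation <- function() rotation_from_angles(stats::runif(3, -pi, pi))

# Numeric-minimization superposition oracle: search rotations directly.
rmsd_min_oracle <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  obj <- function(ang) {
    yr <- yc %*% t(rotation_from_angles(ang))
    sqrt(mean(rowSums((xc - yr)^2)))
  }
  best <- Inf
  for (start in list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, 0),
                     c(0, 0, pi / 2), c(pi, pi / 2, -pi / 2))) {
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-16, maxit = 5000))
    best <- min(best, fit$value)
  }
  best
}

# Running-average oracle: per-point loop with symmetric edge truncation.
running_average_oracle <- function(v, w) {
  n <- length(v)
  h <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)
    mean(v[(i - hi):(i + hi)])
  }, 0)
}

make_series <- function(values, dt = 10, a = "a", b = "b") {
  new_distance_series((seq_along(values) - 1L) * dt, values, a, b)
}
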