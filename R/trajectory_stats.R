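#' Centered running-average smoothing
#'
#' Centered moving mean over the largest odd frame-window whose time span
#' does not exceed `window_ps` (minimum one frame). At the series edges the
#' window shrinks symmetrically so it never extends past the data. Times are
#' unchanged. Matches the 100 ps running-average presentation used for
#' salt-bridge distance traces; statistics in this package are computed on
#' raw values, smoothing is for display.
#'
#' @param series a `distance_series`.
#' @param window_ps window span in ps (> 0, default 100).
#' @return smoothed `distance_series`.
#' @export
running_average <- function(series, window_ps = 100) {
  if (window_ps <= 0) stop("window_ps must be > 0")
  v <- series$values_A
  n <- length(v)
  if (n == 0L) stop("empty series")
  dt <- if (n > 1L) stats::median(diff(series$times_ps)) else Inf
  w <- max(1L, floor(window_ps / dt) + 1L)
  if (w %% 2L == 0L) w <- w - 1L  # largest odd count with span <= window_ps
  h <- (w - 1L) %/% 2L
  i <- seq_len(n)
  hi <- pmin(h, i - 1L, n - i)   # symmetric edge truncation
  cs <- cumsum(c(0, v))
  out <- (cs[i + hi + 1L] - cs[i - hi]) / (2 * hi + 1)
  new_distance_series(series$times_ps, out, series$label_a, series$label_b)
}

#' Pearson anticorrelation between two distance series
#'
#' Normalized (Pearson product-moment) correlation of the two series'
#' values. For a shuttle motif, the central-interface and central-remote
#' distances are strongly anticorrelated (rho close to -1) because the
#' central residue is bound to one partner or the other, never both.
#' Computed on raw (unsmoothed) values; presmoothing inflates |rho| by
#' construction.
#'
#' @param series_a,series_b `distance_series` of equal length (>= 3),
#'   neither constant.
#' @return object of class `correlation_result` with fields `rho`, `n`, and
#'   optional `ci` (set by [block_bootstrap_ci()]).
#' @export
anticorrelation <- function(series_a, series_b) {
  a <- series_a$values_A
  b <- series_b$values_A
  if (length(a) != length(b)) stop("series length mismatch: ", length(a),
                                   " vs ", length(b))
  if (length(a) < 3L) stop("need at least 3 points")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant series")
  }
  structure(list(rho = stats::cor(a, b), n = length(a), ci = NULL),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rho = %.4f (n = %d)", x$rho, x$n))
  if (!is.null(x$ci)) cat(sprintf(", 95%% CI [%.4f, %.4f]", x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

#' Kabsch optimal rigid-body superposition
#'
#' Least-squares superposition of `coords_y` onto `coords_x` using the SVD
#' solution, restricted to proper rotations (a reflection is corrected via
#' the determinant sign convention), with optional per-atom weights.
#'
#' @param coords_x,coords_y `n x 3` matrices, `n >= 3`, not collinear.
#' @param weights optional non-negative per-atom weights (default uniform).
#' @return list with `rotation` (3x3, det = +1), `translation` (length 3),
#'   and `rmsd` in Angstrom; the fit of y onto x is
#'   `y %*% rotation + translation` (rows).
#' @export
kabsch_rmsd <- function(coords_x, coords_y, weights = NULL) {
  coords_x <- as.matrix(coords_x)
  coords_y <- as.matrix(coords_y)
  if (!all(dim(coords_x) == dim(coords_y)) || ncol(coords_x) != 3L) {
    stop("coordinate sets must be equal-sized n x 3 matrices")
  }
  n <- nrow(coords_x)
  if (n < 3L) stop("degenerate geometry: need at least 3 atoms")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  cx <- colSums(coords_x * w)
  cy <- colSums(coords_y * w)
  xc <- sweep(coords_x, 2, cx)
  yc <- sweep(coords_y, 2, cy)
  sv_x <- svd(xc * sqrt(w))$d
  if (sv_x[2] < max(sv_x[1], 1) * 1e-8) {
    stop("degenerate geometry: atoms are collinear")
  }
  h <- crossprod(yc * w, xc)          # 3x3 covariance
  s <- svd(h)
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rot <- t(rot)                       # so that y_fit = yc %*% rot + cx
  yfit <- yc %*% rot
  rmsd <- sqrt(sum(w * rowSums((xc - yfit)^2)))
  list(rotation = rot, translation = as.numeric(cx - cy %*% rot), rmsd = rmsd)
}

#' Cross-RMSD matrix over a trajectory
#'
#' RMSD between every pair of frames after optimal superposition over a
#' named-atom selection (default backbone CA plus CB, the conventional
#' selection for assessing global conformational stability). Uniformly low
#' off-diagonal values indicate the trajectory stays in one conformational
#' basin.
#'
#' @param traj a `trajectory`.
#' @param atom_selection comma-separated atom names (default `"CA,CB"`).
#' @return object of class `cross_rmsd_matrix`: symmetric zero-diagonal
#'   matrix of RMSDs (Angstrom) plus the selection used.
#' @export
cross_rmsd_matrix <- function(traj, atom_selection = "CA,CB") {
  sel_names <- trimws(strsplit(atom_selection, ",", fixed = TRUE)[[1]])
  idx <- which(traj$topology$name %in% sel_names)
  if (length(idx) == 0L) stop("atom selection '", atom_selection,
                              "' matches no atoms")
  if (length(idx) < 3L) stop("atom selection must match at least 3 atoms")
  nf <- n_frames(traj)
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    xi <- traj$coords[idx, , i]
    for (j in seq.int(i + 1L, nf)) {
      r <- kabsch_rmsd(xi, traj$coords[idx, , j])$rmsd
      m[i, j] <- r
      m[j, i] <- r
    }
  }
  structure(list(rmsd = m, atom_selection = atom_selection,
                 times_ps = frame_times(traj)),
            class = "cross_rmsd_matrix")
}

#' @export
print.cross_rmsd_matrix <- function(x, ...) {
  off <- x$rmsd[upper.tri(x$rmsd)]
  cat(sprintf("<cross_rmsd_matrix> %d frames (%s): mean %.3f A, max %.3f A\n",
              nrow(x$rmsd), x$atom_selection,
              if (length(off)) mean(off) else 0,
              if (length(off)) max(off) else 0))
  invisible(x)
}

#' Moving-block bootstrap confidence interval for the correlation
#'
#' Circular moving-block bootstrap over paired frames: blocks of
#' `block_frames` consecutive (a, b) pairs are resampled with replacement
#' (wrapping at the series end) to preserve short-range autocorrelation, and
#' a percentile 95% interval for Pearson's rho is returned. Deterministic
#' given `seed`.
#'
#' @param series_a,series_b paired `distance_series` of equal length.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param block_frames block length in frames (>= 1, <= series length);
#'   should exceed the correlation time of the series.
#' @param seed integer seed.
#' @return a `correlation_result` with `ci = c(lo, hi)`.
#' @export
block_bootstrap_ci <- function(series_a, series_b, n_boot = 1000,
                               block_frames, seed = 1) {
  res <- anticorrelation(series_a, series_b)
  a <- series_a$values_A
  b <- series_b$values_A
  n <- length(a)
  if (block_frames < 1L) stop("block_frames must be >= 1")
  if (block_frames > n) stop("block_frames (", block_frames,
                             ") exceeds series length (", n, ")")
  if (n_boot < 100L) stop("n_boot must be >= 100")
  n_blocks <- ceiling(n / block_frames)
  offsets <- seq_len(block_frames) - 1L
  rhos <- numeric(n_boot)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (r in seq_len(n_boot)) {
    starts <- sample.int(n, n_blocks, replace = TRUE)
    idx <- (rep(starts, each = block_frames) + offsets - 1L) %% n + 1L
    idx <- idx[seq_len(n)]
    ar <- a[idx]
    br <- b[idx]
    rhos[r] <- if (stats::sd(ar) == 0 || stats::sd(br) == 0) NA_real_
    else stats::cor(ar, br)
  }
  res$ci <- unname(stats::quantile(rhos, c(0.025, 0.975), na.rm = TRUE))
  res
}
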