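#' Build the scala tympani centreline
#'
#' Computes the lumen axis of the spiral scala tympani analytically from the
#' spiral parameters: over parameter `tau in [0, 1]` the azimuth advances by
#' `2 * pi * n_turns`, the spiral radius interpolates linearly from base to
#' apex, and the height rises `axial_pitch_m` per turn.  Arc length is
#' accumulated by Gauss-Legendre quadrature of the speed, and each sample
#' carries an orthonormal local frame: tangent `t`, in-plane `xhat` pointing
#' at the inner (modiolar) cochlea wall, and `yhat = t x xhat` pointing at the
#' basilar-membrane side.
#'
#' Arc length `s = 0` is the basal end (array entry point); `s = L` is the
#' apex.  For the degenerate case `n_turns = 0` the curve collapses to a
#' straight radial segment of length `base_radius_m - apex_radius_m` with
#' constant frames.
#'
#' @param params a [cochlea_params()].
#' @param n_samples number of stored samples along the curve.
#' @return An object of class `centerline` with fields `samples` (n x 3
#'   matrix, m), `frames` (n x 3 x 3 array: `[, , 1]` tangent, `[, , 2]`
#'   xhat, `[, , 3]` yhat), `arclength_m` (cumulative, strictly increasing)
#'   and `length_m`.
#' @export
build_centerline <- function(params, n_samples = 257L) {
  stopifnot(inherits(params, "cochlea_params"))
  n_fine <- 2048L
  tau_grid <- seq(0, 1, length.out = n_fine + 1L)
  # 5-point Gauss-Legendre per interval for the cumulative arc length
  gl_x <- c(-0.906179845938664, -0.538469310105683, 0,
            0.538469310105683, 0.906179845938664)
  gl_w <- c(0.236926885056189, 0.478628670499366, 0.568888888888889,
            0.478628670499366, 0.236926885056189)
  h <- 1 / n_fine
  mids <- tau_grid[-(n_fine + 1L)] + h / 2
  seg <- numeric(n_fine)
  for (k in seq_along(gl_x)) {
    seg <- seg + gl_w[k] * spiral_speed(params, mids + gl_x[k] * h / 2)
  }
  seg <- seg * h / 2
  s_grid <- c(0, cumsum(seg))
  L <- s_grid[n_fine + 1L]
  if (!is.finite(L) || L <= 1e-12)
    stop("degenerate spiral parameters: zero-length centerline", call. = FALSE)
  if (any(seg <= 0))
    stop("degenerate spiral parameters: centerline speed vanishes",
         call. = FALSE)

  cl <- structure(list(
    params = params,
    tau_grid = tau_grid,
    s_grid = s_grid,
    length_m = L
  ), class = "centerline")

  s_samp <- seq(0, L, length.out = n_samples)
  ev <- centerline_at(cl, s_samp)
  cl$samples <- ev$point
  frames <- array(NA_real_, dim = c(n_samples, 3L, 3L))
  frames[, , 1L] <- ev$tangent
  frames[, , 2L] <- ev$xhat
  frames[, , 3L] <- ev$yhat
  cl$frames <- frames
  cl$arclength_m <- s_samp
  cl
}

# position of the spiral at parameter tau (vectorised)
spiral_point <- function(params, tau) {
  n <- params$n_turns
  th <- 2 * pi * n * tau
  R <- params$base_radius_m + (params$apex_radius_m - params$base_radius_m) * tau
  cbind(R * cos(th), R * sin(th), params$axial_pitch_m * n * tau)
}

# derivative of spiral_point w.r.t. tau (vectorised)
spiral_deriv <- function(params, tau) {
  n <- params$n_turns
  th <- 2 * pi * n * tau
  thp <- 2 * pi * n
  R <- params$base_radius_m + (params$apex_radius_m - params$base_radius_m) * tau
  Rp <- params$apex_radius_m - params$base_radius_m
  cbind(Rp * cos(th) - R * thp * sin(th),
        Rp * sin(th) + R * thp * cos(th),
        rep(params$axial_pitch_m * n, length(tau)))
}

spiral_speed <- function(params, tau) {
  d <- spiral_deriv(params, tau)
  sqrt(rowSums(d^2))
}

#' Evaluate a centreline at given arc lengths
#'
#' @param cl a [build_centerline()] result.
#' @param s numeric vector of arc lengths in `[0, length_m]` (m).
#' @return A list of matrices (one row per `s`): `point`, `tangent`, `xhat`,
#'   `yhat`, plus the parameter vector `tau`.
#' @export
centerline_at <- function(cl, s) {
  stopifnot(inherits(cl, "centerline"))
  if (any(s < -1e-12 | s > cl$length_m * (1 + 1e-12)))
    stop("arc length out of range", call. = FALSE)
  s <- pmin(pmax(s, 0), cl$length_m)
  tau <- stats::approx(cl$s_grid, cl$tau_grid, xout = s, ties = "ordered")$y
  p <- spiral_point(cl$params, tau)
  d <- spiral_deriv(cl$params, tau)
  tg <- d / sqrt(rowSums(d^2))
  th <- 2 * pi * cl$params$n_turns * tau
  # modiolar direction: inward radial, projected orthogonal to the tangent
  u <- cbind(-cos(th), -sin(th), 0)
  u <- u - rowSums(u * tg) * tg
  nu <- sqrt(rowSums(u^2))
  deg <- nu < 1e-8
  if (any(deg)) {
    # tangent (anti)parallel to the radial direction: fall back to global z
    w <- cbind(0, 0, rep(1, sum(deg))) - tg[deg, , drop = FALSE] * tg[deg, 3]
    u[deg, ] <- w
    nu[deg] <- sqrt(rowSums(w^2))
  }
  xh <- u / nu
  yh <- cbind(tg[, 2] * xh[, 3] - tg[, 3] * xh[, 2],
              tg[, 3] * xh[, 1] - tg[, 1] * xh[, 3],
              tg[, 1] * xh[, 2] - tg[, 2] * xh[, 1])
  list(point = p, tangent = tg, xhat = xh, yhat = yh, tau = tau)
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> length %.3g mm, %d stored samples\n",
              x$length_m * 1e3, nrow(x$samples)))
  invisible(x)
}

# straight centreline along +z used by the toy channel (constant frames)
straight_centerline <- function(length_m) {
  if (!is.finite(length_m) || length_m <= 0)
    stop("length must be positive", call. = FALSE)
  structure(list(length_m = length_m), class = "straight_centerline")
}

straight_at <- function(cl, s) {
  n <- length(s)
  list(point = cbind(0, 0, s),
       tangent = matrix(rep(c(0, 0, 1), each = n), n),
       xhat = matrix(rep(c(1, 0, 0), each = n), n),
       yhat = matrix(rep(c(0, 1, 0), each = n), n))
}

# frame evaluation dispatch used by the mesher
frames_at <- function(cl, s) {
  if (inherits(cl, "centerline")) centerline_at(cl, s) else straight_at(cl, s)
}
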