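# Flicker spectroscopy of giant unilamellar vesicles: equatorial-contour
# fluctuation spectra and Helfrich-spectrum fitting of the bending rigidity,
# plus generalized-polarization maps and Ld/Lo phase-area ratios.

#' Container for an equatorial contour time series
#'
#' @param frames list of closed contours, each an `n x 2` matrix of (x, y)
#'   coordinates in micrometres.
#' @param pixel_size pixel size in micrometres (metadata).
#' @param temperature temperature in kelvin (metadata).
#' @return a list of class `contour_series`.
#' @export
contour_series <- function(frames, pixel_size = 1, temperature = 298.15) {
  stopifnot(is.list(frames), length(frames) >= 1)
  for (f in frames) {
    if (!is.matrix(f) || ncol(f) != 2L || nrow(f) < 64L) {
      stop("each frame must be an n x 2 coordinate matrix with n >= 64")
    }
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 temperature = temperature),
            class = "contour_series")
}

#' @export
print.contour_series <- function(x, ...) {
  cat(sprintf("<contour series> %d frames, %d points/frame\n",
              length(x$frames), nrow(x$frames[[1L]])))
  invisible(x)
}

# polygon area centroid (shoelace); falls back to the vertex mean for
# degenerate (near-zero area) inputs
.polygon_centroid <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((x + xn) * cross) / (6 * a), sum((y + yn) * cross) / (6 * a))
}

#' Normalized radial deviation of one contour
#'
#' Measures the distance from the membrane edge to the vesicle centre (area
#' centroid), interpolates it onto a uniform angular grid and returns the
#' dimensionless deviation about the mean edge position,
#' `u(phi) = (r(phi) - rbar) / rbar`.
#'
#' @param frame `n x 2` coordinate matrix of a closed contour.
#' @param n_angles number of uniform angles (default 512).
#' @return a list: `u` (length `n_angles`), `phi`, `mean_radius`.
#' @export
contour_to_radial <- function(frame, n_angles = 512L) {
  stopifnot(is.matrix(frame), ncol(frame) == 2L, nrow(frame) >= 8L)
  ctr <- .polygon_centroid(frame)
  dx <- frame[, 1L] - ctr[1L]; dy <- frame[, 2L] - ctr[2L]
  theta <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  if (any(r <= 0)) stop("non-star-shaped contour: centre lies on the edge")
  # star-shapedness: r(phi) must be single-valued, i.e. the polar angle is
  # monotone along the traversal (small backward steps are tolerated as
  # digitisation noise) and the contour winds exactly once about the centroid
  dtheta <- diff(c(theta, theta[1L]))
  dtheta <- (dtheta + pi) %% (2 * pi) - pi
  if (abs(abs(sum(dtheta)) - 2 * pi) > 1e-6) {
    stop("non-star-shaped contour: winding number about the centroid is not 1")
  }
  dir <- sign(sum(dtheta))
  if (any(dir * dtheta < -0.05)) {
    stop("non-star-shaped contour: r(phi) is multi-valued about the centroid")
  }
  ord <- order(theta)
  th <- theta[ord]; rr <- r[ord]
  dup <- c(FALSE, diff(th) <= 0)
  th <- th[!dup]; rr <- rr[!dup]
  # periodic extension for wrap-around interpolation
  th_ext <- c(th[length(th)] - 2 * pi, th, th[1L] + 2 * pi)
  rr_ext <- c(rr[length(rr)], rr, rr[1L])
  phi <- seq(-pi, pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  r_u <- stats::approx(th_ext, rr_ext, xout = phi)$y
  rbar <- mean(r_u)
  list(u = (r_u - rbar) / rbar, phi = phi, mean_radius = rbar)
}

#' Fluctuation power spectrum of a contour series
#'
#' For each frame the radial deviation `u(phi)` is Fourier transformed; the
#' per-mode power is `(A_q^2 + B_q^2) / 2` with `A_q, B_q` the cosine/sine
#' coefficients, so that its expectation equals the model mode variance
#' `<|u_q|^2>`.  Powers are averaged over frames with per-mode standard
#' errors.
#'
#' @param series a [contour_series()].
#' @param q_max highest mode (default 20).
#' @param n_angles angular grid size (default 512; must exceed `2 * q_max`).
#' @param noise_floor optional constant variance subtracted from every mode
#'   (camera/pixel noise), applied after averaging.
#' @return a list of class `mode_spectrum`: `spectrum` (data frame `q`,
#'   `variance`, `se`), `n_frames`, `mean_radius`, `temperature`.
#' @export
fluctuation_spectrum <- function(series, q_max = 20L, n_angles = 512L,
                                 noise_floor = NULL) {
  stopifnot(inherits(series, "contour_series"))
  if (q_max >= n_angles / 2) stop("q_max must be below n_angles / 2")
  qs <- 2:q_max
  n <- length(series$frames)
  pow <- matrix(NA_real_, n, length(qs))
  radii <- numeric(n)
  for (i in seq_len(n)) {
    rad <- contour_to_radial(series$frames[[i]], n_angles)
    radii[i] <- rad$mean_radius
    co <- stats::fft(rad$u) / n_angles
    pow[i, ] <- 2 * Mod(co[qs + 1L])^2
  }
  v <- colMeans(pow)
  se <- apply(pow, 2L, stats::sd) / sqrt(n)
  if (!is.null(noise_floor)) v <- pmax(v - noise_floor, 0)
  structure(list(
    spectrum = data.frame(q = qs, variance = v, se = se),
    n_frames = n, mean_radius = mean(radii),
    temperature = series$temperature
  ), class = "mode_spectrum")
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat(sprintf("<mode spectrum> q = %d..%d over %d frames, R = %.2f\n",
              min(x$spectrum$q), max(x$spectrum$q), x$n_frames, x$mean_radius))
  invisible(x)
}

#' Helfrich mode variance of a quasi-spherical vesicle
#'
#' Theoretical equatorial-contour fluctuation variance of mode `q` for a
#' quasi-spherical vesicle with bending rigidity `kappa` (in units of k_B T)
#' and reduced tension `sigma_bar` (= sigma R^2 / kappa):
#' \deqn{\langle|u_q|^2\rangle = \frac{k_BT}{\kappa} \sum_{l=q}^{l_{max}}
#'   \frac{2l+1}{4\pi}\frac{(l-q)!}{(l+q)!}\,[P_l^q(0)]^2\,
#'   \frac{1}{(l-1)(l+2)\,[l(l+1)+\bar\sigma]}}
#' with \eqn{P_l^q} the associated Legendre function; terms with odd
#' \eqn{l+q} vanish at the equator.
#'
#' @param q mode number (integer >= 2; 0 and 1 are excluded as dilation and
#'   translation).
#' @param kappa bending rigidity in k_B T units (> 0).
#' @param sigma_bar dimensionless reduced tension (>= 0 physically; any value
#'   > -6 is accepted numerically).
#' @param l_max spherical-harmonic truncation (default 100; see
#'   [helfrich_truncation_check()]).
#' @return dimensionless variance(s), vectorized over `q`.
#' @export
helfrich_variance <- function(q, kappa, sigma_bar = 0, l_max = 100L) {
  stopifnot(kappa > 0, l_max >= max(q))
  if (any(q < 2)) stop("q must be >= 2 (translation/dilation modes excluded)")
  vapply(q, function(qq) {
    l <- seq.int(qq, l_max)
    l <- l[l >= 2 & ((l + qq) %% 2 == 0)]
    # log of (2l+1)/(4pi) * (l-q)!/(l+q)! * P_l^q(0)^2, Legendre at the
    # equator via the Gamma-function closed form
    lg <- log(2 * l + 1) - log(4 * pi) +
      lgamma(l - qq + 1) - lgamma(l + qq + 1) +
      2 * (qq * log(2) - 0.5 * log(pi) +
             lgamma((l + qq + 1) / 2) - lgamma((l - qq) / 2 + 1))
    denom <- (l - 1) * (l + 2) * (l * (l + 1) + sigma_bar)
    sum(exp(lg) / denom) / kappa
  }, numeric(1))
}

#' Check spherical-harmonic truncation of the Helfrich sum
#'
#' Increases `l_max` until every mode variance changes by less than `rel_tol`.
#'
#' @param q modes of interest.
#' @param kappa,sigma_bar model parameters.
#' @param l_max starting truncation.
#' @param rel_tol relative change tolerance (default 1e-3).
#' @return the adequate `l_max`.
#' @export
helfrich_truncation_check <- function(q, kappa, sigma_bar = 0, l_max = 100L,
                                      rel_tol = 1e-3) {
  repeat {
    v1 <- helfrich_variance(q, kappa, sigma_bar, l_max)
    v2 <- helfrich_variance(q, kappa, sigma_bar, 2L * l_max)
    if (max(abs(v2 - v1) / v2) < rel_tol) return(l_max)
    l_max <- 2L * l_max
    if (l_max > 1e5) stop("Helfrich sum failed to converge")
  }
}

#' Fit the bending rigidity from a fluctuation spectrum
#'
#' Weighted least squares of the measured mode variances against
#' [helfrich_variance()] over modes `q_min`..`q_max`, with free parameters
#' bending rigidity `kappa` (k_B T) and reduced tension `sigma_bar`.  Weights
#' are inverse squared per-mode standard errors.  A negative fitted tension
#' triggers a warning and a refit with `sigma_bar` clamped to 0.
#'
#' @param spectrum a [fluctuation_spectrum()] result.
#' @param q_min,q_max fitted mode range (defaults 6 and 20).
#' @param l_max spherical-harmonic truncation for the model.
#' @return a list of class `rigidity_fit`: `kappa`, `kappa_se`, `sigma_bar`,
#'   `sigma_bar_se`, `fit_modes`, `chisq`, `dof`, `residuals`.
#' @export
fit_bending_rigidity <- function(spectrum, q_min = 6L, q_max = 20L,
                                 l_max = 100L) {
  stopifnot(inherits(spectrum, "mode_spectrum"))
  sp <- spectrum$spectrum
  keep <- sp$q >= q_min & sp$q <= q_max
  if (sum(keep) < 3L) stop("spectrum does not cover the fitted mode range")
  q <- sp$q[keep]; v <- sp$variance[keep]; se <- sp$se[keep]
  if (any(v <= 0)) stop("non-positive mode variances in the fitted range")
  se[se <= 0] <- max(v) * 1e-6   # noiseless input: uniform nominal weights
  resid_fun <- function(par) {
    (helfrich_variance(q, exp(par[1L]), par[2L], l_max) - v) / se
  }
  # initial kappa from the highest modes (tension-insensitive), sigma from 0
  k0 <- stats::median(helfrich_variance(q, 1, 0, l_max) / v)
  fit <- minpack.lm::nls.lm(par = c(log(k0), 0), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 9)) stop("Helfrich fit did not converge: ", fit$message)
  par <- fit$par
  clamped <- FALSE
  if (par[2L] < 0) {
    warning("fitted reduced tension is negative; refitting with sigma_bar = 0")
    clamped <- TRUE
    fit <- minpack.lm::nls.lm(par = c(par[1L], 0), fn = resid_fun,
                              lower = c(-Inf, 0), upper = c(Inf, 0),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    par <- fit$par
  }
  kappa <- exp(par[1L]); sigma_bar <- par[2L]
  r <- resid_fun(par)
  chisq <- sum(r^2)
  dof <- length(q) - if (clamped) 1L else 2L
  # parameter covariance from the numerical Jacobian of the residuals
  J <- .num_jacobian(resid_fun, par)
  if (clamped) J <- J[, 1L, drop = FALSE]
  s2 <- chisq / max(dof, 1L)
  cov <- tryCatch(solve(crossprod(J)) * s2,
                  error = function(e) matrix(NA_real_, ncol(J), ncol(J)))
  kappa_se <- kappa * sqrt(cov[1L, 1L])       # delta method through log-kappa
  sigma_se <- if (clamped) NA_real_ else sqrt(cov[2L, 2L])
  structure(list(kappa = kappa, kappa_se = kappa_se,
                 sigma_bar = sigma_bar, sigma_bar_se = sigma_se,
                 fit_modes = c(q_min, q_max), chisq = chisq, dof = dof,
                 residuals = r, clamped = clamped),
            class = "rigidity_fit")
}

.num_jacobian <- function(f, par, eps = 1e-6) {
  f0 <- f(par)
  J <- matrix(NA_real_, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    p1 <- par; p1[j] <- p1[j] + h
    J[, j] <- (f(p1) - f0) / h
  }
  J
}

#' @export
print.rigidity_fit <- function(x, ...) {
  cat(sprintf("<rigidity fit> kappa = %.2f +/- %.2f kT, sigma_bar = %.2f, modes %d-%d, chisq/dof = %.2f\n",
              x$kappa, x$kappa_se, x$sigma_bar, x$fit_modes[1L], x$fit_modes[2L],
              x$chisq / max(x$dof, 1L)))
  invisible(x)
}

#' Generalized polarization map from two emission channels
#'
#' `GP = (I_ord - I_dis) / (I_ord + I_dis)` per pixel, with the ordered-phase
#' channel first (e.g. 510-580 nm vs 620-750 nm emission windows).  Pixels
#' with non-positive denominator are masked (NA).
#'
#' @param channel_ordered,channel_disordered numeric matrices of identical
#'   shape, non-negative intensities.
#' @param masks optional named list of logical matrices; region mean GP is
#'   reported for each.
#' @return a list of class `gp_image`: `gp` (matrix), `region_means`.
#' @export
gp_map <- function(channel_ordered, channel_disordered, masks = NULL) {
  if (!all(dim(channel_ordered) == dim(channel_disordered))) {
    stop("channel images must have the same shape")
  }
  if (any(channel_ordered < 0, na.rm = TRUE) || any(channel_disordered < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  denom <- channel_ordered + channel_disordered
  gp <- (channel_ordered - channel_disordered) / denom
  gp[!(denom > 0)] <- NA_real_
  region_means <- if (!is.null(masks)) {
    vapply(masks, function(m) mean(gp[m], na.rm = TRUE), numeric(1))
  } else NULL
  structure(list(gp = gp, region_means = region_means), class = "gp_image")
}

# two-class variance-minimizing (Otsu) threshold on a numeric vector
.otsu_threshold <- function(x) {
  xs <- sort(unique(x))
  if (length(xs) < 2L) return(NA_real_)
  cand <- (xs[-1L] + xs[-length(xs)]) / 2
  wcv <- vapply(cand, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  cand[which.min(wcv)]
}

#' Ld/Lo phase-area ratio from an equatorial intensity profile
#'
#' Segments a closed equatorial intensity profile (bright = Ld-partitioning
#' tracer) into two levels with a variance-minimizing threshold and reports
#' the bright-to-dim arc-length ratio.  Profiles without two distinct
#' intensity populations (relative contrast below `min_contrast`) are flagged
#' single-phase.
#'
#' @param profile numeric vector of intensities sampled uniformly along the
#'   contour.
#' @param min_contrast minimum Michelson contrast between the two class means
#'   to accept phase coexistence (default 0.1).
#' @return a list: `ratio` (Ld/Lo; `Inf` with `single_phase = TRUE` when only
#'   one phase is present), `single_phase`, `threshold`, `frac_bright`.
#' @export
phase_area_ratio <- function(profile, min_contrast = 0.1) {
  stopifnot(is.numeric(profile), length(profile) >= 8L, all(profile >= 0))
  thr <- .otsu_threshold(profile)
  if (is.na(thr)) {
    return(list(ratio = Inf, single_phase = TRUE, threshold = NA_real_,
                frac_bright = 1))
  }
  bright <- profile > thr
  mu_hi <- mean(profile[bright]); mu_lo <- mean(profile[!bright])
  contrast <- (mu_hi - mu_lo) / (mu_hi + mu_lo)
  if (!is.finite(contrast) || contrast < min_contrast) {
    return(list(ratio = Inf, single_phase = TRUE, threshold = thr,
                frac_bright = 1))
  }
  fb <- mean(bright)
  list(ratio = fb / (1 - fb), single_phase = FALSE, threshold = thr,
       frac_bright = fb)
}
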