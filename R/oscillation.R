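#' Find a fixed point of the deterministic dynamics
#'
#' Damped Newton iteration on the drift, with the Jacobian from
#' [eco_jacobian()]. The default starting guess is the endpoint of a long
#' deterministic run, which lands in the basin of the coexistence state
#' when one exists. Components are kept nonnegative.
#'
#' @param params An [eco_params()] object.
#' @param guess Starting 9-vector; `NULL` simulates to `t_guess` h and
#'   starts there.
#' @param t_guess Horizon of the guess-generating run (default 500 h).
#' @param tol Convergence tolerance on `max(|drift| / pmax(|x|, 1))`,
#'   an effective per-hour rate (default 1e-6, about the best the
#'   finite-difference Newton resolves across the ~1e9 span of component
#'   magnitudes).
#' @param max_iter Newton iteration cap.
#' @return Named fixed-point vector with attributes `residual` and
#'   `converged`.
#' @export
find_fixed_point <- function(params = eco_params(), guess = NULL,
                             t_guess = 500, tol = 1e-6, max_iter = 200) {
  if (is.null(guess)) {
    tr <- eco_simulate(eco_state(), params, t_end = t_guess, dt = 0.005,
                       record_every = 100000L, mode = "deterministic")
    guess <- unlist(tr[nrow(tr), eco_species()])
  }
  x <- pmax(as_eco_state(guess), 0)
  res <- function(x) max(abs(eco_drift(x, params)) / pmax(abs(x), 1))
  r <- res(x)
  for (it in seq_len(max_iter)) {
    if (r < tol) break
    f <- unname(eco_drift(x, params))
    J <- eco_jacobian(params, x)
    # equilibrate: the state spans ~1e9 .. 1e-7, so scale columns by the
    # component magnitudes and rows by the resulting row maxima before
    # solving (pseudo-inverse guards the near-singular cases)
    sc <- pmax(abs(unname(x)), 1)
    Js <- unclass(J) %*% diag(sc)
    rs <- pmax(apply(abs(Js), 1, max), 1e-300)
    Js <- Js / rs
    sv <- svd(Js)
    inv_d <- ifelse(sv$d > max(sv$d) * 1e-14, 1 / sv$d, 0)
    step <- sc * (sv$v %*% (inv_d * crossprod(sv$u, -f / rs)))[, 1]
    lambda <- 1
    repeat {
      xn <- pmax(unname(x) + lambda * step, 0)
      rn <- res(stats::setNames(xn, eco_species()))
      if (rn < r || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (rn >= r) break
    x <- stats::setNames(xn, eco_species())
    r <- rn
  }
  if (r >= tol)
    warning("fixed-point search did not converge (residual ",
            format(r, digits = 3), ")", call. = FALSE)
  structure(x, residual = r, converged = r < tol)
}

#' Jacobian of the drift by central finite differences
#'
#' @param params An [eco_params()] object.
#' @param point State at which to differentiate.
#' @param fd_scale Relative step scale; the step for component i is
#'   `fd_scale * max(|x_i|, 1)`.
#' @return 9 x 9 matrix with an `"eigenvalues"` attribute.
#' @export
eco_jacobian <- function(params, point, fd_scale = 1e-6) {
  stopifnot(fd_scale > 0)
  x <- as_eco_state(point)
  n <- length(x)
  J <- matrix(0, n, n, dimnames = list(eco_species(), eco_species()))
  for (j in seq_len(n)) {
    h <- fd_scale * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- max(x[j] - h, 0)
    dh <- xp[j] - xm[j]
    J[, j] <- (eco_drift(xp, params) - eco_drift(xm, params)) / dh
  }
  if (any(!is.finite(J)))
    stop("non-finite Jacobian entries", call. = FALSE)
  structure(J, eigenvalues = eigen(J, only.values = TRUE)$values)
}

# Leading complex-conjugate eigenvalue pair (largest real part among
# eigenvalues with nonzero imaginary part); falls back to the overall
# leading eigenvalue if the spectrum is entirely real.
.leading_pair <- function(ev) {
  cx <- ev[abs(Im(ev)) > 1e-12]
  if (!length(cx)) return(ev[which.max(Re(ev))])
  cx[which.max(Re(cx))]
}

#' Dominant oscillation period by FFT
#'
#' Period of a uniformly sampled, post-transient signal as the inverse of
#' the dominant nonzero-frequency peak of its mean-removed discrete
#' Fourier transform.
#'
#' @param signal Numeric time series.
#' @param dt Sampling interval, hours.
#' @param min_snr Minimum ratio of the dominant peak to the median
#'   spectral magnitude; below it the signal is declared non-oscillatory.
#' @return Period in hours, or `NA` with a warning when no spectral peak
#'   stands above the noise floor.
#' @export
oscillation_period <- function(signal, dt, min_snr = 10) {
  x <- signal - mean(signal)
  n <- length(x)
  if (n < 8) stop("signal too short", call. = FALSE)
  sp <- Mod(stats::fft(x))[2:floor(n / 2)]
  if (!length(sp) || max(sp) < min_snr * max(stats::median(sp), 1e-300)) {
    warning("no dominant spectral peak: signal is not oscillatory",
            call. = FALSE)
    return(NA_real_)
  }
  k <- which.max(sp)            # frequency k / (n * dt)
  # parabolic interpolation of the spectral peak removes the coarse
  # bin quantization of long periods
  if (k > 1 && k < length(sp)) {
    y1 <- sp[k - 1]; y2 <- sp[k]; y3 <- sp[k + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) k <- k + 0.5 * (y1 - y3) / denom
  }
  n * dt / k
}

# Autocorrelation-based period (first significant positive-lag peak);
# used as the FFT estimator's cross-check.
.acf_period <- function(signal, dt) {
  x <- signal - mean(signal)
  ac <- stats::acf(x, lag.max = length(x) - 1, plot = FALSE)$acf[, 1, 1]
  # first local max after the initial decay through zero
  below <- which(ac < 0)
  if (!length(below)) return(NA_real_)
  j0 <- below[1]
  seg <- ac[j0:length(ac)]
  pk <- which.max(seg) + j0 - 1L
  (pk - 1L) * dt
}

# Post-transient classification of a deterministic trajectory window:
# extinct (absorbed), sustained (stable peak-to-trough envelope), or
# damped (decaying envelope / negligible amplitude).
.classify_window <- function(time, x, rel_amp_tol = 0.02,
                             peak_var_tol = 0.05) {
  if (x[length(x)] <= 0 || all(x == 0)) return(list(regime = "extinct"))
  amp <- (max(x) - min(x)) / max(mean(x), 1e-300)
  if (!is.finite(amp) || amp < rel_amp_tol)
    return(list(regime = "damped", amplitude = c(min(x), max(x))))
  n <- length(x)
  pk <- which(diff(sign(diff(x))) == -2) + 1L
  if (length(pk) < 3)
    return(list(regime = "damped", amplitude = c(min(x), max(x))))
  heights <- x[pk]
  rel_drift <- abs(heights[length(heights)] - heights[1]) /
    max(mean(heights), 1e-300)
  regime <- if (rel_drift < peak_var_tol) "sustained" else "damped"
  list(regime = regime, amplitude = c(min(x), max(x)),
       n_peaks = length(pk))
}

#' Bifurcation scan over the bacterial degradation rate
#'
#' For each value of `d` the coexistence fixed point is continued (warm
#' starts along the grid), the Jacobian eigenvalues are computed, and an
#' independent deterministic transient run is classified from its
#' post-transient window (last quarter of `t_transient`): `damped`
#' (decaying envelope onto the fixed point), `sustained` (stable
#' peak-to-trough envelope), or `extinct` (absorption). The Hopf point is
#' the smallest grid `d` whose leading complex eigenvalue pair has
#' positive real part; amplitude envelopes and FFT periods are recorded
#' for the sustained window. Rows where the eigenvalue and transient
#' classifications disagree are flagged, never silently dropped.
#'
#' @param params An [eco_params()] object (`d` is overridden by the grid).
#' @param d_grid Increasing grid of degradation rates, 1/h.
#' @param t_transient Length of the transient run, hours (default 2000).
#' @param dt Step size, hours.
#' @return An `eco_bifurcation` object: a list with `results` (one row
#'   per `d`), `hopf_d`, `extinction_d`, and the scan settings.
#' @export
scan_bifurcation <- function(params = eco_params(),
                             d_grid = seq(0.1, 1, by = 0.01),
                             t_transient = 2000, dt = 0.005) {
  stopifnot(!is.unsorted(d_grid))
  guess <- NULL
  rows <- vector("list", length(d_grid))
  for (i in seq_along(d_grid)) {
    p <- eco_update(params, d = d_grid[i])
    fp <- suppressWarnings(
      find_fixed_point(p, guess = guess, t_guess = 500))
    fp_ok <- isTRUE(attr(fp, "converged")) && fp[["c1"]] >= 1 &&
      fp[["c2"]] >= 1
    if (fp_ok) guess <- fp        # warm start for the next d
    lead <- NA_complex_
    if (fp_ok) {
      J <- eco_jacobian(p, fp)
      lead <- .leading_pair(attr(J, "eigenvalues"))
    }
    tr <- eco_simulate(eco_state(), p, t_end = t_transient, dt = dt,
                       record_every = max(1L, round(0.05 / dt)),
                       mode = "deterministic")
    win <- tr$time >= 0.75 * t_transient
    cls <- .classify_window(tr$time[win], tr$c1[win])
    c2win <- tr$c2[win]
    period <- NA_real_
    if (cls$regime == "sustained") {
      dts <- diff(tr$time[win])[1]
      period <- oscillation_period(tr$c1[win], dts)
    }
    eig_unstable <- if (fp_ok) Re(lead) > 0 else NA
    flag <- !is.na(eig_unstable) &&
      ((eig_unstable && cls$regime == "damped") ||
       (!eig_unstable && cls$regime == "sustained"))
    rows[[i]] <- tibble::tibble(
      d = d_grid[i], regime = cls$regime,
      fp_c1 = if (fp_ok) fp[["c1"]] else NA_real_,
      fp_c2 = if (fp_ok) fp[["c2"]] else NA_real_,
      eig_re = Re(lead), eig_im = abs(Im(lead)),
      c1_min = if (!is.null(cls$amplitude)) cls$amplitude[1] else 0,
      c1_max = if (!is.null(cls$amplitude)) cls$amplitude[2] else 0,
      c2_min = min(c2win), c2_max = max(c2win),
      period = period, flagged = flag)
  }
  results <- dplyr::bind_rows(rows)
  cross <- which(!is.na(results$eig_re) & results$eig_re > 0 &
                   results$eig_im > 0)
  hopf_d <- if (length(cross)) results$d[cross[1]] else NA_real_
  ext <- which(results$regime == "extinct")
  extinction_d <- if (length(ext)) results$d[ext[1]] else NA_real_
  structure(list(results = results, hopf_d = hopf_d,
                 extinction_d = extinction_d,
                 t_transient = t_transient, dt = dt, params = params),
            class = "eco_bifurcation")
}

#' @export
print.eco_bifurcation <- function(x, ...) {
  cat(sprintf(
    "<eco_bifurcation> %d values of d in [%g, %g] 1/h\n",
    nrow(x$results), min(x$results$d), max(x$results$d)))
  cat(sprintf("  Hopf onset:  d = %s 1/h\n", format(x$hopf_d)))
  cat(sprintf("  extinction:  d = %s 1/h\n", format(x$extinction_d)))
  if (any(x$results$flagged))
    cat("  note: eigenvalue/transient disagreement at d =",
        paste(x$results$d[x$results$flagged], collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.eco_bifurcation <- function(x, ...) x$results

#' @export
glance.eco_bifurcation <- function(x, ...) {
  sus <- x$results[x$results$regime == "sustained", ]
  tibble::tibble(hopf_d = x$hopf_d, extinction_d = x$extinction_d,
                 n_sustained = nrow(sus),
                 period_min = suppressWarnings(min(sus$period, na.rm = TRUE)),
                 period_max = suppressWarnings(max(sus$period, na.rm = TRUE)))
}

#' Noise-amplitude extinction scan
#'
#' With the degradation rate inside the sustained-oscillation window, the
#' oscillating populations repeatedly visit small values where Langevin
#' noise can absorb them. This scan runs a replicate ensemble at each
#' noise scale epsilon (common random numbers across the grid), records
#' the fraction of replicates with both populations alive at the horizon,
#' and reports the largest epsilon at which every replicate survives and
#' the surviving trajectories still oscillate at the deterministic period
#' (within `period_tol`).
#'
#' @inheritParams scan_bifurcation
#' @param d Degradation rate, 1/h (must be supplied; the study uses 0.5).
#' @param epsilon_grid Increasing noise scales in `[0, 1]`.
#' @param n_replicates Replicates per epsilon (default 20).
#' @param horizon Hours (default 1000).
#' @param base_seed First replicate seed.
#' @param period_tol Optional relative tolerance on the survivors'
#'   median oscillation period (default `NULL`: period deviation is
#'   reported, not gated).
#' @return A list: `scan` (tibble: epsilon, survival fraction, number of
#'   oscillating survivors, median relative period deviation, sustained
#'   flag), `epsilon_star` (largest epsilon whose whole ensemble
#'   survives with sustained oscillations), `deterministic_period`.
#' @export
noise_extinction_scan <- function(params = eco_params(), d = 0.5,
                                  epsilon_grid = seq(0.0025, 0.03,
                                                     by = 0.0025),
                                  n_replicates = 20, horizon = 1000,
                                  base_seed = 1L, period_tol = NULL,
                                  dt = 0.005) {
  stopifnot(!is.unsorted(epsilon_grid), all(epsilon_grid >= 0),
            all(epsilon_grid <= 1))
  p0 <- eco_update(params, d = d)
  det <- eco_simulate(eco_state(), p0, t_end = horizon, dt = dt,
                      record_every = max(1L, round(0.25 / dt)),
                      mode = "deterministic")
  win <- det$time >= horizon / 4
  dts <- diff(det$time[win])[1]
  det_period <- oscillation_period(det$c1[win], dts)
  rows <- vector("list", length(epsilon_grid))
  for (k in seq_along(epsilon_grid)) {
    p <- eco_update(p0, noise_scale = epsilon_grid[k])
    alive <- 0L
    n_osc <- 0L
    per_err <- numeric(0)
    for (i in seq_len(n_replicates)) {
      tr <- eco_simulate(eco_state(), p, t_end = horizon, dt = dt,
                         record_every = max(1L, round(0.25 / dt)),
                         mode = "stochastic", seed = base_seed + i - 1L)
      last <- nrow(tr)
      if (tr$c1[last] > 0 && tr$c2[last] > 0) {
        alive <- alive + 1L
        pe <- suppressWarnings(
          oscillation_period(tr$c1[tr$time >= horizon / 4], dts))
        if (!is.na(pe)) {
          n_osc <- n_osc + 1L
          if (!is.na(det_period))
            per_err <- c(per_err, abs(pe - det_period) / det_period)
        }
      }
    }
    frac <- alive / n_replicates
    med_err <- if (length(per_err)) stats::median(per_err) else NA_real_
    ok <- frac == 1 && n_osc == alive
    if (!is.null(period_tol))
      ok <- ok && !is.na(med_err) && med_err <= period_tol
    rows[[k]] <- tibble::tibble(
      epsilon = epsilon_grid[k], survival = frac,
      n_oscillating = n_osc,
      period_rel_err = med_err,
      sustained = ok)
  }
  scan <- dplyr::bind_rows(rows)
  star <- scan$epsilon[scan$sustained]
  list(scan = scan,
       epsilon_star = if (length(star)) max(star) else NA_real_,
       deterministic_period = det_period,
       d = d, n_replicates = n_replicates, horizon = horizon,
       base_seed = base_seed)
}
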