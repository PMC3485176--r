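#' Advance the state by one Euler-Maruyama step
#'
#' Reference single-step update: `state + drift*dt + B %*% (draws*sqrt(dt))`
#' where `B` is the Langevin noise-coefficient matrix, followed by clamping
#' at zero and absorption of populations below `extinction_threshold`.
#' This is the pure-R counterpart of the compiled integrator and is mainly
#' useful for inspection and testing; [eco_simulate()] is the fast path.
#'
#' @inheritParams eco_propensities
#' @param dt Step size, hours.
#' @param draws 18 standard-normal draws, one per reaction channel. With
#'   `noise_scale = 0` the step reduces to an explicit-Euler ODE step and
#'   `draws` is ignored.
#' @param extinction_threshold Populations below this many cells are set to
#'   0 (absorbing), default 1.
#' @return Named state vector after one step.
#' @export
eco_step <- function(state, params, dt, draws = rep(0, 18),
                     extinction_threshold = 1) {
  x <- as_eco_state(state)
  stopifnot(dt > 0, length(draws) == 18)
  f <- eco_drift(x, params)
  B <- eco_noise_matrix(x, params)
  x <- unname(x) + unname(f) * dt + drop(B %*% (draws * sqrt(dt)))
  if (any(!is.finite(x)))
    stop("non-finite state after step", call. = FALSE)
  x <- pmax(x, 0)
  x[1:2][x[1:2] < extinction_threshold] <- 0
  stats::setNames(x, eco_species())
}

#' Simulate one trajectory of the ecosystem
#'
#' Integrates the chemical Langevin equations with the explicit
#' Euler-Maruyama scheme (one independent Wiener increment per reaction
#' channel per step). In `"deterministic"` mode the noise terms are
#' dropped and the scheme reduces to explicit Euler on the drift. Negative
#' excursions are clamped at zero and each population is absorbed at zero
#' once it falls below `extinction_threshold` cells.
#'
#' @param initial Initial state, see [eco_state()].
#' @param params An [eco_params()] object.
#' @param t_end Horizon, hours.
#' @param dt Step size, hours (default 0.005, chosen so the fastest
#'   first-order rate in the default network satisfies `k*dt <= 0.025`).
#' @param record_every Record every this many steps (default 10, i.e. a
#'   0.05 h output grid at the default `dt`).
#' @param mode `"stochastic"` (chemical Langevin) or `"deterministic"`
#'   (drift only).
#' @param seed Integer RNG seed; fully determines a stochastic trajectory.
#' @param extinction_threshold Absorption threshold, cells (default 1).
#' @return An `eco_trajectory`: a tibble with columns `time` and the nine
#'   species, plus attributes `params`, `seed`, `mode`, `dt`, and
#'   `extinct_at` (time at which both populations were absorbed, or `NA`).
#' @examples
#' tr <- eco_simulate(t_end = 5, mode = "deterministic")
#' tail(tr, 3)
#' @export
eco_simulate <- function(initial = eco_state(), params = eco_params(),
                         t_end = 50, dt = 0.005, record_every = 10L,
                         mode = c("stochastic", "deterministic"),
                         seed = 1L, extinction_threshold = 1) {
  mode <- match.arg(mode)
  x0 <- as_eco_state(initial)
  stopifnot(inherits(params, "eco_params"),
            dt > 0, t_end > 0, record_every >= 1,
            extinction_threshold >= 0)
  n_steps <- as.integer(ceiling(t_end / dt))
  stochastic <- mode == "stochastic" && params$noise_scale > 0
  if (stochastic) {
    old <- get0(".Random.seed", globalenv())
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  }
  res <- .cpp_simulate(unname(x0), cpp_param_vector(params), dt,
                       n_steps, as.integer(record_every),
                       extinction_threshold, stochastic)
  out <- tibble::as_tibble(as.data.frame(res$states))
  names(out) <- eco_species()
  out <- tibble::add_column(out, time = res$times, .before = 1)
  structure(out,
            class = c("eco_trajectory", class(out)),
            params = params, seed = if (mode == "stochastic") seed else NA,
            mode = mode, dt = dt,
            extinction_threshold = extinction_threshold,
            extinct_at = res$extinct_at)
}

#' @export
print.eco_trajectory <- function(x, ...) {
  cat(sprintf("<eco_trajectory> %s, %d records to t = %g h%s\n",
              attr(x, "mode"), nrow(x), max(x$time),
              if (!is.na(attr(x, "extinct_at")))
                sprintf(", extinct at %g h", attr(x, "extinct_at"))
              else ""))
  NextMethod()
}

#' Long (tidy) form of a trajectory
#'
#' @param x An `eco_trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `species`, `value`, `seed`, `mode`.
#' @export
tidy.eco_trajectory <- function(x, ...) {
  out <- tidyr::pivot_longer(tibble::as_tibble(x), -"time",
                             names_to = "species", values_to = "value")
  out$species <- factor(out$species, levels = eco_species())
  out$seed <- attr(x, "seed")
  out$mode <- attr(x, "mode")
  out
}

#' Time for the populations to reach steady state
#'
#' Trailing-window criterion: with window means
#' `m(u) = mean(x on (u - window, u])` (truncated at 0 for early times),
#' a time `s` is quiet when `|m(s) - m(s - window)| / m(s - window) <
#' rel_tol` for both populations; the detected time is the earliest
#' recorded `t >= window` from which every later time is quiet. A
#' constant signal is detected at `t = window`; a still-growing logistic
#' signal is not detected until growth saturates.
#'
#' @param x An `eco_trajectory`, an [eco_ensemble()] (its per-time means
#'   are used), or a data frame with columns `time`, `c1`, `c2`.
#' @param rel_tol Relative-change tolerance (default 0.01).
#' @param window Window length, hours (default 5).
#' @return Detected time in hours, or `NA` if never satisfied.
#' @export
steady_state_time <- function(x, rel_tol = 0.01, window = 5) {
  UseMethod("steady_state_time")
}

#' @export
steady_state_time.data.frame <- function(x, rel_tol = 0.01, window = 5) {
  stopifnot(all(c("time", "c1", "c2") %in% names(x)))
  .ss_time(x$time, cbind(x$c1, x$c2), rel_tol, window)
}

#' @export
steady_state_time.eco_ensemble <- function(x, rel_tol = 0.01, window = 5) {
  m <- tidyr::pivot_wider(
    dplyr::filter(x$summary, .data$species %in% c("c1", "c2")),
    id_cols = "time", names_from = "species", values_from = "mean")
  .ss_time(m$time, cbind(m$c1, m$c2), rel_tol, window)
}

.ss_time <- function(times, pops, rel_tol, window) {
  t_end <- max(times)
  if (window >= t_end)
    stop("window must be shorter than the trajectory", call. = FALSE)
  # trailing-window means on the (uniform) record grid, truncated at t = 0
  n <- length(times)
  quiet <- rep(TRUE, n)
  idx <- seq_len(n)
  lo <- findInterval(times - window, times) + 1L   # first index > t - w
  prev <- pmax(lo - 1L, 1L)                        # index of t - w (or 0)
  for (k in 1:2) {
    cs <- cumsum(pops[, k])
    wm <- (cs - c(0, cs)[lo]) / (idx - lo + 1L)    # mean over (t - w, t]
    mp <- wm[prev]
    rel <- abs(wm - mp) / pmax(abs(mp), .Machine$double.eps)
    quiet <- quiet & (rel < rel_tol)
  }
  ok <- times >= window
  cand <- which(ok & rev(cumprod(rev(quiet))) == 1)
  if (!length(cand)) return(NA_real_)
  times[cand[1]]
}

#' Write a trajectory to a tidy CSV
#'
#' Columns `time`, `species`, `value`, `seed`, `mode`, full double
#' precision.
#'
#' @param x An `eco_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  utils::write.csv(format(as.data.frame(tidy(x)), digits = 17,
                          trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
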