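#' Simulate an ensemble of replicate colonies
#'
#' Runs `n` independent stochastic trajectories (seeds `base_seed` to
#' `base_seed + n - 1`) and accumulates per-time, per-species means and
#' standard deviations across replicates. Extinct replicates are included
#' in the statistics (this is what collapses ensemble averages when many
#' single trajectories reach zero); survivor-only statistics can be formed
#' from the per-time survivor counts also returned.
#'
#' @inheritParams eco_simulate
#' @param n Number of replicate colonies (the study design uses 100).
#' @param base_seed First replicate seed.
#' @return An `eco_ensemble` object with elements
#'   \describe{
#'     \item{summary}{tibble: `time`, `species`, `mean`, `sd` (sample,
#'       n-1 denominator).}
#'     \item{survival}{tibble: `time`, `n_alive` (replicates with both
#'       populations > 0).}
#'     \item{terminal}{tibble of per-replicate terminal states with
#'       `replicate`, `seed`, `extinct_at`.}
#'     \item{n, n_extinct, base_seed, params, config}{metadata.}
#'   }
#' @examples
#' ens <- eco_ensemble(n = 3, t_end = 2)
#' glance(ens)
#' @export
eco_ensemble <- function(initial = eco_state(), params = eco_params(),
                         n = 100, t_end = 50, dt = 0.005,
                         record_every = 10L,
                         mode = c("stochastic", "deterministic"),
                         base_seed = 1L, extinction_threshold = 1) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  seeds <- base_seed + seq_len(n) - 1L
  sum_x <- sum_x2 <- NULL
  n_alive <- NULL
  times <- NULL
  terminal <- vector("list", n)
  extinct_at <- numeric(n)
  for (i in seq_len(n)) {
    tr <- eco_simulate(initial, params, t_end = t_end, dt = dt,
                       record_every = record_every, mode = mode,
                       seed = seeds[i],
                       extinction_threshold = extinction_threshold)
    m <- as.matrix(tr[, eco_species()])
    if (is.null(sum_x)) {
      times <- tr$time
      sum_x <- m * 0
      sum_x2 <- m * 0
      n_alive <- integer(nrow(m))
    }
    sum_x <- sum_x + m
    sum_x2 <- sum_x2 + m^2
    n_alive <- n_alive + (m[, "c1"] > 0 & m[, "c2"] > 0)
    terminal[[i]] <- m[nrow(m), ]
    extinct_at[i] <- attr(tr, "extinct_at")
  }
  mean_x <- sum_x / n
  var_x <- if (n > 1) pmax(sum_x2 - n * mean_x^2, 0) / (n - 1) else mean_x * 0
  summary <- tibble::tibble(
    time = rep(times, times = ncol(mean_x)),
    species = factor(rep(eco_species(), each = length(times)),
                     levels = eco_species()),
    mean = as.vector(mean_x),
    sd = as.vector(sqrt(var_x)))
  term <- tibble::as_tibble(do.call(rbind, terminal))
  term <- tibble::add_column(term, replicate = seq_len(n), seed = seeds,
                             extinct_at = extinct_at, .before = 1)
  structure(
    list(summary = summary,
         survival = tibble::tibble(time = times, n_alive = n_alive),
         terminal = term,
         n = n, n_extinct = sum(!is.na(extinct_at)),
         base_seed = base_seed, params = params,
         config = list(t_end = t_end, dt = dt,
                       record_every = record_every, mode = mode,
                       extinction_threshold = extinction_threshold,
                       initial = as_eco_state(initial),
                       sd_estimator = "sample")),
    class = "eco_ensemble")
}

#' @export
print.eco_ensemble <- function(x, ...) {
  cat(sprintf(
    "<eco_ensemble> %d replicates to t = %g h (%s), %d extinct\n",
    x$n, max(x$summary$time), x$config$mode, x$n_extinct))
  print(steady_state_stats(x, max(x$summary$time)))
  invisible(x)
}

#' Per-species mean and standard deviation at a time point
#'
#' Evaluated at the nearest recorded time.
#'
#' @param ensemble An [eco_ensemble()].
#' @param t_eval Evaluation time, hours (the study reads steady-state
#'   statistics at 50 h).
#' @return Tibble with columns `time`, `species`, `mean`, `sd`.
#' @export
steady_state_stats <- function(ensemble, t_eval) {
  stopifnot(inherits(ensemble, "eco_ensemble"))
  times <- unique(ensemble$summary$time)
  if (t_eval < min(times) || t_eval > max(times))
    stop("t_eval outside the recorded time range", call. = FALSE)
  t0 <- times[which.min(abs(times - t_eval))]
  dplyr::filter(ensemble$summary, .data$time == t0)
}

#' Fraction of replicates with both populations alive
#'
#' @inheritParams steady_state_stats
#' @param t_eval Evaluation time, hours; defaults to the end of the run.
#' @return Fraction in `[0, 1]`.
#' @export
survival_fraction <- function(ensemble, t_eval = NULL) {
  stopifnot(inherits(ensemble, "eco_ensemble"))
  s <- ensemble$survival
  if (is.null(t_eval)) t_eval <- max(s$time)
  if (t_eval < min(s$time) || t_eval > max(s$time))
    stop("t_eval outside the recorded time range", call. = FALSE)
  s$n_alive[which.min(abs(s$time - t_eval))] / ensemble$n
}

#' @export
tidy.eco_ensemble <- function(x, ...) x$summary

#' @export
glance.eco_ensemble <- function(x, ...) {
  ss <- steady_state_stats(x, max(x$summary$time))
  tibble::tibble(
    n = x$n, n_extinct = x$n_extinct,
    survival = survival_fraction(x),
    t_end = max(x$summary$time),
    c1_mean = ss$mean[ss$species == "c1"],
    c1_sd = ss$sd[ss$species == "c1"],
    c2_mean = ss$mean[ss$species == "c2"],
    c2_sd = ss$sd[ss$species == "c2"],
    base_seed = x$base_seed)
}

#' Write ensemble summary and metadata sidecar
#'
#' Writes the per-time summary to `<path>` (CSV, columns time, species,
#' mean, sd, n, n_extinct) and a JSON sidecar `<path>.json` recording the
#' full parameter set, seeds, step size and SD estimator, sufficient to
#' re-run the ensemble identically.
#'
#' @param ensemble An [eco_ensemble()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  out <- ensemble$summary
  out$n <- ensemble$n
  out$n_extinct <- ensemble$n_extinct
  utils::write.csv(format(as.data.frame(out), digits = 17,
                          trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  side <- c(ensemble$config["sd_estimator"],
            list(n = ensemble$n, base_seed = ensemble$base_seed,
                 seeds = ensemble$terminal$seed,
                 t_end = ensemble$config$t_end, dt = ensemble$config$dt,
                 record_every = ensemble$config$record_every,
                 mode = ensemble$config$mode,
                 extinction_threshold = ensemble$config$extinction_threshold,
                 initial = as.list(ensemble$config$initial),
                 params = ensemble$params[setdiff(names(ensemble$params),
                                                  "alpha_unit")],
                 alpha_unit = ensemble$params$alpha_unit))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
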