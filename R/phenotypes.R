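#' Ecological regime classification and survival-threshold searches
#'
#' These functions map parameter regions to the ecological regimes the
#' ecosystem exhibits along the antibiotic (Gc) axis and locate survival
#' boundaries: the monoculture Gc limits, the co-culture lethal Gc, the
#' minimum carrying capacity, and the minimum inocula.
#'
#' @name phenotypes
NULL

# Deterministic survival: alive at the horizon and not still strictly
# declining there. A population decaying slower than ln(n0)/horizon would
# still sit above the absorption threshold at the horizon, so absorption
# alone cannot resolve a growth/death boundary on a finite run; the trend
# check (x(T) >= 0.995 * x(0.95 T)) classifies such doomed populations as
# extinct and recovers the analytic monoculture boundaries k1/k3 and k2/k3.
.det_survives <- function(initial, params, horizon, dt = 0.005,
                          criterion = c("trend", "absorption")) {
  criterion <- match.arg(criterion)
  x0 <- as_eco_state(initial)
  tr <- eco_simulate(x0, params, t_end = horizon, dt = dt,
                     record_every = max(1L, floor(0.05 * horizon / dt)),
                     mode = "deterministic")
  last <- nrow(tr)
  i95 <- which.min(abs(tr$time - 0.95 * horizon))
  for (pop in c("c1", "c2")) {
    if (x0[[pop]] <= 0) next
    xT <- tr[[pop]][last]
    if (xT <= 0) return(FALSE)
    if (criterion == "trend" && xT < 0.995 * tr[[pop]][i95]) return(FALSE)
  }
  TRUE
}

# Stochastic survival: every replicate keeps all initially-present
# populations above the absorption threshold at the horizon. Shared seeds
# (common random numbers) make threshold searches monotone.
.stoch_all_survive <- function(initial, params, horizon, n_replicates,
                               base_seed, dt = 0.005) {
  x0 <- as_eco_state(initial)
  pops <- c("c1", "c2")[x0[1:2] > 0]
  for (i in seq_len(n_replicates)) {
    tr <- eco_simulate(x0, params, t_end = horizon, dt = dt,
                       record_every = 10000L, mode = "stochastic",
                       seed = base_seed + i - 1L)
    if (any(tr[nrow(tr), pops] <= 0)) return(FALSE)
  }
  TRUE
}

#' Classify the ecological regime at a Gc concentration
#'
#' Runs the two monocultures (5e4 cells each) and the co-culture
#' (5e4 + 5e4) at the given Gc and derives the regime from the three
#' survival outcomes: both monocultures survive, `facultative_mutualism`;
#' only bacteria alone survive (with a viable co-culture),
#' `commensalism_bacteria`; neither alone but the co-culture survives,
#' `obligatory_mutualism`; a failed co-culture, `extinction`.
#'
#' @param params An [eco_params()] object.
#' @param Gc Growth-control concentration, M.
#' @param mode `"deterministic"` (default; boundaries are
#'   drift-dominated) or `"stochastic"`.
#' @param survival_horizon Hours allowed for transients to decay
#'   (default 200).
#' @param n_replicates Replicates per condition in stochastic mode.
#' @param base_seed Seed for stochastic mode.
#' @return A one-row tibble: `Gc`, `regime`, and the three survival
#'   booleans `yeast_alone`, `bacteria_alone`, `coculture`.
#' @examples
#' classify_regime(eco_params(), Gc = 3e-8)$regime
#' @export
classify_regime <- function(params = eco_params(), Gc,
                            mode = c("deterministic", "stochastic"),
                            survival_horizon = 200, n_replicates = 25,
                            base_seed = 1L) {
  mode <- match.arg(mode)
  p <- eco_update(params, Gc = Gc)
  surv <- function(init) {
    if (mode == "deterministic")
      .det_survives(init, p, survival_horizon)
    else
      .stoch_all_survive(init, p, survival_horizon, n_replicates, base_seed)
  }
  yeast <- surv(eco_state(c1 = 5e4, c2 = 0))
  bact <- surv(eco_state(c1 = 0, c2 = 5e4))
  co <- surv(eco_state(c1 = 5e4, c2 = 5e4))
  regime <- if (!co) "extinction"
  else if (yeast && bact) "facultative_mutualism"
  else if (bact) "commensalism_bacteria"
  else if (!yeast) "obligatory_mutualism"
  else "commensalism_yeast"  # unreachable while k1 < k2
  tibble::tibble(Gc = Gc,
                 regime = factor(regime,
                                 levels = c("facultative_mutualism",
                                            "commensalism_bacteria",
                                            "obligatory_mutualism",
                                            "extinction",
                                            "commensalism_yeast")),
                 yeast_alone = yeast, bacteria_alone = bact,
                 coculture = co)
}

.bisect_gc <- function(survives, bracket, tol) {
  lo <- bracket[1]; hi <- bracket[2]
  if (!survives(lo) || survives(hi))
    stop("bracket does not straddle the survival boundary", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (survives(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Monoculture Gc survival boundary
#'
#' Bisection over Gc on deterministic monoculture survival (5e4 cells,
#' resistance initially zero). With zero resistance the boundary has the
#' closed form `k1/k3` (yeast) or `k2/k3` (bacteria), used in the test
#' suite as an independent oracle.
#'
#' @inheritParams classify_regime
#' @param species `"yeast"` or `"bacteria"`.
#' @param bracket Gc bracket, M; must straddle the boundary.
#' @param tol Bisection tolerance, M (default 1e-9, i.e. 1 nM).
#' @param criterion Survival criterion; `"trend"` (default) additionally
#'   treats a population still declining at the horizon as doomed, see
#'   Details in the package vignette.
#' @return The boundary Gc, M.
#' @export
monoculture_gc_threshold <- function(params = eco_params(),
                                     species = c("yeast", "bacteria"),
                                     bracket, tol = 1e-9,
                                     survival_horizon = 200,
                                     criterion = c("trend", "absorption")) {
  species <- match.arg(species)
  criterion <- match.arg(criterion)
  init <- if (species == "yeast") eco_state(c1 = 5e4, c2 = 0)
          else eco_state(c1 = 0, c2 = 5e4)
  .bisect_gc(function(gc)
    .det_survives(init, eco_update(params, Gc = gc), survival_horizon,
                  criterion = criterion),
    bracket, tol)
}

#' Lethal Gc concentration for the co-culture
#'
#' Boundary above which a fresh co-culture (5e4 + 5e4 cells, no
#' pre-formed molecular species) cannot establish, located by bisection
#' over Gc. In `"deterministic"` mode survival is the drift-only
#' criterion: the boundary is the point where the resistance-induction
#' race against the initial killing is lost. In `"stochastic"` mode the
#' lethal concentration is the ensemble-extinction boundary: the smallest
#' Gc at which no replicate survives to the horizon (common random
#' numbers across candidates). The stochastic boundary lies well above
#' the deterministic one because clamped Langevin fluctuations in the
#' resistance channels rectify upward and can rescue trajectories whose
#' drift alone is doomed; the published lethal concentration is an
#' ensemble statement of this kind.
#'
#' `start = "steady_state"` instead begins from the established
#' coexistence state at the baseline Gc, which withstands far higher
#' concentrations than a fresh inoculum.
#'
#' @inheritParams monoculture_gc_threshold
#' @param bracket Gc bracket, M (default 1 to 100 uM).
#' @param tol Bisection tolerance, M (default 5e-8).
#' @param survival_horizon Hours (default 500).
#' @param mode `"deterministic"` (drift-only survival) or `"stochastic"`
#'   (ensemble-extinction boundary).
#' @param n_replicates Replicates per candidate in stochastic mode.
#' @param base_seed Seed for stochastic mode (shared across candidates).
#' @param start Initial condition, see above.
#' @return The lethal boundary Gc, M.
#' @export
coculture_lethal_gc <- function(params = eco_params(),
                                bracket = c(1e-6, 1e-4), tol = 5e-8,
                                survival_horizon = 500,
                                mode = c("deterministic", "stochastic"),
                                n_replicates = 20, base_seed = 1L,
                                start = c("inoculum", "steady_state"),
                                criterion = c("trend", "absorption")) {
  mode <- match.arg(mode)
  start <- match.arg(start)
  criterion <- match.arg(criterion)
  init <- eco_state(c1 = 5e4, c2 = 5e4)
  if (start == "steady_state") {
    est <- eco_simulate(init, params, t_end = 200, dt = 0.005,
                        record_every = 40000L, mode = "deterministic")
    init <- as_eco_state(unlist(est[nrow(est), eco_species()]))
  }
  alive <- if (mode == "deterministic") {
    function(gc) .det_survives(init, eco_update(params, Gc = gc),
                               survival_horizon, criterion = criterion)
  } else {
    # ecosystem not yet fully extinct: any replicate with both
    # populations alive at the horizon
    function(gc) {
      p <- eco_update(params, Gc = gc)
      for (i in seq_len(n_replicates)) {
        tr <- eco_simulate(init, p, t_end = survival_horizon, dt = 0.005,
                           record_every = 100000L, mode = "stochastic",
                           seed = base_seed + i - 1L)
        if (tr$c1[nrow(tr)] > 0 && tr$c2[nrow(tr)] > 0) return(TRUE)
      }
      FALSE
    }
  }
  .bisect_gc(alive, bracket, tol)
}

#' Minimum carrying capacity for full ensemble survival
#'
#' Smallest `cmax` at which every stochastic replicate keeps both
#' populations alive at the horizon: an ascending walk over a declared
#' log-spaced grid followed by a log-space bisection refinement between
#' the last failing and first passing grid points, under common random
#' numbers.
#'
#' @inheritParams classify_regime
#' @param n_replicates Replicates per candidate (default 25).
#' @param horizon Hours (default 3000).
#' @param grid Candidate `cmax` grid, cells. The log-spaced default
#'   starts at 1e3 cells, above the degenerate frozen regime of
#'   capacities far below the inoculum (there the logistic clamp stops
#'   all growth while rectified resistance noise suppresses all killing,
#'   so populations freeze and 'survive' trivially).
#' @param refine_rel Relative width at which refinement stops
#'   (default 0.1).
#' @return A list: `cmax` (the refined minimum), `grid_cmax` (first
#'   passing grid point), `n_replicates`, `base_seed`.
#' @export
min_carrying_capacity <- function(params = eco_params(), n_replicates = 25,
                                  horizon = 3000, base_seed = 1L,
                                  grid = 10^seq(3, 8, by = 0.25),
                                  refine_rel = 0.2) {
  grid <- sort(grid)
  ok <- function(cm)
    .stoch_all_survive(eco_state(), eco_update(params, cmax = cm),
                       horizon, n_replicates, base_seed)
  pass <- NA_real_
  fail <- NA_real_
  for (cm in grid) {
    if (ok(cm)) { pass <- cm; break }
    fail <- cm
  }
  if (is.na(pass))
    stop("no carrying capacity on the grid allows full survival",
         call. = FALSE)
  if (is.na(fail))
    return(list(cmax = pass, grid_cmax = pass,
                n_replicates = n_replicates, base_seed = base_seed))
  lo <- fail; hi <- pass
  while (hi / lo > 1 + refine_rel) {
    mid <- sqrt(lo * hi)
    if (ok(mid)) hi <- mid else lo <- mid
  }
  list(cmax = hi, grid_cmax = pass, n_replicates = n_replicates,
       base_seed = base_seed)
}

#' Minimum initial population for ensemble survival
#'
#' Integer bisection (valid because survival is monotone in the inoculum
#' under shared seeds) for the smallest inoculum at which every stochastic
#' replicate keeps both populations alive at the horizon. `search =
#' "both"` varies an equal inoculum of the two species jointly; `"yeast"`
#' or `"bacteria"` varies one species with the other fixed at
#' `fixed_count`.
#'
#' @inheritParams min_carrying_capacity
#' @param search Which inoculum to vary.
#' @param fixed_count Cells of the non-searched species (default 5e4).
#' @param horizon Hours (default 1000).
#' @param range Integer search range (default 1 to 1000).
#' @return A list: `minimum` (cells), `search`, `n_replicates`,
#'   `base_seed`.
#' @export
min_initial_population <- function(params = eco_params(),
                                   search = c("both", "yeast", "bacteria"),
                                   fixed_count = 5e4, n_replicates = 25,
                                   horizon = 1000, range = c(1, 1000),
                                   base_seed = 1L) {
  search <- match.arg(search)
  init <- function(m) switch(search,
    both = eco_state(c1 = m, c2 = m),
    yeast = eco_state(c1 = m, c2 = fixed_count),
    bacteria = eco_state(c1 = fixed_count, c2 = m))
  ok <- function(m)
    .stoch_all_survive(init(m), params, horizon, n_replicates, base_seed)
  lo <- as.integer(range[1]); hi <- as.integer(range[2])
  if (!ok(hi))
    stop("no inoculum in the search range allows full survival",
         call. = FALSE)
  if (ok(lo))
    return(list(minimum = lo, search = search,
                n_replicates = n_replicates, base_seed = base_seed))
  while (hi - lo > 1L) {
    mid <- as.integer(floor((lo + hi) / 2))
    if (ok(mid)) hi <- mid else lo <- mid
  }
  list(minimum = hi, search = search, n_replicates = n_replicates,
       base_seed = base_seed)
}

#' Sweep the resistance attenuation coefficient
#'
#' Runs a replicate ensemble at each value of `alpha` and labels the
#' outcome: `"extinction"` when no replicate survives, `"slow"` when the
#' ensemble means have not reached steady state by the horizon, `"fast"`
#' otherwise. `unit = "per_nM"` interprets the values as nM^-1 (converted
#' per species through its compartment volume); `"molecules"` applies them
#' per molecule.
#'
#' @inheritParams eco_ensemble
#' @param alpha_values Positive sweep values.
#' @param unit Unit of the sweep values.
#' @param t_end Horizon, hours (default 10000: the ecosystem is called
#'   slow when steady state is not reached within this time).
#' @return Tibble with one row per `alpha`: `alpha`, `unit`, `label`,
#'   `steady_state_time`, `survival`, terminal population means; the
#'   ensembles are attached as the `"ensembles"` attribute.
#' @export
alpha_sweep <- function(params = eco_params(), alpha_values,
                        unit = c("molecules", "per_nM"), n = 100,
                        t_end = 10000, dt = 0.005, record_every = 200L,
                        base_seed = 1L) {
  unit <- match.arg(unit)
  stopifnot(all(alpha_values > 0))
  rows <- list(); enss <- list()
  for (i in seq_along(alpha_values)) {
    p <- eco_update(params, alpha = alpha_values[i])
    p$alpha_unit <- unit
    ens <- eco_ensemble(eco_state(), p, n = n, t_end = t_end, dt = dt,
                        record_every = record_every, base_seed = base_seed)
    surv <- survival_fraction(ens)
    tss <- steady_state_time(ens)
    g <- glance(ens)
    label <- if (surv == 0) "extinction" else if (is.na(tss)) "slow"
             else "fast"
    rows[[i]] <- tibble::tibble(
      alpha = alpha_values[i], unit = unit, label = label,
      steady_state_time = tss, survival = surv,
      c1_mean = g$c1_mean, c2_mean = g$c2_mean)
    enss[[i]] <- ens
  }
  structure(dplyr::bind_rows(rows), ensembles = enss)
}
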