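#' Parse a concentration with an optional unit suffix
#'
#' Accepts a bare number (taken as molar) or a string with an `nM`, `uM`
#' (or `µM`), `mM` or `M` suffix.
#'
#' @param x Number or string.
#' @return Concentration in M.
#' @examples
#' parse_conc("250 nM")
#' @export
parse_conc <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  s <- trimws(as.character(x))
  m <- regmatches(s, regexec(
    "^([0-9.eE+-]+)\\s*(nM|uM|µM|μM|mM|M)$", s))[[1]]
  if (length(m) != 3)
    stop("cannot parse concentration: '", x, "'", call. = FALSE)
  val <- as.numeric(m[2])
  mult <- c(nM = 1e-9, uM = 1e-6, mM = 1e-3, M = 1)
  unit <- m[3]
  if (unit %in% c("µM", "μM")) unit <- "uM"
  val * mult[[unit]]
}

#' Write a parameter set to a flat YAML file
#'
#' @param params An [eco_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "eco_params"))
  yaml::write_yaml(unclass(params), path, precision = 17)
  invisible(path)
}

#' Read a parameter set from a flat YAML file
#'
#' Keys are the [eco_params()] field names; missing keys take the default
#' values, so an empty file yields the published defaults exactly.
#' Concentration-valued fields (`Gc`, `AHLR1_conc`, `AHLR2_conc`, `k7b`,
#' `k10b`) accept unit-suffixed strings such as `"250 nM"`. Overriding
#' `alpha` requires an explicit `alpha_unit` key (`molecules` or
#' `per_nM`).
#'
#' @param path YAML file path.
#' @return An [eco_params()] object.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  .params_from_list(raw)
}

.params_from_list <- function(raw) {
  conc_fields <- c("Gc", "AHLR1_conc", "AHLR2_conc", "k7b", "k10b")
  known <- c(names(.eco_defaults()), "alpha_unit")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if ("alpha" %in% names(raw) && !"alpha_unit" %in% names(raw))
    stop("overriding 'alpha' requires an explicit 'alpha_unit' ",
         "('molecules' or 'per_nM')", call. = FALSE)
  unit <- raw$alpha_unit %||% "molecules"
  raw$alpha_unit <- NULL
  for (f in intersect(names(raw), conc_fields))
    raw[[f]] <- parse_conc(raw[[f]])
  do.call(eco_params, c(raw, list(alpha_unit = unit)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.experiments <- c("baseline", "gc_sweep", "alpha_sweep", "cmax_sweep",
                  "inoculum_search", "bifurcation", "noise_scan")

#' Load an experiment configuration
#'
#' A YAML file with a top-level `experiment` name (one of `baseline`,
#' `gc_sweep`, `alpha_sweep`, `cmax_sweep`, `inoculum_search`,
#' `bifurcation`, `noise_scan`), an optional `params` block of parameter
#' overrides (see [read_params()]), and experiment settings (`grid`,
#' `n_replicates`, `base_seed`, `t_end`, `search`, ...).
#'
#' @param path YAML file path.
#' @return A list with elements `experiment`, `params` and `options`,
#'   ready for [run_experiment()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$experiment))
    stop("config must name an 'experiment'", call. = FALSE)
  if (!raw$experiment %in% .experiments)
    stop("unknown experiment '", raw$experiment, "'; must be one of: ",
         paste(.experiments, collapse = ", "), call. = FALSE)
  params <- .params_from_list(raw$params %||% list())
  opts <- raw[setdiff(names(raw), c("experiment", "params"))]
  if ("grid" %in% names(opts)) {
    opts$grid <- vapply(opts$grid, function(v)
      if (is.character(v)) parse_conc(v) else as.numeric(v), numeric(1))
  }
  list(experiment = raw$experiment, params = params, options = opts)
}

#' Run a named experiment and write its outputs
#'
#' Dispatches to the corresponding analysis, writes result tables (CSV,
#' full double precision, deterministic row order) into `out_dir`, plus a
#' JSON sidecar with the fully resolved parameters, seeds and step size,
#' sufficient to re-run identically.
#'
#' @param config A configuration list from [load_config()], or a path to
#'   a YAML config file.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(is.list(config), config$experiment %in% .experiments)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  p <- config$params
  o <- config$options %||% list()
  n <- o$n_replicates %||% 100
  seed <- o$base_seed %||% 1L
  files <- character(0)
  write_tbl <- function(tb, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(format(as.data.frame(tb), digits = 17,
                            trim = TRUE, scientific = NA),
                     f, row.names = FALSE, quote = FALSE)
    files[[name]] <<- f
    f
  }
  message("running experiment '", config$experiment, "'")
  result_meta <- list()
  switch(config$experiment,
    baseline = {
      ens <- eco_ensemble(eco_state(), p, n = n,
                          t_end = o$t_end %||% 50, base_seed = seed)
      write_ensemble(ens, file.path(out_dir, "baseline_summary.csv"))
      files[["baseline_summary.csv"]] <-
        file.path(out_dir, "baseline_summary.csv")
      result_meta$steady_state_time <- tryCatch(
        steady_state_time(ens), error = function(e) NA_real_)
    },
    gc_sweep = {
      grid <- o$grid %||% c(6e-8, 2.5e-7, 1e-5)
      rows <- lapply(grid, function(gc) {
        ens <- eco_ensemble(eco_state(), eco_update(p, Gc = gc), n = n,
                            t_end = o$t_end %||% 50, base_seed = seed)
        g <- glance(ens)
        reg <- classify_regime(p, Gc = gc)
        tibble::tibble(Gc = gc, regime = as.character(reg$regime),
                       survival = g$survival,
                       c1_mean = g$c1_mean, c1_sd = g$c1_sd,
                       c2_mean = g$c2_mean, c2_sd = g$c2_sd)
      })
      write_tbl(dplyr::bind_rows(rows), "gc_sweep.csv")
    },
    alpha_sweep = {
      sw <- alpha_sweep(p, alpha_values = o$grid %||% c(25, 75, 5e4),
                        unit = o$unit %||% "per_nM", n = n,
                        t_end = o$t_end %||% 10000, base_seed = seed)
      write_tbl(sw, "alpha_sweep.csv")
    },
    cmax_sweep = {
      grid <- o$grid %||% 10^(6:9)
      rows <- lapply(grid, function(cm) {
        ens <- eco_ensemble(eco_state(), eco_update(p, cmax = cm), n = n,
                            t_end = o$t_end %||% 50, base_seed = seed)
        g <- glance(ens)
        tibble::tibble(cmax = cm, survival = g$survival,
                       c1_mean = g$c1_mean, c1_sd = g$c1_sd,
                       c2_mean = g$c2_mean, c2_sd = g$c2_sd)
      })
      write_tbl(dplyr::bind_rows(rows), "cmax_sweep.csv")
    },
    inoculum_search = {
      res <- min_initial_population(
        p, search = o$search %||% "both",
        fixed_count = o$fixed_count %||% 5e4,
        n_replicates = n, horizon = o$horizon %||% 1000,
        range = o$range %||% c(1, 1000), base_seed = seed)
      write_tbl(tibble::as_tibble(res[c("minimum", "search",
                                        "n_replicates")]),
                "inoculum_search.csv")
    },
    bifurcation = {
      grid <- o$grid %||% seq(0.1, 1, by = 0.01)
      bf <- scan_bifurcation(p, d_grid = grid,
                             t_transient = o$t_transient %||% 2000)
      write_tbl(tidy(bf), "bifurcation.csv")
      result_meta$hopf_d <- bf$hopf_d
      result_meta$extinction_d <- bf$extinction_d
    },
    noise_scan = {
      ns <- noise_extinction_scan(
        p, d = o$d %||% 0.5,
        epsilon_grid = o$grid %||% seq(0.0025, 0.03, by = 0.0025),
        n_replicates = if (is.null(o$n_replicates)) 20 else n,
        horizon = o$horizon %||% 1000, base_seed = seed)
      write_tbl(ns$scan, "noise_scan.csv")
      result_meta$epsilon_star <- ns$epsilon_star
      result_meta$deterministic_period <- ns$deterministic_period
    })
  sidecar <- list(
    experiment = config$experiment,
    package_version = as.character(utils::packageVersion("ecosim")),
    params = unclass(p)[setdiff(names(p), "alpha_unit")],
    alpha_unit = p$alpha_unit,
    options = o, n_replicates = n, base_seed = seed, dt = 0.005,
    results = result_meta)
  jsonlite::write_json(sidecar, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files[["metadata.json"]] <- file.path(out_dir, "metadata.json")
  invisible(files)
}
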