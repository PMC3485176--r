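#' Kinetic parameters of the bacteria-yeast ecosystem
#'
#' Builds the full parameter set of the mutual-rescue reaction network. The
#' defaults are the published kinetic constants of the network: logistic
#' growth of the two populations, antibiotic (growth-control molecule, Gc)
#' killing attenuated by each species' resistance protein, constitutive
#' production of the two quorum-sensing signals (AHL1 from yeast, AHL2 from
#' bacteria), fourth-order signal-receptor binding, Hill-type induction of
#' the resistance genes, and first-order degradation of all molecular
#' species. Populations and molecular species are reactor-total counts;
#' rate laws printed in concentration units are converted through the
#' compartment factors `V1*Na` (yeast side) and `V2*Na` (bacterial side).
#'
#' @param ... Named overrides of the default values listed below.
#' @param alpha_unit Unit of `alpha`, the resistance attenuation
#'   coefficient. `"molecules"` (default) applies `alpha` per molecule of
#'   resistance protein; `"per_nM"` interprets `alpha` as nM^-1 and converts
#'   per species through its compartment volume.
#'
#' @details Fields (with defaults):
#' \describe{
#'   \item{k1, k2}{Max growth rates of yeast (0.234 h^-1) and bacteria
#'     (0.936 h^-1).}
#'   \item{cmax}{Bioreactor carrying capacity, cells (1e9).}
#'   \item{k3, Gc}{Killing constant (4e6 M^-1 h^-1) and growth-control
#'     concentration (3e-7 M, held constant).}
#'   \item{alpha}{Resistance attenuation coefficient (5e4, see
#'     `alpha_unit`).}
#'   \item{k4, k5}{Per-cell AHL1/AHL2 production rates (5e-6 h^-1).}
#'   \item{k6, k9}{Fourth-order binding constants (3e19 M^-3 h^-1).}
#'   \item{AHLR1_conc, AHLR2_conc}{Fixed receptor concentrations (5e-7 M).}
#'   \item{k7, k10}{Maximal Hill production rates (6e-5 M h^-1).}
#'   \item{k7b, k10b}{Hill half-saturation constants (1e-8 M).}
#'   \item{n1, n2}{Hill coefficients (1).}
#'   \item{k8}{preRes1 -> Res1 maturation rate (5 h^-1), the eukaryotic
#'     gene-expression delay.}
#'   \item{k11, k12}{AHL degradation rates (1.19 h^-1).}
#'   \item{k13, k14}{Complex degradation rates (1.386 h^-1).}
#'   \item{k15, k16}{Resistance-protein degradation rates (4 h^-1).}
#'   \item{V1, V2}{Cell volumes: yeast 3.7e-14 L, E. coli 1e-15 L.}
#'   \item{Na}{Avogadro constant (6.023e23 mol^-1).}
#'   \item{d}{E. coli lysis/degradation rate (0 h^-1).}
#'   \item{noise_scale}{Multiplier on all Langevin noise terms (1).}
#' }
#'
#' @return An object of class `eco_params` (a validated named list).
#' @examples
#' p <- eco_params(Gc = 6e-8)
#' p$Gc
#' @export
eco_params <- function(..., alpha_unit = c("molecules", "per_nM")) {
  alpha_unit <- match.arg(alpha_unit)
  p <- .eco_defaults()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(dots)] <- lapply(dots, as.numeric)
  }
  p$alpha_unit <- alpha_unit
  class(p) <- "eco_params"
  validate_params(p)
  p
}

.eco_defaults <- function() {
  list(
    k1 = 0.234, k2 = 0.936, cmax = 1e9,
    k3 = 4e6, Gc = 3e-7, alpha = 5e4,
    k4 = 5e-6, k5 = 5e-6,
    k6 = 3e19, k9 = 3e19,
    AHLR1_conc = 5e-7, AHLR2_conc = 5e-7,
    k7 = 6e-5, k10 = 6e-5, k7b = 1e-8, k10b = 1e-8,
    n1 = 1, n2 = 1, k8 = 5,
    k11 = 1.19, k12 = 1.19, k13 = 1.386, k14 = 1.386,
    k15 = 4, k16 = 4,
    V1 = 3.7e-14, V2 = 1e-15, Na = 6.023e23,
    d = 0, noise_scale = 1
  )
}

validate_params <- function(p) {
  num <- setdiff(names(.eco_defaults()), character())
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("parameter '", f, "' must be a single finite number",
           call. = FALSE)
    if (v < 0) stop("parameter '", f, "' must be >= 0", call. = FALSE)
  }
  if (p$cmax <= 0) stop("cmax must be > 0", call. = FALSE)
  if (p$n1 < 1 || p$n2 < 1)
    stop("Hill coefficients n1, n2 must be >= 1", call. = FALSE)
  if (p$noise_scale > 1)
    stop("noise_scale must lie in [0, 1]", call. = FALSE)
  if (!p$alpha_unit %in% c("molecules", "per_nM"))
    stop("alpha_unit must be 'molecules' or 'per_nM'", call. = FALSE)
  invisible(p)
}

#' Derived effective constants
#'
#' Recomputes (never caches) the effective constants implied by a parameter
#' set: the compartment factors `om1 = V1*Na`, `om2 = V2*Na`, the folded
#' binding constants `k6_eff = k6*AHLR2_conc^2`, `k9_eff = k9*AHLR1_conc^2`,
#' the killing rate `k3_eff = k3*Gc`, and the per-molecule resistance
#' attenuation coefficients `alpha1`, `alpha2` for the two species (these
#' differ from `alpha` only when `alpha_unit = "per_nM"`, in which case the
#' nM^-1 value is converted through each species' compartment volume).
#'
#' @param params An [eco_params()] object.
#' @return A named list of derived constants.
#' @export
eco_derived <- function(params) {
  stopifnot(inherits(params, "eco_params"))
  om1 <- params$V1 * params$Na
  om2 <- params$V2 * params$Na
  if (params$alpha_unit == "per_nM") {
    alpha1 <- params$alpha / (1e-9 * om1)
    alpha2 <- params$alpha / (1e-9 * om2)
  } else {
    alpha1 <- alpha2 <- params$alpha
  }
  list(
    om1 = om1, om2 = om2,
    k3_eff = params$k3 * params$Gc,
    k6_eff = params$k6 * params$AHLR2_conc^2,
    k9_eff = params$k9 * params$AHLR1_conc^2,
    alpha1 = alpha1, alpha2 = alpha2
  )
}

# Flat parameter vector handed to the C++ integrator; order must match
# the enum in src/sim_core.cpp.
cpp_param_vector <- function(params) {
  d <- eco_derived(params)
  c(params$k1, params$k2, params$cmax, d$k3_eff, d$alpha1, d$alpha2,
    params$k4, params$k5, d$k6_eff, d$k9_eff, d$om1, d$om2,
    params$k7, params$k7b, params$n1, params$k8,
    params$k10, params$k10b, params$n2,
    params$k11, params$k12, params$k13, params$k14, params$k15, params$k16,
    params$d, params$noise_scale)
}

#' @export
print.eco_params <- function(x, ...) {
  cat("<eco_params> synthetic bacteria-yeast ecosystem parameters\n")
  flat <- unlist(x[names(x) != "alpha_unit"])
  cat(sprintf("  %-12s %s\n", names(flat), format(flat, digits = 6)),
      sep = "")
  cat(sprintf("  %-12s %s\n", "alpha_unit", x$alpha_unit))
  invisible(x)
}

#' Update a parameter set
#'
#' @param params An [eco_params()] object.
#' @param ... Named parameter overrides.
#' @return A new validated `eco_params` object.
#' @export
eco_update <- function(params, ...) {
  stopifnot(inherits(params, "eco_params"))
  dots <- list(...)
  if (!length(dots)) return(params)
  unknown <- setdiff(names(dots), setdiff(names(params), "alpha_unit"))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params[names(dots)] <- lapply(dots, as.numeric)
  validate_params(params)
  params
}
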