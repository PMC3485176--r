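#' @useDynLib ecosim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Names of the nine dynamic species
#'
#' `c1` (S. cerevisiae cells), `c2` (E. coli cells), the two diffusible
#' signals `AHL1`/`AHL2`, the signal-receptor complexes `C1` (AHL1:AHLR1,
#' in bacteria) and `C2` (AHL2:AHLR2, in yeast), the yeast expression
#' intermediate `preRes1`, and the two resistance proteins `Res1` (yeast)
#' and `Res2` (bacteria).
#'
#' @return Character vector of length 9.
#' @export
eco_species <- function() {
  c("c1", "c2", "AHL1", "AHL2", "C1", "C2", "preRes1", "Res1", "Res2")
}

#' Ecosystem state vector
#'
#' @param c1,c2 Initial yeast and bacterial populations, cells.
#' @param AHL1,AHL2,C1,C2,preRes1,Res1,Res2 Initial molecular counts
#'   (default 0; only initial cell counts are part of the study design).
#' @return Named numeric vector of length 9.
#' @examples
#' eco_state()             # the standard 5e4 + 5e4 inoculum
#' eco_state(c1 = 0, c2 = 5e4)  # bacterial monoculture
#' @export
eco_state <- function(c1 = 5e4, c2 = 5e4, AHL1 = 0, AHL2 = 0, C1 = 0,
                      C2 = 0, preRes1 = 0, Res1 = 0, Res2 = 0) {
  x <- c(c1 = c1, c2 = c2, AHL1 = AHL1, AHL2 = AHL2, C1 = C1, C2 = C2,
         preRes1 = preRes1, Res1 = Res1, Res2 = Res2)
  if (any(!is.finite(x)) || any(x < 0))
    stop("all state components must be finite and >= 0", call. = FALSE)
  x
}

as_eco_state <- function(x) {
  if (is.numeric(x) && length(x) == 9) {
    if (any(!is.finite(x)) || any(x < 0))
      stop("all state components must be finite and >= 0", call. = FALSE)
    stats::setNames(as.numeric(x), eco_species())
  } else {
    stop("state must be a numeric vector of length 9 (see eco_state())",
         call. = FALSE)
  }
}

#' Stoichiometry matrix of the reaction network
#'
#' The 9 species x 18 reactions matrix of net molecular changes. The two
#' binding reactions consume two signal molecules per complex formed (the
#' receptor is a fixed pool, not a state variable); the Hill induction
#' reactions are catalytic in the inducing complex; reaction 9 is the
#' maturation preRes1 -> Res1; reaction 18 is first-order bacterial lysis.
#'
#' @return Integer matrix with species rows and reaction columns `r1..r18`.
#' @export
eco_stoichiometry <- function() {
  S <- matrix(0L, nrow = 9, ncol = 18,
              dimnames = list(eco_species(), paste0("r", 1:18)))
  S["c1", 1] <- 1L;  S["c2", 2] <- 1L
  S["c1", 3] <- -1L; S["c2", 4] <- -1L
  S["AHL1", 5] <- 1L; S["AHL2", 6] <- 1L
  S["AHL2", 7] <- -2L; S["C2", 7] <- 1L
  S["preRes1", 8] <- 1L
  S["preRes1", 9] <- -1L; S["Res1", 9] <- 1L
  S["AHL1", 10] <- -2L; S["C1", 10] <- 1L
  S["Res2", 11] <- 1L
  S["AHL1", 12] <- -1L; S["AHL2", 13] <- -1L
  S["C1", 14] <- -1L; S["C2", 15] <- -1L
  S["Res1", 16] <- -1L; S["Res2", 17] <- -1L
  S["c2", 18] <- -1L
  S
}

#' Reaction propensities
#'
#' Evaluates the 18 reaction rates (events per hour, in count units) at a
#' state: logistic growth of both populations (clamped to zero at or above
#' the carrying capacity), resistance-attenuated antibiotic killing,
#' constitutive signal production, fourth-order signal-receptor binding,
#' Hill-type induction of the resistance genes, the yeast maturation step,
#' first-order degradations, and bacterial lysis `d*c2`.
#'
#' @param state Named state vector, see [eco_state()].
#' @param params An [eco_params()] object.
#' @return Named nonnegative numeric vector `r1..r18`.
#' @examples
#' a <- eco_propensities(eco_state(c1 = 1, c2 = 0), eco_params())
#' a[["r3"]]  # k3 * Gc * c1 at zero resistance = 1.2 per hour
#' @export
eco_propensities <- function(state, params) {
  x <- as_eco_state(state)
  stopifnot(inherits(params, "eco_params"))
  a <- .cpp_propensities(unname(x), cpp_param_vector(params))
  stats::setNames(a, paste0("r", 1:18))
}

#' Deterministic drift of the chemical Langevin equations
#'
#' The product of the stoichiometry matrix with the propensity vector:
#' the per-species deterministic time derivatives, in cells or molecules
#' per hour.
#'
#' @inheritParams eco_propensities
#' @return Named numeric vector of length 9.
#' @export
eco_drift <- function(state, params) {
  x <- as_eco_state(state)
  stopifnot(inherits(params, "eco_params"))
  f <- .cpp_drift(unname(x), cpp_param_vector(params))
  stats::setNames(f, eco_species())
}

#' Langevin noise-coefficient matrix
#'
#' Entry (i, j) is `noise_scale * S[i, j] * sqrt(a_j)`: the coefficient of
#' reaction j's independent Wiener increment in species i's stochastic
#' differential equation.
#'
#' @inheritParams eco_propensities
#' @return 9 x 18 numeric matrix.
#' @export
eco_noise_matrix <- function(state, params) {
  a <- eco_propensities(state, params)
  S <- eco_stoichiometry()
  params$noise_scale * S * rep(sqrt(pmax(a, 0)), each = nrow(S))
}
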