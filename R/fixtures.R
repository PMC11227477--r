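#' Pinned parameter fixtures
#'
#' A registry of the reference parameter sets used throughout the
#' package's tests and reproduction experiments. The five `case_*`
#' fixtures share a common backbone (`T = 1`, `K1 = I0 = 5000`,
#' `K2 = 10000`, `r3 = 2`, `delta = 1e-3`, `epsilon = 1e-4`) and differ
#' in growth rates and interaction strengths:
#' \describe{
#'   \item{case_I}{slow tumour growth; late tipping with stable healthy
#'     cells (`r1 = 10`, `r2 = 2`, `alpha = 1e-4`, `beta = 1.5e-4`,
#'     `gamma = 1.2e-4`).}
#'   \item{case_II}{fast rates (`r1 = 5000`, `r2 = 1000`) with strong
#'     coupling (`alpha = 0.35`, `beta = 0.2`, `gamma = 0.15`); early
#'     tipping, healthy and immune cells decline from the start.}
#'   \item{case_III}{intermediate rates (`r1 = 50`, `r2 = 10`,
#'     `alpha = 5e-4`, `beta = 6e-4`, `gamma = 2e-4`); early tipping.}
#'   \item{case_IV}{fast rates with `alpha = 0.46`, `beta = 0.11`,
#'     `gamma = 0.11`; late tipping but persistently declining healthy
#'     cells.}
#'   \item{case_V}{fast rates with `alpha = 0.46`, `beta = 0.2`,
#'     `gamma = 0.15`; no crossing within the lifespan.}
#'   \item{fig8}{scaling constants for a three-species ensemble
#'     (`e = 2`, `f = 2`, `d = 10`, `b = 1e5`, `a = c = 5e4`,
#'     `g = 1e-5`, `h = 1.5e-5`, `k = 1.2e-5`, `l = 1e-4`); its
#'     dimensionless system coincides with `case_I`.}
#'   \item{fig11}{abrupt-progression set (`K2 = 10000`, `K1 = 5000`,
#'     `I0 = 850`, `r2 = 1000`, `r1 = 5000`, `r3 = 2`, `alpha = 0.476`,
#'     `beta = 0.6`, `gamma = 0.18`, `delta = 1e-3`): rapid cancer
#'     growth and a sharp late collapse of healthy cells.}
#'   \item{table1_expI}{`case_I` plus the epsilon grid
#'     `1e-4 * (0.98, 0.99, 1, 1.01, 1.02)` for the sensitivity scan.}
#'   \item{table1_expII}{`case_I` plus the epsilon grid
#'     `1e-3 * (0.98, 0.99, 1, 1.01, 1.02)`.}
#' }
#'
#' @param name One of `case_I`, `case_II`, `case_III`, `case_IV`,
#'   `case_V`, `fig8`, `fig11`, `table1_expI`, `table1_expII`.
#' @return For `case_*` and `fig11`, an [lv_params()] object; for
#'   `fig8`, an [scaling_constants()] object; for `table1_*`, a list
#'   with `params` and `epsilons`.
#' @examples
#' lv_fixture("case_I")
#' lv_fixture_names()
#' @export
lv_fixture <- function(name) {
  reg <- fixture_registry()
  if (!is.character(name) || length(name) != 1 || !name %in% names(reg)) {
    abort_invalid(paste0(
      "unknown fixture '", paste(name, collapse = ","),
      "'; available: ", paste(names(reg), collapse = ", ")))
  }
  reg[[name]]()
}

#' @rdname lv_fixture
#' @export
lv_fixture_names <- function() names(fixture_registry())

case_backbone <- function(r1, r2, alpha, beta, gamma) {
  lv_params(r1 = r1, r2 = r2, r3 = 2, K1 = 5000, K2 = 10000,
            alpha = alpha, beta = beta, gamma = gamma, delta = 1e-3,
            I0 = 5000, T = 1, epsilon = 1e-4)
}

fixture_registry <- function() {
  list(
    case_I = function() case_backbone(10, 2, 1e-4, 1.5e-4, 1.2e-4),
    case_II = function() case_backbone(5000, 1000, 0.35, 0.2, 0.15),
    case_III = function() case_backbone(50, 10, 5e-4, 6e-4, 2e-4),
    case_IV = function() case_backbone(5000, 1000, 0.46, 0.11, 0.11),
    case_V = function() case_backbone(5000, 1000, 0.46, 0.2, 0.15),
    fig8 = function() scaling_constants(
      a = 5e4, b = 1e5, c = 5e4, d = 10, e = 2, f = 2,
      g = 1e-5, h = 1.5e-5, k = 1.2e-5, l = 1e-4),
    fig11 = function() lv_params(
      r1 = 5000, r2 = 1000, r3 = 2, K1 = 5000, K2 = 10000,
      alpha = 0.476, beta = 0.6, gamma = 0.18, delta = 1e-3,
      I0 = 0.085 * 10000, T = 1, epsilon = 1e-4),
    table1_expI = function() list(
      params = case_backbone(10, 2, 1e-4, 1.5e-4, 1.2e-4),
      epsilons = c(0.000098, 0.000099, 0.0001, 0.000101, 0.000102)),
    table1_expII = function() list(
      params = case_backbone(10, 2, 1e-4, 1.5e-4, 1.2e-4),
      epsilons = c(0.00098, 0.00099, 0.001, 0.00101, 0.00102))
  )
}

#' Seeded random species ensembles
#'
#' Draws a reproducible synthetic ensemble for exercising the
#' noncorrelation machinery: lifespans are drawn log-uniformly over
#' `lifespan_range`, and each member's rate/interaction constants
#' `(d, e, f, g, h, k, l)` are perturbed by independent log-normal
#' multipliers with log-scale `sigma`. With `sigma = 0` all multipliers
#' are exactly 1, so the ensemble satisfies the shared-constants premise
#' by construction and [verify_noncorrelation()] must hold; `sigma > 0`
#' breaks the premise. Log-uniform lifespans and log-normal multipliers
#' keep every generated quantity automatically positive.
#'
#' @param n_species Number of species (>= 1).
#' @param lifespan_range Length-2 positive range for log-uniform
#'   lifespans; default `c(1, 100)`.
#' @param constants Base [scaling_constants()]; default the `fig8`
#'   fixture.
#' @param sigma Non-negative log-scale of the multiplier perturbations;
#'   default 0 (exact-Peto ensemble).
#' @param seed Integer seed; the same seed always yields the same
#'   ensemble and the caller's RNG state is untouched.
#' @return An [species_ensemble()] object.
#' @examples
#' random_ensemble(3, seed = 1)
#' @export
random_ensemble <- function(n_species, lifespan_range = c(1, 100),
                            constants = lv_fixture("fig8"), sigma = 0,
                            seed = 1L) {
  if (!is.numeric(n_species) || length(n_species) != 1 || n_species < 1) {
    abort_invalid("n_species must be at least 1")
  }
  if (length(lifespan_range) != 2 || any(lifespan_range <= 0) ||
      lifespan_range[1] > lifespan_range[2]) {
    abort_invalid("lifespan_range must be a positive increasing pair")
  }
  if (!is.numeric(sigma) || sigma < 0) {
    abort_invalid("sigma must be non-negative")
  }
  keys <- c("d", "e", "f", "g", "h", "k", "l")
  withr::with_seed(seed, {
    lifespans <- exp(stats::runif(n_species, log(lifespan_range[1]),
                                  log(lifespan_range[2])))
    mult <- if (sigma > 0) {
      tibble::as_tibble(stats::setNames(as.data.frame(
        matrix(exp(stats::rnorm(n_species * length(keys), 0, sigma)),
               nrow = n_species)), keys))
    } else NULL
    species_ensemble(constants, lifespans, multipliers = mult)
  })
}
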