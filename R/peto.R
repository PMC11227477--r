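#' Build a multi-species ensemble from shared scaling constants
#'
#' Instantiates one [lv_params()] member per lifespan by the allometric
#' power laws, optionally perturbing each member's rate and interaction
#' constants `(d, e, f, g, h, k, l)` by multiplicative factors. With all
#' multipliers equal to 1 every member shares identical dimensionless
#' coefficients (an exact-Peto ensemble); any multiplier away from 1
#' breaks that premise for its member.
#'
#' @param constants An [scaling_constants()] object.
#' @param lifespans Positive numeric vector, one lifespan per species.
#' @param multipliers Optional data frame / tibble with columns among
#'   `d, e, f, g, h, k, l` and one row per lifespan; defaults to all 1.
#' @return An `lv_ensemble`: a list with `constants` and a tibble
#'   `members` (columns `species`, `lifespan`, the seven multipliers and
#'   a `params` list-column).
#' @examples
#' sc <- lv_fixture("fig8")
#' ens <- species_ensemble(sc, lifespans = c(1, 10, 100))
#' @export
species_ensemble <- function(constants, lifespans, multipliers = NULL) {
  stopifnot(inherits(constants, "lv_scaling"))
  if (length(lifespans) < 1) abort_invalid("at least one lifespan required")
  bad <- which(!is.finite(lifespans) | lifespans <= 0)
  if (length(bad)) {
    abort_invalid(paste0("invalid lifespan at index ",
                         paste(bad, collapse = ", ")))
  }
  keys <- c("d", "e", "f", "g", "h", "k", "l")
  mult <- tibble::as_tibble(
    stats::setNames(as.data.frame(matrix(1, length(lifespans),
                                         length(keys))), keys))
  if (!is.null(multipliers)) {
    multipliers <- tibble::as_tibble(multipliers)
    if (nrow(multipliers) != length(lifespans)) {
      abort_invalid("multipliers must have one row per lifespan")
    }
    extra <- setdiff(names(multipliers), keys)
    if (length(extra)) {
      abort_invalid(paste0("unknown multiplier columns: ",
                           paste(extra, collapse = ", ")))
    }
    mult[names(multipliers)] <- multipliers
    if (any(!is.finite(as.matrix(mult)) | as.matrix(mult) <= 0)) {
      abort_invalid("multipliers must be positive and finite")
    }
  }
  params <- purrr::map(seq_along(lifespans), function(i) {
    ci <- constants
    for (key in keys) ci[[key]] <- ci[[key]] * mult[[key]][i]
    scale_params(ci, T = lifespans[i])
  })
  members <- dplyr::bind_cols(
    tibble::tibble(species = seq_along(lifespans), lifespan = lifespans),
    mult)
  members$params <- params
  structure(list(constants = constants, members = members),
            class = "lv_ensemble")
}

#' @export
print.lv_ensemble <- function(x, ...) {
  cat(sprintf("<lv_ensemble> %d species, lifespans %s\n",
              nrow(x$members),
              paste(signif(x$members$lifespan, 4), collapse = ", ")))
  invisible(x)
}

#' Verify identical rescaled tipping times across an ensemble
#'
#' Computes each member's tipping time in dimensional time, rescales by
#' its lifespan, and compares the rescaled times pairwise. When every
#' member shares the same scaling constants the nondimensionalized
#' systems coincide, so all rescaled tipping times `t_c/T` -- and hence
#' all lifetime incidences `q(1 - t_c/T)` -- are identical: cancer
#' incidence is uncorrelated with lifespan (Peto's paradox). The verdict
#' is `"holds"` when the maximum pairwise deviation of `t_c/T` is within
#' `tolerance`, `"violated"` otherwise, and `"violated (no crossing)"`
#' if any member never crosses.
#'
#' @param ensemble An [species_ensemble()] object.
#' @param q Per-unit-time cancer probability.
#' @param tolerance Agreement tolerance on `t_c/T` (default `1e-4`,
#'   dominated by solver accuracy, not by the exact identity).
#' @param ... Solver options passed to [find_tipping()].
#' @return An `lv_noncorrelation` object: list with a `species` tibble
#'   (`species`, `lifespan`, `exists`, `t_c`, `t_hat`, `incidence`),
#'   `max_pairwise_deviation`, `tolerance`, `verdict`.
#' @examples
#' ens <- species_ensemble(lv_fixture("fig8"), c(1, 10, 100))
#' verify_noncorrelation(ens)
#' @export
verify_noncorrelation <- function(ensemble, q = 0.5, tolerance = 1e-4,
                                  ...) {
  stopifnot(inherits(ensemble, "lv_ensemble"))
  tips <- purrr::map(ensemble$members$params, find_tipping, q = q, ...)
  species <- tibble::tibble(
    species = ensemble$members$species,
    lifespan = ensemble$members$lifespan,
    exists = purrr::map_lgl(tips, "exists"),
    t_c = purrr::map_dbl(tips, "t_c"),
    t_hat = purrr::map_dbl(tips, "t_c_over_T"),
    incidence = purrr::map_dbl(tips, "incidence"))
  if (!all(species$exists)) {
    verdict <- sprintf("violated (no crossing: species %s)",
                       paste(species$species[!species$exists],
                             collapse = ", "))
    dev <- NA_real_
  } else {
    dev <- if (nrow(species) > 1) diff(range(species$t_hat)) else 0
    verdict <- if (dev <= tolerance) "holds" else "violated"
  }
  structure(list(species = species, max_pairwise_deviation = dev,
                 tolerance = tolerance, verdict = verdict, q = q),
            class = "lv_noncorrelation")
}

#' @export
print.lv_noncorrelation <- function(x, ...) {
  cat(sprintf("<lv_noncorrelation> verdict: %s (max |Δ t_c/T| = %s, tolerance %g)\n",
              x$verdict,
              ifelse(is.na(x$max_pairwise_deviation), "NA",
                     signif(x$max_pairwise_deviation, 3)),
              x$tolerance))
  print(x$species)
  invisible(x)
}

#' @export
tidy.lv_noncorrelation <- function(x, ...) x$species

#' @export
glance.lv_noncorrelation <- function(x, ...) {
  tibble::tibble(n_species = nrow(x$species),
                 max_pairwise_deviation = x$max_pairwise_deviation,
                 tolerance = x$tolerance, verdict = x$verdict, q = x$q)
}

#' Plot rescaled tipping times across an ensemble
#'
#' @param object An `lv_noncorrelation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lv_noncorrelation <- function(object, ...) {
  ggplot2::ggplot(object$species,
                  ggplot2::aes(x = factor(.data$lifespan),
                               y = .data$t_hat)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "lifespan T", y = "rescaled tipping time t_c / T") +
    ggplot2::theme_minimal()
}

#' Invariance of the tipping time under scaling-product-preserving changes
#'
#' Only the products `g*b`, `h*c`, `k*a` and `l*a` enter the
#' dimensionless system, so multiplying the cell-count prefactors
#' `(a, b, c)` by a factor while dividing the interaction constants
#' `(g, h, k, l)` by the same factor leaves every rescaled tipping time
#' unchanged. This runs [verify_noncorrelation()] for the base and the
#' rescaled constants and reports the difference.
#'
#' @param constants An [scaling_constants()] object.
#' @param factor Positive scale factor applied to `(a, b, c)` and
#'   divided out of `(g, h, k, l)`.
#' @param lifespans Lifespans for both ensembles (default `c(1, 10, 100)`).
#' @param q,tolerance,... As in [verify_noncorrelation()].
#' @return List with `base` and `rescaled` (`lv_noncorrelation`
#'   objects), `max_t_hat_shift` (largest change of any species'
#'   `t_c/T`), and logical `invariant` (shift within `tolerance`).
#' @export
scaling_product_invariance <- function(constants, factor,
                                       lifespans = c(1, 10, 100),
                                       q = 0.5, tolerance = 1e-4, ...) {
  stopifnot(inherits(constants, "lv_scaling"))
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    abort_invalid("factor must be a single positive number")
  }
  scaled <- constants
  for (key in c("a", "b", "c")) scaled[[key]] <- scaled[[key]] * factor
  for (key in c("g", "h", "k", "l")) scaled[[key]] <- scaled[[key]] / factor
  base <- verify_noncorrelation(species_ensemble(constants, lifespans),
                                q = q, tolerance = tolerance, ...)
  resc <- verify_noncorrelation(species_ensemble(scaled, lifespans),
                                q = q, tolerance = tolerance, ...)
  shift <- max(abs(base$species$t_hat - resc$species$t_hat))
  list(base = base, rescaled = resc, max_t_hat_shift = shift,
       invariant = is.finite(shift) && shift <= tolerance)
}

#' Per-species time-interval lengths and counts
#'
#' Under the power laws, per-cell changes within one "interval" (a unit
#' of cell-cycle activity) scale so that interval lengths must be
#' proportional to lifespan, giving every species the same number of
#' intervals: self-growth contributes `c1/T` per cell and interaction
#' `c2/T^(m+1)` per cell pair, while cell numbers scale as `T^m`, so the
#' per-interval change scales as `dt * T^(m-1) * T^m`; equal per-size
#' change across species forces `dt` proportional to `T`. The exponent
#' `m` cancels from the interval count `T/dt`.
#'
#' @param lifespans Positive numeric vector.
#' @param m Power-law exponent (does not affect the counts; recorded for
#'   reference). Default 4.76.
#' @param c1,c2 Opaque positive constants for the self-growth and
#'   interaction contributions (units unspecified; they cancel from the
#'   ratios). Defaults 1.
#' @param dt_shortest Interval length assigned to the shortest-lived
#'   species (default `min(lifespans) / 100`).
#' @return A tibble with `lifespan`, `dt` (proportional to lifespan) and
#'   `n_intervals` (identical across species).
#' @examples
#' interval_ratios(c(1, 2, 3))
#' @export
interval_ratios <- function(lifespans, m = 4.76, c1 = 1, c2 = 1,
                            dt_shortest = min(lifespans) / 100) {
  if (any(!is.finite(lifespans) | lifespans <= 0)) {
    abort_invalid("lifespans must be positive and finite")
  }
  if (c1 <= 0 || c2 <= 0) abort_invalid("c1 and c2 must be positive")
  dt <- dt_shortest * lifespans / min(lifespans)
  tibble::tibble(lifespan = lifespans, dt = dt,
                 n_intervals = lifespans / dt, m = m)
}

#' Population-averaged interaction coefficient
#'
#' A species-level interaction coefficient is the average over `N`
#' individuals of each individual's time-averaged coefficient:
#' \deqn{\beta = \frac{1}{N}\sum_{i=1}^{N} \frac{1}{T_i}
#'       \int_0^{T_i} \beta_i(t)\, dt.}
#' Integrals are evaluated by adaptive quadrature
#' ([stats::integrate()], relative tolerance `1e-8`); constant
#' coefficients may be given as plain numbers.
#'
#' @param individuals A list, one element per individual, each a list
#'   with `T` (positive lifespan) and `coef` (a function of time, or a
#'   single number for a constant coefficient).
#' @return The population-averaged coefficient (a single number).
#' @examples
#' population_average_coefficient(list(
#'   list(T = 2, coef = function(t) 2 * t),  # time-average = T = 2
#'   list(T = 1, coef = 0.5)))
#' @export
population_average_coefficient <- function(individuals) {
  if (!is.list(individuals) || length(individuals) == 0) {
    abort_invalid("individuals must be a non-empty list")
  }
  means <- purrr::map_dbl(individuals, function(ind) {
    if (is.null(ind$T) || !is.finite(ind$T) || ind$T <= 0) {
      abort_invalid("each individual needs a positive lifespan T")
    }
    f <- ind$coef
    if (is.numeric(f) && length(f) == 1) return(f)
    if (!is.function(f)) abort_invalid("coef must be a number or function")
    stats::integrate(function(t) vapply(t, f, numeric(1)),
                     0, ind$T, rel.tol = 1e-8)$value / ind$T
  })
  mean(means)
}

#' Convert between rates, lifespans and dimensionless constants
#'
#' In the power-law scaling, a per-time rate and its species'
#' lifespan determine the dimensionless rate constant as
#' `constant = rate * lifespan` (the inversion of `rate = constant / T`).
#' A cell-line doubling time converts to an exponential growth rate as
#' `rate = ln(2) / doubling_time`.
#'
#' @param rate Positive per-time rate.
#' @param lifespan Positive lifespan in the same time units.
#' @return `dimensionless_constant_from_rate()`: the constant
#'   `rate * lifespan`; `growth_rate_from_doubling_time()`: the rate.
#' @examples
#' dimensionless_constant_from_rate(2, 1)
#' growth_rate_from_doubling_time(log(2))
#' @export
dimensionless_constant_from_rate <- function(rate, lifespan) {
  if (any(!is.finite(rate) | rate <= 0) ||
      any(!is.finite(lifespan) | lifespan <= 0)) {
    abort_invalid("rate and lifespan must be positive")
  }
  rate * lifespan
}

#' @rdname dimensionless_constant_from_rate
#' @param doubling_time Positive doubling time.
#' @export
growth_rate_from_doubling_time <- function(doubling_time) {
  if (any(!is.finite(doubling_time) | doubling_time <= 0)) {
    abort_invalid("doubling_time must be positive")
  }
  log(2) / doubling_time
}
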