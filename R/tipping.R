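#' Locate the immune-escape tipping time
#'
#' Finds the first time at which the growing cancer population `C(t)`
#' crosses the declining immune threshold `I(t)` from below (the "dead
#' cross"). The event function `e(t) = C(t) - I(t)` is evaluated on the
#' simulation grid; the first interval with a sign change from
#' non-positive to positive is then refined by re-integrating from the
#' left endpoint inside a bracketing root search ([stats::uniroot()],
#' interval tolerance `1e-12` of a lifespan). The lifetime cancer
#' incidence is `q * (1 - t_c / T)`: a constant per-unit-time cancer
#' probability `q` integrated over the post-tipping fraction of life.
#'
#' If `e(t) < 0` throughout the lifespan the crossing does not exist and
#' the incidence is 0. All sign changes on the grid are counted; if the
#' event function crosses upward more than once the first crossing is
#' reported with a warning.
#'
#' @param params An [lv_params()] or [nondimensionalize()] object
#'   (for the latter, times are already rescaled so `t_c = t_c/T`).
#' @param q Per-unit-time cancer probability after tipping, in (0, 1].
#' @param n Output grid size used for bracketing (default 2001).
#' @param rtol,atol Solver tolerances, as in [lv_simulate()].
#' @param method `deSolve` integration method.
#' @param trajectory Optional precomputed `lv_trajectory` for `params`
#'   (saves one integration; must use the same solver settings).
#' @return An `lv_tipping` object: a list with `exists`, `t_c`,
#'   `t_c_over_T`, `incidence`, `q`, `n_crossings`.
#' @examples
#' find_tipping(lv_fixture("case_I"))
#' @export
find_tipping <- function(params, q = 0.5, n = 2001,
                         rtol = 1e-9, atol = 1e-12, method = "ode45",
                         trajectory = NULL) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q > 1) {
    abort_invalid("q must lie in (0, 1]")
  }
  dimensionless <- inherits(params, "lv_params_hat")
  C0 <- if (dimensionless) params$C0_tilde else params$C0
  I0 <- if (dimensionless) params$I0_tilde else params$I0
  if (C0 >= I0) {
    abort_invalid("C0 < I0 required: no upward crossing is defined")
  }
  horizon <- if (dimensionless) 1 else params$T
  traj <- if (is.null(trajectory)) {
    lv_simulate(params, n = n, rtol = rtol, atol = atol, method = method)
  } else trajectory
  e <- traj$C - traj$I
  up <- which(e[-1] > 0 & e[-length(e)] <= 0)
  n_cross <- length(up)
  if (n_cross > 1) {
    rlang::warn(sprintf(
      "event function C - I crosses upward %d times; reporting the first",
      n_cross), class = "petolv_multiple_crossings")
  }
  if (n_cross == 0) {
    res <- list(exists = FALSE, t_c = NA_real_, t_c_over_T = NA_real_,
                incidence = 0, q = q, T = horizon, n_crossings = 0L)
    return(structure(res, class = "lv_tipping", params = params))
  }
  i <- up[1]
  t_c <- if (e[i] == 0) {
    traj$t[i]
  } else {
    refine_crossing(params, traj, i, rtol = rtol, atol = atol,
                    method = method, dimensionless = dimensionless)
  }
  t_hat <- t_c / horizon
  structure(
    list(exists = TRUE, t_c = t_c, t_c_over_T = t_hat,
         incidence = cancer_incidence(t_hat, q), q = q, T = horizon,
         n_crossings = n_cross),
    class = "lv_tipping", params = params)
}

# Re-integrates over [t_i, t] from the bracketing grid state so the root
# is resolved at solver accuracy rather than grid resolution.
refine_crossing <- function(params, traj, i, rtol, atol, method,
                            dimensionless) {
  func <- if (dimensionless) desolve_func_hat(params) else
    desolve_func(params)
  t_left <- traj$t[i]
  y_left <- c(C = traj$C[i], H = traj$H[i], I = traj$I[i])
  event <- function(t) {
    if (t <= t_left) return(traj$C[i] - traj$I[i])
    o <- deSolve::ode(y = y_left, times = c(t_left, t), func = func,
                      parms = NULL, method = method,
                      rtol = rtol, atol = atol)
    o[2, "C"] - o[2, "I"]
  }
  horizon <- if (dimensionless) 1 else params$T
  stats::uniroot(event, c(t_left, traj$t[i + 1]),
                 tol = 1e-12 * max(1, horizon))$root
}

#' Lifetime cancer incidence from a rescaled tipping time
#'
#' The model's incidence is the constant per-unit-time cancer probability
#' `q` integrated over the post-tipping fraction of the lifespan:
#' `q * (1 - t_c/T)`. [tipping_from_incidence()] inverts the identity.
#'
#' @param t_c_over_T Rescaled tipping time in \[0, 1\] (`NA` means no
#'   crossing, incidence 0).
#' @param q Per-unit-time cancer probability in (0, 1].
#' @return Incidence in \[0, `q`\].
#' @examples
#' cancer_incidence(0.6, q = 0.5)      # 0.2
#' tipping_from_incidence(0.2, q = 0.5) # 0.6
#' @export
cancer_incidence <- function(t_c_over_T, q = 0.5) {
  if (q <= 0 || q > 1) abort_invalid("q must lie in (0, 1]")
  ifelse(is.na(t_c_over_T), 0, q * (1 - t_c_over_T))
}

#' @rdname cancer_incidence
#' @param incidence Lifetime incidence in \[0, `q`\].
#' @export
tipping_from_incidence <- function(incidence, q = 0.5) {
  if (q <= 0 || q > 1) abort_invalid("q must lie in (0, 1]")
  if (any(incidence < 0 | incidence > q)) {
    abort_invalid("incidence must lie in [0, q]")
  }
  1 - incidence / q
}

#' @export
print.lv_tipping <- function(x, ...) {
  if (x$exists) {
    cat(sprintf(
      "<lv_tipping> crossing at t_c = %.6g (t_c/T = %.6g), incidence %.4g (q = %g)\n",
      x$t_c, x$t_c_over_T, x$incidence, x$q))
  } else {
    cat(sprintf("<lv_tipping> no C = I crossing within the lifespan; incidence 0 (q = %g)\n",
                x$q))
  }
  invisible(x)
}

#' @export
tidy.lv_tipping <- function(x, ...) {
  tibble::tibble(exists = x$exists, t_c = x$t_c,
                 t_c_over_T = x$t_c_over_T, incidence = x$incidence,
                 q = x$q, n_crossings = x$n_crossings)
}

#' @export
glance.lv_tipping <- function(x, ...) tidy.lv_tipping(x)

#' Check the admissibility requirements of a parameter set
#'
#' Evaluates the four modelling requirements used to judge whether a
#' parameter set reproduces the essential biology:
#' \enumerate{
#'   \item the cell-count power-law exponent is `m = 4.76` (applicable
#'     only when the parameters were generated from
#'     [scaling_constants()]; otherwise `NA`);
#'   \item tipping occurs late in life, `t_c/T > 0.6`;
#'   \item healthy cells are roughly constant before tipping: the
#'     minimum of `H(t)` on `[0, t_c]` stays at or above `0.95 * H0`;
#'   \item immune depletion by cancer dominates intrinsic decay,
#'     `K1 * delta > r3`.
#' }
#'
#' @param params An [lv_params()] object.
#' @param trajectory Optional precomputed `lv_trajectory`.
#' @param tipping Optional precomputed `lv_tipping`.
#' @param ... Solver options forwarded to [lv_simulate()] /
#'   [find_tipping()] when not precomputed.
#' @return An `lv_requirements` object (one-row tibble) with logical
#'   columns `req1_m_is_4_76`, `req2_late_tipping`, `req3_healthy_stable`,
#'   `req4_depletion_dominates` plus the quantities behind them
#'   (`t_c_over_T`, `min_H_fraction`, `K1_delta`, `r3`).
#' @export
check_requirements <- function(params, trajectory = NULL, tipping = NULL,
                               ...) {
  stopifnot(inherits(params, "lv_params"))
  if (is.null(trajectory)) trajectory <- lv_simulate(params, ...)
  if (is.null(tipping)) {
    tipping <- find_tipping(params, trajectory = trajectory, ...)
  }
  req1 <- if (is.na(params$m)) NA else abs(params$m - 4.76) < 1e-9
  req2 <- isTRUE(tipping$exists) && tipping$t_c_over_T > 0.6
  min_H <- if (isTRUE(tipping$exists)) {
    min(trajectory$H[trajectory$t <= tipping$t_c])
  } else {
    min(trajectory$H)
  }
  min_H_frac <- min_H / params$H0
  req3 <- min_H_frac >= 0.95
  req4 <- params$K1 * params$delta > params$r3
  out <- tibble::tibble(
    req1_m_is_4_76 = req1, req2_late_tipping = req2,
    req3_healthy_stable = req3, req4_depletion_dominates = req4,
    t_c_over_T = tipping$t_c_over_T, min_H_fraction = min_H_frac,
    K1_delta = params$K1 * params$delta, r3 = params$r3)
  class(out) <- c("lv_requirements", class(out))
  out
}

#' Sensitivity of the tipping time to the initial cancer fraction
#'
#' Rebuilds the initial state `C0 = epsilon * K1`,
#' `H0 = (1 - epsilon) * K2` for each requested `epsilon` and recomputes
#' the tipping time. A larger initial cancer fraction advances the
#' crossing, so `t_c/T` decreases with `epsilon`.
#'
#' @param base An [lv_params()] or [scaling_constants()] object supplying
#'   all other coefficients (constants are instantiated at `T = 1`).
#' @param epsilons Numeric vector of initial cancer fractions, each in
#'   (0, 0.1); rows are returned in the given order.
#' @param q Per-unit-time cancer probability.
#' @param ... Solver options forwarded to [find_tipping()].
#' @return A tibble with columns `epsilon`, `exists`, `t_c`,
#'   `t_c_over_T`, `incidence`, `status` (`"ok"` or the integration
#'   error message), of class `lv_sensitivity`.
#' @examples
#' sensitivity_scan(lv_fixture("case_I"), c(1e-4, 2e-4, 5e-4))
#' @export
sensitivity_scan <- function(base, epsilons, q = 0.5, ...) {
  if (inherits(base, "lv_scaling")) base <- scale_params(base, T = 1)
  stopifnot(inherits(base, "lv_params"))
  purrr::walk(epsilons, check_epsilon)
  rows <- purrr::map(epsilons, function(eps) {
    p <- with_epsilon(base, eps)
    tryCatch({
      tip <- find_tipping(p, q = q, ...)
      tibble::tibble(epsilon = eps, exists = tip$exists, t_c = tip$t_c,
                     t_c_over_T = tip$t_c_over_T,
                     incidence = tip$incidence, status = "ok")
    }, petolv_integration_error = function(e) {
      tibble::tibble(epsilon = eps, exists = NA, t_c = NA_real_,
                     t_c_over_T = NA_real_, incidence = NA_real_,
                     status = conditionMessage(e))
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lv_sensitivity", class(out))
  out
}

with_epsilon <- function(params, epsilon) {
  lv_params(r1 = params$r1, r2 = params$r2, r3 = params$r3,
            K1 = params$K1, K2 = params$K2, alpha = params$alpha,
            beta = params$beta, gamma = params$gamma,
            delta = params$delta, I0 = params$I0, T = params$T,
            epsilon = epsilon, m = params$m)
}

#' Plot an epsilon-sensitivity scan
#'
#' @param object An `lv_sensitivity` tibble from [sensitivity_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lv_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$epsilon,
                                       y = .data$t_c_over_T)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "initial cancer fraction ε",
                  y = "rescaled tipping time t_c / T") +
    ggplot2::theme_minimal()
}
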