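#' Integrate the model over a lifespan
#'
#' Solves the cancer-healthy-immune system numerically with an adaptive
#' Dormand-Prince 4(5) Runge-Kutta scheme (`deSolve`'s `"ode45"`) from
#' `t = 0` to the lifespan `T` (or `tau` in \[0, 1\] for a dimensionless
#' parameter set). Default tolerances (relative `1e-9`, absolute `1e-12`)
#' resolve crossing times to well below `1e-4` of a lifespan; both are
#' exposed, as is the integrator (`method`), so a stiff solver such as
#' `"lsoda"` can be substituted.
#'
#' @param params An [lv_params()] or [nondimensionalize()] object.
#' @param n Number of equally spaced output times (default 2001).
#' @param times Optional explicit output times, overriding `n`; must be
#'   strictly increasing, starting at 0 and ending at the lifespan.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param method `deSolve` integration method; default `"ode45"`.
#' @param ... Passed on to [deSolve::ode()].
#' @return An `lv_trajectory`: a tibble with columns `t`, `C`, `H`, `I`,
#'   carrying the parameters and solver settings as attributes.
#' @examples
#' traj <- lv_simulate(lv_fixture("case_I"))
#' dplyr::slice_tail(traj, n = 3)
#' @export
lv_simulate <- function(params, n = 2001, times = NULL,
                        rtol = 1e-9, atol = 1e-12, method = "ode45", ...) {
  UseMethod("lv_simulate")
}

#' @export
lv_simulate.lv_params <- function(params, n = 2001, times = NULL,
                                  rtol = 1e-9, atol = 1e-12,
                                  method = "ode45", ...) {
  y0 <- c(C = params$C0, H = params$H0, I = params$I0)
  integrate_lv(desolve_func(params), y0, horizon = params$T, params = params,
               n = n, times = times, rtol = rtol, atol = atol,
               method = method, ...)
}

#' @export
lv_simulate.lv_params_hat <- function(params, n = 2001, times = NULL,
                                      rtol = 1e-9, atol = 1e-12,
                                      method = "ode45", ...) {
  y0 <- c(C = params$C0_tilde, H = params$H0_tilde, I = params$I0_tilde)
  integrate_lv(desolve_func_hat(params), y0, horizon = 1, params = params,
               n = n, times = times, rtol = rtol, atol = atol,
               method = method, ...)
}

integrate_lv <- function(func, y0, horizon, params, n, times,
                         rtol, atol, method, ...) {
  if (is.null(times)) {
    times <- seq(0, horizon, length.out = n)
  } else {
    if (any(diff(times) <= 0) || times[1] != 0 ||
        abs(times[length(times)] - horizon) > 1e-12 * max(1, horizon)) {
      abort_invalid("times must increase strictly from 0 to the lifespan")
    }
  }
  out <- withCallingHandlers(
    deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                 method = method, rtol = rtol, atol = atol, ...),
    warning = function(w) {
      if (grepl("excessive|not successful|too much accuracy|maxsteps|step size",
                conditionMessage(w))) {
        rlang::abort(paste0("integration failed: ", conditionMessage(w)),
                     class = "petolv_integration_error", parent = w)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (nrow(out) < length(times)) {
    rlang::abort(
      sprintf("integration failed near t = %.6g (%d of %d steps completed)",
              out[nrow(out), 1], nrow(out), length(times)),
      class = "petolv_integration_error")
  }
  traj <- tibble::tibble(t = out[, "time"], C = out[, "C"],
                         H = out[, "H"], I = out[, "I"])
  structure(traj,
            class = c("lv_trajectory", class(traj)),
            params = params,
            solver = list(method = method, rtol = rtol, atol = atol,
                          n_out = length(times)))
}

#' Solver settings and parameters of a trajectory
#'
#' @param x An `lv_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble with the solver method, tolerances, number of
#'   output points, final state and horizon.
#' @export
glance.lv_trajectory <- function(x, ...) {
  s <- attr(x, "solver")
  tibble::tibble(method = s$method, rtol = s$rtol, atol = s$atol,
                 n_out = s$n_out, t_end = x$t[nrow(x)],
                 C_end = x$C[nrow(x)], H_end = x$H[nrow(x)],
                 I_end = x$I[nrow(x)])
}

#' Trajectory parameters
#'
#' @param traj An `lv_trajectory`.
#' @return The parameter object the trajectory was integrated from.
#' @export
trajectory_params <- function(traj) attr(traj, "params")

#' Write a trajectory as CSV
#'
#' Plain `t,C,H,I` columns, readable by any CSV consumer.
#'
#' @param traj An `lv_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj[, c("t", "C", "H", "I")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Plot a trajectory
#'
#' Cell counts over time on an optional log scale, with the
#' immune-escape crossing marked when one exists.
#'
#' @param object An `lv_trajectory`.
#' @param log_y Plot counts on a log10 axis (default `FALSE`).
#' @param mark_tipping Locate and mark the first `C = I` crossing
#'   (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lv_trajectory <- function(object, log_y = FALSE,
                                   mark_tipping = TRUE, ...) {
  df <- trajectory_long(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$count,
                                        colour = .data$compartment)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "time (lifespan units)", y = "cell count",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  if (mark_tipping) {
    tip <- tryCatch(find_tipping(trajectory_params(object)),
                    error = function(e) NULL)
    if (!is.null(tip) && isTRUE(tip$exists)) {
      p <- p + ggplot2::geom_vline(xintercept = tip$t_c,
                                   linetype = "dashed", colour = "grey40")
    }
  }
  p
}

trajectory_long <- function(traj) {
  dplyr::bind_rows(
    tibble::tibble(t = traj$t, compartment = "cancer (C)", count = traj$C),
    tibble::tibble(t = traj$t, compartment = "healthy (H)", count = traj$H),
    tibble::tibble(t = traj$t, compartment = "immune threshold (I)",
                   count = traj$I)
  )
}
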