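#' Reproduction experiments
#'
#' End-to-end reruns of the reference numerical results behind the
#' pinned fixtures: the five qualitative cases, the epsilon-sensitivity
#' table, the three-species rescaled-tipping-time invariance, and the
#' abrupt-progression run. Each experiment is deterministic given its
#' solver settings; reference values are pinned at an absolute tolerance
#' of `5e-3` for 2-significant-figure crossing times and `5e-4` for the
#' 4-decimal sensitivity table.
#'
#' @name experiments
#' @param q Per-unit-time cancer probability.
#' @param ... Solver options forwarded to [find_tipping()].
NULL

case_reference <- function() {
  tibble::tibble(
    case = c("case_I", "case_II", "case_III", "case_IV", "case_V"),
    t_c_ref = c(0.875, 0.22, 0.22, 0.88, NA_real_),
    exists_ref = c(TRUE, TRUE, TRUE, TRUE, FALSE))
}

#' @describeIn experiments Tipping time and requirement report for the
#'   five case fixtures, compared to the pinned reference crossing
#'   times (tolerance `5e-3`).
#' @return `run_cases()`: an `lv_experiment` with a per-case tibble
#'   (`case`, `exists`, `t_c`, `incidence`, requirement flags,
#'   `t_c_ref`, `pass`).
#' @export
run_cases <- function(q = 0.5, ...) {
  ref <- case_reference()
  rows <- purrr::map(ref$case, function(nm) {
    p <- lv_fixture(nm)
    traj <- lv_simulate(p, ...)
    tip <- find_tipping(p, q = q, trajectory = traj, ...)
    req <- check_requirements(p, trajectory = traj, tipping = tip)
    tibble::tibble(case = nm, exists = tip$exists, t_c = tip$t_c,
                   incidence = tip$incidence,
                   req2_late_tipping = req$req2_late_tipping,
                   req3_healthy_stable = req$req3_healthy_stable,
                   req4_depletion_dominates = req$req4_depletion_dominates)
  })
  result <- dplyr::left_join(dplyr::bind_rows(rows), ref, by = "case")
  result$pass <- (result$exists == result$exists_ref) &
    (!result$exists_ref | abs(result$t_c - result$t_c_ref) <= 5e-3)
  new_experiment("cases", list(q = q), result)
}

table1_reference <- function() {
  tibble::tibble(
    experiment = rep(c("I", "II"), each = 5),
    epsilon = c(0.000098, 0.000099, 0.0001, 0.000101, 0.000102,
                0.00098, 0.00099, 0.001, 0.00101, 0.00102),
    t_hat_ref = c(0.8759, 0.8750, 0.8741, 0.8732, 0.8723,
                  0.6679, 0.6669, 0.6660, 0.6651, 0.6643))
}

#' @describeIn experiments Epsilon-sensitivity table: ten
#'   `(epsilon, t_c/T)` pairs against their pinned 4-decimal reference
#'   values (tolerance `5e-4`).
#' @export
run_table1 <- function(q = 0.5, ...) {
  ref <- table1_reference()
  scans <- purrr::map(c("table1_expI", "table1_expII"), function(nm) {
    fx <- lv_fixture(nm)
    sensitivity_scan(fx$params, fx$epsilons, q = q, ...)
  })
  result <- dplyr::bind_rows(scans)[, c("epsilon", "t_c_over_T",
                                        "incidence", "status")]
  result <- dplyr::bind_cols(ref["experiment"], result,
                             ref["t_hat_ref"])
  result$pass <- result$status == "ok" &
    abs(result$t_c_over_T - result$t_hat_ref) <= 5e-4
  new_experiment("table1", list(q = q), result)
}

#' @describeIn experiments Three-species ensemble (lifespans 1, 10,
#'   100) from the `fig8` constants: asserts that all rescaled tipping
#'   times agree within `1e-4` and match the tipping time of the
#'   dimensionless system integrated directly on the unit lifespan.
#' @export
run_fig8_9 <- function(q = 0.5, ...) {
  sc <- lv_fixture("fig8")
  ens <- species_ensemble(sc, lifespans = c(1, 10, 100))
  report <- verify_noncorrelation(ens, q = q, tolerance = 1e-4, ...)
  hat <- nondimensionalize(ens$members$params[[1]])
  tip_hat <- find_tipping(hat, q = q, ...)
  result <- report$species
  result$t_hat_dimensionless <- tip_hat$t_c_over_T
  result$pass <- abs(result$t_hat - tip_hat$t_c_over_T) <= 1e-4
  new_experiment(
    "fig8_9", list(q = q, tolerance = 1e-4),
    result,
    extra = list(verdict = report$verdict,
                 max_pairwise_deviation = report$max_pairwise_deviation,
                 t_hat_dimensionless = tip_hat$t_c_over_T))
}

#' @describeIn experiments Abrupt-progression fixture (`fig11`):
#'   reports the tipping result plus a descriptive "abruptness"
#'   statistic -- the largest drop of the healthy-cell count over any
#'   sliding window spanning 5 percent of the lifespan -- side by side
#'   with the same statistic for `case_I`. The statistic is this
#'   package's operationalization of "sharp decrease" and is reported,
#'   not asserted against any reference.
#' @param window Sliding-window width as a fraction of the lifespan.
#' @export
run_fig11 <- function(q = 0.5, window = 0.05, ...) {
  p11 <- lv_fixture("fig11")
  p1 <- lv_fixture("case_I")
  traj11 <- lv_simulate(p11, ...)
  traj1 <- lv_simulate(p1, ...)
  tip11 <- find_tipping(p11, q = q, trajectory = traj11, ...)
  result <- tibble::tibble(
    fixture = c("fig11", "case_I"),
    exists = c(tip11$exists,
               find_tipping(p1, q = q, trajectory = traj1, ...)$exists),
    t_c = c(tip11$t_c, NA_real_),
    abruptness = c(max_window_drop(traj11, window),
                   max_window_drop(traj1, window)))
  new_experiment("fig11", list(q = q, window = window), result)
}

# Largest decrease of H across any time window of width `window * T`.
max_window_drop <- function(traj, window = 0.05) {
  tt <- traj$t
  w <- window * (tt[length(tt)] - tt[1])
  drops <- vapply(seq_along(tt), function(i) {
    j <- which(tt <= tt[i] + w)
    traj$H[i] - min(traj$H[j[j >= i]])
  }, numeric(1))
  max(drops)
}

#' @describeIn experiments Runs all four experiments; optionally writes
#'   `report.json`, `table1.csv` and per-case trajectory CSVs to
#'   `out_dir`.
#' @param out_dir Optional output directory.
#' @return `run_all_experiments()`: a named list of `lv_experiment`
#'   objects.
#' @export
run_all_experiments <- function(q = 0.5, out_dir = NULL, ...) {
  reports <- list(cases = run_cases(q = q, ...),
                  table1 = run_table1(q = q, ...),
                  fig8_9 = run_fig8_9(q = q, ...),
                  fig11 = run_fig11(q = q, ...))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      purrr::map(reports, experiment_payload),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    utils::write.csv(as.data.frame(reports$table1$result),
                     file.path(out_dir, "table1.csv"), row.names = FALSE)
    for (nm in case_reference()$case) {
      write_trajectory_csv(lv_simulate(lv_fixture(nm)),
                           file.path(out_dir, paste0("traj_", nm, ".csv")))
    }
  }
  reports
}

new_experiment <- function(name, inputs, result, extra = list()) {
  structure(list(name = name, inputs = inputs, result = result,
                 extra = extra),
            class = "lv_experiment")
}

experiment_payload <- function(x) {
  list(name = x$name, inputs = x$inputs,
       result = as.data.frame(x$result), extra = x$extra)
}

#' @export
print.lv_experiment <- function(x, ...) {
  cat(sprintf("<lv_experiment> %s\n", x$name))
  print(x$result)
  if (length(x$extra)) {
    cat("extra:\n")
    utils::str(x$extra, give.attr = FALSE)
  }
  invisible(x)
}

#' @export
tidy.lv_experiment <- function(x, ...) x$result
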