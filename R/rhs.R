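#' Right-hand side of the cancer-healthy-immune system
#'
#' Evaluates the instantaneous derivatives of the three-compartment
#' Lotka-Volterra system at a state `(C, H, I)`:
#' cancer cells grow logistically toward `K1` and are suppressed by
#' competition with healthy cells (`alpha`) and immune killing (`beta`);
#' healthy cells grow logistically toward `K2` under competition from
#' cancer (`gamma`); the immune threshold decays with age (`r3`) and is
#' depleted by fighting cancer (`delta`).
#'
#' @param state Named numeric vector with elements `C`, `H`, `I` (finite,
#'   non-negative), or a one-row data frame with those columns.
#' @param params An [lv_params()] object.
#' @return Named numeric vector `c(dC, dH, dI)`.
#' @examples
#' p <- lv_fixture("case_I")
#' lv_rhs(c(C = 0.5, H = 9999, I = 5000), p)
#' @export
lv_rhs <- function(state, params) {
  stopifnot(inherits(params, "lv_params"))
  s <- as_state(state)
  if (!all(is.finite(s))) abort_invalid("state must be finite")
  with(params, {
    C <- s[["C"]]; H <- s[["H"]]; I <- s[["I"]]
    c(dC = r1 * C * (1 - C / K1) - alpha * C * H - beta * C * I,
      dH = r2 * H * (1 - H / K2) - gamma * H * C,
      dI = -r3 * I - delta * I * C)
  })
}

#' Right-hand side with mutational influx from healthy cells
#'
#' Variant in which new cancer cells arise by mutation of healthy cells:
#' the cancer equation gains the source term `r1 * p(t) * H`, where `p`
#' is the per-unit-time probability of mutational transition (so cancer
#' can grow from `C0 = 0`). Healthy-cell and immune equations are
#' unchanged.
#'
#' @inheritParams lv_rhs
#' @param p Mutation probability: a single number in \[0, 1) or a
#'   function of time returning such a number. Default 0.
#' @param t Time at which to evaluate `p` when it is a function.
#' @return Named numeric vector `c(dC, dH, dI)`.
#' @export
lv_rhs_mutation <- function(state, params, p = 0, t = 0) {
  base <- lv_rhs(state, params)
  pt <- if (is.function(p)) p(t) else p
  if (!is.numeric(pt) || !is.finite(pt) || pt < 0 || pt >= 1) {
    abort_invalid("mutation probability p(t) must lie in [0, 1)")
  }
  s <- as_state(state)
  base[["dC"]] <- base[["dC"]] + params$r1 * pt * s[["H"]]
  base
}

as_state <- function(state) {
  if (is.data.frame(state)) state <- unlist(state[1, c("C", "H", "I")])
  if (!is.numeric(state) || is.null(names(state)) ||
      !all(c("C", "H", "I") %in% names(state))) {
    abort_invalid("state must be a named numeric vector with C, H, I")
  }
  state[c("C", "H", "I")]
}

# deSolve-facing derivative closures ---------------------------------------

desolve_func <- function(params) {
  r1 <- params$r1; r2 <- params$r2; r3 <- params$r3
  K1 <- params$K1; K2 <- params$K2
  al <- params$alpha; be <- params$beta; ga <- params$gamma
  de <- params$delta
  function(t, y, parms) {
    C <- y[1L]; H <- y[2L]; I <- y[3L]
    list(c(r1 * C * (1 - C / K1) - al * C * H - be * C * I,
           r2 * H * (1 - H / K2) - ga * H * C,
           -r3 * I - de * I * C))
  }
}

desolve_func_hat <- function(hp) {
  function(t, y, parms) {
    C <- y[1L]; H <- y[2L]; I <- y[3L]
    list(c(hp$r1_hat * C * (1 - C) - hp$alpha_hat * C * H -
             hp$beta_hat * C * I,
           hp$r2_hat * H * (1 - H) - hp$gamma_hat * H * C,
           -hp$r3_hat * I - hp$delta_hat * I * C))
  }
}
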