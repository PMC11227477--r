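#' Dimensional model parameters
#'
#' Bundles the coefficients of the three-compartment cancer--healthy--immune
#' Lotka-Volterra system together with the species' lifespan and initial
#' state. The state variables are `C` (cancer cells), `H` (healthy cells)
#' and `I` (the immune-escape threshold, the declining competence level
#' below which cancer escapes immune control):
#'
#' \deqn{dC/dt = r_1 C (1 - C/K_1) - \alpha C H - \beta C I}
#' \deqn{dH/dt = r_2 H (1 - H/K_2) - \gamma H C}
#' \deqn{dI/dt = -r_3 I - \delta I C}
#'
#' Units: rates `r1, r2, r3` are 1/time, carrying capacities `K1, K2` and
#' all initial values are cell counts, interaction coefficients
#' `alpha, beta, gamma, delta` are 1/(time x cell), and `T` is the lifespan
#' in time units. Unit bookkeeping is documentation only; no runtime unit
#' system is imposed.
#'
#' Unless all three of `C0`, `H0`, `I0` are supplied, the initial state is
#' constructed from the initial cancer fraction `epsilon`:
#' `C0 = epsilon * K1`, `H0 = (1 - epsilon) * K2`, with `I0` required.
#' A meaningful upward crossing of `C` over `I` requires `C0 < I0` (`I0`
#' is the highest value the monotonically decaying threshold ever takes),
#' and this is enforced.
#'
#' `delta > 0` encodes net depletion of immune competence while fighting
#' cancer cells; `delta <= 0` is accepted but triggers a warning since the
#' model's qualitative analysis assumes net depletion.
#'
#' @param r1,r2,r3 Positive growth/decay rates (1/time) for cancer cells,
#'   healthy cells and the immune threshold.
#' @param K1,K2 Positive carrying capacities (cells) for cancer and
#'   healthy cells.
#' @param alpha,beta,gamma Non-negative interaction coefficients
#'   (1/(time x cell)).
#' @param delta Real interaction coefficient (1/(time x cell)); a warning
#'   is issued when `delta <= 0`.
#' @param T Positive lifespan (time units). Default 1.
#' @param I0 Positive initial immune threshold (cells).
#' @param C0,H0 Optional explicit initial cell counts; either both given
#'   (overriding `epsilon`) or both `NULL`.
#' @param epsilon Initial cancer fraction in (0, 0.1); default `1e-4`.
#' @param m Power-law exponent recorded when the parameters were generated
#'   from [scaling_constants()]; `NA` otherwise.
#'
#' @return An object of class `lv_params` (a named list).
#' @seealso [scale_params()], [nondimensionalize()], [lv_simulate()]
#' @examples
#' p <- lv_params(r1 = 10, r2 = 2, r3 = 2, K1 = 5000, K2 = 10000,
#'                alpha = 1e-4, beta = 1.5e-4, gamma = 1.2e-4,
#'                delta = 1e-3, I0 = 5000)
#' tidy(p)
#' @export
lv_params <- function(r1, r2, r3, K1, K2, alpha, beta, gamma, delta,
                      I0, T = 1, C0 = NULL, H0 = NULL, epsilon = 1e-4,
                      m = NA_real_) {
  num <- c(r1 = r1, r2 = r2, r3 = r3, K1 = K1, K2 = K2, alpha = alpha,
           beta = beta, gamma = gamma, delta = delta, I0 = I0, T = T)
  if (!all(is.finite(num))) {
    abort_invalid("all model parameters must be finite numbers")
  }
  pos <- c("r1", "r2", "r3", "K1", "K2", "T", "I0")
  if (any(num[pos] <= 0)) {
    abort_invalid(paste0("strictly positive values required for: ",
                         paste(pos[num[pos] <= 0], collapse = ", ")))
  }
  if (any(num[c("alpha", "beta", "gamma")] < 0)) {
    abort_invalid("alpha, beta, gamma must be non-negative")
  }
  if (delta <= 0) {
    rlang::warn("delta <= 0: the model assumes net immune depletion (delta > 0)",
                class = "petolv_delta_warning")
  }
  explicit <- !is.null(C0) && !is.null(H0)
  if (xor(is.null(C0), is.null(H0))) {
    abort_invalid("override C0 and H0 together, or neither")
  }
  if (!explicit) {
    check_epsilon(epsilon)
    C0 <- epsilon * K1
    H0 <- (1 - epsilon) * K2
  }
  if (!all(is.finite(c(C0, H0))) || C0 < 0 || H0 < 0) {
    abort_invalid("C0 and H0 must be finite and non-negative")
  }
  if (C0 >= I0) {
    abort_invalid("C0 < I0 is required (I0 is the highest immune threshold)")
  }
  structure(
    list(r1 = r1, r2 = r2, r3 = r3, K1 = K1, K2 = K2,
         alpha = alpha, beta = beta, gamma = gamma, delta = delta,
         T = T, C0 = C0, H0 = H0, I0 = I0,
         epsilon = if (explicit) NA_real_ else epsilon, m = m),
    class = "lv_params"
  )
}

#' Species-independent scaling constants
#'
#' The constants that generate one species' dimensional parameters from
#' its lifespan `T` through allometric power laws: cell counts scale as
#' `K1 = a T^m`, `K2 = b T^m`, `I0 = c T^m`; per-time rates scale as
#' `r1 = d/T`, `r2 = e/T`, `r3 = f/T`; and interaction coefficients as
#' `alpha = g T^-(m+1)`, `beta = h T^-(m+1)`, `gamma = k T^-(m+1)`,
#' `delta = l T^-(m+1)`. `d, e, f` are dimensionless; `a, b, c` carry
#' cells/time^m and `g, h, k, l` carry time^m/cells.
#'
#' When every species shares the same constants, the nondimensionalized
#' system is species-independent and all species share one rescaled
#' tipping time -- the model's sufficient condition for Peto's paradox.
#'
#' @param a,b,c Positive cell-count prefactors.
#' @param d,e,f Positive dimensionless rate constants.
#' @param g,h,k,l Positive interaction constants.
#' @param m Power-law exponent linking cell number to lifespan;
#'   default 4.76 (empirical mass-lifespan allometry).
#' @param epsilon Initial cancer fraction in (0, 0.1); default 1e-4.
#' @param q Per-unit-time cancer probability after tipping, in (0, 1];
#'   default 0.5.
#'
#' @return An object of class `lv_scaling` (a named list).
#' @seealso [scale_params()], [species_ensemble()]
#' @export
scaling_constants <- function(a, b, c, d, e, f, g, h, k, l,
                              m = 4.76, epsilon = 1e-4, q = 0.5) {
  num <- c(a = a, b = b, c = c, d = d, e = e, f = f, g = g, h = h,
           k = k, l = l, m = m, q = q)
  if (!all(is.finite(c(num, epsilon)))) {
    abort_invalid("all scaling constants must be finite numbers")
  }
  if (any(num <= 0)) {
    abort_invalid(paste0("strictly positive values required for: ",
                         paste(names(num)[num <= 0], collapse = ", ")))
  }
  if (q > 1) abort_invalid("q must lie in (0, 1]")
  check_epsilon(epsilon)
  structure(as.list(c(num[c("a", "b", "c", "d", "e", "f", "g", "h",
                            "k", "l", "m")], epsilon = epsilon,
                      q = num[["q"]])),
            class = "lv_scaling")
}

check_epsilon <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || !is.finite(epsilon) ||
      epsilon <= 0 || epsilon >= 0.1) {
    abort_invalid("epsilon must lie in (0, 0.1)")
  }
  invisible(epsilon)
}

abort_invalid <- function(msg) {
  rlang::abort(msg, class = "petolv_invalid_input")
}

#' Generate one species' parameters from its lifespan
#'
#' Applies the allometric power laws of [scaling_constants()] at lifespan
#' `T`: carrying capacities and the initial immune threshold scale as
#' `T^m`, rates as `1/T`, interactions as `T^-(m+1)`, and the initial
#' state is `C0 = epsilon K1`, `H0 = (1 - epsilon) K2`.
#'
#' @param constants An [scaling_constants()] object.
#' @param T Positive lifespan.
#' @param epsilon Optional override of the constants' initial cancer
#'   fraction.
#' @return An `lv_params` object; its `m` field records the exponent used.
#' @examples
#' sc <- scaling_constants(a = 5e4, b = 1e5, c = 5e4, d = 10, e = 2,
#'                         f = 2, g = 1e-5, h = 1.5e-5, k = 1.2e-5,
#'                         l = 1e-4)
#' scale_params(sc, T = 10)
#' @export
scale_params <- function(constants, T, epsilon = NULL) {
  stopifnot(inherits(constants, "lv_scaling"))
  if (!is.numeric(T) || length(T) != 1 || !is.finite(T) || T <= 0) {
    abort_invalid("lifespan T must be a single positive finite number")
  }
  eps <- if (is.null(epsilon)) constants$epsilon else epsilon
  with(constants, lv_params(
    r1 = d / T, r2 = e / T, r3 = f / T,
    K1 = a * T^m, K2 = b * T^m, I0 = c * T^m,
    alpha = g * T^(-(m + 1)), beta = h * T^(-(m + 1)),
    gamma = k * T^(-(m + 1)), delta = l * T^(-(m + 1)),
    T = T, epsilon = eps, m = m
  ))
}

#' Nondimensionalize a parameter set
#'
#' Rescales states by their characteristic sizes (`C` by `K1`, `H` by
#' `K2`, `I` by `I0`) and time by the lifespan `T`, giving the hatted
#' coefficients `alpha_hat = alpha K2 T`, `beta_hat = beta I0 T`,
#' `gamma_hat = gamma K1 T`, `delta_hat = delta K1 T` and
#' `ri_hat = ri T`, with rescaled initial state
#' `C0_tilde = C0/K1`, `H0_tilde = H0/K2` and `I0_tilde = 1` exactly.
#' The rescaled system lives on the unit lifespan `tau` in \[0, 1\].
#'
#' For parameters generated by [scale_params()] the hatted coefficients
#' are lifespan-free in closed form: `alpha_hat = g b`, `beta_hat = h c`,
#' `gamma_hat = k a`, `delta_hat = l a`, `r1_hat = d`, `r2_hat = e`,
#' `r3_hat = f`.
#'
#' @param params An `lv_params` object.
#' @return An object of class `lv_params_hat`.
#' @export
nondimensionalize <- function(params) {
  stopifnot(inherits(params, "lv_params"))
  with(params, {
    if (any(c(K1, K2, I0, T) <= 0)) {
      abort_invalid("characteristic scales K1, K2, I0, T must be positive")
    }
    structure(
      list(r1_hat = r1 * T, r2_hat = r2 * T, r3_hat = r3 * T,
           alpha_hat = alpha * K2 * T, beta_hat = beta * I0 * T,
           gamma_hat = gamma * K1 * T, delta_hat = delta * K1 * T,
           C0_tilde = C0 / K1, H0_tilde = H0 / K2, I0_tilde = 1),
      class = "lv_params_hat"
    )
  })
}

#' @export
print.lv_params <- function(x, ...) {
  cat("<lv_params> cancer-healthy-immune Lotka-Volterra parameters\n")
  cat(sprintf("  rates      r1=%g  r2=%g  r3=%g\n", x$r1, x$r2, x$r3))
  cat(sprintf("  capacities K1=%g  K2=%g\n", x$K1, x$K2))
  cat(sprintf("  coupling   alpha=%g  beta=%g  gamma=%g  delta=%g\n",
              x$alpha, x$beta, x$gamma, x$delta))
  cat(sprintf("  lifespan   T=%g\n", x$T))
  cat(sprintf("  initial    C0=%g  H0=%g  I0=%g\n", x$C0, x$H0, x$I0))
  invisible(x)
}

#' @export
print.lv_scaling <- function(x, ...) {
  cat("<lv_scaling> lifespan power-law constants\n")
  cat(sprintf("  counts a=%g b=%g c=%g  rates d=%g e=%g f=%g\n",
              x$a, x$b, x$c, x$d, x$e, x$f))
  cat(sprintf("  coupling g=%g h=%g k=%g l=%g  m=%g\n",
              x$g, x$h, x$k, x$l, x$m))
  cat(sprintf("  epsilon=%g  q=%g\n", x$epsilon, x$q))
  invisible(x)
}

#' @export
print.lv_params_hat <- function(x, ...) {
  cat("<lv_params_hat> dimensionless parameters on the unit lifespan\n")
  cat(sprintf("  r1_hat=%g r2_hat=%g r3_hat=%g\n",
              x$r1_hat, x$r2_hat, x$r3_hat))
  cat(sprintf("  alpha_hat=%g beta_hat=%g gamma_hat=%g delta_hat=%g\n",
              x$alpha_hat, x$beta_hat, x$gamma_hat, x$delta_hat))
  cat(sprintf("  C0_tilde=%g H0_tilde=%g I0_tilde=%g\n",
              x$C0_tilde, x$H0_tilde, x$I0_tilde))
  invisible(x)
}

#' Tidy parameter objects into term/value tibbles
#'
#' @param x An `lv_params`, `lv_scaling` or `lv_params_hat` object.
#' @param ... Unused.
#' @return A tibble with columns `term` and `value`.
#' @export
tidy.lv_params <- function(x, ...) {
  vals <- unlist(x, use.names = TRUE)
  tibble::tibble(term = names(vals), value = unname(vals))
}

#' @rdname tidy.lv_params
#' @export
tidy.lv_scaling <- tidy.lv_params

#' @rdname tidy.lv_params
#' @export
tidy.lv_params_hat <- tidy.lv_params
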