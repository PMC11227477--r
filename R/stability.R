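#' Equilibria of the cancer-healthy-immune system
#'
#' The system has four fixed points, all with the immune threshold at
#' `I* = 0` (the threshold only decays): the origin `(0, 0, 0)`, the
#' healthy-only state `(0, K2, 0)`, the cancer-only state `(K1, 0, 0)`,
#' and a cancer-healthy coexistence point
#' \deqn{\left(\frac{r_2 K_1 (r_1 - \alpha K_2)}{r_1 r_2 - \alpha\gamma K_1 K_2},\;
#'       \frac{r_1 K_2 (r_2 - \gamma K_1)}{r_1 r_2 - \alpha\gamma K_1 K_2},\; 0\right).}
#' The coexistence point exists (with both populations inside their
#' carrying capacities) iff `r1 - alpha*K2 >= 0`, `r2 - gamma*K1 >= 0`
#' and the denominator `r1*r2 - alpha*gamma*K1*K2` is strictly positive;
#' numerically the formula is only evaluated when the denominator
#' exceeds `1e-12 * r1 * r2`. At the doubly degenerate limit
#' `r1 = alpha*K2` and `r2 = gamma*K1` the fixed points form a whole
#' line segment `C*K2 + H*K1 = K1*K2` (0 < C < K1), reported as a
#' `degenerate_line` row.
#'
#' @param params An [lv_params()] object.
#' @param classify Fill eigenvalues and stability classes via
#'   [classify_equilibrium()] (default `TRUE`).
#' @param tol Eigenvalue real-part tolerance for classification.
#' @return A tibble of class `lv_equilibria` with columns `label`, `C`,
#'   `H`, `I`, `exists`, and (when classified) list-column `eigenvalues`
#'   and character `classification`
#'   (`"stable"`/`"unstable"`/`"non_hyperbolic"`), plus `note`.
#' @examples
#' equilibria(lv_fixture("case_I"))
#' @export
equilibria <- function(params, classify = TRUE, tol = 1e-9) {
  stopifnot(inherits(params, "lv_params"))
  p <- params
  disc1 <- p$r1 - p$alpha * p$K2
  disc2 <- p$r2 - p$gamma * p$K1
  den <- p$r1 * p$r2 - p$alpha * p$gamma * p$K1 * p$K2
  degenerate <- abs(disc1) <= 1e-12 * p$r1 && abs(disc2) <= 1e-12 * p$r2
  rows <- tibble::tibble(
    label = c("origin", "healthy_only", "cancer_only"),
    C = c(0, 0, p$K1), H = c(0, p$K2, 0), I = 0,
    exists = TRUE, note = "")
  if (degenerate) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      label = "degenerate_line", C = NA_real_, H = NA_real_, I = 0,
      exists = TRUE,
      note = "line of equilibria C*K2 + H*K1 = K1*K2, 0 < C < K1"))
  } else {
    co_exists <- disc1 >= 0 && disc2 >= 0 && den > 1e-12 * p$r1 * p$r2
    co <- if (co_exists) {
      c(p$r2 * p$K1 * disc1 / den, p$r1 * p$K2 * disc2 / den)
    } else c(NA_real_, NA_real_)
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      label = "coexistence", C = co[1], H = co[2], I = 0,
      exists = co_exists,
      note = if (co_exists) "" else "existence conditions not met"))
  }
  if (classify) {
    cls <- purrr::pmap(rows, function(label, C, H, I, exists, note) {
      if (label == "degenerate_line" || !exists) {
        list(eigenvalues = complex(0),
             classification = if (label == "degenerate_line")
               "non_hyperbolic" else NA_character_)
      } else {
        classify_equilibrium(c(C = C, H = H, I = I), params, tol = tol)
      }
    })
    rows$eigenvalues <- purrr::map(cls, "eigenvalues")
    rows$classification <- purrr::map_chr(cls, "classification")
  }
  class(rows) <- c("lv_equilibria", class(rows))
  rows
}

#' Jacobian of the model right-hand side
#'
#' Analytic linearization at an arbitrary state, rows ordered (C, H, I).
#'
#' @param state Named numeric vector with `C`, `H`, `I`.
#' @param params An [lv_params()] object.
#' @return A 3x3 numeric matrix with dimnames `C`, `H`, `I`.
#' @export
lv_jacobian <- function(state, params) {
  stopifnot(inherits(params, "lv_params"))
  s <- as_state(state)
  if (!all(is.finite(s))) abort_invalid("state must be finite")
  C <- s[["C"]]; H <- s[["H"]]; I <- s[["I"]]
  with(params, matrix(
    c(r1 * (1 - 2 * C / K1) - alpha * H - beta * I, -alpha * C, -beta * C,
      -gamma * H, r2 * (1 - 2 * H / K2) - gamma * C, 0,
      -delta * I, 0, -r3 - delta * C),
    nrow = 3, byrow = TRUE, dimnames = list(c("C", "H", "I"),
                                            c("C", "H", "I"))))
}

#' Eigenvalue stability classification of a fixed point
#'
#' Computes the eigenvalues of the Jacobian at the point and classifies:
#' `stable` when all real parts are below `-tol`, `unstable` when any
#' real part exceeds `+tol`, `non_hyperbolic` otherwise.
#'
#' @param point Named numeric vector `c(C, H, I)` of an equilibrium.
#' @param params An [lv_params()] object.
#' @param tol Real-part tolerance (default `1e-9`).
#' @return List with `eigenvalues` (complex, length 3) and
#'   `classification`.
#' @export
classify_equilibrium <- function(point, params, tol = 1e-9) {
  J <- lv_jacobian(point, params)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- as.complex(ev)
  re <- Re(ev)
  classification <- if (all(re < -tol)) "stable"
  else if (any(re > tol)) "unstable"
  else "non_hyperbolic"
  list(eigenvalues = ev, classification = classification)
}

#' @export
print.lv_equilibria <- function(x, ...) {
  cat("<lv_equilibria> fixed points of the cancer-healthy-immune system\n")
  NextMethod()
}
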