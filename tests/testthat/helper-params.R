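# Shared helpers: quick constructors and a seeded positive parameter draw.

case_I_params <- function() lv_fixture("case_I")

# Log-uniform positive parameter draw covering stable/unstable regimes of
# the boundary equilibria. Assumes the caller controls the RNG seed.
draw_params <- function() {
  suppressWarnings(lv_params(
    r1 = 10^runif(1, -1, 2), r2 = 10^runif(1, -1, 2),
    r3 = 10^runif(1, -1, 2),
    K1 = 10^runif(1, 2, 5), K2 = 10^runif(1, 2, 5),
    alpha = 10^runif(1, -6, -2), beta = 10^runif(1, -6, -2),
    gamma = 10^runif(1, -6, -2), delta = 10^runif(1, -6, -2),
    I0 = 10^runif(1, 2, 5)))
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual - expected) <=
                    rel_tol * pmax(abs(expected), .Machine$double.eps)),
              label = sprintf("max rel err %.3g within %.1g",
                              max(abs(actual - expected) /
                                    pmax(abs(expected), .Machine$double.eps)),
                              rel_tol))
}
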