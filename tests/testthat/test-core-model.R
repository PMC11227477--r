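test_that("right-hand side matches hand arithmetic on the model equations", {
  p <- case_I_params()
  # zero state and capacity state annihilate every term
  expect_equal(unname(lv_rhs(c(C = 0, H = 0, I = 0), p)), c(0, 0, 0))
  expect_equal(unname(lv_rhs(c(C = p$K1, H = 0, I = 0), p)), c(0, 0, 0))
  # direct term-by-term arithmetic oracle at a generic state
  C <- 0.5; H <- 9999; I <- 5000
  expected <- c(
    10 * C * (1 - C / 5000) - 1e-4 * C * H - 1.5e-4 * C * I,
    2 * H * (1 - H / 10000) - 1.2e-4 * H * C,
    -2 * I - 1e-3 * I * C)
  expect_equal(expected, c(4.12455, 1.39986, -10002.5))  # frozen oracle values
  expect_equal(unname(lv_rhs(c(C = C, H = H, I = I), p)), expected)
  expect_error(lv_rhs(c(C = Inf, H = 1, I = 1), p),
               class = "petolv_invalid_input")
})

test_that("mutational influx adds exactly r1*p*H to the cancer equation", {
  p <- case_I_params()
  states <- list(c(C = 0.5, H = 9999, I = 5000),
                 c(C = 0, H = p$H0, I = p$I0),
                 c(C = 321, H = 4567, I = 89))
  for (s in states) {
    expect_identical(lv_rhs_mutation(s, p, p = 0), lv_rhs(s, p))
    diff <- lv_rhs_mutation(s, p, p = 1e-6) - lv_rhs(s, p)
    expect_equal(unname(diff), c(p$r1 * 1e-6 * s[["H"]], 0, 0))
  }
  # growth from a null cancer population
  s0 <- c(C = 0, H = p$H0, I = p$I0)
  expect_equal(lv_rhs_mutation(s0, p, p = 0.01)[["dC"]],
               p$r1 * 0.01 * p$H0)
  # time-dependent p and domain validation
  expect_equal(lv_rhs_mutation(s0, p, p = function(t) t / 10, t = 0.5)[["dC"]],
               p$r1 * 0.05 * p$H0)
  expect_error(lv_rhs_mutation(s0, p, p = 1.2),
               class = "petolv_invalid_input")
  expect_error(lv_rhs_mutation(s0, p, p = -0.1),
               class = "petolv_invalid_input")
})

test_that("lifespan power laws generate the dimensional coefficients", {
  sc <- lv_fixture("fig8")
  p1 <- scale_params(sc, T = 1)
  # at T = 1 every power factor is 1
  expect_equal(p1$K2, 1e5)
  expect_equal(p1$K1, 5e4)
  expect_equal(p1$r1, 10)
  expect_equal(p1$r2, 2)
  expect_equal(p1$alpha, 1e-5)
  expect_equal(p1$C0, 1e-4 * 5e4)
  expect_equal(p1$H0, (1 - 1e-4) * 1e5)
  # T = 10 checked in log space against the closed-form exponents
  p10 <- scale_params(sc, T = 10)
  expect_equal(log10(p10$K2), log10(1e5) + 4.76)
  expect_equal(log10(p10$alpha), log10(1e-5) - 5.76)
  expect_equal(p10$r3, 2 / 10)
  expect_equal(p10$T, 10)
  expect_equal(p10$m, 4.76)
  expect_error(scale_params(sc, T = -1), class = "petolv_invalid_input")
})

test_that("nondimensionalization gives the hatted coefficients", {
  hat <- nondimensionalize(case_I_params())
  expect_equal(hat$alpha_hat, 1e-4 * 10000 * 1)
  expect_equal(hat$beta_hat, 1.5e-4 * 5000 * 1)
  expect_equal(hat$gamma_hat, 1.2e-4 * 5000 * 1)
  expect_equal(hat$delta_hat, 1e-3 * 5000 * 1)
  expect_equal(c(hat$r1_hat, hat$r2_hat, hat$r3_hat), c(10, 2, 2))
  expect_identical(hat$I0_tilde, 1)
  expect_equal(hat$C0_tilde, 1e-4)
  # identity characteristic scales leave coefficients untouched
  p <- lv_params(r1 = 0.3, r2 = 0.7, r3 = 0.2, K1 = 1, K2 = 1,
                 alpha = 0.11, beta = 0.13, gamma = 0.17, delta = 0.19,
                 I0 = 1, T = 1, epsilon = 0.01)
  h <- nondimensionalize(p)
  expect_equal(c(h$alpha_hat, h$beta_hat, h$gamma_hat, h$delta_hat),
               c(0.11, 0.13, 0.17, 0.19))
})

test_that("hatted coefficients from power-law parameters are lifespan-free", {
  sc <- lv_fixture("fig8")
  target <- c(sc$g * sc$b, sc$h * sc$c, sc$k * sc$a, sc$l * sc$a,
              sc$d, sc$e, sc$f)
  for (T in c(0.37, 1, 12.3, 250)) {
    hat <- nondimensionalize(scale_params(sc, T))
    got <- c(hat$alpha_hat, hat$beta_hat, hat$gamma_hat, hat$delta_hat,
             hat$r1_hat, hat$r2_hat, hat$r3_hat)
    expect_rel_equal(got, target, 1e-12)
    expect_identical(hat$I0_tilde, 1)
  }
})

test_that("dimensional and dimensionless trajectories coincide after rescaling", {
  sc <- lv_fixture("fig8")
  hat <- nondimensionalize(scale_params(sc, T = 1))
  traj_hat <- lv_simulate(hat, n = 201)
  for (T in c(1, 10)) {
    p <- scale_params(sc, T)
    traj <- lv_simulate(p, n = 201)
    expect_rel_equal(traj$C / p$K1, traj_hat$C, 1e-6)
    expect_rel_equal(traj$H / p$K2, traj_hat$H, 1e-6)
    expect_rel_equal(traj$I / p$I0, traj_hat$I, 1e-6)
    expect_equal(traj$t / p$T, traj_hat$t)
  }
})

test_that("parameter validation enforces the model's domain", {
  expect_error(lv_params(r1 = -1, r2 = 2, r3 = 2, K1 = 5000, K2 = 1e4,
                         alpha = 1e-4, beta = 1e-4, gamma = 1e-4,
                         delta = 1e-3, I0 = 5000),
               class = "petolv_invalid_input")
  expect_warning(lv_params(r1 = 1, r2 = 2, r3 = 2, K1 = 5000, K2 = 1e4,
                           alpha = 1e-4, beta = 1e-4, gamma = 1e-4,
                           delta = -1e-3, I0 = 5000),
                 class = "petolv_delta_warning")
  # upward crossing needs C0 below the intact immune threshold
  expect_error(lv_params(r1 = 1, r2 = 2, r3 = 2, K1 = 5000, K2 = 1e4,
                         alpha = 1e-4, beta = 1e-4, gamma = 1e-4,
                         delta = 1e-3, I0 = 5000, C0 = 6000, H0 = 1e4),
               class = "petolv_invalid_input")
  expect_error(lv_params(r1 = 1, r2 = 2, r3 = 2, K1 = 5000, K2 = 1e4,
                         alpha = 1e-4, beta = 1e-4, gamma = 1e-4,
                         delta = 1e-3, I0 = 5000, epsilon = 0.5),
               class = "petolv_invalid_input")
  expect_error(scaling_constants(a = 1, b = 1, c = 1, d = 0, e = 1, f = 1,
                                 g = 1, h = 1, k = 1, l = 1),
               class = "petolv_invalid_input")
})

test_that("parameter objects round-trip through JSON and YAML losslessly", {
  objects <- list(case_I_params(), lv_fixture("fig8"),
                  nondimensionalize(lv_fixture("fig11")))
  for (obj in objects) {
    for (ext in c(".json", ".yaml")) {
      path <- withr::local_tempfile(fileext = ext)
      write_params(obj, path)
      back <- read_params(path)
      expect_identical(class(back), class(obj))
      expect_identical(unclass(back)[names(unclass(obj))], unclass(obj))
    }
  }
})
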