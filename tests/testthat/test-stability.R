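test_that("the coexistence point matches its closed form and zeroes the RHS", {
  p <- case_I_params()
  eq <- equilibria(p)
  co <- eq[eq$label == "coexistence", ]
  # closed form evaluated by independent arithmetic:
  # disc1 = 10 - 1e-4*1e4 = 9, disc2 = 2 - 1.2e-4*5e3 = 1.4,
  # den = 20 - 1e-4*1.2e-4*5e3*1e4 = 19.4
  expect_equal(co$C, 2 * 5000 * 9 / 19.4)
  expect_equal(co$H, 10 * 10000 * 1.4 / 19.4)
  expect_equal(co$C, 4639.175, tolerance = 1e-6)
  expect_equal(co$H, 7216.495, tolerance = 1e-6)
  res <- lv_rhs(c(C = co$C, H = co$H, I = 0), p)
  expect_lt(max(abs(res)), 1e-8 * max(p$r1 * co$C, p$r2 * co$H))
  # the three boundary points always zero the RHS too
  for (i in 1:3) {
    resi <- lv_rhs(c(C = eq$C[i], H = eq$H[i], I = eq$I[i]), p)
    expect_equal(unname(resi), c(0, 0, 0))
  }
})

test_that("coexistence degenerates onto the boundary points at the limits", {
  # r1 = alpha*K2: coexistence collapses onto the healthy-only point
  p <- lv_params(r1 = 1, r2 = 2, r3 = 2, K1 = 5000, K2 = 10000,
                 alpha = 1 / 10000, beta = 1.5e-4, gamma = 1.2e-4,
                 delta = 1e-3, I0 = 5000)
  co <- dplyr::filter(equilibria(p, classify = FALSE),
                      label == "coexistence")
  expect_identical(c(co$C, co$H), c(0, 10000))
  # r2 = gamma*K1: coexistence collapses onto the cancer-only point
  p2 <- lv_params(r1 = 10, r2 = 5000 * 1.2e-4, r3 = 2, K1 = 5000,
                  K2 = 10000, alpha = 1e-4, beta = 1.5e-4,
                  gamma = 1.2e-4, delta = 1e-3, I0 = 5000)
  co2 <- dplyr::filter(equilibria(p2, classify = FALSE),
                       label == "coexistence")
  expect_identical(c(co2$C, co2$H), c(5000, 0))
  # both limits at once: a whole line of equilibria
  p3 <- lv_params(r1 = 1, r2 = 0.6, r3 = 2, K1 = 5000, K2 = 10000,
                  alpha = 1e-4, beta = 1.5e-4, gamma = 1.2e-4,
                  delta = 1e-3, I0 = 5000)
  eq3 <- equilibria(p3)
  line <- eq3[eq3$label == "degenerate_line", ]
  expect_identical(nrow(line), 1L)
  expect_identical(line$classification, "non_hyperbolic")
  expect_match(line$note, "line of equilibria")
  # points on the line C*K2 + H*K1 = K1*K2 are genuine equilibria
  for (C in c(1000, 2500, 4000)) {
    H <- (p3$K1 * p3$K2 - C * p3$K2) / p3$K1
    expect_equal(unname(lv_rhs(c(C = C, H = H, I = 0), p3)), c(0, 0, 0))
  }
})

test_that("the analytic Jacobian agrees with central finite differences", {
  p <- case_I_params()
  expect_equal(lv_jacobian(c(C = 0, H = 0, I = 0), p),
               diag(c(p$r1, p$r2, -p$r3)), ignore_attr = "dimnames")
  J_cap <- lv_jacobian(c(C = p$K1, H = 0, I = 0), p)
  expect_equal(J_cap["C", "C"], -p$r1)
  expect_equal(J_cap["I", "I"], -p$r3 - p$delta * p$K1)
  withr::with_seed(11, {
    for (rep in 1:20) {
      s <- c(C = runif(1, 0, 6000), H = runif(1, 0, 12000),
             I = runif(1, 0, 6000))
      J <- lv_jacobian(s, p)
      fd <- matrix(0, 3, 3)
      for (j in 1:3) {
        hstep <- max(1e-4, 1e-6 * abs(s[j]))
        sp <- s; sm <- s
        sp[j] <- s[j] + hstep; sm[j] <- s[j] - hstep
        fd[, j] <- (lv_rhs(sp, p) - lv_rhs(sm, p)) / (2 * hstep)
      }
      expect_rel_equal(as.numeric(J)[abs(fd) > 0],
                       as.numeric(fd)[abs(fd) > 0], 1e-6)
      expect_true(all(J[as.numeric(fd) == 0] == 0))
    }
  })
})

test_that("eigenvalue classification reproduces the known stability facts", {
  # one of each regime, classified from scratch
  p <- case_I_params()
  eq <- equilibria(p)
  expect_identical(eq$classification[eq$label == "origin"], "unstable")
  expect_identical(eq$classification[eq$label == "coexistence"], "stable")
  # strongly immune-suppressed regime: r1 < alpha*K2
  p_sup <- lv_params(r1 = 1, r2 = 2, r3 = 2, K1 = 5000, K2 = 10000,
                     alpha = 1e-3, beta = 1.5e-4, gamma = 1.2e-4,
                     delta = 1e-3, I0 = 5000)
  expect_lt(p_sup$r1 - p_sup$alpha * p_sup$K2, 0)
  eq_sup <- equilibria(p_sup)
  expect_identical(eq_sup$classification[eq_sup$label == "healthy_only"],
                   "stable")
  expect_false(any(eq_sup$classification[
    eq_sup$label %in% c("origin", "cancer_only")] == "stable"))
})

test_that("stability statements hold over 200 random positive parameter draws", {
  withr::with_seed(7, {
    for (i in 1:200) {
      p <- draw_params()
      eq <- equilibria(p)
      disc1 <- p$r1 - p$alpha * p$K2
      disc2 <- p$r2 - p$gamma * p$K1
      expect_identical(eq$classification[eq$label == "origin"], "unstable")
      expect_identical(eq$classification[eq$label == "healthy_only"],
                       if (disc1 < 0) "stable" else "unstable")
      expect_identical(eq$classification[eq$label == "cancer_only"],
                       if (disc2 < 0) "stable" else "unstable")
      boundary <- eq[eq$label %in% c("origin", "healthy_only",
                                     "cancer_only"), ]
      if (disc1 < 0 && disc2 >= 0) {
        expect_identical(boundary$label[boundary$classification == "stable"],
                         "healthy_only")
      }
      if (disc2 < 0 && disc1 >= 0) {
        expect_identical(boundary$label[boundary$classification == "stable"],
                         "cancer_only")
      }
      co <- eq[eq$label == "coexistence", ]
      if (isTRUE(co$exists)) {
        expect_identical(co$classification, "stable")
        res <- lv_rhs(c(C = co$C, H = co$H, I = 0), p)
        expect_lt(max(abs(res)), 1e-8 * max(p$r1 * co$C, p$r2 * co$H, 1))
      }
    }
  })
})

test_that("the coexistence cancer population vanishes continuously at the boundary", {
  # r1 decreasing toward alpha*K2 = 1 from above
  C_star <- vapply(c(1.5, 1.1, 1.01, 1.001, 1.0001), function(r1) {
    p <- lv_params(r1 = r1, r2 = 2, r3 = 2, K1 = 5000, K2 = 10000,
                   alpha = 1e-4, beta = 1.5e-4, gamma = 1.2e-4,
                   delta = 1e-3, I0 = 5000)
    eq <- equilibria(p, classify = FALSE)
    eq$C[eq$label == "coexistence"]
  }, numeric(1))
  expect_true(all(diff(C_star) < 0))
  expect_lt(C_star[length(C_star)], 1)
})
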