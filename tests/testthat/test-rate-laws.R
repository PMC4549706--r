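test_that("mm_rate evaluates the inhibition rate laws correctly", {
  # zero substrate gives zero rate under every modality
  for (m in c("competitive", "noncompetitive", "uncompetitive")) {
    expect_equal(mm_rate(0, 1e-6, Vmax = 1, Km = 1e-5, Ki = 1e-7, modality = m), 0)
  }
  expect_equal(mm_rate(0, 1e-6, Vmax = 1, Km = 1e-5, modality = "mixed",
                       Kic = 1e-7, Kiu = 2e-7), 0)
  # Michaelis point without inhibitor
  expect_equal(mm_rate(1e-5, 0, Vmax = 2, Km = 1e-5, Ki = 1e-7,
                       modality = "competitive"), 1)
  # competitive at I = Ki and S = Km: Vmax S/(2 Km + S) = Vmax/3
  expect_equal(mm_rate(80e-6, 394.7e-9, Vmax = 1, Km = 80e-6, Ki = 394.7e-9,
                       modality = "competitive"), 1 / 3)
  expect_error(mm_rate(1e-5, 1e-6, Vmax = -1, Km = 1e-5, Ki = 1e-7,
                       modality = "competitive"), "Vmax")
  expect_error(mm_rate(1e-5, 1e-6, Vmax = 1, Km = 1e-5, Ki = 1e-7,
                       modality = "cooperative"), "modality")
})

test_that("mm_rate is monotone increasing in S and non-increasing in I", {
  S <- seq(1e-6, 2e-4, length.out = 40)
  I <- seq(0, 5e-6, length.out = 40)
  for (m in c("competitive", "noncompetitive", "uncompetitive")) {
    vS <- mm_rate(S, 1e-7, Vmax = 1, Km = 8e-5, Ki = 4e-7, modality = m)
    vI <- mm_rate(8e-5, I, Vmax = 1, Km = 8e-5, Ki = 4e-7, modality = m)
    expect_true(all(diff(vS) > 0), info = m)
    expect_true(all(diff(vI) < 0), info = m)
  }
})

test_that("double-reciprocal transform has the textbook convergence pattern", {
  S <- seq(20, 120, by = 20) * 1e-6
  Ilev <- c(0, 0.5, 1, 2) * 1e-6
  # competitive: all 1/v intercepts equal 1/Vmax
  ints <- sapply(Ilev, function(i) {
    v <- mm_rate(S, i, Vmax = 3, Km = 80e-6, Ki = 4e-7, modality = "competitive")
    coef(lm(I(1 / v) ~ I(1 / S)))[["(Intercept)"]]
  })
  expect_equal(ints, rep(1 / 3, length(Ilev)), tolerance = 1e-12)
  # noncompetitive: lines cross the 1/S axis at -1/Km
  xint <- sapply(Ilev, function(i) {
    v <- mm_rate(S, i, Vmax = 3, Km = 80e-6, Ki = 4e-7, modality = "noncompetitive")
    cf <- coef(lm(I(1 / v) ~ I(1 / S)))
    -cf[["(Intercept)"]] / cf[["I(1/S)"]]
  })
  expect_equal(xint, rep(-1 / 80e-6, length(Ilev)), tolerance = 1e-9)
})

test_that("slow-binding progress curve matches its limits and hand values", {
  # no slow phase: pure line, kobs irrelevant
  expect_equal(slow_binding_progress(50, 2, 2, 0.01), 100)
  # kobs -> 0 limit approaches v0 * t
  expect_equal(slow_binding_progress(100, 1, 0.2, 1e-9), 100, tolerance = 1e-6)
  # direct evaluation
  expect_equal(slow_binding_progress(100, 1, 0.2, 0.01),
               20 + 80 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(slow_binding_progress(100, 1, 0.2, 0.01), 70.5696,
               tolerance = 1e-4)
  expect_equal(slow_binding_progress(0, 1, 0.2, 0.01), 0)
  expect_error(slow_binding_progress(10, 1, 0.2, -0.01), "kobs")
})

test_that("progress model agrees with ODE integration of the binding scheme", {
  skip_if_not_installed("deSolve")
  # Two-state scheme: EI forms at k+0_app * I and decays at k-0, with the
  # instantaneous rate proportional to free enzyme. Parameterised by
  # (v0, vs, kobs): kon_I = kobs (1 - vs/v0), koff = kobs vs/v0.
  cases <- expand.grid(v0 = c(1, 1e-8), vs_frac = c(0.1, 0.5),
                       kobs = c(0.005, 0.02, 0.1))
  for (i in seq_len(nrow(cases))) {
    v0 <- cases$v0[i]
    vs <- cases$vs_frac[i] * v0
    kobs <- cases$kobs[i]
    kon_I <- kobs * (1 - vs / v0)
    koff <- kobs * vs / v0
    times <- seq(0, 400, by = 2)
    sol <- deSolve::lsoda(
      c(ei = 0, p = 0), times,
      function(t, y, parms) {
        list(c(kon_I * (1 - y[1]) - koff * y[1],  # bound fraction
               v0 * (1 - y[1])))                  # turnover by free enzyme
      }, parms = NULL, rtol = 1e-10, atol = 1e-12)
    expect_equal(slow_binding_progress(times[-1], v0, vs, kobs),
                 sol[-1, "p"], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("kobs law reproduces hand arithmetic and its S-dependence", {
  # I = 0 returns the dissociation constant alone
  expect_equal(kobs_law(0, 1e-5, 6.6e5, 0.00271, modality = "noncompetitive"),
               0.00271)
  # noncompetitive at 50 nM with the reference constants (nM units)
  expect_equal(kobs_law(50, 60, K_PLUS0_NC, K_MINUS0_NC,
                        modality = "noncompetitive"), 0.03571)
  # competitive at S = Km halves the association term
  expect_equal(kobs_law(100, 80, K_PLUS0_C, K_MINUS0_C, Km = 80,
                        modality = "competitive"),
               K_MINUS0_C + 0.00038 * 100 / 2)
  # competitive at S = 0 equals noncompetitive
  expect_equal(kobs_law(25, 0, 6.6e5, 0.00271, Km = 8e-5, modality = "competitive"),
               kobs_law(25, 0, 6.6e5, 0.00271, modality = "noncompetitive"))
  # competitive kobs strictly decreasing in S at fixed I > 0
  ks <- kobs_law(50e-9, seq(1e-5, 2e-4, length.out = 20), 6.6e5, 0.00271,
                 Km = 8e-5, modality = "competitive")
  expect_true(all(diff(ks) < 0))
  expect_error(kobs_law(1, 1, 1, 1, modality = "mixed"), "modality")
})

test_that("generated curves satisfy the vs/v0 steady-state identity", {
  d <- ref_designs$lead_dbh2_slow
  tr <- ref_truths$lead_dbh2_slow
  curves <- generate_progress_curves(d, tr, noise = list(sigma_frac = 0), seed = 3)
  man <- attr(curves, "truth")
  man <- man[man$I > 0, ]
  Ki <- tr$k_minus0 / tr$k_plus0
  Ki_app <- Ki * (1 + man$S / tr$Km)
  expect_equal(man$vs, man$v0 / (1 + man$I / Ki_app), tolerance = 1e-12)
})
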