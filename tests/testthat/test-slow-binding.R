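test_that("kobs regression recovers exact apparent constants", {
  I_nM <- c(0, 15, 20, 30, 40, 50)
  kobs <- K_MINUS0_NC + K_PLUS0_NC * I_nM
  reg <- regress_kobs_vs_inhibitor(kobs, I_nM)
  expect_equal(reg$A, K_PLUS0_NC, tolerance = 1e-12)
  expect_equal(reg$B, K_MINUS0_NC, tolerance = 1e-12)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
  expect_error(regress_kobs_vs_inhibitor(c(1, 2), c(0, 1)), "insufficient")
})

test_that("noisy kobs regressions recover the association constant on average", {
  I_nM <- seq(0, 50, length.out = 6)
  A_hat <- sapply(1:200, function(s) {
    set.seed(s)
    kobs <- K_MINUS0_NC + K_PLUS0_NC * I_nM
    kobs <- kobs * (1 + rnorm(6, 0, 0.05))
    regress_kobs_vs_inhibitor(kobs, I_nM)$A
  })
  expect_equal(mean(A_hat), K_PLUS0_NC, tolerance = 0.05)
})

test_that("modality classification reads the A/B substrate signature", {
  S <- seq(20, 120, by = 20)  # uM
  Km <- 80
  # competitive signature: A = k+0/(1 + S/Km), B constant
  ab_comp <- data.frame(S = S, A = K_PLUS0_C / (1 + S / Km), B = K_MINUS0_C)
  expect_equal(classify_slow_binding_modality(ab_comp)$modality, "competitive")
  # flat A and B: noncompetitive
  ab_nc <- data.frame(S = S, A = K_PLUS0_NC, B = K_MINUS0_NC)
  expect_equal(classify_slow_binding_modality(ab_nc)$modality, "noncompetitive")
  # too few substrate levels: undetermined with a reason
  short <- classify_slow_binding_modality(ab_comp[1:2, ])
  expect_equal(short$modality, "undetermined")
  expect_match(short$evidence$conclusion[1], "fewer than 3")
})

test_that("pure noise in A and B is not mistaken for competition", {
  S <- seq(20, 120, by = 20)
  verdicts <- sapply(1:200, function(s) {
    set.seed(s)
    ab <- data.frame(S = S,
                     A = K_PLUS0_NC * (1 + rnorm(6, 0, 0.05)),
                     B = K_MINUS0_NC * (1 + rnorm(6, 0, 0.05)))
    classify_slow_binding_modality(ab)$modality
  })
  expect_lte(mean(verdicts == "competitive"), 0.07)
  expect_gt(mean(verdicts == "noncompetitive"), 0.5)
})

test_that("classifier type-I error under noncompetitive truth stays below 7%", {
  # 1000 simulated studies at the fixed-substrate-grid design: kobs drawn
  # around the noncompetitive law at each of 6 substrate levels, regressed
  # per level, then classified.
  S <- seq(20, 120, by = 20)
  I_nM <- c(15, 20, 30, 40, 50)
  verdicts <- vapply(1:1000, function(s) {
    set.seed(s)
    ab <- do.call(rbind, lapply(S, function(sl) {
      kobs <- (K_MINUS0_NC + K_PLUS0_NC * I_nM) * (1 + rnorm(5, 0, 0.05))
      r <- regress_kobs_vs_inhibitor(kobs, I_nM, S = sl)
      data.frame(S = sl, A = r$A, B = r$B, se_A = r$se_A, se_B = r$se_B)
    }))
    classify_slow_binding_modality(ab)$modality
  }, character(1))
  expect_lte(mean(verdicts == "competitive"), 0.07)
})

test_that("kobs horizontality across substrate levels flags noncompetitive", {
  S <- seq(4, 48, length.out = 6)
  expect_equal(test_kobs_horizontality(rep(0.025, 6) + c(1, -1, 2, -2, 1, -1) * 1e-4, S)$modality,
               "noncompetitive")
  ks <- kobs_law(35, S, K_PLUS0_C, K_MINUS0_C, Km = 10, modality = "competitive")
  expect_equal(test_kobs_horizontality(ks, S)$modality, "competitive")
  expect_error(test_kobs_horizontality(c(1, 2), c(1, 2)), "substrate levels")
})

test_that("microscopic constants reproduce the reference worked examples", {
  # noncompetitive: k+0 = A, k-0 = B (nM units in, nM units out)
  nc <- derive_microscopic_constants(
    data.frame(S = 60, A = K_PLUS0_NC, B = K_MINUS0_NC), "noncompetitive")
  expect_equal(nc$Ki, 4.106, tolerance = 1e-3)
  expect_equal(round(nc$Ki, 1), 4.1)

  # competitive with the reference constants: Ki = 13.4 nM at one decimal
  S <- seq(20, 120, by = 20)
  ab <- data.frame(S = S, A = K_PLUS0_C / (1 + S / 80), B = K_MINUS0_C)
  cp <- derive_microscopic_constants(ab, "competitive", Km = 80)
  expect_equal(cp$k_plus0, K_PLUS0_C, tolerance = 1e-10)
  expect_equal(cp$Ki, 13.395, tolerance = 1e-3)
  expect_equal(round(cp$Ki, 1), 13.4)

  # Km co-estimation from the 1/A line
  cp2 <- derive_microscopic_constants(ab, "competitive")
  expect_equal(cp2$Km, 80, tolerance = 1e-9)
  expect_equal(cp2$k_plus0, K_PLUS0_C, tolerance = 1e-9)

  # ratio identity: A = B = k gives Ki = 1 in the inhibitor unit used
  expect_equal(derive_microscopic_constants(
    data.frame(S = 1, A = 0.003, B = 0.003), "noncompetitive")$Ki, 1)

  expect_error(derive_microscopic_constants(
    data.frame(S = 1, A = -1, B = 0.01), "noncompetitive"), "non-positive|inconsistent")
})

test_that("Ki is invariant to the inhibitor concentration unit", {
  S <- seq(20, 120, by = 20)
  ab_nM <- data.frame(S = S, A = K_PLUS0_C / (1 + S / 80), B = K_MINUS0_C)
  ab_M <- transform(ab_nM, A = A * 1e9)  # I in molar: A scales by 1e9
  ki_nM <- derive_microscopic_constants(ab_nM, "competitive", Km = 80)$Ki
  ki_M <- derive_microscopic_constants(ab_M, "competitive", Km = 80)$Ki
  expect_equal(ki_M * 1e9, ki_nM, tolerance = 1e-12)
})

test_that("the full chain round-trips generator truth on noiseless studies", {
  # noncompetitive fixed-substrate study
  st <- analyze_slow_binding(generate_progress_curves(
    ref_designs$lead_cytc_slow, ref_truths$lead_cytc_slow,
    noise = list(sigma_frac = 0), seed = 1))
  expect_equal(st$modality, "noncompetitive")
  expect_equal(st$constants$k_plus0 * 1e-9, K_PLUS0_NC, tolerance = 1e-6)
  expect_equal(st$constants$k_minus0, K_MINUS0_NC, tolerance = 1e-6)
  expect_equal(st$constants$Ki * 1e9, 4.106, tolerance = 1e-3)

  # competitive multi-substrate study, Km fixed and co-estimated
  curves <- generate_progress_curves(
    ref_designs$lead_dbh2_slow, ref_truths$lead_dbh2_slow,
    noise = list(sigma_frac = 0), seed = 1)
  st2 <- analyze_slow_binding(curves, Km = 80e-6)
  expect_equal(st2$modality, "competitive")
  expect_equal(st2$constants$k_plus0 * 1e-9, K_PLUS0_C, tolerance = 1e-6)
  expect_equal(st2$constants$Ki * 1e9, 13.395, tolerance = 1e-3)
  st3 <- analyze_slow_binding(curves)
  expect_equal(st3$constants$Km * 1e6, 80, tolerance = 1e-4)
})
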