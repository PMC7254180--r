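# White-box and property tests of the discrete-event engine.

test_that("with all risks off and utility 1, the simulated QALY is the closed-form annuity", {
  par <- null_params()
  coh <- hand_cohort(5, status = "not_at_risk", age = 60)
  res <- simulate_cohort(coh, scenario_config(), par, seed = 1)
  expect_equal(res$mean_qaly, annuity(40), tolerance = 1e-6)
  # a CHR-P entrant with no transition/remission stays at utility 1 as well
  coh2 <- hand_cohort(5, status = "chr_p", age = 70)
  res2 <- simulate_cohort(coh2, scenario_config(), par, seed = 1)
  expect_equal(res2$mean_qaly, annuity(30), tolerance = 1e-6)
  # and at a zero discount rate the QALY is the survival time itself
  res3 <- simulate_cohort(coh, scenario_config(), par, seed = 1,
                          annual_rate = 0)
  expect_equal(res3$mean_qaly, 40, tolerance = 1e-6)
})

test_that("identical scenario and seed reproduce the arm result exactly", {
  coh <- generate_cohort(300, the_baseline, seed = 2)
  a <- simulate_cohort(coh, scenario_config(), the_baseline, seed = 9)
  b <- simulate_cohort(coh, scenario_config(), the_baseline, seed = 9)
  expect_identical(a$mean_cost, b$mean_cost)
  expect_identical(a$mean_qaly, b$mean_qaly)
  expect_identical(a$counts, b$counts)
})

test_that("mixed management with a zero CRHT fraction is bit-identical to hospital only", {
  coh <- generate_cohort(400, the_baseline, seed = 2)
  hosp <- simulate_cohort(coh, scenario_config(acute_management = "hospital_only"),
                          the_baseline, seed = 9)
  mix0 <- simulate_cohort(coh, scenario_config(acute_management = "mixed_crht",
                                               crht_fraction = 0),
                          the_baseline, seed = 9)
  expect_identical(hosp$mean_cost, mix0$mean_cost)
  expect_identical(hosp$mean_qaly, mix0$mean_qaly)
})

test_that("episode management changes costs but never the clinical course", {
  coh <- generate_cohort(800, the_baseline, seed = 4)
  hosp <- simulate_cohort(coh, scenario_config(acute_management = "hospital_only"),
                          the_baseline, seed = 9)
  mix <- simulate_cohort(coh, scenario_config(acute_management = "mixed_crht",
                                              crht_fraction = 0.5),
                         the_baseline, seed = 9)
  expect_identical(hosp$mean_qaly, mix$mean_qaly)
  expect_identical(hosp$counts, mix$counts)
  expect_lt(mix$mean_cost, hosp$mean_cost)
})

test_that("a null CBT effect leaves QALYs unchanged and costs differ by the course cost", {
  par <- the_baseline
  par["rr_cbt_transition"] <- 1
  coh <- generate_cohort(600, par, seed = 5)
  pau <- simulate_cohort(coh, scenario_config(chr_intervention = "pau"),
                         par, seed = 9)
  cbt <- simulate_cohort(coh, scenario_config(chr_intervention = "pau_plus_cbt"),
                         par, seed = 9)
  expect_equal(cbt$mean_qaly, pau$mean_qaly, tolerance = 1e-12)
  n_cbt <- cbt$counts[["cbt"]]
  expect_gt(n_cbt, 0)
  course <- 16 * 97  # charged at entry, so undiscounted
  expect_equal(cbt$mean_cost - pau$mean_cost, n_cbt * course / nrow(coh),
               tolerance = 1e-9)
})

test_that("transitions to psychosis are monotone in the CBT effect: prevent <= delay <= none", {
  coh <- generate_cohort(1500, the_baseline, seed = 6)
  runs <- lapply(list(
    none = scenario_config(chr_intervention = "pau"),
    delay = scenario_config(chr_intervention = "pau_plus_cbt",
                            cbt_effect_mode = "delay"),
    prevent = scenario_config(chr_intervention = "pau_plus_cbt",
                              cbt_effect_mode = "prevent")),
    function(s) simulate_cohort(coh, s, the_baseline, seed = 9))
  expect_lte(runs$prevent$counts[["transition"]],
             runs$delay$counts[["transition"]])
  expect_lte(runs$delay$counts[["transition"]],
             runs$none$counts[["transition"]])
  expect_lt(runs$prevent$counts[["transition"]],
            runs$none$counts[["transition"]])
})

test_that("treatment-resistance entries fall as antipsychotic persistence rises", {
  coh <- generate_cohort(800, the_baseline, seed = 8)
  # sweep the first-line discontinuation odds ratio across its observed range
  trs_entries <- vapply(c(1.0, 0.24, 0.11), function(or) {
    par <- the_baseline
    par["or_disc_haloperidol"] <- or
    r <- simulate_cohort(coh, scenario_config(fep_first_line = "haloperidol"),
                         par, seed = 9)
    r$counts[["trs"]]
  }, 0)
  expect_true(all(diff(trs_entries) <= 0))
  expect_lt(trs_entries[3], trs_entries[1])
})

test_that("every patient terminates within the horizon and counters are sane", {
  coh <- generate_cohort(200, the_baseline, seed = 10)
  ctx <- schizwdm:::.build_ctx(scenario_config(), the_baseline)
  for (i in seq_len(50)) {
    set.seed(i)
    r <- simulate_patient(coh[i, ], scenario_config(), the_baseline, ctx = ctx)
    expect_lte(r$t_end, 100 - coh$age_at_entry[i] + 1e-9)
    expect_gte(r$t_end, 0)
    expect_true(all(r$counts >= 0))
    segs <- r$trajectory$segments
    if (nrow(segs) > 1) {
      segs <- segs[order(segs[, "t0"]), , drop = FALSE]
      expect_true(all(segs[-1, "t0"] >= segs[-nrow(segs), "t1"] - 1e-9))
    }
    expect_true(all(segs[, "utility"] >= 0 & segs[, "utility"] <= 1))
    expect_true(all(r$trajectory$points[, "amount"] >= 0))
  }
})

test_that("family intervention reduces relapses under common random numbers", {
  coh <- generate_cohort(1200, the_baseline, seed = 12)
  ap <- simulate_cohort(coh, scenario_config(family_intervention = "ap_only"),
                        the_baseline, seed = 9)
  apfi <- simulate_cohort(coh, scenario_config(family_intervention = "ap_plus_fi"),
                          the_baseline, seed = 9)
  expect_lt(apfi$counts[["relapses"]], ap$counts[["relapses"]])
  expect_gt(apfi$counts[["fi"]], 0)
})
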