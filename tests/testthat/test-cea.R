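test_that("the ICER is the cost difference over the QALY difference", {
  r <- icer(list(mean_cost = 0, mean_qaly = 0),
            list(mean_cost = 1670, mean_qaly = 0.0071))
  expect_equal(r$icer, 1670 / 0.0071)
  same <- icer(list(mean_cost = 100, mean_qaly = 1),
               list(mean_cost = 100, mean_qaly = 1))
  expect_true(is.na(same$icer))
  expect_equal(same$status, "equivalent")
  expect_equal(same$delta_cost, 0)
  dom <- icer(list(mean_cost = 100, mean_qaly = 1),
              list(mean_cost = 50, mean_qaly = 1))
  expect_equal(dom$status, "dominating")
})

test_that("single and two-arm frontiers behave as expected", {
  one <- efficiency_frontier(data.frame(arm = "a", cost = 10, qaly = 1))
  expect_equal(one$status, "on_frontier")
  two <- efficiency_frontier(data.frame(arm = c("a", "b"),
                                        cost = c(10, 20), qaly = c(1, 1)))
  expect_equal(two$status[two$arm == "b"], "dominated")
  expect_equal(two$label[two$arm == "a"], "dominating")
})

test_that("the frontier algorithm matches the brute-force mixture oracle", {
  set.seed(2024)
  n_fail <- 0
  for (rep in 1:10000) {
    m <- sample(2:6, 1)
    df <- data.frame(arm = paste0("a", seq_len(m)),
                     cost = runif(m, 0, 100), qaly = runif(m, 0, 10))
    got <- efficiency_frontier(df)
    want <- frontier_oracle(df)
    if (!identical(got$status, want)) n_fail <- n_fail + 1
  }
  expect_equal(n_fail, 0)
})

test_that("ICERs strictly increase along any returned frontier", {
  set.seed(7)
  for (rep in 1:200) {
    m <- sample(3:8, 1)
    df <- data.frame(arm = paste0("a", seq_len(m)),
                     cost = runif(m, 0, 100), qaly = runif(m, 0, 10))
    fr <- efficiency_frontier(df)
    on <- fr[fr$status == "on_frontier", ]
    on <- on[order(on$cost), ]
    ic <- on$icer[!is.na(on$icer)]
    if (length(ic) > 1) expect_true(all(diff(ic) > 0))
    if (nrow(on) > 1) expect_true(all(diff(on$qaly) > 0))
  }
})

test_that("net monetary benefit is linear in willingness to pay", {
  expect_equal(net_monetary_benefit(list(mean_cost = 0, mean_qaly = 1), 20000),
               20000)
  expect_equal(net_monetary_benefit(list(mean_cost = 20000, mean_qaly = 1),
                                    20000), 0)
})

test_that("the NMB argmax lies on the efficiency frontier", {
  set.seed(31)
  for (rep in 1:200) {
    m <- sample(3:6, 1)
    df <- data.frame(arm = paste0("a", seq_len(m)),
                     cost = runif(m, 0, 100), qaly = runif(m, 0, 10))
    fr <- efficiency_frontier(df)
    wtp <- runif(1, 0, 50)
    nmb <- wtp * df$qaly - df$cost
    best <- df$arm[which.max(nmb)]
    expect_equal(fr$status[fr$arm == best], "on_frontier")
  }
})

test_that("CEAC probabilities sum to 1 at every willingness to pay", {
  set.seed(5)
  draws <- do.call(rbind, lapply(1:40, function(d)
    data.frame(draw = d, arm = c("a", "b", "c"),
               cost = runif(3, 0, 100), qaly = runif(3, 0, 10))))
  cc <- ceac_from_draws(draws, wtp = c(0, 10, 20, 50))
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_equal(unname(sums), rep(1, 4), ignore_attr = TRUE)
})

test_that("an arm cheaper and more effective in every draw wins the whole CEAC", {
  draws <- do.call(rbind, lapply(1:10, function(d)
    data.frame(draw = d, arm = c("a", "b"),
               cost = c(10, 20) + d, qaly = c(2, 1))))
  cc <- ceac_from_draws(draws, wtp = c(0, 20000))
  expect_equal(cc$probability[cc$arm == "a"], c(1, 1))
  expect_equal(cc$probability[cc$arm == "b"], c(0, 0))
})

test_that("exact NMB ties split the probability evenly", {
  draws <- data.frame(draw = 1, arm = c("a", "b"),
                      cost = c(10, 10), qaly = c(1, 1))
  cc <- ceac_from_draws(draws, wtp = 20000)
  expect_equal(cc$probability, c(0.5, 0.5))
})

test_that("a degenerate all-fixed registry gives an all-or-nothing CEAC", {
  reg <- as.data.frame(the_registry)
  reg$family <- "fixed"
  reg$param1 <- NA; reg$param2 <- NA
  f <- tempfile(fileext = ".csv")
  utils::write.csv(reg, f, row.names = FALSE)
  fixed_reg <- load_registry(f)
  scen <- list(hosp = scenario_config(acute_management = "hospital_only"),
               mix = scenario_config(acute_management = "mixed_crht"))
  psa <- run_psa(scen, fixed_reg, k_samples = 3, n_patients = 150, seed = 1)
  expect_true(all(psa$ceac$probability %in% c(0, 1)))
  # every draw identical
  expect_equal(length(unique(round(psa$draws$cost[psa$draws$arm == "hosp"], 6))), 1)
})

test_that("one-way sensitivity analysis at the baseline value reproduces the base case", {
  scen <- list(ap = scenario_config(family_intervention = "ap_only"),
               apfi = scenario_config(family_intervention = "ap_plus_fi"))
  sa <- one_way_sa(scen, the_registry, "rr_fi_relapse", values = 0.63,
                   n_patients = 300, seed = 2)
  coh <- generate_cohort(300, the_baseline, seed = 2)
  base <- simulate_cohort(coh, scen$apfi, the_baseline, seed = 2)
  expect_equal(sa$cost[sa$arm == "apfi"], base$mean_cost)
  expect_equal(sa$qaly[sa$arm == "apfi"], base$mean_qaly)
  expect_error(one_way_sa(scen, the_registry, "no_such_par", 1), "unknown")
})

test_that("weakening family intervention shrinks its benefit monotonically", {
  scen <- list(ap = scenario_config(family_intervention = "ap_only"),
               apfi = scenario_config(family_intervention = "ap_plus_fi"))
  sa <- one_way_sa(scen, the_registry, "rr_fi_relapse",
                   values = c(0.63, 0.83, 1.0), n_patients = 800, seed = 2)
  benefit <- vapply(c(0.63, 0.83, 1.0), function(v) {
    s <- sa[sa$value == v, ]
    (20000 * s$qaly[s$arm == "apfi"] - s$cost[s$arm == "apfi"]) -
      (20000 * s$qaly[s$arm == "ap"] - s$cost[s$arm == "ap"])
  }, 0)
  expect_true(all(diff(benefit) <= 1e-9))
})
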