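# Shared fixtures and independent oracles.

the_registry <- load_registry(default_registry())
the_baseline <- baseline_parameters(the_registry)

# Parameter set with every transition, relapse, adverse-event and mortality
# risk switched off and all utilities at 1: survival is deterministic to the
# horizon and the discounted QALY has the closed annuity form.
null_params <- function(par = the_baseline) {
  par[c("p_chr_transition_annual", "p_chr_remission_annual",
        "p_relapse_annual", "mort_makeham_a", "mort_gompertz_b")] <- 0
  par[grep("^p_ae_", names(par))] <- 0
  par[c("utility_chr", "utility_remission", "utility_relapse",
        "utility_out_of_scope")] <- 1
  par[c("disutility_weight_gain", "disutility_eps",
        "disutility_diabetes")] <- 0
  par
}

# A fixed tiny cohort built by hand (no RNG).
hand_cohort <- function(n, status = "fep", age = 30, sex = "male") {
  data.frame(id = seq_len(n), sex = sex, age_at_entry = age,
             status = status, entry_time = 0, stringsAsFactors = FALSE)
}

# Closed-form discounted annuity: value of a unit flow over [0, T] at annual
# discount rate r (continuous convention).
annuity <- function(T, r = 0.035) {
  rho <- log(1 + r)
  if (rho == 0) T else (1 - exp(-rho * T)) / rho
}

# Brute-force frontier oracle, independent of the package's iterative
# algorithm: dominance by pairwise comparison, extended dominance by exact
# segment (mixture) checks against every pair of other arms.
frontier_oracle <- function(df) {
  n <- nrow(df)
  status <- rep("on_frontier", n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    if (any(df$cost[others] <= df$cost[i] & df$qaly[others] >= df$qaly[i] &
            (df$cost[others] < df$cost[i] | df$qaly[others] > df$qaly[i])))
      status[i] <- "dominated"
  }
  for (i in which(status == "on_frontier")) {
    found <- FALSE
    for (j in seq_len(n)) {
      if (found) break
      for (k in seq_len(n)) {
        if (j >= k || j == i || k == i) next
        q1 <- df$qaly[j]; q2 <- df$qaly[k]
        if (q1 == q2) next
        lam <- (df$qaly[i] - q2) / (q1 - q2)
        if (lam < 0 || lam > 1) next
        cm <- lam * df$cost[j] + (1 - lam) * df$cost[k]
        if (cm < df$cost[i] - 1e-9) { found <- TRUE; break }
      }
    }
    if (found) status[i] <- "extendedly_dominated"
  }
  status
}

# The seven deterministic first-episode-psychosis arm results as published
# (cost per person in GBP, QALYs per person).
published_fep_arms <- function() {
  data.frame(
    arm = c("quetiapine", "haloperidol", "aripiprazole", "risperidone",
            "placebo", "amisulpride", "olanzapine"),
    cost = c(168539, 168538, 171340, 166869, 174128, 165813, 167455),
    qaly = c(19.2005, 19.1981, 19.1977, 19.1934, 19.1931, 19.1822, 19.1794),
    stringsAsFactors = FALSE
  )
}
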