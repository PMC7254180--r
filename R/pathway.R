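# Arm vocabularies.
.fep_drugs <- c("amisulpride", "aripiprazole", "haloperidol", "olanzapine",
                "placebo", "quetiapine", "risperidone")
.trs_drugs <- c("clozapine", "haloperidol", "olanzapine", "quetiapine",
                "risperidone")
.ae_kinds <- c("weight_gain", "eps", "diabetes", "neutropenia")
# Fallback order for subsequent treatment lines after a discontinuation.
.default_line_seq <- c("amisulpride", "olanzapine", "risperidone",
                       "quetiapine", "haloperidol", "aripiprazole")

# Fixed per-patient uniform draw plan. Every patient consumes the same
# block regardless of status or scenario, so random streams are common
# across arms (common random numbers) by construction.
.u_cbt_offer <- 1L; .u_cbt_take <- 2L; .u_trans <- 3L; .u_remit <- 4L
.u_death <- 5L; .u_ap <- 6L; .u_fi_offer <- 7L; .u_fi_take <- 8L
.u_disc0 <- 8L       # lines 1..8 at 9..16
.u_ae0 <- 16L        # (line-1)*4 + kind at 17..48
.u_rel0 <- 48L       # relapse gaps 1..64 at 49..112
.u_mgmt0 <- 112L     # episode management 1..64 at 113..176
.n_u <- 176L
.max_relapses <- 64L
.max_lines <- 8L

#' Convert an odds ratio into a probability
#'
#' Applies an odds ratio \code{or} to a reference probability \code{p0}:
#' \code{or * o0 / (1 + or * o0)} with \code{o0 = p0 / (1 - p0)}. Used to
#' turn the per-drug discontinuation odds ratios into annual
#' discontinuation probabilities.
#'
#' @param p0 Reference probability, strictly inside (0, 1).
#' @param or Odds ratio, positive.
#' @return Probability.
#' @export
#' @examples
#' odds_ratio_to_probability(0.82, 0.11)  # olanzapine vs placebo
odds_ratio_to_probability <- function(p0, or) {
  stopifnot(all(or > 0))
  if (any(p0 <= 0 | p0 >= 1))
    stop("p0 must be strictly inside (0, 1): odds undefined at 0 or 1")
  o <- or * p0 / (1 - p0)
  o / (1 + o)
}

#' Convert an annual event probability into an exponential rate
#'
#' \code{-log(1 - p)} per year, so that an exponential waiting time with
#' this rate has annual event probability \code{p}.
#'
#' @param p Probability in [0, 1).
#' @return Rate per year.
#' @export
annual_probability_to_rate <- function(p) {
  if (any(p < 0 | p >= 1)) stop("p must be in [0, 1)")
  -log1p(-p)
}

#' @rdname annual_probability_to_rate
#' @param rate Rate per year (non-negative).
#' @export
rate_to_annual_probability <- function(rate) {
  stopifnot(all(rate >= 0))
  -expm1(-rate)
}

#' Apply a relative risk to a probability
#'
#' Multiplies on the probability scale and caps at 1; treatment effects are
#' applied this way before conversion to exponential rates.
#'
#' @param p Probability in [0, 1].
#' @param rr Relative risk, positive.
#' @return \code{min(rr * p, 1)}.
#' @export
apply_relative_risk <- function(p, rr) {
  stopifnot(all(p >= 0 & p <= 1), all(rr > 0))
  pmin(rr * p, 1)
}

#' Scenario configuration for one intervention arm
#'
#' One choice per decision node of the care pathway, plus structural toggles.
#' \code{chr_intervention = "pau_plus_cbt"} offers CBT to people at clinical
#' high risk at the observed provision and take-up rates; \code{"pau"}
#' removes it. \code{cbt_effect_mode} selects whether CBT prevents
#' transition to psychosis (hazard reduction for life) or only delays it
#' (hazard reduction during \code{cbt_effect_window} years). The family
#' intervention node offers FI at observed provision and take-up in the
#' \code{"fi_only"} and \code{"ap_plus_fi"} arms; \code{fi_brief = TRUE}
#' halves the number of sessions and moves the relapse relative risk halfway
#' to 1.
#'
#' @param chr_intervention "pau_plus_cbt" or "pau".
#' @param acute_management "mixed_crht" or "hospital_only".
#' @param crht_fraction Fraction of acute episodes managed by the crisis
#'   resolution and home treatment team under \code{"mixed_crht"}.
#' @param fep_first_line First-line oral antipsychotic for first-episode
#'   psychosis (one of amisulpride, aripiprazole, haloperidol, olanzapine,
#'   placebo, quetiapine, risperidone).
#' @param family_intervention "ap_plus_fi", "ap_only" or "fi_only".
#' @param fi_sessions Number of family-intervention sessions (NULL = registry
#'   default).
#' @param fi_brief Halve FI sessions and effectiveness (structural toggle).
#' @param trs_first_line First-line antipsychotic after treatment resistance
#'   (one of clozapine, haloperidol, olanzapine, quetiapine, risperidone).
#' @param cbt_effect_mode "delay" or "prevent".
#' @param cbt_effect_window Years the CBT hazard reduction lasts in delay
#'   mode.
#' @param lines_before_trs Failed adequate antipsychotic trials defining
#'   treatment resistance.
#' @param horizon_age Age cap of the lifetime horizon (years).
#' @return A \code{wdm_scenario} list.
#' @export
scenario_config <- function(chr_intervention = c("pau_plus_cbt", "pau"),
                            acute_management = c("mixed_crht", "hospital_only"),
                            crht_fraction = 0.5,
                            fep_first_line = "olanzapine",
                            family_intervention = c("ap_plus_fi", "ap_only",
                                                    "fi_only"),
                            fi_sessions = NULL,
                            fi_brief = FALSE,
                            trs_first_line = "clozapine",
                            cbt_effect_mode = c("delay", "prevent"),
                            cbt_effect_window = 3,
                            lines_before_trs = 2,
                            horizon_age = 100) {
  chr_intervention <- match.arg(chr_intervention)
  acute_management <- match.arg(acute_management)
  family_intervention <- match.arg(family_intervention)
  cbt_effect_mode <- match.arg(cbt_effect_mode)
  if (!fep_first_line %in% .fep_drugs)
    stop("fep_first_line must be one of: ", paste(.fep_drugs, collapse = ", "))
  if (!trs_first_line %in% .trs_drugs)
    stop("trs_first_line must be one of: ", paste(.trs_drugs, collapse = ", "))
  stopifnot(crht_fraction >= 0, crht_fraction <= 1,
            cbt_effect_window >= 0, horizon_age > 0,
            lines_before_trs >= 1, lines_before_trs <= 6)
  structure(list(chr_intervention = chr_intervention,
                 acute_management = acute_management,
                 crht_fraction = crht_fraction,
                 fep_first_line = fep_first_line,
                 family_intervention = family_intervention,
                 fi_sessions = fi_sessions,
                 fi_brief = fi_brief,
                 trs_first_line = trs_first_line,
                 cbt_effect_mode = cbt_effect_mode,
                 cbt_effect_window = cbt_effect_window,
                 lines_before_trs = lines_before_trs,
                 horizon_age = horizon_age),
            class = "wdm_scenario")
}

# Engine guard: probabilities fed to the rate conversion after multiplier
# composition are capped just below 1 to keep rates finite.
.p_cap <- 0.99

.rate_capped <- function(p) annual_probability_to_rate(pmin(p, .p_cap))

# Precompute everything the per-patient simulation needs.
.build_ctx <- function(scenario, params) {
  g <- function(nm) .pv(params, nm)
  p0 <- g("p_disc_placebo")
  p_disc_fep <- vapply(.fep_drugs, function(d) {
    if (d == "placebo") p0
    else odds_ratio_to_probability(p0, g(paste0("or_disc_", d)))
  }, 0)
  pcz <- g("p_disc_clozapine_ineff")
  p_disc_trs <- vapply(.trs_drugs, function(d) {
    if (d == "clozapine") pcz
    else odds_ratio_to_probability(pcz, g(paste0("or_trs_", d)))
  }, 0)
  ae_drugs <- unique(c(.fep_drugs, "clozapine"))
  rate_ae <- sapply(ae_drugs, function(d) {
    vapply(.ae_kinds, function(k) {
      .rate_capped(g(paste0("p_ae_", k, "_", d)))
    }, 0)
  })  # kinds x drugs
  dcost_yr <- vapply(ae_drugs, function(d)
    g(paste0("cost_ap_day_", d)) * 365.25, 0)
  fi_rr <- g("rr_fi_relapse")
  fi_sessions <- if (!is.null(scenario$fi_sessions)) scenario$fi_sessions
                 else g("fi_sessions")
  if (isTRUE(scenario$fi_brief)) {
    fi_rr <- (fi_rr + 1) / 2
    fi_sessions <- ceiling(fi_sessions / 2)
  }
  list(
    p_disc_fep = p_disc_fep, rate_disc_fep = .rate_capped(p_disc_fep),
    p_disc_trs = p_disc_trs, rate_disc_trs = .rate_capped(p_disc_trs),
    rate_ae = rate_ae, dcost_yr = dcost_yr,
    p_rel = g("p_relapse_annual"),
    off_mult = g("rr_relapse_off_treatment"),
    trs_mult = g("rr_relapse_trs_nonclozapine"),
    gap = g("off_treatment_gap_years"),
    rel_dur = g("relapse_duration_years"),
    eps_dur = g("eps_duration_years"),
    cloz_delay = g("clozapine_delay_years"),
    p_trans = g("p_chr_transition_annual"),
    rr_cbt = g("rr_cbt_transition"),
    rate_remit = .rate_capped(g("p_chr_remission_annual")),
    cbt_prob = g("cbt_provision") * g("cbt_takeup"),
    ap_prob = g("ap_provision") * g("ap_takeup_fep"),
    fi_prov = g("fi_provision"), fi_take = g("fi_takeup"),
    fi_rr = fi_rr,
    cbt_cost = g("cbt_sessions") * g("cost_cbt_session"),
    fi_cost = fi_sessions * g("cost_fi_session"),
    u_chr = g("utility_chr"), u_rem = g("utility_remission"),
    u_rel = g("utility_relapse"), u_oos = g("utility_out_of_scope"),
    du_wg = g("disutility_weight_gain"), du_eps = g("disutility_eps"),
    du_dm = g("disutility_diabetes"),
    c_maint = g("cost_maintenance_year"), c_chr = g("cost_chr_year"),
    c_assess_acute = g("cost_assessment_acute"),
    c_assess_nonacute = g("cost_assessment_nonacute"),
    c_hosp_episode = g("bed_days_relapse") * g("cost_bed_day"),
    c_crht_episode = g("n_crht_contacts") * g("cost_crht_contact"),
    c_clinic_yr = g("n_clozapine_clinic_visits_year") *
      g("cost_clozapine_clinic_visit"),
    c_wg1 = g("cost_weight_gain_year1"), c_wg2 = g("cost_weight_gain_later"),
    c_eps = g("cost_eps_episode"), c_dm = g("cost_diabetes_year"),
    c_neut = g("cost_neutropenia_episode"),
    mort_a = g("mort_makeham_a"), mort_b = g("mort_gompertz_b"),
    mort_c = g("mort_gompertz_c"), hr_male = g("mort_hr_male"),
    smr = g("smr_psychosis")
  )
}

# Gompertz-Makeham cumulative hazard over [0, t] from age `age0`.
.cum_mort <- function(t, age0, a, b, cc, hr) {
  gomp <- if (b > 0) (b / cc) * (exp(cc * (age0 + t)) - exp(cc * age0)) else 0
  hr * (a * t + gomp)
}

# Invert total mortality hazard E, with multiplier `smr` from `t_psych` on.
.invert_mort <- function(E, age0, ctx, hr, smr, t_psych) {
  H <- function(t) {
    if (t <= t_psych)
      .cum_mort(t, age0, ctx$mort_a, ctx$mort_b, ctx$mort_c, hr)
    else
      .cum_mort(t_psych, age0, ctx$mort_a, ctx$mort_b, ctx$mort_c, hr) +
        smr * (.cum_mort(t, age0, ctx$mort_a, ctx$mort_b, ctx$mort_c, hr) -
               .cum_mort(t_psych, age0, ctx$mort_a, ctx$mort_b, ctx$mort_c, hr))
  }
  up <- 150
  if (H(up) <= E) return(Inf)
  stats::uniroot(function(t) H(t) - E, c(0, up), tol = 1e-10)$root
}

# Next event time for a piecewise-constant hazard: phases with starts `s`,
# ends `e` (contiguous, sorted), rates `r`; accumulate hazard from `tau`
# until it reaches E.
.pw_next <- function(tau, E, s, e, r) {
  i <- findInterval(tau, s)
  if (i < 1L) i <- 1L
  cur <- tau
  rem <- E
  n <- length(s)
  while (i <= n) {
    if (r[i] > 0) {
      dt <- rem / r[i]
      if (cur + dt < e[i]) return(cur + dt)
      rem <- rem - r[i] * (e[i] - cur)
    }
    cur <- e[i]
    i <- i + 1L
  }
  Inf
}

# Build the treatment-line phase sequence of the psychosis pathway from t_p
# to T_end. Returns a list of parallel vectors plus flags. `mult` is the
# relapse-hazard multiplier of the phase (excluding family intervention),
# `line` indexes the discontinuation/adverse-event draw streams.
.psych_phases <- function(ctx, scenario, t_p, T_end, E_disc, on_ap) {
  s <- numeric(0); e <- numeric(0); mult <- numeric(0)
  drug <- character(0); line <- integer(0); dcost <- numeric(0)
  clinic <- logical(0)
  add <- function(s1, e1, m, d, l, dc, cl) {
    if (e1 > s1 + 1e-12) {
      s <<- c(s, s1); e <<- c(e, e1); mult <<- c(mult, m)
      drug <<- c(drug, d); line <<- c(line, l); dcost <<- c(dcost, dc)
      clinic <<- c(clinic, cl)
    }
  }
  trs <- FALSE; failed <- 0L
  done <- function() list(s = s, e = e, mult = mult, drug = drug,
                          line = line, dcost = dcost, clinic = clinic,
                          trs = trs, lines_failed = failed)
  if (!on_ap) {
    add(t_p, T_end, ctx$off_mult, NA_character_, NA_integer_, 0, FALSE)
    return(done())
  }
  cur <- t_p; k <- 1L
  first <- scenario$fep_first_line
  fallback <- setdiff(.default_line_seq, first)
  while (failed < scenario$lines_before_trs && k <= .max_lines) {
    d <- if (k == 1L) first else fallback[k - 1L]
    r <- ctx$rate_disc_fep[[d]]
    D <- if (r > 0) E_disc[k] / r else Inf
    m <- if (d == "placebo") ctx$off_mult else 1
    add(cur, min(cur + D, T_end), m, d, k, ctx$dcost_yr[[d]], FALSE)
    if (cur + D >= T_end) return(done())
    add(cur + D, min(cur + D + ctx$gap, T_end), ctx$off_mult,
        NA_character_, NA_integer_, 0, FALSE)
    failed <- failed + 1L
    if (cur + D + ctx$gap >= T_end) return(done())
    cur <- cur + D + ctx$gap
    k <- k + 1L
  }
  trs <- TRUE
  t_first <- scenario$trs_first_line
  if (t_first != "clozapine" && k <= .max_lines) {
    r <- ctx$rate_disc_trs[[t_first]]
    D <- if (r > 0) E_disc[k] / r else Inf
    add(cur, min(cur + D, T_end), ctx$trs_mult, t_first, k,
        ctx$dcost_yr[[t_first]], FALSE)
    if (cur + D >= T_end) return(done())
    add(cur + D, min(cur + D + ctx$gap, T_end), ctx$off_mult,
        NA_character_, NA_integer_, 0, FALSE)
    if (cur + D + ctx$gap >= T_end) return(done())
    cur <- cur + D + ctx$gap
    k <- k + 1L
  }
  # real-world delay before clozapine initiation: interim antipsychotic
  add(cur, min(cur + ctx$cloz_delay, T_end), ctx$trs_mult, "interim",
      NA_integer_, ctx$dcost_yr[["olanzapine"]], FALSE)
  if (cur + ctx$cloz_delay >= T_end) return(done())
  cur <- cur + ctx$cloz_delay
  r <- ctx$rate_disc_trs[["clozapine"]]
  D <- if (r > 0 && k <= .max_lines) E_disc[min(k, .max_lines)] / r else Inf
  add(cur, min(cur + D, T_end), 1, "clozapine", min(k, .max_lines),
      ctx$dcost_yr[["clozapine"]], TRUE)
  if (cur + D < T_end) {
    # clozapine discontinued for inefficacy: absorbing maintenance on a
    # non-clozapine antipsychotic
    add(cur + D, T_end, ctx$trs_mult, "postcloz", NA_integer_,
        ctx$dcost_yr[["olanzapine"]], FALSE)
  }
  done()
}

#' Simulate one patient through the whole-disease model
#'
#' Executes the full pathway for a single patient under a scenario: initial
#' assessment; the clinical-high-risk pathway (CBT offer, transition to
#' psychosis or remission); the psychosis pathway (antipsychotic lines,
#' all-cause discontinuation, untreated gaps, treatment resistance,
#' clozapine with its initiation delay, relapses managed by hospital
#' admission or crisis resolution and home treatment, adverse events, family
#' intervention); and death from a Gompertz-Makeham background hazard with a
#' standardized-mortality-ratio multiplier from psychosis onset. All
#' stochastic draws come from the fixed-length uniform block \code{u}, keyed
#' by purpose, so identical \code{u} across scenarios gives common random
#' numbers.
#'
#' Mostly useful for white-box testing; \code{\link{simulate_cohort}} is the
#' user-facing entry point.
#'
#' @param patient One-row data frame (or list) with \code{sex},
#'   \code{age_at_entry}, \code{status}.
#' @param scenario A \code{wdm_scenario}.
#' @param params A \code{wdm_params}.
#' @param u Uniform draw block of length 176 (see
#'   \code{\link{simulate_cohort}} for the stream layout); drawn internally
#'   if missing.
#' @param ctx Precomputed context (internal; built from scenario and params
#'   if missing).
#' @return List with \code{qaly}, \code{cost}, \code{cost_by_category},
#'   \code{counts} (named: transition, relapses, trs, lines_failed, death,
#'   cbt, fi), \code{t_end}, and the \code{\link{trajectory}}.
#' @export
simulate_patient <- function(patient, scenario, params, u = stats::runif(.n_u),
                             ctx = .build_ctx(scenario, params)) {
  p <- as.list(patient)
  age0 <- p$age_at_entry
  T_hor <- max(scenario$horizon_age - age0, 0)
  hr <- if (identical(p$sex, "male")) ctx$hr_male else 1
  E_death <- -log(u[.u_death])
  segs <- NULL   # rows t0, t1, base utility
  pts <- NULL    # rows t, amount, category
  fls <- NULL    # rows t0, t1, amount_per_year, category
  addp <- function(t, a, cat) pts <<- rbind(pts, c(t, a, cat))
  addf <- function(t0, t1, a, cat) {
    if (t1 > t0 + 1e-12) fls <<- rbind(fls, c(t0, t1, a, cat))
  }
  counts <- c(transition = 0, relapses = 0, trs = 0, lines_failed = 0,
              death = 0, cbt = 0, fi = 0)

  status <- p$status
  t_p <- NA_real_   # psychosis onset time (NA = never)
  t_oos <- NA_real_ # exit to out-of-scope (remission from CHR)
  t_chr_end <- NA_real_

  if (status == "not_at_risk") {
    t_death <- .invert_mort(E_death, age0, ctx, hr, 1, Inf)
    T_end <- min(t_death, T_hor)
    addp(0, ctx$c_assess_nonacute, 1)
    segs <- rbind(segs, c(0, T_end, ctx$u_oos))
  } else if (status == "chr_p") {
    addp(0, ctx$c_assess_nonacute, 1)
    cbt <- scenario$chr_intervention == "pau_plus_cbt" &&
      u[.u_cbt_offer] < .pv(params, "cbt_provision") &&
      u[.u_cbt_take] < .pv(params, "cbt_takeup")
    if (cbt) {
      counts["cbt"] <- 1
      addp(0, ctx$cbt_cost, 2)
    }
    rate_tr <- .rate_capped(ctx$p_trans)
    rate_tr_cbt <- .rate_capped(apply_relative_risk(ctx$p_trans, ctx$rr_cbt))
    E_tr <- -log(u[.u_trans])
    t_trans <- if (!cbt) {
      if (rate_tr > 0) E_tr / rate_tr else Inf
    } else if (scenario$cbt_effect_mode == "prevent") {
      if (rate_tr_cbt > 0) E_tr / rate_tr_cbt else Inf
    } else {
      w <- scenario$cbt_effect_window
      if (E_tr < rate_tr_cbt * w) {
        E_tr / rate_tr_cbt
      } else if (rate_tr > 0) {
        w + (E_tr - rate_tr_cbt * w) / rate_tr
      } else Inf
    }
    t_remit <- if (ctx$rate_remit > 0) -log(u[.u_remit]) / ctx$rate_remit else Inf
    t_death0 <- .invert_mort(E_death, age0, ctx, hr, 1, Inf)
    if (t_trans < min(t_remit, t_death0, T_hor)) {
      counts["transition"] <- 1
      t_p <- t_trans
      t_death <- .invert_mort(E_death, age0, ctx, hr, ctx$smr, t_p)
    } else {
      t_death <- t_death0
      if (t_remit < min(t_death0, T_hor)) t_oos <- t_remit
    }
    T_end <- min(t_death, T_hor)
    t_chr_end <- min(c(t_p, t_oos, T_end), na.rm = TRUE)
    segs <- rbind(segs, c(0, t_chr_end, ctx$u_chr))
    addf(0, t_chr_end, ctx$c_chr, 3)
    if (!is.na(t_oos) && t_oos < T_end)
      segs <- rbind(segs, c(t_oos, T_end, ctx$u_oos))
  } else if (status == "fep") {
    t_p <- 0
    t_death <- .invert_mort(E_death, age0, ctx, hr, ctx$smr, 0)
    T_end <- min(t_death, T_hor)
  } else stop("unknown status: ", status)

  eps_ep <- NULL; t_wg <- Inf; t_dm <- Inf
  if (!is.na(t_p) && t_p < T_end) {
    addp(t_p, ctx$c_assess_acute, 1)
    on_ap <- scenario$family_intervention != "fi_only" &&
      u[.u_ap] < ctx$ap_prob
    fi <- scenario$family_intervention %in% c("fi_only", "ap_plus_fi") &&
      u[.u_fi_offer] < ctx$fi_prov && u[.u_fi_take] < ctx$fi_take
    if (fi) {
      counts["fi"] <- 1
      addp(t_p, ctx$fi_cost, 2)
    }
    E_disc <- -log(u[.u_disc0 + seq_len(.max_lines)])
    ph <- .psych_phases(ctx, scenario, t_p, T_end, E_disc, on_ap)
    counts["trs"] <- as.numeric(ph$trs)
    counts["lines_failed"] <- ph$lines_failed

    # adverse events per treatment-line phase
    for (i in seq_along(ph$s)) {
      d <- ph$drug[i]; k <- ph$line[i]
      if (is.na(d) || is.na(k) || !(d %in% colnames(ctx$rate_ae))) next
      for (j in seq_along(.ae_kinds)) {
        r <- ctx$rate_ae[j, d]
        if (r <= 0) next
        t_ae <- ph$s[i] - log(u[.u_ae0 + (k - 1L) * 4L + j]) / r
        if (t_ae >= ph$e[i]) next
        kind <- .ae_kinds[j]
        if (kind == "weight_gain") {
          if (t_ae < t_wg) t_wg <- t_ae
        } else if (kind == "diabetes") {
          if (t_ae < t_dm) t_dm <- t_ae
        } else if (kind == "eps") {
          eps_ep <- rbind(eps_ep, c(t_ae, min(t_ae + ctx$eps_dur, T_end)))
          addp(t_ae, ctx$c_eps, 5)
        } else {
          addp(t_ae, ctx$c_neut, 5)
        }
      }
    }
    if (t_wg < T_end) {
      segs_wg_end <- min(t_wg + 1, T_end)
      addf(t_wg, segs_wg_end, ctx$c_wg1, 5)
      addf(segs_wg_end, T_end, ctx$c_wg2, 5)
    }
    if (t_dm < T_end) addf(t_dm, T_end, ctx$c_dm, 5)

    # relapse process over the phase timeline
    fi_factor <- if (fi) ctx$fi_rr else 1
    rel_rate <- .rate_capped(pmin(ctx$p_rel * ph$mult * fi_factor, 1))
    episodes <- NULL
    tau <- t_p; i_rel <- 1L
    while (tau < T_end && i_rel <= .max_relapses) {
      E <- -log(u[.u_rel0 + i_rel])
      t_r <- .pw_next(tau, E, ph$s, ph$e, rel_rate)
      if (t_r >= T_end) break
      dur <- min(ctx$rel_dur, T_end - t_r)
      episodes <- rbind(episodes, c(t_r, t_r + dur))
      addp(t_r, ctx$c_assess_acute, 1)
      crht <- scenario$acute_management == "mixed_crht" &&
        u[.u_mgmt0 + i_rel] < scenario$crht_fraction
      addp(t_r, if (crht) ctx$c_crht_episode else ctx$c_hosp_episode, 4)
      tau <- t_r + dur
      i_rel <- i_rel + 1L
    }
    counts["relapses"] <- i_rel - 1L

    # utility over the psychosis pathway: remission utility, overridden by
    # relapse-episode utility
    if (is.null(episodes)) {
      segs <- rbind(segs, c(t_p, T_end, ctx$u_rem))
      addf(t_p, T_end, ctx$c_maint, 3)
    } else {
      cur <- t_p
      for (i in seq_len(nrow(episodes))) {
        if (episodes[i, 1] > cur) {
          segs <- rbind(segs, c(cur, episodes[i, 1], ctx$u_rem))
          addf(cur, episodes[i, 1], ctx$c_maint, 3)
        }
        segs <- rbind(segs, c(episodes[i, 1], episodes[i, 2], ctx$u_rel))
        cur <- episodes[i, 2]
      }
      if (cur < T_end) {
        segs <- rbind(segs, c(cur, T_end, ctx$u_rem))
        addf(cur, T_end, ctx$c_maint, 3)
      }
    }
    # drug and monitoring costs per phase
    for (i in seq_along(ph$s)) {
      if (ph$dcost[i] > 0) addf(ph$s[i], ph$e[i], ph$dcost[i], 3)
      if (ph$clinic[i]) addf(ph$s[i], ph$e[i], ctx$c_clinic_yr, 3)
    }
  }
  counts["death"] <- as.numeric(T_end < T_hor)

  # overlay adverse-event disutilities on the base-utility segments
  segs <- .apply_disutilities(segs, T_end, t_wg, t_dm, eps_ep,
                              ctx$du_wg, ctx$du_dm, ctx$du_eps)
  traj <- trajectory(segments = segs, points = pts, flows = fls)
  acc <- accumulate_trajectory(traj, annual_rate = attr(params, "wdm_rate") %||% 0.035)
  list(qaly = acc$qaly, cost = acc$cost,
       cost_by_category = acc$cost_by_category,
       counts = counts, t_end = T_end, trajectory = traj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split base-utility segments at decrement breakpoints and subtract active
# decrements, flooring the effective utility at 0.
.apply_disutilities <- function(segs, T_end, t_wg, t_dm, eps_ep,
                                du_wg, du_dm, du_eps) {
  if (is.null(segs)) return(NULL)
  colnames(segs) <- c("t0", "t1", "utility")
  bounds <- c(t_wg, t_dm)
  if (!is.null(eps_ep)) bounds <- c(bounds, eps_ep[, 1], eps_ep[, 2])
  bounds <- bounds[is.finite(bounds) & bounds > 0 & bounds < T_end]
  if (!length(bounds)) {
    segs[, "utility"] <- pmax(segs[, "utility"], 0)
    return(segs)
  }
  out <- NULL
  for (i in seq_len(nrow(segs))) {
    bp <- sort(unique(c(segs[i, 1], bounds[bounds > segs[i, 1] &
                                             bounds < segs[i, 2]], segs[i, 2])))
    lo <- bp[-length(bp)]; hi <- bp[-1]
    mid <- (lo + hi) / 2
    dec <- ifelse(mid >= t_wg, du_wg, 0) + ifelse(mid >= t_dm, du_dm, 0)
    if (!is.null(eps_ep)) {
      for (r in seq_len(nrow(eps_ep)))
        dec <- dec + ifelse(mid >= eps_ep[r, 1] & mid < eps_ep[r, 2], du_eps, 0)
    }
    out <- rbind(out, cbind(lo, hi, pmax(segs[i, 3] - dec, 0)))
  }
  colnames(out) <- c("t0", "t1", "utility")
  out
}

#' Simulate a cohort through the whole-disease model under one scenario
#'
#' Runs every patient through the full care pathway and accumulates
#' discounted costs and QALYs per person. Each patient has a private random
#' stream derived from \code{(seed, patient id)} with a fixed block layout
#' (one uniform per decision, keyed by purpose), so re-running with a
#' different scenario but the same seed gives exact common random numbers:
#' arms differ only where the interventions differ.
#'
#' @param cohort A \code{wdm_cohort} from \code{\link{generate_cohort}} (or
#'   any data frame with \code{id}, \code{sex}, \code{age_at_entry},
#'   \code{status}).
#' @param scenario A \code{wdm_scenario} from \code{\link{scenario_config}}.
#' @param params A \code{wdm_params}.
#' @param seed Integer seed for the patient-level streams.
#' @param annual_rate Annual discount rate for costs and QALYs.
#' @param arm_name Label carried into the result.
#' @param keep_patients Keep the per-patient cost/QALY/event table.
#' @return A \code{wdm_arm_result}: list with \code{arm_name},
#'   \code{mean_cost}, \code{mean_qaly}, \code{n_patients},
#'   \code{cost_by_category} (means), \code{counts} (event totals), and
#'   optionally \code{patients}.
#' @export
#' @examples
#' reg <- load_registry(default_registry())
#' par <- baseline_parameters(reg)
#' coh <- generate_cohort(200, par, seed = 1)
#' res <- simulate_cohort(coh, scenario_config(), par, seed = 7)
#' c(res$mean_cost, res$mean_qaly)
simulate_cohort <- function(cohort, scenario, params, seed = 1L,
                            annual_rate = 0.035, arm_name = "arm",
                            keep_patients = FALSE) {
  stopifnot(inherits(scenario, "wdm_scenario"))
  n <- nrow(cohort)
  ctx <- .build_ctx(scenario, params)
  attr(params, "wdm_rate") <- annual_rate
  tot_cost <- 0; tot_qaly <- 0
  tot_cat <- stats::setNames(numeric(length(.cost_categories)),
                             .cost_categories)
  tot_counts <- c(transition = 0, relapses = 0, trs = 0, lines_failed = 0,
                  death = 0, cbt = 0, fi = 0)
  pat <- if (keep_patients)
    matrix(NA_real_, n, 4, dimnames = list(NULL, c("id", "cost", "qaly",
                                                   "relapses"))) else NULL
  sexes <- cohort$sex; ages <- cohort$age_at_entry; stats_ <- cohort$status
  ids <- cohort$id
  for (i in seq_len(n)) {
    ps <- (as.numeric(seed) * 48271 + as.numeric(ids[i]) * 16807) %% 2147483629
    set.seed(as.integer(ps))
    u <- stats::runif(.n_u)
    r <- simulate_patient(list(sex = sexes[i], age_at_entry = ages[i],
                               status = stats_[i]),
                          scenario, params, u = u, ctx = ctx)
    tot_cost <- tot_cost + r$cost
    tot_qaly <- tot_qaly + r$qaly
    tot_cat <- tot_cat + r$cost_by_category
    tot_counts <- tot_counts + r$counts
    if (keep_patients) pat[i, ] <- c(ids[i], r$cost, r$qaly,
                                     r$counts[["relapses"]])
  }
  structure(list(arm_name = arm_name,
                 mean_cost = if (n > 0) tot_cost / n else NA_real_,
                 mean_qaly = if (n > 0) tot_qaly / n else NA_real_,
                 n_patients = n,
                 cost_by_category = if (n > 0) tot_cat / n else tot_cat,
                 counts = tot_counts,
                 patients = if (keep_patients) as.data.frame(pat) else NULL),
            class = "wdm_arm_result")
}

#' @export
print.wdm_arm_result <- function(x, ...) {
  cat(sprintf("<wdm_arm_result> %s: n = %d, mean cost = %.0f GBP, mean QALY = %.4f\n",
              x$arm_name, x$n_patients, x$mean_cost, x$mean_qaly))
  invisible(x)
}
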