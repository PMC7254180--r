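#' Incremental cost-effectiveness ratio between two arms
#'
#' Difference in mean cost divided by difference in mean QALYs,
#' comparator minus reference. When the QALY difference is zero the ICER is
#' undefined; the cost difference and a dominance label are reported
#' instead ("dominating" if the comparator is cheaper, "dominated" if more
#' expensive, "equivalent" if equal).
#'
#' @param reference,comparator \code{wdm_arm_result}s, or lists with
#'   \code{mean_cost} and \code{mean_qaly}.
#' @return List with \code{delta_cost}, \code{delta_qaly}, \code{icer}
#'   (NA when undefined) and \code{status}.
#' @export
#' @examples
#' icer(list(mean_cost = 166869, mean_qaly = 19.1934),
#'      list(mean_cost = 168539, mean_qaly = 19.2005))$icer  # 235 211
icer <- function(reference, comparator) {
  dc <- comparator$mean_cost - reference$mean_cost
  dq <- comparator$mean_qaly - reference$mean_qaly
  if (dq == 0) {
    status <- if (dc < 0) "dominating" else if (dc > 0) "dominated"
              else "equivalent"
    return(list(delta_cost = dc, delta_qaly = 0, icer = NA_real_,
                status = status))
  }
  list(delta_cost = dc, delta_qaly = dq, icer = dc / dq,
       status = if (dc <= 0 && dq > 0) "dominating" else "defined")
}

#' Efficiency frontier with dominance and extended dominance
#'
#' Strictly dominated arms (another arm weakly cheaper and weakly more
#' effective, strictly better in at least one) are removed first; then arms
#' are removed iteratively while the ICERs along the cost-sorted frontier
#' fail to be strictly increasing (extended dominance: a mixture of two
#' other arms yields more QALYs at lower cost). Frontier arms carry the
#' ICER against the previous frontier arm; the cheapest frontier arm is the
#' reference. A frontier arm that is weakly cheaper and weakly more
#' effective than every other arm is labelled \code{"dominating"}.
#'
#' @param arms Data frame with columns \code{arm}, \code{cost}, \code{qaly},
#'   or a list of \code{wdm_arm_result}s.
#' @return A \code{wdm_cea_table} data frame: \code{arm}, \code{cost},
#'   \code{qaly}, \code{status} (\code{on_frontier}, \code{dominated},
#'   \code{extendedly_dominated}), \code{label}, \code{inc_cost},
#'   \code{inc_qaly}, \code{icer}.
#' @export
efficiency_frontier <- function(arms) {
  df <- .as_arm_df(arms)
  stopifnot(nrow(df) >= 1)
  n <- nrow(df)
  status <- rep("on_frontier", n)
  # strict dominance
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$cost[j] <= df$cost[i] && df$qaly[j] >= df$qaly[i] &&
          (df$cost[j] < df$cost[i] || df$qaly[j] > df$qaly[i])) {
        status[i] <- "dominated"
        break
      }
    }
  }
  # extended dominance: restore strictly increasing ICERs along the
  # cost-sorted candidate frontier
  repeat {
    idx <- which(status == "on_frontier")
    idx <- idx[order(df$cost[idx], df$qaly[idx])]
    if (length(idx) < 3) break
    ic <- diff(df$cost[idx]) / diff(df$qaly[idx])
    bad <- which(diff(ic) <= 0)
    if (!length(bad)) break
    status[idx[bad[1] + 1]] <- "extendedly_dominated"
  }
  idx <- which(status == "on_frontier")
  idx <- idx[order(df$cost[idx], df$qaly[idx])]
  inc_cost <- inc_qaly <- icer_v <- rep(NA_real_, n)
  if (length(idx) > 1) {
    inc_cost[idx[-1]] <- diff(df$cost[idx])
    inc_qaly[idx[-1]] <- diff(df$qaly[idx])
    icer_v[idx[-1]] <- inc_cost[idx[-1]] / inc_qaly[idx[-1]]
  }
  label <- status
  for (i in idx) {
    dominates_all <- all(vapply(seq_len(n)[-i], function(j)
      df$cost[i] <= df$cost[j] && df$qaly[i] >= df$qaly[j], TRUE))
    label[i] <- if (n > 1 && dominates_all) "dominating"
                else if (is.na(icer_v[i])) "reference"
                else sprintf("ICER %.0f", icer_v[i])
  }
  out <- data.frame(arm = df$arm, cost = df$cost, qaly = df$qaly,
                    status = status, label = label, inc_cost = inc_cost,
                    inc_qaly = inc_qaly, icer = icer_v,
                    stringsAsFactors = FALSE)
  structure(out, class = c("wdm_cea_table", "data.frame"))
}

.as_arm_df <- function(arms) {
  if (is.data.frame(arms)) {
    stopifnot(all(c("arm", "cost", "qaly") %in% names(arms)))
    return(arms[, c("arm", "cost", "qaly")])
  }
  data.frame(
    arm = vapply(arms, function(a) a$arm_name, ""),
    cost = vapply(arms, function(a) a$mean_cost, 0),
    qaly = vapply(arms, function(a) a$mean_qaly, 0),
    stringsAsFactors = FALSE
  )
}

#' Net monetary benefit of an arm
#'
#' \code{wtp * mean_qaly - mean_cost}.
#'
#' @param arm A \code{wdm_arm_result} or list with \code{mean_cost},
#'   \code{mean_qaly}.
#' @param wtp Willingness to pay per QALY (GBP, non-negative). Vectorised.
#' @return Net monetary benefit in GBP.
#' @export
net_monetary_benefit <- function(arm, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * arm$mean_qaly - arm$mean_cost
}

#' Cost-effectiveness acceptability curve from PSA draws
#'
#' For each willingness-to-pay value, the probability that each arm has the
#' highest net monetary benefit across the PSA draws; ties split evenly.
#'
#' @param draws Data frame with columns \code{draw}, \code{arm},
#'   \code{cost}, \code{qaly} (one row per arm per PSA draw).
#' @param wtp Vector of willingness-to-pay values (GBP per QALY).
#' @return Data frame \code{wtp}, \code{arm}, \code{probability}; at each
#'   WTP the probabilities sum to 1.
#' @export
ceac_from_draws <- function(draws, wtp = c(20000, 30000)) {
  arms <- unique(draws$arm)
  out <- NULL
  for (w in wtp) {
    nmb <- w * draws$qaly - draws$cost
    wins <- stats::setNames(numeric(length(arms)), arms)
    for (d in unique(draws$draw)) {
      i <- draws$draw == d
      v <- nmb[i]
      best <- abs(v - max(v)) < 1e-9
      wins[draws$arm[i][best]] <- wins[draws$arm[i][best]] + 1 / sum(best)
    }
    out <- rbind(out, data.frame(wtp = w, arm = arms,
                                 probability = unname(wins / length(unique(draws$draw))),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Probabilistic sensitivity analysis over a set of arms
#'
#' For each of \code{k_samples} joint parameter draws, regenerates the
#' cohort and simulates every arm under common random numbers with a fixed
#' patient-level seed (so draws differ only through parameter uncertainty),
#' then summarises the per-draw results as a cost-effectiveness
#' acceptability curve.
#'
#' @param scenarios Named list of \code{wdm_scenario}s, one per arm.
#' @param registry A \code{wdm_registry}.
#' @param k_samples Number of PSA draws (>= 1).
#' @param n_patients Cohort size per draw.
#' @param seed Integer seed; draw j uses parameter seed \code{seed + j} and
#'   the fixed patient-level seed \code{seed}.
#' @param wtp Willingness-to-pay grid for the CEAC.
#' @param annual_rate Discount rate.
#' @return List with \code{draws} (per-draw arm results) and \code{ceac}.
#' @export
run_psa <- function(scenarios, registry, k_samples = 1000,
                    n_patients = 10000, seed = 1L, wtp = c(20000, 30000),
                    annual_rate = 0.035) {
  stopifnot(k_samples >= 1, length(names(scenarios)) == length(scenarios))
  draws <- NULL
  for (j in seq_len(k_samples)) {
    pj <- tryCatch(sample_parameters(registry, seed + j),
                   error = function(e) stop("PSA draw ", j, ": ",
                                            conditionMessage(e)))
    coh <- generate_cohort(n_patients, pj, mode = "stratified", seed = seed)
    for (a in names(scenarios)) {
      r <- simulate_cohort(coh, scenarios[[a]], pj, seed = seed,
                           annual_rate = annual_rate, arm_name = a)
      draws <- rbind(draws, data.frame(draw = j, arm = a, cost = r$mean_cost,
                                       qaly = r$mean_qaly,
                                       stringsAsFactors = FALSE))
    }
  }
  list(draws = draws, ceac = ceac_from_draws(draws, wtp))
}

#' One-way (and structural) sensitivity analysis
#'
#' Re-runs a deterministic comparison for each value of a single parameter,
#' everything else at baseline. \code{parameter} may be a registry entry
#' name or the name of a scenario field (e.g. \code{cbt_effect_mode},
#' \code{fi_brief}), in which case the value is patched into every
#' scenario (a structural sensitivity analysis).
#'
#' @param scenarios Named list of \code{wdm_scenario}s.
#' @param registry A \code{wdm_registry}.
#' @param parameter Registry entry or scenario field name.
#' @param values Values to sweep.
#' @param n_patients Cohort size per run.
#' @param seed Integer seed (shared across values: common random numbers).
#' @param annual_rate Discount rate.
#' @return Data frame with \code{value}, \code{arm}, \code{cost},
#'   \code{qaly}.
#' @export
one_way_sa <- function(scenarios, registry, parameter, values,
                       n_patients = 10000, seed = 1L, annual_rate = 0.035) {
  base <- baseline_parameters(registry)
  is_scen <- parameter %in% names(scenarios[[1]])
  if (!is_scen && !parameter %in% names(base))
    stop("unknown parameter: '", parameter, "'")
  out <- NULL
  for (v in values) {
    par <- base
    scen <- scenarios
    if (is_scen) {
      scen <- lapply(scenarios, function(s) { s[[parameter]] <- v; s })
    } else {
      par[parameter] <- as.numeric(v)
    }
    coh <- generate_cohort(n_patients, par, mode = "stratified", seed = seed)
    for (a in names(scen)) {
      r <- simulate_cohort(coh, scen[[a]], par, seed = seed,
                           annual_rate = annual_rate, arm_name = a)
      out <- rbind(out, data.frame(value = v, arm = a, cost = r$mean_cost,
                                   qaly = r$mean_qaly,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}
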