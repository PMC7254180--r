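# Largest-remainder apportionment of n among proportions p (sums to n exactly).
.largest_remainder <- function(n, p) {
  raw <- n * p / sum(p)
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

# Mean of a normal(mu, sd) truncated below at `lo`.
.trunc_mean <- function(mu, sd, lo) {
  a <- (lo - mu) / sd
  mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# Pre-truncation location giving a truncated-at-`lo` mean equal to `target`.
.trunc_adjust <- function(target, sd, lo) {
  stats::uniroot(function(m) .trunc_mean(m, sd, lo) - target,
                 lower = target - 3 * sd, upper = target + sd,
                 tol = 1e-10)$root
}

#' Generate the simulated population entering secondary-care assessment
#'
#' Patients referred to secondary mental health care with psychotic symptoms:
#' a mix of people not at risk of psychosis, people at clinical high risk
#' (CHR-P), and people presenting with first-episode psychosis (FEP). Ages
#' are Normal(mean 23.52, SD 5.1) truncated below at 14 years, with the
#' pre-truncation location shifted so the post-truncation mean equals the
#' target (the truncation correction); roughly 60.4% are men.
#'
#' In \code{"stratified"} mode sex and disease-status counts are exact
#' (largest-remainder rounding of n times the baseline proportions), so a
#' cohort of 200 000 has exactly 120 800 men and 69 800 people at CHR-P. In
#' \code{"random"} mode each patient's sex and status are drawn
#' independently.
#'
#' @param n Cohort size (non-negative integer).
#' @param params A \code{wdm_params} parameter set (needs \code{age_mean},
#'   \code{age_sd_individual}, \code{prop_male}, \code{p_start_*}).
#' @param mode \code{"stratified"} (default) or \code{"random"}.
#' @param seed Integer seed for ages and the within-cohort assignment order.
#' @param age_min Lower truncation bound for age at entry (years).
#' @return A \code{wdm_cohort} data frame with columns \code{id}, \code{sex}
#'   (\code{"male"}/\code{"female"}), \code{age_at_entry}, \code{status}
#'   (\code{"not_at_risk"}, \code{"chr_p"}, \code{"fep"}), \code{entry_time}.
#' @export
#' @examples
#' reg <- load_registry(default_registry())
#' coh <- generate_cohort(1000, baseline_parameters(reg), seed = 1)
#' table(coh$status)
generate_cohort <- function(n, params, mode = c("stratified", "random"),
                            seed = 1L, age_min = 14) {
  mode <- match.arg(mode)
  if (length(n) != 1 || is.na(n) || n < 0 || n != floor(n))
    stop("n must be a single non-negative integer")
  n <- as.integer(n)
  statuses <- c("not_at_risk", "chr_p", "fep")
  p_status <- c(.pv(params, "p_start_not_at_risk"),
                .pv(params, "p_start_chr"),
                .pv(params, "p_start_fep"))
  p_male <- .pv(params, "prop_male")
  age_mu <- .pv(params, "age_mean")
  age_sd <- .pv(params, "age_sd_individual")
  if (n == 0L) {
    return(structure(data.frame(id = integer(0), sex = character(0),
                                age_at_entry = numeric(0),
                                status = character(0),
                                entry_time = numeric(0)),
                     class = c("wdm_cohort", "data.frame")))
  }
  set.seed(seed)
  if (mode == "stratified") {
    ks <- .largest_remainder(n, p_status)
    status <- sample(rep(statuses, times = ks))
    n_male <- .largest_remainder(n, c(p_male, 1 - p_male))[1]
    sex <- sample(rep(c("male", "female"), times = c(n_male, n - n_male)))
  } else {
    status <- sample(statuses, n, replace = TRUE, prob = p_status)
    sex <- ifelse(stats::runif(n) < p_male, "male", "female")
  }
  mu_adj <- .trunc_adjust(age_mu, age_sd, age_min)
  plo <- stats::pnorm(age_min, mu_adj, age_sd)
  age <- stats::qnorm(plo + stats::runif(n) * (1 - plo), mu_adj, age_sd)
  structure(data.frame(id = seq_len(n), sex = sex, age_at_entry = age,
                       status = status, entry_time = 0,
                       stringsAsFactors = FALSE),
            class = c("wdm_cohort", "data.frame"))
}
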