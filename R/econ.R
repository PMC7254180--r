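# Cost categories used throughout the engine.
.cost_categories <- c("assessment", "intervention", "maintenance",
                      "relapse_management", "adverse_event")

#' Discount a point cost
#'
#' Present value of an amount incurred at time \code{t}:
#' \code{amount / (1 + annual_rate)^t}.
#'
#' @param amount Amount (e.g. GBP). Vectorised.
#' @param t Time of the cost in years from model start (\code{t >= 0}).
#' @param annual_rate Annual discount rate (default 0.035).
#' @return Discounted amount(s).
#' @export
#' @examples
#' discount_point(100, 1, 0.035)  # 96.6184
discount_point <- function(amount, t, annual_rate = 0.035) {
  stopifnot(all(t >= 0), annual_rate > -1)
  amount / (1 + annual_rate)^t
}

#' Discount a constant flow over an interval
#'
#' Continuous-time discounting of a constant flow (cost per year, or a
#' utility) over \code{[t0, t1]} at force of interest
#' \code{rho = log(1 + annual_rate)}:
#' \code{flow * (exp(-rho t0) - exp(-rho t1)) / rho}, with the
#' \code{rho = 0} limit \code{flow * (t1 - t0)}. Continuous discounting
#' agrees with annual-cycle discounting at integer years, and is the natural
#' convention for a discrete-event model in which events occur in continuous
#' time.
#'
#' @param flow Flow per year (GBP/year, or a utility in [0, 1]). Vectorised
#'   along with \code{t0}, \code{t1}.
#' @param t0,t1 Interval bounds in years, \code{0 <= t0 <= t1}.
#' @param annual_rate Annual discount rate (default 0.035).
#' @return Discounted total over the interval (GBP, or QALYs).
#' @export
#' @examples
#' discount_flow(1, 0, 1, 0.035)       # one year of full health, discounted
#' 0.80 / log(1.035)                   # limit of discount_flow(0.80, 0, Inf)
discount_flow <- function(flow, t0, t1, annual_rate = 0.035) {
  stopifnot(all(t0 >= 0), all(t1 >= t0), annual_rate > -1)
  rho <- log1p(annual_rate)
  if (rho == 0) return(flow * (t1 - t0))
  flow * (exp(-rho * t0) - exp(-rho * t1)) / rho
}

#' Build a trajectory object
#'
#' A trajectory is the economic summary of one simulated patient: utility
#' segments (piecewise-constant health-state utility net of adverse-event
#' decrements, floored at 0) plus point and flow cost items, each tagged with
#' a category.
#'
#' @param segments Matrix or data frame with columns \code{t0, t1, utility}.
#'   Segments must not overlap.
#' @param points Matrix or data frame with columns \code{t, amount, category}
#'   (category as an index into the package's category set, or a character
#'   vector of category names).
#' @param flows Matrix or data frame with columns
#'   \code{t0, t1, amount_per_year, category}.
#' @return A \code{wdm_trajectory} list.
#' @export
trajectory <- function(segments = NULL, points = NULL, flows = NULL) {
  as_cat <- function(x) {
    if (is.character(x)) match(x, .cost_categories) else as.numeric(x)
  }
  fix <- function(m, cols) {
    if (is.null(m) || NROW(m) == 0) {
      return(matrix(numeric(0), ncol = length(cols),
                    dimnames = list(NULL, cols)))
    }
    if (is.matrix(m) && is.null(colnames(m))) {
      stopifnot(ncol(m) == length(cols))
      colnames(m) <- cols
    }
    m <- as.data.frame(m)
    if ("category" %in% names(m)) m$category <- as_cat(m$category)
    as.matrix(m[, cols, drop = FALSE])
  }
  structure(list(
    segments = fix(segments, c("t0", "t1", "utility")),
    points = fix(points, c("t", "amount", "category")),
    flows = fix(flows, c("t0", "t1", "amount_per_year", "category"))
  ), class = "wdm_trajectory")
}

#' Accumulate discounted costs and QALYs over a trajectory
#'
#' QALYs are the sum of discounted utility flows over the utility segments;
#' costs are the sum of discounted point costs and cost flows, with
#' per-category subtotals that sum to the total exactly. Overlapping utility
#' segments are rejected.
#'
#' @param traj A \code{wdm_trajectory} (see \code{\link{trajectory}}).
#' @param annual_rate Annual discount rate (default 0.035).
#' @return List with \code{cost}, \code{qaly}, and named
#'   \code{cost_by_category}.
#' @export
#' @examples
#' tr <- trajectory(segments = data.frame(t0 = 0, t1 = 1, utility = 0.71))
#' accumulate_trajectory(tr)$qaly
accumulate_trajectory <- function(traj, annual_rate = 0.035) {
  seg <- traj$segments
  if (nrow(seg) > 1) {
    o <- order(seg[, "t0"])
    seg <- seg[o, , drop = FALSE]
    if (any(seg[-1, "t0"] < seg[-nrow(seg), "t1"] - 1e-9))
      stop("overlapping utility segments")
  }
  qaly <- if (nrow(seg)) {
    sum(discount_flow(seg[, "utility"], seg[, "t0"], seg[, "t1"], annual_rate))
  } else 0
  by_cat <- stats::setNames(numeric(length(.cost_categories)), .cost_categories)
  pts <- traj$points
  if (nrow(pts)) {
    d <- discount_point(pts[, "amount"], pts[, "t"], annual_rate)
    for (k in seq_along(.cost_categories))
      by_cat[k] <- by_cat[k] + sum(d[pts[, "category"] == k])
  }
  fl <- traj$flows
  if (nrow(fl)) {
    d <- discount_flow(fl[, "amount_per_year"], fl[, "t0"], fl[, "t1"],
                       annual_rate)
    for (k in seq_along(.cost_categories))
      by_cat[k] <- by_cat[k] + sum(d[fl[, "category"] == k])
  }
  list(cost = sum(by_cat), qaly = qaly, cost_by_category = by_cat)
}
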