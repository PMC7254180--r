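#' @keywords internal
"_PACKAGE"

# Supported distribution families and the meaning of param1/param2:
#   beta                 param1 = alpha, param2 = beta
#   gamma                param1 = shape, param2 = scale
#   lognormal            param1 = sd of log (baseline is the median)
#   normal               param1 = standard error (mean is the baseline)
#   dirichlet_component  param1 = count n, param2 = total N (N keys the group)
#   weibull              param1 = shape, param2 = scale
#   fixed                no parameters; always the baseline
.wdm_families <- c("beta", "gamma", "lognormal", "normal",
                   "dirichlet_component", "weibull", "fixed")

# Units whose values live on [0, 1]
.unit_01 <- c("probability", "proportion", "utility", "disutility")
# Units that must be non-negative
.unit_nonneg <- c("GBP", "GBP_per_day", "GBP_per_year", "GBP_per_28d",
                  "GBP_per_30d", "years", "count", "per_year", "RR", "OR")

#' Path to the parameter registry shipped with the package
#'
#' The registry transcribes the published parameter summary for the UK
#' schizophrenia whole-disease model (distribution family, parameters,
#' baseline value, units) and adds explicitly flagged placeholder entries for
#' quantities the published summary does not report (baseline event risks,
#' adverse-event incidences, mortality). Placeholders can be enumerated with
#' \code{\link{placeholder_entries}}.
#'
#' @return File path of the shipped CSV registry.
#' @export
default_registry <- function() {
  system.file("extdata", "parameters.csv", package = "schizwdm",
              mustWork = TRUE)
}

.validate_entry <- function(e) {
  errs <- character(0)
  bad <- function(msg) errs <<- c(errs, sprintf("entry '%s': %s", e$name, msg))
  if (!e$family %in% .wdm_families)
    return(sprintf("entry '%s': unknown family '%s'", e$name, e$family))
  p1 <- e$param1; p2 <- e$param2; b <- e$baseline
  needs2 <- e$family %in% c("beta", "gamma", "dirichlet_component", "weibull")
  if (needs2) {
    if (is.na(p1) || is.na(p2)) bad("family requires param1 and param2")
    else if (p1 <= 0 || p2 <= 0) bad("distribution parameters must be strictly positive")
  }
  if (e$family %in% c("lognormal", "normal")) {
    if (is.na(p1) || p1 <= 0) bad("param1 (spread) must be strictly positive")
  }
  if (e$family == "dirichlet_component" && !is.na(p1) && !is.na(p2) && p1 > p2)
    bad("dirichlet_component requires n <= N")
  if (is.na(b)) bad("baseline missing")
  else {
    # baseline within the distribution's support
    if (e$family %in% c("beta", "dirichlet_component") && (b <= 0 || b >= 1))
      bad("baseline outside (0, 1) support")
    if (e$family %in% c("gamma", "weibull", "lognormal") && b <= 0)
      bad("baseline outside positive support")
    if (e$units %in% .unit_01 && (b < 0 || b > 1))
      bad(sprintf("baseline %g outside [0, 1] for units '%s'", b, e$units))
    if (e$units %in% .unit_nonneg && b < 0)
      bad(sprintf("baseline %g negative for units '%s'", b, e$units))
  }
  errs
}

#' Load and validate a parameter registry
#'
#' Reads a flat CSV with columns \code{name, family, param1, param2,
#' baseline, units, provenance, citation}. All rows are validated (known
#' family, strictly positive distribution parameters, baseline inside the
#' distribution's support, probabilities and utilities in [0, 1]); validation
#' failures are aggregated into a single error naming every offending entry.
#'
#' @param path Path to a registry CSV file.
#' @return An object of class \code{wdm_registry}: the registry data frame.
#' @seealso \code{\link{default_registry}}, \code{\link{mean_of}},
#'   \code{\link{sample_parameters}}
#' @export
#' @examples
#' reg <- load_registry(default_registry())
#' reg[reg$name == "cbt_provision", ]
load_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "family", "param1", "param2", "baseline", "units",
            "provenance", "citation")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("registry is missing columns: ", paste(miss, collapse = ", "))
  df$param1 <- as.numeric(df$param1)
  df$param2 <- as.numeric(df$param2)
  df$baseline <- as.numeric(df$baseline)
  if (anyDuplicated(df$name))
    stop("duplicate registry entries: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  errs <- unlist(lapply(seq_len(nrow(df)), function(i) .validate_entry(df[i, ])))
  if (length(errs))
    stop("invalid registry:\n  ", paste(errs, collapse = "\n  "))
  structure(df, class = c("wdm_registry", "data.frame"))
}

#' Write a registry back to CSV
#'
#' Inverse of \code{\link{load_registry}}; a load/write/load round trip
#' reproduces the registry exactly.
#'
#' @param registry A \code{wdm_registry}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE)
  invisible(path)
}

#' Enumerate placeholder entries of a registry
#'
#' @param registry A \code{wdm_registry}.
#' @return Data frame of entries whose provenance is \code{"placeholder"}.
#' @export
placeholder_entries <- function(registry) {
  as.data.frame(registry)[registry$provenance == "placeholder", ]
}

#' Analytic mean of a registry distribution
#'
#' beta: a/(a+b); gamma: shape x scale; normal: mean; dirichlet component:
#' n/N; lognormal (baseline = median): baseline x exp(sdlog^2 / 2); weibull:
#' scale x Gamma(1 + 1/shape); fixed: the baseline.
#'
#' @param spec A single registry row (one-row data frame or list with fields
#'   \code{family, param1, param2, baseline}).
#' @return The analytic mean, a scalar.
#' @export
#' @examples
#' mean_of(list(family = "beta", param1 = 1011, param2 = 1454, baseline = 0.4101))
mean_of <- function(spec) {
  spec <- as.list(spec)
  switch(spec$family,
    beta = spec$param1 / (spec$param1 + spec$param2),
    gamma = spec$param1 * spec$param2,
    normal = spec$baseline,
    dirichlet_component = spec$param1 / spec$param2,
    lognormal = spec$baseline * exp(spec$param1^2 / 2),
    weibull = spec$param2 * gamma(1 + 1 / spec$param1),
    fixed = spec$baseline,
    stop("unknown family '", spec$family, "'")
  )
}

#' Deterministic parameter set (every entry at its baseline)
#'
#' @param registry A \code{wdm_registry}.
#' @return A \code{wdm_params} named numeric vector with attribute
#'   \code{mode = "deterministic"}.
#' @export
baseline_parameters <- function(registry) {
  v <- stats::setNames(registry$baseline, registry$name)
  structure(v, mode = "deterministic", seed = NA_integer_, resamples = 0L,
            class = "wdm_params")
}

# Relative mean discrepancy beyond which a PSA gamma/weibull draw is rescaled
# so that its mean equals the printed baseline (shape, hence CV, preserved).
.rescale_tol <- 0.05

.draw_entry <- function(e) {
  switch(e$family,
    beta = stats::rbeta(1, e$param1, e$param2),
    gamma = {
      sc <- e$param2
      m <- e$param1 * e$param2
      if (abs(m - e$baseline) / e$baseline > .rescale_tol)
        sc <- e$baseline / e$param1
      stats::rgamma(1, shape = e$param1, scale = sc)
    },
    lognormal = stats::rlnorm(1, meanlog = log(e$baseline), sdlog = e$param1),
    normal = stats::rnorm(1, mean = e$baseline, sd = e$param1),
    weibull = {
      m <- e$param2 * gamma(1 + 1 / e$param1)
      f <- if (abs(m - e$baseline) / e$baseline > .rescale_tol) e$baseline / m else 1
      f * stats::rweibull(1, shape = e$param1, scale = e$param2)
    },
    fixed = e$baseline
  )
}

.entry_support_ok <- function(x, e) {
  if (e$units %in% .unit_01 && (x < 0 || x > 1)) return(FALSE)
  if (e$units %in% .unit_nonneg && x < 0) return(FALSE)
  TRUE
}

#' Draw one joint parameter sample for probabilistic sensitivity analysis
#'
#' Each entry is drawn independently from its family (relative risks and odds
#' ratios on the log scale with median at the baseline), except that
#' \code{dirichlet_component} entries sharing a total N are drawn as one
#' proper joint Dirichlet so the shares sum to 1. Draws that land outside the
#' support implied by an entry's units (probabilities and utilities in
#' [0, 1], costs non-negative) are redrawn; the number of redraws is recorded
#' in the \code{resamples} attribute. \code{fixed} entries always take their
#' baseline. Reproducible under the same seed.
#'
#' @param registry A \code{wdm_registry}.
#' @param seed Integer seed for the joint draw.
#' @return A \code{wdm_params} named numeric vector, attribute
#'   \code{mode = "sampled"}.
#' @export
sample_parameters <- function(registry, seed) {
  set.seed(seed)
  n <- nrow(registry)
  out <- numeric(n)
  resamples <- 0L
  dir_done <- list()
  for (i in seq_len(n)) {
    e <- as.list(as.data.frame(registry)[i, ])
    if (e$family == "dirichlet_component") {
      key <- as.character(e$param2)
      if (is.null(dir_done[[key]])) {
        idx <- which(registry$family == "dirichlet_component" &
                       registry$param2 == e$param2)
        g <- stats::rgamma(length(idx), shape = registry$param1[idx], scale = 1)
        dir_done[[key]] <- stats::setNames(g / sum(g), registry$name[idx])
      }
      out[i] <- dir_done[[key]][[e$name]]
      next
    }
    x <- .draw_entry(e)
    tries <- 0L
    while (!.entry_support_ok(x, e)) {
      tries <- tries + 1L
      if (tries > 1000L) stop("entry '", e$name, "': cannot sample within support")
      x <- .draw_entry(e)
    }
    resamples <- resamples + tries
    out[i] <- x
  }
  structure(stats::setNames(out, registry$name), mode = "sampled",
            seed = as.integer(seed), resamples = resamples,
            class = "wdm_params")
}

#' @export
print.wdm_params <- function(x, ...) {
  cat(sprintf("<wdm_params> %d parameters, mode = %s\n",
              length(x), attr(x, "mode")))
  invisible(x)
}

#' @export
print.wdm_registry <- function(x, ...) {
  cat(sprintf("<wdm_registry> %d entries (%d placeholder)\n",
              nrow(x), sum(x$provenance == "placeholder")))
  NextMethod()
}

# Internal: fetch a parameter value, failing loudly on unresolved names.
.pv <- function(params, name) {
  v <- params[name]
  if (is.na(names(v)) || is.na(v))
    stop("unresolved parameter name: '", name, "'", call. = FALSE)
  unname(v)
}
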