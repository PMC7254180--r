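# The five decision topics and their intervention arms. Every arm runs the
# entire whole-disease model; arms within a topic differ only at the topic's
# decision node.
.topics <- c("chr", "acute", "fep-ap", "fep-fi", "trs-ap")

#' Decision topics known to the model
#'
#' @return Character vector of topic identifiers: \code{chr} (CBT for people
#'   at clinical high risk), \code{acute} (hospital admission vs a mix with
#'   crisis resolution and home treatment), \code{fep-ap} (first-line oral
#'   antipsychotic for first-episode psychosis), \code{fep-fi} (family
#'   intervention), \code{trs-ap} (antipsychotic for treatment resistance).
#' @export
wdm_topics <- function() .topics

#' Path of the shipped configuration file for a topic
#'
#' @param topic One of \code{wdm_topics()}.
#' @return File path of the YAML config.
#' @export
topic_config_path <- function(topic) {
  if (!topic %in% .topics)
    stop("unknown topic '", topic, "'; expected one of: ",
         paste(.topics, collapse = ", "))
  system.file("extdata", "topics", paste0(topic, ".yaml"),
              package = "schizwdm", mustWork = TRUE)
}

#' Read a topic configuration
#'
#' A topic config is a YAML file with fields \code{topic},
#' \code{n_patients}, \code{seed}, \code{wtp}, and \code{arms}: a named map
#' of scenario-field overrides applied on top of
#' \code{\link{scenario_config}} defaults.
#'
#' @param path YAML config path.
#' @return List with \code{topic}, \code{n_patients}, \code{seed},
#'   \code{wtp}, and \code{scenarios} (named list of \code{wdm_scenario}).
#' @export
read_topic_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("topic", "n_patients", "seed", "arms")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("malformed config '", path, "': missing ",
         paste(miss, collapse = ", "))
  scenarios <- lapply(cfg$arms, function(ov) do.call(scenario_config,
                                                     as.list(ov)))
  list(topic = cfg$topic, n_patients = cfg$n_patients, seed = cfg$seed,
       wtp = cfg$wtp %||% c(20000, 30000), scenarios = scenarios)
}

#' Run one decision topic end to end
#'
#' Loads the topic configuration, generates the cohort once, simulates every
#' arm of the topic through the entire whole-disease model under common
#' random numbers with deterministic (baseline) parameters, performs the
#' incremental analysis, optionally runs a probabilistic sensitivity
#' analysis, and writes the result bundle (arm results, CEA table, CEAC if
#' requested, JSON manifest, text log) to \code{out_dir}. Re-running the
#' same configuration reproduces the outputs byte-identically.
#'
#' @param topic One of \code{wdm_topics()}.
#' @param out_dir Output directory (created if needed).
#' @param registry_path Registry CSV (default: shipped registry).
#' @param config_path Topic YAML (default: shipped config).
#' @param n_patients,seed Optional overrides of the config values.
#' @param k_samples PSA draws; 0 (default) skips the PSA.
#' @param psa_n_patients Cohort size per PSA draw.
#' @param annual_rate Discount rate.
#' @return Invisibly, a list with \code{arms} (list of
#'   \code{wdm_arm_result}), \code{cea} (the \code{wdm_cea_table}),
#'   \code{ceac} (or NULL), and \code{manifest}.
#' @export
run_topic <- function(topic, out_dir, registry_path = default_registry(),
                      config_path = topic_config_path(topic),
                      n_patients = NULL, seed = NULL, k_samples = 0,
                      psa_n_patients = 10000, annual_rate = 0.035) {
  cfg <- read_topic_config(config_path)
  if (!identical(cfg$topic, topic))
    stop("config at '", config_path, "' is for topic '", cfg$topic, "'")
  if (!is.null(n_patients)) cfg$n_patients <- n_patients
  if (!is.null(seed)) cfg$seed <- seed
  registry <- load_registry(registry_path)
  params <- baseline_parameters(registry)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- generate_cohort(cfg$n_patients, params, mode = "stratified",
                            seed = cfg$seed)
  arms <- lapply(names(cfg$scenarios), function(a)
    simulate_cohort(cohort, cfg$scenarios[[a]], params, seed = cfg$seed,
                    annual_rate = annual_rate, arm_name = a))
  names(arms) <- names(cfg$scenarios)
  cea <- efficiency_frontier(arms)

  arm_df <- data.frame(
    arm = vapply(arms, function(a) a$arm_name, ""),
    mean_cost = vapply(arms, function(a) a$mean_cost, 0),
    mean_qaly = vapply(arms, function(a) a$mean_qaly, 0),
    n_patients = vapply(arms, function(a) a$n_patients, 0L),
    row.names = NULL)
  cats <- t(vapply(arms, function(a) a$cost_by_category,
                   numeric(length(.cost_categories))))
  arm_df <- cbind(arm_df, as.data.frame(cats, row.names = NULL))
  utils::write.csv(arm_df, file.path(out_dir, "arm_results.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(cea), file.path(out_dir, "cea_table.csv"),
                   row.names = FALSE)

  ceac <- NULL
  if (k_samples > 0) {
    psa <- run_psa(cfg$scenarios, registry, k_samples = k_samples,
                   n_patients = psa_n_patients, seed = cfg$seed,
                   wtp = cfg$wtp, annual_rate = annual_rate)
    ceac <- psa$ceac
    utils::write.csv(psa$ceac, file.path(out_dir, "ceac.csv"),
                     row.names = FALSE)
    utils::write.csv(psa$draws, file.path(out_dir, "psa_draws.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    topic = topic,
    registry = registry_path,
    registry_md5 = unname(tools::md5sum(registry_path)),
    config = config_path,
    config_md5 = unname(tools::md5sum(config_path)),
    arms = names(cfg$scenarios),
    n_patients = cfg$n_patients,
    seed = cfg$seed,
    k_samples = k_samples,
    annual_rate = annual_rate,
    package_version = as.character(utils::packageVersion("schizwdm"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  ph <- placeholder_entries(registry)
  log_lines <- c(
    sprintf("topic: %s", topic),
    sprintf("arms: %s", paste(names(cfg$scenarios), collapse = ", ")),
    sprintf("n_patients: %d, seed: %d, k_samples: %d",
            cfg$n_patients, cfg$seed, k_samples),
    "placeholder parameters in use:",
    sprintf("  %s = %g (%s)", ph$name, ph$baseline, ph$citation))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(arms = arms, cea = cea, ceac = ceac, manifest = manifest))
}
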