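#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated list.
#' Per-stage seeds are derived deterministically from the master seed by a
#' fixed counter scheme, so individual stages can be rerun in isolation.
#'
#' @param input Path to the item-response CSV (header of 16 item labels,
#'   one integer row per respondent).
#' @param output_dir Directory for all result files (created if needed).
#' @param cutoff Screening cutoff for both totals (default 5).
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param rule Edge symmetrization rule, `"AND"` or `"OR"`.
#' @param boot_B Replicates for edge CIs and difference tests (default 1000).
#' @param cs_B Subsamples per drop proportion for the CS-coefficient
#'   (default 1000).
#' @param drop_grid Case-dropping proportions (default 0.10-0.75 by 0.05).
#' @param nira_mode `"exact"` or `"mc"`.
#' @param n_samples Gibbs draws per score in mc mode.
#' @param mantel_perm Mantel permutations (default 9999).
#' @param seed Master seed (integer).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, output_dir, cutoff = 5, gamma = 0.25,
                            rule = "AND", boot_B = 1000, cs_B = 1000,
                            drop_grid = seq(0.10, 0.75, by = 0.05),
                            nira_mode = "exact", n_samples = 10000,
                            mantel_perm = 9999, seed = 1) {
  cfg <- list(input = input, output_dir = output_dir, cutoff = cutoff,
              gamma = gamma, rule = rule, boot_B = boot_B, cs_B = cs_B,
              drop_grid = drop_grid, nira_mode = nira_mode,
              n_samples = n_samples, mantel_perm = mantel_perm,
              seed = as.integer(seed))
  stopifnot(cfg$cutoff >= 1, cfg$gamma >= 0, cfg$rule %in% c("AND", "OR"),
            cfg$boot_B >= 100, cfg$cs_B >= 1,
            cfg$nira_mode %in% c("exact", "mc"))
  class(cfg) <- "pipeline_config"
  cfg
}

# fixed counter scheme keeping derived seeds within 32-bit range
stage_seed <- function(master, k) {
  as.integer((as.numeric(master) + 1000003 * k) %% 2147483647L)
}

expected_item_labels <- function() c(paste0("PHQ", 1:9), paste0("GAD", 1:7))

#' Run the full symptom-network pipeline
#'
#' Executes, in order: descriptive statistics and screening prevalence;
#' binarization and eLasso Ising estimation (plus the partial-correlation
#' network and a Mantel comparison of the two); centrality; bootstrap
#' accuracy/stability; simulated alleviating and aggravating interventions;
#' and the correlations of intervention outcomes with thresholds and EI.
#' Every table named in the stage modules is written to `output_dir` as
#' plain CSV/JSON together with a run manifest. Any stage error aborts with a
#' stage-named message and leaves a `FAILED` marker next to the partial
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("symptomnet")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                 out("FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[length(manifest$stages) + 1]] <<-
      list(name = name, seed = stage_seed(config$seed, length(manifest$stages) + 1))
    res
  }

  items <- read_items_csv(config$input)
  missing <- setdiff(expected_item_labels(), colnames(items))
  if (length(missing)) {
    stop("input is missing item column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  items <- item_matrix(unclass(items)[, expected_item_labels()])
  communities <- ifelse(attr(items, "scale") == "PHQ", "depression", "anxiety")

  desc <- stage("descriptives", function() {
    d <- describe_items(items)
    utils::write.csv(d, out("descriptives.csv"), row.names = FALSE)
    prev <- classify_comorbidity(items, cutoff = config$cutoff)
    jsonlite::write_json(
      list(n_total = prev$n_total, counts = as.list(prev$counts),
           proportions = as.list(prev$proportions),
           per_symptom_prevalence = as.list(prev$per_symptom_prevalence),
           alpha = list(PHQ = cronbach_alpha(items, "PHQ"),
                        GAD = cronbach_alpha(items, "GAD"))),
      out("prevalence.json"), digits = NA, auto_unbox = TRUE)
    prev
  })

  net <- stage("network", function() {
    bin <- binarize(items)
    fit <- fit_elasso(bin, gamma = config$gamma, rule = config$rule,
                      communities = communities)
    write_ising_json(fit, out("ising_model.json"))
    pr <- pair_index(fit$labels)
    utils::write.csv(
      data.frame(node_i = fit$labels[pr$i], node_j = fit$labels[pr$j],
                 weight = fit$omega[cbind(pr$i, pr$j)]),
      out("edges.csv"), row.names = FALSE)
    utils::write.csv(data.frame(label = fit$labels, tau = unname(fit$tau)),
                     out("thresholds.csv"), row.names = FALSE)
    pcn <- partial_correlation_network(items)
    mt <- mantel_test(fit$omega, pcn, n_perm = config$mantel_perm,
                      seed = stage_seed(config$seed, 2))
    jsonlite::write_json(mt, out("mantel.json"), digits = NA, auto_unbox = TRUE)
    list(fit = fit, bin = bin)
  })

  cen <- stage("centrality", function() {
    ct <- centrality_table(net$fit)
    utils::write.csv(ct, out("centrality.csv"), row.names = FALSE)
    ct
  })

  stab <- stage("stability", function() {
    boot <- bootstrap_networks(net$bin, B = config$boot_B,
                               seed = stage_seed(config$seed, 4),
                               communities = communities,
                               gamma = config$gamma, rule = config$rule)
    ci <- edge_ci_bootstrap(boot)
    utils::write.csv(ci, out("edge_ci.csv"), row.names = FALSE)
    dt <- difference_tests(boot)
    cs_ei <- cs_coefficient(net$bin, "EI", drop_grid = config$drop_grid,
                            B = config$cs_B,
                            seed = stage_seed(config$seed, 5),
                            gamma = config$gamma, rule = config$rule)
    cs_bei <- cs_coefficient(net$bin, "bridgeEI",
                             drop_grid = config$drop_grid, B = config$cs_B,
                             seed = stage_seed(config$seed, 6),
                             communities = communities,
                             gamma = config$gamma, rule = config$rule)
    jsonlite::write_json(
      list(B = config$boot_B, drop_grid = config$drop_grid,
           cs = list(EI = as.numeric(cs_ei), bridgeEI = as.numeric(cs_bei)),
           significant_edge_differences = mean(dt$edges[upper.tri(dt$edges)]),
           significant_ei_differences = mean(dt$ei[upper.tri(dt$ei)]),
           significant_bridge_ei_differences =
             mean(dt$bridge_ei[upper.tri(dt$bridge_ei)])),
      out("stability.json"), digits = NA, auto_unbox = TRUE)
    list(cs_ei = cs_ei, cs_bei = cs_bei)
  })

  nira_one <- function(direction, counter) {
    res <- nira_run(net$fit, direction = direction, mode = config$nira_mode,
                    seed = stage_seed(config$seed, counter),
                    n_samples = config$n_samples)
    utils::write.csv(res$table,
                     out(paste0("nira_", direction, ".csv")),
                     row.names = FALSE)
    res
  }
  nal <- stage("nira_alleviating", function() nira_one("alleviating", 7))
  nag <- stage("nira_aggravating", function() nira_one("aggravating", 8))

  stage("correlations", function() {
    ei <- expected_influence(net$fit)
    tau <- net$fit$tau
    res <- list(
      alleviating_vs_threshold = correlate_outcomes(nal$table$nira_outcome, tau),
      alleviating_vs_ei = correlate_outcomes(nal$table$nira_outcome, ei),
      aggravating_vs_threshold = correlate_outcomes(nag$table$nira_outcome, tau),
      aggravating_vs_ei = correlate_outcomes(nag$table$nira_outcome, ei)
    )
    jsonlite::write_json(res, out("nira_correlations.json"),
                         digits = NA, auto_unbox = TRUE)
    res
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, out("manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(manifest)
}

#' Write a synthetic dataset and its ground truth to disk
#'
#' Generates item responses from an Ising model (by default the fixed
#' [reference_network()]) and writes the CSV alongside the ground-truth model
#' JSON, so a subsequent [run_pipeline()] on the CSV can be compared against
#' the truth.
#'
#' @param output_dir Output directory (created if needed).
#' @param n Number of respondents.
#' @param seed Integer seed.
#' @param model Generating [ising_model()] (default [reference_network()]).
#' @param ... Passed to [make_questionnaire_data()].
#' @return Invisibly, a list with the two file paths.
#' @export
simulate_dataset <- function(output_dir, n = 708, seed = 1,
                             model = reference_network(), ...) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  items <- make_questionnaire_data(model, n = n, seed = seed, ...)
  csv <- file.path(output_dir, "items.csv")
  mod <- file.path(output_dir, "true_model.json")
  write_items_csv(items, csv)
  write_ising_json(model, mod)
  invisible(list(items = csv, model = mod))
}
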