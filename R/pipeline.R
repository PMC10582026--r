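# End-to-end demo pipeline: simulate a cohort, analyse one subject's
# canopy recording and graded test, prescribe the two session types,
# analyse a simulated session, and produce the trial summary table —
# all from one config, with one seed, writing a run manifest.

#' Run the demonstration pipeline from a config
#'
#' Config fields (YAML file or list): `out_dir` (required), `seed`
#' (default 1), `n_comb`/`n_mict` (cohort sizes, default 4),
#' `demo_preset` (subject preset for the single-subject stages, default
#' `"COMB_W0"`). Outputs: the cohort trial table, the group-by-time summary
#' table with ANOVA p-values, the demo subject's BMR and graded-test
#' results, both session plans, the simulated-session summary, and a
#' `manifest.json` listing every file written. Numeric outputs are
#' bit-reproducible for a fixed config + seed.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return the run manifest (a list), invisibly.
#' @export
run_pipeline <- function(config) {
  cfg_path <- NULL
  if (is.character(config) && length(config) == 1L) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_domain("config must be a list or a YAML path")
  if (is.null(config$out_dir)) stop_domain("config field 'out_dir' is required")
  defaults <- list(seed = 1L, n_comb = 4L, n_mict = 4L,
                   demo_preset = "COMB_W0")
  unknown <- setdiff(names(config),
                     c(names(defaults), "out_dir"))
  if (length(unknown))
    stop_domain("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  demo_preset <- group_preset(cfg$demo_preset)  # errors on unknown preset
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit_json <- function(x, name) {
    path <- file.path(cfg$out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    outputs <<- c(outputs, path)
    path
  }
  emit_csv <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    write.table(df, path, sep = ",", quote = TRUE, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  # 1. cohort + trial statistics
  cohort <- simulate_cohort(cfg$n_comb, cfg$n_mict, seed = cfg$seed)
  tt_path <- file.path(cfg$out_dir, "trial_table.csv")
  write_trial_table(cohort, tt_path)
  outputs <- c(outputs, tt_path)
  table1 <- build_table1(cohort)
  emit_csv(table1, "summary_table.csv")
  anovas <- lapply(trial_outcomes(cohort), function(oc) {
    a <- mixed_anova_2x2(cohort, oc)
    list(outcome = oc, effects = a$effects, posthoc = a$posthoc,
         n_per_group = as.list(a$n_per_group))
  })
  emit_json(anovas, "anova_results.json")

  # 2. single-subject stages
  subj <- make_subject(demo_preset, seed = cfg$seed + 1L)
  noise <- noise_model(seed = cfg$seed + 2L)
  bmr_rec <- simulate_bmr_recording(subj, noise)
  bmr_res <- analyze_bmr(bmr_rec)
  emit_json(bmr_res, "bmr_result.json")
  grad_rec <- simulate_graded_test(subj, noise_model(seed = cfg$seed + 3L))
  grad <- analyze_graded(grad_rec, subject = subj,
                         pox = resting_pox(bmr_res$bmr_mj_day))
  emit_json(grad[setdiff(names(grad), "stages")], "graded_result.json")
  emit_csv(grad$stages, "graded_stages.csv")
  comb_plan <- design_comb_session(grad, subj$ffm)
  mict_plan <- design_mict_session(grad, subj$ffm)
  emit_json(list(COMB = unclass(comb_plan), MICT = unclass(mict_plan)),
            "session_plans.json")
  sess <- simulate_submax_session(subj, mict_plan,
                                  noise_model(seed = cfg$seed + 4L))
  summ <- summarize_session(sess, subject = subj)
  emit_json(summ[setdiff(names(summ), "windows")], "session_summary.json")

  manifest <- list(command = "run_pipeline",
                   config = cfg,
                   config_file = cfg_path,
                   config_hash = if (!is.null(cfg_path))
                     unname(tools::md5sum(cfg_path)) else NA,
                   seed = cfg$seed,
                   package_version = as.character(packageVersion("oxitrain")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      usetz = TRUE),
                   outputs = outputs,
                   schema_version = 1L)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}
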