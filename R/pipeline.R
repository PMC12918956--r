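#' Run the analysis pipeline end to end
#'
#' Drives the stages on a single configuration: simulate (or load) a
#' monolayer, compute the V_rms time course, detect T1 events and rates,
#' compute shape metrics, and test the rate-speed relation. Outputs are
#' written to one directory per run with stage subdirectories and a JSON
#' manifest at the root recording the software version, a hash of the
#' configuration, output checksums, per-stage timings and accumulated
#' warnings. Re-running the same configuration reproduces all seeded outputs
#' bit-identically.
#'
#' @param config Named list (or path to a JSON file): fields of
#'   [monolayer_config()] plus optional `stages` (subset of `"simulate"`,
#'   `"kinematics"`, `"topology"`, `"nullmodel"`), `vrms_window_frames`,
#'   `rate_bin_h`, `n_boot`, `trajectory_csv` (analyze an existing
#'   trajectory instead of simulating).
#' @param out_dir Output directory (created; must be empty or absent).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stages <- config$stages %||% c("simulate", "kinematics", "topology",
                                 "nullmodel")
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  warnings_log <- character(0)
  timings <- list()
  outputs <- character(0)
  note <- function(expr, stage) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, paste0(stage, ": ",
                                              conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  cfg_fields <- intersect(names(config),
                          names(formals(monolayer_config)))
  mc <- do.call(monolayer_config, config[cfg_fields])
  sim <- NULL
  traj <- NULL
  if ("simulate" %in% stages && is.null(config$trajectory_csv)) {
    sim <- note(generate_monolayer(mc), "simulate")
    traj <- sim$trajectories
    sd <- file.path(out_dir, "simulate")
    dir.create(sd, showWarnings = FALSE)
    outputs <- c(outputs,
                 write_trajectory_csv(traj, file.path(sd, "trajectories.csv")),
                 write_edges_csv(sim$graphs, file.path(sd, "edges.csv")),
                 write_events_csv(sim$events,
                                  file.path(sd, "events_ground_truth.csv")))
  } else if (!is.null(config$trajectory_csv)) {
    traj <- read_trajectory_csv(config$trajectory_csv, mc$box_um,
                                mc$periodic)
  }
  if ("kinematics" %in% stages && !is.null(traj)) {
    tc <- note(vrms_timecourse(traj,
                               config$vrms_window_frames %||% 1L),
               "kinematics")
    kd <- file.path(out_dir, "kinematics")
    dir.create(kd, showWarnings = FALSE)
    p <- file.path(kd, "vrms_timecourse.csv")
    utils::write.csv(tc, p, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, p)
  }
  rates <- NULL
  if ("topology" %in% stages && !is.null(sim)) {
    ev <- note(detect_t1(sim$graphs, k = sim$persistence_k, traj = traj),
               "topology")
    rates <- t1_rate(ev, sim$graphs, config$rate_bin_h %||% (4 * mc$dt))
    shp <- shape_metrics(sim$tessellation)
    td <- file.path(out_dir, "topology")
    dir.create(td, showWarnings = FALSE)
    outputs <- c(outputs,
                 write_events_csv(ev, file.path(td, "events_detected.csv")))
    p1 <- file.path(td, "t1_rates.csv")
    utils::write.csv(rates, p1, row.names = FALSE, quote = FALSE)
    p2 <- file.path(td, "shape_metrics.csv")
    utils::write.csv(shp, p2, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, p1, p2)
  }
  if ("nullmodel" %in% stages && !is.null(rates) && !is.null(traj)) {
    tc <- vrms_timecourse(traj, config$vrms_window_frames %||% 1L)
    bins <- findInterval(tc$t_mid, rates$t_start)
    ok <- bins >= 1L & bins <= nrow(rates)
    pairs <- data.frame(vrms = tapply(tc$vrms[ok], bins[ok], mean),
                        rate = rates$rate_per_cell_h[sort(unique(bins[ok]))])
    nd <- file.path(out_dir, "nullmodel")
    dir.create(nd, showWarnings = FALSE)
    p <- file.path(nd, "rate_speed_pairs.csv")
    utils::write.csv(pairs, p, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, p)
    if (nrow(pairs) >= 5L && stats::var(pairs$vrms) > 0) {
      rel <- note(rate_speed_test(pairs, config$n_boot %||% 2000L,
                                  seed = mc$seed), "nullmodel")
      pred <- rigid_pack_prediction(pairs$vrms,
                                    c(pairs$vrms[1L], pairs$rate[1L]))
      rep_path <- file.path(nd, "rate_speed_test.json")
      write_json_report(list(slope = rel$slope, ci = rel$ci,
                             p_value = rel$p_value, n_pairs = rel$n_pairs,
                             null_predicted_rate = pred$predicted_rate[1L],
                             seed = mc$seed),
                        rep_path)
      outputs <- c(outputs, rep_path)
    }
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tmp <- tempfile(fileext = ".json")
  writeLines(cfg_json, tmp)
  manifest <- list(
    software = paste0("epijam ",
                      as.character(utils::packageVersion("epijam"))),
    config = config,
    config_md5 = unname(tools::md5sum(tmp)),
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs)),
    timings_s = timings,
    warnings = warnings_log,
    run_time = format(Sys.time(), tz = "UTC"))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
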