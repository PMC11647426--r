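log_msg <- function(level, ...) {
  if (getOption("parkfield.log_level", "info") == "quiet") return(invisible())
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

group_label <- function(drug, dose) ifelse(drug == "saline", "saline",
                                           paste(drug, dose))

#' Simulate stage: dosing plan plus trajectory files
#'
#' @param cfg A `run_config`.
#' @param out Output directory.
#' @return The cohort manifest (invisibly), written as `manifest.csv`.
#' @export
stage_simulate <- function(cfg, out) {
  plan <- make_lattice_design(cfg$design$n_animals,
                              doses = as.list(cfg$design$doses),
                              n_rounds = cfg$design$n_rounds,
                              seed = cfg$seed)
  log_msg("info", "simulate: ", nrow(plan), " sessions -> ", out)
  simulate_cohort(plan, pd = config_pd(cfg), bp = config_behavior(cfg),
                  seed = cfg$seed, dt = cfg$session$dt,
                  duration = cfg$session$duration_min * 60,
                  arena = config_arena(cfg), dir = out)
}

read_manifest <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir, call. = FALSE)
  utils::read.csv(mf, stringsAsFactors = FALSE,
                  colClasses = c(slot = "character"))
}

#' Metrics stage: TOI summaries and per-bin metric table
#'
#' @param traj_dir Directory with trajectory CSVs and `manifest.csv`.
#' @param cfg A `run_config`.
#' @param out Output directory for `metrics.csv` and `bins.csv`.
#' @return List with `metrics` and `bins` data.frames.
#' @export
stage_metrics <- function(traj_dir, cfg, out) {
  manifest <- read_manifest(traj_dir)
  mc <- cfg$metrics
  toi <- mc$toi_min * 60
  res <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p))
      stop("missing trajectory for session ", manifest$session_id[i],
           ": ", p, call. = FALSE)
    traj <- read_trajectory(p)
    log_msg("debug", "metrics: ", manifest$session_id[i])
    s <- toi_summary(traj, toi = toi, v_thresh = mc$v_thresh,
                     min_dur = mc$min_dur, smooth_win = mc$smooth_win,
                     filter_cap = mc$filter_cap)
    b <- bin_metrics(traj, filter_cap = mc$filter_cap,
                     bin_width = mc$bin_width_min * 60)
    b$session_id <- s$session_id
    b$group <- group_label(s$drug, s$dose)
    b$drug <- s$drug
    list(s = s, b = b)
  })
  metrics <- do.call(rbind, lapply(res, `[[`, "s"))
  bins <- do.call(rbind, lapply(res, `[[`, "b"))
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  utils::write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)
  utils::write.csv(bins, file.path(out, "bins.csv"), row.names = FALSE)
  list(metrics = metrics, bins = bins)
}

#' Zones stage: occupancy fractions and dwell heatmaps
#'
#' @param traj_dir Directory with trajectories and manifest.
#' @param cfg A `run_config`.
#' @param out Output directory (`zones.csv` plus one plain-text heatmap
#'   matrix per session under `heatmaps/`).
#' @return The zones data.frame.
#' @export
stage_zones <- function(traj_dir, cfg, out) {
  manifest <- read_manifest(traj_dir)
  if (!dir.exists(file.path(out, "heatmaps")))
    dir.create(file.path(out, "heatmaps"), recursive = TRUE)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    traj <- read_trajectory(manifest$path[i])
    occ <- zone_occupancy(traj)
    utils::write.table(
      round(occ$heatmap, 6),
      file.path(out, "heatmaps", paste0(manifest$session_id[i], ".txt")),
      row.names = FALSE, col.names = FALSE)
    data.frame(session_id = manifest$session_id[i], drug = manifest$drug[i],
               dose = manifest$dose[i],
               frac_corner = occ$fractions[["corner"]],
               frac_wall = occ$fractions[["wall"]],
               frac_center = occ$fractions[["center"]])
  })
  zones <- do.call(rbind, rows)
  utils::write.csv(zones, file.path(out, "zones.csv"), row.names = FALSE)
  zones
}

#' Statistics stage: one-way ANOVA + Dunnett per metric, per-drug heatmaps
#'
#' @param metrics TOI summary data.frame (from [stage_metrics()]).
#' @param bins Long per-bin data.frame (from [stage_metrics()]).
#' @param cfg A `run_config`.
#' @param out Output directory.
#' @return List of per-metric results (`anova`, `dunnett`) and per-drug
#'   `heatmaps`.
#' @export
stage_stats <- function(metrics, bins, cfg, out) {
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  control <- cfg$stats$control
  toi_metrics <- c("distance_cm", "rotations_total", "abs_max_speed",
                   "avg_max_speed", "mobile_episode_count",
                   "pct_time_immobile", "freezing_episode_count",
                   "pct_time_freezing")
  metrics$group <- group_label(metrics$drug, metrics$dose)
  per_metric <- list()
  anova_rows <- list()
  for (m in toi_metrics) {
    groups <- split(metrics[[m]], metrics$group)
    groups <- groups[vapply(groups, length, 0L) >= 2L]
    if (length(groups) < 2L || !control %in% names(groups)) next
    gm <- grouped_metric(groups, metric = m, control = control)
    aov1 <- tryCatch(one_way_anova(gm), error = function(e) NULL)
    if (is.null(aov1)) { # degenerate metric (all values identical)
      log_msg("info", "stats: skipping degenerate metric ", m)
      next
    }
    dun <- dunnett_vs_control(gm)
    utils::write.csv(dun, file.path(out, paste0("dunnett_", m, ".csv")),
                     row.names = FALSE)
    anova_rows[[m]] <- data.frame(metric = m, F = aov1$F,
                                  df_between = aov1$df_between,
                                  df_within = aov1$df_within, p = aov1$p)
    per_metric[[m]] <- list(anova = aov1, dunnett = dun)
  }
  utils::write.csv(do.call(rbind, anova_rows), file.path(out, "anova.csv"),
                   row.names = FALSE)
  heatmaps <- list()
  for (drug in setdiff(unique(bins$drug), "saline")) {
    for (m in unique(bins$metric)) {
      sub <- bins[bins$metric == m & (bins$drug == drug | bins$group == control), ]
      if (length(unique(sub$group)) < 2L) next
      fit <- tryCatch(two_way_anova_timecourse(
        data.frame(session = sub$session_id, group = sub$group,
                   bin_start = sub$bin_start, value = sub$value),
        control = control, family = cfg$stats$sidak_family),
        error = function(e) NULL)
      if (is.null(fit)) next
      hm <- pvalue_heatmap(fit)
      utils::write.csv(hm, file.path(out, paste0("heatmap_", drug, "_", m,
                                                 ".csv")))
      heatmaps[[paste(drug, m)]] <- fit
    }
  }
  list(per_metric = per_metric, heatmaps = heatmaps)
}

#' Run the full pipeline: simulate, metrics, zones, stats
#'
#' Stages write into a staging directory that is promoted to `out` only when
#' every stage succeeds, so a failed run never leaves partial outputs in
#' place.  A machine-readable `run_log.json` records the seed, config hash
#' and package version; reruns with an identical config are bit-identical
#' except for timestamps.
#'
#' @param cfg A `run_config` (or path to a JSON config).
#' @param out Output directory.
#' @return List with `manifest`, `metrics`, `bins`, `zones`, `stats`
#'   (invisibly).
#' @export
run_pipeline <- function(cfg = default_config(), out = "parkfield_run") {
  if (is.character(cfg)) cfg <- load_config(cfg)
  staging <- paste0(out, ".staging")
  if (dir.exists(staging)) unlink(staging, recursive = TRUE)
  dir.create(staging, recursive = TRUE)
  cfg_path <- file.path(staging, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- stage_simulate(cfg, file.path(staging, "trajectories"))
  utils::write.csv(manifest, file.path(staging, "manifest.csv"),
                   row.names = FALSE)
  mb <- stage_metrics(file.path(staging, "trajectories"), cfg, staging)
  zones <- stage_zones(file.path(staging, "trajectories"), cfg, staging)
  stats_res <- stage_stats(mb$metrics, mb$bins, cfg,
                           file.path(staging, "stats"))
  run_log <- list(seed = cfg$seed,
                  config_md5 = unname(tools::md5sum(cfg_path)),
                  package_version = as.character(utils::packageVersion("parkfield")),
                  r_version = R.version.string,
                  n_sessions = nrow(manifest),
                  timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(run_log, file.path(staging, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (dir.exists(out)) unlink(out, recursive = TRUE)
  if (!file.rename(staging, out))
    stop("could not promote staging directory to ", out, call. = FALSE)
  log_msg("info", "pipeline complete -> ", out)
  invisible(list(manifest = manifest, metrics = mb$metrics, bins = mb$bins,
                 zones = zones, stats = stats_res))
}

#' Regenerate figures from a completed run directory
#'
#' Reads only the output CSVs (the numeric pipeline has no plotting
#' dependency) and renders: per-metric time-course curves (group mean +/-
#' SEM), adjusted p-value heatmaps, and the pooled position heatmap.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @param file Output PDF path (default `figures.pdf` inside `run_dir`).
#' @return `file`, invisibly.
#' @export
report_figures <- function(run_dir, file = file.path(run_dir, "figures.pdf")) {
  bins <- utils::read.csv(file.path(run_dir, "bins.csv"))
  grDevices::pdf(file, width = 8, height = 5)
  on.exit(grDevices::dev.off())
  for (m in unique(bins$metric)) {
    sub <- bins[bins$metric == m & !is.na(bins$value), ]
    agg_m <- tapply(sub$value, list(sub$bin_start, sub$group), mean)
    agg_s <- tapply(sub$value, list(sub$bin_start, sub$group),
                    function(v) stats::sd(v) / sqrt(length(v)))
    tt <- as.numeric(rownames(agg_m)) / 60 + 2.5
    graphics::matplot(tt, agg_m, type = "b", pch = 16, lty = 1,
                      xlab = "time post-injection (min)", ylab = m,
                      main = paste("Time course:", m))
    for (j in seq_len(ncol(agg_m))) {
      pos <- which(!is.na(agg_s[, j]) & agg_s[, j] > 0)
      if (length(pos))
        graphics::arrows(tt[pos], agg_m[pos, j] - agg_s[pos, j], tt[pos],
                         agg_m[pos, j] + agg_s[pos, j], angle = 90, code = 3,
                         length = 0.02, col = j, lwd = 0.5)
    }
    graphics::legend("topright", colnames(agg_m), col = seq_len(ncol(agg_m)),
                     pch = 16, cex = 0.7)
  }
  hm_files <- list.files(file.path(run_dir, "stats"), "^heatmap_.*\\.csv$",
                         full.names = TRUE)
  for (hf in hm_files) {
    hm <- as.matrix(utils::read.csv(hf, row.names = 1, check.names = FALSE))
    graphics::image(t(hm[rev(seq_len(nrow(hm))), , drop = FALSE]),
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    axes = FALSE, main = basename(hf))
    graphics::axis(1, at = seq(0, 1, length.out = ncol(hm)),
                   labels = colnames(hm), cex.axis = 0.6)
    graphics::axis(2, at = seq(0, 1, length.out = nrow(hm)),
                   labels = rev(rownames(hm)), las = 2, cex.axis = 0.6)
  }
  invisible(file)
}

#' Command-line entry point
#'
#' Subcommands mirror the pipeline stages: `simulate`, `metrics`, `zones`,
#' `stats`, `report`, and `run` (all stages).  Global flags: `--config`,
#' `--out`, `--in`, `--seed`, `--log-level`.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Exit status, invisibly.
#' @export
parkfield_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: parkfield <simulate|metrics|zones|stats|report|run> [--config cfg.json] [--in dir] [--out dir] [--seed n] [--log-level info|quiet]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  flag <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  cfg <- if (is.null(flag("config"))) default_config() else
    load_config(flag("config"))
  if (!is.null(flag("seed"))) cfg$seed <- as.integer(flag("seed"))
  options(parkfield.log_level = flag("log-level", "info"))
  out <- flag("out", "parkfield_out")
  indir <- flag("in", out)
  switch(cmd,
    simulate = stage_simulate(cfg, out),
    metrics = stage_metrics(indir, cfg, out),
    zones = stage_zones(indir, cfg, out),
    stats = {
      mets <- utils::read.csv(file.path(indir, "metrics.csv"))
      bins <- utils::read.csv(file.path(indir, "bins.csv"))
      stage_stats(mets, bins, cfg, out)
    },
    report = report_figures(indir),
    run = run_pipeline(cfg, out),
    stop("unknown command: ", cmd, call. = FALSE))
  invisible(0L)
}
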