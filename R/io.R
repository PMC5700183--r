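#  cli_io: CSV readers/writers with sidecar metadata, body-model config,
#  the trial manifest, and the pipeline driver. CSV (not a binary motion
#  format) is the interchange dialect so that synthetic-first testing needs
#  no binary dependencies.

sidecar_path <- function(path) {
  for (ext in c(".yaml", ".yml", ".json")) {
    p <- paste0(sub("\\.[^.]+$", "", path), ext)
    if (file.exists(p)) return(p)
  }
  NULL
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (is.null(sp)) return(list())
  if (grepl("\\.json$", sp)) jsonlite::read_json(sp, simplifyVector = TRUE)
  else yaml::read_yaml(sp)
}

check_columns <- function(df, needed, path) {
  miss <- setdiff(needed, names(df))
  if (length(miss))
    jm_stop("missing_channel",
            sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  for (col in needed) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      jm_stop("non_finite_value",
              sprintf("%s: non-finite value in column '%s' at row %d",
                      path, col, bad[1]))
  }
}

#' Read a force-plate trial from CSV
#'
#' Expects a header row naming at least `time`, `fx`, `fy`, `fz` (N;
#' x = anteroposterior, z = vertical) and optionally `copx`, `copy` (m).
#' The sampling rate comes from the `rate` argument, a sidecar YAML/JSON
#' file next to the CSV (same stem), or the time column, in that order of
#' precedence; a sidecar `bodyweight` (N) is carried along when present.
#'
#' @param path CSV path.
#' @param rate optional sampling rate in Hz.
#' @return object of class `force_trial`: `forces` (N x 3
#'   [sampled_signal()]), `cop` (N x 2 matrix or `NULL`), `rate`,
#'   `bodyweight` (or `NA`).
#' @export
read_force_csv <- function(path, rate = NULL) {
  if (!file.exists(path)) jm_stop("missing_file", paste("no such file:", path))
  df <- utils::read.csv(path)
  check_columns(df, c("time", "fx", "fy", "fz"), path)
  meta <- read_sidecar(path)
  if (is.null(rate)) rate <- meta$rate
  if (is.null(rate)) rate <- 1 / stats::median(diff(df$time))
  dt_file <- stats::median(diff(df$time))
  if (is.finite(dt_file) && abs(dt_file - 1 / rate) > 0.01 / rate)
    jm_stop("rate_mismatch",
            sprintf("%s: time column spacing %.6g s disagrees with rate %g Hz",
                    path, dt_file, rate))
  cop <- NULL
  if (all(c("copx", "copy") %in% names(df))) {
    check_columns(df, c("copx", "copy"), path)
    cop <- as.matrix(df[, c("copx", "copy")])
  }
  structure(list(forces = sampled_signal(as.matrix(df[, c("fx", "fy", "fz")]),
                                         rate, df$time[1], "N"),
                 cop = cop, rate = rate,
                 bodyweight = if (!is.null(meta$bodyweight)) meta$bodyweight
                              else NA_real_),
            class = "force_trial")
}

#' Write a force trial to CSV (with a YAML sidecar holding the rate)
#'
#' @param trial a `force_trial` or an N x 3 [sampled_signal()].
#' @param path output CSV path.
#' @param bodyweight optional bodyweight in N for the sidecar.
#' @return `path`, invisibly.
#' @export
write_force_csv <- function(trial, path, bodyweight = NULL) {
  sig <- if (inherits(trial, "force_trial")) trial$forces else trial
  stopifnot(inherits(sig, "sampled_signal"), is.matrix(sig$values))
  df <- data.frame(time = signal_times(sig), fx = sig$values[, 1],
                   fy = sig$values[, 2], fz = sig$values[, 3])
  if (inherits(trial, "force_trial") && !is.null(trial$cop)) {
    df$copx <- trial$cop[, 1]; df$copy <- trial$cop[, 2]
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(rate = sig$rate)
  if (!is.null(bodyweight)) meta$bodyweight <- bodyweight
  yaml::write_yaml(meta, paste0(sub("\\.[^.]+$", "", path), ".yaml"))
  invisible(path)
}

#' Read a marker/CoM trajectory table from CSV
#'
#' Expects a `time` column plus `<label>_x`, `<label>_y`, `<label>_z`
#' triplets (m); e.g. `com_x, com_y, com_z` for a CoM trace.
#'
#' @param path CSV path.
#' @param rate optional sampling rate in Hz (sidecar or time column
#'   otherwise).
#' @return object of class `kinematic_trial`: `markers` (named list of
#'   N x 3 matrices), `rate`, `start_time`.
#' @export
read_markers_csv <- function(path, rate = NULL) {
  if (!file.exists(path)) jm_stop("missing_file", paste("no such file:", path))
  df <- utils::read.csv(path)
  check_columns(df, "time", path)
  if (is.null(rate)) rate <- read_sidecar(path)$rate
  if (is.null(rate)) rate <- 1 / stats::median(diff(df$time))
  labels <- unique(sub("_[xyz]$", "", grep("_[xyz]$", names(df), value = TRUE)))
  if (!length(labels))
    jm_stop("missing_channel", sprintf("%s: no <label>_x/_y/_z columns found", path))
  markers <- lapply(labels, function(l) {
    cols <- paste0(l, c("_x", "_y", "_z"))
    check_columns(df, cols, path)
    as.matrix(df[, cols])
  })
  names(markers) <- labels
  structure(list(markers = markers, rate = rate, start_time = df$time[1]),
            class = "kinematic_trial")
}

#' @rdname read_markers_csv
#' @param trial a `kinematic_trial`.
#' @param path output CSV path.
#' @export
write_markers_csv <- function(trial, path) {
  stopifnot(inherits(trial, "kinematic_trial"))
  n <- nrow(trial$markers[[1]])
  df <- data.frame(time = trial$start_time + (seq_len(n) - 1) / trial$rate)
  for (l in names(trial$markers))
    for (j in 1:3)
      df[[paste0(l, c("_x", "_y", "_z")[j])]] <- trial$markers[[l]][, j]
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(rate = trial$rate), paste0(sub("\\.[^.]+$", "", path), ".yaml"))
  invisible(path)
}

#' Read a body-model configuration (YAML/JSON)
#'
#' The file lists `segments` (name, mass in kg, optional diagonal inertia
#' in kg m^2) and optionally a `prosthesis` block (`total_mass`,
#' `joint_after`, and `cuboids` with `width`/`length`/`thickness`/
#' `position`), which is assembled via [prosthesis_spec()] and
#' [build_prosthesis()].
#'
#' @param path YAML or JSON path.
#' @return object of class `body_model`: `segments` (data.frame),
#'   `prosthesis` (built composite or `NULL`).
#' @export
read_model <- function(path) {
  if (!file.exists(path)) jm_stop("missing_file", paste("no such file:", path))
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg$segments)) jm_stop("invalid_input", "model config needs 'segments'")
  segs <- do.call(rbind, lapply(cfg$segments, function(s)
    data.frame(name = s$name, mass = s$mass)))
  pros <- NULL
  if (!is.null(cfg$prosthesis)) {
    ps <- cfg$prosthesis
    spec <- prosthesis_spec(ps$cuboids, ps$total_mass, ps$joint_after)
    pros <- build_prosthesis(spec)
  }
  structure(list(segments = segs, prosthesis = pros), class = "body_model")
}

#' Trial manifest
#'
#' Describes one recorded (or generated) trial for [run_pipeline()]:
#' which kind it is, where its channels live (paths or in-memory objects),
#' and the athlete metadata needed for group-specific conventions.
#'
#' @param kind `"sprint"`, `"jump"` or `"static"`.
#' @param forces for `jump`/`static`: one `force_trial` or CSV path; for
#'   `sprint`: named list of per-leg `force_trial`s or paths.
#' @param kinematics `kinematic_trial` or CSV path (jump trials; must hold
#'   a `com` marker).
#' @param laser [sampled_signal()] or CSV path with columns
#'   `time`, `position` (sprint trials).
#' @param bodyweight bodyweight in N (required unless `kind = "static"`).
#' @param body_mass body mass in kg (default `bodyweight / 9.81`).
#' @param group `"BKA"` or `"non_amputee"`.
#' @param takeoff_leg label of the take-off leg among the names of
#'   `forces` (sprint asymmetry).
#' @param toe_tip_ap toe-tip anteroposterior position (m, jump trials).
#' @param max_speed optional sprint maximum speed (jump trials, for the
#'   touchdown/maximum ratio).
#' @return object of class `trial_manifest`.
#' @export
trial_manifest <- function(kind = c("sprint", "jump", "static"),
                           forces = NULL, kinematics = NULL, laser = NULL,
                           bodyweight = NULL, body_mass = NULL,
                           group = c("non_amputee", "BKA"),
                           takeoff_leg = "takeoff", toe_tip_ap = NULL,
                           max_speed = NULL) {
  kind <- match.arg(kind); group <- match.arg(group)
  if (kind != "static" && is.null(bodyweight))
    jm_stop("invalid_input",
            "bodyweight (from a static trial) is required before normalized outputs")
  structure(list(kind = kind, forces = forces, kinematics = kinematics,
                 laser = laser, bodyweight = bodyweight,
                 body_mass = if (is.null(body_mass) && !is.null(bodyweight))
                   bodyweight / GRAVITY else body_mass,
                 group = group, takeoff_leg = takeoff_leg,
                 toe_tip_ap = toe_tip_ap, max_speed = max_speed),
            class = "trial_manifest")
}

resolve_force <- function(x) {
  if (is.character(x)) read_force_csv(x) else x
}

#' Run the analysis pipeline on one trial
#'
#' Executes the stage graph appropriate to the trial kind and returns a
#' report list; optionally writes the report as JSON plus a one-row summary
#' CSV. Static trials yield the bodyweight; sprint trials yield per-leg
#' force descriptors, spatiotemporal parameters, asymmetry and (when a
#' laser trace is present) maximum speed; jump trials yield the full
#' take-off-step summary including the theoretical jump distance. Metrics
#' whose inputs are absent (e.g. speed-dependent ones without a laser
#' trace) are reported as `NA` rather than failing the stage.
#'
#' @param manifest a [trial_manifest()].
#' @param config list; recognized: `threshold` (N, default 20),
#'   `filter_cutoff` (Hz, default 50; `NA` skips force filtering).
#' @param out optional output stem; writes `<out>.json` and `<out>.csv`.
#' @return report list (invisible components mirror the summary tables).
#' @export
run_pipeline <- function(manifest, config = list(), out = NULL) {
  stopifnot(inherits(manifest, "trial_manifest"))
  threshold <- config$threshold %||% 20
  cutoff <- config$filter_cutoff %||% 50
  filt <- function(sig) if (is.na(cutoff)) sig else lowpass_filter(sig, cutoff, 4)
  report <- list(kind = manifest$kind, group = manifest$group)
  if (manifest$kind == "static") {
    ft <- resolve_force(manifest$forces)
    report$bodyweight <- mean(ft$forces$values[, 3])
  } else if (manifest$kind == "sprint") {
    bw <- manifest$bodyweight
    legs <- lapply(manifest$forces, resolve_force)
    per_leg <- list(); events <- NULL
    for (leg in names(legs)) {
      sig <- filt(legs[[leg]]$forces)
      # events from the raw resultant: edge ringing of the low-pass filter
      # dilates 20 N crossings on the filtered record
      sts <- detect_stances(legs[[leg]]$forces, threshold)
      if (!length(sts)) next
      asf <- mean(vapply(sts, function(s) stance_average_force(sig, s, bw),
                         numeric(1)))
      imp <- lapply(sts, function(s) impulses(sig, s, bw))
      per_leg[[leg]] <- list(
        asf = asf,
        vertical_impulse = mean(vapply(imp, `[[`, numeric(1), "vertical_impulse")),
        net_horizontal_impulse = mean(vapply(imp, `[[`, numeric(1),
                                             "net_horizontal_impulse")),
        contact_time = mean(vapply(sts, `[[`, numeric(1), "duration")),
        peak_vertical_force = max(sig$values[, 3]) / bw)
      events <- rbind(events, data.frame(
        leg = leg,
        touchdown = vapply(sts, `[[`, numeric(1), "touchdown_time"),
        toeoff = vapply(sts, `[[`, numeric(1), "toeoff_time")))
    }
    report$per_leg <- per_leg
    if (!is.null(manifest$laser)) {
      laser <- if (is.character(manifest$laser)) {
        df <- utils::read.csv(manifest$laser)
        check_columns(df, c("time", "position"), manifest$laser)
        sampled_signal(df$position, 1 / stats::median(diff(df$time)), df$time[1], "m")
      } else manifest$laser
      report$max_speed <- laser_speed(laser)$max_speed
    } else report$max_speed <- NA_real_
    report$spatiotemporal <-
      if (!is.null(events)) spatiotemporal(events, report$max_speed) else NULL
    tl <- manifest$takeoff_leg
    other <- setdiff(names(per_leg), tl)
    if (tl %in% names(per_leg) && length(other) == 1)
      report$asymmetry <- directional_asymmetry(per_leg[[tl]]$asf,
                                                per_leg[[other]]$asf)
  } else {  # jump
    ft <- resolve_force(manifest$forces)
    kin <- if (is.character(manifest$kinematics)) read_markers_csv(manifest$kinematics)
           else manifest$kinematics
    if (!"com" %in% names(kin$markers))
      jm_stop("missing_channel", "jump kinematics must include a 'com' marker")
    com <- kin$markers$com
    report$takeoff <- takeoff_summary(
      filt(ft$forces), detection_grf = ft$forces,
      sampled_signal(com[, 1], kin$rate, kin$start_time, "m"),
      sampled_signal(com[, 3], kin$rate, kin$start_time, "m"),
      bodyweight = manifest$bodyweight, mass = manifest$body_mass,
      toe_tip_ap = manifest$toe_tip_ap, max_speed = manifest$max_speed,
      threshold = threshold)
    report$distance <- report$takeoff$distance
  }
  if (!is.null(out)) {
    clean <- report
    if (!is.null(clean$takeoff)) clean$takeoff$state <- unclass(clean$takeoff$state)
    jsonlite::write_json(clean, paste0(out, ".json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    flat <- unlist(clean[!vapply(clean, is.null, logical(1))])
    utils::write.csv(data.frame(metric = names(flat), value = unname(flat)),
                     paste0(out, ".csv"), row.names = FALSE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
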