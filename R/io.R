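#' Write an ergometer trace to CSV (with JSON sidecar)
#'
#' Trace dialect: UTF-8 CSV, header
#' `time_s,torque_left_Nm,torque_right_Nm,velocity_left_ms,velocity_right_ms[,heart_rate_bpm]`,
#' one row per sample, decimal point. Numbers are written with `%.17g`, so
#' a write -> read round trip reproduces every channel bit-exactly.
#' Metadata (participant, wheelchair, test type, protocol parameters,
#' `test_start`) go into a JSON sidecar next to the CSV (same name, `.json`).
#'
#' @param trace an [ergometer_trace()].
#' @param path CSV path.
#' @param meta named list of sidecar metadata; `rate` and `test_start` are
#'   added automatically.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, meta = list()) {
  stopifnot(inherits(trace, "ergometer_trace"))
  df <- data.frame(
    time_s = sprintf("%.17g", trace$time),
    torque_left_Nm = sprintf("%.17g", trace$torque_left),
    torque_right_Nm = sprintf("%.17g", trace$torque_right),
    velocity_left_ms = sprintf("%.17g", trace$velocity_left),
    velocity_right_ms = sprintf("%.17g", trace$velocity_right))
  if (!is.null(trace$heart_rate)) {
    df$heart_rate_bpm <- ifelse(is.na(trace$heart_rate), "",
                                sprintf("%.17g", trace$heart_rate))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta$rate <- trace$rate
  meta$test_start <- trace$test_start
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

# last-observation-carried-forward (with back-fill of leading NAs), used to
# step-interpolate a lower-rate heart-rate channel onto the trace clock.
locf <- function(x) {
  idx <- which(!is.na(x))
  if (length(idx) == 0) return(x)
  filled <- x[idx][findInterval(seq_along(x), idx)]
  filled[seq_len(idx[1] - 1L)] <- x[idx[1]]
  filled
}

#' Read an ergometer trace from CSV (with JSON sidecar)
#'
#' Reads the trace dialect written by [write_trace()]. The sampling rate
#' and `test_start` come from the sidecar when present, otherwise the rate
#' is inferred from the median time step. A heart-rate column with gaps is
#' step-interpolated onto the trace clock. A non-uniform time base is
#' rejected with an error naming the first offending row.
#'
#' @param path CSV path.
#' @return an [ergometer_trace()] with the sidecar list attached as
#'   attribute `"meta"`.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  required <- c("time_s", "torque_left_Nm", "torque_right_Nm",
                "velocity_left_ms", "velocity_right_ms")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_wheelcap(paste0("trace file misses required column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "wheelcap_structure_error")
  }
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else list()
  rate <- if (!is.null(meta$rate)) meta$rate
          else 1 / stats::median(diff(df$time_s))
  hr <- if ("heart_rate_bpm" %in% names(df)) locf(df$heart_rate_bpm) else NULL
  trace <- ergometer_trace(
    torque_left = df$torque_left_Nm, torque_right = df$torque_right_Nm,
    velocity_left = df$velocity_left_ms,
    velocity_right = df$velocity_right_ms,
    rate = rate, time = df$time_s, heart_rate = hr,
    test_start = meta$test_start)
  attr(trace, "meta") <- meta
  trace
}

#' Load the bundled 20-participant reference cohort
#'
#' Individual characteristics and test outcomes of twenty able-bodied
#' novices who completed the four-test protocol (isometric strength,
#' sprint, Wingate, GXT) on instrumented roller ergometers, as published.
#' Missing cells (hardware failures, aborted tests) are `NA`: isometric
#' strength is available for 19 participants, sprint and Wingate for all
#' 20, the GXT for 17. Participant 10's Wingate `v_max` is stored at the
#' text-reported precision (3.01 m/s).
#'
#' @return data frame with one row per participant.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "wheelcap",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

empty_row <- function() {
  cols <- c("f_iso_N", "f_iso_N_per_kg",
            "sprint_v_mean_ms", "sprint_v_max_ms", "sprint_po_mean_W",
            "sprint_po_mean_W_per_kg", "sprint_po_max_W",
            "sprint_po_max_W_per_kg",
            "p30_est_W", "p30_meas_W", "d_p30_pct", "p30_meas_W_per_kg",
            "p5_W", "want_po_max_W", "rf_pct", "want_v_mean_ms",
            "want_v_max_ms",
            "popeak_est_W", "popeak_meas_W", "d_popeak_pct",
            "popeak_meas_W_per_kg",
            "gxt_duration_s", "hr_peak_bpm",
            "rpe_central", "rpe_peripheral", "rpe_overall")
  row <- as.list(rep(NA_real_, length(cols)))
  names(row) <- cols
  row
}

# Extraction chain for one participant's test set: every stage is wrapped so
# a failure (missing trace, unusable data) yields NA in the cohort row
# instead of aborting the cohort run.
analyze_participant <- function(tests, config) {
  p <- tests$participant
  setup <- setup_for(p, config)
  row <- empty_row()
  fp <- function(tr) compute_force_power(filter_trace(tr), setup)
  try_null <- function(expr) tryCatch(expr, error = function(e) NULL)

  iso <- try_null(isometric_strength(lapply(tests$isometric, fp), p$body_mass))
  if (!is.null(iso)) {
    row$f_iso_N <- iso$f_iso
    row$f_iso_N_per_kg <- iso$f_iso_per_kg
    est <- estimate_p30(iso$f_iso, p$body_mass)
    if (!est$flagged) row$p30_est_W <- est$p30_est
  }
  spr <- try_null(sprint_outcomes(lapply(tests$sprint, fp)))
  if (!is.null(spr)) {
    row$sprint_v_mean_ms <- spr$v_mean; row$sprint_v_max_ms <- spr$v_max
    row$sprint_po_mean_W <- spr$po_mean; row$sprint_po_max_W <- spr$po_max
    row$sprint_po_mean_W_per_kg <- spr$po_mean / p$body_mass
    row$sprint_po_max_W_per_kg <- spr$po_max / p$body_mass
  }
  want <- if (is.null(tests$wingate)) NULL
          else try_null(wingate_outcomes(fp(tests$wingate)))
  if (!is.null(want)) {
    row$p30_meas_W <- want$p30
    row$p30_meas_W_per_kg <- want$p30 / p$body_mass
    row$p5_W <- want$p5; row$want_po_max_W <- want$po_max
    row$rf_pct <- want$rf
    row$want_v_mean_ms <- want$v_mean; row$want_v_max_ms <- want$v_max
    if (!is.na(row$p30_est_W)) {
      row$d_p30_pct <- percent_deviation(row$p30_est_W, want$p30)
    }
  }
  if (!is.null(want) && !is.null(tests$gxt)) {
    g <- try_null(gxt_outcomes(fp(tests$gxt$trace),
                               rpe_central = tests$gxt$rpe_central,
                               rpe_peripheral = tests$gxt$rpe_peripheral))
    if (!is.null(g)) {
      row$popeak_est_W <- estimate_popeak(want$p30, p$body_mass)$po_peak_est
      row$popeak_meas_W <- g$po_peak
      row$popeak_meas_W_per_kg <- g$po_peak / p$body_mass
      row$gxt_duration_s <- g$duration
      row$hr_peak_bpm <- g$hr_peak
      row$rpe_central <- g$rpe_central
      row$rpe_peripheral <- g$rpe_peripheral
      row$rpe_overall <- g$rpe_overall
      row$d_popeak_pct <- percent_deviation(row$popeak_est_W, g$po_peak)
    }
  }
  cbind(data.frame(participant = p$id, sex = p$sex, age_yr = p$age,
                   body_mass_kg = p$body_mass, height_cm = NA_real_,
                   training_h_per_week = NA_real_),
        as.data.frame(row))
}

#' Run the full protocol pipeline over a cohort
#'
#' Executes the chained analysis — isometric strength -> P30 estimate ->
#' Wingate resistance -> Wingate outcomes -> POpeak estimate -> GXT
#' schedule -> GXT outcomes — for every participant and assembles a cohort
#' table in the bundled dataset's schema. Stage failures (missing or
#' unusable traces, e.g. a brake failure during the isometric test)
#' propagate as `NA` in that participant's row; the run continues.
#'
#' @param cohort either a list of per-participant test sets (as produced
#'   by [simulate_cohort_tests()]) or the path of a cohort directory
#'   written by [write_cohort_dir()].
#' @param config a [sim_config()] supplying the wheelchair geometry.
#' @return data frame with one row per participant.
#' @export
run_protocol <- function(cohort, config = sim_config()) {
  if (is.character(cohort)) cohort <- read_cohort_dir(cohort, config)
  do.call(rbind, lapply(cohort, analyze_participant, config = config))
}

#' Write a cohort of simulated test traces to a directory
#'
#' One subdirectory per participant with `isometric_<k>.csv`,
#' `sprint_<k>.csv`, `wingate.csv`, `gxt.csv` and JSON sidecars carrying
#' participant, wheelchair and protocol metadata.
#'
#' @param tests list of per-participant test sets
#'   (see [simulate_participant_tests()]).
#' @param dir target directory (created if needed).
#' @param config the [sim_config()] used for simulation.
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(tests, dir, config = sim_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tst in tests) {
    p <- tst$participant
    pdir <- file.path(dir, sprintf("p%02d", p$id))
    dir.create(pdir, showWarnings = FALSE)
    base_meta <- list(
      participant = list(id = p$id, sex = p$sex, age = p$age,
                         body_mass = p$body_mass),
      wheelchair = list(mass = config$wheelchair_mass,
                        wheel_radius = config$wheel_radius,
                        rim_radius = config$rim_radius))
    for (k in seq_along(tst$isometric)) {
      write_trace(tst$isometric[[k]],
                  file.path(pdir, sprintf("isometric_%d.csv", k)),
                  c(base_meta, list(test_type = "isometric")))
    }
    for (k in seq_along(tst$sprint)) {
      write_trace(tst$sprint[[k]],
                  file.path(pdir, sprintf("sprint_%d.csv", k)),
                  c(base_meta, list(test_type = "sprint",
                                    protocol = list(mu = config$sprint_mu))))
    }
    if (!is.null(tst$wingate)) {
      write_trace(tst$wingate, file.path(pdir, "wingate.csv"),
                  c(base_meta, list(
                    test_type = "wingate",
                    protocol = list(mu = tst$prescription$mu,
                                    target_v = tst$prescription$target_v))))
    }
    if (!is.null(tst$gxt)) {
      write_trace(tst$gxt$trace, file.path(pdir, "gxt.csv"),
                  c(base_meta, list(
                    test_type = "gxt",
                    protocol = list(
                      stage_mus = tst$schedule$stage_mus,
                      velocity = tst$schedule$constant_velocity),
                    rpe_central = tst$gxt$rpe_central,
                    rpe_peripheral = tst$gxt$rpe_peripheral)))
    }
  }
  invisible(dir)
}

read_cohort_dir <- function(dir, config) {
  pdirs <- list.dirs(dir, recursive = FALSE)
  lapply(pdirs, function(pdir) {
    paths <- list.files(pdir, pattern = "\\.csv$", full.names = TRUE)
    traces <- lapply(paths, read_trace)
    meta1 <- attr(traces[[1]], "meta")
    pm <- meta1$participant
    p <- make_participant(id = pm$id, sex = pm$sex, age = pm$age,
                          body_mass = pm$body_mass,
                          f_iso_per_kg = 1, p30_per_kg = 1,
                          po_peak_per_kg = 1)
    types <- vapply(traces, function(tr) attr(tr, "meta")$test_type,
                    character(1))
    gxt <- NULL
    if (any(types == "gxt")) {
      tr <- traces[[which(types == "gxt")[1]]]
      m <- attr(tr, "meta")
      gxt <- list(trace = tr,
                  rpe_central = if (is.null(m$rpe_central)) NA else m$rpe_central,
                  rpe_peripheral = if (is.null(m$rpe_peripheral)) NA else m$rpe_peripheral)
    }
    list(participant = p,
         isometric = traces[types == "isometric"],
         sprint = traces[types == "sprint"],
         wingate = if (any(types == "wingate"))
           traces[[which(types == "wingate")[1]]] else NULL,
         gxt = gxt)
  })
}
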