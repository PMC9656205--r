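#' Synthetic-data configuration
#'
#' Bundles the seed and the ground-truth parameters for the three generators
#' ([generate_matrix()], [generate_pk()], [generate_tumour_study()]). A
#' config's seed fully determines every generated value.
#'
#' Named presets encode the study designs the generators emulate:
#' `"mts-default"` (5 x 5 grid, 12.5-200 nM x 0.25-4 nM, 72 h, 4
#' replicates), `"rtglo-default"` (7 x 7 grid, 62.5-4000 nM x 0.625-40 nM,
#' kinetic timepoints 12-80 h, 3 replicates), `"pk-hdm201-plasma"` /
#' `"pk-trametinib-plasma"` (one-compartment oral profiles sampled at 1.5, 4,
#' 8 and 24 h, n = 3 per timepoint) and `"efficacy-combo-100-1"` (exponential
#' xenograft growth, 6 animals per arm, qdx3/qdx6 schedules).
#'
#' @param seed integer seed.
#' @param preset one of the names above, or `NULL` to take every default as
#'   given by the individual generator arguments.
#' @return object of class `synth_config` (a list of defaults the generators
#'   consume; individual generator arguments override preset fields).
#' @export
synth_config <- function(seed = 1L, preset = NULL) {
  cfg <- list(seed = as.integer(seed))
  if (!is.null(preset)) {
    presets <- c("mts-default", "rtglo-default", "pk-hdm201-plasma",
                 "pk-trametinib-plasma", "efficacy-combo-100-1")
    if (!preset %in% presets) {
      stop("unknown preset '", preset, "'; available: ",
           paste(presets, collapse = ", "))
    }
    cfg$preset <- preset
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Dose grids of the two assay layouts
#'
#' Two-fold serial dilutions: the 5-concentration layout spans 12.5-200 nM
#' (row drug) x 0.25-4 nM (column drug); the 7-concentration layout spans
#' 62.5-4000 nM x 0.625-40 nM. A zero (vehicle) dose is prepended to both
#' axes so generated matrices carry monotherapy edges.
#'
#' @param grid `"mts"` (5 x 5) or `"rtglo"` (7 x 7).
#' @param with_zero prepend the vehicle dose.
#' @return list with `doses_row` and `doses_col` (nM).
#' @export
dose_grid <- function(grid = c("rtglo", "mts"), with_zero = TRUE) {
  grid <- match.arg(grid)
  g <- if (grid == "mts") {
    list(doses_row = 200 / 2^(4:0), doses_col = 4 / 2^(4:0))
  } else {
    list(doses_row = 4000 / 2^(6:0), doses_col = 40 / 2^(6:0))
  }
  if (with_zero) {
    g$doses_row <- c(0, g$doses_row)
    g$doses_col <- c(0, g$doses_col)
  }
  g
}

#' Default ground-truth MuSyC surface for a synthetic assay
#'
#' Potencies follow the observed monotherapy IC50s of the emulated assay
#' (row drug ~65.7 nM / ~260 nM, column drug ~0.58 nM / ~0.8 nM for the
#' 5 x 5 and 7 x 7 layouts respectively); single-agent plateaus leave a
#' resistant fraction (E1 = 0.4, E2 = 0.3 surviving), the combination kills
#' deeper (E3 chosen so beta is near the reported ~0.23 efficacy synergy)
#' and potency folds sit at the reported ~2.2.
#'
#' @param grid `"mts"` or `"rtglo"` (sets the EC50s).
#' @return a [musyc_surface()].
#' @export
default_truth_surface <- function(grid = c("rtglo", "mts")) {
  grid <- match.arg(grid)
  if (grid == "mts") {
    musyc_surface(E0 = 1, E1 = 0.4, E2 = 0.3, E3 = 0.14,
                  h1 = 1.5, h2 = 1.2, C1 = 65.7, C2 = 0.58,
                  alpha12 = 2.2, alpha21 = 2.2)
  } else {
    musyc_surface(E0 = 1, E1 = 0.4, E2 = 0.3, E3 = 0.14,
                  h1 = 1.2, h2 = 1.0, C1 = 260.1, C2 = 0.8,
                  alpha12 = 2.2, alpha21 = 2.2)
  }
}

# evaluate a named-null inhibition surface (%) on a dose grid
null_surface <- function(truth, doses_row, doses_col) {
  type <- truth$type
  if (type == "bliss") {
    y1 <- pmin(pmax(hill_predict(truth$curve_row, doses_row), 0), 100)
    y2 <- pmin(pmax(hill_predict(truth$curve_col, doses_col), 0), 100)
    100 * outer(y1 / 100, y2 / 100, bliss_expected)
  } else if (type == "hsa") {
    y1 <- pmin(pmax(hill_predict(truth$curve_row, doses_row), 0), 100)
    y2 <- pmin(pmax(hill_predict(truth$curve_col, doses_col), 0), 100)
    outer(y1, y2, pmax)
  } else if (type == "loewe_sham") {
    total <- outer(doses_row, doses_col, `+`)
    matrix(hill_predict(truth$curve_row, as.vector(total)),
           length(doses_row), length(doses_col))
  } else {
    stop("unknown null surface '", type, "'")
  }
}

#' A named null ground truth for the matrix generator
#'
#' * `"bliss"`: the surface is exactly the Bliss combination of the two
#'   monotherapy Hill curves (zero Bliss delta by construction).
#' * `"loewe_sham"`: one drug combined with itself, response a function of
#'   the summed dose (zero Loewe delta by construction).
#' * `"hsa"`: the surface equals the better monotherapy everywhere.
#'
#' Default monotherapy curves are full-kill (`E0 = 0`, `Emax = 100`) so the
#' Bliss null also satisfies the bounded-response convention of ZIP.
#'
#' @param type null name.
#' @param curve_row,curve_col inhibition-scale [hill_curve()]s (for the sham
#'   null only `curve_row` is used).
#' @return a null-truth specification consumed by [generate_matrix()].
#' @export
null_truth <- function(type = c("bliss", "loewe_sham", "hsa"),
                       curve_row = hill_curve(0, 100, 65.7, 1.5),
                       curve_col = hill_curve(0, 100, 0.58, 1.2)) {
  type <- match.arg(type)
  structure(list(type = type, curve_row = curve_row, curve_col = curve_col),
            class = "null_truth")
}

# time-dependence multiplier: kill amplitude ramps linearly from the onset
# delay to full effect at the reference time (cytotoxicity of both drugs is
# concentration- AND time-dependent, with negligible effect before ~24 h)
time_effect <- function(timepoint_h, onset_delay_h = 24, t_ref_h = 80) {
  pmin(pmax((timepoint_h - onset_delay_h) / (t_ref_h - onset_delay_h), 0), 1)
}

#' Generate synthetic checkerboard matrices
#'
#' Evaluates a ground-truth surface (a [musyc_surface()] or a [null_truth()])
#' on the dose grid, adds i.i.d. Gaussian plate noise on the % response
#' scale, and returns one inhibition-scale [response_matrix()] per
#' replicate x timepoint. Time dependence scales the kill amplitude linearly
#' from an onset delay (default 24 h, emulating the response delay of
#' MDM2/MEK inhibition) to its full value at 80 h; a single 72 h timepoint
#' with `onset_delay_h = 0` gives the static end-point layout.
#'
#' @param config a [synth_config()]; its seed drives all randomness.
#' @param grid `"mts"`, `"rtglo"` or a list with `doses_row`, `doses_col`.
#' @param truth ground-truth surface; defaults to
#'   [default_truth_surface()] for the chosen grid.
#' @param noise_sd plate noise SD in % response (default 5, the typical
#'   noise level of large-scale combination screens).
#' @param timepoints_h readout times; defaults per preset (72 for `"mts"`,
#'   the kinetic series 12-80 h for `"rtglo"`).
#' @param replicates number of independent replicates (4 for `"mts"`, 3 for
#'   `"rtglo"`).
#' @param onset_delay_h,t_ref_h time-effect ramp (set `onset_delay_h = 0`,
#'   `t_ref_h = max(timepoints_h)` for full effect at all timepoints; the
#'   ramp only applies to [musyc_surface()] truths).
#' @param drug_row,drug_col,assay_label labels for the generated matrices.
#' @return list of `response_matrix` objects (inhibition scale, unclipped
#'   noisy values kept in `$response_raw`).
#' @export
generate_matrix <- function(config = synth_config(),
                            grid = NULL, truth = NULL, noise_sd = 5,
                            timepoints_h = NULL, replicates = NULL,
                            onset_delay_h = 24, t_ref_h = 80,
                            drug_row = "HDM201", drug_col = "Trametinib",
                            assay_label = NULL) {
  preset <- config$preset
  if (is.null(grid)) {
    grid <- if (identical(preset, "mts-default")) "mts" else "rtglo"
  }
  if (is.character(grid)) {
    grid_name <- match.arg(grid, c("rtglo", "mts"))
    g <- dose_grid(grid_name)
  } else {
    grid_name <- "custom"
    g <- grid
  }
  if (is.null(truth)) {
    truth <- default_truth_surface(if (grid_name == "mts") "mts" else "rtglo")
  }
  if (is.character(truth)) truth <- null_truth(truth)
  if (is.null(timepoints_h)) {
    timepoints_h <- if (grid_name == "mts") 72
                    else c(12, 24, 28, 32, 36, 48, 52, 56, 60, 72, 76, 80)
  }
  if (is.null(replicates)) replicates <- if (grid_name == "mts") 4L else 3L
  if (is.null(assay_label)) {
    assay_label <- switch(grid_name, mts = "MTS", rtglo = "RealTime-Glo",
                          "custom")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  set.seed(config$seed)
  out <- list()
  for (rep_id in seq_len(replicates)) {
    for (tp in timepoints_h) {
      if (inherits(truth, "musyc_surface")) {
        m <- time_effect(tp, onset_delay_h, t_ref_h)
        s <- truth
        # ramp each asymptote from no-effect (1) toward its full-time value
        s$E1 <- 1 - m * (1 - truth$E1)
        s$E2 <- 1 - m * (1 - truth$E2)
        s$E3 <- 1 - m * (1 - truth$E3)
        viab <- musyc_predict_grid(s, g$doses_row, g$doses_col)
        inhib <- 100 * (1 - viab)
      } else {
        inhib <- null_surface(truth, g$doses_row, g$doses_col)
      }
      noisy <- inhib + stats::rnorm(length(inhib), 0, noise_sd)
      mat <- response_matrix(pmin(pmax(noisy, 0), 100),
                             g$doses_row, g$doses_col,
                             drug_row = drug_row, drug_col = drug_col,
                             response_scale = "inhibition",
                             timepoint_h = tp, replicate_id = rep_id,
                             assay_label = assay_label)
      mat$response_raw <- matrix(noisy, nrow(inhib), ncol(inhib))
      out[[length(out) + 1]] <- mat
    }
  }
  out
}

#' Generate synthetic sparse-sampling PK profiles
#'
#' One-compartment oral absorption: `C(t) = A * (exp(-ke t) - exp(-ka t))`,
#' with `A` scaled so the profile's true peak equals `cmax_target`.
#' Per-animal log-normal variability multiplies the whole profile (one
#' biological scale factor per animal); the profile is sampled destructively
#' at the configured timepoints with `n_per_timepoint` animals each. A
#' combination condition rescales `A` by `combo_multiplier`, emulating
#' exposure interaction in either direction.
#'
#' @param config a [synth_config()]. The `"pk-hdm201-plasma"` preset uses
#'   fast absorption (`ka = 2`/h, peak before the 4 h sample, target Cmax
#'   9778 nM, combination multiplier 1.49); `"pk-trametinib-plasma"` uses
#'   slower absorption (`ka = 0.5`/h, peak near 4 h, target Cmax 567 nM,
#'   combination multiplier 0.62, i.e. exposure drops in combination).
#' @param ka,ke absorption and elimination rate constants (/h; `ka != ke`).
#' @param cmax_target peak concentration of the noise-free profile (nM).
#' @param timepoints_h destructive sampling times.
#' @param n_per_timepoint animals per timepoint.
#' @param cv_lognormal between-animal coefficient of variation (sdlog).
#' @param combo_multiplier scale applied under the combination condition.
#' @param analyte,tissue labels.
#' @return list with `alone` and `combination` [conc_profile()]s.
#' @export
generate_pk <- function(config = synth_config(),
                        ka = NULL, ke = 0.1, cmax_target = NULL,
                        timepoints_h = c(1.5, 4, 8, 24),
                        n_per_timepoint = 3, cv_lognormal = 0.25,
                        combo_multiplier = NULL,
                        analyte = NULL, tissue = "plasma") {
  preset <- config$preset
  if (identical(preset, "pk-trametinib-plasma")) {
    if (is.null(ka)) ka <- 0.5
    if (is.null(cmax_target)) cmax_target <- 567
    if (is.null(combo_multiplier)) combo_multiplier <- 0.62
    if (is.null(analyte)) analyte <- "Trametinib"
  } else {
    if (is.null(ka)) ka <- 2
    if (is.null(cmax_target)) cmax_target <- 9778
    if (is.null(combo_multiplier)) combo_multiplier <- 1.49
    if (is.null(analyte)) analyte <- "HDM201"
  }
  if (ka == ke) stop("ka must differ from ke")

  t_peak <- log(ka / ke) / (ka - ke)
  shape <- function(t) exp(-ke * t) - exp(-ka * t)
  A <- cmax_target / shape(t_peak)

  set.seed(config$seed)
  sample_condition <- function(scale, condition) {
    conc <- matrix(0, n_per_timepoint, length(timepoints_h))
    for (j in seq_along(timepoints_h)) {
      animal_scale <- stats::rlnorm(n_per_timepoint,
                                    -cv_lognormal^2 / 2, cv_lognormal)
      conc[, j] <- scale * A * shape(timepoints_h[j]) * animal_scale
    }
    conc_profile(timepoints_h, conc, analyte = analyte,
                 tissue = tissue, condition = condition)
  }
  list(alone = sample_condition(1, "alone"),
       combination = sample_condition(combo_multiplier, "combination"))
}

#' Dose-day kill factor matching a target treated/control volume ratio
#'
#' In the exponential-growth model each dosing day multiplies the treated
#' volume by `(1 - kill)`, so after `n_doses` the treated/control ratio is
#' `(1 - kill)^n_doses`; this inverts that relation.
#'
#' @param ratio target treated/control mean volume ratio after the full
#'   schedule (e.g. 0.04).
#' @param n_doses number of dosing days (3 for qdx3, 6 for qdx6).
#' @return kill factor in `[0, 1)`.
#' @export
kill_for_ratio <- function(ratio, n_doses) {
  stopifnot(ratio > 0, ratio <= 1, n_doses >= 1)
  1 - ratio^(1 / n_doses)
}

#' Generate a synthetic xenograft efficacy study
#'
#' Control tumours grow exponentially from `v0_mm3` (per-animal log-normal
#' initial volumes and growth-rate jitter); each treated arm multiplies the
#' day's growth by `(1 - kill)` on its dosing days (qdx3 = days 0-2,
#' qdx6 = days 0-5). Calliper width/length pairs are back-computed from
#' volume with a fixed aspect ratio, and volumes are measured on a
#' 2-3x/week schedule.
#'
#' @param config a [synth_config()]. The `"efficacy-combo-100-1"` preset
#'   emulates the best combination arm: control + one treated arm whose kill
#'   factor drives the treated/control ratio to 0.04 by end of dosing.
#' @param arms named list of treated arms, each
#'   `list(kill = , n_doses = )`; default per preset.
#' @param n_animals animals per arm.
#' @param v0_mm3 mean initial volume (mm^3).
#' @param growth_rate exponential growth rate (/day); the default doubles
#'   control volume roughly every 5 days.
#' @param days measurement days.
#' @param cv_v0,sd_growth between-animal variability (sdlog of initial
#'   volume; SD of the per-animal growth rate).
#' @param aspect_ratio calliper width / length used to emit (d, D) pairs.
#' @return a [tumour_study()].
#' @export
generate_tumour_study <- function(config = synth_config(),
                                  arms = NULL, n_animals = 6,
                                  v0_mm3 = 165, growth_rate = 0.14,
                                  days = c(0, 3, 5, 7, 10, 12, 14),
                                  cv_v0 = 0.1, sd_growth = 0.01,
                                  aspect_ratio = 0.8) {
  if (is.null(arms)) {
    arms <- list("combo-100-1" = list(kill = kill_for_ratio(0.04, 6),
                                      n_doses = 6))
  }
  for (a in arms) {
    if (a$kill < 0 || a$kill >= 1) stop("kill must lie in [0, 1)")
  }
  if (growth_rate <= 0) stop("growth rate must be > 0")

  set.seed(config$seed)
  simulate_arm <- function(label, kill, n_doses) {
    rows <- lapply(seq_len(n_animals), function(animal) {
      v0 <- v0_mm3 * stats::rlnorm(1, -cv_v0^2 / 2, cv_v0)
      g <- stats::rnorm(1, growth_rate, sd_growth)
      all_days <- 0:max(days)
      mult <- exp(g) * ifelse(all_days[-1] - 1 < n_doses, 1 - kill, 1)
      vols <- v0 * cumprod(c(1, mult))
      v <- vols[days + 1]
      # V = d^2 D / 2 with d = aspect * D  =>  D = (2 V / aspect^2)^(1/3)
      D <- (2 * v / aspect_ratio^2)^(1 / 3)
      data.frame(group = label, animal_id = paste0(label, "-", animal),
                 day = days, width_mm = aspect_ratio * D, length_mm = D)
    })
    do.call(rbind, rows)
  }
  measurements <- rbind(
    simulate_arm("vehicle", 0, 0),
    do.call(rbind, lapply(names(arms), function(nm) {
      simulate_arm(nm, arms[[nm]]$kill, arms[[nm]]$n_doses)
    }))
  )
  schedule <- vapply(arms, function(a) paste0("qdx", a$n_doses), character(1))
  tumour_study(measurements, control_label = "vehicle", schedule = schedule)
}
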