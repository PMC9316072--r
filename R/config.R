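# Parameter roster ------------------------------------------------------

# Electrical-cardiometry beat parameters plus cuff vitals. "generated"
# parameters receive their own stage multipliers and noise; "derived" ones
# are computed per beat from identities and therefore carry no multipliers:
#   co  = sv * hr / 1000          (L/min)
#   si  = sv / bsa, ci = co / bsa
#   str = pep / lvet
#   ftc = lvet / sqrt(RR in s)    (Bazett)
#   map = (sbp + 2 * dbp) / 3
#   ccc = running beat counter
.ec_generated <- c("sv", "hr", "pep", "lvet", "icon", "svv", "hrv",
                   "vic", "hrc", "mse", "pnn", "stat", "sbp", "dbp")
.ec_derived <- c("co", "si", "ci", "str", "ftc", "map", "ccc")

#' Names of all simulated beat-level parameters
#'
#' Electrical-cardiometry parameters (stroke volume, heart rate, cardiac
#' output, stroke/cardiac index, systolic time intervals, contractility
#' index, variability indices, complexity channels) plus oscillometric cuff
#' pressures carried along as slowly varying channels.
#'
#' @return character vector of beat-table column names (excluding
#'   subject/stage/time bookkeeping columns).
#' @export
ec_parameters <- function() c(.ec_generated, .ec_derived)

# Default stage-response medians (multiplicative level vs baseline) for the
# generated parameters, stages ordered baseline, -15, -30, -45, recovery.
# Values at -45 mmHg and several at other stages follow the printed stage
# medians of the LBNP study the generator emulates; the remaining entries
# are physiologically plausible monotone interpolations (see the methods
# vignette).
.default_multipliers <- function() {
  m <- rbind(
    sv_tte = c(1, 0.88, 0.78, 0.657, 0.95),
    sv     = c(1, 0.93, 0.87, 0.799, 0.92),
    hr     = c(1, 0.969, 1.022, 1.095, 0.92),
    pep    = c(1, 1.05, 1.12, 1.22, 1.02),
    lvet   = c(1, 0.97, 0.93, 0.88, 0.98),
    icon   = c(1, 0.90, 0.80, 0.704, 0.85),
    svv    = c(1, 1.15, 1.35, 1.60, 1.05),
    hrv    = c(1, 0.90, 0.75, 0.60, 1.10),
    vic    = c(1, 1, 1, 1, 1),
    hrc    = c(1, 1, 1, 1, 1),
    mse    = c(1, 1, 1, 1, 1),
    pnn    = c(1, 1, 1, 1, 1),
    stat   = c(1, 1, 1, 1, 1),
    sbp    = c(1, 0.98, 0.953, 0.948, 1.00),
    dbp    = c(1, 1.00, 1.01, 1.027, 1.038)
  )
  colnames(m) <- c("baseline", "lbnp15", "lbnp30", "lbnp45", "recovery")
  m
}

# Stage-level parameter-specific log-noise SDs. Calibrated (once, by
# simulation at large n) so that, with the shared latent volume trajectory,
# the median intra-subject Pearson correlations with SV-TTE match the
# configured correlation targets.
.default_stage_noise <- c(
  sv_tte = 0.000,
  sv   = 0.0569,
  hr   = 0.0973,
  pep  = 0.0728,
  lvet = 0.0200,
  icon = 0.0972,
  svv  = 0.2764,
  hrv  = 0.1877,
  vic  = 0.05, hrc = 0.05, mse = 0.05, pnn = 0.05, stat = 0.05,
  sbp  = 0.0393,
  dbp  = 0.02
)

# Beat-to-beat log-scale coefficients of variation.
.default_beat_cv <- c(
  sv = 0.05, pep = 0.03, lvet = 0.02, icon = 0.08, svv = 0.10,
  hrv = 0.15, vic = 0.10, hrc = 0.05, mse = 0.05, pnn = 0.20,
  stat = 0.05, sbp = 0.01, dbp = 0.01
)

# Target median intra-subject Pearson correlations with SV-TTE (signed),
# as printed for the study cohort.
.default_correlation_targets <- c(
  sv = 0.856, icon = 0.806, pep = -0.839, str = -0.902,
  svv = -0.706, hrv = 0.797, sbp = 0.624, hr = -0.576
)

#' Synthetic-cohort generator configuration
#'
#' Bundles every tunable of the LBNP cohort simulator: stage-response
#' medians, between-subject heterogeneity, the shared latent central-volume
#' noise that induces intra-subject correlations, parameter-specific stage
#' and beat noise, echo/EC missingness rates and the echo measurement
#' geometry.
#'
#' @param stage_multipliers numeric matrix, rows = generated parameters
#'   (plus `sv_tte`), columns = protocol stages; multiplicative median
#'   level versus baseline. Baseline column must be exactly 1; all entries
#'   strictly positive.
#' @param between_subject_sd log-scale SD of the shared subject
#'   responsiveness effect (how strongly a subject reacts to LBNP).
#' @param response_jitter_sd log-scale SD of the parameter-specific jitter
#'   multiplying the shared responsiveness.
#' @param latent_stage_sd SD of the shared per-(subject, stage) latent
#'   central-volume fluctuation (log scale) that couples all responsive
#'   parameters.
#' @param stage_noise named numeric vector of parameter-specific stage-level
#'   log-noise SDs; the defaults are calibrated so intra-subject
#'   correlations with SV-TTE match `correlation_targets`.
#' @param beat_cv named numeric vector of beat-to-beat log-noise SDs.
#' @param rr_jitter_sd log-scale SD of beat-to-beat RR-interval variation.
#' @param correlation_targets named numeric vector of signed target median
#'   intra-subject Pearson correlations with SV-TTE (documentation of the
#'   calibration target; used by validation tests).
#' @param missingness_rate_echo probability in [0, 1) that a (subject,
#'   stage) echo acquisition is missing.
#' @param missingness_rate_absolute probability in [0, 1) that a (subject,
#'   stage) EC recording is missing entirely.
#' @param noise_scale global multiplier applied to every stochastic
#'   magnitude except between-subject heterogeneity (`stage_noise`,
#'   `beat_cv`, `latent_stage_sd`, `rr_jitter_sd`, `vti_cv`); e.g.
#'   `noise_scale = 0.25` gives a low-noise cohort with unchanged
#'   subject-level response spread.
#' @param vti_n number of Doppler velocity-time-integral samples per stage.
#' @param vti_cv log-scale SD of individual VTI samples around the stage
#'   target.
#' @param lvot_mean,lvot_sd mean and SD (cm) of the baseline LVOT diameter.
#' @param seed optional integer seed; `generate_cohort()` seeds the RNG
#'   with it for full reproducibility.
#' @return Object of class `lbnp_config` (a list of the above, validated).
#' @examples
#' cfg <- generator_config(seed = 1)
#' cfg$stage_multipliers["sv_tte", ]
#' @export
generator_config <- function(stage_multipliers = .default_multipliers(),
                             between_subject_sd = 0.35,
                             response_jitter_sd = 0.10,
                             latent_stage_sd = 0.04,
                             stage_noise = .default_stage_noise,
                             beat_cv = .default_beat_cv,
                             rr_jitter_sd = 0.03,
                             correlation_targets = .default_correlation_targets,
                             missingness_rate_echo = 0.055,
                             missingness_rate_absolute = 0,
                             noise_scale = 1,
                             vti_n = 9,
                             vti_cv = 0.03,
                             lvot_mean = 2.1,
                             lvot_sd = 0.08,
                             seed = NULL) {
  if (!is.matrix(stage_multipliers) || is.null(rownames(stage_multipliers))) {
    stop("configuration error: stage_multipliers must be a named matrix")
  }
  if (any(stage_multipliers <= 0)) {
    stop("configuration error: stage multipliers must be strictly positive")
  }
  if (any(abs(stage_multipliers[, 1] - 1) > 1e-12)) {
    stop("configuration error: baseline multiplier must be 1 for every parameter")
  }
  for (r in c("missingness_rate_echo", "missingness_rate_absolute")) {
    v <- get(r)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v >= 1) {
      stop("configuration error: ", r, " must lie in [0, 1)")
    }
  }
  stopifnot(
    between_subject_sd >= 0, response_jitter_sd >= 0, latent_stage_sd >= 0,
    all(stage_noise >= 0), all(beat_cv >= 0), rr_jitter_sd >= 0,
    noise_scale > 0, vti_n >= 1, vti_cv >= 0, lvot_mean > 0, lvot_sd >= 0
  )
  structure(
    list(
      stage_multipliers = stage_multipliers,
      between_subject_sd = between_subject_sd,
      response_jitter_sd = response_jitter_sd,
      latent_stage_sd = latent_stage_sd * noise_scale,
      stage_noise = stage_noise * noise_scale,
      beat_cv = beat_cv * noise_scale,
      rr_jitter_sd = rr_jitter_sd * noise_scale,
      correlation_targets = correlation_targets,
      missingness_rate_echo = missingness_rate_echo,
      missingness_rate_absolute = missingness_rate_absolute,
      noise_scale = noise_scale,
      vti_n = vti_n,
      vti_cv = vti_cv * noise_scale,
      lvot_mean = lvot_mean,
      lvot_sd = lvot_sd,
      seed = seed
    ),
    class = "lbnp_config"
  )
}

#' @export
print.lbnp_config <- function(x, ...) {
  cat("LBNP generator config: ", nrow(x$stage_multipliers),
      " response parameters, noise_scale = ", x$noise_scale,
      ", echo missingness = ", x$missingness_rate_echo, "\n", sep = "")
  invisible(x)
}

#' Serialize / restore a generator configuration
#'
#' Round-trip-safe YAML serialization of an [generator_config()] object.
#'
#' @param config an `lbnp_config`.
#' @param path file path to write to / read from.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the restored `lbnp_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "lbnp_config"))
  x <- unclass(config)
  for (f in c("stage_noise", "beat_cv", "correlation_targets")) {
    x[[f]] <- as.list(x[[f]])  # keep names through YAML
  }
  x$stage_multipliers <- list(
    params = rownames(config$stage_multipliers),
    stages = colnames(config$stage_multipliers),
    values = as.vector(config$stage_multipliers)
  )
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  sm <- matrix(unlist(x$stage_multipliers$values),
               nrow = length(x$stage_multipliers$params),
               dimnames = list(unlist(x$stage_multipliers$params),
                               unlist(x$stage_multipliers$stages)))
  generator_config(
    stage_multipliers = sm,
    between_subject_sd = x$between_subject_sd,
    response_jitter_sd = x$response_jitter_sd,
    latent_stage_sd = x$latent_stage_sd,
    stage_noise = unlist(x$stage_noise),
    beat_cv = unlist(x$beat_cv),
    rr_jitter_sd = x$rr_jitter_sd,
    correlation_targets = unlist(x$correlation_targets),
    missingness_rate_echo = x$missingness_rate_echo,
    missingness_rate_absolute = x$missingness_rate_absolute,
    noise_scale = 1,  # already folded into stage_noise / beat_cv
    vti_n = x$vti_n,
    vti_cv = x$vti_cv,
    lvot_mean = x$lvot_mean,
    lvot_sd = x$lvot_sd,
    seed = x$seed
  )
}
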