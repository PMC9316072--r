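# Coupling of each generated parameter to the shared latent central-volume
# fluctuation (+1: moves with circulating volume, -1: counter-regulatory,
# 0: uncoupled complexity/development channel).
.latent_coupling <- c(
  sv_tte = 1, sv = 1, hr = -1, pep = -1, lvet = 1, icon = 1,
  svv = -1, hrv = 1, vic = 0, hrc = 0, mse = 0, pnn = 0, stat = 0,
  sbp = 1, dbp = -1
)

# Baseline physiological levels (log-normal medians and log-SDs).
.baseline_spec <- list(
  sv   = c(95, 0.10),  hr  = c(62, 0.08), pep = c(95, 0.08),
  lvet = c(300, 0.06), icon = c(60, 0.25), svv = c(10, 0.20),
  hrv  = c(55, 0.30),  vic = c(15, 0.20), hrc = c(1.1, 0.15),
  mse  = c(1.3, 0.15), pnn = c(18, 0.30), stat = c(0.85, 0.10),
  sbp  = c(122, 0.06), dbp = c(70, 0.07)
)

#' Stroke volume from LVOT diameter and VTI samples
#'
#' Echocardiographic stroke volume: cross-sectional area of the left
#' ventricular outflow tract times the median velocity-time integral,
#' `SV = pi * (d/2)^2 * median(VTI)`.
#'
#' @param lvot_diameter LVOT diameter in cm (baseline diameter, reused at
#'   every stage).
#' @param vti_samples numeric vector of VTI measurements in cm (at least
#'   one).
#' @return stroke volume in mL.
#' @examples
#' compute_sv_from_vti(2.0, c(18, 20, 22))  # pi * 1^2 * 20
#' @export
compute_sv_from_vti <- function(lvot_diameter, vti_samples) {
  if (!is.numeric(lvot_diameter) || length(lvot_diameter) != 1 ||
      !is.finite(lvot_diameter) || lvot_diameter <= 0) {
    stop("domain error: lvot_diameter must be a single positive number")
  }
  if (length(vti_samples) < 1 || !is.numeric(vti_samples)) {
    stop("domain error: need at least one VTI sample")
  }
  pi * (lvot_diameter / 2)^2 * stats::median(vti_samples)
}

#' Body surface area (DuBois)
#'
#' @param weight_kg body weight in kg.
#' @param height_cm body height in cm.
#' @return BSA in square metres.
#' @export
bsa_dubois <- function(weight_kg, height_cm) {
  stopifnot(all(weight_kg > 0), all(height_cm > 0))
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

# Draw subject anthropometrics + per-parameter baselines and random effects.
.draw_subjects <- function(n, config) {
  height <- pmin(pmax(stats::rnorm(n, 183.5, 3.5), 168), 200)
  weight <- pmin(pmax(exp(stats::rnorm(n, log(79), 0.11)), 58), 115)
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    height_cm = height,
    weight_kg = weight,
    bsa_m2 = bsa_dubois(weight, height),
    responsiveness = exp(stats::rnorm(n, 0, config$between_subject_sd)),
    stringsAsFactors = FALSE
  )
  for (p in names(.baseline_spec)) {
    sp <- .baseline_spec[[p]]
    v <- exp(stats::rnorm(n, log(sp[1]), sp[2]))
    if (p == "sv") v <- pmin(pmax(v, 60), 130)
    if (p == "hr") v <- pmin(pmax(v, 50), 100)
    subjects[[paste0("base_", p)]] <- v
  }
  subjects
}

# Stage-level log deviations from baseline for one parameter:
#   a_ip * log(m_p(stage)) + c_p * z_is + d_p * w_ips
# a_ip: subject responsiveness (shared g_i times parameter jitter),
# z_is: shared latent volume fluctuation, w_ips: parameter-specific noise.
.stage_log_levels <- function(param, subjects, z, config) {
  n <- nrow(subjects)
  stages <- colnames(config$stage_multipliers)
  S <- length(stages)
  logm <- log(config$stage_multipliers[param, ])
  a <- subjects$responsiveness *
    exp(stats::rnorm(n, 0, config$response_jitter_sd))
  d <- config$stage_noise[[param]]
  if (is.null(d) || is.na(d)) d <- 0
  cpl <- .latent_coupling[[param]]
  w <- matrix(stats::rnorm(n * S, 0, d), n, S)
  lev <- outer(a, logm) + cpl * z + w
  dimnames(lev) <- list(subjects$subject_id, stages)
  lev
}

#' Generate a synthetic LBNP cohort
#'
#' Simulates beat-to-beat electrical-cardiometry streams and per-stage
#' echocardiographic reference stroke volume for `n_subjects` volunteers
#' undergoing the graded LBNP protocol. Stage responses are multiplicative
#' (log-normal subject effects on the configured stage medians), all
#' volume-responsive parameters share one latent per-(subject, stage)
#' central-volume fluctuation (inducing the intra-subject correlation
#' structure), and beats carry parameter-specific log-normal noise at
#' heart-rate-determined intervals. Values are stationary within a stage.
#'
#' Derived identities hold per beat: `si = sv / bsa`, `co = sv * hr / 1000`,
#' `ci = co / bsa`, `str = pep / lvet`, `ftc = lvet / sqrt(RR)` (Bazett),
#' `map = (sbp + 2 dbp) / 3`.
#'
#' @param n_subjects number of volunteers (>= 1).
#' @param config an [generator_config()].
#' @param protocol an [lbnp_protocol()].
#' @return Object of class `lbnp_cohort`: list with `subjects` (one row per
#'   subject with anthropometrics and baselines), `beats` (data.table, one
#'   row per heartbeat with all parameters of [ec_parameters()]), `echo`
#'   (one row per subject x stage: LVOT diameter, VTI samples, derived
#'   `sv_tte_ml`, `missing` flag), and the provenance `config`/`protocol`.
#' @examples
#' coh <- generate_cohort(3, generator_config(seed = 1))
#' head(coh$echo)
#' @export
generate_cohort <- function(n_subjects,
                            config = generator_config(),
                            protocol = lbnp_protocol()) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects < 1) {
    stop("domain error: n_subjects must be >= 1")
  }
  n_subjects <- as.integer(n_subjects)
  stopifnot(inherits(config, "lbnp_config"), inherits(protocol, "lbnp_protocol"))
  stages <- protocol$stages$stage
  if (!identical(stages, colnames(config$stage_multipliers))) {
    stop("configuration error: config stages must match protocol stages")
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  subjects <- .draw_subjects(n_subjects, config)
  S <- length(stages)
  # shared latent central-volume fluctuation per (subject, stage)
  z <- matrix(stats::rnorm(n_subjects * S, 0, config$latent_stage_sd),
              n_subjects, S)

  gen <- .ec_generated
  lev <- lapply(stats::setNames(c("sv_tte", gen), c("sv_tte", gen)),
                function(p) .stage_log_levels(p, subjects, z, config))

  # --- echo reference (per subject x stage) ---
  lvot <- pmax(stats::rnorm(n_subjects, config$lvot_mean, config$lvot_sd), 1.6)
  csa <- pi * (lvot / 2)^2
  sv_tte_base <- subjects$base_sv * exp(stats::rnorm(n_subjects, 0, 0.08))
  echo <- vector("list", n_subjects * S)
  k <- 0L
  vti_mat <- matrix(NA_real_, n_subjects * S, config$vti_n)
  for (i in seq_len(n_subjects)) {
    for (s in seq_len(S)) {
      k <- k + 1L
      target_sv <- sv_tte_base[i] * exp(lev$sv_tte[i, s])
      target_vti <- target_sv / csa[i]
      vti <- target_vti * exp(stats::rnorm(config$vti_n, 0, config$vti_cv))
      vti_mat[k, ] <- vti
      echo[[k]] <- data.frame(
        subject_id = subjects$subject_id[i],
        stage = stages[s],
        lvot_diameter_cm = lvot[i],
        sv_tte_ml = compute_sv_from_vti(lvot[i], vti),
        missing = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  echo <- do.call(rbind, echo)
  colnames(vti_mat) <- paste0("vti_", seq_len(config$vti_n))
  echo <- cbind(echo[c("subject_id", "stage", "lvot_diameter_cm")],
                as.data.frame(vti_mat),
                echo[c("sv_tte_ml", "missing")])

  # --- beat-to-beat EC streams ---
  dur <- protocol$stages$duration_s
  beat_list <- vector("list", n_subjects * S)
  k <- 0L
  for (i in seq_len(n_subjects)) {
    for (s in seq_len(S)) {
      k <- k + 1L
      hr_stage <- subjects$base_hr[i] * exp(lev$hr[i, s])
      rr_mean <- 60 / hr_stage
      n_beats <- max(1L, floor(dur[s] / rr_mean) + 5L)
      rr <- rr_mean * exp(stats::rnorm(n_beats, 0, config$rr_jitter_sd))
      t <- cumsum(rr)
      keep <- t < dur[s]
      rr <- rr[keep]; t <- t[keep]
      nb <- length(rr)
      if (nb == 0L) { rr <- rr_mean; t <- rr_mean; nb <- 1L }
      b <- data.table::data.table(
        subject_id = subjects$subject_id[i],
        stage = stages[s],
        time_s = t
      )
      b$hr <- 60 / rr
      for (p in setdiff(gen, "hr")) {
        cv <- config$beat_cv[[p]]
        if (is.null(cv) || is.na(cv)) cv <- 0
        stage_val <- subjects[[paste0("base_", p)]][i] * exp(lev[[p]][i, s])
        b[[p]] <- stage_val * exp(stats::rnorm(nb, 0, cv))
      }
      b$co <- b$sv * b$hr / 1000
      b$si <- b$sv / subjects$bsa_m2[i]
      b$ci <- b$co / subjects$bsa_m2[i]
      b$str <- b$pep / b$lvet
      b$ftc <- b$lvet / sqrt(rr)
      b$map <- (b$sbp + 2 * b$dbp) / 3
      b$ccc <- seq_len(nb)
      beat_list[[k]] <- b
    }
  }
  beats <- data.table::rbindlist(beat_list)
  data.table::setcolorder(
    beats, c("subject_id", "stage", "time_s", ec_parameters()))

  cohort <- structure(
    list(subjects = subjects, beats = beats, echo = echo,
         config = config, protocol = protocol),
    class = "lbnp_cohort"
  )
  inject_missingness(cohort, config, reseed = FALSE)
}

#' Flag missing echo acquisitions and EC recordings
#'
#' Applies the configured missingness mechanisms to a cohort: each
#' (subject, stage) echo acquisition is independently missing with
#' `missingness_rate_echo` (its VTI samples and derived stroke volume are
#' blanked and the `missing` flag set; beats are untouched), and each
#' (subject, stage) EC recording is dropped entirely with
#' `missingness_rate_absolute`.
#'
#' @param cohort an `lbnp_cohort`.
#' @param config an [generator_config()] supplying the rates.
#' @param reseed if `TRUE` (default when called directly), seed the RNG
#'   from `config$seed` first.
#' @return the cohort with missingness applied.
#' @export
inject_missingness <- function(cohort, config = cohort$config, reseed = TRUE) {
  stopifnot(inherits(cohort, "lbnp_cohort"))
  for (r in c(config$missingness_rate_echo, config$missingness_rate_absolute)) {
    if (!is.numeric(r) || r < 0 || r >= 1) {
      stop("configuration error: missingness rates must lie in [0, 1)")
    }
  }
  if (reseed && !is.null(config$seed)) set.seed(config$seed + 1L)
  if (config$missingness_rate_echo > 0) {
    miss <- stats::runif(nrow(cohort$echo)) < config$missingness_rate_echo
    cohort$echo$missing <- cohort$echo$missing | miss
    vti_cols <- grep("^vti_", names(cohort$echo), value = TRUE)
    cohort$echo[cohort$echo$missing, c(vti_cols, "sv_tte_ml")] <- NA_real_
  }
  if (config$missingness_rate_absolute > 0) {
    pairs <- unique(cohort$beats[, c("subject_id", "stage")])
    drop <- stats::runif(nrow(pairs)) < config$missingness_rate_absolute
    if (any(drop)) {
      dropped <- pairs[drop, ]
      key <- paste(cohort$beats$subject_id, cohort$beats$stage)
      cohort$beats <- cohort$beats[!(key %in% paste(dropped$subject_id,
                                                    dropped$stage)), ]
    }
  }
  cohort
}

#' @export
print.lbnp_cohort <- function(x, ...) {
  cat("Synthetic LBNP cohort: ", nrow(x$subjects), " subjects, ",
      nrow(x$beats), " beats, ", sum(x$echo$missing),
      " missing echo acquisitions\n", sep = "")
  invisible(x)
}

#' Write cohort tables as CSV
#'
#' @param cohort an `lbnp_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written (`beats.csv`, `echo.csv`,
#'   `subjects.csv`).
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lbnp_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("beats.csv", "echo.csv", "subjects.csv"))
  data.table::fwrite(cohort$beats, paths[1])
  data.table::fwrite(cohort$echo, paths[2])
  data.table::fwrite(cohort$subjects, paths[3])
  invisible(paths)
}
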