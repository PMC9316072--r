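#' LBNP study protocol definition
#'
#' Describes the timing of a graded lower-body negative pressure (LBNP)
#' session: an ordered set of stages (label, chamber pressure, duration),
#' the initial interval of each stage that is excluded from analysis
#' (pressure-transition settling), and the analysis window taken at the end
#' of each stage.
#'
#' The default is the 5-stage protocol used throughout the package:
#' baseline (0 mmHg, 10 min), three LBNP stages (-15, -30, -45 mmHg,
#' 7 min each) and recovery (0 mmHg, 10 min). The first two minutes of each
#' LBNP stage and the first seven minutes of recovery are excluded; the
#' analysis window is the last two minutes of every stage.
#'
#' @param stages data.frame with columns `stage` (character label),
#'   `pressure_mmhg` (numeric), `duration_s` (numeric, > 0).
#' @param exclusion_head_s numeric vector, one value per stage: seconds at
#'   the start of the stage excluded from analysis.
#' @param window_length_s length of the analysis window at stage end, in
#'   seconds.
#' @return An object of class `lbnp_protocol`.
#' @examples
#' p <- lbnp_protocol()
#' p$stages
#' @export
lbnp_protocol <- function(stages = NULL,
                          exclusion_head_s = NULL,
                          window_length_s = 120) {
  if (is.null(stages)) {
    stages <- data.frame(
      stage = c("baseline", "lbnp15", "lbnp30", "lbnp45", "recovery"),
      pressure_mmhg = c(0, -15, -30, -45, 0),
      duration_s = c(600, 420, 420, 420, 600),
      stringsAsFactors = FALSE
    )
    if (is.null(exclusion_head_s)) {
      exclusion_head_s <- c(0, 120, 120, 120, 420)
    }
  }
  if (is.null(exclusion_head_s)) {
    exclusion_head_s <- rep(0, nrow(stages))
  }
  stopifnot(
    is.data.frame(stages),
    all(c("stage", "pressure_mmhg", "duration_s") %in% names(stages)),
    nrow(stages) >= 1,
    !anyDuplicated(stages$stage),
    all(stages$duration_s > 0),
    length(exclusion_head_s) == nrow(stages),
    all(exclusion_head_s >= 0),
    window_length_s > 0
  )
  bad <- stages$duration_s < exclusion_head_s + window_length_s
  if (any(bad)) {
    stop("protocol error: stage(s) ", paste(stages$stage[bad], collapse = ", "),
         " shorter than exclusion_head + window_length")
  }
  structure(
    list(
      stages = stages,
      exclusion_head_s = exclusion_head_s,
      window_length_s = window_length_s
    ),
    class = "lbnp_protocol"
  )
}

#' @export
print.lbnp_protocol <- function(x, ...) {
  cat("LBNP protocol:", nrow(x$stages), "stages, analysis window",
      x$window_length_s, "s\n")
  df <- x$stages
  df$exclusion_head_s <- x$exclusion_head_s
  print(df, row.names = FALSE)
  invisible(x)
}

#' Stage order helper
#'
#' Integer rank of each stage label in protocol order.
#' @param stage character vector of stage labels.
#' @param protocol an [lbnp_protocol()].
#' @return integer vector of ranks (1 = first stage).
#' @keywords internal
stage_rank <- function(stage, protocol) {
  r <- match(stage, protocol$stages$stage)
  if (anyNA(r)) stop("unknown stage label(s): ",
                     paste(unique(stage[is.na(r)]), collapse = ", "))
  r
}

#' Analysis-window time bounds per stage
#'
#' @param protocol an [lbnp_protocol()].
#' @return data.frame with stage, window start and end (seconds from stage
#'   start). Errors if a window would overlap the excluded head interval.
#' @keywords internal
window_bounds <- function(protocol) {
  end <- protocol$stages$duration_s
  start <- end - protocol$window_length_s
  if (any(start < protocol$exclusion_head_s)) {
    stop("protocol error: analysis window overlaps an excluded interval")
  }
  data.frame(
    stage = protocol$stages$stage,
    window_start_s = start,
    window_end_s = end,
    stringsAsFactors = FALSE
  )
}
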