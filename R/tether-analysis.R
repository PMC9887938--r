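#' Zero-force offset from a pre-contact recording
#'
#' The mean force of the Brownian recording taken before the bead touches the
#' cell defines the point of zero force for that pull; the offset returned
#' here is subtracted from the whole curve downstream.
#'
#' @param precontact a [trap_trace()] covering only the pre-contact segment,
#'   or a numeric vector of positions in the trace's units
#' @param cal a `calibration_result`
#' @return baseline offset in pN
#' @export
zero_baseline <- function(precontact, cal) {
  stopifnot(inherits(cal, "calibration_result"))
  x <- if (inherits(precontact, "trap_trace")) precontact$position_x
       else as.numeric(precontact)
  if (length(x) == 0) stop("empty pre-contact segment")
  cal$kappa * cal$beta * mean(x)
}

# classify stage samples into stationary/moving episodes and map the episode
# sequence onto the protocol phase order; velocity threshold is a fraction
# of the protocol retraction speed
segment_stage <- function(time, stage, protocol, speed_frac = 0.1) {
  n <- length(stage)
  dt <- mean(diff(time))
  thr <- speed_frac * protocol$retract_speed
  # forward-difference velocity: sample i is "moving" when the stage moves
  # between i and i+1, so episode edges are sample-exact on clean channels
  v_raw <- c(diff(stage), 0) / dt
  # light smoothing only for blip rejection on noisy channels
  w <- max(3L, min(25L, round(0.05 / dt)))
  v_sm <- stats::filter(v_raw, rep(1 / w, w), sides = 2)
  v_sm[is.na(v_sm)] <- 0
  moving <- abs(v_raw) > thr & abs(v_sm) > 0.5 * thr
  r <- rle(as.vector(moving))
  # drop blips shorter than the smoothing window
  keep <- r$lengths >= w
  if (!all(keep)) {
    vals <- r$values
    for (i in which(!keep)) vals[i] <- NA
    vals <- zoo_fill(vals)
    r <- rle(vals)
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ep <- data.frame(start = starts, end = ends, moving = r$values)
  # map: the longest moving episode is the retraction; what follows is hold,
  # what precedes is contact, the moving episode before that is the
  # approach, anything earlier is baseline
  mov_idx <- which(ep$moving)
  if (length(mov_idx) == 0) {
    return(rep("contact", n))  # stage never moves: single stationary phase
  }
  i_ret <- mov_idx[which.max(ep$end[mov_idx] - ep$start[mov_idx])]
  phase <- rep(NA_character_, nrow(ep))
  phase[i_ret] <- "retract"
  if (i_ret < nrow(ep)) phase[(i_ret + 1):nrow(ep)] <- "hold"
  if (i_ret > 1) phase[i_ret - 1] <- "contact"
  if (i_ret > 2) phase[i_ret - 2] <- "approach"
  if (i_ret > 3) phase[seq_len(i_ret - 3)] <- "baseline"
  lab <- rep(NA_character_, n)
  for (i in seq_len(nrow(ep))) lab[ep$start[i]:ep$end[i]] <- phase[i]
  lab
}

# forward/backward fill of NAs in a vector (no zoo dependency)
zoo_fill <- function(x) {
  for (i in seq_along(x)) if (is.na(x[i]) && i > 1) x[i] <- x[i - 1]
  for (i in rev(seq_along(x))) if (is.na(x[i]) && i < length(x)) x[i] <- x[i + 1]
  x
}

#' Convert a calibrated pull recording into a force-time curve
#'
#' Multiplies bead displacement from the trap centre by the calibrated trap
#' stiffness (and detector sensitivity for raw-unit traces), subtracts the
#' pre-contact baseline, and labels the protocol phases by segmenting the
#' stage-position channel into stationary and constant-velocity episodes
#' matched against the declared protocol.
#'
#' @param trace a [trap_trace()] with a stage channel
#' @param cal a `calibration_result`
#' @param protocol a [pull_protocol()]
#' @param baseline baseline offset in pN; `NULL` (default) computes it with
#'   [zero_baseline()] from the samples labelled `baseline`
#' @param speed_frac stage-velocity threshold as a fraction of the protocol
#'   retraction speed (default 0.1)
#' @return object of class `force_curve`: a data.frame with columns `time`
#'   (s), `force` (pN), `stage` (um), `phase`
#' @export
to_force_curve <- function(trace, cal, protocol, baseline = NULL,
                           speed_frac = 0.1) {
  stopifnot(inherits(trace, "trap_trace"),
            inherits(cal, "calibration_result"),
            inherits(protocol, "pull_protocol"))
  if (is.null(trace$stage_position))
    stop("stage channel missing: cannot segment protocol phases")
  force <- cal$kappa * cal$beta * trace$position_x
  phase <- segment_stage(trace$time, trace$stage_position, protocol,
                         speed_frac)
  if (is.null(baseline)) {
    pre <- force[phase == "baseline"]
    baseline <- if (length(pre) > 0) mean(pre) else 0
  }
  out <- data.frame(time = trace$time,
                    force = force - baseline,
                    stage = trace$stage_position,
                    phase = phase,
                    stringsAsFactors = FALSE)
  attr(out, "baseline_pN") <- baseline
  attr(out, "protocol") <- protocol
  class(out) <- c("force_curve", "data.frame")
  out
}

#' Extract peak and steady-state tether forces from a force curve
#'
#' The peak force (PF) is the maximum force over the retraction and hold
#' phases; the steady-state force (SSF) is the mean force over the final
#' `hold_duration` seconds of the hold, during which the bead is stationary
#' at full tether extension. A pull whose hold-phase mean falls below
#' `lost_floor` is flagged `tether_lost` (the metrics are still reported).
#' Optionally a moving-median filter of odd width `smooth_width` is applied
#' before the PF search; smoothing reduces the upward noise bias of the
#' max statistic and is off by default.
#'
#' @param curve a `force_curve` from [to_force_curve()]
#' @param hold_duration SSF window length in s (default: the protocol's hold
#'   duration, 30 s)
#' @param lost_floor tether-lost QC threshold in pN (default 1)
#' @param smooth_width odd moving-median width in samples, or `NULL` for no
#'   smoothing (default)
#' @return object of class `tether_metrics`: list with `peak_force`,
#'   `steady_state_force`, `baseline_offset`, `hold_window` (start/end s),
#'   `qc_flags` (character vector, possibly empty)
#' @export
extract_metrics <- function(curve, hold_duration = NULL, lost_floor = 1,
                            smooth_width = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  protocol <- attr(curve, "protocol")
  if (is.null(hold_duration))
    hold_duration <- if (!is.null(protocol)) protocol$hold_duration else 30
  if (!any(curve$phase == "hold")) stop("curve has no hold phase")
  if (!any(curve$phase == "retract")) stop("curve has no retract phase")
  f <- curve$force
  if (!is.null(smooth_width)) {
    stopifnot(smooth_width %% 2 == 1)
    f <- stats::runmed(f, smooth_width)
  }
  sel_pf <- curve$phase %in% c("retract", "hold")
  pf <- max(f[sel_pf])

  t_hold <- curve$time[curve$phase == "hold"]
  t_end <- max(t_hold)
  t_start <- t_end - hold_duration
  sel_ssf <- curve$phase == "hold" & curve$time >= t_start
  ssf <- mean(curve$force[sel_ssf])

  qc <- character(0)
  hold_mean <- mean(curve$force[curve$phase == "hold"])
  if (hold_mean < lost_floor) qc <- c(qc, "tether_lost")
  if (pf < ssf) qc <- c(qc, "pf_below_ssf")
  structure(list(peak_force = pf,
                 steady_state_force = ssf,
                 baseline_offset = attr(curve, "baseline_pN"),
                 hold_window = c(t_start, t_end),
                 qc_flags = qc),
            class = "tether_metrics")
}

#' @export
print.tether_metrics <- function(x, ...) {
  cat(sprintf("tether metrics: PF = %.2f pN, SSF = %.2f pN over [%.1f, %.1f] s%s\n",
              x$peak_force, x$steady_state_force,
              x$hold_window[1], x$hold_window[2],
              if (length(x$qc_flags)) paste0(" [", paste(x$qc_flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Analyse a batch of tether pulls
#'
#' Runs [to_force_curve()] and [extract_metrics()] over a list of traces (or
#' trace file paths), collecting one row per pull. Failures on individual
#' pulls are recorded in the `error` column and do not abort the batch.
#'
#' @param inputs list of [trap_trace()] objects or file paths readable by
#'   [read_trace()]; names are used as pull ids
#' @param cal a `calibration_result`
#' @param protocol a [pull_protocol()] shared by the batch
#' @param group optional group label (recycled) recorded per row
#' @param ... passed to [extract_metrics()]
#' @return data.frame with columns pull_id, group, PF_pN, SSF_pN,
#'   baseline_pN, qc, error
#' @export
batch_pulls <- function(inputs, cal, protocol, group = NA_character_, ...) {
  ids <- names(inputs)
  if (is.null(ids)) ids <- as.character(seq_along(inputs))
  ids[ids == ""] <- as.character(which(ids == ""))
  group <- rep_len(group, max(length(inputs), 1L))
  rows <- lapply(seq_along(inputs), function(i) {
    res <- tryCatch({
      tr <- inputs[[i]]
      if (is.character(tr)) tr <- read_trace(tr)
      m <- extract_metrics(to_force_curve(tr, cal, protocol), ...)
      data.frame(pull_id = ids[i], group = group[i],
                 PF_pN = m$peak_force, SSF_pN = m$steady_state_force,
                 baseline_pN = m$baseline_offset,
                 qc = paste(m$qc_flags, collapse = ";"),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(pull_id = ids[i], group = group[i],
                 PF_pN = NA_real_, SSF_pN = NA_real_, baseline_pN = NA_real_,
                 qc = "", error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  if (length(rows) == 0) {
    return(data.frame(pull_id = character(0), group = character(0),
                      PF_pN = numeric(0), SSF_pN = numeric(0),
                      baseline_pN = numeric(0), qc = character(0),
                      error = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
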