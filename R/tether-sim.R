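#' Tether pulling protocol
#'
#' Describes the stage motion of one tether pull: a pre-contact baseline
#' recording, approach to the cell, a stationary contact period, a short test
#' retraction to verify attachment, constant-speed retraction over the pull
#' distance, and a stationary hold at full extension. Presets encode the two
#' cell-type protocols: fibroblasts are pulled at 0.1 um/s over 10 um,
#' neurons at 0.5 um/s over 20 um, both with 5 s contact and a 30 s hold.
#'
#' @param retract_speed retraction speed in um/s
#' @param pull_distance total pull distance in um
#' @param contact_duration stationary contact period in s (default 5)
#' @param test_retract attachment-test retraction in um (default 0.25)
#' @param hold_duration stationary hold at full extension in s (default 30)
#' @param baseline_duration pre-contact Brownian recording in s (default 5)
#' @param preset optional preset name, `"fibroblast"` or `"neuron"`; when
#'   given, `retract_speed` and `pull_distance` are taken from the preset
#' @return object of class `pull_protocol`
#' @examples
#' pull_protocol(preset = "fibroblast") # 0.1 um/s x 10 um -> 100 s retraction
#' @export
pull_protocol <- function(retract_speed = NULL, pull_distance = NULL,
                          contact_duration = 5, test_retract = 0.25,
                          hold_duration = 30, baseline_duration = 5,
                          preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("fibroblast", "neuron"))
    if (preset == "fibroblast") {
      retract_speed <- 0.1; pull_distance <- 10
    } else {
      retract_speed <- 0.5; pull_distance <- 20
    }
  }
  if (is.null(retract_speed) || is.null(pull_distance))
    stop("retract_speed and pull_distance required (or use a preset)")
  vals <- c(retract_speed = retract_speed, pull_distance = pull_distance,
            contact_duration = contact_duration, test_retract = test_retract,
            hold_duration = hold_duration, baseline_duration = baseline_duration)
  if (any(!is.finite(vals) | vals <= 0))
    stop("all protocol durations and distances must be strictly positive")
  structure(list(retract_speed = retract_speed,
                 pull_distance = pull_distance,
                 contact_duration = contact_duration,
                 test_retract = test_retract,
                 hold_duration = hold_duration,
                 baseline_duration = baseline_duration,
                 preset = preset),
            class = "pull_protocol")
}

#' Duration of each protocol phase in seconds
#'
#' The approach and test-retract stage moves run at the protocol retraction
#' speed. Phase order: baseline, approach, contact, retract, hold.
#'
#' @param protocol a [pull_protocol()]
#' @return named numeric vector of phase durations (s)
#' @export
protocol_phase_durations <- function(protocol) {
  stopifnot(inherits(protocol, "pull_protocol"))
  c(baseline = protocol$baseline_duration,
    approach = protocol$test_retract / protocol$retract_speed,
    contact = protocol$contact_duration,
    retract = protocol$pull_distance / protocol$retract_speed,
    hold = protocol$hold_duration)
}

#' Parameters for a synthetic tether pull
#'
#' Ground-truth description of one pull. The noise-free force trajectory is
#' zero before contact, rises linearly at `attachment_stiffness x speed`
#' during retraction until it reaches `peak_force`, relaxes exponentially
#' (time constant `relax_time`) toward `steady_state_force` over the rest of
#' the retraction, and equals `steady_state_force` throughout the hold.
#' Gaussian white noise of `noise_sd` is added on top. The recording is
#' stored as bead position (force / trap stiffness) so that the analysis
#' chain exercises the same calibration step as real data.
#'
#' @param peak_force ground-truth PF in pN
#' @param steady_state_force ground-truth SSF in pN
#' @param attachment_stiffness force loading stiffness during the initial
#'   rise, in pN/um
#' @param relax_time exponential relaxation time from peak toward the
#'   plateau, in s; must be much shorter than the retraction so the hold
#'   phase sits exactly on the plateau
#' @param noise_sd additive force noise SD in pN
#' @param protocol a [pull_protocol()]
#' @param stiffness_kappa trap stiffness used to encode force as bead
#'   position, pN/nm
#' @param sampling_rate recording rate in Hz
#' @param seed integer RNG seed
#' @return object of class `tether_sim_params`
#' @export
tether_sim_params <- function(peak_force = 60,
                              steady_state_force = 30,
                              attachment_stiffness = 100,
                              relax_time = 5,
                              noise_sd = 2,
                              protocol = pull_protocol(preset = "fibroblast"),
                              stiffness_kappa = 0.05,
                              sampling_rate = 200,
                              seed = 1L) {
  if (!is.finite(peak_force) || !is.finite(steady_state_force) ||
      peak_force < steady_state_force || steady_state_force < 0)
    stop("invalid parameters: need peak_force >= steady_state_force >= 0")
  if (relax_time <= 0) stop("relax_time must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(inherits(protocol, "pull_protocol"),
            attachment_stiffness > 0, stiffness_kappa > 0, sampling_rate > 0)
  structure(list(peak_force = peak_force,
                 steady_state_force = steady_state_force,
                 attachment_stiffness = attachment_stiffness,
                 relax_time = relax_time,
                 noise_sd = noise_sd,
                 protocol = protocol,
                 stiffness_kappa = stiffness_kappa,
                 sampling_rate = sampling_rate,
                 seed = as.integer(seed)),
            class = "tether_sim_params")
}

#' Simulate a tether pull recording
#'
#' Produces a [trap_trace()] whose position channel encodes the noisy force
#' curve (position = force / kappa) and whose stage channel encodes the pull
#' protocol, plus the noise-free ground truth. The stage moves away from the
#' cell during approach is reversed: here stage position increases with
#' distance pulled, starting at 0.
#'
#' @param params a [tether_sim_params()]
#' @return list with elements `trace` (a [trap_trace()]), `ground_truth`
#'   (list: peak_force, steady_state_force, phase boundaries in s and sample
#'   index, noise-free force vector) and `params`
#' @examples
#' sim <- simulate_tether_pull(tether_sim_params(noise_sd = 0))
#' max(sim$ground_truth$force_true) # == 60
#' @export
simulate_tether_pull <- function(params) {
  stopifnot(inherits(params, "tether_sim_params"))
  pr <- params$protocol
  durs <- protocol_phase_durations(pr)
  fs <- params$sampling_rate
  dt <- 1 / fs
  n_per <- round(durs * fs)
  if (any(n_per < 1)) stop("sampling_rate too low to resolve protocol phases")
  n <- sum(n_per)
  time <- seq(0, by = dt, length.out = n)
  phase <- rep(names(n_per), times = n_per)

  # stage channel, um: 0 during baseline; approach moves test_retract toward
  # 0 contact offset (we let approach end at 0); retract ramps to
  # pull_distance; hold stays there
  bounds <- cumsum(c(0, durs))
  names(bounds) <- c(names(durs), "end")
  stage <- numeric(n)
  idx <- split(seq_len(n), factor(phase, levels = names(durs)))
  t_ph <- function(p) time[idx[[p]]] - bounds[[p]]
  stage[idx$baseline] <- -pr$test_retract
  stage[idx$approach] <- -pr$test_retract + pr$retract_speed * t_ph("approach")
  stage[idx$contact] <- 0
  stage[idx$retract] <- pr$retract_speed * t_ph("retract")
  stage[idx$hold] <- pr$pull_distance

  # noise-free force, pN
  force <- numeric(n)
  t_rise <- params$peak_force / (params$attachment_stiffness * pr$retract_speed)
  retract_dur <- durs[["retract"]]
  if (t_rise >= retract_dur)
    stop("peak_force not reachable during retraction at this attachment stiffness")
  tr <- t_ph("retract")
  rise <- tr <= t_rise
  f_ret <- numeric(length(tr))
  f_ret[rise] <- params$attachment_stiffness * pr$retract_speed * tr[rise]
  f_ret[!rise] <- params$steady_state_force +
    (params$peak_force - params$steady_state_force) *
    exp(-(tr[!rise] - t_rise) / params$relax_time)
  force[idx$retract] <- f_ret
  force[idx$hold] <- params$steady_state_force
  # make the requested peak exact regardless of sample alignment
  i_peak <- idx$retract[which.min(abs(tr - t_rise))]
  force[i_peak] <- params$peak_force

  noisy <- force
  if (params$noise_sd > 0) {
    noisy <- force + with_seed(params$seed,
                               stats::rnorm(n, sd = params$noise_sd))
  }
  trace <- trap_trace(time = time,
                      position_x = noisy / params$stiffness_kappa,
                      stage_position = stage,
                      sampling_rate = fs,
                      units_flag = "physical")
  list(trace = trace,
       ground_truth = list(
         peak_force = params$peak_force,
         steady_state_force = params$steady_state_force,
         phase_bounds_s = bounds,
         phase_start_index = stats::setNames(
           cumsum(c(1, utils::head(n_per, -1))), names(n_per)),
         phase = phase,
         force_true = force),
       params = params)
}
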