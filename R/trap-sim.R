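#' Parameters for simulating a bead in a harmonic optical trap
#'
#' The trapped bead is modelled as an overdamped Hookean spring-mass system:
#' an Ornstein-Uhlenbeck (OU) process with relaxation time tau = gamma/kappa,
#' gamma = 6 pi eta r, and equipartition variance k_B T / kappa.
#'
#' @param stiffness_kappa trap stiffness in pN/nm
#' @param bead_radius bead radius in um (default 1.08, i.e. a 2.16 um bead)
#' @param viscosity fluid dynamic viscosity in Pa s
#' @param temperature absolute temperature in K
#' @param sampling_rate acquisition rate in Hz
#' @param duration trace duration in s
#' @param seed integer RNG seed
#' @return object of class `trap_sim_params`
#' @export
trap_sim_params <- function(stiffness_kappa = 0.05,
                            bead_radius = 1.08,
                            viscosity = 1e-3,
                            temperature = 298.15,
                            sampling_rate = 20000,
                            duration = 10,
                            seed = 1L) {
  vals <- c(stiffness_kappa = stiffness_kappa, bead_radius = bead_radius,
            viscosity = viscosity, temperature = temperature,
            sampling_rate = sampling_rate, duration = duration)
  bad <- !is.finite(vals) | vals <= 0
  if (any(bad)) {
    stop("invalid trap parameter(s), must be strictly positive: ",
         paste(names(vals)[bad], collapse = ", "))
  }
  gamma <- stokes_drag_pN_s_nm(bead_radius, viscosity)
  f_c <- stiffness_kappa / (2 * pi * gamma)
  if (sampling_rate < 2 * f_c) {
    warning(sprintf(
      "sampling_rate (%.0f Hz) is below 2x the expected corner frequency (%.0f Hz)",
      sampling_rate, f_c))
  }
  structure(list(stiffness_kappa = stiffness_kappa,
                 bead_radius = bead_radius,
                 viscosity = viscosity,
                 temperature = temperature,
                 sampling_rate = sampling_rate,
                 duration = duration,
                 seed = as.integer(seed)),
            class = "trap_sim_params")
}

#' Construct a trap trace object
#'
#' A uniformly sampled recording of bead position (and optionally stage
#' position). Positions are in nm when `units_flag = "physical"`, or in raw
#' detector units with `units_flag = "detector"`.
#'
#' @param time time stamps in s (uniform)
#' @param position_x,position_y lateral bead positions
#' @param stage_position optional stage position channel in um
#' @param sampling_rate sampling rate in Hz
#' @param units_flag "physical" (nm) or "detector"
#' @return object of class `trap_trace`
#' @export
trap_trace <- function(time, position_x, position_y = NULL,
                       stage_position = NULL,
                       sampling_rate = NULL,
                       units_flag = c("physical", "detector")) {
  units_flag <- match.arg(units_flag)
  n <- length(time)
  if (n < 2) stop("trace must have length >= 2")
  if (length(position_x) != n) stop("position_x length mismatch")
  dt <- diff(time)
  if (any(!is.finite(time)) || any(!is.finite(position_x)))
    stop("non-finite values in trace")
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("non-uniform sampling: max time-step jitter exceeds 1e-6 of dt")
  if (is.null(sampling_rate)) sampling_rate <- 1 / mean(dt)
  if (!is.null(position_y) && length(position_y) != n)
    stop("position_y length mismatch")
  if (!is.null(stage_position) && length(stage_position) != n)
    stop("stage_position length mismatch")
  structure(list(time = as.numeric(time),
                 position_x = as.numeric(position_x),
                 position_y = if (!is.null(position_y)) as.numeric(position_y),
                 stage_position = if (!is.null(stage_position)) as.numeric(stage_position),
                 sampling_rate = sampling_rate,
                 units_flag = units_flag),
            class = "trap_trace")
}

#' @export
print.trap_trace <- function(x, ...) {
  cat(sprintf("trap_trace: %d samples @ %.6g Hz (%.3g s), units: %s%s\n",
              length(x$time), x$sampling_rate,
              length(x$time) / x$sampling_rate, x$units_flag,
              if (!is.null(x$stage_position)) ", with stage channel" else ""))
  invisible(x)
}

# exact OU update over one time step: x' = a x + s xi, with the stationary
# variance sig2 = kBT/kappa; a = exp(-dt/tau) and s^2 = sig2 (1 - a^2).
# Implemented with a recursive filter so long traces stay cheap.
ou_path <- function(n, a, sig_eq, x0) {
  innov <- stats::rnorm(n, sd = sig_eq * sqrt(1 - a^2))
  as.numeric(stats::filter(innov, a, method = "recursive", init = x0))
}

#' Simulate the Brownian motion of a trapped bead
#'
#' Generates both lateral axes of a bead in a harmonic trap using the exact
#' discretization of the Ornstein-Uhlenbeck process,
#' x_{n+1} = x_n exp(-dt/tau) + xi_n sqrt((k_B T / kappa)(1 - exp(-2 dt/tau))),
#' with tau = gamma/kappa and gamma = 6 pi eta r. The exact update (rather
#' than an Euler scheme) keeps the stationary variance and autocorrelation
#' correct at any time step. The two axes are independent; the initial state
#' is drawn from the stationary distribution. Deterministic under the
#' parameter seed.
#'
#' @param params a [trap_sim_params()] object
#' @return a [trap_trace()] in physical units (nm)
#' @examples
#' tr <- simulate_trapped_bead(trap_sim_params(duration = 0.5, seed = 7))
#' sd(tr$position_x) # ~ sqrt(kB T / kappa) = 9.07 nm
#' @export
simulate_trapped_bead <- function(params) {
  stopifnot(inherits(params, "trap_sim_params"))
  gamma <- stokes_drag_pN_s_nm(params$bead_radius, params$viscosity)
  tau <- gamma / params$stiffness_kappa
  dt <- 1 / params$sampling_rate
  n <- max(2L, round(params$duration * params$sampling_rate))
  a <- exp(-dt / tau)
  sig_eq <- sqrt(kbt_pN_nm(params$temperature) / params$stiffness_kappa)
  xy <- with_seed(params$seed, {
    x0 <- stats::rnorm(2, sd = sig_eq)
    list(x = ou_path(n, a, sig_eq, x0[1]),
         y = ou_path(n, a, sig_eq, x0[2]))
  })
  trap_trace(time = seq(0, by = dt, length.out = n),
             position_x = xy$x, position_y = xy$y,
             sampling_rate = params$sampling_rate,
             units_flag = "physical")
}
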