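# Poisson spike simulation for place, head-direction and phase-precessing
# cells, driven by a ground-truth trajectory.

#' Instantaneous firing rate of a neuron along a trajectory
#'
#' @param traj a `trajectory`.
#' @param neuron a [neuron_spec()].
#' @return numeric rate (Hz) at each trajectory sample.
#' @export
neuron_rate <- function(traj, neuron) {
  stopifnot(inherits(traj, "trajectory"), inherits(neuron, "neuron_spec"))
  switch(neuron$kind,
    place = ,
    phase_precessing = {
      d2 <- (traj$x - neuron$center[1])^2 + (traj$y - neuron$center[2])^2
      neuron$baseline_rate + neuron$peak_rate * exp(-d2 / (2 * neuron$sigma^2))
    },
    head_direction = {
      th <- (traj$hd_deg - neuron$preferred_deg) * pi / 180
      neuron$baseline_rate +
        neuron$peak_rate * exp(neuron$kappa * (cos(th) - 1))
    })
}

#' Simulate a spike train from a tuned neuron
#'
#' Spikes are drawn from an inhomogeneous Poisson process whose rate follows
#' the neuron's tuning along the trajectory (thinning algorithm). For
#' phase-precessing cells a perfectly periodic theta-peak train is emitted as
#' well, and each spike is moved within its theta cycle so that its phase
#' decreases linearly (at the specified slope, plus circular noise) with the
#' signed distance travelled through the field.
#'
#' @param traj a `trajectory`.
#' @param neuron a [neuron_spec()].
#' @param seed integer seed.
#' @param phase_noise_deg SD of Gaussian phase noise added to phase-precessing
#'   spikes, degrees.
#' @param phase_at_center theta phase assigned at the field centre, degrees.
#' @return object of class `spike_train`: list with `times` (s, sorted),
#'   `theta_peaks` (s, or NULL), and `neuron`.
#' @export
simulate_spikes <- function(traj, neuron, seed, phase_noise_deg = 25,
                            phase_at_center = 180) {
  stopifnot(inherits(traj, "trajectory"), inherits(neuron, "neuron_spec"))
  T_end <- max(traj$times)
  lambda_max <- neuron$baseline_rate + neuron$peak_rate
  if (lambda_max == 0) {
    return(structure(list(times = numeric(0),
                          theta_peaks = theta_peak_train(neuron, T_end),
                          neuron = neuron), class = "spike_train"))
  }
  rate <- neuron_rate(traj, neuron)
  with_local_seed(seed, {
    n_cand <- stats::rpois(1, lambda_max * T_end)
    cand <- sort(stats::runif(n_cand, 0, T_end))
    lam <- stats::approx(traj$times, rate, xout = cand)$y
    keep <- stats::runif(n_cand) < lam / lambda_max
    spikes <- cand[keep]
    peaks <- theta_peak_train(neuron, T_end)
    if (neuron$kind == "phase_precessing" && length(spikes)) {
      # signed distance through the field along the instantaneous heading
      sx <- stats::approx(traj$times, traj$x, xout = spikes)$y
      sy <- stats::approx(traj$times, traj$y, xout = spikes)$y
      hx <- stats::approx(traj$times, cos(traj$hd_deg * pi / 180), xout = spikes)$y
      hy <- stats::approx(traj$times, sin(traj$hd_deg * pi / 180), xout = spikes)$y
      s <- ((sx - neuron$center[1]) * hx + (sy - neuron$center[2]) * hy) /
        sqrt(hx^2 + hy^2)
      target <- wrap_deg(phase_at_center + neuron$precession_slope * s +
                           stats::rnorm(length(s), 0, phase_noise_deg))
      period <- 1 / neuron$theta_rate
      cyc <- floor(spikes / period)
      spikes <- sort(cyc * period + target / 360 * period)
      spikes <- spikes[spikes >= 0 & spikes <= T_end]
    }
    structure(list(times = spikes,
                   theta_peaks = if (neuron$kind == "phase_precessing") peaks,
                   neuron = neuron),
              class = "spike_train")
  })
}

#' @noRd
theta_peak_train <- function(neuron, T_end) {
  if (neuron$kind != "phase_precessing") return(NULL)
  seq(0, T_end, by = 1 / neuron$theta_rate)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s cell: %d spikes%s\n", x$neuron$kind,
              length(x$times),
              if (!is.null(x$theta_peaks))
                sprintf(", %d theta peaks", length(x$theta_peaks)) else ""))
  invisible(x)
}
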