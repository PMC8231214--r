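#' Configuration for the synthetic herd generator
#'
#' Defines the statistical structure of simulated collar traces. Behaviour
#' is a bout-level semi-Markov chain: a state sequence drawn from
#' `transition_matrix` (zero diagonal) with exponential dwell times around
#' `dwell_means` (minutes), truncated below at one minute -- behaviours are
#' bouts lasting minutes, which a per-sample Markov chain cannot produce.
#' Within a bout the signal follows the state:
#' * `RUMINATION`: an amplitude-modulated chewing sinusoid at `chew_freq_hz`,
#'   gated off for about 2 s at every rumination cycle (the regurgitation
#'   pause); cycle length is drawn per bout from `rumination_cycle_s`.
#' * `EATING`: the chewing oscillation at higher amplitude plus sporadic
#'   broadband head-motion bursts.
#' * `OTHER`: quiescence with sporadic short spikes.
#' Each axis adds an independent slowly drifting offset (a random walk with
#' step `gravity_drift_scale`) representing the gravity component of a
#' rotating collar, plus white measurement noise of sd `noise_sd`.
#'
#' @param n_animals number of animals in the herd
#' @param hours_per_animal trace duration per animal (hours)
#' @param seed global seed; animal `i` uses sub-seed `seed + i`, so growing
#'   the herd never perturbs earlier animals
#' @param transition_matrix 3x3 row-stochastic bout transition matrix with
#'   zero diagonal, states ordered as [behaviour_levels()]
#' @param dwell_means named per-state mean bout length in minutes
#' @param rumination_cycle_s range (low, high) of seconds between
#'   rumination contraction pauses
#' @param chew_freq_hz chewing oscillation frequency (Hz)
#' @param state_amplitudes named per-state motion amplitude (accelerometer
#'   units); per-bout log-normal jitter makes eating and rumination
#'   amplitudes overlap, so the classes are learnable but not trivially
#'   separable
#' @param gravity_drift_scale random-walk step sd of the per-axis offset
#' @param noise_sd white measurement noise sd
#' @param sampling_rate sampling frequency (Hz)
#'
#' @return an object of class `synth_config`
#' @export
synth_config <- function(n_animals = 18,
                         hours_per_animal = 6,
                         seed = 1,
                         transition_matrix = default_transitions(),
                         dwell_means = c(RUMINATION = 30, EATING = 25,
                                         OTHER = 20),
                         rumination_cycle_s = c(40, 60),
                         chew_freq_hz = 1.2,
                         state_amplitudes = c(RUMINATION = 0.30,
                                              EATING = 0.55,
                                              OTHER = 0.12),
                         gravity_drift_scale = 0.002,
                         noise_sd = 0.05,
                         sampling_rate = 10) {
  tm <- as.matrix(transition_matrix)
  states <- behaviour_levels()
  stopifnot(all(dim(tm) == c(3, 3)))
  dimnames(tm) <- list(states, states)
  if (any(abs(rowSums(tm) - 1) > 1e-8) || any(diag(tm) != 0) || any(tm < 0)) {
    stop("transition_matrix must be row-stochastic with zero diagonal",
         call. = FALSE)
  }
  dwell_means <- dwell_means[states]
  state_amplitudes <- state_amplitudes[states]
  if (anyNA(dwell_means) || any(dwell_means <= 0)) {
    stop("dwell_means must be positive and named for all three states",
         call. = FALSE)
  }
  if (anyNA(state_amplitudes) || any(state_amplitudes < 0)) {
    stop("state_amplitudes must be non-negative and named for all states",
         call. = FALSE)
  }
  stopifnot(length(rumination_cycle_s) == 2,
            rumination_cycle_s[1] <= rumination_cycle_s[2],
            chew_freq_hz >= 0, gravity_drift_scale >= 0, noise_sd >= 0)
  structure(
    list(n_animals = as.integer(n_animals),
         hours_per_animal = hours_per_animal,
         seed = as.integer(seed),
         transition_matrix = tm,
         dwell_means = dwell_means,
         rumination_cycle_s = rumination_cycle_s,
         chew_freq_hz = chew_freq_hz,
         state_amplitudes = state_amplitudes,
         gravity_drift_scale = gravity_drift_scale,
         noise_sd = noise_sd,
         sampling_rate = sampling_rate),
    class = "synth_config"
  )
}

#' Default bout-level transition matrix
#'
#' After either feeding behaviour the animal most often settles into
#' other activity; from other activity it resumes rumination or eating
#' with equal probability.
#'
#' @return 3x3 row-stochastic matrix with zero diagonal
#' @export
default_transitions <- function() {
  m <- matrix(c(0.0, 0.3, 0.7,
                0.3, 0.0, 0.7,
                0.5, 0.5, 0.0),
              nrow = 3, byrow = TRUE,
              dimnames = list(behaviour_levels(), behaviour_levels()))
  m
}

#' Dwell-weighted stationary label distribution of a herd configuration
#'
#' Analytic long-run fraction of samples in each state: the stationary
#' distribution of the embedded bout chain weighted by expected dwell time.
#' The one-minute dwell truncation is accounted for in closed form
#' (`E[max(c, X)] = c + m * exp(-c/m)` for exponential dwell with mean `m`).
#'
#' @param config a [synth_config()]
#' @return named numeric vector of per-state sample fractions (sums to 1)
#' @export
stationary_label_fractions <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  P <- config$transition_matrix
  # left eigenvector of P for eigenvalue 1
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  pi_embed <- Re(e$vectors[, i])
  pi_embed <- pi_embed / sum(pi_embed)
  m_s <- config$dwell_means * 60
  trunc_s <- 60
  eff <- trunc_s + m_s * exp(-trunc_s / m_s)
  w <- pi_embed * eff
  stats::setNames(w / sum(w), behaviour_levels())
}

# semi-Markov bout plan covering at least n_samples samples
simulate_bouts <- function(config, n_samples) {
  states <- behaviour_levels()
  fs <- config$sampling_rate
  state <- sample.int(3, 1)
  out_state <- integer(0)
  out_len <- integer(0)
  total <- 0L
  while (total < n_samples) {
    dwell_s <- max(60, stats::rexp(1, rate = 1 / (config$dwell_means[state] * 60)))
    len <- as.integer(round(dwell_s * fs))
    out_state <- c(out_state, state)
    out_len <- c(out_len, len)
    total <- total + len
    state <- sample.int(3, 1, prob = config$transition_matrix[state, ])
  }
  excess <- total - n_samples
  out_len[length(out_len)] <- out_len[length(out_len)] - excess
  list(state = states[out_state], length = out_len)
}

# one bout's shared (pre-axis-loading) motion signal
simulate_bout_signal <- function(state, len, config) {
  fs <- config$sampling_rate
  t_loc <- (seq_len(len) - 1) / fs
  amp <- config$state_amplitudes[state] * exp(stats::rnorm(1, 0, 0.15))
  sig <- numeric(len)
  if (state == "RUMINATION") {
    phase <- stats::runif(1, 0, 2 * pi)
    osc <- amp * sin(2 * pi * config$chew_freq_hz * t_loc + phase)
    cycle <- stats::runif(1, config$rumination_cycle_s[1],
                          config$rumination_cycle_s[2])
    gate <- as.numeric((t_loc %% cycle) >= 2)  # ~2 s regurgitation pause
    sig <- osc * gate
  } else if (state == "EATING") {
    phase <- stats::runif(1, 0, 2 * pi)
    sig <- amp * sin(2 * pi * config$chew_freq_hz * t_loc + phase)
    n_burst <- stats::rpois(1, lambda = 0.15 * len / fs)
    if (n_burst > 0) {
      for (b in seq_len(n_burst)) {
        dur <- round(stats::runif(1, 0.5, 2) * fs)
        start <- sample.int(max(1L, len - dur), 1)
        idx <- start:min(len, start + dur - 1L)
        sig[idx] <- sig[idx] + stats::rnorm(length(idx), 0, amp)
      }
    }
  } else { # OTHER: sporadic spikes over quiescence
    n_spike <- stats::rpois(1, lambda = 0.05 * len / fs)
    if (n_spike > 0) {
      at <- sample.int(len, min(n_spike, len))
      sig[at] <- amp * stats::runif(length(at), 2, 6) *
        sample(c(-1, 1), length(at), replace = TRUE)
    }
  }
  sig
}

# one animal's labelled trace; RNG state assumed set by the caller
simulate_trace <- function(animal_id, config, t0 = 0) {
  fs <- config$sampling_rate
  n <- as.integer(round(config$hours_per_animal * 3600 * fs))
  if (n < 1) stop("trace duration must be positive", call. = FALSE)
  bouts <- simulate_bouts(config, n)
  labels <- rep(bouts$state, bouts$length)
  signal <- numeric(n)
  loading <- matrix(0, n, 3)
  base_loading <- c(1, 0.6, 0.35)
  pos <- 0L
  for (b in seq_along(bouts$state)) {
    len <- bouts$length[b]
    if (len == 0L) next
    idx <- pos + seq_len(len)
    signal[idx] <- simulate_bout_signal(bouts$state[b], len, config)
    lw <- base_loading * exp(stats::rnorm(3, 0, 0.1))
    loading[idx, ] <- matrix(lw, len, 3, byrow = TRUE)
    pos <- pos + len
  }
  accel <- matrix(0, n, 3)
  for (ax in 1:3) {
    offset0 <- stats::runif(1, -1, 1)  # initial gravity projection
    drift <- offset0 +
      cumsum(stats::rnorm(n, 0, config$gravity_drift_scale))
    noise <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd)
             else 0
    accel[, ax] <- loading[, ax] * signal + drift + noise
  }
  labelled_trace(animal_id, t0 + (seq_len(n) - 1) / fs, accel,
                 labels = labels, sampling_rate = fs)
}

#' Generate a synthetic herd of labelled collar traces
#'
#' @param config a [synth_config()]
#' @return list of [labelled_trace()] objects, one per animal, with ids
#'   `"animal_01"`, `"animal_02"`, ...
#' @export
generate_herd <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_animals < 1 || config$hours_per_animal <= 0) {
    stop("herd must contain at least one animal with positive duration",
         call. = FALSE)
  }
  lapply(seq_len(config$n_animals), function(i) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(config$seed + i)
    simulate_trace(sprintf("animal_%02d", i), config,
                   t0 = (i - 1) * 1e6)
  })
}

#' Split a herd into train/validation and held-out test animals
#'
#' Emulates the evaluation protocol of selecting complete animal traces at
#' random for testing, so no animal contributes windows to both sides.
#'
#' @param traces list of [labelled_trace()] objects
#' @param n_test_animals number of animals reserved for testing
#' @param seed RNG seed for the random selection
#' @return list with elements `train` and `test` (disjoint animal sets)
#' @export
make_split_fixture <- function(traces, n_test_animals, seed = 1) {
  stopifnot(is.list(traces), length(traces) > 0)
  if (n_test_animals >= length(traces)) {
    stop("n_test_animals must be smaller than the herd size", call. = FALSE)
  }
  if (n_test_animals < 1) stop("need at least one test animal", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  test_idx <- sort(sample.int(length(traces), n_test_animals))
  list(train = traces[-test_idx], test = traces[test_idx])
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
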