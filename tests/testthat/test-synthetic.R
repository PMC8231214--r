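test_that("herd generation is deterministic given (config, seed)", {
  cfg <- synth_config(n_animals = 2, hours_per_animal = 0.1, seed = 5)
  h1 <- generate_herd(cfg)
  h2 <- generate_herd(cfg)
  expect_identical(h1, h2)

  # extending the herd does not perturb earlier animals
  cfg3 <- synth_config(n_animals = 3, hours_per_animal = 0.1, seed = 5)
  h3 <- generate_herd(cfg3)
  expect_identical(h3[1:2], h1)

  # a different seed gives different traces
  h4 <- generate_herd(synth_config(n_animals = 2, hours_per_animal = 0.1,
                                   seed = 6))
  expect_false(identical(h4[[1]]$accel, h1[[1]]$accel))
})

test_that("label fractions approach the dwell-weighted stationary distribution", {
  # uniform transitions, distinct dwell means; the bout chain (which is
  # exactly what per-sample trace labels replicate) is simulated for the
  # equivalent of 1000 h so sampling noise is well inside the band
  tm <- matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3, byrow = TRUE)
  cfg <- synth_config(n_animals = 1, hours_per_animal = 1000, seed = 2,
                      transition_matrix = tm,
                      dwell_means = c(RUMINATION = 20, EATING = 15,
                                      OTHER = 25))
  expected <- stationary_label_fractions(cfg)
  set.seed(2)
  bouts <- collarcnn:::simulate_bouts(cfg, 1000 * 3600 * 10)
  occupancy <- tapply(bouts$length, factor(bouts$state, behaviour_levels()),
                      sum) / sum(bouts$length)
  expect_lt(max(abs(as.numeric(occupancy) - expected)), 0.05)

  # per-sample trace labels are the bout sequence expanded sample-wise, so
  # shorter real traces inherit the same occupancy structure
  cfg10 <- synth_config(n_animals = 2, hours_per_animal = 5, seed = 2,
                        transition_matrix = tm,
                        dwell_means = c(RUMINATION = 20, EATING = 15,
                                        OTHER = 25))
  herd <- generate_herd(cfg10)
  labs <- unlist(lapply(herd, function(tr) as.character(tr$labels)))
  observed <- table(factor(labs, behaviour_levels())) / length(labs)
  expect_lt(max(abs(as.numeric(observed) - expected)), 0.15)
})

test_that("noise-free OTHER-only traces are piecewise constant", {
  tm <- matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3, byrow = TRUE)
  cfg <- synth_config(n_animals = 1, hours_per_animal = 0.05, seed = 9,
                      transition_matrix = tm,
                      dwell_means = c(RUMINATION = 1e6, EATING = 1e6,
                                      OTHER = 1e6),
                      state_amplitudes = c(RUMINATION = 0, EATING = 0,
                                           OTHER = 0.2),
                      gravity_drift_scale = 0, noise_sd = 0)
  # with astronomically long OTHER-favouring dwell the single bout is fixed;
  # regenerate until the bout is OTHER (start state is random)
  tr <- NULL
  for (s in 1:20) {
    cfg$seed <- s
    cand <- generate_herd(cfg)[[1]]
    if (all(cand$labels == "OTHER")) { tr <- cand; break }
  }
  expect_false(is.null(tr))
  d <- diff_trace(tr)
  # differences vanish except at sporadic spikes
  nonzero <- abs(d$accel) > 1e-12
  expect_lt(mean(nonzero), 0.02)
})

test_that("rumination segments carry the chewing frequency after differencing", {
  cfg <- synth_config(n_animals = 1, hours_per_animal = 0.2,
                      dwell_means = c(RUMINATION = 1e6, EATING = 1,
                                      OTHER = 1))
  tr <- NULL
  for (s in 1:20) {  # start state is random; find an all-rumination trace
    cfg$seed <- s
    cand <- generate_herd(cfg)[[1]]
    if (all(cand$labels == "RUMINATION")) { tr <- cand; break }
  }
  expect_false(is.null(tr))
  d <- diff_trace(tr)
  rum <- which(d$labels == "RUMINATION")
  seg <- d$accel[rum[1:4096], 1]
  spec <- Mod(fft(seg - mean(seg)))[1:2048]
  freq <- (seq_len(2048) - 1) * 10 / 4096
  peak <- freq[which.max(spec)]
  expect_lt(abs(peak - cfg$chew_freq_hz), 0.1)
})

test_that("train/test splits are disjoint at the animal level", {
  herd <- generate_herd(synth_config(n_animals = 6, hours_per_animal = 0.05,
                                     seed = 1))
  sp <- make_split_fixture(herd, 2, seed = 3)
  expect_length(sp$train, 4)
  expect_length(sp$test, 2)
  ids <- function(x) vapply(x, `[[`, "", "animal_id")
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)

  sp11 <- make_split_fixture(herd[1:2], 1, seed = 1)
  expect_length(sp11$train, 1)
  expect_length(sp11$test, 1)
  expect_error(make_split_fixture(herd[1:2], 2), "smaller than the herd")
})

test_that("degenerate configurations are rejected", {
  expect_error(synth_config(transition_matrix = diag(3)), "zero diagonal")
  expect_error(synth_config(dwell_means = c(RUMINATION = -1, EATING = 1,
                                            OTHER = 1)), "positive")
  expect_error(generate_herd(synth_config(n_animals = 0)),
               "at least one animal")
})
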