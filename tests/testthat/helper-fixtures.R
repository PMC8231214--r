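# Shared fixtures, built in code. Heavyweight objects are memoised in this
# environment so several test files can reuse them within one run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a small labelled trace with known content
toy_trace <- function(n = 30, animal = "toy", labelled = TRUE, t0 = 0) {
  set.seed(42)
  labelled_trace(
    animal, t0 + (seq_len(n) - 1) / 10,
    cbind(x = sin(seq_len(n)), y = cos(seq_len(n)), z = seq_len(n) / n),
    labels = if (labelled) rep(behaviour_levels(), length.out = n),
    sampling_rate = 10
  )
}

# small synthetic herd shared by preprocessing/training tests; 6 h per
# animal so that every animal exhibits all three behaviour classes
small_herd <- function() {
  fixture("small_herd", function() {
    generate_herd(synth_config(n_animals = 6, hours_per_animal = 6,
                               seed = 7))
  })
}

small_windows <- function() {
  fixture("small_windows", function() {
    windows_from_traces(small_herd(), 90)
  })
}

# window set with two trivially separable classes for optimiser tests:
# strong oscillation vs near-silence
easy_windows <- function(n_per_class = 40, L = 300, animals = c("a", "b")) {
  set.seed(11)
  n <- 2 * n_per_class
  dat <- array(0, dim = c(3, L, n))
  labs <- character(n)
  for (i in seq_len(n)) {
    cls <- if (i <= n_per_class) "EATING" else "OTHER"
    amp <- if (cls == "EATING") 1.0 else 0.02
    for (ax in 1:3) {
      dat[ax, , i] <- amp * sin(2 * pi * 1.2 * (1:L) / 10 + runif(1, 0, 6)) +
        rnorm(L, 0, 0.02)
    }
    labs[i] <- cls
  }
  window_set(dat, labs, rep(animals, length.out = n), seq_len(n), L / 10)
}

# two classes with identical per-sample marginals (same amplitude) that
# differ only in oscillation frequency: separable by a kernel wide enough
# to see the waveform, invisible to kernel-1 layers
freq_windows <- function(n_per_class = 24, L = 120, animals = c("a", "b")) {
  set.seed(21)
  n <- 2 * n_per_class
  dat <- array(0, dim = c(3, L, n))
  labs <- character(n)
  for (i in seq_len(n)) {
    cls <- if (i <= n_per_class) "EATING" else "OTHER"
    f <- if (cls == "EATING") 0.6 else 3.0
    for (ax in 1:3) {
      dat[ax, , i] <- sin(2 * pi * f * (1:L) / 10 + runif(1, 0, 6)) +
        rnorm(L, 0, 0.05)
    }
    labs[i] <- cls
  }
  window_set(dat, labs, rep(animals, length.out = n), seq_len(n), L / 10)
}

tiny_spec <- function(dropout_p = 0) {
  architecture_spec(
    data.frame(out_channels = c(6, 8), kernel = c(5, 1), stride = c(2, 1)),
    dropout_p = dropout_p
  )
}
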