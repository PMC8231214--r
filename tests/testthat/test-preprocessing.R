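test_that("differencing matches hand arithmetic and removes offsets", {
  tr <- labelled_trace("a", (0:2) / 10, cbind(c(1, 4, 2), c(0, 0, 0),
                                              c(5, 5, 5)),
                       labels = rep("OTHER", 3))
  d <- diff_trace(tr)
  expect_equal(length(d), 2)
  expect_equal(d$accel[, 1], c(3, -2))
  expect_equal(d$accel[, 2], c(0, 0))
  expect_equal(d$accel[, 3], c(0, 0))
  expect_equal(d$timestamps, tr$timestamps[-1])
  expect_equal(as.character(d$labels), c("OTHER", "OTHER"))

  # constant per-axis offsets cancel: diff(x + c) == diff(x) up to one ulp
  tr2 <- toy_trace(900)
  shifted <- labelled_trace(tr2$animal_id, tr2$timestamps,
                            sweep(tr2$accel, 2, c(3, -7, 0.5), "+"),
                            labels = as.character(tr2$labels))
  expect_equal(diff_trace(shifted)$accel, diff_trace(tr2)$accel,
               tolerance = 1e-12)
  expect_equal(length(diff_trace(tr2)), 899)

  expect_error(diff_trace(toy_trace(1)), "at least 2")
})

test_that("windowing cuts exact non-overlapping blocks and drops remainders", {
  herd1 <- generate_herd(synth_config(n_animals = 1, hours_per_animal = 0.5,
                                      seed = 8))[[1]]  # 30 min
  d <- diff_trace(herd1)
  ws <- segment_windows(d, 90)
  expect_equal(length(ws), 19)  # 17999 diffed samples -> 19 windows of 900
  expect_equal(dim(ws$data)[2], 900)

  # 95 s trace -> one 90 s window, 5 s dropped
  short <- labelled_trace("s", (0:949) / 10,
                          matrix(rnorm(950 * 3), ncol = 3),
                          labels = rep("EATING", 950))
  expect_equal(length(segment_windows(short, 90)), 1)

  # 60 s vs 90 s window counts are in 3:2 ratio (floor arithmetic)
  n60 <- length(segment_windows(d, 60))
  n90 <- length(segment_windows(d, 90))
  expect_equal(n60, (length(d) %/% 600))
  expect_equal(n90, (length(d) %/% 900))

  # the window payload is the trace slice, bit for bit
  expect_identical(ws$data[, , 2], unname(t(d$accel[901:1800, ])))
  expect_error(segment_windows(toy_trace(10, labelled = FALSE), 90),
               "labelled")
  expect_warning(segment_windows(diff_trace(toy_trace(30)), 90),
                 "shorter than one window")
})

test_that("majority vote counts labels and breaks ties by declaration order", {
  expect_equal(majority_label(rep("EATING", 900)), "EATING")
  expect_equal(majority_label(c(rep("EATING", 600), rep("RUMINATION", 300))),
               "EATING")
  # exact tie: RUMINATION precedes EATING in the declared order
  expect_equal(majority_label(c(rep("EATING", 450), rep("RUMINATION", 450))),
               "RUMINATION")
  expect_equal(majority_label(c(rep("OTHER", 5), rep("EATING", 5))),
               "EATING")
  expect_error(majority_label(character(0)), "empty")
})

test_that("balancing equalises every (animal, class) cell by undersampling", {
  ws <- small_windows()
  b <- balance_windows(ws, seed = 3)
  counts <- window_counts(b)
  expect_true(all(counts == counts[1, 1]))
  expect_equal(counts[1, 1], min(window_counts(ws)))
  expect_lte(length(b), length(ws))
  # deterministic given the seed
  b2 <- balance_windows(ws, seed = 3)
  expect_identical(b$start_time, b2$start_time)
  # already balanced input is returned with unchanged membership
  b3 <- balance_windows(b, seed = 99)
  expect_setequal(paste(b3$animal_id, b3$start_time),
                  paste(b$animal_id, b$start_time))

  # an animal missing a class is a hard error naming the animal
  drop <- !(ws$animal_id == ws$animal_id[1] & ws$labels == "RUMINATION")
  expect_error(balance_windows(ws[drop], seed = 1),
               paste0(ws$animal_id[1], ".*RUMINATION"))
})

test_that("fold plans partition animals with near-equal sizes", {
  ids <- sprintf("steer_%02d", 1:15)
  plan <- make_folds(ids, 5, seed = 2)
  expect_equal(plan$k, 5)
  expect_true(all(lengths(plan$folds) == 3))
  expect_setequal(unlist(plan$folds), ids)
  expect_equal(anyDuplicated(unlist(plan$folds)), 0)

  # singleton folds when |ids| == k
  plan5 <- make_folds(ids[1:5], 5, seed = 1)
  expect_true(all(lengths(plan5$folds) == 1))

  # sizes differ by at most one when k does not divide |ids|
  plan7 <- make_folds(ids[1:7], 3, seed = 1)
  expect_lte(diff(range(lengths(plan7$folds))), 1)

  expect_error(make_folds(ids[1:4], 5), "at least k")
})

test_that("fold partition properties hold across many random plans", {
  for (s in 1:25) {
    n <- sample(5:40, 1)
    ids <- sprintf("a%03d", seq_len(n))
    k <- sample(2:min(8, n), 1)
    plan <- make_folds(ids, k, seed = s)
    expect_setequal(unlist(plan$folds), ids)
    expect_equal(anyDuplicated(unlist(plan$folds)), 0)
    expect_lte(diff(range(lengths(plan$folds))), 1)
  }
})
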