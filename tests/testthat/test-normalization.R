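test_that("trimmed blank statistics match hand computation and handle edge cases", {
  # constant blanks: zero spread, threshold collapses onto the mean
  bs <- trimmed_blank_stats(rep(10, 20))
  expect_equal(bs$trimmed_mean, 10)
  expect_equal(bs$trimmed_sd, 0)
  expect_equal(bs$detection_threshold, 10)
  expect_equal(bs$n_blanks_used, 18)

  # blanks 1..20 at 5% trim: one spot per tail removed, stats on 2..19
  bs <- trimmed_blank_stats(1:20, trim_fraction = 0.05, sd_multiplier = 2)
  expect_equal(bs$n_blanks_used, 18)
  expect_equal(bs$trimmed_mean, 10.5)
  expect_equal(bs$trimmed_sd, sqrt(28.5))       # sample SD of 2..19
  expect_equal(bs$detection_threshold, 10.5 + 2 * sqrt(28.5))

  # below 20 blanks the floor rule removes nothing
  bs <- trimmed_blank_stats(1:19, trim_fraction = 0.05)
  expect_equal(bs$n_blanks_used, 19)
  expect_equal(bs$trimmed_mean, 10)

  expect_error(trimmed_blank_stats(c(1, 2), trim_fraction = 0),
               class = "mirscreen_insufficient_blanks_error")
  expect_error(trimmed_blank_stats(c(-1, 2, 3, 4)),
               class = "mirscreen_validation_error")
})

test_that("trimmed blank statistics agree with a brute-force oracle on random draws", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    blanks <- rlnorm(n, log(30), runif(1, 0.1, 0.8))
    spots <- data.frame(probe_id = c("m1", sprintf("b%03d", seq_len(n))),
                        spot_class = c("probe", rep("blank", n)),
                        intensity = c(1e5, blanks))
    scan <- array_scan("S", "FM", spots)
    bs <- trimmed_blank_stats(blanks)
    orc <- oracle_normalize(scan)
    expect_equal(bs$trimmed_mean, orc$mean)
    expect_equal(bs$trimmed_sd, orc$sd)
    expect_equal(bs$detection_threshold, orc$threshold)
  }
})

test_that("presence calling is strict at the threshold and monotone in intensity", {
  bs <- trimmed_blank_stats(rep(c(10, 12), 10))  # mean 11, threshold 11 + 2*sd
  thr <- bs$detection_threshold
  expect_false(call_presence(thr, bs))           # "more than": boundary absent
  expect_true(call_presence(thr + 1e-6, bs))
  expect_false(call_presence(0, bs))

  set.seed(11)
  x <- sort(runif(100, 0, 3 * thr))
  flags <- call_presence(x, bs)
  expect_true(all(diff(flags) >= 0))             # once present, stays present
})

test_that("background subtraction returns positive residuals and rejects absent spots", {
  blanks <- c(rep(10, 18), 2, 30)
  bs <- trimmed_blank_stats(blanks)              # mean 10, sd 0, threshold 10
  expect_equal(subtract_background(100, bs), 90)
  expect_error(subtract_background(10, bs), class = "mirscreen_contract_error")
  expect_error(subtract_background(5, bs), class = "mirscreen_contract_error")

  set.seed(12)
  bs2 <- trimmed_blank_stats(rlnorm(50, log(10), 0.3))
  x <- bs2$detection_threshold * runif(50, 1.0001, 10)
  expect_true(all(subtract_background(x, bs2) > 0))
})

test_that("global normalization scales the median onto the target exactly", {
  out <- global_normalize(c(a = 10, b = 20, c = 30), target_median = 25)
  expect_equal(out$values, c(a = 12.5, b = 25, c = 37.5))
  expect_equal(out$scale_factor, 1.25)

  expect_equal(unname(global_normalize(rep(7, 5))$values), rep(25, 5))

  set.seed(13)
  for (i in 1:25) {
    x <- rlnorm(sample(3:101, 1), runif(1, 1, 8), runif(1, 0.2, 2))
    scaled <- global_normalize(x)$values
    expect_equal(median(scaled), 25, tolerance = 1e-9)
  }

  expect_error(global_normalize(numeric(0)),
               class = "mirscreen_empty_profile_error")
  expect_error(global_normalize(c(-5, 0, 5)),
               class = "mirscreen_degenerate_profile_error")
})

test_that("normalize_scan matches the straight-line oracle on random small scans", {
  set.seed(14)
  for (i in 1:40) {
    scan <- make_scan(n_probe = sample(3:10, 1), n_blank = sample(20:30, 1))
    prof <- normalize_scan(scan)
    orc <- oracle_normalize(scan)
    expect_equal(prof$values, orc$values)
    expect_equal(prof$present, orc$present)
  }
})

test_that("normalize_scan is invariant under global intensity rescaling", {
  set.seed(15)
  scan <- make_scan(n_probe = 12, n_blank = 40)
  base <- normalize_scan(scan)
  for (c_scale in c(0.01, 0.37, 4, 1e3)) {
    scaled <- scan
    scaled$spots$intensity <- scan$spots$intensity * c_scale
    prof <- normalize_scan(scaled)
    expect_equal(prof$values, base$values, tolerance = 1e-12)
    expect_identical(prof$present, base$present)
  }
})

test_that("normalize_scan flags a fully sub-threshold array and honours absent_policy", {
  spots <- data.frame(probe_id = c("m1", "m2", sprintf("b%02d", 1:20)),
                      spot_class = c("probe", "probe", rep("blank", 20)),
                      intensity = c(5, 8, rep(10, 20)))
  expect_error(normalize_scan(array_scan("S", "FM", spots)),
               class = "mirscreen_empty_profile_error")

  spots$intensity[1] <- 100
  prof0 <- normalize_scan(array_scan("S", "FM", spots))
  expect_equal(unname(prof0$values), c(25, 0))   # absent probe stored as zero
  profNA <- normalize_scan(array_scan("S", "FM", spots),
                           normalization_config(absent_policy = "set_missing"))
  expect_true(is.na(profNA$values[["m2"]]))
  # absent probes never enter the median
  expect_equal(median(profNA$values[profNA$present]), 25)
})

test_that("the group-mean filter uses a strict OR rule and is idempotent", {
  em <- make_matrix(control = rbind(6, 5.0, 0, 12), fm = rbind(0, 5.0, 0, 80),
                    mirna_ids = c("c_only", "boundary", "zero", "both"))
  kept <- heatmap_filter(em, min_group_mean = 5)
  expect_setequal(rownames(kept$values), c("c_only", "both"))
  # boundary case: exactly 5 in both groups is dropped (strictly "more than")
  expect_false("boundary" %in% rownames(kept$values))

  twice <- heatmap_filter(kept, min_group_mean = 5)
  expect_identical(twice$values, kept$values)
  expect_true(all(rownames(kept$values) %in% rownames(em$values)))

  solo <- expression_matrix(matrix(1, 1, 1, dimnames = list("m", "FM1")),
                            c(FM1 = "FM"))
  expect_error(heatmap_filter(solo), class = "mirscreen_validation_error")
})
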