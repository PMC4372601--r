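test_that("Spearman rho handles perfect, reversed, and tied rankings", {
  x <- c(2, 5, 9, 11, 20)
  expect_equal(spearman_rho(x, x^3)$rho, 1)
  expect_equal(spearman_rho(x, rev(x))$rho, -1)
  expect_error(spearman_rho(x, rep(3, 5)),
               class = "mirscreen_constant_input_error")
  expect_error(spearman_rho(1:2, 2:1), class = "mirscreen_validation_error")

  # tied observations: rho from explicit midrank formula
  xt <- c(1, 2, 2, 3, 4); yt <- c(5, 3, 4, 4, 1)
  orc <- oracle_spearman(xt, yt)
  res <- spearman_rho(xt, yt)
  expect_equal(res$rho, orc$rho)
  expect_equal(res$p_value, orc$p_value)
})

test_that("Spearman rho matches brute-force permutation and base-R oracles", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(4:6, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- spearman_rho(x, y)
    orc <- oracle_spearman(x, y)
    expect_equal(mine$rho, orc$rho)
    expect_equal(mine$p_value, orc$p_value)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(mine$rho, unname(ref$estimate))
    expect_equal(mine$p_value, ref$p.value)
  }
  # invariance under strictly monotone transforms of either variable
  for (i in 1:10) {
    x <- rlnorm(7); y <- rlnorm(7)
    base <- spearman_rho(x, y)
    expect_equal(spearman_rho(log(x), y), base)
    expect_equal(spearman_rho(x, y^3), base)
  }
})

test_that("exact and t-approximate Spearman p-values stay within a sanity envelope", {
  # Exhaustive over every distinct ranking. The 0.05 envelope is a property
  # of n = 6 and 7; at n <= 5 the t approximation deviates by up to 0.15, so
  # the exact permutation path is the one that matters there.
  for (n in 6:7) {
    perms <- mirscreen:::permutation_matrix(n)
    x <- seq_len(n)
    worst <- 0
    for (j in seq_len(nrow(perms))) {
      exact <- spearman_rho(x, perms[j, ], exact_n_max = 9)$p_value
      approx <- spearman_rho(x, perms[j, ], exact_n_max = 0)$p_value
      worst <- max(worst, abs(exact - approx))
    }
    expect_lt(worst, 0.05)
  }
})

test_that("clinical correlation is shaped per miRNA x score with pairwise deletion", {
  set.seed(43)
  n <- 11
  scores <- data.frame(sample_id = sprintf("FM%02d", 1:n),
                       FIQ = runif(n, 45, 95), GF = sample(15:20, n, TRUE),
                       PF = sample(15:19, n, TRUE), MF = sample(8:19, n, TRUE),
                       RA = sample(5:20, n, TRUE), RM = sample(5:20, n, TRUE))
  expr <- data.frame(sample_id = scores$sample_id,
                     "mir-a" = rlnorm(n), "mir-b" = rlnorm(n),
                     check.names = FALSE)
  res <- correlate_clinical(expr, scores)
  expect_equal(nrow(res), 2 * 6)
  expect_true(all(res$n == n))
  expect_true(all(abs(res$rho) <= 1))

  # a missing measurement shrinks that miRNA's n only (pairwise-complete)
  expr2 <- expr; expr2[["mir-a"]][c(2, 5)] <- NA
  res2 <- correlate_clinical(expr2, scores)
  expect_true(all(res2$n[res2$mirna_id == "mir-a"] == n - 2))
  expect_true(all(res2$n[res2$mirna_id == "mir-b"] == n))

  # fewer than three complete pairs: flagged, not an error
  expr3 <- expr; expr3[["mir-a"]][1:9] <- NA
  res3 <- correlate_clinical(expr3, scores)
  expect_true(all(!res3$computable[res3$mirna_id == "mir-a"]))
  expect_true(all(is.na(res3$rho[res3$mirna_id == "mir-a"])))
})

test_that("clinical correlation recovers an implanted monotone association", {
  set.seed(44)
  scores <- data.frame(sample_id = sprintf("FM%02d", 1:11),
                       MF = c(8, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19))
  expr <- data.frame(sample_id = scores$sample_id,
                     "mir-mono" = exp(-scores$MF / 3) * (1 + rnorm(11, 0, 1e-3)),
                     check.names = FALSE)
  res <- correlate_clinical(expr, scores, score_names = "MF")
  expect_lt(res$rho, -0.95)
  expect_lt(res$p_value, 0.05)
})

test_that("small-RNA fraction comparison summarizes groups and tests exchangeability", {
  sheet <- data.frame(sample_id = c(sprintf("FM%d", 1:4), sprintf("C%d", 1:4)),
                      group = rep(c("FM", "control"), each = 4))
  same <- data.frame(sample_id = sheet$sample_id,
                     small_rna_fraction = rep(c(0.12, 0.14, 0.16, 0.18), 2))
  res <- compare_small_rna_fractions(same, sheet)
  expect_equal(res$summary$mean[1], res$summary$mean[2])
  expect_gt(res$p_value, 0.9)

  bad <- same; bad$small_rna_fraction[1] <- 1.2
  expect_error(compare_small_rna_fractions(bad, sheet),
               class = "mirscreen_validation_error")

  # sampling at the published group levels reproduces them within 3 SE
  set.seed(45)
  cohort <- simulate_cohort(simulation_config(n_mirna = 20, n_blank = 20,
                                              broad_down_fraction = 0))
  frac <- cohort$sample_sheet[, c("sample_id", "small_rna_fraction")]
  res2 <- compare_small_rna_fractions(frac, cohort$sample_sheet)
  ctrl <- res2$summary[res2$summary$group == "control", ]
  fm <- res2$summary[res2$summary$group == "FM", ]
  expect_lt(abs(ctrl$mean - 0.140), 3 * 0.034 / sqrt(ctrl$n))
  expect_lt(abs(fm$mean - 0.161), 3 * 0.102 / sqrt(fm$n))
})

test_that("the extreme mental-fatigue patient is flagged with its signature ranks", {
  sig <- c("mir-s1", "mir-s2", "mir-s3", "mir-s4", "mir-s5")
  # cases strongly downregulated except FM03, which sits at control-like levels
  control <- matrix(rep(c(100, 120, 140), each = 5), 5, 3)
  fm <- matrix(rep(c(10, 12, 11, 9), each = 5), 5, 4)
  fm[1:4, 3] <- c(130, 130, 95, 95)   # 2 above control minimum, 2 within 2-fold
  em <- make_matrix(control, fm, mirna_ids = sig)
  scores <- data.frame(sample_id = paste0("FM", 1:4), MF = c(15, 14, 8, 16))
  rep <- flag_outlier_patient(em, scores, sig)
  expect_identical(rep$sample_id, "FM3")
  expect_equal(rep$mf_score, 8)
  expect_equal(rep$n_highest_in_fm, 4)
  expect_equal(rep$n_exceed, 2)
  per <- rep$per_mirna
  expect_equal(per$fold_to_control_min[per$mirna_id == "mir-s3"], 100 / 95)

  # identical cases below control range: one flagged sample, zero exceedances
  fm_flat <- matrix(10, 5, 4)
  em2 <- make_matrix(control, fm_flat, mirna_ids = sig)
  expect_message(rep2 <- flag_outlier_patient(em2, scores2 <- data.frame(
    sample_id = paste0("FM", 1:4), MF = c(12, 12, 14, 15)), sig), "tied")
  expect_identical(rep2$sample_id, "FM1")
  expect_equal(rep2$n_exceed, 0)
})
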