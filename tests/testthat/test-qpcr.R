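test_that("relative expression follows the 2^-dCt rule", {
  expect_equal(relative_expression(24, 24), 1.0)
  expect_equal(relative_expression(25, 24), 0.5)
  expect_equal(relative_expression(30, 24), 2^-6)
  expect_equal(relative_expression(c(20, 22), c(21, 21)), c(2, 0.5))
  expect_error(relative_expression(46, 20), class = "mirscreen_validation_error")
  expect_error(relative_expression(0, 20), class = "mirscreen_validation_error")

  # strictly decreasing in ct, strictly increasing in the reference ct
  ct <- seq(15, 35, by = 0.5)
  expect_true(all(diff(relative_expression(ct, 20)) < 0))
  expect_true(all(diff(relative_expression(25, ct)) > 0))

  # efficiency knob: 90% efficiency shrinks the per-cycle fold
  expect_equal(relative_expression(25, 24, efficiency = 1.9), 1 / 1.9)
})

test_that("Mann-Whitney U matches exact enumeration on separated samples", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 0.1)    # 2 of the 20 labelings are as extreme
  expect_identical(res$method, "exact")

  same <- mann_whitney_u(c(3, 1, 2), c(2, 1, 3))
  expect_equal(same$p_value, 1)

  flat <- mann_whitney_u(rep(2, 5), rep(2, 4))
  expect_equal(flat$p_value, 1)

  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "mirscreen_validation_error")
})

test_that("Mann-Whitney U agrees with brute-force and base-R oracles", {
  set.seed(31)
  for (i in 1:40) {
    a <- rnorm(sample(2:5, 1)); b <- rnorm(sample(2:5, 1))
    mine <- mann_whitney_u(a, b)
    orc <- oracle_mwu(a, b)
    expect_equal(mine$u, orc$u)
    expect_equal(mine$p_value, orc$p_value)
  }
  # tie-corrected, continuity-corrected normal approximation
  for (i in 1:40) {
    a <- sample(1:8, sample(8:14, 1), replace = TRUE)
    b <- sample(1:8, sample(8:14, 1), replace = TRUE)
    mine <- mann_whitney_u(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(mine$u, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U is invariant under common monotone transforms", {
  set.seed(32)
  for (i in 1:20) {
    a <- rlnorm(6); b <- rlnorm(7)
    base <- mann_whitney_u(a, b)
    for (f in list(log, sqrt, function(x) 3 * x + 1)) {
      tr <- mann_whitney_u(f(a), f(b))
      expect_equal(tr$u, base$u)
      expect_equal(tr$p_value, base$p_value)
    }
  }
})

test_that("qPCR validation detects an implanted strong downregulation", {
  set.seed(33)
  sheet <- data.frame(sample_id = c(sprintf("FM%02d", 1:11), sprintf("C%02d", 1:10)),
                      group = rep(c("FM", "control"), c(11, 10)))
  ct_ref <- rnorm(21, 20, 0.3)
  # 10-fold down in cases (log2(10) extra cycles), low noise; plus a null miRNA
  qpcr <- rbind(
    data.frame(sample_id = sheet$sample_id, mirna_id = "mir-down",
               ct = ct_ref + 6 + c(rep(log2(10), 11), rep(0, 10)) + rnorm(21, 0, 0.3),
               ct_reference = ct_ref),
    data.frame(sample_id = sheet$sample_id, mirna_id = "mir-null",
               ct = ct_ref + 6 + rnorm(21, 0, 0.3),
               ct_reference = ct_ref))
  res <- validate_mirnas(qpcr, sheet)
  down <- res[res$mirna_id == "mir-down", ]
  expect_true(down$significant)
  expect_identical(down$direction, "down_in_FM")
  expect_equal(down$n_fm, 11)
  expect_false(res$significant[res$mirna_id == "mir-null"])
})

test_that("qPCR validation averages technical replicates and skips unmatched miRNAs", {
  sheet <- data.frame(sample_id = c("FM1", "FM2", "C1", "C2"),
                      group = c("FM", "FM", "control", "control"))
  # duplicate rows per (sample, miRNA) are technical replicates on the Ct scale
  qpcr <- data.frame(
    sample_id = rep(c("FM1", "FM2", "C1", "C2"), each = 2),
    mirna_id = "mir-x",
    ct = c(25, 27, 26, 26, 22, 24, 23, 23),
    ct_reference = 20)
  singles <- data.frame(sample_id = c("FM1", "FM2", "C1", "C2"),
                        mirna_id = "mir-x", ct = c(26, 26, 23, 23),
                        ct_reference = 20)
  expect_equal(validate_mirnas(qpcr, sheet, min_per_group = 2),
               validate_mirnas(singles, sheet, min_per_group = 2))

  # a miRNA measured in one group only is skipped with a warning
  lone <- rbind(singles,
                data.frame(sample_id = c("FM1", "FM2"), mirna_id = "mir-lone",
                           ct = c(30, 31), ct_reference = 20))
  expect_warning(res <- validate_mirnas(lone, sheet), "mir-lone")
  expect_false("mir-lone" %in% res$mirna_id)
})

test_that("the validation test holds its nominal type-I error under the null", {
  set.seed(34)
  n_rep <- 400
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    fm <- rnorm(11); ctrl <- rnorm(10)
    if (mann_whitney_u(fm, ctrl)$p_value < 0.05) rejections <- rejections + 1L
  }
  # nominal 0.05 within Monte-Carlo slack for 400 replicates
  expect_gt(rejections / n_rep, 0.02)
  expect_lt(rejections / n_rep, 0.08)
})
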