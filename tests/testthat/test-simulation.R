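test_that("the packaged design matches its documented structure", {
  tab <- sim_design_params()
  expect_identical(nrow(tab), 25L)
  expect_identical(tab$a, rep(c(1.3, 1.4, 1.5, 1.7, 1.6), 5))
  # DIF-item counts by proportion regime
  expect_identical(sum(tab$gamma_small_high != 0), 14L)
  expect_identical(sum(tab$gamma_small_medium != 0), 10L)
  expect_identical(sum(tab$gamma_small_low != 0), 5L)
  # large effects are exactly double the small ones
  expect_identical(tab$gamma_large_high, 2 * tab$gamma_small_high)
  # every design cell satisfies the minimal-L1 condition
  for (col in grep("^gamma_", names(tab), value = TRUE)) {
    expect_true(check_prop1(tab[[col]], tab$a)$holds, label = col)
    expect_identical(ml1_shift(tab[[col]], tab$a), 0)
  }
})

test_that("response generation is reproducible and respects group structure", {
  p <- sim_params("large", "large", "medium")
  d1 <- sim_responses(p, 501, seed = 5)
  d2 <- sim_responses(p, 501, seed = 5)
  expect_identical(d1, d2)
  expect_false(identical(d1, sim_responses(p, 501, seed = 6)))
  # odd N: focal group gets the extra respondent
  expect_identical(sum(d1$group == 1), 251L)
  expect_identical(sum(d1$group == 0), 250L)
  expect_true(all(as.matrix(d1[, -1]) %in% 0:1))
})

test_that("generated item proportions match the quadrature-implied marginals", {
  # no DIF and matched group distributions: pooled proportions have a
  # closed quadrature oracle
  p <- mimic_params(beta = 0, sigma2 = 1, a = c(1.3, 1.5, 1.7),
                    d = c(0.8, -0.4, -1.0), gamma = rep(0, 3))
  n <- 4000
  dat <- sim_responses(p, n, seed = 8)
  q <- gh_quadrature(61)
  for (j in 1:3) {
    marg <- sum(exp(q$logw) * plogis(p$a[j] * sqrt(2) * q$t + p$d[j]))
    obs <- mean(dat[[paste0("y", j)]])
    expect_lt(abs(obs - marg), 3 * sqrt(marg * (1 - marg) / n))
  }
  # DIF sign shows in the focal-minus-reference proportion gap
  p2 <- mimic_params(0, 1, rep(1.4, 3), rep(0, 3), c(1.2, 0, -1.2))
  d2 <- sim_responses(p2, 3000, seed = 9)
  gap <- colMeans(d2[d2$group == 1, -1]) - colMeans(d2[d2$group == 0, -1])
  expect_gt(gap[1], 0)
  expect_lt(gap[3], 0)
})

test_that("replicated mean-squared errors reduce to the arithmetic definition", {
  truth <- small_design(4, dif = c(0, 0.5, 0, -0.5))
  expect_equal(compute_mse(list(truth, truth), truth)$mse, rep(0, 5))
  e1 <- mimic_params(0.6, 0.36, truth$a + 0.1, truth$d, truth$gamma)
  e2 <- mimic_params(0.4, 0.16, truth$a - 0.3, truth$d, truth$gamma + 0.2)
  got <- compute_mse(list(e1, e2), truth)
  expect_equal(got$mse[got$block == "a"], (0.1^2 + 0.3^2) / 2)
  expect_equal(got$mse[got$block == "gamma"], (0 + 0.2^2) / 2)
  expect_equal(got$mse[got$block == "beta"], (0.1^2 + 0.1^2) / 2)
  expect_equal(got$mse[got$block == "sigma"], (0.1^2 + 0.1^2) / 2)
  expect_error(compute_mse(list(e1), truth), "at least 2")
})

test_that("false discovery proportions follow the 0/0 convention", {
  truth <- c(TRUE, TRUE, FALSE, FALSE)    # items 1-2 truly DIF
  det_all_correct <- rbind(c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(compute_fdr(det_all_correct, truth), 0)
  expect_equal(compute_fdr(matrix(FALSE, 3, 4), truth), 0)
  det <- rbind(c(TRUE, TRUE, TRUE, TRUE))  # 2 true, 2 false of 4
  expect_equal(compute_fdr(det, truth), 0.5)
  two_reps <- rbind(c(TRUE, FALSE, TRUE, FALSE),   # 1 false of 2
                    c(TRUE, TRUE, FALSE, FALSE))   # 0 false of 2
  expect_equal(compute_fdr(two_reps, truth), 0.25)
})

test_that("coverage counts interval hits per item", {
  truth <- c(0, 0.5)
  iv <- tibble::tibble(
    rep = c(1, 1, 2, 2),
    item_index = c(1, 2, 1, 2),
    ci_lo = c(-1, 0.4, 0.1, -2),
    ci_hi = c(1, 0.6, 0.2, 2))
  cov <- compute_coverage(iv, truth)
  expect_equal(cov$coverage, c(0.5, 1))
  # whole-line intervals always cover; empty-width misses never do
  iv2 <- tibble::tibble(rep = 1, item_index = 1:2,
                        ci_lo = c(-Inf, 0.2), ci_hi = c(Inf, 0.2))
  expect_equal(compute_coverage(iv2, truth)$coverage, c(1, 0))
})

test_that("averaged ROC behaves at its extremes and matches pROC on one replication", {
  is_dif <- c(rep(FALSE, 5), rep(TRUE, 5))
  perfect <- matrix(rep(c(rep(0.9, 5), rep(0.001, 5)), 3), 3, byrow = TRUE)
  expect_equal(compute_roc_auc(perfect, is_dif)$auc, 1, tolerance = 1e-6)
  set.seed(14)
  rand <- matrix(runif(200 * 10), 200, 10)
  expect_lt(abs(compute_roc_auc(rand, is_dif)$auc - 0.5), 0.06)
  # single-replication AUC agrees with pROC's trapezoid AUC
  set.seed(15)
  scores <- runif(10)^(1 + as.numeric(is_dif))
  ours <- compute_roc_auc(matrix(scores, 1), is_dif, n_grid = 4096)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = is_dif,
                                        predictor = scores, quiet = TRUE,
                                        direction = ">")))
  expect_equal(ours, ref, tolerance = 0.02)
  expect_error(compute_roc_auc(matrix(0.5, 1, 3), c(TRUE, TRUE, TRUE)),
               "both DIF and non-DIF")
})

test_that("a small replication study wires all metrics together", {
  st <- sim_setting(300, "small", "large", "low")
  study <- run_study(st, n_reps = 2, methods = c("proposed", "lrt-2",
                                                 "wald-2"),
                     M = 500, master_seed = 3, nodes = 21)
  expect_s3_class(study, "dif_study")
  expect_identical(sort(unique(study$fdr$method)), c("lrt-2", "proposed"))
  expect_identical(nrow(study$mse), 5L)
  expect_true(all(study$mse$mse >= 0))
  expect_true(all(study$fdr$fdr >= 0 & study$fdr$fdr <= 1))
  expect_true(all(study$coverage$coverage >= 0 &
                  study$coverage$coverage <= 1))
  expect_true(all(study$auc$auc >= 0 & study$auc$auc <= 1))
  # wald rows carry intervals for non-anchor items only
  expect_identical(
    sort(unique(study$inference$item_index[study$inference$method ==
                                             "wald-2"])), 3:25)
  # lrt p-values exist for non-anchor items only
  expect_identical(
    sort(unique(study$inference$item_index[study$inference$method ==
                                             "lrt-2"])), 3:25)
})
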