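test_that("pooled likelihoods match hand arithmetic and scale with 1/q", {
  # single length class: raised (CD + CC) = 3, raised PC = 1, r = 0.75
  ds <- toy_dataset(length_cm = 20, n_CD = 2, n_CC = 1, n_PC = 1)
  p <- clogit_params(1, class_mark(20), 2 * log(3) / log(9))  # r(20.5) shaped below
  # pick params so r at the midpoint is exactly 0.75: logit = 0.75 at
  # L50 + SR/2; choose L50 = 20.5 - SR/2
  sr <- 4
  p <- clogit_params(1, class_mark(20) - sr / 2, sr)
  expect_equal(clogit_retention(class_mark(20), p), 0.75)
  expect_equal(nll_smp(ds, p), -(3 * log(0.75) + 1 * log(0.25)))

  # q = 0.5 everywhere doubles every term
  ds_q <- toy_dataset(length_cm = 20, n_CD = 2, n_CC = 1, n_PC = 1,
                      q_CD = 0.5, q_CC = 0.5, q_PC = 0.5)
  expect_equal(nll_smp(ds_q, p), 2 * nll_smp(ds, p))

  # codend: one class, nCD = nCC, minimum at r = 0.5 with value -2n ln(1/2)
  ds_cd <- toy_dataset(length_cm = 25, n_CD = 7, n_CC = 7)
  p_half <- logit_params(class_mark(25), 5)  # r(L50) = 0.5
  expect_equal(nll_codend(ds_cd, p_half), -14 * log(0.5))
  # any other retention is worse
  expect_gt(nll_codend(ds_cd, logit_params(20, 5)), -14 * log(0.5))
})

test_that("likelihoods agree with an independent row-by-row summation", {
  for (seed in c(3, 17, 91)) {
    ds <- random_dataset(seed, m = 3, q = c(1, 0.5, 0.25))
    sp <- clogit_params(0.7, 24, 5)
    cp <- logit_params(23, 4)
    expect_equal(nll_smp(ds, sp), oracle_nll(ds, sp, "smp"))
    expect_equal(nll_codend(ds, cp), oracle_nll(ds, cp, "codend"))
  }
})

test_that("retention 1 with observed escapees gives +Inf, not an error", {
  ds <- toy_dataset(length_cm = 20, n_CD = 5, n_CC = 3, n_PC = 2)
  # C = 0 forces r_SMP = 1 while PC fish exist
  expect_identical(nll_smp(ds, clogit_params(0, 30, 5)), Inf)
  # codend: L50 far below the data pushes r -> 1 with CC fish present
  expect_identical(nll_codend(ds, logit_params(0.1, 0.1)), Inf)
})

test_that("noise-free expected-count data recover the generating parameters", {
  lens <- 15:45
  r <- logit_retention(class_mark(lens), logit_params(30, 5))
  total <- 4000
  ds <- selectivity_dataset(tibble::tibble(
    haul_id = 1, length_cm = lens, n_CD = total * r, n_CC = total * (1 - r),
    q_CD = 1, q_CC = 1))
  fit <- fit_codend(ds)
  expect_equal(fit$params$L50, 30, tolerance = 1e-3)
  expect_equal(fit$params$SR, 5, tolerance = 1e-3)
  expect_true(fit$converged)
  # a perfect fit has deviance ~0 and p ~1
  expect_lt(fit$deviance, 1e-6)
  expect_equal(fit$p_value, 1, tolerance = 1e-6)

  # same for the clogit model with partial contact
  r_smp <- clogit_retention(class_mark(lens), clogit_params(0.4, 30, 6))
  ds_smp <- selectivity_dataset(tibble::tibble(
    haul_id = 1, length_cm = lens, n_CD = total * r_smp / 2,
    n_CC = total * r_smp / 2, n_PC = total * (1 - r_smp),
    q_CD = 1, q_CC = 1, q_PC = 1))
  fit_s <- fit_smp(ds_smp)
  expect_equal(fit_s$params$C, 0.4, tolerance = 1e-3)
  expect_equal(fit_s$params$L50, 30, tolerance = 1e-2)
  expect_equal(fit_s$params$SR, 6, tolerance = 1e-2)
})

test_that("degenerate one-sided data hit the boundary and are flagged", {
  # every fish retained in the codend at every length
  ds <- toy_dataset(length_cm = 20:24, n_CD = rep(10, 5), n_CC = rep(0, 5))
  fit <- fit_codend(ds)
  expect_true(fit$boundary)
  expect_true(all(logit_retention(class_mark(20:24), fit$params) > 0.99))
  # empty data errors
  expect_error(fit_codend(toy_dataset(n_CD = rep(0, 5), n_CC = rep(0, 5))),
               class = "trawlselect_fit_error")
})

test_that("diagnostics: perfect cells give zero deviance; dof counts cells minus params", {
  ds <- random_dataset(11, m = 2)
  fit <- fit_codend(ds)
  ncells <- sum(ds$data$n_CD + ds$data$n_CC > 0)
  expect_equal(fit$dof, ncells - 2L)
  d0 <- model_diagnostics(ds, fit$params)
  expect_gte(d0$deviance, 0)
  expect_equal(d0$p_value, pchisq(d0$deviance, d0$dof, lower.tail = FALSE))
  # pooled-length-class cell convention is available
  dl <- model_diagnostics(ds, fit$params, cells = "length")
  expect_lte(dl$dof, d0$dof)
  # dof <= 0 warns and reports NA
  tiny <- toy_dataset(length_cm = 20:21, n_CD = c(3, 5), n_CC = c(5, 2))
  expect_warning(d_tiny <- model_diagnostics(tiny, logit_params(20, 3)),
                 "degrees of freedom")
  expect_true(is.na(d_tiny$p_value))
})

test_that("deviance residuals are signed and their squares sum to the deviance", {
  ds <- random_dataset(23, m = 3)
  fit <- fit_smp(ds)
  res <- deviance_residuals(ds, fit$params)
  expect_equal(sum(res$residual^2), model_diagnostics(ds, fit$params)$deviance)
  expect_equal(sign(res$residual), sign(res$observed - res$expected))
  # a cell with observed == expected has residual 0
  lens <- 20:30
  r <- logit_retention(class_mark(lens), logit_params(25, 4))
  exact <- selectivity_dataset(tibble::tibble(
    haul_id = 1, length_cm = lens, n_CD = 100 * r, n_CC = 100 * (1 - r),
    q_CD = 1, q_CC = 1))
  res0 <- deviance_residuals(exact, logit_params(25, 4))
  expect_true(all(abs(res0$residual) < 1e-6))
})

test_that("optimum nll matches a grid-search oracle on tiny datasets", {
  # quick version (3 datasets, coarser grid); the acceptance suite runs the
  # full 20-dataset sweep at 0.01 resolution
  for (seed in 1:3) {
    ds <- random_dataset(seed, m = 2, lengths = 24:26, lambda = 8)
    fit <- fit_smp(ds)
    gmin <- grid_min_nll_smp(ds, c_step = 0.02, l_step = 0.02, sr_step = 0.02)
    expect_lte(fit$nll, gmin + 1e-6)
  }
})
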