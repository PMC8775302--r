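test_that("entering population sums raised counts over compartments and hauls", {
  ds <- toy_dataset(length_cm = 30, n_CD = 3, n_CC = 2, n_PC = 1)
  pop <- estimate_entering_population(ds)
  expect_equal(pop$n, 6)
  # q = 0.5 in CC doubles the CC contribution
  ds_q <- toy_dataset(length_cm = 30, n_CD = 3, n_CC = 2, n_PC = 1, q_CC = 0.5)
  expect_equal(estimate_entering_population(ds_q)$n, 3 + 4 + 1)
  # multi-haul fixture vs brute-force sum
  ds_m <- random_dataset(55, m = 4, q = c(1, 0.5, 0.25))
  pop_m <- estimate_entering_population(ds_m)
  d <- ds_m$data
  for (l in unique(d$length_cm)) {
    rows <- d[d$length_cm == l, ]
    expect_equal(pop_m$n[pop_m$length_cm == l],
                 sum(rows$n_CD / rows$q_CD + rows$n_CC / rows$q_CC +
                       rows$n_PC / rows$q_PC))
  }
  # no PC compartment -> no full accounting
  expect_error(estimate_entering_population(toy_dataset()), "PC")
})

test_that("retained population scales the entering population by the curve", {
  pop <- population_structure(20:29, rep(10, 10))
  # flat r = 1 (no panel contact, codend saturated far below the lengths)
  all_in <- combined_params(logit_params(0.1, 0.1), clogit_params(0, 30, 5))
  rp <- retained_population(pop, all_in)
  expect_equal(rp$n_retained, pop$n, tolerance = 1e-12)
  # flat r = 0.5: panel flat at 0.5 via C = 0.5 and L50 far above data
  half <- combined_params(logit_params(0.1, 0.1), clogit_params(0.5, 1000, 5))
  expect_equal(retained_population(pop, half)$n_retained, pop$n / 2,
               tolerance = 1e-9)
  # hand check against the published hake SMP_BL + CD_S point estimates
  cp <- combined_params(hake_cd_s(), hake_smp_bl())
  rp <- retained_population(pop, cp)
  expect_equal(rp$n_retained,
               pop$n * combined_retention(class_mark(pop$length_cm), cp))
})

test_that("indicators obey their defining identities on random fixtures", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      pop <- population_structure(15:40, runif(26, 0, 100) + 1)
      cp <- combined_params(logit_params(runif(1, 15, 35), runif(1, 1, 8)),
                            clogit_params(runif(1), runif(1, 15, 35), runif(1, 1, 8)))
      ind <- exploitation_indicators(pop, cp, mcrs = 27)
      r <- combined_retention(class_mark(pop$length_cm), cp)
      below <- pop$length_cm < 27
      R_minus <- sum(r[below] * pop$n[below])
      R_plus <- sum(r[!below] * pop$n[!below])
      expect_equal(ind$nDiscard, 100 * R_minus / (R_minus + R_plus),
                   tolerance = 1e-9)
      # scale invariance
      pop2 <- population_structure(pop$length_cm, pop$n * 137)
      ind2 <- exploitation_indicators(pop2, cp, mcrs = 27)
      expect_equal(ind2$nP_minus, ind$nP_minus, tolerance = 1e-9)
      expect_equal(ind2$nP_plus, ind$nP_plus, tolerance = 1e-9)
      expect_equal(ind2$nDiscard, ind$nDiscard, tolerance = 1e-9)
    }
  })
})

test_that("full and knife-edge retention give the textbook indicator values", {
  pop <- population_structure(c(20, 25, 30, 35), c(20, 20, 30, 30))
  all_in <- combined_params(logit_params(0.1, 0.1), clogit_params(0, 30, 5))
  ind <- exploitation_indicators(pop, all_in, mcrs = 27)
  expect_equal(ind$nP_minus, 100, tolerance = 1e-9)
  expect_equal(ind$nP_plus, 100, tolerance = 1e-9)
  expect_equal(ind$nDiscard, 40, tolerance = 1e-9)  # 40 of 100 fish below MCRS
  # knife edge at MCRS: nothing below retained
  knife <- combined_params(logit_params(26.9, 0.1))
  ind_k <- exploitation_indicators(pop, knife, mcrs = 27)
  expect_equal(ind_k$nP_minus, 0, tolerance = 1e-6)
  expect_equal(ind_k$nP_plus, 100, tolerance = 1e-4)
  expect_equal(ind_k$nDiscard, 0, tolerance = 1e-6)
})

test_that("boundary class counts as at-or-above MCRS (nearest-cm-below labels)", {
  # a fish labelled 27 lies in [27, 28): at or above an MCRS of 27
  pop <- population_structure(c(26, 27), c(10, 10))
  all_in <- combined_params(logit_params(0.1, 0.1), clogit_params(0, 30, 5))
  ind <- exploitation_indicators(pop, all_in, mcrs = 27)
  expect_equal(ind$nDiscard, 50, tolerance = 1e-9)
  # monotonicity: raising retention weakly raises nP- and nP+
  lo <- combined_params(logit_params(30, 5))
  hi <- combined_params(logit_params(25, 5))  # higher retention everywhere
  ind_lo <- exploitation_indicators(pop, lo, 27)
  ind_hi <- exploitation_indicators(pop, hi, 27)
  expect_gte(ind_hi$nP_minus, ind_lo$nP_minus)
  expect_gte(ind_hi$nP_plus, ind_lo$nP_plus)
})

test_that("indicator CIs equal Efron percentiles of independently recomputed per-rep values", {
  truth <- default_truth()
  ds <- simulate_dataset(simulation_config(m = 5, total = 300, seed = 13), truth)
  B <- 50
  e_smp <- double_bootstrap(ds, "smp", B = B, seed = 41)
  e_cd <- double_bootstrap(ds, "codend", B = B, seed = 42)
  comb <- combine_ensembles(e_cd, e_smp)
  pop_ens <- bootstrap_population(ds, B = B, seed = 43)
  ind <- indicator_cis(pop_ens, comb, mcrs = 27)
  # independent recomputation of the per-rep discard ratio
  per_rep <- vapply(seq_len(B), function(i) {
    p <- pop_ens$reps[[i]]
    r <- combined_retention(class_mark(p$length_cm), comb$reps[[i]])
    below <- p$length_cm < 27
    100 * sum(r[below] * p$n[below]) / sum(r * p$n)
  }, numeric(1))
  exp_ci <- unname(quantile(per_rep, c(0.025, 0.975), type = 7))
  got <- ind$cis[ind$cis$indicator == "nDiscard", ]
  expect_equal(c(got$lo, got$hi), exp_ci, tolerance = 1e-12)
  # degenerate single-rep ensembles collapse onto point values
  one_curve <- comb
  one_curve$reps <- comb$reps[1]
  one_curve$B <- 1L
  ind1 <- indicator_cis(pop_ens$reps[[1]], one_curve, mcrs = 27)
  r1 <- combined_retention(class_mark(pop_ens$reps[[1]]$length_cm), comb$reps[[1]])
  expect_equal(ind1$cis$lo[ind1$cis$indicator == "nP_minus"],
               ind1$cis$hi[ind1$cis$indicator == "nP_minus"])
  # mismatched B rejected
  expect_error(indicator_cis(pop_ens, one_curve, 27), "equal B")
})

test_that("traffic light endpoints, midpoint and orientation are right", {
  g <- traffic_light(0, "higher_is_worse")
  expect_equal(g$category, "green")
  expect_equal(g$rgb, c(0L, 255L, 0L))
  r <- traffic_light(100, "higher_is_worse")
  expect_equal(r$category, "red")
  expect_equal(r$rgb, c(255L, 0L, 0L))
  # higher_is_better flips: 100 is pure green
  expect_equal(traffic_light(100, "higher_is_better")$rgb, c(0L, 255L, 0L))
  expect_equal(traffic_light(0, "higher_is_better")$rgb, c(255L, 0L, 0L))
  # 50 is pure yellow either way
  expect_equal(traffic_light(50, "higher_is_worse")$rgb, c(255L, 255L, 0L))
  expect_equal(traffic_light(50, "higher_is_better")$rgb, c(255L, 255L, 0L))
  expect_warning(out <- traffic_light(105, "higher_is_worse"), "clamped")
  expect_equal(out$value, 100)
})
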