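test_that("efron_ci uses linear-interpolation percentiles", {
  # 1..1000 at level 0.95 under the type-7 rule: order statistic positions
  # 1 + 999 * 0.025 = 25.975 and 1 + 999 * 0.975 = 975.025
  ci <- efron_ci(1:1000, 0.95)
  expect_equal(unname(ci), c(25.975, 975.025))
  # constant collection collapses
  expect_equal(unname(efron_ci(rep(3.5, 50))), c(3.5, 3.5))
  # symmetric values give an interval symmetric about the median
  v <- c(-5:-1, 1:5)
  ci <- efron_ci(v, 0.8)
  expect_equal(ci[["lo"]], -ci[["hi"]])
  expect_error(efron_ci(numeric(0)), "empty")
})

test_that("same seed gives bit-identical ensembles; different seeds differ", {
  ds <- random_dataset(31, m = 4, lambda = 10)
  e1 <- double_bootstrap(ds, "codend", B = 25, seed = 99)
  e2 <- double_bootstrap(ds, "codend", B = 25, seed = 99)
  expect_identical(e1$reps, e2$reps)
  e3 <- double_bootstrap(ds, "codend", B = 25, seed = 100)
  expect_false(identical(e1$reps, e3$reps))
  expect_error(double_bootstrap(ds, "codend", B = 0), "B must be")
})

test_that("noise-free single-haul data give a near-degenerate ensemble", {
  lens <- 15:45
  r <- logit_retention(class_mark(lens), logit_params(30, 5))
  total <- 1e5  # huge expected counts: resampling noise is negligible
  ds <- selectivity_dataset(tibble::tibble(
    haul_id = 1, length_cm = lens, n_CD = round(total * r),
    n_CC = round(total * (1 - r)), q_CD = 1, q_CC = 1))
  ens <- double_bootstrap(ds, "codend", B = 30, seed = 5)
  l50s <- vapply(ens$reps, function(p) p$L50, numeric(1))
  ci <- efron_ci(l50s)
  expect_lt(ci[["hi"]] - ci[["lo"]], 0.05)
  expect_equal(mean(l50s), 30, tolerance = 0.01)
})

test_that("curve bands bracket the point curve and collapse for tiny ensembles", {
  ds <- random_dataset(8, m = 4, lambda = 12)
  lengths <- class_mark(18:30)
  ens <- double_bootstrap(ds, "codend", B = 60, seed = 2)
  band <- curve_band(ens, lengths)
  expect_true(all(band$lo <= band$hi))
  expect_true(all(band$lo >= 0 & band$hi <= 1))
  # the point curve should mostly lie inside its own 95% band
  inside <- band$mean >= band$lo & band$mean <= band$hi
  expect_gte(mean(inside), 0.95)

  # single-rep ensemble collapses onto the rep's curve
  one <- ens
  one$reps <- ens$reps[1]
  one$B <- 1L
  b1 <- curve_band(one, lengths)
  r1 <- retention(ens$reps[[1]], lengths)
  expect_equal(b1$lo, r1)
  expect_equal(b1$hi, r1)

  # two-rep ensemble at level -> 1 spans elementwise min/max
  two <- ens
  two$reps <- ens$reps[1:2]
  two$B <- 2L
  b2 <- curve_band(two, lengths, level = 0.999999)
  r2 <- retention(ens$reps[[2]], lengths)
  expect_equal(b2$lo, pmin(r1, r2), tolerance = 1e-4)
  expect_equal(b2$hi, pmax(r1, r2), tolerance = 1e-4)
})

test_that("delta of an ensemble with itself is exactly zero with no significant ranges", {
  ds <- random_dataset(12, m = 3, lambda = 10)
  ens <- double_bootstrap(ds, "smp", B = 40, seed = 3)
  lengths <- class_mark(18:30)
  dc <- delta_curve(ens, ens, lengths)
  expect_equal(dc$curve$delta, rep(0, length(lengths)))
  expect_equal(dc$curve$lo, rep(0, length(lengths)))
  expect_equal(dc$curve$hi, rep(0, length(lengths)))
  expect_equal(nrow(dc$significant_ranges), 0)
})

test_that("constant curves offset by 0.2 give a zero-width all-significant delta", {
  mk_const <- function(C) {
    # C = 1 - r: a clogit far above all data lengths is flat at 1 - C
    ens <- list(reps = lapply(1:20, function(i) clogit_params(C, 1000, 5)),
                B = 20L, seed = 1, model = "smp",
                point = clogit_params(C, 1000, 5), fit = NULL, n_failed = 0L)
    structure(ens, class = "bootstrap_ensemble")
  }
  lengths <- seq(10, 40, by = 1)
  dc <- delta_curve(mk_const(0.1), mk_const(0.3), lengths)
  expect_equal(dc$curve$delta, rep(0.2, length(lengths)), tolerance = 1e-9)
  expect_equal(dc$curve$lo, dc$curve$hi, tolerance = 1e-12)
  expect_equal(nrow(dc$significant_ranges), 1)
  expect_equal(dc$significant_ranges$from, 10)
  expect_equal(dc$significant_ranges$to, 40)
})

test_that("a true L50 shift yields a significant range bracketing the true maximum difference", {
  truth_a <- combined_params(logit_params(24, 4))
  truth_b <- combined_params(logit_params(29, 4))  # 5 cm shift
  cfg <- simulation_config(m = 6, total = 400, between_haul_sd = 0.02, seed = 21)
  ds_a <- simulate_dataset(cfg, truth_a)
  cfg$seed <- 22
  ds_b <- simulate_dataset(cfg, truth_b)
  ens_a <- double_bootstrap(ds_a, "codend", B = 200, seed = 31)
  ens_b <- double_bootstrap(ds_b, "codend", B = 200, seed = 32)
  lengths <- class_mark(10:50)
  dc <- delta_curve(ens_b, ens_a, lengths)
  # true delta is most negative at the crossing midpoint ~26.5 cm
  true_delta <- retention(truth_b, lengths) - retention(truth_a, lengths)
  l_max <- lengths[which.min(true_delta)]
  expect_gte(nrow(dc$significant_ranges), 1)
  widest <- dc$significant_ranges[which.max(dc$significant_ranges$to -
                                              dc$significant_ranges$from), ]
  expect_true(widest$from <= l_max && l_max <= widest$to)
  # unequal B errors
  short <- ens_a
  short$reps <- short$reps[1:100]
  short$B <- 100L
  expect_error(delta_curve(ens_b, short, lengths), "equal B")
})

test_that("combined ensembles pair by index and feed delta curves", {
  ds <- random_dataset(44, m = 4, lambda = 15)
  e_smp <- double_bootstrap(ds, "smp", B = 30, seed = 7)
  e_cd <- double_bootstrap(ds, "codend", B = 30, seed = 8)
  comb <- combine_ensembles(e_cd, e_smp)
  expect_equal(comb$B, 30L)
  l <- class_mark(18:30)
  # rep i of the combined ensemble is the product of the component reps i
  r5 <- retention(comb$reps[[5]], l)
  expect_equal(r5, retention(e_smp$reps[[5]], l) * retention(e_cd$reps[[5]], l))
  # codend-only combination
  bare <- combine_ensembles(e_cd)
  expect_equal(retention(bare$reps[[3]], l), retention(e_cd$reps[[3]], l))
  # mismatched B rejected
  e_cd_small <- double_bootstrap(ds, "codend", B = 10, seed = 9)
  expect_error(combine_ensembles(e_cd_small, e_smp), "equal B")
  # delta of a combined ensemble against itself is zero
  dc <- delta_curve(comb, comb, l)
  expect_equal(max(abs(dc$curve$delta)), 0)
})
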