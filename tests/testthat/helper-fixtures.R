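# Fixture builders and independent oracles shared across test files.

toy_dataset <- function(haul_id = 1, length_cm = 20:24,
                        n_CD = c(2, 5, 9, 12, 15), n_CC = c(8, 6, 4, 2, 1),
                        n_PC = NULL, q_CD = 1, q_CC = 1, q_PC = 1,
                        gear = NA_character_) {
  d <- tibble::tibble(haul_id = haul_id, length_cm = length_cm,
                      n_CD = n_CD, n_CC = n_CC, q_CD = q_CD, q_CC = q_CC)
  if (!is.null(n_PC)) {
    d$n_PC <- n_PC
    d$q_PC <- q_PC
  }
  selectivity_dataset(d, gear = gear)
}

# random multi-haul dual-cover dataset with guaranteed fish in every
# compartment somewhere
random_dataset <- function(seed, m = 2, lengths = 18:30, lambda = 6,
                           q = c(1, 1, 1)) {
  withr::with_seed(seed, {
    repeat {
      d <- do.call(rbind, lapply(seq_len(m), function(j) {
        tibble::tibble(haul_id = j, length_cm = lengths,
                       n_CD = rpois(length(lengths), lambda),
                       n_CC = rpois(length(lengths), lambda),
                       n_PC = rpois(length(lengths), lambda / 2),
                       q_CD = q[1], q_CC = q[2], q_PC = q[3])
      }))
      if (sum(d$n_CD) > 0 && sum(d$n_CC) > 0 && sum(d$n_PC) > 0) break
    }
    selectivity_dataset(d)
  })
}

# Independent oracle for the pooled negative log-likelihoods: naive double
# loop over (haul, length) rows, never touching the package's pooled path.
oracle_nll <- function(ds, params, model, at = "midpoint") {
  d <- ds$data
  tot <- 0
  for (i in seq_len(nrow(d))) {
    l <- trawlselect::class_mark(d$length_cm[i], at)
    if (model == "smp") {
      r <- trawlselect::clogit_retention(l, params)
      n_in <- d$n_CD[i] / d$q_CD[i] + d$n_CC[i] / d$q_CC[i]
      n_out <- d$n_PC[i] / d$q_PC[i]
    } else {
      r <- trawlselect::logit_retention(l, params)
      n_in <- d$n_CD[i] / d$q_CD[i]
      n_out <- d$n_CC[i] / d$q_CC[i]
    }
    if (n_in > 0) tot <- tot - n_in * log(r)
    if (n_out > 0) tot <- tot - n_out * log(1 - r)
  }
  tot
}

# Exhaustive grid search oracle over (C, L50, SR) for the SMP likelihood on
# tiny datasets; returns the minimum pooled nll found on the grid.
grid_min_nll_smp <- function(ds, at = "midpoint",
                             c_step = 0.01, l_step = 0.01, sr_step = 0.01,
                             sr_max = 6) {
  pooled <- trawlselect::pool_over_hauls(ds)
  wide <- tidyr::pivot_wider(pooled, names_from = "compartment",
                             values_from = "n_raised", values_fill = 0)
  l <- trawlselect::class_mark(wide$length_cm, at)
  n_in <- wide$CD + wide$CC
  n_out <- wide$PC
  l50s <- seq(max(0.1, min(l) - 2), max(l) + 2, by = l_step)
  srs <- seq(0.1, sr_max, by = sr_step)
  grid <- expand.grid(L50 = l50s, SR = srs)
  # logistic escape-curve retention for every (L50, SR), lengths in rows
  rl <- matrix(0, nrow = length(l), ncol = nrow(grid))
  for (i in seq_along(l)) {
    rl[i, ] <- plogis(log(9) * (l[i] - grid$L50) / grid$SR)
  }
  best <- Inf
  for (C in seq(0, 1, by = c_step)) {
    r <- 1 - C + C * rl
    nll <- -(colSums(n_in * log(r)) + colSums(n_out * log1p(-r)))
    nll[is.nan(nll)] <- Inf
    best <- min(best, min(nll))
  }
  best
}

hake_smp_bl <- function() trawlselect::sea_trial_params("hake", "SMP_BL")
hake_cd_s <- function() trawlselect::sea_trial_params("hake", "CD_S")

default_truth <- function() {
  trawlselect::combined_params(trawlselect::logit_params(24, 4),
                               trawlselect::clogit_params(0.4, 30, 6))
}
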