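# Synthetic covered-codend experiments with known ground truth. Fish fates
# are independent Bernoulli draws through the sequential gear: a fish first
# passes the SMP zone (escape with probability 1 - r_SMP into the panel
# cover), then the codend (retained with probability r_CD, else codend
# cover). Measured counts are binomial thinnings of true counts at the
# subsampling rate q. Between-haul variation perturbs the L50s per haul by a
# log-normal factor, the simplest structure that makes the between-haul
# bootstrap component consequential.

#' Simulation configuration for a synthetic covered-codend experiment
#'
#' Defaults emulate a mid-scale selectivity cruise on a demersal roundfish
#' population: a bimodal length structure (juvenile and adult modes), 10
#' hauls of 500 fish entering the gear, 5% between-haul coefficient of
#' variation on the L50s, and full measurement (`q = 1`).
#'
#' @param components Tibble/data.frame of population mixture components with
#'   columns `mean` (cm), `sd` (cm), `weight`.
#' @param total Expected number of fish entering the gear per haul.
#' @param m Number of hauls.
#' @param between_haul_sd Standard deviation of the log-normal multiplicative
#'   perturbation applied to each haul's L50s (0 = identical hauls).
#' @param q Named subsampling factors in (0, 1] for `CD`, `CC`, `PC`.
#' @param length_range Two integers: smallest and largest length-class label.
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(components = tibble::tibble(mean = c(22, 35),
                                                          sd = c(4, 5),
                                                          weight = c(0.6, 0.4)),
                              total = 500, m = 10, between_haul_sd = 0.05,
                              q = c(CD = 1, CC = 1, PC = 1),
                              length_range = c(10, 50), seed = 1) {
  stopifnot(nrow(components) >= 1, all(components$weight > 0),
            all(components$sd >= 0), total > 0, m >= 1, between_haul_sd >= 0,
            all(q > 0), all(q <= 1), length(length_range) == 2,
            length_range[1] < length_range[2], length_range[1] >= 0)
  q <- q[c("CD", "CC", "PC")]
  structure(list(components = tibble::as_tibble(components), total = total,
                 m = m, between_haul_sd = between_haul_sd, q = q,
                 length_range = as.integer(length_range), seed = seed),
            class = "simulation_config")
}

#' Expected length structure of a mixture population
#'
#' Discretizes a mixture of bell-shaped components to 1-cm classes: each
#' class receives the normal probability mass on \[label, label + 1), summed
#' over components with their weights, renormalized over the length range and
#' scaled to the requested total. A zero-sd component puts all its mass in
#' the class containing its mean.
#'
#' @param components Tibble with columns `mean`, `sd`, `weight`.
#' @param total Total number of fish.
#' @param length_range Two integers: smallest and largest class label.
#' @return A [population_structure()] of expected counts.
#' @export
simulate_population <- function(components, total = 1000, length_range = c(10, 50)) {
  components <- tibble::as_tibble(components)
  if (nrow(components) == 0) rlang::abort("empty mixture")
  stopifnot(all(c("mean", "sd", "weight") %in% names(components)), total > 0)
  lens <- seq(length_range[1], length_range[2])
  mass <- rep(0, length(lens))
  w <- components$weight / sum(components$weight)
  for (k in seq_len(nrow(components))) {
    mk <- if (components$sd[k] == 0) {
      as.numeric(lens == floor(components$mean[k]))
    } else {
      stats::pnorm(lens + 1, components$mean[k], components$sd[k]) -
        stats::pnorm(lens, components$mean[k], components$sd[k])
    }
    if (sum(mk) == 0) rlang::abort("mixture component has no mass in length_range")
    mass <- mass + w[k] * mk / sum(mk)
  }
  population_structure(lens, total * mass / sum(mass))
}

#' Simulate one covered-codend haul from known selectivity
#'
#' Entrants per length class are Poisson draws around the population's
#' expected counts. Each fish independently escapes through the panel with
#' probability `1 - r_SMP(l)` (landing in the panel cover), otherwise reaches
#' the codend and is retained with probability `r_CD(l)` (codend) or escapes
#' into the codend cover. With no panel in `truth` the PC compartment is
#' absent. Measured counts are binomial thinnings at rate `q` per
#' compartment. Uses the current RNG state (seed upstream).
#'
#' @param pop A [population_structure()] of expected entrants.
#' @param truth A [combined_params()] (the ground-truth selectivity).
#' @param haul_id Identifier for the haul.
#' @param q Named subsampling factors for `CD`, `CC` and (if panel) `PC`.
#' @param at Length-class evaluation point for the true curves.
#' @return A one-haul [selectivity_dataset()].
#' @export
simulate_haul <- function(pop, truth, haul_id = 1, q = c(CD = 1, CC = 1, PC = 1),
                          at = "midpoint") {
  stopifnot(inherits(pop, "population_structure"), inherits(truth, "combined_params"))
  l_eval <- class_mark(pop$length_cm, at)
  entrants <- stats::rpois(length(l_eval), pop$n)
  has_smp <- !is.null(truth$smp)
  if (has_smp) {
    r_smp <- clogit_retention(l_eval, truth$smp)
    stay <- stats::rbinom(length(entrants), entrants, r_smp)
    n_pc <- entrants - stay
  } else {
    stay <- entrants
    n_pc <- NULL
  }
  r_cd <- logit_retention(l_eval, truth$codend)
  n_cd <- stats::rbinom(length(stay), stay, r_cd)
  n_cc <- stay - n_cd
  d <- tibble::tibble(
    haul_id = haul_id, length_cm = pop$length_cm,
    n_CD = stats::rbinom(length(n_cd), n_cd, q[["CD"]]),
    n_CC = stats::rbinom(length(n_cc), n_cc, q[["CC"]]),
    q_CD = q[["CD"]], q_CC = q[["CC"]])
  if (has_smp) {
    d$n_PC <- stats::rbinom(length(n_pc), n_pc, q[["PC"]])
    d$q_PC <- q[["PC"]]
  }
  selectivity_dataset(d)
}

#' Simulate a multi-haul covered-codend dataset
#'
#' Draws `m` hauls via [simulate_haul()]. Between-haul variation multiplies
#' each haul's panel and codend L50 by an independent log-normal factor with
#' log-sd `between_haul_sd`; contact probability and selection ranges are
#' shared. Bit-identical output for identical `(config, truth)`.
#'
#' @param config A [simulation_config()].
#' @param truth A [combined_params()] ground truth.
#' @return A [selectivity_dataset()] with attribute `"truth"`.
#' @export
simulate_dataset <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"), inherits(truth, "combined_params"))
  pop <- simulate_population(config$components, config$total, config$length_range)
  has_smp <- !is.null(truth$smp)
  hauls <- withr::with_seed(config$seed, lapply(seq_len(config$m), function(j) {
    f <- if (config$between_haul_sd > 0) {
      stats::rlnorm(2, 0, config$between_haul_sd)
    } else {
      c(1, 1)
    }
    truth_j <- combined_params(
      logit_params(truth$codend$L50 * f[1], truth$codend$SR),
      if (has_smp) clogit_params(truth$smp$C, truth$smp$L50 * f[2], truth$smp$SR))
    simulate_haul(pop, truth_j, haul_id = j, q = config$q)$data
  }))
  ds <- selectivity_dataset(dplyr::bind_rows(hauls), gear = "synthetic",
                            species = "synthetic")
  attr(ds, "truth") <- truth
  ds
}

#' Write the canonical synthetic fixture suite
#'
#' Writes plain-text fixtures used throughout examples and tests: the
#' published sea-trial parameter estimates as JSON
#' ([sea_trial_estimates()]), three population-scenario CSVs (mostly below
#' 20 cm; centred near the hake MCRS; mostly above 22 cm), and a small and a
#' large synthetic dataset CSV, each with a JSON ground-truth sidecar
#' (filenames carry a `synthetic_` prefix). Regeneration with the same seed
#' is byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the synthetic datasets.
#' @return Character vector of the files written, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wpath <- function(f) file.path(out_dir, f)

  est <- sea_trial_estimates()
  jsonlite::write_json(est, wpath("sea_trial_estimates.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, wpath("sea_trial_estimates.json"))

  scenarios <- list(
    below_20 = tibble::tibble(mean = c(14, 18), sd = c(2, 2.5), weight = c(0.5, 0.5)),
    near_mcrs = tibble::tibble(mean = c(24, 28), sd = c(2.5, 3), weight = c(0.6, 0.4)),
    above_22 = tibble::tibble(mean = c(27, 33), sd = c(3, 4), weight = c(0.5, 0.5)))
  for (nm in names(scenarios)) {
    pop <- simulate_population(scenarios[[nm]], total = 10000, length_range = c(8, 50))
    f <- wpath(paste0("population_", nm, ".csv"))
    readr::write_csv(pop, f, progress = FALSE)
    files <- c(files, f)
  }

  truth <- combined_params(logit_params(24, 4), clogit_params(0.4, 30, 6))
  for (size in c("small", "large")) {
    cfg <- simulation_config(total = if (size == "small") 120 else 500,
                             m = if (size == "small") 3 else 10,
                             seed = seed + (size == "large"))
    ds <- simulate_dataset(cfg, truth)
    f <- wpath(paste0("synthetic_hauls_", size, ".csv"))
    write_selectivity(ds, f)
    jsonlite::write_json(
      list(model = "combined",
           smp = list(model = "clogit", C = truth$smp$C, L50 = truth$smp$L50,
                      SR = truth$smp$SR),
           codend = list(model = "logit", L50 = truth$codend$L50,
                         SR = truth$codend$SR),
           config = list(total = cfg$total, m = cfg$m,
                         between_haul_sd = cfg$between_haul_sd, seed = cfg$seed)),
      wpath(paste0("synthetic_hauls_", size, "_truth.json")),
      auto_unbox = TRUE, digits = NA)
    files <- c(files, f, wpath(paste0("synthetic_hauls_", size, "_truth.json")))
  }
  invisible(files)
}
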