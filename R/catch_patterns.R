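# Population entering the gear, retained-catch projection, and
# exploitation-pattern indicators with traffic-light categorization.

#' Construct a length-structured population
#'
#' Numbers of fish entering the gear per 1-cm length class.
#'
#' @param length_cm Integer-valued class labels (lower bounds, cm).
#' @param n Nonnegative numbers per class; total must be positive.
#' @return A `population_structure` tibble with columns `length_cm`, `n`.
#' @export
population_structure <- function(length_cm, n) {
  stopifnot(length(length_cm) == length(n), all(n >= 0), sum(n) > 0,
            all(length_cm >= 0), !anyDuplicated(length_cm))
  out <- tibble::tibble(length_cm = length_cm, n = n) |>
    dplyr::arrange(.data$length_cm)
  class(out) <- c("population_structure", class(out))
  out
}

#' Estimate the population entering the gear
#'
#' In a dual-cover experiment every fish entering the gear ends up in exactly
#' one of codend, codend cover or panel cover, so the entering population per
#' length class is the pooled raised `CD + CC + PC` count.
#'
#' @param ds A [selectivity_dataset()] with a PC compartment.
#' @return A [population_structure()].
#' @export
estimate_entering_population <- function(ds) {
  stopifnot(inherits(ds, "selectivity_dataset"))
  if (!ds$has_pc) {
    rlang::abort("entering population requires full accounting: PC compartment missing")
  }
  pooled <- pool_over_hauls(ds) |>
    dplyr::group_by(.data$length_cm) |>
    dplyr::summarise(n = sum(.data$n_raised), .groups = "drop")
  population_structure(pooled$length_cm, pooled$n)
}

#' Double-bootstrap the entering population
#'
#' Applies the same double resampling as [double_bootstrap()] (hauls with
#' replacement, multinomial within haul and compartment) and recomputes the
#' entering population per repetition, yielding the population ensemble that
#' pairs with curve ensembles in [retained_population()] and
#' [indicator_cis()].
#'
#' @param ds A [selectivity_dataset()] with a PC compartment.
#' @param B Number of repetitions.
#' @param seed Integer seed.
#' @return A `population_ensemble`: list with `reps` (list of
#'   [population_structure()]), `B`, `seed`, `point`.
#' @export
bootstrap_population <- function(ds, B = 1000, seed = 1) {
  if (!ds$has_pc) rlang::abort("population bootstrap requires a PC compartment")
  if (B < 1) rlang::abort("B must be >= 1")
  point <- estimate_entering_population(ds)
  mats <- ds_matrices(ds)
  m <- length(mats$hauls)
  reps <- withr::with_seed(seed, lapply(seq_len(B), function(i) {
    idx <- sample.int(m, m, replace = TRUE)
    tot <- Reduce(`+`, lapply(COMPARTMENTS, function(cp) {
      rs <- resample_matrix(mats$counts[[cp]], idx)
      as.numeric(rs %*% (1 / mats$q[[cp]][idx]))
    }))
    population_structure(mats$lens, tot)
  }))
  structure(list(reps = reps, B = as.integer(B), seed = seed, point = point),
            class = "population_ensemble")
}

#' Project the population retained by a combined gear
#'
#' Applies the combined panel-by-codend selection curve to the population
#' entering the gear: `nr_l = nPop_l * r_comb(l)`. When a curve ensemble
#' (and optionally a population ensemble of equal `B`, paired by index) is
#' supplied, pointwise Efron confidence bounds are attached.
#'
#' @param pop A [population_structure()].
#' @param params A [combined_params()] (or any `selectivity_params`).
#' @param ens Optional [combine_ensembles()]/[double_bootstrap()] ensemble.
#' @param pop_ens Optional [bootstrap_population()] ensemble, same `B` as `ens`.
#' @param level Confidence level for the bounds.
#' @param at Length-class evaluation point, see [class_mark()].
#' @return A tibble `length_cm`, `n_pop`, `n_retained` and, with `ens`,
#'   `lo`, `hi`.
#' @export
retained_population <- function(pop, params, ens = NULL, pop_ens = NULL,
                                level = 0.95, at = "midpoint") {
  stopifnot(inherits(pop, "population_structure"),
            inherits(params, "selectivity_params"))
  l_eval <- class_mark(pop$length_cm, at)
  out <- tibble::tibble(length_cm = pop$length_cm, n_pop = pop$n,
                        n_retained = pop$n * retention(params, l_eval))
  if (!is.null(ens)) {
    stopifnot(inherits(ens, "bootstrap_ensemble"))
    if (!is.null(pop_ens)) {
      stopifnot(inherits(pop_ens, "population_ensemble"))
      if (pop_ens$B != ens$B) {
        rlang::abort("population and curve ensembles must have equal B")
      }
      pops <- lapply(pop_ens$reps, function(p) {
        n <- rep(0, length(pop$length_cm))
        n[match(p$length_cm, pop$length_cm)] <- p$n
        n
      })
    } else {
      pops <- rep(list(pop$n), ens$B)
    }
    rm_ <- ens_curve_matrix(ens, l_eval)  # lengths x B
    nm <- do.call(cbind, pops) * rm_
    ci <- apply(nm, 1, efron_ci, level = level)
    out$lo <- ci[1, ]
    out$hi <- ci[2, ]
  }
  out
}

indicator_core <- function(length_cm, n_pop, r, mcrs) {
  below <- length_cm < mcrs
  ret <- r * n_pop
  nP_minus <- if (sum(n_pop[below]) > 0) 100 * sum(ret[below]) / sum(n_pop[below]) else NA_real_
  nP_plus <- if (sum(n_pop[!below]) > 0) 100 * sum(ret[!below]) / sum(n_pop[!below]) else NA_real_
  nDiscard <- if (sum(ret) > 0) 100 * sum(ret[below]) / sum(ret) else NA_real_
  c(nP_minus = nP_minus, nP_plus = nP_plus, nDiscard = nDiscard)
}

#' Exploitation-pattern indicators
#'
#' Three catch-pattern indicators for a gear fishing a given population,
#' relative to the species' minimum conservation reference size (MCRS; for
#' species without one, a marketable-size proxy):
#' * `nP_minus` — percent of entering fish below MCRS that are retained;
#' * `nP_plus` — percent of entering fish at or above MCRS that are retained;
#' * `nDiscard` — percent of the total retained catch that is below MCRS
#'   (the discard ratio).
#'
#' A length class labelled by its lower bound counts as below MCRS when
#' `label < mcrs`: a fish recorded as 27 cm lies in \[27, 28) and is at or
#' above an MCRS of 27. Indicators whose denominator is empty (no fish on one
#' side of MCRS, or nothing retained) are reported `NA` with a warning.
#'
#' @param pop A [population_structure()].
#' @param params A `selectivity_params` object (typically [combined_params()]).
#' @param mcrs MCRS in cm (hake: 27; blue whiting marketable-size proxy: 18).
#' @param at Length-class evaluation point, see [class_mark()].
#' @return An `indicator_set`: list with `nP_minus`, `nP_plus`, `nDiscard`
#'   (percent), `mcrs`.
#' @export
exploitation_indicators <- function(pop, params, mcrs, at = "midpoint") {
  stopifnot(inherits(pop, "population_structure"), mcrs >= 0)
  r <- retention(params, class_mark(pop$length_cm, at))
  ind <- indicator_core(pop$length_cm, pop$n, r, mcrs)
  if (anyNA(ind)) rlang::warn("indicator(s) undefined (empty denominator); reported as NA")
  structure(list(nP_minus = ind[["nP_minus"]], nP_plus = ind[["nP_plus"]],
                 nDiscard = ind[["nDiscard"]], mcrs = mcrs, cis = NULL),
            class = "indicator_set")
}

#' Exploitation-pattern indicators with bootstrap confidence intervals
#'
#' Recomputes the three indicators for every bootstrap repetition, pairing
#' the combined-curve ensemble with the population ensemble by repetition
#' index, and attaches Efron percentile intervals. `pop_ens` may be a plain
#' [population_structure()] to treat the population as fixed.
#'
#' @param pop_ens A [bootstrap_population()] ensemble or a
#'   [population_structure()].
#' @param curve_ens A [combine_ensembles()]/[double_bootstrap()] ensemble.
#' @param mcrs MCRS in cm.
#' @param level Confidence level.
#' @param at Length-class evaluation point.
#' @return An `indicator_set` with point values (from the point population
#'   and point curve) and `cis`, a tibble `indicator`, `lo`, `hi`.
#' @export
indicator_cis <- function(pop_ens, curve_ens, mcrs, level = 0.95, at = "midpoint") {
  stopifnot(inherits(curve_ens, "bootstrap_ensemble"))
  if (inherits(pop_ens, "population_structure")) {
    point_pop <- pop_ens
    pops <- rep(list(pop_ens), curve_ens$B)
  } else {
    stopifnot(inherits(pop_ens, "population_ensemble"))
    if (pop_ens$B != curve_ens$B) {
      rlang::abort("population and curve ensembles must have equal B")
    }
    point_pop <- pop_ens$point
    pops <- pop_ens$reps
  }
  per_rep <- vapply(seq_len(curve_ens$B), function(i) {
    p <- pops[[i]]
    r <- retention(curve_ens$reps[[i]], class_mark(p$length_cm, at))
    indicator_core(p$length_cm, p$n, r, mcrs)
  }, numeric(3))
  point <- exploitation_indicators(point_pop, curve_ens$point, mcrs, at = at)
  point$cis <- tibble::tibble(
    indicator = rownames(per_rep),
    lo = unname(apply(per_rep, 1, function(v) efron_ci(v, level)[[1]])),
    hi = unname(apply(per_rep, 1, function(v) efron_ci(v, level)[[2]])))
  point$level <- level
  point
}

#' @export
print.indicator_set <- function(x, ...) {
  cat(sprintf("<indicator_set> MCRS = %g cm\n", x$mcrs))
  vals <- c(nP_minus = x$nP_minus, nP_plus = x$nP_plus, nDiscard = x$nDiscard)
  for (nm in names(vals)) {
    ci <- if (!is.null(x$cis)) x$cis[x$cis$indicator == nm, ] else NULL
    cat(sprintf("  %-9s %6.2f%%", nm, vals[[nm]]))
    if (!is.null(ci) && nrow(ci) == 1) cat(sprintf("  (%.2f-%.2f)", ci$lo, ci$hi))
    cat("\n")
  }
  invisible(x)
}

#' Traffic-light categorization of an indicator value
#'
#' Maps an indicator value in \[0, 100\] to a gradual green-yellow-red color:
#' the best end is pure green, 50 on the badness scale is yellow, the worst
#' end pure red, with linear RGB interpolation in between. `direction` states
#' which end is bad: the discard ratio and `nP_minus` are
#' `"higher_is_worse"`, `nP_plus` is `"higher_is_better"`. Values outside
#' \[0, 100\] are clamped with a warning.
#'
#' @param value Indicator value in percent.
#' @param direction `"higher_is_worse"` or `"higher_is_better"`.
#' @return A `traffic_light`: list with `value`, `badness` (0 best, 100
#'   worst), `rgb` (integer triple, 0-255), `hex`, and `category` (`"green"`,
#'   `"yellow"` or `"red"`, split at badness thirds).
#' @export
traffic_light <- function(value, direction = c("higher_is_worse", "higher_is_better")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  if (value < 0 || value > 100) {
    rlang::warn("indicator value outside [0, 100]; clamped")
    value <- min(100, max(0, value))
  }
  b <- if (direction == "higher_is_worse") value else 100 - value
  rgb_ <- if (b <= 50) {
    c(round(255 * b / 50), 255, 0)          # green -> yellow
  } else {
    c(255, round(255 * (1 - (b - 50) / 50)), 0)  # yellow -> red
  }
  category <- if (b <= 100 / 3) "green" else if (b <= 200 / 3) "yellow" else "red"
  structure(list(value = value, badness = b, rgb = as.integer(rgb_),
                 hex = grDevices::rgb(rgb_[1], rgb_[2], rgb_[3], maxColorValue = 255),
                 category = category),
            class = "traffic_light")
}

#' @export
print.traffic_light <- function(x, ...) {
  cat(sprintf("<traffic_light> value %.2f -> %s (%s)\n", x$value, x$category, x$hex))
  invisible(x)
}
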