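# Double bootstrap: outer resampling of hauls (between-haul variation) and,
# within each selected haul, multinomial resampling of the measured fish over
# length classes per compartment (within-haul variation). Measured counts are
# resampled and then re-raised by q, since measurement subsampling is the
# within-haul observation process and q is a known raising constant.
#
# Internals work on (length class x haul) count matrices rather than dataset
# objects: a bootstrap run performs thousands of refits.

ds_matrices <- function(ds) {
  d <- ds$data
  lens <- sort(unique(d$length_cm))
  hauls <- unique(d$haul_id)
  ri <- match(d$length_cm, lens)
  ci <- match(d$haul_id, hauls)
  comps <- if (ds$has_pc) COMPARTMENTS else c("CD", "CC")
  counts <- lapply(comps, function(cp) {
    m <- matrix(0, nrow = length(lens), ncol = length(hauls))
    m[cbind(ri, ci)] <- d[[paste0("n_", cp)]]
    m
  })
  q <- lapply(comps, function(cp) {
    qv <- rep(NA_real_, length(hauls))
    qv[ci] <- d[[paste0("q_", cp)]]
    qv
  })
  names(counts) <- names(q) <- comps
  list(lens = lens, hauls = hauls, counts = counts, q = q)
}

resample_matrix <- function(m, idx) {
  out <- m[, idx, drop = FALSE]
  for (k in seq_along(idx)) {
    tot <- sum(out[, k])
    if (tot > 0) out[, k] <- stats::rmultinom(1, tot, out[, k])
  }
  out
}

params_to_theta <- function(params) {
  if (inherits(params, "clogit_params")) {
    c(stats::qlogis(min(1 - 1e-9, max(1e-9, params$C))), params$L50, params$SR)
  } else {
    c(params$L50, params$SR)
  }
}

#' Double-bootstrap a selectivity fit
#'
#' Each repetition resamples the hauls with replacement (between-haul
#' variation), then within every selected haul resamples the measured fish of
#' each compartment multinomially over length classes, preserving the
#' compartment's measured total (within-haul variation). The resampled counts
#' are raised by their subsampling factors, pooled, and the model is refitted
#' (warm-started from the point estimate, with the default multi-start grid as
#' fallback). Repetitions whose refit fails are redrawn so that the ensemble
#' keeps exactly `B` entries in fixed order — the index pairing other
#' functions rely on; more than 20% failed refits aborts.
#'
#' @param ds A [selectivity_dataset()].
#' @param model `"smp"` or `"codend"`.
#' @param B Number of bootstrap repetitions (default 1000).
#' @param seed Integer seed; ensembles are bit-identical for identical
#'   `(ds, model, B, seed)`.
#' @param at Length-class evaluation point, see [class_mark()].
#' @return A `bootstrap_ensemble`: list with `reps` (list of fitted parameter
#'   sets, length `B`), `B`, `seed`, `model`, `point` (point-estimate
#'   parameters), `fit` (the point [fit_smp()]/[fit_codend()] result) and
#'   `n_failed` (redrawn refits).
#' @export
double_bootstrap <- function(ds, model = c("smp", "codend"), B = 1000,
                             seed = 1, at = "midpoint") {
  model <- match.arg(model)
  if (B < 1) rlang::abort("B must be >= 1")
  point_fit <- if (model == "smp") fit_smp(ds, at = at) else fit_codend(ds, at = at)
  mats <- ds_matrices(ds)
  m <- length(mats$hauls)
  l_eval <- class_mark(mats$lens, at)
  warm <- params_to_theta(point_fit$params)
  fallback <- if (model == "smp") c(0, stats::median(l_eval), 4) else c(stats::median(l_eval), 4)
  comps <- if (model == "smp") COMPARTMENTS else c("CD", "CC")

  reps <- vector("list", B)
  n_failed <- 0L
  withr::with_seed(seed, {
    i <- 1L
    while (i <= B) {
      idx <- sample.int(m, m, replace = TRUE)
      pooled <- lapply(comps, function(cp) {
        rs <- resample_matrix(mats$counts[[cp]], idx)
        as.numeric(rs %*% (1 / mats$q[[cp]][idx]))
      })
      names(pooled) <- comps
      if (model == "smp") {
        g <- list(l = l_eval, n_in = pooled$CD + pooled$CC, n_out = pooled$PC)
      } else {
        g <- list(l = l_eval, n_in = pooled$CD, n_out = pooled$CC)
      }
      fp <- tryCatch(
        fit_pooled(g, model, starts = list(warm, fallback), reltol = 1e-9),
        error = function(e) NULL)
      if (is.null(fp) || !is.finite(fp$nll)) {
        n_failed <- n_failed + 1L
        if (n_failed > 0.2 * B) {
          rlang::abort(sprintf(
            "more than 20%% of bootstrap refits failed (%d of %d attempts)",
            n_failed, B + n_failed), class = "trawlselect_bootstrap_error")
        }
        next
      }
      reps[[i]] <- fp$params
      i <- i + 1L
    }
  })
  structure(
    list(reps = reps, B = as.integer(B), seed = seed, model = model,
         point = point_fit$params, fit = point_fit, n_failed = n_failed),
    class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat("<bootstrap_ensemble> ", x$model, " model, B = ", x$B,
      ", seed = ", x$seed, "\n  point: ", format(x$point), "\n", sep = "")
  if (isTRUE(x$n_failed > 0)) cat("  ", x$n_failed, " failed refit(s) redrawn\n", sep = "")
  invisible(x)
}

#' Pair panel and codend ensembles into a combined-gear ensemble
#'
#' Builds the ensemble of combined (panel x codend) retention parameter sets
#' by pairing the two component ensembles repetition-by-repetition, which is
#' valid because the two bootstrap resamplings are random and independent.
#' With `smp_ens = NULL` the combined gear is the bare codend.
#'
#' @param codend_ens A `"codend"` [double_bootstrap()] ensemble.
#' @param smp_ens An `"smp"` ensemble with the same `B`, or `NULL`.
#' @return A `bootstrap_ensemble` of [combined_params()] (model `"combined"`).
#' @export
combine_ensembles <- function(codend_ens, smp_ens = NULL) {
  stopifnot(inherits(codend_ens, "bootstrap_ensemble"), codend_ens$model == "codend")
  if (is.null(smp_ens)) {
    reps <- lapply(codend_ens$reps, combined_params)
    point <- combined_params(codend_ens$point)
  } else {
    stopifnot(inherits(smp_ens, "bootstrap_ensemble"), smp_ens$model == "smp")
    if (smp_ens$B != codend_ens$B) {
      rlang::abort("ensembles must have equal B to pair by repetition index")
    }
    reps <- Map(function(cd, sp) combined_params(cd, sp),
                codend_ens$reps, smp_ens$reps)
    point <- combined_params(codend_ens$point, smp_ens$point)
  }
  structure(
    list(reps = reps, B = codend_ens$B,
         seed = c(codend = codend_ens$seed,
                  smp = if (is.null(smp_ens)) NA_integer_ else smp_ens$seed),
         model = "combined", point = point, fit = NULL, n_failed = NA_integer_),
    class = "bootstrap_ensemble")
}

#' Efron percentile confidence interval
#'
#' Empirical percentiles of a bootstrap collection at `(1 - level)/2` and
#' `1 - (1 - level)/2`, with linear interpolation between order statistics
#' (the R default quantile definition, type 7).
#'
#' @param values Nonempty numeric vector (one value per bootstrap repetition).
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(lo, hi)`.
#' @export
efron_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) == 0) rlang::abort("empty collection")
  stopifnot(level > 0, level < 1)
  a <- (1 - level) / 2
  q <- stats::quantile(values, c(a, 1 - a), type = 7, names = FALSE)
  c(lo = q[1], hi = q[2])
}

ens_curve_matrix <- function(ens, lengths) {
  vapply(ens$reps, function(p) retention(p, lengths),
         numeric(length(lengths)))  # lengths x B
}

#' Bootstrap confidence band of a selection curve
#'
#' Evaluates every bootstrap repetition's curve on a length grid and takes
#' pointwise Efron percentile intervals; the central curve is the
#' point-estimate fit.
#'
#' @param ens A [double_bootstrap()] (or [combine_ensembles()]) ensemble.
#' @param lengths Numeric length grid (cm) on which to evaluate the curves.
#' @param level Confidence level.
#' @return A `curve_band` tibble: `length`, `mean`, `lo`, `hi`.
#' @export
curve_band <- function(ens, lengths, level = 0.95) {
  stopifnot(inherits(ens, "bootstrap_ensemble"))
  cm <- ens_curve_matrix(ens, lengths)
  ci <- apply(cm, 1, efron_ci, level = level)
  out <- tibble::tibble(length = lengths,
                        mean = retention(ens$point, lengths),
                        lo = ci[1, ], hi = ci[2, ])
  attr(out, "level") <- level
  class(out) <- c("curve_band", class(out))
  out
}

runs_to_ranges <- function(lengths, flag) {
  if (!any(flag)) {
    return(tibble::tibble(from = numeric(0), to = numeric(0)))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(from = lengths[starts[keep]], to = lengths[ends[keep]])
}

#' Delta selectivity between a treatment and a baseline gear
#'
#' The delta curve is the length-wise difference in retention probability
#' `treatment - baseline`. Its confidence band comes from the per-repetition
#' differences of the two ensembles, paired by bootstrap index (valid since
#' the two resamplings are independent). Length classes where the band
#' excludes 0 mark a significant selectivity difference.
#'
#' @param treat,base [double_bootstrap()] or [combine_ensembles()] ensembles
#'   with equal `B`.
#' @param lengths Numeric length grid (cm).
#' @param level Confidence level.
#' @return A `delta_curve_result`: list with `curve` (tibble `length`,
#'   `delta`, `lo`, `hi`), `significant_ranges` (tibble `from`, `to` of
#'   contiguous grid runs where the band excludes 0) and `level`.
#' @export
delta_curve <- function(treat, base, lengths, level = 0.95) {
  stopifnot(inherits(treat, "bootstrap_ensemble"),
            inherits(base, "bootstrap_ensemble"))
  if (treat$B != base$B) {
    rlang::abort("ensembles must have equal B to pair by repetition index")
  }
  dm <- ens_curve_matrix(treat, lengths) - ens_curve_matrix(base, lengths)
  ci <- apply(dm, 1, efron_ci, level = level)
  curve <- tibble::tibble(
    length = lengths,
    delta = retention(treat$point, lengths) - retention(base$point, lengths),
    lo = ci[1, ], hi = ci[2, ])
  sig <- runs_to_ranges(lengths, curve$lo > 0 | curve$hi < 0)
  structure(list(curve = curve, significant_ranges = sig, level = level),
            class = "delta_curve_result")
}

#' @export
print.delta_curve_result <- function(x, ...) {
  cat("<delta_curve_result> ", nrow(x$curve), " length classes, level = ",
      x$level, "\n", sep = "")
  if (nrow(x$significant_ranges) == 0) {
    cat("  no length classes with a significant retention difference\n")
  } else {
    cat("  significant ranges (cm): ",
        paste(sprintf("[%g, %g]", x$significant_ranges$from,
                      x$significant_ranges$to), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
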