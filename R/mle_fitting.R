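# Pooled binomial maximum likelihood for panel (CLogit) and codend (logit)
# selectivity. The likelihood sums raised counts over hauls and length
# classes; since the retention probability does not depend on the haul, the
# sums are collapsed to per-length-class totals before optimization.

# x * log(r) with the convention 0 * log(anything) = 0
xlogy <- function(x, r) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(r[pos])
  out
}

nll_core <- function(r, n_in, n_out) {
  v <- -(sum(xlogy(n_in, r)) + sum(xlogy(n_out, 1 - r)))
  if (is.nan(v)) Inf else v
}

# Pooled per-length-class counts for the two binomial comparisons:
#   smp:    "in" = CD + CC (stayed in the gear), "out" = PC (escaped panel)
#   codend: "in" = CD (retained),               "out" = CC (escaped codend)
pooled_groups <- function(ds, model = c("smp", "codend"), at = "midpoint") {
  model <- match.arg(model)
  if (model == "smp" && !ds$has_pc) {
    rlang::abort("SMP fit requires a panel cover (PC) compartment")
  }
  d <- ds$data
  lens <- sort(unique(d$length_cm))
  idx <- match(d$length_cm, lens)
  raised <- function(cp) {
    as.numeric(tapply(d[[paste0("n_", cp)]] / d[[paste0("q_", cp)]], idx, sum,
                      default = 0))
  }
  if (model == "smp") {
    n_in <- raised("CD") + raised("CC")
    n_out <- raised("PC")
  } else {
    n_in <- raised("CD")
    n_out <- raised("CC")
  }
  keep <- n_in + n_out > 0
  list(length_cm = lens[keep], l = class_mark(lens[keep], at),
       n_in = n_in[keep], n_out = n_out[keep])
}

#' Pooled negative log-likelihood of the panel (SMP) selection model
#'
#' The dual-cover experiment splits fish entering the panel zone into those
#' that stayed in the gear (codend + codend cover) and those that escaped
#' through the panel (panel cover). Retention is modeled by the CLogit curve;
#' the likelihood is binomial per (haul, length class) cell, pooled by summing
#' raised counts: `-sum[(nCD/qCD + nCC/qCC) ln r + (nPC/qPC) ln(1 - r)]`.
#' Zero raised counts contribute 0; a retention of 1 where panel escapees
#' were observed yields `+Inf` (not an error), steering optimizers away.
#'
#' @param ds A [selectivity_dataset()] with a PC compartment.
#' @param params A [clogit_params()].
#' @param at Length-class evaluation point, see [class_mark()].
#' @return The negative log-likelihood (possibly `Inf`).
#' @export
nll_smp <- function(ds, params, at = "midpoint") {
  stopifnot(inherits(params, "clogit_params"))
  g <- pooled_groups(ds, "smp", at)
  nll_core(clogit_retention(g$l, params), g$n_in, g$n_out)
}

#' Pooled negative log-likelihood of the codend selection model
#'
#' Binomial comparison of fish retained in the codend against fish that
#' escaped into the codend cover, with logistic retention:
#' `-sum[(nCD/qCD) ln r + (nCC/qCC) ln(1 - r)]` over hauls and length classes.
#'
#' @param ds A [selectivity_dataset()].
#' @param params A [logit_params()].
#' @inheritParams nll_smp
#' @return The negative log-likelihood (possibly `Inf`).
#' @export
nll_codend <- function(ds, params, at = "midpoint") {
  stopifnot(inherits(params, "logit_params"))
  g <- pooled_groups(ds, "codend", at)
  nll_core(logit_retention(g$l, params), g$n_in, g$n_out)
}

# --- optimizer internals -----------------------------------------------------
# CLogit likelihoods are multimodal in C, so fits run a deterministic
# multi-start Nelder-Mead search. C is searched through a logistic transform
# (no hard clipping); L50 and SR are clamped at the 0.1 cm estimation bound
# inside the objective so boundary estimates land exactly on 0.1.

theta_to_params <- function(theta, model) {
  if (model == "smp") {
    clogit_params(stats::plogis(theta[1]),
                  max(PAR_LOWER, theta[2]), max(PAR_LOWER, theta[3]))
  } else {
    logit_params(max(PAR_LOWER, theta[1]), max(PAR_LOWER, theta[2]))
  }
}

obj_fun <- function(g, model) {
  l <- g$l; n_in <- g$n_in; n_out <- g$n_out
  k <- log(9)
  if (model == "smp") {
    function(theta) {
      C <- stats::plogis(theta[1])
      r <- 1 - C + C * stats::plogis(k * (l - max(PAR_LOWER, theta[2])) / max(PAR_LOWER, theta[3]))
      nll_core(r, n_in, n_out)
    }
  } else {
    function(theta) {
      r <- stats::plogis(k * (l - max(PAR_LOWER, theta[1])) / max(PAR_LOWER, theta[2]))
      nll_core(r, n_in, n_out)
    }
  }
}

default_starts <- function(g, model) {
  w <- g$n_in + g$n_out
  qs <- if (model == "smp") c(0.25, 0.5, 0.75) else c(0.1, 0.25, 0.5, 0.75)
  l50s <- if (length(g$l) >= 2) {
    unique(pmax(PAR_LOWER, stats::approx(
      cumsum(w) / sum(w), g$l, xout = qs, rule = 2, ties = "ordered")$y))
  } else {
    pmax(PAR_LOWER, g$l + c(-2, 0, 2))
  }
  srs <- c(1, 5, 10)
  if (model == "smp") {
    cs <- stats::qlogis(c(0.1, 0.5, 0.9))
    starts <- expand.grid(c = cs, L50 = l50s, SR = srs)
    lapply(seq_len(nrow(starts)), function(i) as.numeric(starts[i, ]))
  } else {
    starts <- expand.grid(L50 = l50s, SR = srs)
    lapply(seq_len(nrow(starts)), function(i) as.numeric(starts[i, ]))
  }
}

fit_pooled <- function(g, model, starts = NULL, reltol = 1e-10) {
  if (length(g$l) == 0 || sum(g$n_in) + sum(g$n_out) == 0) {
    rlang::abort("no data to fit: all counts are zero after filtering",
                 class = "trawlselect_fit_error")
  }
  if (is.null(starts)) starts <- default_starts(g, model)
  f <- obj_fun(g, model)
  best <- NULL
  for (th in starts) {
    res <- tryCatch(
      stats::optim(th, f, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = reltol)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) &&
        (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    rlang::abort("optimization failed from every starting point",
                 class = "trawlselect_fit_error")
  }
  params <- theta_to_params(best$par, model)
  boundary <- sum(g$n_out) == 0 || sum(g$n_in) == 0 ||
    params$L50 <= PAR_LOWER || params$SR <= PAR_LOWER ||
    (model == "smp" && (params$C < 1e-4 || params$C > 1 - 1e-4))
  list(params = params, nll = best$value,
       converged = best$convergence == 0, boundary = boundary,
       n_starts_used = length(starts))
}

finish_fit <- function(ds, model, fp, at) {
  diag <- model_diagnostics(ds, fp$params, at = at)
  structure(
    list(model = model, params = fp$params, nll = fp$nll,
         deviance = diag$deviance, dof = diag$dof, p_value = diag$p_value,
         converged = fp$converged, boundary = fp$boundary,
         n_starts_used = fp$n_starts_used, at = at),
    class = "selectivity_fit")
}

#' Fit the panel (SMP) CLogit selection model by pooled maximum likelihood
#'
#' Minimizes [nll_smp()] over `(C, L50, SR)` with `C` in `[0, 1]` (searched
#' through a logistic transform) and `L50, SR >= 0.1` cm, using a
#' deterministic multi-start Nelder-Mead search (27 starting points spanning
#' the observed length range). Goodness of fit is summarized by the deviance
#' against its degrees of freedom and the corresponding chi-square p-value.
#'
#' Datasets in which one outcome group is empty (e.g. no panel escapees at
#' any length) are fitted to the boundary and flagged `boundary = TRUE`
#' rather than rejected.
#'
#' @param ds A [selectivity_dataset()] with a PC compartment.
#' @param at Length-class evaluation point, see [class_mark()].
#' @return A `selectivity_fit`: list with `params`, `nll`, `deviance`, `dof`,
#'   `p_value`, `converged`, `boundary`, `n_starts_used`.
#' @export
fit_smp <- function(ds, at = "midpoint") {
  g <- pooled_groups(ds, "smp", at)
  finish_fit(ds, "smp", fit_pooled(g, "smp"), at)
}

#' Fit the codend logit selection model by pooled maximum likelihood
#'
#' Minimizes [nll_codend()] over `(L50, SR)` with both bounded below at
#' 0.1 cm, using a deterministic multi-start Nelder-Mead search (12 starting
#' points).
#'
#' @inheritParams fit_smp
#' @return A `selectivity_fit`, as in [fit_smp()].
#' @export
fit_codend <- function(ds, at = "midpoint") {
  g <- pooled_groups(ds, "codend", at)
  finish_fit(ds, "codend", fit_pooled(g, "codend"), at)
}

#' @export
print.selectivity_fit <- function(x, ...) {
  cat("<selectivity_fit> ", x$model, " model\n  ", format(x$params), "\n", sep = "")
  cat(sprintf("  nll = %.4f, deviance = %.2f, dof = %d, p = %s\n",
              x$nll, x$deviance, x$dof,
              if (is.na(x$p_value)) "NA" else sprintf("%.4f", x$p_value)))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  if (x$boundary) cat("  note: estimate on a parameter boundary\n")
  invisible(x)
}

diag_cells <- function(ds, params, at, cells) {
  model <- if (inherits(params, "clogit_params")) "smp" else "codend"
  if (model == "smp" && !ds$has_pc) {
    rlang::abort("SMP diagnostics require a PC compartment")
  }
  d <- ds$data
  if (model == "smp") {
    o <- d$n_CD / d$q_CD + d$n_CC / d$q_CC
    t_ <- o + d$n_PC / d$q_PC
  } else {
    o <- d$n_CD / d$q_CD
    t_ <- o + d$n_CC / d$q_CC
  }
  cell <- tibble::tibble(haul_id = d$haul_id, length_cm = d$length_cm,
                         observed = o, total = t_)
  if (cells == "length") {
    cell <- cell |>
      dplyr::group_by(length_cm) |>
      dplyr::summarise(observed = sum(observed), total = sum(total),
                       .groups = "drop") |>
      dplyr::mutate(haul_id = NA, .before = 1)
  }
  cell <- cell[cell$total > 0, ]
  cell$expected <- cell$total * retention(params, class_mark(cell$length_cm, at))
  cell
}

#' Deviance, degrees of freedom and goodness-of-fit p-value
#'
#' The model deviance is `2 * sum[o ln(o/e) + (t - o) ln((t - o)/(t - e))]`
#' over cells with raised total `t > 0`, where `o` is the raised count in the
#' retained group and `e = t * r(l)` the fitted expectation. By default a
#' cell is a (haul, length class) pair (`cells = "haul_length"`); pooled
#' per-length-class cells are available via `cells = "length"`. Degrees of
#' freedom are the number of cells minus the number of model parameters. The
#' p-value is the upper-tail chi-square probability of the deviance at those
#' degrees of freedom: a p-value above 0.05 means the discrepancy between
#' model and data may well be coincidental, while a small p-value with
#' deviance much larger than the degrees of freedom calls for residual
#' inspection ([deviance_residuals()]) to diagnose over-dispersion.
#'
#' @param ds A [selectivity_dataset()].
#' @param params A fitted [clogit_params()] (panel) or [logit_params()]
#'   (codend); the model is inferred from the class.
#' @param at Length-class evaluation point, see [class_mark()].
#' @param cells Cell convention for the deviance sum.
#' @return A list with `deviance`, `dof`, `p_value` (`NA` with a warning when
#'   `dof <= 0`).
#' @export
model_diagnostics <- function(ds, params, at = "midpoint",
                              cells = c("haul_length", "length")) {
  cells <- match.arg(cells)
  cell <- diag_cells(ds, params, at, cells)
  dev <- 2 * sum(xlogy(cell$observed, cell$observed / cell$expected) +
                 xlogy(cell$total - cell$observed,
                       (cell$total - cell$observed) / (cell$total - cell$expected)))
  npar <- if (inherits(params, "clogit_params")) 3L else 2L
  dof <- nrow(cell) - npar
  list(deviance = dev, dof = as.integer(dof), p_value = gof_p_value(dev, dof))
}

#' Goodness-of-fit p-value from a deviance and its degrees of freedom
#'
#' Upper-tail chi-square survival probability of the deviance: the p-value
#' [model_diagnostics()] reports, usable directly on published
#' (deviance, dof) pairs such as those in [sea_trial_estimates()].
#'
#' @param deviance Nonnegative model deviance (vectorized).
#' @param dof Degrees of freedom; `<= 0` yields `NA` with a warning.
#' @return P-value(s) in `[0, 1]`.
#' @export
gof_p_value <- function(deviance, dof) {
  out <- rep(NA_real_, length(deviance))
  ok <- dof > 0
  if (any(!ok)) rlang::warn("degrees of freedom <= 0; p-value undefined")
  out[ok] <- stats::pchisq(deviance[ok], dof[ok], lower.tail = FALSE)
  out
}

#' Signed deviance residuals per cell
#'
#' One signed residual per (haul, length class) cell: the square root of the
#' cell's deviance contribution, signed by `observed - expected`. Squared
#' residuals sum to the total deviance of [model_diagnostics()].
#'
#' @inheritParams model_diagnostics
#' @return A tibble with `haul_id`, `length_cm`, `observed`, `total`,
#'   `expected`, `residual`.
#' @export
deviance_residuals <- function(ds, params, at = "midpoint") {
  cell <- diag_cells(ds, params, at, "haul_length")
  dev_i <- 2 * (xlogy(cell$observed, cell$observed / cell$expected) +
                xlogy(cell$total - cell$observed,
                      (cell$total - cell$observed) / (cell$total - cell$expected)))
  cell$residual <- sign(cell$observed - cell$expected) * sqrt(pmax(0, dev_i))
  cell
}
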