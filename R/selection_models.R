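# Closed-form retention models. The logistic is parameterized by L50 (length
# at 50% retention) and SR = L75 - L25, so the slope is ln(9)/SR.

PAR_LOWER <- 0.1  # estimation lower bound for L50 and SR (cm)

#' Logistic codend selectivity parameters
#'
#' @param L50 Length at 50% retention probability (cm), `>= 0.1`.
#' @param SR Selection range `L75 - L25` (cm), `>= 0.1`.
#' @return An object of class `logit_params`.
#' @export
logit_params <- function(L50, SR) {
  stopifnot(is.numeric(L50), is.numeric(SR), length(L50) == 1, length(SR) == 1)
  if (!is.finite(SR) || SR < PAR_LOWER) rlang::abort("SR must be >= 0.1 cm")
  if (!is.finite(L50) || L50 < PAR_LOWER) rlang::abort("L50 must be >= 0.1 cm")
  structure(list(L50 = L50, SR = SR), class = c("logit_params", "selectivity_params"))
}

#' Contact-conditioned (CLogit) panel selectivity parameters
#'
#' `C` is the probability that a fish entering the square-mesh-panel zone
#' contacts the panel and is thereby subject to length-dependent escape;
#' fish that never contact the panel (probability `1 - C`) are retained
#' regardless of length.
#'
#' @param C Contact probability in `[0, 1]`.
#' @inheritParams logit_params
#' @return An object of class `clogit_params`.
#' @export
clogit_params <- function(C, L50, SR) {
  stopifnot(is.numeric(C), length(C) == 1)
  if (!is.finite(C) || C < 0 || C > 1) rlang::abort("C must lie in [0, 1]")
  lp <- logit_params(L50, SR)
  structure(list(C = C, L50 = lp$L50, SR = lp$SR),
            class = c("clogit_params", "selectivity_params"))
}

#' Combined panel-and-codend selectivity parameters
#'
#' Sequential selection: a fish is retained by the whole gear only if it is
#' retained in the panel zone and then in the codend, so the combined
#' retention is the product of the two component retentions. An absent panel
#' (`smp = NULL`) is equivalent to contact probability 0 (no escape upstream
#' of the codend).
#'
#' @param codend A [logit_params()].
#' @param smp A [clogit_params()] or `NULL` for gears without a panel.
#' @return An object of class `combined_params`.
#' @export
combined_params <- function(codend, smp = NULL) {
  stopifnot(inherits(codend, "logit_params"))
  if (!is.null(smp)) stopifnot(inherits(smp, "clogit_params"))
  structure(list(smp = smp, codend = codend),
            class = c("combined_params", "selectivity_params"))
}

#' @export
format.selectivity_params <- function(x, ...) {
  if (inherits(x, "combined_params")) {
    paste0("combined[", if (is.null(x$smp)) "no SMP" else format(x$smp), " x ",
           format(x$codend), "]")
  } else if (inherits(x, "clogit_params")) {
    sprintf("CLogit(C = %.3g, L50 = %.4g, SR = %.4g)", x$C, x$L50, x$SR)
  } else {
    sprintf("Logit(L50 = %.4g, SR = %.4g)", x$L50, x$SR)
  }
}

#' @export
print.selectivity_params <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

logit_curve <- function(l, L50, SR) {
  z <- log(9) * (l - L50) / SR
  stats::plogis(z)
}

#' Logistic retention probability
#'
#' `r(l) = exp(ln 9 (l - L50) / SR) / (1 + exp(ln 9 (l - L50) / SR))`, the
#' standard codend selection curve: strictly increasing in length, 0.5 at
#' `L50`, 0.25/0.75 at `L50 -/+ SR/2`.
#'
#' @param l Length(s) in cm (vectorized).
#' @param params A [logit_params()].
#' @return Retention probabilities in (0, 1).
#' @export
logit_retention <- function(l, params) {
  stopifnot(inherits(params, "logit_params"))
  logit_curve(l, params$L50, params$SR)
}

#' Contact-conditioned (CLogit) retention probability
#'
#' `r(l) = 1 - C + C * logit(l, L50, SR)`: a fraction `1 - C` of fish never
#' contact the panel and are retained regardless of length, the rest follow
#' the logistic escape curve. Bounded in `[1 - C, 1]`; reduces to
#' [logit_retention()] when `C = 1` and to constant 1 when `C = 0`.
#'
#' @param l Length(s) in cm (vectorized).
#' @param params A [clogit_params()].
#' @return Retention probabilities in `[1 - C, 1]`.
#' @export
clogit_retention <- function(l, params) {
  stopifnot(inherits(params, "clogit_params"))
  1 - params$C + params$C * logit_curve(l, params$L50, params$SR)
}

#' Combined panel-by-codend retention probability
#'
#' Product of the panel (CLogit) and codend (logit) retentions; with no panel
#' the codend retention alone.
#'
#' @param l Length(s) in cm (vectorized).
#' @param params A [combined_params()].
#' @return Retention probabilities in `[0, 1]`.
#' @export
combined_retention <- function(l, params) {
  stopifnot(inherits(params, "combined_params"))
  r <- logit_retention(l, params$codend)
  if (!is.null(params$smp)) r <- r * clogit_retention(l, params$smp)
  r
}

#' Evaluate any selectivity parameter set at given lengths
#'
#' Generic dispatcher over [logit_params()], [clogit_params()] and
#' [combined_params()]; used wherever curves from mixed model types are
#' evaluated uniformly (bootstrap bands, delta curves, catch projections).
#'
#' @param params A `selectivity_params` object.
#' @param l Length(s) in cm.
#' @return Retention probabilities.
#' @export
retention <- function(params, l) UseMethod("retention")

#' @export
retention.logit_params <- function(params, l) logit_retention(l, params)

#' @export
retention.clogit_params <- function(params, l) clogit_retention(l, params)

#' @export
retention.combined_params <- function(params, l) combined_retention(l, params)

#' Length at a given retention probability
#'
#' Inverse of [logit_retention()]:
#' `l = L50 + SR * ln(p / (1 - p)) / ln 9`. In particular `p = 0.25` gives
#' L25 and `p = 0.75` gives L75, whose difference is exactly `SR`.
#'
#' @param p Retention probability strictly inside (0, 1) (vectorized).
#' @param params A [logit_params()].
#' @return Length(s) in cm.
#' @export
retention_quantile <- function(p, params) {
  stopifnot(inherits(params, "logit_params"))
  if (any(p <= 0 | p >= 1)) rlang::abort("p must lie strictly in (0, 1)")
  params$L50 + params$SR * log(p / (1 - p)) / log(9)
}
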