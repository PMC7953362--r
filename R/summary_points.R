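#' Fix one accuracy measure
#'
#' The headline output of the package is the posterior of one accuracy
#' measure while the user fixes the other at a clinically chosen value
#' (for instance the median specificity reported by the included
#' studies).
#'
#' @param fixed_measure `"specificity"` or `"sensitivity"` (the measure
#'   the user pins down).
#' @param value the fixed value, strictly inside (0, 1).
#' @return An object of class `fixed_target`.
#' @export
#' @examples
#' fixed_target("specificity", 0.8)
fixed_target <- function(fixed_measure = c("specificity", "sensitivity"),
                         value) {
  fixed_measure <- match.arg(fixed_measure)
  if (!is.numeric(value) || length(value) != 1L ||
      value <= 0 || value >= 1)
    stop("the fixed value must be strictly inside (0, 1)", call. = FALSE)
  structure(list(fixed_measure = fixed_measure, value = value,
                 estimated = if (fixed_measure == "specificity")
                   "sensitivity" else "specificity"),
            class = "fixed_target")
}

#' Sensitivity on the summary ROC curve at a fixed specificity
#'
#' The summary ROC curve implied by the average location parameter
#' `Lambda` and scale parameter `beta` is
#' `logit(sens) = Lambda * exp(-beta/2) + exp(-beta) * logit(1 - spec)`.
#' With `beta = 0` this is the constant log-diagnostic-odds-ratio curve
#' `logit(sens) - logit(1 - spec) = Lambda`.
#'
#' @param Lambda average location (accuracy) parameter, log-DOR scale.
#' @param beta scale (asymmetry) parameter.
#' @param spec fixed specificity, strictly in (0, 1).
#' @return Sensitivity in (0, 1). Vectorised over all arguments.
#' @export
#' @examples
#' sens_at_spec(2, 0, 0.5)  # invlogit(2)
sens_at_spec <- function(Lambda, beta, spec) {
  if (!is.numeric(spec) || any(spec <= 0 | spec >= 1))
    stop("spec must be strictly inside (0, 1)", call. = FALSE)
  clamp01(stats::plogis(Lambda * exp(-beta / 2) +
                          exp(-beta) * stats::qlogis(1 - spec)))
}

#' Specificity on the summary ROC curve at a fixed sensitivity
#'
#' Exact algebraic inverse of [sens_at_spec()]:
#' `spec = 1 - invlogit(exp(beta) * (logit(sens) - Lambda*exp(-beta/2)))`.
#'
#' @inheritParams sens_at_spec
#' @param sens fixed sensitivity, strictly in (0, 1).
#' @return Specificity in (0, 1). Vectorised over all arguments.
#' @export
spec_at_sens <- function(Lambda, beta, sens) {
  if (!is.numeric(sens) || any(sens <= 0 | sens >= 1))
    stop("sens must be strictly inside (0, 1)", call. = FALSE)
  clamp01(1 - stats::plogis(exp(beta) *
                              (stats::qlogis(sens) -
                                 Lambda * exp(-beta / 2))))
}

#' Append the summary accuracy quantities to posterior draws
#'
#' For every retained state, evaluates the non-fixed accuracy measure at
#' the fixed value: `other_snsp[i]` (i = 1..N studies) uses study i's
#' accuracy parameter `alpha_i` together with that state's `beta`, and
#' `other_snsp[max]` uses the hyper-mean `alpha_g` (Lambda) — the
#' summary point for the average study, not a predictive draw for a new
#' one. The new quantities are inserted before `lp__` so the summary
#' table keeps the conventional row order.
#'
#' @param draws an `hsroc_draws` object from [run_mcmc()].
#' @param target a [fixed_target()].
#' @return The draws object with the `other_snsp` quantities appended
#'   and `target` recorded.
#' @export
derived_quantities <- function(draws, target) {
  if (!inherits(draws, "hsroc_draws"))
    stop("draws must come from run_mcmc()", call. = FALSE)
  if (!inherits(target, "fixed_target"))
    stop("target must be a fixed_target()", call. = FALSE)
  qn <- dimnames(draws$values)[[3]]
  n <- length(draws$study_names)
  need <- c(paste0("alpha[", seq_len(n), "]"), "alpha_g", "beta")
  miss <- setdiff(need, qn)
  if (length(miss))
    stop("draws are missing monitored quantities: ",
         paste(miss, collapse = ", "), call. = FALSE)
  transform <- if (target$fixed_measure == "specificity")
    function(a, b) sens_at_spec(a, b, target$value)
  else
    function(a, b) spec_at_sens(a, b, target$value)
  beta <- draws$values[, , "beta"]
  new_names <- c(paste0("other_snsp[", seq_len(n), "]"), "other_snsp[max]")
  dm <- dim(draws$values)
  add <- array(NA_real_, dim = c(dm[1], dm[2], n + 1L),
               dimnames = list(NULL, NULL, new_names))
  for (i in seq_len(n))
    add[, , i] <- transform(draws$values[, , paste0("alpha[", i, "]")],
                            beta)
  add[, , n + 1L] <- transform(draws$values[, , "alpha_g"], beta)
  keep <- setdiff(qn, c(new_names, "lp__"))
  tail_q <- intersect("lp__", qn)
  values <- array(NA_real_,
                  dim = c(dm[1], dm[2], length(keep) + n + 1L +
                            length(tail_q)),
                  dimnames = list(NULL, NULL,
                                  c(keep, new_names, tail_q)))
  values[, , keep] <- draws$values[, , keep]
  values[, , new_names] <- add
  if (length(tail_q)) values[, , "lp__"] <- draws$values[, , "lp__"]
  draws$values <- values
  draws$target <- target
  draws
}

#' The headline summary point
#'
#' Posterior mean and equal-tailed 95% credible interval of the summary
#' accuracy quantity `other_snsp[max]` (the non-fixed measure evaluated
#' at the fixed value using the hyper-mean accuracy parameter), pooled
#' over chains.
#'
#' @param draws an `hsroc_draws` object already augmented by
#'   [derived_quantities()] (or produced by [run_mcmc()] with a
#'   `target`).
#' @param target the [fixed_target()]; defaults to the one recorded in
#'   `draws`.
#' @return An object of class `hsroc_summary_point`: list with
#'   `measure`, `estimate`, `cri_low`, `cri_high`, `fixed_measure`,
#'   `fixed_value`.
#' @export
summary_point <- function(draws, target = draws$target) {
  if (is.null(target))
    stop("no fixed_target recorded; run derived_quantities() first",
         call. = FALSE)
  x <- as.numeric(draws_matrix(draws, "other_snsp[max]"))
  qs <- stats::quantile(x, c(.025, .975), names = FALSE, type = 7)
  est <- mean(x)
  stopifnot(qs[1] <= qs[2], est > 0, est < 1)
  structure(list(measure = target$estimated, estimate = est,
                 cri_low = qs[1], cri_high = qs[2],
                 fixed_measure = target$fixed_measure,
                 fixed_value = target$value),
            class = "hsroc_summary_point")
}

#' @export
print.hsroc_summary_point <- function(x, ...) {
  cat(sprintf("Summary %s at fixed %s = %.3f:\n", x$measure,
              x$fixed_measure, x$fixed_value))
  cat(sprintf("  %.3f (95%% CrI %.3f to %.3f)\n", x$estimate,
              x$cri_low, x$cri_high))
  invisible(x)
}
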