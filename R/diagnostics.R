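#' Split-chain R-hat convergence diagnostic
#'
#' The Gelman-Rubin potential scale reduction factor computed on
#' half-chains: each chain is split in half (an odd draw is dropped), the
#' within-half-chain variance W and between-half-chain variance B are
#' combined as `sqrt(((n-1)/n * W + B/n) / W)` with n the half-chain
#' length. Splitting makes the statistic sensitive to trends within a
#' chain, not only to disagreement between chains. Values near 1 indicate
#' the chains have mixed; the conventional acceptance rule is
#' R-hat <= 1.1.
#'
#' @param x draws of one scalar quantity: a draws x chains numeric
#'   matrix, or a list of equal-length per-chain vectors.
#' @return Scalar R-hat; `NaN` when every draw is identical (W = 0).
#' @export
split_rhat <- function(x) {
  x <- as_chain_matrix(x)
  if (ncol(x) < 2L) stop("at least 2 chains are required", call. = FALSE)
  if (nrow(x) < 4L)
    stop("at least 4 draws per chain are required", call. = FALSE)
  half <- split_halves(x)
  n <- nrow(half)
  W <- mean(apply(half, 2, stats::var))
  B <- n * stats::var(colMeans(half))
  if (W == 0) return(NaN)
  sqrt(((n - 1) / n * W + B / n) / W)
}

as_chain_matrix <- function(x) {
  if (is.list(x)) {
    len <- lengths(x)
    if (length(unique(len)) != 1L)
      stop("chains must have equal length", call. = FALSE)
    x <- do.call(cbind, x)
  }
  if (!is.matrix(x)) stop("x must be a matrix or list of chains",
                          call. = FALSE)
  x
}

split_halves <- function(x) {
  n <- nrow(x) - nrow(x) %% 2L
  h <- n %/% 2L
  cbind(x[seq_len(h), , drop = FALSE],
        x[h + seq_len(h), , drop = FALSE])
}

#' Autocorrelation-adjusted effective sample size
#'
#' Estimates `n_eff = (chains * n) / (1 + 2 * sum(rho_t))` where the lag
#' autocorrelations `rho_t` combine chain-averaged autocovariances with
#' the between-chain variance (so non-overlapping chains reduce ESS), and
#' the sum is truncated by Geyer's initial monotone sequence criterion:
#' successive pairs `rho_{2k} + rho_{2k+1}` are kept while positive and
#' forced non-increasing.
#'
#' @inheritParams split_rhat
#' @return Scalar effective sample size; `NaN` for constant draws.
#' @export
effective_sample_size <- function(x) {
  x <- as_chain_matrix(x)
  if (ncol(x) < 2L) stop("at least 2 chains are required", call. = FALSE)
  if (nrow(x) < 4L)
    stop("at least 4 draws per chain are required", call. = FALSE)
  n <- nrow(x); m <- ncol(x)
  chain_var <- apply(x, 2, stats::var)
  W <- mean(chain_var)
  if (W == 0) return(NaN)
  B_over_n <- stats::var(colMeans(x))
  var_plus <- (n - 1) / n * W + B_over_n
  # chain-averaged autocovariances (acf's divisor-n estimator)
  acov <- sapply(seq_len(m), function(j) {
    stats::acf(x[, j], lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus  # rho[1] corresponds to lag 0
  # Geyer initial monotone sequence on pair sums of lags (1,2), (3,4), ...
  max_pairs <- (n - 2) %/% 2
  tau <- 1  # rho_0 contributes 1
  prev <- Inf
  for (k in seq_len(max_pairs)) {
    p <- rho[2 * k] + rho[2 * k + 1]
    if (!is.finite(p) || p < 0) break
    p <- min(p, prev)
    tau <- tau + 2 * p
    prev <- p
  }
  m * n / tau
}

#' Posterior summary table
#'
#' One row per monitored quantity with the classic MCMC summary columns:
#' pooled posterior mean, Monte-Carlo standard error of the mean
#' (`se_mean = sd / sqrt(n_eff)`), pooled SD, the 2.5/25/50/75/97.5%
#' quantiles (interpolated order statistics, quantile type 7), effective
#' sample size and split R-hat. Rows follow the monitored-quantity order
#' of the draws object: per-study `theta` and `alpha` blocks, `beta`, the
#' hyper-parameters, the probability-scale blocks (`pi_1`, `pi_0`, `sn`,
#' `sp`), any `other_snsp` quantities, and `lp__` last.
#'
#' @param draws an `hsroc_draws` object from [run_mcmc()].
#' @return A data.frame of class `hsroc_summary` with columns `name`,
#'   `mean`, `se_mean`, `sd`, `q2.5`, `q25`, `q50`, `q75`, `q97.5`,
#'   `n_eff`, `rhat`.
#' @export
summarize_draws <- function(draws) {
  if (!inherits(draws, "hsroc_draws"))
    stop("draws must come from run_mcmc()", call. = FALSE)
  qn <- dimnames(draws$values)[[3]]
  if (length(qn) == 0L || prod(dim(draws$values)) == 0L)
    stop("no draws to summarize", call. = FALSE)
  rows <- lapply(qn, function(q) {
    m <- draws_matrix(draws, q)
    pooled <- as.numeric(m)
    qs <- stats::quantile(pooled, c(.025, .25, .5, .75, .975),
                          names = FALSE, type = 7)
    sdv <- stats::sd(pooled)
    neff <- effective_sample_size(m)
    data.frame(name = q, mean = mean(pooled),
               se_mean = sdv / sqrt(neff), sd = sdv,
               q2.5 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4],
               q97.5 = qs[5], n_eff = neff, rhat = split_rhat(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hsroc_summary", "data.frame")
  out
}

#' Check MCMC convergence
#'
#' Applies the standard usage rule: results should only be interpreted if
#' the chains converged, operationalised as every monitored quantity's
#' split R-hat (including, in particular, the summary accuracy quantity
#' `other_snsp[max]`) being at or below the threshold. `NaN` R-hat rows
#' (constant draws) are excluded from the maximum but flagged with a
#' warning.
#'
#' @param t an [summarize_draws()] table.
#' @param threshold R-hat acceptance threshold, default 1.1.
#' @return An object of class `hsroc_convergence`: list with `converged`
#'   (logical), `offending` (data.frame of name, rhat for rows above the
#'   threshold), and `threshold`.
#' @export
check_convergence <- function(t, threshold = 1.1) {
  if (!"rhat" %in% names(t))
    stop("summary table has no rhat column", call. = FALSE)
  nan <- is.nan(t$rhat)
  if (any(nan))
    warning("R-hat is undefined (constant draws) for: ",
            paste(t$name[nan], collapse = ", "), call. = FALSE)
  bad <- !nan & t$rhat > threshold
  structure(list(converged = !any(bad),
                 offending = data.frame(name = t$name[bad],
                                        rhat = t$rhat[bad]),
                 threshold = threshold),
            class = "hsroc_convergence")
}

#' @export
print.hsroc_convergence <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Converged: all split R-hat <= %.3g\n", x$threshold))
  } else {
    cat(sprintf("NOT converged: %d quantities above R-hat %.3g\n",
                nrow(x$offending), x$threshold))
    print(x$offending, row.names = FALSE)
    cat("Do not interpret the results until convergence is reached.\n")
  }
  invisible(x)
}

#' @export
print.hsroc_summary <- function(x, ...) {
  cat(sprintf("HSROC posterior summary: %d monitored quantities\n",
              nrow(x)))
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits = 5)
  print.data.frame(y, row.names = FALSE, ...)
  invisible(x)
}
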