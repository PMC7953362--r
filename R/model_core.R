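#' The Rutter-Gatsonis HSROC model
#'
#' @description
#' Each study i in a diagnostic accuracy meta-analysis is modelled on a
#' latent logistic scale by a cut-point (positivity threshold) parameter
#' `theta_i` and an accuracy parameter `alpha_i` (the log diagnostic odds
#' ratio when the curve is symmetric). With disease-group coding
#' X = +1/2 for diseased and -1/2 for non-diseased subjects, the
#' probability of a positive test result is
#'
#' \deqn{logit(\pi_{1i}) = (\theta_i + \alpha_i/2)\, e^{-\beta/2}}
#' \deqn{logit(\pi_{0i}) = (\theta_i - \alpha_i/2)\, e^{+\beta/2}}
#'
#' so `pi1` is study i's sensitivity and `1 - pi0` its specificity; the
#' scale parameter `beta` controls the asymmetry of the summary ROC curve
#' (`beta = 0` gives a curve of constant log diagnostic odds ratio).
#' Across studies, `theta_i ~ N(theta_g, s_theta^2)` and
#' `alpha_i ~ N(alpha_g, s_alpha^2)`; the hyper-mean `alpha_g` is the
#' average location parameter (often written Lambda) that drives the
#' summary-point transform in [sens_at_spec()].
#'
#' `hsroc_params()` bundles one point in this parameter space.
#'
#' @param theta,alpha numeric vectors of per-study parameters, equal
#'   length (one entry per study).
#' @param theta_g,alpha_g hyper-means of `theta` and `alpha`.
#' @param beta scale (asymmetry) parameter.
#' @param s_theta,s_alpha non-negative between-study standard deviations.
#' @return An object of class `hsroc_params` (a named list).
#' @seealso [study_probabilities()], [log_posterior()], [run_mcmc()]
#' @export
hsroc_params <- function(theta, alpha, theta_g, alpha_g, beta,
                         s_theta, s_alpha) {
  if (length(theta) != length(alpha))
    stop("theta and alpha must have one entry per study", call. = FALSE)
  p <- list(theta = as.numeric(theta), alpha = as.numeric(alpha),
            theta_g = as.numeric(theta_g)[1L],
            alpha_g = as.numeric(alpha_g)[1L],
            beta = as.numeric(beta)[1L],
            s_theta = as.numeric(s_theta)[1L],
            s_alpha = as.numeric(s_alpha)[1L])
  scal <- unlist(p[c("theta_g", "alpha_g", "beta", "s_theta", "s_alpha")])
  if (anyNA(c(p$theta, p$alpha, scal)) ||
      any(!is.finite(c(p$theta, p$alpha, scal))))
    stop("all parameter components must be finite", call. = FALSE)
  if (p$s_theta < 0 || p$s_alpha < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  class(p) <- "hsroc_params"
  p
}

#' Prior configuration
#'
#' Non-informative priors: improper flat priors on the hyper-means and the
#' scale parameter (optionally truncated to `(-hypermean_halfwidth,
#' +hypermean_halfwidth)`) and Uniform(0, `sd_upper`) on the two
#' between-study standard deviations. The defaults (`Inf`, `Inf`) give the
#' fully non-informative specification; the posterior is proper whenever
#' the dataset has two or more studies.
#'
#' @param sd_upper upper truncation for the uniform priors on `s_theta`
#'   and `s_alpha`; positive, default `Inf`.
#' @param hypermean_halfwidth half-width of the flat prior on `theta_g`,
#'   `alpha_g` and `beta`; positive, default `Inf` (improper flat).
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(sd_upper = Inf, hypermean_halfwidth = Inf) {
  if (!is.numeric(sd_upper) || length(sd_upper) != 1L || sd_upper <= 0)
    stop("sd_upper must be a positive scalar", call. = FALSE)
  if (!is.numeric(hypermean_halfwidth) || length(hypermean_halfwidth) != 1L ||
      hypermean_halfwidth <= 0)
    stop("hypermean_halfwidth must be a positive scalar", call. = FALSE)
  structure(list(sd_upper = sd_upper,
                 hypermean_halfwidth = hypermean_halfwidth),
            class = "prior_config")
}

#' Within-study positive-test probabilities
#'
#' Evaluates the HSROC link for one or more studies: the probability of a
#' positive test among diseased (`pi1`, the sensitivity) and among
#' non-diseased (`pi0`, one minus the specificity) subjects. Vectorised
#' over `theta_i` and `alpha_i`.
#'
#' @param theta_i,alpha_i study cut-point and accuracy parameters.
#' @param beta scalar scale parameter.
#' @return A list with numeric components `pi1` and `pi0`, both strictly
#'   inside (0, 1).
#' @export
#' @examples
#' study_probabilities(0, 2, 0)  # invlogit(+-1)
study_probabilities <- function(theta_i, alpha_i, beta) {
  if (anyNA(theta_i) || anyNA(alpha_i) || anyNA(beta) ||
      any(!is.finite(c(theta_i, alpha_i, beta))))
    stop("theta_i, alpha_i and beta must be finite", call. = FALSE)
  list(pi1 = clamp01(stats::plogis((theta_i + alpha_i / 2) *
                                     exp(-beta / 2))),
       pi0 = clamp01(stats::plogis((theta_i - alpha_i / 2) *
                                     exp(beta / 2))))
}

# Keep probabilities strictly inside (0,1): plogis saturates to exactly 0
# or 1 in double precision for |x| beyond ~37, which would break logs and
# the open-interval contract on probability-scale quantities.
clamp01 <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

#' Binomial log-likelihood of the HSROC model
#'
#' Sum over studies of the exact binomial log-probabilities of the
#' observed TP count among diseased and FP count among non-diseased
#' subjects, at the within-study probabilities implied by `p`. Zero cells
#' need no continuity correction: the likelihood is finite for any finite
#' parameter values.
#'
#' @param d a [dta_dataset()].
#' @param p an [hsroc_params()] whose study vectors match `nrow(d)`.
#' @return A finite scalar log-likelihood.
#' @export
log_likelihood <- function(d, p) {
  if (length(p$theta) != nrow(d))
    stop("parameter vectors have length ", length(p$theta),
         " but the dataset has ", nrow(d), " studies", call. = FALSE)
  pr <- study_probabilities(p$theta, p$alpha, p$beta)
  sum(stats::dbinom(d$tp, d$tp + d$fn, pr$pi1, log = TRUE)) +
    sum(stats::dbinom(d$fp, d$fp + d$tn, pr$pi0, log = TRUE))
}

#' Log-prior density
#'
#' Flat (zero) inside the support defined by `c`, `-Inf` outside: a
#' standard deviation below zero or at/above `sd_upper`, or a hyper-mean
#' or `beta` outside `(-hypermean_halfwidth, +hypermean_halfwidth)`,
#' excludes the state.
#'
#' @param p an [hsroc_params()].
#' @param c a [prior_config()].
#' @return 0 or `-Inf`.
#' @export
log_prior <- function(p, c = prior_config()) {
  h <- c$hypermean_halfwidth
  ok <- p$s_theta >= 0 && p$s_alpha >= 0 &&
    p$s_theta <= c$sd_upper && p$s_alpha <= c$sd_upper &&
    abs(p$theta_g) <= h && abs(p$alpha_g) <= h && abs(p$beta) <= h
  if (ok) 0 else -Inf
}

#' Log-posterior density (up to a constant)
#'
#' [log_likelihood()] plus the hierarchical normal terms
#' `sum(dnorm(theta_i, theta_g, s_theta, log))` and the analogous sum for
#' `alpha`, plus [log_prior()]. `-Inf` propagates; a zero hyper-SD with
#' any study parameter away from its hyper-mean is degenerate and yields
#' `-Inf` (with all of them exactly at the mean the density is singular
#' and also reported as `-Inf`).
#'
#' @inheritParams log_likelihood
#' @param c a [prior_config()].
#' @return Scalar log-density, possibly `-Inf`.
#' @export
log_posterior <- function(d, p, c = prior_config()) {
  lp <- log_prior(p, c)
  if (!is.finite(lp)) return(-Inf)
  if (p$s_theta == 0 || p$s_alpha == 0) return(-Inf)
  lp + log_likelihood(d, p) +
    sum(stats::dnorm(p$theta, p$theta_g, p$s_theta, log = TRUE)) +
    sum(stats::dnorm(p$alpha, p$alpha_g, p$s_alpha, log = TRUE))
}

#' Simulate a dataset from the HSROC generative model
#'
#' Draws per-study `theta_i`, `alpha_i` from the hyper-normals, converts
#' to within-study probabilities, and draws binomial 2x2 counts. Used for
#' parameter-recovery checks and as a test fixture generator.
#'
#' @param hyper named list or vector with `theta_g`, `alpha_g`, `beta`,
#'   `s_theta`, `s_alpha`.
#' @param n_studies number of studies (>= 2).
#' @param n_diseased,n_nondiseased subjects per group in every study
#'   (>= 1).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return A [dta_dataset()] with studies named `"S1"`, `"S2"`, ...
#' @export
#' @examples
#' simulate_dataset(list(theta_g = 0, alpha_g = 2.5, beta = 0,
#'                       s_theta = 0.5, s_alpha = 0.8),
#'                  n_studies = 5, n_diseased = 100,
#'                  n_nondiseased = 100, seed = 42)
simulate_dataset <- function(hyper, n_studies, n_diseased, n_nondiseased,
                             seed) {
  hyper <- as.list(hyper)
  stopifnot(n_studies >= 2, n_diseased >= 1, n_nondiseased >= 1,
            hyper$s_theta >= 0, hyper$s_alpha >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  theta <- stats::rnorm(n_studies, hyper$theta_g, hyper$s_theta)
  alpha <- stats::rnorm(n_studies, hyper$alpha_g, hyper$s_alpha)
  pr <- study_probabilities(theta, alpha, hyper$beta)
  tp <- stats::rbinom(n_studies, n_diseased, pr$pi1)
  fp <- stats::rbinom(n_studies, n_nondiseased, pr$pi0)
  dta_dataset(paste0("S", seq_len(n_studies)),
              tp = tp, fn = n_diseased - tp,
              fp = fp, tn = n_nondiseased - fp)
}
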