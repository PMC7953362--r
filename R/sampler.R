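#' MCMC configuration
#'
#' Defaults replicate the canonical run configuration: 4 chains, 1000
#' iterations each, 500 warmup, thinning 1, hence 500 retained draws per
#' chain and 2000 in total.
#'
#' @param chains number of chains (>= 2; split R-hat needs at least two).
#' @param iter iterations per chain.
#' @param warmup warmup (adaptation) iterations per chain, `< iter`;
#'   warmup draws are discarded.
#' @param thin keep every `thin`-th post-warmup draw (>= 1).
#' @param seed integer seed driving every stochastic element of the run.
#' @param refine internal oversampling factor (>= 1). The sampler runs
#'   `refine` times more iterations with `refine` times coarser thinning,
#'   so the retained-draw arithmetic (`floor((iter - warmup)/thin)` per
#'   chain) is unchanged while each retained draw is less autocorrelated.
#'   The default 5 gives the random-walk updates an effective sample size
#'   comparable to a Hamiltonian sampler at the same retained-draw count.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4L, iter = 1000L, warmup = 500L,
                        thin = 1L, seed = 1L, refine = 5L) {
  chains <- as.integer(chains); iter <- as.integer(iter)
  warmup <- as.integer(warmup); thin <- as.integer(thin)
  refine <- as.integer(refine)
  if (chains < 2L)
    stop("at least 2 chains are required (split R-hat)", call. = FALSE)
  if (warmup >= iter) stop("warmup must be < iter", call. = FALSE)
  if (thin < 1L) stop("thin must be >= 1", call. = FALSE)
  if (refine < 1L) stop("refine must be >= 1", call. = FALSE)
  if (floor((iter - warmup) / thin) < 1L)
    stop("configuration retains no draws", call. = FALSE)
  structure(list(chains = chains, iter = iter, warmup = warmup,
                 thin = thin, seed = as.integer(seed), refine = refine),
            class = "mcmc_config")
}

#' Empirical-logit chain initialization
#'
#' Sets each study's parameters from its continuity-corrected empirical
#' logits (0.5 added to every cell, for initialization only): with
#' `l1 = logit((tp + 0.5)/(tp + fn + 1))` and
#' `l0 = logit((fp + 0.5)/(fp + tn + 1))`, `theta_i = (l1 + l0)/2` and
#' `alpha_i = l1 - l0`; hyper-parameters from the empirical moments of
#' those vectors, `beta = 0`. Optionally jitters every component with the
#' current RNG so chains start overdispersed.
#'
#' @param d a [dta_dataset()].
#' @param jitter standard deviation of Gaussian jitter added to each
#'   location component (half of it, on the log scale, to the SDs);
#'   0 gives the deterministic empirical start.
#' @return An [hsroc_params()].
#' @export
initialize_chain <- function(d, jitter = 0) {
  l1 <- stats::qlogis((d$tp + 0.5) / (d$tp + d$fn + 1))
  l0 <- stats::qlogis((d$fp + 0.5) / (d$fp + d$tn + 1))
  theta <- (l1 + l0) / 2
  alpha <- l1 - l0
  s_th <- max(stats::sd(theta), 0.05)
  s_al <- max(stats::sd(alpha), 0.05)
  if (jitter > 0) {
    n <- length(theta)
    theta <- theta + stats::rnorm(n, 0, jitter)
    alpha <- alpha + stats::rnorm(n, 0, jitter)
    tg <- mean(theta) + stats::rnorm(1, 0, jitter)
    ag <- mean(alpha) + stats::rnorm(1, 0, jitter)
    be <- stats::rnorm(1, 0, jitter)
    s_th <- s_th * exp(stats::rnorm(1, 0, jitter / 2))
    s_al <- s_al * exp(stats::rnorm(1, 0, jitter / 2))
  } else {
    tg <- mean(theta); ag <- mean(alpha); be <- 0
  }
  hsroc_params(theta, alpha, tg, ag, be, s_th, s_al)
}

# Binomial log-likelihood per study at given (theta, alpha, beta);
# vectorised over studies.
.ll_study <- function(d, theta, alpha, beta) {
  pr <- study_probabilities(theta, alpha, beta)
  stats::dbinom(d$tp, d$tp + d$fn, pr$pi1, log = TRUE) +
    stats::dbinom(d$fp, d$fp + d$tn, pr$pi0, log = TRUE)
}

# Draw sigma^2 from its inverse-gamma full conditional under the flat
# prior on sigma, truncated to sigma <= sd_upper via the inverse CDF.
.gibbs_var <- function(x, mu, sd_upper) {
  n <- length(x)
  ss <- sum((x - mu)^2)
  shape <- (n - 1) / 2
  rate <- ss / 2
  lo <- if (is.finite(sd_upper)) rate / sd_upper^2 else 0
  plo <- stats::pgamma(lo, shape)
  u <- stats::runif(1, plo, 1)
  g <- stats::qgamma(pmin(u, 1 - 1e-16), shape)
  rate / max(g, 1e-300)
}

# Draw a hyper-mean from N(mean(x), sigma^2/n), truncated to
# [-halfwidth, halfwidth] via the inverse CDF.
.gibbs_mean <- function(x, sigma, halfwidth) {
  m <- mean(x); s <- sigma / sqrt(length(x))
  if (!is.finite(halfwidth))
    return(stats::rnorm(1, m, s))
  plo <- stats::pnorm(-halfwidth, m, s)
  phi <- stats::pnorm(halfwidth, m, s)
  stats::qnorm(stats::runif(1, plo, phi), m, s)
}

#' Draw from the HSROC posterior
#'
#' Samples the joint posterior of the model described in [hsroc_params()]
#' with a blocked sampler: adaptive joint random-walk Metropolis for each
#' study's `(theta_i, alpha_i)` pair (studies are conditionally
#' independent given the hyper-parameters, so all pairs update in one
#' vectorised sweep) and for `beta`; exact Gibbs draws for the
#' hyper-means (truncated normal) and the hyper-variances (the flat prior
#' on the SD induces an inverse-gamma full conditional on the variance).
#' Proposal scales adapt during warmup toward 25-45% acceptance and are
#' frozen afterwards. Identical `(d, config, prior, target, fix, seed)`
#' give byte-identical draws.
#'
#' @param d a [dta_dataset()] (validated on entry).
#' @param config an [mcmc_config()].
#' @param prior a [prior_config()].
#' @param target optional [fixed_target()]; when supplied the returned
#'   draws already include the `other_snsp` quantities via
#'   [derived_quantities()].
#' @param fix optional named list pinning `beta`, `s_theta` and/or
#'   `s_alpha` at constants (the pinned blocks are skipped). Setting both
#'   SDs to 0 collapses the model to two pooled binomials: all studies
#'   share `theta_g` and `alpha_g`, which are then updated jointly by
#'   Metropolis. Fixing only one SD to 0 is not supported.
#' @return An object of class `hsroc_draws`: a list with `values` (array
#'   indexed chain x draw x quantity, with quantity dimnames), `config`,
#'   `prior`, `study_names`, and per-chain Metropolis acceptance rates.
#' @export
#' @examples
#' d <- example_dataset()
#' fit <- run_mcmc(d, mcmc_config(seed = 7, iter = 200, warmup = 100,
#'                                refine = 1))
#' dim(fit$values)
run_mcmc <- function(d, config = mcmc_config(), prior = prior_config(),
                     target = NULL, fix = NULL) {
  validate_dataset(d, warn = FALSE)
  if (!inherits(config, "mcmc_config"))
    stop("config must be an mcmc_config()", call. = FALSE)
  if (!inherits(prior, "prior_config"))
    stop("prior must be a prior_config()", call. = FALSE)
  n <- nrow(d)
  fix <- as.list(fix)
  bad_fix <- setdiff(names(fix), c("beta", "s_theta", "s_alpha"))
  if (length(bad_fix))
    stop("cannot fix: ", paste(bad_fix, collapse = ", "), call. = FALSE)
  collapsed <- identical(fix$s_theta, 0) && identical(fix$s_alpha, 0)
  if (!collapsed &&
      (identical(fix$s_theta, 0) || identical(fix$s_alpha, 0)))
    stop("fixing a single SD at 0 is not supported; fix both to ",
         "collapse the hierarchy", call. = FALSE)

  iter_i <- config$iter * config$refine
  warm_i <- config$warmup * config$refine
  thin_i <- config$thin * config$refine
  n_keep <- floor((config$iter - config$warmup) / config$thin)

  qn <- c(paste0("theta[", seq_len(n), "]"),
          paste0("alpha[", seq_len(n), "]"),
          "beta", "theta_g", "alpha_g", "s_theta", "s_alpha",
          paste0("pi_1[", seq_len(n), "]"),
          paste0("pi_0[", seq_len(n), "]"),
          paste0("sn[", seq_len(n), "]"),
          paste0("sp[", seq_len(n), "]"),
          "lp__")
  values <- array(NA_real_, dim = c(config$chains, n_keep, length(qn)),
                  dimnames = list(NULL, NULL, qn))
  accept <- matrix(NA_real_, config$chains, 2,
                   dimnames = list(NULL, c("study_pairs", "beta")))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  for (ch in seq_len(config$chains)) {
    st <- NULL
    for (try in 1:50) {
      cand <- initialize_chain(d, jitter = if (try == 1 && ch == 1) 0
                               else 0.5)
      if (!is.null(fix$beta)) cand$beta <- fix$beta
      if (!is.null(fix$s_theta)) cand$s_theta <- max(fix$s_theta, 0)
      if (!is.null(fix$s_alpha)) cand$s_alpha <- max(fix$s_alpha, 0)
      if (collapsed) {
        cand$theta <- rep(cand$theta_g, n)
        cand$alpha <- rep(cand$alpha_g, n)
      }
      h <- prior$hypermean_halfwidth
      cand$theta_g <- max(min(cand$theta_g, h), -h)
      cand$alpha_g <- max(min(cand$alpha_g, h), -h)
      cand$beta <- max(min(cand$beta, h), -h)
      if (is.finite(prior$sd_upper)) {
        cand$s_theta <- min(cand$s_theta, 0.9 * prior$sd_upper)
        cand$s_alpha <- min(cand$s_alpha, 0.9 * prior$sd_upper)
      }
      lp0 <- if (collapsed)
        sum(.ll_study(d, cand$theta, cand$alpha, cand$beta))
      else log_posterior(d, cand, prior)
      if (is.finite(lp0)) { st <- cand; break }
    }
    if (is.null(st))
      stop("could not find a finite-posterior initial state", call. = FALSE)

    theta <- st$theta; alpha <- st$alpha
    tg <- st$theta_g; ag <- st$alpha_g; be <- st$beta
    s_th <- st$s_theta; s_al <- st$s_alpha
    ll <- .ll_study(d, theta, alpha, be)
    h <- prior$hypermean_halfwidth

    # per-study proposal scales (shared by the pair), plus beta's two
    # move types (conditional random walk, likelihood-invariant ridge)
    lsc <- rep(log(0.5), n)
    lsc_b <- log(0.3)
    lsc_r <- log(0.5)
    acc_n <- 0; acc_d <- 0; accb_n <- 0; accb_d <- 0
    k <- 0L

    for (t in seq_len(iter_i)) {
      adapting <- t <= warm_i
      if (!collapsed) {
        ## --- per-study (theta_i, alpha_i) pairs, one vectorised sweep
        sc <- exp(lsc)
        th_p <- theta + sc * stats::rnorm(n)
        al_p <- alpha + sc * stats::rnorm(n)
        ll_p <- .ll_study(d, th_p, al_p, be)
        dlp <- ll_p - ll +
          stats::dnorm(th_p, tg, s_th, log = TRUE) -
          stats::dnorm(theta, tg, s_th, log = TRUE) +
          stats::dnorm(al_p, ag, s_al, log = TRUE) -
          stats::dnorm(alpha, ag, s_al, log = TRUE)
        acc <- log(stats::runif(n)) < dlp
        theta[acc] <- th_p[acc]; alpha[acc] <- al_p[acc]
        ll[acc] <- ll_p[acc]
        if (adapting)
          lsc <- lsc + (as.numeric(acc) - 0.35) * min(0.25, 3 / sqrt(t))
        if (!adapting) { acc_n <- acc_n + sum(acc); acc_d <- acc_d + n }

        ## --- beta (random walk, full likelihood)
        if (is.null(fix$beta)) {
          be_p <- be + exp(lsc_b) * stats::rnorm(1)
          if (abs(be_p) <= h) {
            ll_p <- .ll_study(d, theta, alpha, be_p)
            ok <- log(stats::runif(1)) < sum(ll_p) - sum(ll)
            if (ok) { be <- be_p; ll <- ll_p }
          } else ok <- FALSE
          if (adapting)
            lsc_b <- lsc_b + (as.numeric(ok) - 0.35) * min(0.25, 3 / sqrt(t))
          if (!adapting) { accb_n <- accb_n + ok; accb_d <- accb_d + 1 }
        }

        ## --- beta ridge move: propose beta jointly with the per-study
        ## rescaling that keeps both within-study logits (and hence the
        ## likelihood) exactly fixed. In u = theta + alpha/2,
        ## v = theta - alpha/2 coordinates the map is u -> c*u, v -> v/c
        ## with c = exp((beta' - beta)/2), so the Jacobian is 1 and the
        ## acceptance ratio involves only the hierarchy terms.
        if (is.null(fix$beta)) {
          be_p <- be + exp(lsc_r) * stats::rnorm(1)
          if (abs(be_p) <= h) {
            cc <- exp((be_p - be) / 2)
            u <- (theta + alpha / 2) * cc
            v <- (theta - alpha / 2) / cc
            th_p <- (u + v) / 2
            al_p <- u - v
            dlp <- sum(stats::dnorm(th_p, tg, s_th, log = TRUE) -
                         stats::dnorm(theta, tg, s_th, log = TRUE) +
                         stats::dnorm(al_p, ag, s_al, log = TRUE) -
                         stats::dnorm(alpha, ag, s_al, log = TRUE))
            ok <- log(stats::runif(1)) < dlp
            if (ok) { be <- be_p; theta <- th_p; alpha <- al_p }
          } else ok <- FALSE
          if (adapting)
            lsc_r <- lsc_r + (as.numeric(ok) - 0.35) * min(0.25, 3 / sqrt(t))
        }

        ## --- hyper-variances (Gibbs), then hyper-means (Gibbs)
        if (is.null(fix$s_theta))
          s_th <- sqrt(.gibbs_var(theta, tg, prior$sd_upper))
        if (is.null(fix$s_alpha))
          s_al <- sqrt(.gibbs_var(alpha, ag, prior$sd_upper))
        tg <- .gibbs_mean(theta, s_th, h)
        ag <- .gibbs_mean(alpha, s_al, h)
      } else {
        ## --- collapsed pooled model: joint RW on (theta_g, alpha_g)
        sc <- exp(lsc[1])
        tg_p <- tg + sc * stats::rnorm(1)
        ag_p <- ag + sc * stats::rnorm(1)
        if (abs(tg_p) <= h && abs(ag_p) <= h) {
          ll_p <- .ll_study(d, rep(tg_p, n), rep(ag_p, n), be)
          ok <- log(stats::runif(1)) < sum(ll_p) - sum(ll)
          if (ok) { tg <- tg_p; ag <- ag_p; ll <- ll_p }
        } else ok <- FALSE
        if (adapting)
          lsc[1] <- lsc[1] + (as.numeric(ok) - 0.35) * min(0.25, 3 / sqrt(t))
        if (!adapting) { acc_n <- acc_n + ok; acc_d <- acc_d + 1 }
        theta <- rep(tg, n); alpha <- rep(ag, n)
        if (is.null(fix$beta)) {
          be_p <- be + exp(lsc_b) * stats::rnorm(1)
          if (abs(be_p) <= h) {
            ll_p <- .ll_study(d, theta, alpha, be_p)
            okb <- log(stats::runif(1)) < sum(ll_p) - sum(ll)
            if (okb) { be <- be_p; ll <- ll_p }
          } else okb <- FALSE
          if (adapting)
            lsc_b <- lsc_b + (as.numeric(okb) - 0.35) * min(0.25, 3 / sqrt(t))
          if (!adapting) { accb_n <- accb_n + okb; accb_d <- accb_d + 1 }
        }
      }

      ## --- store retained state
      if (t > warm_i && (t - warm_i) %% thin_i == 0L && k < n_keep) {
        k <- k + 1L
        pr <- study_probabilities(theta, alpha, be)
        lp <- sum(ll)
        if (!collapsed)
          lp <- lp + sum(stats::dnorm(theta, tg, s_th, log = TRUE)) +
            sum(stats::dnorm(alpha, ag, s_al, log = TRUE))
        values[ch, k, ] <- c(theta, alpha, be, tg, ag, s_th, s_al,
                             pr$pi1, pr$pi0, pr$pi1, 1 - pr$pi0, lp)
      }
    }
    accept[ch, ] <- c(if (acc_d) acc_n / acc_d else NA_real_,
                      if (accb_d) accb_n / accb_d else NA_real_)
  }

  draws <- structure(list(values = values, config = config, prior = prior,
                          study_names = d$study_name, accept = accept,
                          target = NULL),
                     class = "hsroc_draws")
  if (!is.null(target)) draws <- derived_quantities(draws, target)
  draws
}

#' @export
print.hsroc_draws <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf(paste0("HSROC posterior draws: %d chains x %d draws, ",
                     "%d monitored quantities\n"), dm[1], dm[2], dm[3]))
  cat(sprintf("  studies: %d; seed: %d; iter=%d warmup=%d thin=%d\n",
              length(x$study_names), x$config$seed, x$config$iter,
              x$config$warmup, x$config$thin))
  if (!is.null(x$target))
    cat(sprintf("  fixed %s = %g\n", x$target$fixed_measure,
                x$target$value))
  invisible(x)
}

# Pooled draws of one monitored quantity as a draws x chains matrix.
draws_matrix <- function(draws, quantity) {
  qn <- dimnames(draws$values)[[3]]
  if (!quantity %in% qn)
    stop("quantity '", quantity, "' is not monitored", call. = FALSE)
  m <- draws$values[, , quantity]
  if (is.null(dim(m))) m <- matrix(m, nrow = dim(draws$values)[1])
  t(m)
}
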