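test_that("the HSROC link gives the expected within-study probabilities", {
  p <- study_probabilities(0, 0, 0)
  expect_equal(p$pi1, 0.5)
  expect_equal(p$pi0, 0.5)

  p <- study_probabilities(0, 2, 0)
  expect_equal(p$pi1, 0.731059, tolerance = 1e-5)
  expect_equal(p$pi0, 0.268941, tolerance = 1e-5)

  # frozen from an independent high-precision evaluation of the link
  p <- study_probabilities(0.5, 3.0, 0.2)
  expect_equal(p$pi1, 0.8593226, tolerance = 1e-6)
  expect_equal(p$pi0, 0.2487723, tolerance = 1e-6)

  expect_error(study_probabilities(Inf, 0, 0), "finite")
  expect_error(study_probabilities(0, NA, 0), "finite")
})

test_that("with beta = 0 the log-DOR equals alpha for any cut-point", {
  for (theta in seq(-3, 3, by = 0.75)) {
    for (alpha in c(-1, 0.5, 2, 4)) {
      p <- study_probabilities(theta, alpha, 0)
      expect_equal(stats::qlogis(p$pi1) - stats::qlogis(p$pi0), alpha,
                   tolerance = 1e-10)
    }
  }
})

test_that("the binomial log-likelihood matches closed forms and is finite with zero cells", {
  d1 <- data.frame(study_name = "x", tp = 1, fn = 1, fp = 1, tn = 1)
  p1 <- hsroc_params(0, 0, 0, 0, 0, 1, 1)
  expect_equal(log_likelihood(d1, p1), 2 * log(0.5), tolerance = 1e-9)

  dz <- data.frame(study_name = c("a", "b"), tp = c(0, 5), fn = c(5, 0),
                   fp = c(3, 0), tn = c(0, 7))
  pz <- hsroc_params(c(0, 0), c(1, 1), 0, 1, 0, 1, 1)
  expect_true(is.finite(log_likelihood(dz, pz)))

  expect_error(log_likelihood(example_dataset(), p1), "9 studies")
})

test_that("the single-study likelihood peaks at the empirical logits", {
  d1 <- data.frame(study_name = "x", tp = 30, fn = 10, fp = 5, tn = 35)
  th_hat <- (stats::qlogis(30 / 40) + stats::qlogis(5 / 40)) / 2
  al_hat <- stats::qlogis(30 / 40) - stats::qlogis(5 / 40)
  at_mode <- log_likelihood(
    d1, hsroc_params(th_hat, al_hat, 0, 0, 0, 1, 1))
  for (dt in seq(-1, 1, by = 0.25)) {
    for (da in seq(-1, 1, by = 0.25)) {
      if (dt == 0 && da == 0) next
      ll <- log_likelihood(
        d1, hsroc_params(th_hat + dt, al_hat + da, 0, 0, 0, 1, 1))
      expect_lt(ll, at_mode)
    }
  }
})

test_that("the flat prior excludes states outside its support", {
  inside <- hsroc_params(0, 0, 0, 2, 0.1, 0.5, 0.5)
  expect_identical(log_prior(inside, prior_config()), 0)
  neg_sd <- inside; neg_sd$s_theta <- -0.1
  expect_identical(log_prior(neg_sd, prior_config()), -Inf)
  wide_beta <- hsroc_params(0, 0, 0, 2, 9, 0.5, 0.5)
  expect_identical(
    log_prior(wide_beta, prior_config(hypermean_halfwidth = 5)), -Inf)
  big_sd <- hsroc_params(0, 0, 0, 2, 0, 3, 0.5)
  expect_identical(log_prior(big_sd, prior_config(sd_upper = 2)), -Inf)
})

test_that("log-posterior matches a term-by-term brute-force oracle", {
  d <- example_dataset()
  set.seed(11)
  for (rep in 1:25) {
    p <- random_valid_params(nrow(d))
    expect_equal(log_posterior(d, p),
                 oracle_log_posterior(d, p),
                 tolerance = 1e-10)
  }
  # truncated priors too
  cfg <- prior_config(sd_upper = 1.5, hypermean_halfwidth = 3)
  set.seed(12)
  for (rep in 1:25) {
    p <- random_valid_params(nrow(d))
    expect_equal(log_posterior(d, p, cfg),
                 oracle_log_posterior(d, p, 1.5, 3),
                 tolerance = 1e-10)
  }
})

test_that("log-posterior is additive over studies and order-invariant", {
  d <- example_dataset()
  set.seed(21)
  p <- random_valid_params(nrow(d))
  full <- log_posterior(d, p)

  i <- 4L
  d_minus <- d[-i, ]
  p_minus <- hsroc_params(p$theta[-i], p$alpha[-i], p$theta_g,
                          p$alpha_g, p$beta, p$s_theta, p$s_alpha)
  pr <- study_probabilities(p$theta[i], p$alpha[i], p$beta)
  study_terms <-
    stats::dbinom(d$tp[i], d$tp[i] + d$fn[i], pr$pi1, log = TRUE) +
    stats::dbinom(d$fp[i], d$fp[i] + d$tn[i], pr$pi0, log = TRUE) +
    stats::dnorm(p$theta[i], p$theta_g, p$s_theta, log = TRUE) +
    stats::dnorm(p$alpha[i], p$alpha_g, p$s_alpha, log = TRUE)
  expect_equal(full, log_posterior(d_minus, p_minus) + study_terms,
               tolerance = 1e-10)

  perm <- c(3, 1, 9, 5, 4, 2, 8, 7, 6)
  d_perm <- d[perm, ]
  p_perm <- hsroc_params(p$theta[perm], p$alpha[perm], p$theta_g,
                         p$alpha_g, p$beta, p$s_theta, p$s_alpha)
  expect_equal(full, log_posterior(d_perm, p_perm), tolerance = 1e-12)

  degen <- p; degen$s_theta <- 0
  expect_identical(log_posterior(d, degen), -Inf)
})

test_that("the simulator is reproducible and obeys the generative model", {
  hyper <- list(theta_g = 0.3, alpha_g = 2, beta = 0,
                s_theta = 0.4, s_alpha = 0.6)
  a <- simulate_dataset(hyper, 9, 100, 120, seed = 99)
  b <- simulate_dataset(hyper, 9, 100, 120, seed = 99)
  expect_identical(a, b)
  expect_equal(nrow(a), 9L)
  expect_true(all(a$tp + a$fn == 100L))
  expect_true(all(a$fp + a$tn == 120L))

  # with no between-study variation and beta = 0, the empirical log-DOR
  # of every study converges to alpha_g (law of large numbers at n=1e5)
  big <- simulate_dataset(list(theta_g = 0.3, alpha_g = 2, beta = 0,
                               s_theta = 0, s_alpha = 0),
                          5, 1e5, 1e5, seed = 7)
  ldor <- stats::qlogis(big$tp / (big$tp + big$fn)) -
    stats::qlogis(big$fp / (big$fp + big$tn))
  expect_true(all(abs(ldor - 2) < 0.06))
})
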