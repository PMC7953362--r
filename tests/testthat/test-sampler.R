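test_that("the retained-draw arithmetic follows the configuration", {
  d <- tiny_dataset()
  fit <- run_mcmc(d, mcmc_config(seed = 3, iter = 100, warmup = 50,
                                 refine = 1))
  expect_equal(dim(fit$values)[1:2], c(4L, 50L))

  fit5 <- run_mcmc(d, mcmc_config(seed = 3, iter = 100, warmup = 50,
                                  thin = 5, refine = 1))
  expect_equal(dim(fit5$values)[2], 10L)

  # the internal refinement factor must not change the retained count
  fit_r <- run_mcmc(d, mcmc_config(seed = 3, iter = 100, warmup = 50,
                                   refine = 3))
  expect_equal(dim(fit_r$values)[1:2], c(4L, 50L))

  expect_error(mcmc_config(chains = 1), "2 chains")
  expect_error(mcmc_config(iter = 100, warmup = 100), "warmup")
  expect_error(mcmc_config(thin = 0), "thin")
})

test_that("identical seeds give byte-identical draws, different seeds differ", {
  d <- tiny_dataset()
  cfg <- mcmc_config(seed = 42, iter = 120, warmup = 60, refine = 1)
  a <- run_mcmc(d, cfg)
  b <- run_mcmc(d, cfg)
  expect_identical(a$values, b$values)
  c2 <- run_mcmc(d, mcmc_config(seed = 43, iter = 120, warmup = 60,
                                refine = 1))
  expect_false(identical(a$values, c2$values))
})

test_that("run_mcmc does not disturb the caller's RNG stream", {
  d <- tiny_dataset()
  set.seed(500)
  before <- stats::rnorm(3)
  set.seed(500)
  invisible(run_mcmc(d, mcmc_config(seed = 9, iter = 60, warmup = 30,
                                    refine = 1)))
  expect_identical(stats::rnorm(3), before)
})

test_that("empirical-logit initialization matches hand arithmetic", {
  d <- example_dataset()
  init <- initialize_chain(d, jitter = 0)
  # logit(90.5/101) - logit(20.5/101), continuity-corrected counts
  expect_equal(init$alpha[1], 3.5218069, tolerance = 1e-6)
  expect_equal(init$beta, 0)
  expect_equal(init$theta_g, mean(init$theta))

  bal <- dta_dataset(c("A", "B"), tp = c(20, 30), fn = c(20, 30),
                     fp = c(15, 25), tn = c(15, 25))
  expect_equal(initialize_chain(bal, jitter = 0)$theta,
               c(0, 0), tolerance = 1e-12)

  init2 <- initialize_chain(d, jitter = 0)
  expect_identical(init, init2)
})

test_that("monitored quantities respect their supports", {
  fit <- run_mcmc(tiny_dataset(),
                  mcmc_config(seed = 5, iter = 200, warmup = 100,
                              refine = 1),
                  target = fixed_target("specificity", 0.7))
  expect_true(all(is.finite(fit$values)))
  qn <- dimnames(fit$values)[[3]]
  for (q in qn[grepl("^(pi_|sn|sp|other_snsp)", qn)]) {
    x <- fit$values[, , q]
    expect_true(all(x > 0 & x < 1), info = q)
  }
  expect_true(all(fit$values[, , "s_theta"] >= 0))
  expect_true(all(fit$values[, , "s_alpha"] >= 0))
})

test_that("the collapsed pooled model matches 2-D grid quadrature", {
  # with both hierarchy SDs pinned at 0 and beta at 0, all studies share
  # one (theta_g, alpha_g) and the posterior is two pooled binomials
  d <- tiny_dataset()
  fit <- run_mcmc(d, mcmc_config(seed = 31, refine = 2),
                  fix = list(beta = 0, s_theta = 0, s_alpha = 0))
  tab <- summarize_draws(fit)
  for (q in c("pi_1[1]", "pi_0[1]", "theta_g", "alpha_g")) {
    row <- tab[tab$name == q, ]
    truth <- oracle_collapsed_moment(d, 0, switch(
      q,
      "pi_1[1]" = function(th, al, pi1, pi0) pi1,
      "pi_0[1]" = function(th, al, pi1, pi0) pi0,
      "theta_g" = function(th, al, pi1, pi0) th,
      "alpha_g" = function(th, al, pi1, pi0) al))
    expect_lt(abs(row$mean - truth), 3 * row$se_mean + 1e-4,
              label = paste(q, "vs quadrature"))
  }
  # every draw honours the pinned values
  expect_true(all(fit$values[, , "beta"] == 0))
  expect_true(all(fit$values[, , "s_theta"] == 0))
  expect_equal(fit$values[, , "theta[2]"], fit$values[, , "theta_g"])
})

test_that("fixing a single SD at zero is rejected", {
  expect_error(run_mcmc(tiny_dataset(), mcmc_config(seed = 1),
                        fix = list(s_theta = 0)),
               "not supported")
  expect_error(run_mcmc(tiny_dataset(), mcmc_config(seed = 1),
                        fix = list(gamma = 1)),
               "cannot fix")
})

test_that("simulate-then-fit recovers hyper-parameters within credible intervals", {
  truth <- list(theta_g = 0.2, alpha_g = 2.5, beta = 0.2,
                s_theta = 0.5, s_alpha = 0.6)
  d <- simulate_dataset(truth, n_studies = 25, n_diseased = 500,
                        n_nondiseased = 500, seed = 81)
  fit <- run_mcmc(d, mcmc_config(seed = 82, refine = 2))
  tab <- summarize_draws(fit)
  hits <- vapply(names(truth), function(q) {
    row <- tab[tab$name == q, ]
    row$q2.5 <= truth[[q]] && truth[[q]] <= row$q97.5
  }, logical(1))
  # one narrow miss among five intervals is within nominal behaviour
  expect_gte(sum(hits), 4L)
})
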