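test_that("the summary ROC transform matches closed forms", {
  expect_equal(sens_at_spec(2, 0, 0.5), stats::plogis(2),
               tolerance = 1e-9)
  for (s in c(0.1, 0.3, 0.5, 0.8, 0.95))
    expect_equal(sens_at_spec(0, 0, s), 1 - s, tolerance = 1e-12)
  # frozen from an independent high-precision evaluation at the worked
  # example's posterior means; the plug-in value deliberately differs
  # from the posterior mean of the transform (mean of transform !=
  # transform of means)
  expect_equal(sens_at_spec(2.711888, 0.138255, 0.8), 0.7897574,
               tolerance = 1e-6)
  expect_equal(spec_at_sens(2.711888, 0.138255, 0.7897574), 0.8,
               tolerance = 1e-6)
  expect_equal(spec_at_sens(0, 0, 0.3), 0.7, tolerance = 1e-12)
  expect_error(sens_at_spec(2, 0, 1), "inside")
  expect_error(spec_at_sens(2, 0, 0), "inside")
})

test_that("spec_at_sens is the exact algebraic inverse of sens_at_spec", {
  grid <- expand.grid(Lambda = c(-1, 0, 1.5, 3),
                      beta = c(-0.8, 0, 0.4, 1.2),
                      s = c(0.05, 0.3, 0.5, 0.8, 0.99))
  sens <- sens_at_spec(grid$Lambda, grid$beta, grid$s)
  expect_equal(spec_at_sens(grid$Lambda, grid$beta, sens), grid$s,
               tolerance = 1e-10)
})

test_that("the transform is monotone in Lambda and in the fixed specificity", {
  for (beta in c(-0.5, 0, 0.7)) {
    lam <- seq(-2, 4, by = 0.25)
    expect_true(all(diff(sens_at_spec(lam, beta, 0.8)) > 0))
    sp <- seq(0.05, 0.95, by = 0.05)
    expect_true(all(diff(sens_at_spec(1.5, beta, sp)) < 0))
  }
})

test_that("derived quantities use per-study alpha and the hyper-mean correctly", {
  # two identical states so every summary statistic is exact
  fd <- fake_draws(list("alpha[1]" = c(2, 2), "alpha[2]" = c(1, 1),
                        "alpha_g" = c(2, 2), "beta" = c(0, 0),
                        "lp__" = c(-1, -1)),
                   c("A", "B"))
  aug <- derived_quantities(fd, fixed_target("specificity", 0.5))
  qn <- dimnames(aug$values)[[3]]
  expect_equal(qn[length(qn)], "lp__")
  expect_true(all(c("other_snsp[1]", "other_snsp[2]", "other_snsp[max]")
                  %in% qn))
  expect_equal(unique(as.numeric(aug$values[, , "other_snsp[1]"])),
               0.880797, tolerance = 1e-6)
  expect_equal(aug$values[, , "other_snsp[max]"],
               aug$values[, , "other_snsp[1]"])
  expect_equal(unique(as.numeric(aug$values[, , "other_snsp[2]"])),
               stats::plogis(1), tolerance = 1e-9)

  # fixing sensitivity swaps to the inverse transform
  aug2 <- derived_quantities(fd, fixed_target("sensitivity", 0.8))
  expect_equal(unique(as.numeric(aug2$values[, , "other_snsp[max]"])),
               spec_at_sens(2, 0, 0.8), tolerance = 1e-9)

  fd_missing <- fake_draws(list("alpha[1]" = c(2, 2)), c("A", "B"))
  expect_error(derived_quantities(fd_missing,
                                  fixed_target("specificity", 0.5)),
               "missing monitored")
})

test_that("per-draw identities tie the probability-scale blocks together", {
  fit <- run_mcmc(tiny_dataset(),
                  mcmc_config(seed = 66, iter = 200, warmup = 100,
                              refine = 1),
                  target = fixed_target("specificity", 0.8))
  for (i in 1:3) {
    expect_identical(fit$values[, , paste0("sn[", i, "]")],
                     fit$values[, , paste0("pi_1[", i, "]")])
    expect_equal(fit$values[, , paste0("sp[", i, "]")] +
                   fit$values[, , paste0("pi_0[", i, "]")],
                 array(1, dim(fit$values)[1:2]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("summary_point pools draws into an estimate and 95% CrI", {
  fd <- fake_draws(list("alpha[1]" = c(2, 2), "alpha_g" = c(2, 2),
                        "beta" = c(0, 0)), "A")
  aug <- derived_quantities(fd, fixed_target("specificity", 0.5))
  sp <- summary_point(aug)
  expect_equal(sp$estimate, 0.880797, tolerance = 1e-6)
  expect_equal(sp$cri_low, sp$cri_high)
  expect_equal(sp$measure, "sensitivity")

  set.seed(70)
  x <- stats::plogis(stats::rnorm(400, 1, 0.5))
  fd2 <- fake_draws(list("alpha[1]" = x, "alpha_g" = x,
                         "beta" = rep(0, 400)), "A")
  aug2 <- derived_quantities(fd2, fixed_target("specificity", 0.5))
  sp2 <- summary_point(aug2)
  med <- stats::median(as.numeric(aug2$values[, , "other_snsp[max]"]))
  expect_lte(sp2$cri_low, med)
  expect_gte(sp2$cri_high, med)
  expect_error(summary_point(fd2), "fixed_target")
})

test_that("fixed_target validates its value", {
  expect_error(fixed_target("specificity", 1.2), "inside")
  expect_error(fixed_target("specificity", 0), "inside")
  tg <- fixed_target("sensitivity", 0.9)
  expect_equal(tg$estimated, "specificity")
})
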