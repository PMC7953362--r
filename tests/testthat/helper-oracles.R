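# Shared fixtures and independent oracles for the test suite.

# The worked nine-study example as literal CSV text (numeric IDs).
example_csv_text <- function() {
  paste(
    "study_name,TP,FN,FP,TN",
    "1,90,10,20,80", "2,40,10,5,45", "3,60,40,10,90",
    "4,200,50,100,200", "5,10,5,5,15", "6,80,20,10,90",
    "7,60,40,30,70", "8,8,2,1,9", "9,250,50,100,200",
    sep = "\n")
}

tiny_dataset <- function() {
  dta_dataset(c("A", "B", "C"),
              tp = c(30, 18, 45), fn = c(10, 12, 15),
              fp = c(5, 4, 12), tn = c(35, 26, 48))
}

# --- brute-force log-posterior oracle -------------------------------------
# Written term by term from first principles (lgamma binomials, explicit
# normal densities); independent of the package's vectorised path.
oracle_log_binom <- function(k, n, p) {
  lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1) +
    k * log(p) + (n - k) * log1p(-p)
}

oracle_log_norm <- function(x, m, s) {
  -0.5 * log(2 * pi) - log(s) - (x - m)^2 / (2 * s^2)
}

oracle_log_posterior <- function(d, p, sd_upper = Inf, halfwidth = Inf) {
  if (p$s_theta <= 0 || p$s_alpha <= 0 ||
      p$s_theta > sd_upper || p$s_alpha > sd_upper ||
      abs(p$theta_g) > halfwidth || abs(p$alpha_g) > halfwidth ||
      abs(p$beta) > halfwidth)
    return(-Inf)
  total <- 0
  for (i in seq_len(nrow(d))) {
    pi1 <- 1 / (1 + exp(-((p$theta[i] + p$alpha[i] / 2) *
                            exp(-p$beta / 2))))
    pi0 <- 1 / (1 + exp(-((p$theta[i] - p$alpha[i] / 2) *
                            exp(p$beta / 2))))
    total <- total +
      oracle_log_binom(d$tp[i], d$tp[i] + d$fn[i], pi1) +
      oracle_log_binom(d$fp[i], d$fp[i] + d$tn[i], pi0) +
      oracle_log_norm(p$theta[i], p$theta_g, p$s_theta) +
      oracle_log_norm(p$alpha[i], p$alpha_g, p$s_alpha)
  }
  total
}

random_valid_params <- function(n_studies) {
  hsroc_params(theta = stats::rnorm(n_studies, 0, 1),
               alpha = stats::rnorm(n_studies, 2, 1),
               theta_g = stats::rnorm(1, 0, 1),
               alpha_g = stats::rnorm(1, 2, 1),
               beta = stats::rnorm(1, 0, 0.5),
               s_theta = stats::runif(1, 0.1, 2),
               s_alpha = stats::runif(1, 0.1, 2))
}

# --- quadrature oracle for the collapsed pooled model ---------------------
# With both hierarchy SDs fixed at 0 and beta fixed, all studies share
# (theta_g, alpha_g) and the posterior is 2-D with flat priors. Posterior
# expectations of functions of (theta_g, alpha_g) by grid quadrature.
oracle_collapsed_moment <- function(d, beta, fun, n_grid = 400) {
  tp <- sum(d$tp); n1 <- sum(d$tp + d$fn)
  fp <- sum(d$fp); n0 <- sum(d$fp + d$tn)
  l1 <- stats::qlogis((tp + 0.5) / (n1 + 1))
  l0 <- stats::qlogis((fp + 0.5) / (n0 + 1))
  se1 <- sqrt(1 / (tp + 0.5) + 1 / (n1 - tp + 0.5))
  se0 <- sqrt(1 / (fp + 0.5) + 1 / (n0 - fp + 0.5))
  th_grid <- seq((l1 + l0) / 2 - 8 * (se1 + se0),
                 (l1 + l0) / 2 + 8 * (se1 + se0), length.out = n_grid)
  al_grid <- seq((l1 - l0) - 8 * (se1 + se0),
                 (l1 - l0) + 8 * (se1 + se0), length.out = n_grid)
  g <- expand.grid(th = th_grid, al = al_grid)
  pi1 <- stats::plogis((g$th + g$al / 2) * exp(-beta / 2))
  pi0 <- stats::plogis((g$th - g$al / 2) * exp(beta / 2))
  ll <- tp * log(pi1) + (n1 - tp) * log1p(-pi1) +
    fp * log(pi0) + (n0 - fp) * log1p(-pi0)
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  sum(w * fun(g$th, g$al, pi1, pi0))
}

# AR(1) chains with known autocorrelation, for ESS checks.
make_ar1_chains <- function(n, m, rho, seed) {
  set.seed(seed)
  sapply(seq_len(m), function(j) {
    x <- numeric(n)
    x[1] <- stats::rnorm(1)
    for (t in 2:n)
      x[t] <- rho * x[t - 1] + sqrt(1 - rho^2) * stats::rnorm(1)
    x
  })
}

# Minimal hand-built draws object for transform-level tests.
fake_draws <- function(states, study_names) {
  # states: named list of equal-length numeric vectors (pooled draws),
  # reshaped into 2 chains.
  qn <- names(states)
  len <- length(states[[1]])
  stopifnot(len %% 2 == 0)
  values <- array(NA_real_, dim = c(2, len / 2, length(qn)),
                  dimnames = list(NULL, NULL, qn))
  for (q in qn)
    values[, , q] <- matrix(states[[q]], nrow = 2, byrow = TRUE)
  structure(list(values = values,
                 config = mcmc_config(chains = 2, iter = len / 2 + 1,
                                      warmup = 1, thin = 1, refine = 1),
                 prior = prior_config(), study_names = study_names,
                 accept = NULL, target = NULL),
            class = "hsroc_draws")
}

# Printed reference values of the worked example's posterior summary
# (mean, se_mean, and for the headline quantity the 97.5% quantile).
reference_summary <- function() {
  list(
    "other_snsp[max]" = list(mean = 0.771449, se = 0.001708,
                             q97.5 = 0.900959),
    "alpha_g" = list(mean = 2.711888, se = 0.013666),
    "beta"    = list(mean = 0.138255, se = 0.026523),
    "theta_g" = list(mean = -0.01723, se = 0.01817),
    "s_theta" = list(mean = 0.561636, se = 0.006513),
    "s_alpha" = list(mean = 1.001177, se = 0.013187),
    "sn[1]"   = list(mean = 0.87702, se = 0.000709),
    "sp[4]"   = list(mean = 0.671328, se = 0.000526))
}

# Reproduction tolerance: 3 Monte-Carlo SEs or an absolute floor
# (0.02 on the probability scale, 0.10 on unbounded scales).
repro_tol <- function(se, prob_scale) {
  max(3 * se, if (prob_scale) 0.02 else 0.10)
}
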