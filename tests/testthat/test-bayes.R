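mu_mat <- function(treated, control, times = c("T0", "T1", "T2")) {
  m <- rbind(treated = treated, control = control)
  colnames(m) <- times
  m
}

test_that("log posterior matches hand-evaluated closed-form densities", {
  # one observation y = 0 in one cell, mu = 0, sigma = 50, others empty
  tab <- data.frame(tumor_id = "tr_01", group = "treated",
                    time_label = "T0", day = 0, pa_value = 0)
  params <- list(mu = mu_mat(0, 0, "T0"),
                 sigma = c(treated = 50, control = 50))
  got <- log_posterior(params, tab)
  want <- dnorm(0, 0, 50, log = TRUE) +                  # likelihood
    2 * dnorm(0, 0, 100, log = TRUE) +                   # mu priors (2 cells)
    2 * (log(2) + dnorm(50, 0, 50, log = TRUE))          # sigma priors
  expect_equal(got, want)
})

test_that("log posterior is symmetric under joint sign flip and rejects sigma <= 0", {
  tab <- tiny_table()
  p <- list(mu = mu_mat(c(25, 28, 30), c(19, 18, 17)),
            sigma = c(treated = 3, control = 2))
  tab_neg <- tab; tab_neg$pa_value <- -tab$pa_value
  p_neg <- list(mu = -p$mu, sigma = p$sigma)
  expect_equal(log_posterior(p, tab), log_posterior(p_neg, tab_neg))
  p0 <- p; p0$sigma["treated"] <- 0
  expect_equal(log_posterior(p0, tab), -Inf)
})

test_that("conjugate fixed-sigma update matches its closed form", {
  # no data -> the prior itself
  expect_equal(conjugate_posterior_fixed_sigma(numeric(0), 10),
               c(mean = 0, sd = 100))
  # prior N(0, 100^2), sigma = 10, n = 4, ybar = 5
  got <- conjugate_posterior_fixed_sigma(rep(5, 4), 10)
  expect_equal(unname(got["mean"]), (4 * 5 / 100) / (1 / 10000 + 4 / 100))
  expect_equal(unname(got["sd"]), sqrt(1 / (1 / 10000 + 4 / 100)))
  # flat-prior limit -> sample mean
  y <- c(4.2, 5.8, 5.1, 4.9)
  got2 <- conjugate_posterior_fixed_sigma(y, 2, prior_sd = 1e9)
  expect_equal(unname(got2["mean"]), mean(y), tolerance = 1e-6)
  expect_error(conjugate_posterior_fixed_sigma(1:3, -1), "sigma")
})

test_that("sampler is deterministic and honors the draw budget", {
  tab <- simulate_cohort(cohort_config(seed = 5))
  cfg <- sampler_config(chains = 2, tune = 50, draws = 100, seed = 77)
  d1 <- sample_posterior(tab, model_spec(), cfg)
  d2 <- sample_posterior(tab, model_spec(), cfg)
  expect_identical(d1$draws, d2$draws)
  expect_equal(dim(d1$draws), c(100L, 2L, 8L))
  # the default configuration carries the reference sampler budget
  def <- sampler_config()
  expect_equal(def$tune, 1000L)
  expect_equal(def$draws, 2000L)
  expect_equal(def$chains, 4L)
  expect_error(sampler_config(chains = 1), "chains")
})

test_that("with sigma fixed, the sampled posterior matches the conjugate form", {
  set.seed(101)
  y <- rnorm(20, mean = 12, sd = 4)
  tab <- data.frame(tumor_id = sprintf("tr_%02d", 1:20),
                    group = "treated", time_label = "T0", day = 0,
                    pa_value = y)
  dr <- sample_posterior(tab, model_spec(),
                         sampler_config(chains = 4, tune = 200,
                                        draws = 2000, seed = 9),
                         sigma_fixed = 4)
  cf <- conjugate_posterior_fixed_sigma(y, 4)
  x <- draws_of(dr, "mu_treated_T0")
  ess <- bulk_ess(chains_of(dr, "mu_treated_T0"))
  mcse_mean <- cf["sd"] / sqrt(ess)
  mcse_sd <- cf["sd"] / sqrt(2 * ess)
  expect_lt(abs(mean(x) - cf["mean"]), 3 * mcse_mean)
  expect_lt(abs(sd(x) - cf["sd"]), 3 * mcse_sd)
})

test_that("an empty table recovers the prior", {
  tab <- data.frame(tumor_id = character(0), group = character(0),
                    time_label = character(0), day = numeric(0),
                    pa_value = numeric(0))
  dr <- sample_posterior(tab, model_spec(),
                         sampler_config(chains = 2, tune = 100,
                                        draws = 2000, seed = 31))
  x <- draws_of(dr, "mu_treated_T1")
  # prior N(0, 100): Monte-Carlo bands at 4000 draws
  expect_lt(abs(mean(x)), 3 * 100 / sqrt(length(x)))
  expect_lt(abs(sd(x) - 100), 3 * 100 / sqrt(2 * length(x)))
})

test_that("posterior means recover the generating group x time means", {
  cfg <- cohort_config(seed = 42)
  tab <- simulate_cohort(cfg)
  dr <- sample_posterior(tab, model_spec(),
                         sampler_config(chains = 2, tune = 500,
                                        draws = 1000, seed = 2))
  for (grp in c("treated", "control")) {
    for (i in 1:3) {
      x <- draws_of(dr, paste0("mu_", grp, "_T", i - 1))
      expect_lt(abs(mean(x) - cfg$means[[grp]][i]), 3 * sd(x))
    }
  }
})

test_that("shifting all observations shifts means but not changes or effects", {
  tab <- simulate_cohort(cohort_config(seed = 13))
  shift <- 30
  tab2 <- tab; tab2$pa_value <- tab$pa_value + shift
  cfg <- sampler_config(chains = 2, tune = 500, draws = 2000, seed = 3)
  d1 <- sample_posterior(tab, model_spec(), cfg)
  d2 <- sample_posterior(tab2, model_spec(), cfg)
  for (p in grep("^mu_", d1$parameters, value = TRUE)) {
    m1 <- mean(draws_of(d1, p))
    m2 <- mean(draws_of(d2, p))
    expect_lt(abs((m2 - m1) - shift), 0.02 * shift)
  }
  e1 <- delta_and_effect(d1)$summary
  e2 <- delta_and_effect(d2)$summary
  expect_equal(e2$mean, e1$mean, tolerance = 0.5)
})

test_that("pooled variance sharing collapses to a single sigma parameter", {
  tab <- simulate_cohort(cohort_config(seed = 8))
  dr <- sample_posterior(tab, model_spec(sigma_sharing = "pooled"),
                         sampler_config(chains = 2, tune = 100,
                                        draws = 200, seed = 4))
  expect_true("sigma" %in% dr$parameters)
  expect_false(any(c("sigma_treated", "sigma_control") %in%
                     dr$parameters))
})
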