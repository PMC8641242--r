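test_that("frozen coefficient values at n = 1, s_p = 3, s_l = 0.5", {
  g <- information_gain_quadratic(1, 3, 0.5)
  expect_equal(g$gradient_coeff, 3 / 24.5, tolerance = 1e-12)
  expect_equal(g$intercept, -0.5 * (log(1 / 7) + 6 / 7), tolerance = 1e-12)
  expect_equal(g$intercept, 0.544384, tolerance = 1e-6)

  u <- uncertainty_quadratic(1, 3, 0.5, 0.5)
  expect_equal(u$gradient_coeff, 0.020408, tolerance = 1e-5)
  expect_equal(u$intercept, 1.500936, tolerance = 1e-6)

  f <- free_energy_quadratic(1, 3, 0.5, 0.5)
  expect_equal(f$gradient_coeff, 1 / 7, tolerance = 1e-12)
  expect_equal(f$intercept, 2.045320, tolerance = 1e-6)
  expect_equal(f$gradient_coeff, g$gradient_coeff + u$gradient_coeff,
               tolerance = 1e-12)
  expect_equal(f$intercept, g$intercept + u$intercept, tolerance = 1e-10)

  expect_error(information_gain_quadratic(0, 1, 1),
               class = "arousalfe_invalid_params")
  expect_error(uncertainty_quadratic(1, 1, 1, -0.1),
               class = "arousalfe_invalid_params")
})

test_that("gain quadratic equals the Gaussian KL from posterior to prior", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(c(1:5, 10, 50), 1)
    s_p <- runif(1, 0.1, 8)
    s_l <- runif(1, 0.1, 8)
    delta <- rnorm(1, 0, 2)
    eta <- rnorm(1)
    form <- information_gain_quadratic(n, s_p, s_l)
    post <- posterior_update(gaussian_belief(eta, s_p),
                             sample_summary(n, eta + delta, 1),
                             sensory_model(s_l))
    expect_lt(abs(predict(form, delta) -
                    gaussian_kl(post, gaussian_belief(eta, s_p))), 1e-10)
  }
  # delta = 0 with a vanishing prior variance: posterior ~ prior, no gain
  expect_lt(predict(information_gain_quadratic(1, 1e-10, 1), 0), 1e-9)
})

test_that("uncertainty quadratic matches the Monte-Carlo posterior expectation", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(1:6, 1)
    s_p <- runif(1, 0.3, 5)
    s_l <- runif(1, 0.3, 5)
    S <- runif(1, 0, 2)
    delta <- rnorm(1, 0, 1.5)
    eta <- 0
    summary <- sample_summary(n, eta + delta, S)
    sens <- sensory_model(s_l)
    post <- posterior_update(gaussian_belief(eta, s_p), summary, sens)
    draws <- rnorm(1e5, post$mean, sqrt(post$variance))
    nll <- neg_log_likelihood(summary, draws, sens)
    se <- sd(nll) / sqrt(length(nll))
    form_val <- predict(uncertainty_quadratic(n, s_p, s_l, S), delta)
    expect_lt(abs(form_val - mean(nll)), 3 * se)
  }
})

test_that("free-energy quadratic matches a discretized free-energy oracle", {
  n <- 3; s_p <- 2; s_l <- 0.8; S <- 0.6; delta <- 1.3; eta <- 0.2
  summary <- sample_summary(n, eta + delta, S)
  sens <- sensory_model(s_l)
  grid <- seq(eta - 10, eta + 10, length.out = 8001)
  w_prior <- dnorm(grid, eta, sqrt(s_p)); w_prior <- w_prior / sum(w_prior)
  nll <- neg_log_likelihood(summary, grid, sens)
  lik <- exp(-(nll - min(nll)))          # scaled joint likelihood
  scale <- 0.5 / max(lik)
  model <- discrete_generative_model(w_prior,
                                     cbind(scale * lik, 1 - scale * lik))
  post <- posterior_update(gaussian_belief(eta, s_p), summary, sens)
  q <- dnorm(grid, post$mean, sqrt(post$variance)); q <- q / sum(q)
  # discrete F uses the scaled likelihood; undo the scaling and min-shift
  f_discrete <- free_energy(model, q, 1) + min(nll) + log(scale)
  f_cont <- predict(free_energy_quadratic(n, s_p, s_l, S), delta)
  expect_equal(f_discrete, f_cont, tolerance = 1e-3)
})

test_that("additivity A_F = A_G + A_U, B_F = B_G + B_U across a grid", {
  grid <- expand.grid(n = c(1, 2, 10), s_p = c(0.1, 0.7, 3, 10),
                      s_l = c(0.1, 0.7, 3, 10), S = c(0, 1))
  for (k in seq_len(nrow(grid))) {
    p <- grid[k, ]
    g <- information_gain_quadratic(p$n, p$s_p, p$s_l)
    u <- uncertainty_quadratic(p$n, p$s_p, p$s_l, p$S)
    f <- free_energy_quadratic(p$n, p$s_p, p$s_l, p$S)
    expect_equal(f$gradient_coeff, g$gradient_coeff + u$gradient_coeff,
                 tolerance = 1e-12)
    expect_equal(f$intercept, g$intercept + u$intercept, tolerance = 1e-12)
    delta <- c(0, 0.5, 2)
    expect_equal(predict(f, delta), predict(g, delta) + predict(u, delta),
                 tolerance = 1e-12)
    expect_gte(g$gradient_coeff, 0)
    expect_gt(u$gradient_coeff, 0)
  }
})

test_that("staged measures reduce to single-stage forms at n = 0", {
  delta <- seq(-3, 3, by = 0.5)
  for (m in c(1, 4)) {
    s <- staged_measures(0, m, 3, 0.5, 0.5, delta)
    expect_equal(s$gain, predict(information_gain_quadratic(m, 3, 0.5), delta),
                 tolerance = 1e-12)
    expect_equal(s$uncertainty,
                 predict(uncertainty_quadratic(m, 3, 0.5, 0.5), delta),
                 tolerance = 1e-12)
    expect_equal(s$free_energy, s$gain + s$uncertainty, tolerance = 1e-12)
  }
})

test_that("staged gain equals the KL between consecutive staged beliefs", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(0:20, 1); m <- sample(1:10, 1)
    s_p <- runif(1, 0.2, 5); s_l <- runif(1, 0.2, 5)
    delta <- rnorm(1, 0, 2); eta <- rnorm(1)
    sens <- sensory_model(s_l)
    prior <- gaussian_belief(eta, s_p)
    xbar <- eta + delta
    belief_n <- posterior_update(prior, sample_summary(n, xbar, 1), sens)
    belief_nm <- posterior_update(prior, sample_summary(n + m, xbar, 1), sens)
    s <- staged_measures(n, m, s_p, s_l, 0, delta)
    expect_lt(abs(s$gain - gaussian_kl(belief_nm, belief_n)), 1e-10)
    expect_gte(s$gain, -1e-12)
  }
})

test_that("staged uncertainty is the posterior-expected batch likelihood (MC)", {
  # discriminates the staged posterior-variance term s_p / ((n+m) s_p + s_l)
  # from the alternative s_l / ((n+m) s_p + s_l)
  set.seed(23)
  n <- 5; m <- 3; s_p <- 2.5; s_l <- 0.6; S <- 0.9; delta <- 1.1; eta <- 0
  sens <- sensory_model(s_l)
  staged_post <- posterior_update(gaussian_belief(eta, s_p),
                                  sample_summary(n + m, eta + delta, S), sens)
  draws <- rnorm(2e5, staged_post$mean, sqrt(staged_post$variance))
  nll <- neg_log_likelihood(sample_summary(m, eta + delta, S), draws, sens)
  se <- sd(nll) / sqrt(length(nll))
  s <- staged_measures(n, m, s_p, s_l, S, delta)
  expect_lt(abs(s$uncertainty - mean(nll)), 3 * se)
  # the printed alternative lies many standard errors away
  t_nm <- (n + m) * s_p + s_l
  alt <- s$uncertainty + m / 2 * (s_l - s_p) / t_nm
  expect_gt(abs(alt - mean(nll)), 10 * se)
})

test_that("gain vanishes and uncertainty converges to m times the entropy", {
  lim <- asymptotic_limits(1, 0.5)
  expect_identical(lim$gain_limit, 0)
  expect_equal(asymptotic_limits(1, 1)$uncertainty_limit, 1.418939,
               tolerance = 1e-6)
  for (m in c(1, 5)) {
    s <- staged_measures(1e8, m, 3, 0.5, 0.5, delta = 2)
    lim <- asymptotic_limits(m, 0.5)
    expect_lt(s$gain, 1e-6)
    expect_lt(abs(s$uncertainty - lim$uncertainty_limit), 1e-5)
  }
  # uncertainty decreases monotonically in the absorbed sample count
  ns <- c(0, 1, 2, 5, 10, 100, 1e4, 1e6)
  u <- vapply(ns, function(n) staged_measures(n, 2, 3, 0.5, 0.5, 1.5)$uncertainty,
              numeric(1))
  expect_true(all(diff(u) < 0))
})

test_that("quadratic JSON serialization carries all coefficients", {
  f <- free_energy_quadratic(2, 1.5, 0.5, 0.25)
  txt <- write_quadratic(f)
  obj <- jsonlite::fromJSON(txt)
  expect_equal(obj$A, f$gradient_coeff)
  expect_equal(obj$B, f$intercept)
  expect_identical(obj$quantity, "free_energy")
  path <- withr::local_tempfile(fileext = ".json")
  write_quadratic(f, path)
  expect_equal(jsonlite::fromJSON(path)$B, f$intercept)
})
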