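# reference parameters of the two cohorts (area and volume features)
tbl_area <- list(normal = list(mu = 0.3711, sigma = 0.0825),
                 patient = list(mu = 0.1749, sigma = 0.2341))
tbl_vol <- list(normal = list(mu = 0.4121, sigma = 0.0762),
                patient = list(mu = 0.1996, sigma = 0.1981))

make_models <- function(tbl, p1 = 0.5) {
  structure(list(normal = c(tbl$normal, list(prior = p1, label = "normal")),
                 patient = c(tbl$patient, list(prior = 1 - p1,
                                               label = "patient"))),
            class = "gaussian_class_models")
}

# independent grid-search oracle for posterior crossings: coarse scan for
# sign changes of the log-posterior difference, then a 1e-6-step fine grid
# around each
grid_crossings <- function(models, lo, hi) {
  g <- function(x)
    log(models$normal$prior) + dnorm(x, models$normal$mu,
                                     models$normal$sigma, log = TRUE) -
    log(models$patient$prior) - dnorm(x, models$patient$mu,
                                      models$patient$sigma, log = TRUE)
  coarse <- seq(lo, hi, by = 1e-3)
  v <- g(coarse)
  idx <- which(diff(sign(v)) != 0)
  out <- numeric()
  for (i in idx) {
    fine <- seq(coarse[i] - 5e-4, coarse[i + 1] + 5e-4, by = 1e-6)
    fv <- g(fine)
    j <- which(diff(sign(fv)) != 0)
    out <- c(out, (fine[j] + fine[j + 1]) / 2)
  }
  out <- sort(out)
  out[c(TRUE, diff(out) > 1e-5)]
}

test_that("per-class Gaussian fitting uses closed-form moments and priors", {
  f <- fit_class_models(c(0, 2, 5, 6, 9), c("normal", "normal", "patient",
                                            "patient", "patient"))
  expect_equal(f$normal$mu, 1)
  expect_equal(f$normal$sigma, sqrt(2))
  labels <- rep(c("normal", "patient"), c(12, 25))
  f2 <- fit_class_models(seq_along(labels), labels, prior = "empirical")
  expect_equal(f2$normal$prior, 12 / 37)
  expect_equal(f2$patient$prior, 25 / 37)
  f3 <- fit_class_models(seq_along(labels), labels, prior = "equal")
  expect_equal(f3$normal$prior, 0.5)
  expect_error(fit_class_models(c(1, 2, 3), c("normal", "patient", "patient")),
               class = "airtrapcad_fit_error")
  expect_error(fit_class_models(c(1, 1, 2, 3),
                                rep(c("normal", "patient"), each = 2)),
               class = "airtrapcad_fit_error")   # zero within-class variance
})

test_that("fitting recovers generating parameters from large simulated draws", {
  co <- generate_cohort_features(1e5, 1e5,
                                 normal_mean = c(0.3711, 0.4121),
                                 patient_mean = c(0.1749, 0.1996),
                                 seed = 21)
  f <- fit_class_models(co$delta_S_N, co$label)
  expect_lt(abs(f$normal$mu - 0.3711) / 0.3711, 0.01)
  expect_lt(abs(f$normal$sigma - 0.0825) / 0.0825, 0.01)
  expect_lt(abs(f$patient$mu - 0.1749) / 0.1749, 0.01)
  expect_lt(abs(f$patient$sigma - 0.2341) / 0.2341, 0.01)
  # mu recovered within 3 sigma / sqrt(n) across small-sample refits
  for (seed in 1:5) {
    n <- 200
    sm <- generate_cohort_features(n, n, seed = seed)
    fs <- fit_class_models(sm$delta_V_N, sm$label)
    expect_lt(abs(fs$normal$mu - 0.4121), 3 * 0.0762 / sqrt(n))
  }
})

test_that("likelihood ratio equals the explicit Gaussian density ratio", {
  m_eq <- make_models(list(normal = list(mu = 0.3, sigma = 0.1),
                           patient = list(mu = 0.3, sigma = 0.1)))
  expect_equal(likelihood_ratio(c(-1, 0, 0.3, 2), m_eq), rep(1, 4))
  m_sym <- make_models(list(normal = list(mu = 0, sigma = 1),
                            patient = list(mu = 2, sigma = 1)))
  expect_equal(likelihood_ratio(1, m_sym), 1)
  m <- make_models(tbl_area, p1 = 12 / 37)
  x <- c(-0.1, 0.1, 0.276, 0.5, 0.9)
  dens <- function(x, mu, s) exp(-(x - mu)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  expect_equal(likelihood_ratio(x, m),
               dens(x, 0.3711, 0.0825) / dens(x, 0.1749, 0.2341),
               tolerance = 1e-12)
})

test_that("decision thresholds solve posterior equality", {
  m_sym <- make_models(list(normal = list(mu = 0, sigma = 1),
                            patient = list(mu = 2, sigma = 1)))
  expect_equal(decision_thresholds(m_sym), 1)
  m_var <- make_models(list(normal = list(mu = 0, sigma = 0.5),
                            patient = list(mu = 0, sigma = 2)))
  th <- decision_thresholds(m_var)
  expect_length(th, 2)
  expect_equal(sort(th), sort(-th))      # symmetric about the common mean
  # posterior equality at every root, for the reference parameter sets
  for (m in list(make_models(tbl_area, 12 / 37), make_models(tbl_vol, 12 / 37),
                 m_sym, m_var)) {
    for (t in decision_thresholds(m))
      expect_lt(abs(posterior_patient(t, m) - 0.5), 1e-8)
  }
})

test_that("threshold between the class means matches the grid-search oracle", {
  m <- make_models(tbl_area, 12 / 37)
  th <- decision_thresholds(m)
  root <- th[th > 0.1749 & th < 0.3711]
  expect_length(root, 1)
  cross <- grid_crossings(m, 0, 1)
  expect_lt(min(abs(cross - root)), 1e-6)
})

test_that("posterior comparison and likelihood-ratio rule agree everywhere", {
  set.seed(42)
  for (i in 1:50) {
    m <- make_models(list(normal = list(mu = runif(1), sigma = runif(1, 0.05, 0.4)),
                          patient = list(mu = runif(1), sigma = runif(1, 0.05, 0.4))),
                     p1 = runif(1, 0.1, 0.9))
    x <- rnorm(40, 0.5, 0.5)
    by_post <- classify_bayes(x, m)$label
    lr <- likelihood_ratio(x, m)
    by_lr <- factor(ifelse(lr > m$patient$prior / m$normal$prior,
                           "normal", "patient"),
                    levels = c("normal", "patient"))
    expect_identical(by_post, by_lr)
  }
})

test_that("ties at the boundary go to the patient class", {
  m <- make_models(list(normal = list(mu = 0, sigma = 1),
                        patient = list(mu = 2, sigma = 1)))
  out <- classify_bayes(1, m)            # exactly at the threshold
  expect_equal(as.character(out$label), "patient")
  narrow <- make_models(list(normal = list(mu = 0.4, sigma = 0.01),
                             patient = list(mu = 0.2, sigma = 0.5)))
  expect_equal(as.character(classify_bayes(0.4, narrow)$label), "normal")
})

test_that("severity lines are exact least squares", {
  ds <- seq(0.1, 0.6, length.out = 10)
  exact <- data.frame(delta_S_N = rep(ds, 2),
                      delta_V_N = rep(0.855 * ds + 0.095, 2),
                      label = rep(c("normal", "patient"), each = 10))
  fits <- fit_severity_lines(exact)
  expect_equal(fits$normal$slope, 0.855, tolerance = 1e-10)
  expect_equal(fits$normal$intercept, 0.095, tolerance = 1e-10)
  expect_equal(fits$normal$r_squared, 1, tolerance = 1e-10)

  const <- exact
  const$delta_V_N <- 0.3
  fc <- fit_severity_lines(const)
  expect_equal(fc$patient$slope, 0, tolerance = 1e-12)
  expect_equal(fc$patient$r_squared, 0)

  set.seed(9)
  noisy <- data.frame(delta_S_N = runif(30), label = "normal")
  noisy$delta_V_N <- 0.6 * noisy$delta_S_N + 0.1 + rnorm(30, 0, 0.05)
  noisy <- rbind(noisy, transform(noisy, label = "patient"))
  fn <- fit_severity_lines(noisy)
  X <- cbind(1, noisy$delta_S_N[noisy$label == "normal"])
  yv <- noisy$delta_V_N[noisy$label == "normal"]
  beta <- solve(t(X) %*% X, t(X) %*% yv)
  expect_equal(fn$normal$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fn$normal$slope, beta[2], tolerance = 1e-10)

  degen <- exact
  degen$delta_S_N <- 0.2
  expect_error(fit_severity_lines(degen), class = "airtrapcad_fit_error")
})

test_that("the fitted model object supports the standard methods", {
  co <- generate_cohort_features(12, 25, seed = 4)
  fit <- airtrap_model(co)
  expect_s3_class(fit, "airtrap_model")
  expect_output(print(fit), "Gaussian Bayes")
  cf <- coef(fit)
  expect_equal(dim(cf), c(4, 3))
  pred <- predict(fit, co)
  expect_equal(nrow(pred), 37)
  expect_true(all(pred$posterior_patient >= 0 & pred$posterior_patient <= 1))
  sim <- simulate(fit, nsim = 100, seed = 8)
  expect_equal(nrow(sim), 100)
  expect_identical(sim, simulate(fit, nsim = 100, seed = 8))
  expect_length(residuals(fit, "normal"), 12)
  f <- tempfile(fileext = ".json")
  write_model(fit, f)
  fit2 <- read_model(f)
  expect_equal(predict(fit2, co)$label, pred$label)
  expect_equal(fit2$models$volume$normal$mu, fit$models$volume$normal$mu)
})

test_that("severity scoring reports the defined quantities", {
  co <- generate_cohort_features(12, 25, seed = 4)
  fit <- airtrap_model(co)
  mu_n <- fit$models$volume$normal$mu
  sd_n <- fit$models$volume$normal$sigma
  rec <- data.frame(delta_S_N = 0.2, delta_V_N = mu_n)
  expect_equal(severity_score(rec, fit)$z_air_trapping, 0)
  rec$delta_V_N <- mu_n - sd_n
  sc <- severity_score(rec, fit)
  expect_equal(sc$z_air_trapping, 1)
  expect_true(all(is.finite(unlist(sc))))
  expect_identical(sc, severity_score(rec, fit))
})
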