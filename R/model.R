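#' Fit per-class univariate Gaussian models
#'
#' For one feature, fits a Gaussian to each class: mean, sample standard
#' deviation (n - 1 denominator), and prior (empirical class frequency or
#' 0.5 each).
#'
#' @param x numeric feature values.
#' @param labels class labels, `"normal"` / `"patient"` (factor or
#'   character), same length as `x`.
#' @param prior `"empirical"` (class frequencies) or `"equal"`.
#' @return an object of class `gaussian_class_models`: a list with elements
#'   `normal` and `patient`, each `list(label, mu, sigma, prior, n)`.
#' @export
fit_class_models <- function(x, labels, prior = c("empirical", "equal")) {
  prior <- match.arg(prior)
  labels <- as.character(labels)
  if (length(x) != length(labels))
    abort("x and labels must have equal length", "airtrapcad_input_error")
  bad <- setdiff(unique(labels), c("normal", "patient"))
  if (length(bad))
    abort(paste0("unknown label(s): ", paste(bad, collapse = ", ")),
          "airtrapcad_input_error")
  out <- list()
  n_tot <- length(x)
  for (cls in c("normal", "patient")) {
    xi <- x[labels == cls]
    if (length(xi) < 2L)
      abort(sprintf("class '%s' has fewer than 2 samples", cls),
            "airtrapcad_fit_error")
    s <- sd(xi)
    if (!is.finite(s) || s <= 0)
      abort(sprintf("class '%s' has zero variance", cls),
            "airtrapcad_fit_error")
    out[[cls]] <- list(label = cls, mu = mean(xi), sigma = s,
                       prior = if (prior == "equal") 0.5 else length(xi) / n_tot,
                       n = length(xi))
  }
  structure(out, class = "gaussian_class_models", prior_mode = prior)
}

#' Likelihood ratio of the two class densities
#'
#' `l_r(x) = p(x | normal) / p(x | patient)`; the minimum-error rule assigns
#' `x` to the normal class exactly when `l_r(x) > p(patient) / p(normal)`.
#'
#' @param x numeric feature values.
#' @param models a [fit_class_models()] result.
#' @return the likelihood ratio at each `x`.
#' @export
likelihood_ratio <- function(x, models) {
  dnorm(x, models$normal$mu, models$normal$sigma) /
    dnorm(x, models$patient$mu, models$patient$sigma)
}

#' Decision threshold(s) of a two-class Gaussian rule
#'
#' Solves the quadratic obtained from equality of the two log-posteriors.
#' With unequal variances there are up to two real roots; with equal
#' variances exactly one.  Roots are returned sorted ascending, except that
#' the classification-relevant root - the one lying between the two class
#' means - is reported first when it exists.  When no real root exists (one
#' posterior dominates everywhere) an empty vector is returned with a
#' warning, and classification falls back to pure posterior comparison.
#'
#' @param models a [fit_class_models()] result.
#' @return numeric vector of boundary points (possibly empty).
#' @export
decision_thresholds <- function(models) {
  m1 <- models$normal; m2 <- models$patient
  a <- 1 / (2 * m2$sigma^2) - 1 / (2 * m1$sigma^2)
  b <- m1$mu / m1$sigma^2 - m2$mu / m2$sigma^2
  cc <- m2$mu^2 / (2 * m2$sigma^2) - m1$mu^2 / (2 * m1$sigma^2) +
    log((m1$prior * m2$sigma) / (m2$prior * m1$sigma))
  if (abs(a) < .Machine$double.eps) {
    if (abs(b) < .Machine$double.eps) {
      warning("class posteriors never cross; no decision threshold",
              call. = FALSE)
      return(numeric())
    }
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) {
      warning("class posteriors never cross; no decision threshold",
              call. = FALSE)
      return(numeric())
    }
    # numerically stable quadratic roots (avoids cancellation)
    q <- -(b + sign(b + (b == 0)) * sqrt(disc)) / 2
    roots <- sort(c(q / a, if (q != 0) cc / q else -b / a))
  }
  # polish with Newton steps on the log-posterior difference
  gfun <- function(x)
    log(m1$prior) + dnorm(x, m1$mu, m1$sigma, log = TRUE) -
    log(m2$prior) - dnorm(x, m2$mu, m2$sigma, log = TRUE)
  gprime <- function(x) -(x - m1$mu) / m1$sigma^2 + (x - m2$mu) / m2$sigma^2
  for (i in seq_along(roots)) for (k in 1:3) {
    gp <- gprime(roots[i])
    if (abs(gp) < 1e-12) break
    roots[i] <- roots[i] - gfun(roots[i]) / gp
  }
  roots <- sort(roots)
  lo <- min(m1$mu, m2$mu); hi <- max(m1$mu, m2$mu)
  between <- roots >= lo & roots <= hi
  c(roots[between], roots[!between])
}

#' Posterior probability of the patient class
#'
#' @param x numeric feature values.
#' @param models a [fit_class_models()] result.
#' @return `p(patient | x)` at each `x`.
#' @export
posterior_patient <- function(x, models) {
  # log-space for numerical stability far in the tails
  l1 <- log(models$normal$prior) +
    dnorm(x, models$normal$mu, models$normal$sigma, log = TRUE)
  l2 <- log(models$patient$prior) +
    dnorm(x, models$patient$mu, models$patient$sigma, log = TRUE)
  1 / (1 + exp(l1 - l2))
}

#' Classify feature values with the Gaussian Bayes rule
#'
#' Labels by posterior comparison (exactly equivalent to the likelihood-ratio
#' rule); a tie at the boundary is broken toward `"patient"`, favouring
#' sensitivity in a screening context.
#'
#' @param x numeric feature values.
#' @param models a [fit_class_models()] result.
#' @return a data frame with columns `label` (factor normal/patient) and
#'   `posterior_patient`.
#' @export
classify_bayes <- function(x, models) {
  post <- posterior_patient(x, models)
  lab <- factor(ifelse(post >= 0.5, "patient", "normal"),
                levels = c("normal", "patient"))
  data.frame(label = lab, posterior_patient = post)
}

#' Bayes-optimal accuracy of a two-class Gaussian mixture
#'
#' The accuracy of the ideal minimum-error classifier, computed by numeric
#' integration of the pointwise maximum of the two weighted class densities.
#'
#' @param models a [fit_class_models()] result (or any list with the same
#'   shape, e.g. known generating parameters).
#' @return the Bayes-optimal accuracy as a fraction in \[0.5, 1\].
#' @export
bayes_optimal_accuracy <- function(models) {
  m1 <- models$normal; m2 <- models$patient
  f <- function(x) pmax(m1$prior * dnorm(x, m1$mu, m1$sigma),
                        m2$prior * dnorm(x, m2$mu, m2$sigma))
  lo <- min(m1$mu - 10 * m1$sigma, m2$mu - 10 * m2$sigma)
  hi <- max(m1$mu + 10 * m1$sigma, m2$mu + 10 * m2$sigma)
  integrate(f, lo, hi, rel.tol = 1e-10)$value
}

#' Per-class linear severity fits
#'
#' Ordinary least squares of the volume variation on the area variation
#' within each class, the linear model relating the two air-trapping
#' features.
#'
#' @param data data frame with columns `delta_S_N`, `delta_V_N`, `label`.
#' @return a list with elements `normal` and `patient`, each
#'   `list(label, slope, intercept, r_squared, n)` with the fitted `lm`
#'   object attached as attribute `fit`.
#' @export
fit_severity_lines <- function(data) {
  out <- list()
  for (cls in c("normal", "patient")) {
    di <- data[as.character(data$label) == cls, , drop = FALSE]
    if (nrow(di) < 3L)
      abort(sprintf("class '%s' has fewer than 3 records", cls),
            "airtrapcad_fit_error")
    if (var(di$delta_S_N) <= 0)
      abort(sprintf("class '%s' has zero area-variation variance", cls),
            "airtrapcad_fit_error")
    fit <- lm(delta_V_N ~ delta_S_N, data = di)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((di$delta_V_N - mean(di$delta_V_N))^2)
    ln <- list(label = cls, slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
               n = nrow(di))
    attr(ln, "fit") <- fit
    out[[cls]] <- ln
  }
  out
}

#' Fit the air-trapping diagnosis model
#'
#' The central fitting function of the package.  From a per-subject feature
#' table it fits, for each of the two features (area variation `delta_S_N`
#' and volume variation `delta_V_N`):
#' a two-class univariate Gaussian model (mean, n-1 standard deviation and
#' prior per class), the Bayes minimum-error decision threshold(s)
#' ([decision_thresholds()]), and the per-class linear severity models
#' ([fit_severity_lines()]).  Classification ([predict.airtrap_model()])
#' uses the volume-variation feature by default - the 3-D feature that
#' needs no cross-phase slice correspondence - with the area feature as an
#' option.
#'
#' @param data data frame with columns `delta_S_N`, `delta_V_N`, `label`
#'   (`"normal"` / `"patient"`).
#' @param feature default decision feature, `"volume"` or `"area"`.
#' @param prior `"empirical"` class frequencies or `"equal"` (0.5 each).
#' @return an object of class `airtrap_model` with components `models`
#'   (per-feature [fit_class_models()]), `thresholds` (per feature),
#'   `severity` ([fit_severity_lines()]), `feature`, `prior_mode`, `n`,
#'   `call`.
#' @seealso [predict.airtrap_model()], [simulate.airtrap_model()],
#'   [severity_score()]
#' @examples
#' cohort <- generate_cohort_features(12, 25, seed = 1)
#' fit <- airtrap_model(cohort)
#' fit
#' predict(fit, cohort)[1:3, ]
#' @export
airtrap_model <- function(data, feature = c("volume", "area"),
                          prior = c("empirical", "equal")) {
  feature <- match.arg(feature)
  prior <- match.arg(prior)
  need <- c("delta_S_N", "delta_V_N", "label")
  if (!all(need %in% names(data)))
    abort(paste("data must have columns", paste(need, collapse = ", ")),
          "airtrapcad_input_error")
  data <- data[!is.na(data$label), , drop = FALSE]
  models <- list(
    area = fit_class_models(data$delta_S_N, data$label, prior),
    volume = fit_class_models(data$delta_V_N, data$label, prior))
  thresholds <- lapply(models, function(m)
    withCallingHandlers(decision_thresholds(m),
                        warning = function(w) invokeRestart("muffleWarning")))
  severity <- fit_severity_lines(data)
  structure(list(models = models, thresholds = thresholds,
                 severity = severity, feature = feature, prior_mode = prior,
                 n = table(factor(data$label, c("normal", "patient"))),
                 call = match.call()),
            class = "airtrap_model")
}

#' @export
print.airtrap_model <- function(x, digits = 4, ...) {
  cat("Two-class Gaussian Bayes air-trapping model\n")
  cat(sprintf("  n = %d normal, %d patient; %s priors (%.3f / %.3f)\n",
              x$n[["normal"]], x$n[["patient"]], x$prior_mode,
              x$models$volume$normal$prior, x$models$volume$patient$prior))
  for (f in c("area", "volume")) {
    m <- x$models[[f]]
    th <- x$thresholds[[f]]
    cat(sprintf("  %s variation: normal %0.*f (SD %0.*f), patient %0.*f (SD %0.*f); threshold %s\n",
                f, digits, m$normal$mu, digits, m$normal$sigma,
                digits, m$patient$mu, digits, m$patient$sigma,
                if (length(th)) format(round(th[1], digits)) else "none"))
  }
  for (cls in c("normal", "patient")) {
    s <- x$severity[[cls]]
    cat(sprintf("  severity line (%s): dV = %0.3f dS + %0.3f  (R^2 = %0.3f)\n",
                cls, s$slope, s$intercept, s$r_squared))
  }
  cat(sprintf("  decision feature: %s variation\n", x$feature))
  invisible(x)
}

#' @export
summary.airtrap_model <- function(object, ...) {
  structure(list(model = object,
                 ttests = NULL), class = "summary.airtrap_model")
}

#' @export
print.summary.airtrap_model <- function(x, ...) {
  print(x$model)
  invisible(x)
}

#' @export
coef.airtrap_model <- function(object, ...) {
  rows <- list()
  for (f in c("area", "volume")) for (cls in c("normal", "patient")) {
    m <- object$models[[f]][[cls]]
    rows[[paste(f, cls, sep = ".")]] <- c(mu = m$mu, sigma = m$sigma,
                                          prior = m$prior)
  }
  do.call(rbind, rows)
}

#' Classify new subjects
#'
#' @param object an [airtrap_model()].
#' @param newdata data frame with the feature columns (at least the one
#'   selected by `feature`), or a numeric vector of feature values.
#' @param feature decision feature; defaults to the model's.
#' @param ... unused.
#' @return a data frame with `label` and `posterior_patient` (plus
#'   `subject_id` when present in `newdata`).
#' @export
predict.airtrap_model <- function(object, newdata,
                                  feature = object$feature, ...) {
  feature <- match.arg(feature, c("volume", "area"))
  col <- if (feature == "volume") "delta_V_N" else "delta_S_N"
  x <- if (is.numeric(newdata)) newdata else newdata[[col]]
  if (is.null(x))
    abort(sprintf("newdata lacks column '%s'", col), "airtrapcad_input_error")
  out <- classify_bayes(x, object$models[[feature]])
  if (!is.numeric(newdata) && "subject_id" %in% names(newdata))
    out <- cbind(subject_id = newdata$subject_id, out)
  out
}

#' Simulate feature draws from a fitted model
#'
#' Draws subjects from the fitted two-class Gaussian mixture of the model's
#' decision feature (class sizes proportional to the fitted priors), a
#' parametric-bootstrap companion to [airtrap_model()].
#'
#' @param object an [airtrap_model()].
#' @param nsim number of subjects to draw.
#' @param seed optional RNG seed (caller's RNG state preserved).
#' @param ... unused.
#' @return data frame with the simulated feature value and `label`.
#' @export
simulate.airtrap_model <- function(object, nsim = 1, seed = NULL, ...) {
  m <- object$models[[object$feature]]
  gen <- function() {
    lab <- sample(c("normal", "patient"), nsim, replace = TRUE,
                  prob = c(m$normal$prior, m$patient$prior))
    x <- ifelse(lab == "normal",
                rnorm(nsim, m$normal$mu, m$normal$sigma),
                rnorm(nsim, m$patient$mu, m$patient$sigma))
    col <- if (object$feature == "volume") "delta_V_N" else "delta_S_N"
    out <- data.frame(x = x, label = factor(lab, c("normal", "patient")))
    names(out)[1] <- col
    out
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' @export
residuals.airtrap_model <- function(object, class = c("normal", "patient"),
                                    ...) {
  class <- match.arg(class)
  residuals(attr(object$severity[[class]], "fit"))
}

#' Plot a fitted air-trapping model
#'
#' Class-conditional densities of the decision feature with the decision
#' threshold(s) marked.
#'
#' @param x an [airtrap_model()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.airtrap_model <- function(x, ...) {
  m <- x$models[[x$feature]]
  lo <- min(m$normal$mu - 4 * m$normal$sigma, m$patient$mu - 4 * m$patient$sigma)
  hi <- max(m$normal$mu + 4 * m$normal$sigma, m$patient$mu + 4 * m$patient$sigma)
  xs <- seq(lo, hi, length.out = 400)
  d1 <- m$normal$prior * dnorm(xs, m$normal$mu, m$normal$sigma)
  d2 <- m$patient$prior * dnorm(xs, m$patient$mu, m$patient$sigma)
  graphics::plot(xs, d1, type = "l", col = "forestgreen",
                 xlab = sprintf("%s variation", x$feature),
                 ylab = "prior-weighted density",
                 ylim = c(0, max(d1, d2)), ...)
  graphics::lines(xs, d2, col = "firebrick")
  for (t in x$thresholds[[x$feature]]) graphics::abline(v = t, lty = 2)
  graphics::legend("topright", c("normal", "patient"),
                   col = c("forestgreen", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Air-trapping severity report for one subject
#'
#' Combines the quantities the fitted models already define into a severity
#' report: the volume variation itself, its air-trapping z-score relative to
#' the normal class (`(mu_normal - dV) / sigma_normal`; larger = more
#' trapping), the posterior patient probability, and the subject's residual
#' from each class's severity line.
#'
#' @param record one-row data frame with `delta_S_N` and `delta_V_N`.
#' @param model an [airtrap_model()].
#' @return a one-row data frame: `delta_V_N`, `z_air_trapping`,
#'   `posterior_patient`, `residual_normal`, `residual_patient`.
#' @export
severity_score <- function(record, model) {
  dv <- record$delta_V_N[1]
  ds <- record$delta_S_N[1]
  mn <- model$models$volume$normal
  res <- function(cls) {
    s <- model$severity[[cls]]
    dv - (s$intercept + s$slope * ds)
  }
  data.frame(delta_V_N = dv,
             z_air_trapping = (mn$mu - dv) / mn$sigma,
             posterior_patient = posterior_patient(dv, model$models$volume),
             residual_normal = res("normal"),
             residual_patient = res("patient"))
}

#' Write a fitted model to JSON
#'
#' Serializes the per-class Gaussian parameters, thresholds and severity-line
#' coefficients (not the underlying `lm` objects).
#'
#' @param model an [airtrap_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    feature = model$feature, prior_mode = model$prior_mode,
    n = as.list(model$n),
    models = lapply(model$models, function(m)
      lapply(unclass(m), function(cl) cl[c("label", "mu", "sigma", "prior", "n")])),
    thresholds = model$thresholds,
    severity = lapply(model$severity, function(s)
      s[c("label", "slope", "intercept", "r_squared", "n")]))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path a file written by [write_model()].
#' @return an `airtrap_model` (without refittable `lm` internals).
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(p$models, function(m) {
    out <- lapply(m, as.list)
    structure(out, class = "gaussian_class_models", prior_mode = p$prior_mode)
  })
  structure(list(models = models,
                 thresholds = lapply(p$thresholds, as.numeric),
                 severity = lapply(p$severity, as.list),
                 feature = p$feature, prior_mode = p$prior_mode,
                 n = unlist(p$n), call = NULL),
            class = "airtrap_model")
}
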