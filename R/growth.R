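#' Fit a growth trajectory against age
#'
#' Ordinary least squares fit of one regional measure against age in days,
#' with one of three model forms commonly used for early-childhood
#' development curves:
#' \describe{
#'   \item{logarithmic}{\eqn{y = a \ln(\mathrm{age}) + b}}
#'   \item{linear}{\eqn{y = a\,\mathrm{age} + b}}
#'   \item{quadratic}{\eqn{y = c_2\,\mathrm{age}^2 + c_1\,\mathrm{age} + c_0}}
#' }
#' Age enters in days; the logarithm is natural. The fit is an ordinary
#' \code{\link[stats]{lm}} on the transformed design.
#'
#' @param age_days Numeric vector of ages, days (positive).
#' @param values Numeric vector of the measure, same length.
#' @param form One of \code{"logarithmic"}, \code{"linear"},
#'   \code{"quadratic"}.
#' @return An object of class \code{"growth_fit"} with components
#'   \code{form}, \code{coefficients} (named \code{slope}/\code{intercept},
#'   or \code{c2}/\code{c1}/\code{c0}), \code{rss}, \code{n_obs},
#'   \code{bic}, and the underlying \code{lm} fit.
#' @seealso [select_growth_model()], [age_residuals()], [BIC.growth_fit()]
#' @export
#' @examples
#' age <- c(400, 800, 1600)
#' y <- -0.23 * log(age) + 4.452
#' coef(growth_fit(age, y, "logarithmic"))
growth_fit <- function(age_days, values,
                       form = c("logarithmic", "linear", "quadratic")) {
  form <- match.arg(form)
  stopifnot(length(age_days) == length(values))
  ok <- stats::complete.cases(age_days, values)
  age_days <- age_days[ok]; values <- values[ok]
  if (any(age_days <= 0)) stop("ages must be positive")
  k <- if (form == "quadratic") 3L else 2L
  if (length(values) < k + 1L)
    stop("need at least ", k + 1L, " observations for a ", form, " fit")
  if (length(unique(age_days)) < k)
    stop("rank-deficient design: too few distinct ages")
  df <- data.frame(age = age_days, y = values)
  lmfit <- switch(form,
                  logarithmic = stats::lm(y ~ log(age), data = df),
                  linear = stats::lm(y ~ age, data = df),
                  quadratic = stats::lm(y ~ I(age^2) + age, data = df))
  cf <- stats::coef(lmfit)
  coefs <- switch(form,
                  logarithmic = ,
                  linear = c(slope = unname(cf[2]), intercept = unname(cf[1])),
                  quadratic = c(c2 = unname(cf[2]), c1 = unname(cf[3]),
                                c0 = unname(cf[1])))
  rss <- sum(stats::residuals(lmfit)^2)
  n <- length(values)
  tss <- sum((values - mean(values))^2)
  obj <- structure(list(form = form, coefficients = coefs, rss = rss,
                        tss = tss, n_obs = n, lm = lmfit),
                   class = "growth_fit")
  obj$bic <- BIC(obj)
  obj
}

#' Bayesian Information Criterion of a growth fit
#'
#' Uses the least-squares convention
#' \eqn{\mathrm{BIC} = n \ln(\mathrm{RSS}/n) + k \ln n} with \eqn{k} the
#' number of regression coefficients (2 for logarithmic/linear, 3 for
#' quadratic); additive constants independent of the model cancel in BIC
#' differences, which is all model selection uses. A perfect fit
#' (\eqn{\mathrm{RSS} = 0}) returns \code{-Inf} with attribute
#' \code{perfect_fit = TRUE}.
#'
#' @param object A \code{"growth_fit"}.
#' @param ... Ignored.
#' @return Scalar BIC.
#' @export
BIC.growth_fit <- function(object, ...) {
  n <- object$n_obs
  k <- length(object$coefficients)
  # a fit whose residuals are pure numerical dust counts as perfect
  tss <- object$tss %||% sum((stats::fitted(object$lm) +
                                stats::residuals(object$lm) -
                                mean(stats::fitted(object$lm)))^2)
  if (object$rss <= 1e-20 * max(tss, .Machine$double.xmin))
    return(structure(-Inf, perfect_fit = TRUE))
  n * log(object$rss / n) + k * log(n)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Growth fit (%s), n = %d\n", x$form, x$n_obs))
  print(signif(x$coefficients, 6))
  cat(sprintf("RSS = %.6g, BIC = %.4f\n", x$rss, x$bic))
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  s <- summary(object$lm)
  cat(sprintf("Growth fit, %s form: ", object$form))
  cat(switch(object$form,
             logarithmic = "y = a*ln(age_days) + b\n",
             linear = "y = a*age_days + b\n",
             quadratic = "y = c2*age_days^2 + c1*age_days + c0\n"))
  print(signif(object$coefficients, 6))
  cat(sprintf("n = %d, RSS = %.6g, sigma = %.4g, BIC = %.4f\n",
              object$n_obs, object$rss, s$sigma, object$bic))
  invisible(s)
}

#' @export
predict.growth_fit <- function(object, age_days, ...) {
  if (missing(age_days)) return(stats::fitted(object$lm))
  cf <- object$coefficients
  switch(object$form,
         logarithmic = cf[["slope"]] * log(age_days) + cf[["intercept"]],
         linear = cf[["slope"]] * age_days + cf[["intercept"]],
         quadratic = cf[["c2"]] * age_days^2 + cf[["c1"]] * age_days +
           cf[["c0"]])
}

#' @export
residuals.growth_fit <- function(object, ...) {
  unname(stats::residuals(object$lm))
}

#' @export
fitted.growth_fit <- function(object, ...) unname(stats::fitted(object$lm))

#' Simulate new measure values from a fitted trajectory
#'
#' Draws Gaussian observations around the fitted curve with residual SD
#' \eqn{\sqrt{\mathrm{RSS}/(n-k)}} at the original ages.
#'
#' @param object A \code{"growth_fit"}.
#' @param nsim Number of simulated series.
#' @param seed Optional seed.
#' @param ... Ignored.
#' @return Data frame with \code{nsim} columns of simulated values.
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  stats::simulate(object$lm, nsim = nsim)
}

#' @export
plot.growth_fit <- function(x, xlab = "age (days)", ylab = "measure", ...) {
  age <- x$lm$model$age
  y <- x$lm$model$y
  graphics::plot(age, y, xlab = xlab, ylab = ylab, ...)
  grid <- seq(min(age), max(age), length.out = 200)
  graphics::lines(grid, predict(x, grid), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Fit all growth model forms and select by BIC
#'
#' Fits the logarithmic, quadratic and linear forms to the same series and
#' returns the selection; see [select_growth_model()].
#'
#' @inheritParams growth_fit
#' @param tie_threshold Models within this BIC difference of the minimum are
#'   reported as ties (default 2, the conventional "barely worth
#'   mentioning" band).
#' @return A \code{"growth_selection"}.
#' @export
fit_growth_models <- function(age_days, values, tie_threshold = 2) {
  fits <- lapply(c("logarithmic", "quadratic", "linear"),
                 function(f) growth_fit(age_days, values, f))
  names(fits) <- c("logarithmic", "quadratic", "linear")
  select_growth_model(fits, tie_threshold)
}

#' Select the best growth model by minimal BIC
#'
#' Given fits of several model forms to the same data (or a named vector of
#' BIC values), picks the form with minimal BIC. Forms whose BIC lies
#' within \code{tie_threshold} of the minimum are reported as ties. Exact
#' BIC ties are broken deterministically by the fixed form order
#' logarithmic, quadratic, linear.
#'
#' @param fits Named list of \code{"growth_fit"} objects fitted to the same
#'   observations, or a named numeric vector of BIC values.
#' @param tie_threshold BIC difference below which competing forms are
#'   flagged as ties (default 2).
#' @return An object of class \code{"growth_selection"}: list with
#'   \code{bic} (named vector), \code{best}, \code{ties} (forms other than
#'   \code{best} within the threshold), \code{tie_threshold}, and
#'   \code{fits} when fits were supplied.
#' @export
#' @examples
#' select_growth_model(c(logarithmic = 164.18, quadratic = 168.59,
#'                       linear = 163.46))$best   # "linear"
select_growth_model <- function(fits, tie_threshold = 2) {
  form_order <- c("logarithmic", "quadratic", "linear")
  if (is.numeric(fits)) {
    bic <- fits
    fit_list <- NULL
  } else {
    stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "growth_fit")))
    if (is.null(names(fits)))
      names(fits) <- vapply(fits, `[[`, "", "form")
    n_obs <- vapply(fits, `[[`, 0, "n_obs")
    if (length(unique(n_obs)) != 1)
      stop("fits were made on differing numbers of observations")
    bic <- vapply(fits, function(f) as.numeric(f$bic), 0)
    fit_list <- fits
  }
  if (is.null(names(bic)) || any(!nzchar(names(bic))))
    stop("fits/BIC values must be named by model form")
  ord <- order(match(names(bic), form_order))
  bic <- bic[ord]
  best <- names(bic)[which.min(bic)]   # first minimum in canonical order
  delta <- bic - min(bic)
  ties <- setdiff(names(bic)[delta < tie_threshold], best)
  structure(list(bic = bic, best = best, ties = ties,
                 tie_threshold = tie_threshold,
                 fits = if (!is.null(fit_list)) fit_list[ord]),
            class = "growth_selection")
}

#' @export
print.growth_selection <- function(x, ...) {
  cat("BIC model selection:\n")
  print(round(x$bic, 2))
  cat("best:", x$best,
      if (length(x$ties)) paste0("(ties: ", paste(x$ties, collapse = ", "),
                                 " at dBIC < ", x$tie_threshold, ")"),
      "\n")
  invisible(x)
}

#' Age-residualize a measure
#'
#' Removes the fitted age trend from a measure by subtracting the model
#' prediction (OLS residuals), so cross-measure correlations reflect
#' age-independent coupling. The residuals have mean zero to machine
#' precision.
#'
#' @inheritParams growth_fit
#' @param form Model form of the trend; the logarithmic form is the default
#'   used throughout the coupling analysis.
#' @return Numeric vector of residuals, same length as \code{values}.
#' @export
age_residuals <- function(age_days, values, form = "logarithmic") {
  residuals(growth_fit(age_days, values, form))
}
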