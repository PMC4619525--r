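#' Design matrix for the blood-use prediction model
#'
#' Intercept, indicator terms for the academic and teaching strata
#' (reference level: general) and a bed-count main effect; optionally
#' separate per-type bed slopes for sensitivity analysis.
#'
#' @param pop A `hospital_population` (or any data frame with `type` and
#'   `beds`).
#' @param per_type_slopes Add `beds:academic` and `beds:teaching`
#'   interaction columns.
#' @param covariates Terms besides the intercept: any of `"type"`, `"beds"`.
#' @return Numeric model matrix, one row per hospital.
#' @keywords internal
model_matrix_hospitals <- function(pop, per_type_slopes = FALSE,
                                   covariates = c("type", "beds")) {
  acad <- as.numeric(pop$type == "academic")
  teach <- as.numeric(pop$type == "teaching")
  X <- cbind("(Intercept)" = rep(1, nrow(pop)))
  if ("type" %in% covariates) {
    X <- cbind(X, typeacademic = acad, typeteaching = teach)
  }
  if ("beds" %in% covariates) X <- cbind(X, beds = pop$beds)
  if (per_type_slopes) {
    X <- cbind(X, "beds:typeacademic" = pop$beds * acad,
               "beds:typeteaching" = pop$beds * teach)
  }
  X
}

#' Fit the Poisson blood-use prediction model on a sample
#'
#' Fits, by iteratively reweighted least squares with a log link, the Poisson
#' regression of one product's annual count on hospital type (indicator
#' terms, reference level `general`) and bed count. Convergence is declared
#' when the relative deviance change falls below `epsilon` (default `1e-8`,
#' capped at `maxit` iterations); for a converged fit with an intercept the
#' score equations make the fitted means sum to the observed counts.
#'
#' @param sample A `hospital_population` subset (the drawn sample); must
#'   contain every stratum whose indicator is in the model.
#' @param product Which count to model: `"rbc"`, `"ffp"` or `"plt"`.
#' @param per_type_slopes Also estimate per-type bed slopes (off by default;
#'   small samples cannot support interactions).
#' @param covariates Terms besides the intercept (default type indicators
#'   and the beds main effect); reduce for degenerate designs, e.g.
#'   `character(0)` for an intercept-only fit.
#' @param epsilon,maxit IRLS convergence tolerance and iteration cap.
#' @return An object of class `poisson_fit` with components `coefficients`
#'   (log scale), `converged`, `iterations`, `deviance`, `product`, `n`.
#' @examples
#' pop <- generate_population(generator_config(seed = 3))
#' fit <- fit_poisson(pop[pop$hospital_id %in%
#'                          select_largest(pop)$hospital_ids, ], "rbc")
#' coef(fit)
#' @export
fit_poisson <- function(sample, product = PRODUCTS,
                        per_type_slopes = FALSE,
                        covariates = c("type", "beds"),
                        epsilon = 1e-8, maxit = 100) {
  product <- match.arg(product)
  if (nrow(sample) == 0) stop_validation("cannot fit on an empty sample")
  y <- sample[[product]]
  X <- model_matrix_hospitals(sample, per_type_slopes, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_validation("rank-deficient design: term(s) ",
                    paste(dropped, collapse = ", "),
                    " not estimable from this sample")
  }
  fit <- stats::glm.fit(X, y, family = stats::poisson(),
                        control = stats::glm.control(epsilon = epsilon,
                                                     maxit = maxit))
  structure(list(coefficients = stats::coef(fit),
                 converged = isTRUE(fit$converged),
                 iterations = fit$iter,
                 deviance = fit$deviance,
                 fitted.values = stats::setNames(fit$fitted.values,
                                                 sample$hospital_id),
                 y = stats::setNames(y, sample$hospital_id),
                 product = product,
                 per_type_slopes = per_type_slopes,
                 covariates = covariates,
                 n = nrow(sample)),
            class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf("Poisson blood-use model [%s], n = %d, %sconverged in %d iterations\n",
              toupper(x$product), x$n, if (x$converged) "" else "NOT ",
              x$iterations))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
coef.poisson_fit <- function(object, ...) object$coefficients

#' Predicted mean counts for a set of hospitals
#'
#' @param object A `poisson_fit`.
#' @param newdata A `hospital_population` (defaults to nothing; required).
#' @param ... Unused.
#' @return Named numeric vector of strictly positive predicted means,
#'   `exp(X beta)`, one per hospital.
#' @export
predict.poisson_fit <- function(object, newdata, ...) {
  X <- model_matrix_hospitals(newdata, object$per_type_slopes,
                              object$covariates)
  eta <- drop(X %*% object$coefficients)
  stats::setNames(exp(eta), newdata$hospital_id)
}

#' @export
fitted.poisson_fit <- function(object, ...) object$fitted.values

#' @export
residuals.poisson_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted.values
  if (type == "pearson") r <- r / sqrt(object$fitted.values)
  r
}

#' Predict blood use for every hospital in the population
#'
#' Applies a converged sample fit to the whole population (sampled and
#' unsampled hospitals alike), giving the model-based estimate of each
#' hospital's annual product count.
#'
#' @param fit A converged `poisson_fit`.
#' @param pop The full `hospital_population`.
#' @return Named numeric vector of predicted mean counts, all positive.
#' @export
predict_counts <- function(fit, pop) {
  stopifnot(inherits(fit, "poisson_fit"))
  if (!fit$converged) {
    stop_validation("model fit did not converge; refusing to predict")
  }
  predict(fit, pop)
}
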