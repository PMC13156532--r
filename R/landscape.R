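#' Ordinary / weighted least-squares fit with a tidy summary
#'
#' Thin wrapper over [stats::lm()] returning the quantities the landscape
#' layer reports: coefficients, standard errors, t values, p values, AIC
#' (Gaussian log-likelihood convention of [stats::AIC()]) and R-squared.
#' Rank deficiency is an error naming the collinear columns.
#'
#' @param data data.frame holding response and predictors.
#' @param response name of the response column.
#' @param predictors character vector of predictor column names (empty for
#'   the intercept-only model).
#' @param weights optional observation weights (WLS).
#' @return a `model_fit` list: `response`, `predictors`, `coefficients`
#'   (data.frame: term, estimate, se, t, p), `aic`, `r_squared`, `fit`.
#' @export
fit_lm <- function(data, response, predictors = character(0), weights = NULL) {
  n <- nrow(data)
  if (n <= length(predictors) + 1L) stop("more parameters than observations")
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = data, weights = weights)
  if (fit$rank < length(predictors) + 1L) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient fit; collinear terms: ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  list(response = response, predictors = predictors,
       coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                                 se = co[, 2], t = co[, 3], p = co[, 4],
                                 row.names = NULL),
       aic = stats::AIC(fit), r_squared = sm$r.squared, fit = fit)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor j
#' on all other predictors. Perfect collinearity yields `Inf`.
#'
#' @param data data.frame of predictors.
#' @param predictors character vector of column names (>= 2).
#' @param threshold flag value; predictors with `VIF >= threshold` are
#'   flagged (default 5).
#' @return data.frame: predictor, vif, flagged.
#' @export
vif <- function(data, predictors, threshold = 5) {
  if (length(predictors) < 2) stop("need at least two predictors")
  out <- vapply(predictors, function(p) {
    others <- setdiff(predictors, p)
    fml <- stats::as.formula(paste(p, "~", paste(others, collapse = " + ")))
    r2 <- summary(stats::lm(fml, data = data))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = predictors, vif = unname(out),
             flagged = unname(out) >= threshold)
}

#' Moran's I with inverse-distance weights
#'
#' Spatial autocorrelation of `values` at the supplied coordinates, with
#' weights `w_ij = 1 / d_ij` from great-circle distances and `w_ii = 0`;
#' expectation `E[I] = -1/(n-1)` and a normal-approximation p-value. The
#' engine is [ape::Moran.I()], which row-standardises the weight matrix
#' before evaluating the statistic.
#'
#' @param values numeric vector (length >= 4).
#' @param coords data.frame with `lat`, `lon` (one row per value).
#' @return list with `I`, `expected`, `sd`, `p`.
#' @export
morans_i <- function(values, coords) {
  if (length(values) < 4) stop("need at least 4 observations")
  if (stats::sd(values) == 0) stop("constant values")
  dm <- greatcircle_km(coords)
  w <- 1 / dm
  diag(w) <- 0
  res <- ape::Moran.I(values, w)
  list(I = res$observed, expected = res$expected, sd = res$sd, p = res$p.value)
}

#' Exhaustive small-model selection with conditional model averaging
#'
#' Fits every linear model with at most `max_terms` predictors drawn from
#' `covariates` (`1 + p + choose(p, 2)` candidates for the default
#' `max_terms = 2`), ranks them by AIC, restricts to the set with
#' `delta AIC < delta_max`, computes Akaike weights
#' `w_m = exp(-delta_m / 2) / sum(...)` over that set, and averages each term
#' over the models that contain it (conditional averaging), renormalising the
#' weights within that subset. The averaged standard error follows
#' Burnham & Anderson: `se_j = sum_m w'_m * sqrt(se_jm^2 + (b_jm - b_j)^2)`.
#' z-scores are `|b_j| / se_j` with two-sided normal p-values.
#'
#' @param data data.frame.
#' @param response response column name.
#' @param covariates character vector of candidate predictor names.
#' @param max_terms maximum predictors per model (default 2).
#' @param delta_max delta-AIC cutoff for the averaging set (default 2).
#' @param weights optional WLS weights applied to every candidate model.
#' @param use_aicc use the small-sample AICc instead of AIC.
#' @return an `averaged_model`: list with `models` (data.frame: model, aic,
#'   delta, weight, r_squared, in_set), `average` (data.frame: term,
#'   estimate, se, z, p, n_models) and `fits`.
#' @export
dredge_average <- function(data, response, covariates, max_terms = 2L,
                           delta_max = 2, weights = NULL, use_aicc = FALSE) {
  sets <- list(character(0))
  for (k in seq_len(min(max_terms, length(covariates)))) {
    sets <- c(sets, utils::combn(covariates, k, simplify = FALSE))
  }
  n <- nrow(data)
  fits <- lapply(sets, function(s) {
    tryCatch(fit_lm(data, response, s, weights = weights),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no candidate model could be estimated")
  fits <- fits[ok]; sets <- sets[ok]
  aic <- vapply(fits, function(f) {
    k <- length(f$predictors) + 2  # intercept + sigma
    if (use_aicc) f$aic + 2 * k * (k + 1) / (n - k - 1) else f$aic
  }, numeric(1))
  delta <- aic - min(aic)
  in_set <- delta < delta_max
  w <- exp(-delta / 2) * in_set
  w <- w / sum(w)
  labels <- vapply(sets, function(s) {
    if (length(s)) paste("~", paste(s, collapse = " + ")) else "~ 1"
  }, character(1))
  models <- data.frame(model = labels, aic = aic, delta = delta,
                       weight = ifelse(in_set, w, 0),
                       r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
                       in_set = in_set)
  ord <- order(models$aic)
  models <- models[ord, ]; fits <- fits[ord]; sets <- sets[ord]
  w <- models$weight

  terms_all <- unique(unlist(sets[models$in_set]))
  average <- do.call(rbind, lapply(terms_all, function(tm) {
    has <- which(models$in_set & vapply(sets, function(s) tm %in% s, logical(1)))
    wk <- w[has] / sum(w[has])
    est <- vapply(fits[has], function(f) {
      f$coefficients$estimate[f$coefficients$term == tm]
    }, numeric(1))
    se <- vapply(fits[has], function(f) {
      f$coefficients$se[f$coefficients$term == tm]
    }, numeric(1))
    b <- sum(wk * est)
    se_adj <- sum(wk * sqrt(se^2 + (est - b)^2))
    z <- abs(b) / se_adj
    data.frame(term = tm, estimate = b, se = se_adj, z = z,
               p = 2 * stats::pnorm(-z), n_models = length(has))
  }))
  structure(list(models = models, average = average, fits = fits),
            class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat(sprintf("averaged_model: %d candidate models, %d in the dAIC set\n",
              nrow(x$models), sum(x$models$in_set)))
  print(x$average, row.names = FALSE)
  invisible(x)
}
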