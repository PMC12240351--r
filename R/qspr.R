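#' Curvilinear model families
#'
#' The five single-descriptor families used in curve-estimation QSPR work:
#' \describe{
#'   \item{linear}{\eqn{Y = a + b_1 X}}
#'   \item{quadratic}{\eqn{Y = a + b_1 X + b_2 X^2}}
#'   \item{cubic}{\eqn{Y = a + b_1 X + b_2 X^2 + b_3 X^3}}
#'   \item{logarithmic}{\eqn{Y = a + b_1 \ln X}}
#'   \item{exponential}{\eqn{Y = a\, e^{b_1 X}}, fitted by ordinary least
#'     squares of \eqn{\ln Y} on \eqn{X}; goodness-of-fit statistics are
#'     reported on the log scale (the curve-estimation convention).}
#' }
#'
#' @return character vector of family names.
#' @export
qspr_families <- function() {
  c("linear", "quadratic", "cubic", "logarithmic", "exponential")
}

family_k <- function(family, powers = NULL) {
  if (family %in% c("quadratic", "cubic") && !is.null(powers)) return(length(powers))
  switch(family, linear = 1L, quadratic = 2L, cubic = 3L,
         logarithmic = 1L, exponential = 1L)
}

default_powers <- function(family) {
  switch(family, quadratic = 1:2, cubic = 1:3, NULL)
}

# evaluate a family equation on the response scale
eval_family <- function(family, a, b, x, powers = NULL) {
  a <- unname(a)
  b <- unname(b)
  switch(family,
    linear = a + b[1] * x,
    quadratic = ,
    cubic = {
      p <- if (is.null(powers)) default_powers(family) else powers
      a + colSums(t(outer(x, p, `^`)) * b)
    },
    logarithmic = {
      if (any(x <= 0)) stop("logarithmic family requires x > 0", call. = FALSE)
      a + b[1] * log(x)
    },
    exponential = a * exp(b[1] * x),
    stop("unknown family '", family, "'", call. = FALSE)
  )
}

#' Fit one curvilinear QSPR model
#'
#' Ordinary least squares of a property on a single descriptor under one of
#' the five families of [qspr_families()].  Polynomial families use the raw
#' design \eqn{\{1, x, \dots, x^k\}}; the logarithmic family regresses
#' \eqn{y} on \eqn{\ln x}; the exponential family regresses \eqn{\ln y} on
#' \eqn{x} and is reported multiplicatively as \eqn{Y = a e^{b_1 X}} with
#' \eqn{a = e^{\hat\alpha}}.
#'
#' The statistics block follows the curve-estimation convention:
#' \eqn{r^2 = 1 - SSE/SST}; \eqn{r = \mathrm{sign}(b_1)\sqrt{r^2}} for
#' single-predictor families and \eqn{+\sqrt{r^2}} for polynomial ones;
#' adjusted \eqn{R^2 = 1 - (1 - r^2)(n-1)/(n-k-1)};
#' \eqn{SE = \sqrt{SSE/(n-k-1)}}; \eqn{F = (r^2/k)/((1-r^2)/(n-k-1))} with a
#' \eqn{(k, n-k-1)} upper-tail p-value; 95% coefficient confidence intervals
#' from the t distribution on \eqn{n-k-1} degrees of freedom.  For
#' transformed families all of these live on the fitted (transformed) scale.
#'
#' @param data a data frame holding the descriptor and response columns (and
#'   optionally a `compound` label column).
#' @param family one of [qspr_families()].
#' @param x,y names (bare or quoted) of the descriptor and response columns;
#'   default `x` and `y`.
#' @param powers for the polynomial families only: the exponents of the design
#'   terms (default `1:2` / `1:3`).  `powers = c(2, 3)` fits the cubic with the
#'   linear term excluded, the parameterization under which the published
#'   cubic tables were produced (see the package vignette).
#' @param conf_level confidence level for coefficient intervals.
#' @return an object of class `qspr_fit`; see [tidy.qspr_fit()],
#'   [glance.qspr_fit()], [predict.qspr_fit()], [residual_table()],
#'   [autoplot.qspr_fit()].
#' @examples
#' d <- dplyr::inner_join(crc_descriptors(), crc_properties(), by = "compound")
#' fit <- fit_model(d, "linear", x = Ent_ABC, y = MW)
#' glance(fit)
#' @export
fit_model <- function(data, family, x = "x", y = "y", powers = NULL,
                      conf_level = 0.95) {
  family <- match.arg(family, qspr_families())
  xname <- as_colname(rlang::enquo(x), data, "x")
  yname <- as_colname(rlang::enquo(y), data, "y")
  xv <- data[[xname]]
  yv <- data[[yname]]
  labels <- if ("compound" %in% names(data)) as.character(data$compound) else
    as.character(seq_along(xv))
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]; labels <- labels[keep]
  n <- length(xv)

  if (!is.null(powers)) {
    if (!family %in% c("quadratic", "cubic")) {
      stop("`powers` applies to the polynomial families only", call. = FALSE)
    }
    stopifnot(all(powers >= 1), all(powers == round(powers)), !anyDuplicated(powers))
  }
  k <- family_k(family, powers)
  if (n < k + 2) {
    stop(family, " fit needs at least ", k + 2, " observations (got ", n, ")",
         call. = FALSE)
  }
  if (family == "logarithmic" && any(xv <= 0)) {
    stop("logarithmic fit requires strictly positive descriptor values", call. = FALSE)
  }
  if (family == "exponential" && any(yv <= 0)) {
    stop("exponential fit requires strictly positive response values", call. = FALSE)
  }
  if (length(unique(xv)) == 1) stop("degenerate predictor: all x equal", call. = FALSE)

  pw <- if (family %in% c("quadratic", "cubic")) {
    if (is.null(powers)) default_powers(family) else as.integer(powers)
  } else NULL
  design <- switch(family,
    linear = tibble::tibble(.y = yv, x1 = xv),
    quadratic = ,
    cubic = {
      d <- tibble::as_tibble(stats::setNames(
        lapply(pw, function(p) xv^p), paste0("x", seq_along(pw))))
      dplyr::bind_cols(tibble::tibble(.y = yv), d)
    },
    logarithmic = tibble::tibble(.y = yv, x1 = log(xv)),
    exponential = tibble::tibble(.y = log(yv), x1 = xv)
  )
  lmfit <- stats::lm(.y ~ ., data = design)
  if (anyNA(stats::coef(lmfit))) stop("singular design", call. = FALSE)
  stats_block <- qspr_statistics(lmfit, k = k, conf_level = conf_level)

  est <- stats::coef(lmfit)
  a <- unname(est[1])
  b <- unname(est[-1])
  if (family == "exponential") a <- exp(a)
  r <- if (k == 1) sign(b[1]) * sqrt(stats_block$r2) else sqrt(stats_block$r2)
  std_beta <- if (k == 1) {
    b[1] * stats::sd(design[[2]]) / stats::sd(design$.y)
  } else NA_real_

  structure(list(
    family = family, powers = pw,
    a = a, b = stats::setNames(b, paste0("b", seq_along(b))),
    r = r, r2 = stats_block$r2, adj_r2 = stats_block$adj_r2,
    se = stats_block$se, statistic = stats_block$F, p_value = stats_block$p,
    std_beta = std_beta, df = c(k = k, df2 = n - k - 1L), n = n,
    coef = stats_block$coef, conf_level = conf_level,
    xname = xname, yname = yname,
    data = tibble::tibble(compound = labels, x = xv, y = yv),
    model = lmfit
  ), class = "qspr_fit")
}

as_colname <- function(quo, data, default) {
  expr <- rlang::quo_get_expr(quo)
  nm <- if (rlang::is_symbol(expr)) rlang::as_string(expr) else
    if (is.character(expr)) expr else default
  if (!nm %in% names(data)) {
    # a variable holding the column name, e.g. x = some_string
    val <- tryCatch(rlang::eval_tidy(quo), error = function(e) NULL)
    if (is.character(val) && length(val) == 1 && val %in% names(data)) return(val)
    stop("column '", nm, "' not found in `data`", call. = FALSE)
  }
  nm
}

# goodness-of-fit block from a completed least-squares solve
qspr_statistics <- function(lmfit, k, conf_level = 0.95) {
  y <- stats::model.response(stats::model.frame(lmfit))
  n <- length(y)
  df2 <- n - k - 1L
  if (df2 <= 0) stop("not enough residual degrees of freedom", call. = FALSE)
  sse <- sum(stats::residuals(lmfit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  Fst <- if (r2 >= 1) Inf else (r2 / k) / ((1 - r2) / df2)
  ci <- stats::confint(lmfit, level = conf_level)
  cs <- stats::coef(summary(lmfit))
  list(
    r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1) / df2,
    se = sqrt(sse / df2),
    F = Fst,
    p = stats::pf(Fst, k, df2, lower.tail = FALSE),
    coef = tibble::tibble(
      term = rownames(cs),
      estimate = unname(cs[, 1]), std.error = unname(cs[, 2]),
      statistic = unname(cs[, 3]), p.value = unname(cs[, 4]),
      conf.low = unname(ci[, 1]), conf.high = unname(ci[, 2])
    )
  )
}

#' @export
print.qspr_fit <- function(x, ...) {
  cat("<qspr_fit> ", x$yname, " ~ ", x$family, "(", x$xname, ")\n", sep = "")
  eq <- switch(x$family,
    exponential = sprintf("%s = %.4g * exp(%.4g * %s)", x$yname, x$a, x$b[1], x$xname),
    logarithmic = sprintf("%s = %.4g + %.4g ln(%s)", x$yname, x$a, x$b[1], x$xname),
    paste0(x$yname, " = ", sprintf("%.4g", x$a),
           paste(sprintf(" %+.4g %s^%d", x$b, x$xname,
                         if (is.null(x$powers)) 1L else x$powers), collapse = ""))
  )
  cat("  ", eq, "\n", sep = "")
  cat(sprintf("  n = %d, r = %.3f, r2 = %.3f, adj R2 = %.3f, SE = %.3f, F = %.2f, p = %.4g\n",
              x$n, x$r, x$r2, x$adj_r2, x$se, x$statistic, x$p_value))
  invisible(x)
}

#' Tidy a fitted QSPR model
#'
#' Coefficient-level summary in broom layout.  For the exponential family the
#' rows are on the fitted (log) scale; the multiplicative front factor is
#' `exp(estimate)` of the intercept row.
#'
#' @param x a [fit_model()] result.
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.qspr_fit <- function(x, ...) x$coef

#' Model-level summary of a fitted QSPR model
#'
#' @param x a [fit_model()] result.
#' @param ... unused.
#' @return a one-row tibble: `family`, `r`, `r.squared`, `adj.r.squared`,
#'   `sigma` (standard error of estimate), `statistic` (F), `p.value`, `df`,
#'   `df.residual`, `nobs`.
#' @export
glance.qspr_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, r = x$r, r.squared = x$r2, adj.r.squared = x$adj_r2,
    sigma = x$se, statistic = x$statistic, p.value = x$p_value,
    df = x$df[["k"]], df.residual = x$df[["df2"]], nobs = x$n
  )
}

#' Predict from a fitted QSPR model
#'
#' Evaluates the family equation on the response scale (for the exponential
#' family, \eqn{a e^{b_1 x}}).
#'
#' @param object a [fit_model()] result.
#' @param newdata a data frame containing the descriptor column the model was
#'   fitted on, or a numeric vector of descriptor values.
#' @param ... unused.
#' @return numeric vector of predicted property values.
#' @export
predict.qspr_fit <- function(object, newdata = NULL, ...) {
  xv <- if (is.null(newdata)) object$data$x
    else if (is.data.frame(newdata)) {
      if (!object$xname %in% names(newdata)) {
        stop("`newdata` lacks descriptor column '", object$xname, "'", call. = FALSE)
      }
      newdata[[object$xname]]
    } else as.numeric(newdata)
  eval_family(object$family, object$a, object$b, xv, powers = object$powers)
}

#' Per-compound fitted values and residuals
#'
#' Residuals of a fitted model on its training data.  `scale = "model"` (the
#' default) works on the scale the least squares was solved on -- the log
#' scale for the exponential family -- where residuals sum to zero;
#' `scale = "response"` back-transforms to property units.
#'
#' @param fit a [fit_model()] result.
#' @param scale `"model"` or `"response"`.
#' @return a tibble with columns `compound`, `x`, `observed`, `fitted`,
#'   `residual`, carrying `mean_residual` and `rmse` as attributes.
#' @export
residual_table <- function(fit, scale = c("model", "response")) {
  stopifnot(inherits(fit, "qspr_fit"))
  scale <- match.arg(scale)
  if (scale == "model") {
    obs <- stats::model.response(stats::model.frame(fit$model))
    fitted <- stats::fitted(fit$model)
  } else {
    obs <- fit$data$y
    fitted <- predict(fit)
  }
  out <- tibble::tibble(
    compound = fit$data$compound, x = fit$data$x,
    observed = as.numeric(obs), fitted = as.numeric(fitted),
    residual = as.numeric(obs) - as.numeric(fitted)
  )
  attr(out, "mean_residual") <- mean(out$residual)
  attr(out, "rmse") <- sqrt(mean(out$residual^2))
  out
}
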