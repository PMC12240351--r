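#' A QSPR model from printed coefficients
#'
#' Wraps literature-reported coefficients as a first-class model, so a
#' validation run does not depend on refitting (or on regenerating the
#' training structures).  The equation is the one of [qspr_families()];
#' cubic coefficients are `b = c(b1, b2, b3)` for
#' \eqn{Y = a + b_1 X + b_2 X^2 + b_3 X^3}.
#'
#' @param family one of [qspr_families()].
#' @param a intercept (multiplicative front factor for the exponential
#'   family).
#' @param b slope coefficient(s), length matching the family.
#' @param property name of the property the model predicts (e.g. `"MW"`).
#' @param descriptor name of the descriptor column it consumes
#'   (e.g. `"Ent_ISI"`).
#' @param powers optional polynomial exponents (default `1:length(b)`).
#' @return an object of class `qspr_model`.
#' @examples
#' m <- qspr_model("cubic", a = 323.0, b = c(18.4, -75.9, 24.7),
#'                 property = "MW", descriptor = "Ent_ISI")
#' predict(m, 3.01)  # 364.31
#' @export
qspr_model <- function(family, a, b, property = NULL, descriptor = NULL,
                       powers = NULL) {
  family <- match.arg(family, qspr_families())
  k <- family_k(family, powers)
  if (length(b) != k) {
    stop(family, " family needs ", k, " slope coefficient(s), got ", length(b),
         call. = FALSE)
  }
  structure(list(
    family = family, a = a, b = stats::setNames(as.numeric(b), paste0("b", seq_len(k))),
    powers = if (family %in% c("quadratic", "cubic")) {
      if (is.null(powers)) seq_len(k) else as.integer(powers)
    } else NULL,
    property = property, descriptor = descriptor
  ), class = "qspr_model")
}

#' @export
print.qspr_model <- function(x, ...) {
  cat("<qspr_model> ", x$family,
      if (!is.null(x$property)) paste0(": ", x$property),
      if (!is.null(x$descriptor)) paste0(" ~ f(", x$descriptor, ")"), "\n", sep = "")
  cat("  a =", x$a, " b =", paste(x$b, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname qspr_model
#' @param object a `qspr_model`.
#' @param newdata numeric descriptor values, or a data frame containing the
#'   model's descriptor column.
#' @param ... unused.
#' @export
predict.qspr_model <- function(object, newdata, ...) {
  xv <- if (is.data.frame(newdata)) {
    if (is.null(object$descriptor) || !object$descriptor %in% names(newdata)) {
      stop("`newdata` lacks descriptor column '", object$descriptor, "'", call. = FALSE)
    }
    newdata[[object$descriptor]]
  } else as.numeric(newdata)
  eval_family(object$family, object$a, object$b, xv, powers = object$powers)
}

model_label <- function(m) {
  paste0(m$family, "(", if (is.null(m$descriptor)) "x" else m$descriptor, ")")
}

#' Experimental-versus-calculated validation table
#'
#' Applies a set of models (fitted [fit_model()] objects or printed-coefficient
#' [qspr_model()]s) to new compounds and tabulates calculated against
#' experimental values, one record per model per compound.  Calculated values
#' are kept at full precision; round at serialization (the published tables
#' print 2 decimal places).
#'
#' @param models a single model or a list of models; each must name the
#'   descriptor column it consumes (and, for residuals, the property).
#' @param descriptors descriptor tibble for the new compounds (column
#'   `compound` plus descriptor columns).
#' @param properties optional property tibble with experimental values.
#' @return a tibble with columns `compound`, `property`, `model`,
#'   `descriptor`, `x`, `calculated`, `experimental`, `residual`
#'   (`experimental - calculated`; `NA` when no experimental value exists).
#' @examples
#' validation_table(crc_validation_models(),
#'                  crc_validation_descriptors(),
#'                  crc_validation_properties())
#' @export
validation_table <- function(models, descriptors, properties = NULL) {
  if (inherits(models, "qspr_model") || inherits(models, "qspr_fit")) {
    models <- list(models)
  }
  stopifnot("compound" %in% names(descriptors))
  rows <- purrr::map(models, function(m) {
    desc <- if (inherits(m, "qspr_fit")) m$xname else m$descriptor
    prop <- if (inherits(m, "qspr_fit")) m$yname else m$property
    if (is.null(desc) || !desc %in% names(descriptors)) {
      stop("missing descriptor column '", desc %||% "?", "' for model ",
           model_label(m), call. = FALSE)
    }
    xv <- descriptors[[desc]]
    calc <- if (inherits(m, "qspr_fit")) predict(m, xv) else predict(m, xv)
    expv <- if (!is.null(properties) && !is.null(prop) && prop %in% names(properties)) {
      properties[[prop]][match(descriptors$compound, properties$compound)]
    } else rep(NA_real_, length(xv))
    tibble::tibble(
      compound = descriptors$compound,
      property = prop %||% NA_character_,
      model = model_label(if (inherits(m, "qspr_fit")) {
        list(family = m$family, descriptor = m$xname)
      } else m),
      descriptor = desc, x = xv, calculated = calc,
      experimental = expv, residual = expv - calc
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a validation table as CSV
#'
#' Calculated values and residuals are rounded to 2 decimal places at
#' serialization, matching the printed comparison tables.
#'
#' @param records a [validation_table()] tibble.
#' @param file output path.
#' @return `records`, invisibly.
#' @export
write_validation_csv <- function(records, file) {
  out <- dplyr::mutate(records,
                       calculated = round(.data$calculated, 2),
                       residual = round(.data$residual, 2))
  readr::write_csv(out, file)
  invisible(records)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
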