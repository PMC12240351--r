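#' Full descriptor-by-property-by-family fit report
#'
#' Fits every requested (entropy index, property, family) combination and
#' collects the coefficient and goodness-of-fit block into one tibble, the
#' layout of the published statistical-parameter tables.  Values are kept at
#' full precision; [format_fit_report()] applies the printed rounding.
#'
#' @param descriptors a descriptor tibble (column `compound` plus descriptor
#'   columns, e.g. from [crc_descriptors()] or [descriptor_table()]).
#' @param properties a property tibble (column `compound` plus property
#'   columns, e.g. [crc_properties()]).
#' @param indices descriptor columns to use; default all non-`compound`
#'   columns of `descriptors`.
#' @param props property columns to use; default all non-`compound` columns
#'   of `properties`.
#' @param families model families; default all of [qspr_families()].
#' @param powers optional `powers` override forwarded to [fit_model()] for
#'   the polynomial families.
#' @param alpha significance threshold for the indicator column.
#' @return a tibble with one row per combination: `descriptor`, `property`,
#'   `family`, `a`, `b1`, `b2`, `b3`, `r`, `r2`, `adj_r2`, `se`, `statistic`,
#'   `p_value`, `significant`.
#' @examples
#' rep <- fit_report(crc_descriptors(), crc_properties(),
#'                   indices = "Ent_ABC", props = "MW")
#' @export
fit_report <- function(descriptors, properties, indices = NULL, props = NULL,
                       families = qspr_families(), powers = NULL, alpha = 0.05) {
  stopifnot("compound" %in% names(descriptors), "compound" %in% names(properties))
  only_d <- setdiff(descriptors$compound, properties$compound)
  only_p <- setdiff(properties$compound, descriptors$compound)
  if (length(only_d) || length(only_p)) {
    stop("compound labels do not align; only in descriptors: [",
         paste(only_d, collapse = ", "), "]; only in properties: [",
         paste(only_p, collapse = ", "), "]", call. = FALSE)
  }
  if (is.null(indices)) indices <- setdiff(names(descriptors), "compound")
  if (is.null(props)) props <- setdiff(names(properties), "compound")
  families <- vapply(families, match.arg, "", choices = qspr_families())
  joined <- dplyr::inner_join(descriptors, properties, by = "compound",
                              suffix = c("", ".prop"))

  grid <- tidyr::expand_grid(descriptor = indices, property = props,
                             family = unname(families))
  rows <- purrr::pmap(grid, function(descriptor, property, family) {
    d <- tibble::tibble(compound = joined$compound,
                        x = joined[[descriptor]], y = joined[[property]])
    fit <- fit_model(d, family, powers = powers)
    b <- c(unname(fit$b), rep(NA_real_, 3 - length(fit$b)))
    tibble::tibble(
      descriptor = descriptor, property = property, family = family,
      a = fit$a, b1 = b[1], b2 = b[2], b3 = b[3],
      r = fit$r, r2 = fit$r2, adj_r2 = fit$adj_r2, se = fit$se,
      statistic = fit$statistic, p_value = fit$p_value,
      significant = ifelse(fit$p_value <= alpha, "Significant", "Insignificant")
    )
  })
  dplyr::bind_rows(rows)
}

#' Select the best family per descriptor and property
#'
#' Argmax of \eqn{r^2} within each (descriptor, property) group; ties break
#' toward the family with fewer slope coefficients.
#'
#' @param report a [fit_report()] tibble.
#' @return a tibble with one row per (descriptor, property): the selected
#'   `family` and its `r2`.
#' @export
best_model <- function(report) {
  if (nrow(report) == 0) stop("empty report", call. = FALSE)
  kmap <- c(linear = 1, logarithmic = 1, exponential = 1, quadratic = 2, cubic = 3)
  report |>
    dplyr::mutate(.k = kmap[.data$family]) |>
    dplyr::group_by(.data$descriptor, .data$property) |>
    dplyr::arrange(dplyr::desc(.data$r2), .data$.k, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("descriptor", "property", "family", "r2")
}

#' Round a fit report the way the published tables print it
#'
#' Coefficients, intercept, standard error and F to 1 decimal place, `r` to
#' 2 and `r2` to 3, p-values printed to 3 decimals (so anything below 0.0005
#' shows as `"0.000"`).
#'
#' @param report a [fit_report()] tibble.
#' @return a tibble with rounded numeric columns and a character `p_value`.
#' @export
format_fit_report <- function(report) {
  report |>
    dplyr::mutate(
      dplyr::across(c("a", "b1", "b2", "b3", "se", "statistic"), ~ round(.x, 1)),
      r = round(.data$r, 2), r2 = round(.data$r2, 3),
      adj_r2 = round(.data$adj_r2, 3),
      p_value = sprintf("%.3f", .data$p_value)
    )
}

#' Write a fit report as CSV
#'
#' @param report a [fit_report()] tibble.
#' @param file output path.
#' @param formatted apply [format_fit_report()] rounding first (default).
#' @return `report`, invisibly.
#' @export
write_fit_report <- function(report, file, formatted = TRUE) {
  out <- if (formatted) format_fit_report(report) else report
  readr::write_csv(out, file)
  invisible(report)
}
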