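test_that("linear fit of MW on Ent_ABC reproduces the published statistics", {
  fit <- fit_model(crc_joined(), "linear", x = Ent_ABC, y = MW)
  expect_equal(round(fit$b[["b1"]], 3), 290.601)
  expect_equal(round(fit$a, 3), -531.321)
  expect_equal(round(fit$std_beta, 3), 0.891)
  ci <- dplyr::filter(tidy(fit), term != "(Intercept)")
  expect_equal(round(ci$conf.low, 3), 197.417)
  expect_equal(round(ci$conf.high, 3), 383.786)
  ici <- dplyr::filter(tidy(fit), term == "(Intercept)")
  expect_equal(round(ici$conf.low, 3), -839.585)
  expect_equal(round(ici$conf.high, 3), -223.057)
  expect_equal(round(fit$statistic, 1), 46.2)
  expect_equal(round(fit$se, 1), 82.7)
  expect_equal(round(fit$r, 2), 0.89)
  expect_lt(fit$p_value, 0.0005)
})

test_that("exponential fit is log-linear OLS reported multiplicatively", {
  fit <- fit_model(crc_joined(), "exponential", x = Ent_ABC, y = MW)
  expect_equal(round(fit$a, 1), 32.1)
  expect_equal(round(fit$b[["b1"]], 1), 0.8)
  expect_equal(round(fit$r2, 3), 0.808)
  expect_equal(round(fit$se, 1), 0.2)
  # identical to a linear fit on the pre-transformed response
  d <- dplyr::mutate(crc_joined(), logMW = log(MW))
  ref <- fit_model(d, "linear", x = Ent_ABC, y = logMW)
  expect_equal(log(fit$a), ref$a, tolerance = 1e-12)
  expect_equal(unname(fit$b), unname(ref$b), tolerance = 1e-12)
  expect_equal(fit$r2, ref$r2, tolerance = 1e-12)
  # predictions are on the response scale
  expect_equal(predict(fit, 0), fit$a)
})

test_that("logarithmic fit equals a linear fit on pre-transformed ln x", {
  d <- dplyr::mutate(crc_joined(), lnx = log(Ent_ABC))
  f1 <- fit_model(crc_joined(), "logarithmic", x = Ent_ABC, y = MW)
  f2 <- fit_model(d, "linear", x = lnx, y = MW)
  expect_equal(f1$a, f2$a, tolerance = 1e-12)
  expect_equal(unname(f1$b), unname(f2$b), tolerance = 1e-12)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-12)
  expect_equal(round(f1$b[["b1"]], 1), 876.5)
  expect_equal(round(f1$a, 1), -607.9)
  expect_equal(round(f1$r2, 3), 0.744)
})

test_that("quadratic fit of MW on Ent_ABC reproduces the published row", {
  fit <- fit_model(crc_joined(), "quadratic", x = Ent_ABC, y = MW)
  expect_equal(round(fit$b[["b1"]], 1), -641.9)
  expect_equal(round(fit$b[["b2"]], 1), 145.6)
  expect_equal(round(fit$a, 1), 922.2)
  expect_equal(round(fit$r2, 3), 0.867)
  expect_equal(round(fit$se, 1), 69.3)
})

test_that("a noiseless cubic is recovered exactly (interpolation limit)", {
  x <- c(0.5, 1, 1.7, 2.2, 3.1, 4)
  d <- tibble::tibble(x = x, y = 2 + 3 * x - x^2 + 0.5 * x^3)
  suppressWarnings(fit <- fit_model(d, "cubic"))
  expect_equal(fit$a, 2, tolerance = 1e-8)
  expect_equal(unname(fit$b), c(3, -1, 0.5), tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$se, 0, tolerance = 1e-6)
  # nested polynomial families can only lose fit
  suppressWarnings({
    r2s <- vapply(c("linear", "quadratic", "cubic"),
                  function(f) fit_model(d, f)$r2, 0)
  })
  expect_true(all(diff(r2s) >= -1e-12))
})

test_that("r2 is monotone across nested polynomial degrees on real data", {
  d <- crc_joined()
  for (prop in c("MW", "C", "P")) {
    r2s <- vapply(c("linear", "quadratic", "cubic"), function(f) {
      fit_model(d, f, x = "Ent_ABC", y = prop)$r2
    }, 0)
    expect_true(all(diff(r2s) >= -1e-12))
  }
})

test_that("every family agrees with a brute-force normal-equations oracle", {
  set.seed(42)
  for (rep in 1:5) {
    x <- runif(10, 1, 4)
    y <- exp(runif(10, 1, 3))
    d <- tibble::tibble(x = x, y = y)
    designs <- list(
      linear = cbind(1, x),
      quadratic = cbind(1, x, x^2),
      cubic = cbind(1, x, x^2, x^3),
      logarithmic = cbind(1, log(x))
    )
    for (fam in names(designs)) {
      fit <- fit_model(d, fam)
      expect_equal(unname(c(fit$a, fit$b)), oracle_ols(designs[[fam]], y),
                   tolerance = 1e-8)
    }
    efit <- fit_model(d, "exponential")
    eref <- oracle_ols(cbind(1, x), log(y))
    expect_equal(unname(c(log(efit$a), efit$b)), eref, tolerance = 1e-8)
  }
})

test_that("the statistics block is internally consistent", {
  d <- crc_joined()
  for (fam in qspr_families()) {
    fit <- fit_model(d, fam, x = Ent_ISI, y = MV)
    # r2 = r^2, within sign handling
    expect_equal(fit$r^2, fit$r2, tolerance = 1e-12)
    expect_gte(fit$r2, 0); expect_lte(fit$r2, 1)
    expect_gte(fit$statistic, 0)
    expect_gte(fit$p_value, 0); expect_lte(fit$p_value, 1)
    # each CI contains its point estimate
    co <- tidy(fit)
    expect_true(all(co$conf.low <= co$estimate & co$estimate <= co$conf.high))
    # residuals of the least-squares solve sum to zero
    rt <- residual_table(fit)
    expect_equal(mean(rt$residual), 0, tolerance = 1e-9)
    # r2 equals squared correlation of fitted vs observed on the fitted scale
    expect_equal(cor(rt$fitted, rt$observed)^2, fit$r2, tolerance = 1e-10)
    # adjusted R2 identity
    k <- fit$df[["k"]]
    expect_equal(fit$adj_r2,
                 1 - (1 - fit$r2) * (fit$n - 1) / (fit$n - k - 1),
                 tolerance = 1e-12)
  }
})

test_that("family preconditions are enforced", {
  d <- tibble::tibble(x = c(1, 2, 3), y = c(1, 2, 3))
  expect_error(fit_model(d, "cubic"), "at least 5 observations")
  expect_error(fit_model(tibble::tibble(x = c(1, 1, 1, 1), y = 1:4), "linear"),
               "degenerate predictor")
  expect_error(fit_model(tibble::tibble(x = c(-1, 1, 2, 3), y = 1:4),
                         "logarithmic"), "positive descriptor")
  expect_error(fit_model(tibble::tibble(x = 1:4, y = c(-1, 1, 2, 3)),
                         "exponential"), "positive response")
  expect_error(fit_model(crc_joined(), "linear", x = nope, y = MW), "not found")
  expect_error(fit_model(crc_joined(), "banana", x = Ent_ABC, y = MW))
})

test_that("fit_report covers the full descriptor-property-family grid", {
  rep <- fit_report(crc_descriptors(), crc_properties())
  expect_equal(nrow(rep), 10 * 7 * 5)
  expect_equal(nrow(dplyr::distinct(rep, descriptor)), 10)

  one <- fit_report(crc_descriptors(), crc_properties(),
                    indices = "Ent_ABC", props = "MW", families = "cubic")
  expect_equal(nrow(one), 1)

  row <- dplyr::filter(rep, descriptor == "Ent_ABC", property == "MW",
                       family == "linear")
  expect_equal(round(row$b1, 1), 290.6)
  expect_equal(round(row$a, 1), -531.3)
  expect_equal(round(row$r, 2), 0.89)
  expect_equal(round(row$r2, 2), 0.79)
  expect_equal(round(row$se, 1), 82.7)
  expect_equal(round(row$statistic, 1), 46.2)
  expect_equal(row$significant, "Significant")

  # surface area and density are essentially unpredictable from these indices
  weak <- dplyr::filter(rep, property %in% c("TSA", "D"),
                        family != "cubic")
  expect_lt(max(weak$r2), 0.35)
  weak_cubic <- fit_report(crc_descriptors(), crc_properties(),
                           props = c("TSA", "D"), families = "cubic",
                           powers = c(2, 3))
  expect_lt(max(weak_cubic$r2), 0.35)

  expect_error(
    fit_report(crc_descriptors(),
               dplyr::mutate(crc_properties(),
                             compound = replace(compound, 1, "Unknownium"))),
    "Unknownium")
})

test_that("the published cubic parameterization omits the linear term", {
  # OLS on {1, x^2, x^3} reproduces the printed cubic block for MW ~ Ent_ABC
  fit <- fit_model(crc_joined(), "cubic", x = Ent_ABC, y = MW, powers = c(2, 3))
  expect_equal(round(fit$a, 1), 323)
  expect_equal(round(fit$b[["b1"]], 1), -75.9)  # x^2 term
  expect_equal(round(fit$b[["b2"]], 1), 24.7)   # x^3 term
  expect_equal(round(fit$r2, 3), 0.877)
  expect_equal(round(fit$se, 1), 66.5)
  expect_equal(round(fit$statistic, 1), 39.4)
  # the full cubic fits strictly better, as it must
  full <- fit_model(crc_joined(), "cubic", x = Ent_ABC, y = MW)
  expect_gt(full$r2, fit$r2)
  expect_error(fit_model(crc_joined(), "linear", x = Ent_ABC, y = MW,
                         powers = c(2, 3)), "polynomial")
})

test_that("best_model maximizes r2 with ties broken toward fewer parameters", {
  rep <- fit_report(crc_descriptors(), crc_properties(),
                    indices = "Ent_ABC", props = "MW")
  expect_equal(best_model(rep)$family, "cubic")

  tie <- tibble::tibble(
    descriptor = "d", property = "p",
    family = c("linear", "cubic"), r2 = c(0.9, 0.9)
  )
  expect_equal(best_model(tie)$family, "linear")
  single <- dplyr::filter(rep, family == "logarithmic")
  expect_equal(best_model(single)$family, "logarithmic")
  expect_error(best_model(rep[0, ]), "empty")
})

test_that("formatted reports round the way the published tables print", {
  rep <- fit_report(crc_descriptors(), crc_properties(),
                    indices = "Ent_ABC", props = "MW")
  fm <- format_fit_report(rep)
  lin <- dplyr::filter(fm, family == "linear")
  expect_equal(lin$b1, 290.6)
  expect_equal(lin$p_value, "0.000")
  f <- withr::local_tempfile(fileext = ".csv")
  write_fit_report(rep, f)
  expect_true(file.exists(f))
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(back), 5)
})
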