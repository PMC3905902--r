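test_that("the shared rate is recovered exactly from noiseless series", {
  ts <- make_timeseries(k = 0.015, a0 = c(1, 0.8, 1.2), b0 = c(1, 0.9, 1.1))
  fit <- fit_shared_rate(ts)
  expect_lt(abs(fit$k - 0.015) / 0.015, 1e-6)
  expect_equal(as.numeric(fit$amplitudes),
               c(1, 0.8, 1.2, 1, 0.9, 1.1), tolerance = 1e-6)
  expect_false(fit$at_bound)
})

test_that("a single noiseless rise matches the closed-form rate at any point", {
  k0 <- 0.004
  ts <- make_timeseries(k = k0, a0 = numeric(0), b0 = 2,
                        timepoints = seq(0, 900, length.out = 12))
  fit <- fit_shared_rate(ts)
  b0 <- fit$amplitudes[[1]]
  t1 <- ts$times[5]; bt <- predict(fit, t1)[1, 1]
  k_closed <- unname(-log(1 - bt / b0) / t1)
  expect_equal(fit$k, k_closed, tolerance = 1e-6)
  expect_equal(fit$k, k0, tolerance = 1e-6)
})

test_that("paired amplitudes conserve total intensity along the fit", {
  ts <- make_timeseries(k = 0.02, a0 = 1.5, b0 = 1.5)
  fit <- fit_shared_rate(ts)
  tgrid <- seq(0, 200, length.out = 50)
  pr <- predict(fit, tgrid)
  expect_equal(pr[, 1] + pr[, 2], rep(1.5, 50), tolerance = 1e-6)
})

test_that("recovery error shrinks as noise decreases", {
  med_err <- sapply(c(0.10, 0.05, 0.01), function(sg) {
    errs <- sapply(1:15, function(r) {
      ts <- make_timeseries(noise_sd = sg, seed = 400 + r)
      abs(fit_shared_rate(ts)$k - 0.015) / 0.015
    })
    median(errs)
  })
  expect_true(all(diff(med_err) < 0))
  expect_lt(med_err[2], 0.05)
})

test_that("degenerate series are rejected and boundary rates are flagged", {
  flat <- peak_series(0:5, matrix(1, 6, 2), c("decay", "rise"))
  expect_error(fit_shared_rate(flat), "not identifiable")
  two <- make_timeseries(timepoints = c(0, 50))
  expect_error(fit_shared_rate(two), "3 time points")
  # rate far outside the heuristic bracket lands on the search bound
  fastest <- make_timeseries(k = 5, timepoints = seq(0, 5000, length.out = 20))
  expect_warning(fit_shared_rate(fastest), "bound")
})

test_that("the profiled fit agrees with an independent joint nonlinear fit", {
  skip_if_not_installed("minpack.lm")
  ts <- make_timeseries(k = 0.015, a0 = c(1, 0.7, 1.3), b0 = c(1.1, 0.9, 1),
                        noise_sd = 0.03, seed = 99)
  fit <- fit_shared_rate(ts)
  df <- data.frame(
    t = rep(ts$times, ncol(ts$series)),
    y = as.numeric(ts$series),
    peak = factor(rep(colnames(ts$series), each = length(ts$times))),
    rise = rep(ts$direction == "rise", each = length(ts$times)))
  start <- c(list(k = 0.01), as.list(setNames(rep(1, 6), paste0("A", 1:6))))
  amp_expr <- paste0("ifelse(peak == '", colnames(ts$series), "', A",
                     1:6, ", 0)", collapse = " + ")
  form <- as.formula(paste(
    "y ~ (", amp_expr, ") * ifelse(rise, 1 - exp(-k * t), exp(-k * t))"))
  ref <- minpack.lm::nlsLM(form, data = df, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  expect_equal(fit$k, coef(ref)[["k"]], tolerance = 1e-5)
  expect_equal(fit$k_stderr, summary(ref)$coefficients["k", "Std. Error"],
               tolerance = 1e-3)
})

test_that("rate_fit behaves like a fitted model object", {
  ts <- make_timeseries(noise_sd = 0.02, seed = 7)
  fit <- fit_shared_rate(ts)
  expect_s3_class(fit, "rate_fit")
  expect_named(coef(fit)[1], "k")
  expect_equal(dim(fitted(fit)), dim(ts$series))
  expect_equal(residuals(fit), ts$series - fitted(fit))
  expect_output(print(fit), "shared rate|Global first-order")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.rate_fit")
  expect_output(print(sm), "half-life")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "peak_series")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("time series round-trip through TSV with their direction row", {
  ts <- make_timeseries(noise_sd = 0.01, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_timeseries(ts, path)
  back <- read_timeseries(path)
  expect_equal(back$times, ts$times)
  expect_equal(back$direction, ts$direction)
  expect_equal(unname(back$series), unname(ts$series), tolerance = 1e-9)
})
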