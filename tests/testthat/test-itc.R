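# One-site isotherm simulation and fitting.

test_that("null enthalpy gives pure baseline heats", {
  tg <- simulate_titration(binding_params(1, 0.05, dH = 0, q0 = 0.7),
                           itc_protocol())
  expect_equal(tg$heat_ucal, rep(0.7, 24), tolerance = 1e-12)
})

test_that("simulation is deterministic under a fixed seed", {
  p <- binding_params(1, 0.051, -8000)
  a <- simulate_titration(p, noise_sd = 0.05, seed = 42)
  b <- simulate_titration(p, noise_sd = 0.05, seed = 42)
  expect_identical(a, b)
  c <- simulate_titration(p, noise_sd = 0.05, seed = 43)
  expect_false(identical(a$heat_ucal, c$heat_ucal))
})

test_that("negating dH negates every heat", {
  prot <- itc_protocol()
  up <- simulate_titration(binding_params(1, 0.2, 8000), prot)
  dn <- simulate_titration(binding_params(1, 0.2, -8000), prot)
  expect_equal(up$heat_ucal, -dn$heat_ucal, tolerance = 1e-12)
})

test_that("tight-binding heat sums to the closed-form total", {
  prot <- itc_protocol()
  for (n in c(0.8, 1, 1.2)) {
    tg <- simulate_titration(binding_params(n, 1e-6, -8000), prot)
    total <- sum(tg$heat_ucal)
    closed <- n * prot$cell_conc * -8000 * prot$cell_volume * 1e-6
    # agreement up to the O(v/V0) displacement correction (v/V0 = 19%)
    expect_equal(total, closed, tolerance = 0.05)
  }
})

test_that("errors and degenerate inputs are handled explicitly", {
  expect_error(binding_params(1, Kd = -1, dH = 1), "Kd")
  expect_error(binding_params(0, Kd = 1, dH = 1), "n")
  tg <- simulate_titration(binding_params(1, 0.05, -8000),
                           itc_protocol(n_injections = 4L))
  expect_error(fit_one_site(tg, itc_protocol(n_injections = 4L)),
               "at least 6")
  # all-zero thermogram: dH ~ 0 and unidentifiable Kd must be flagged
  zero <- simulate_titration(binding_params(1, 0.05, 0), itc_protocol())
  fit <- fit_one_site(zero, itc_protocol())
  expect_lt(abs(coef(fit)[["dH"]]), 1)
  expect_false(fit$identifiable)
})

test_that("noiseless fit recovers the wild-type affinity within 1%", {
  prot <- itc_protocol()
  truth <- binding_params(1, 0.051, -8000, q0 = 0)
  fit <- fit_one_site(simulate_titration(truth, prot), prot)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["Kd"]] / 0.051 - 1), 0.01)
  expect_lt(abs(coef(fit)[["n"]] - 1), 0.01)
  expect_lt(abs(coef(fit)[["dH"]] / -8000 - 1), 0.01)
})

test_that("1% noise keeps Kd recovery within 10% (fixed seed)", {
  prot <- itc_protocol()
  truth <- binding_params(1, 0.051, -8000)
  scale <- max(abs(simulate_titration(truth, prot)$heat_ucal))
  tg <- simulate_titration(truth, prot, noise_sd = 0.01 * scale, seed = 1)
  fit <- fit_one_site(tg, prot)
  expect_lt(abs(coef(fit)[["Kd"]] / 0.051 - 1), 0.10)
})

test_that("baseline offset and drop_first are honoured", {
  prot <- itc_protocol()
  truth <- binding_params(1, 0.1, -6000, q0 = 0.4)
  fit <- fit_one_site(simulate_titration(truth, prot), prot)
  expect_lt(abs(coef(fit)[["q0"]] - 0.4), 0.01)
  fit2 <- fit_one_site(simulate_titration(truth, prot), prot,
                       drop_first = TRUE)
  expect_equal(length(fit2$residuals), 23L)
  expect_lt(abs(coef(fit2)[["Kd"]] / 0.1 - 1), 0.01)
})

test_that("refitting from recovered parameters is idempotent", {
  prot <- itc_protocol()
  tg <- simulate_titration(binding_params(1, 0.5, -7000), prot,
                           noise_sd = 0.05, seed = 9)
  f1 <- fit_one_site(tg, prot)
  f2 <- fit_one_site(tg, prot, init = as.list(coef(f1)))
  expect_lt(abs(f2$rss - f1$rss) / max(f1$rss, 1e-12), 1e-6)
})

test_that("itc_fit methods are coherent", {
  prot <- itc_protocol()
  tg <- simulate_titration(binding_params(1, 0.051, -8000), prot,
                           noise_sd = 0.03, seed = 2)
  fit <- fit_one_site(tg, prot)
  expect_named(coef(fit), c("n", "Kd", "dH", "q0"))
  expect_equal(fitted(fit) + residuals(fit), tg$heat_ucal, tolerance = 1e-9)
  expect_equal(predict(fit)[fit$use], fitted(fit), tolerance = 1e-9)
  expect_equal(dim(vcov(fit)), c(4L, 4L))
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "thermogram")
  expect_output(print(fit), "One-site ITC fit")
  expect_output(print(summary(fit)), "fittable")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("fold changes reproduce the published affinity ratios", {
  # 5mC-modified site vs wild type: 2336 nM vs 51 nM, beyond 45-fold
  expect_gt(fold_change(2.336, 0.051), 45)
  expect_equal(fold_change(2.336, 0.051), 45.8, tolerance = 0.01)
  expect_equal(fold_change(1, 1), 1)
  # the strongest core base-pair mutants fall in the ~20-50-fold band
  expect_equal(fold_change(2.59, 0.051), 50.8, tolerance = 0.01)
  expect_equal(fold_change(2.004, 0.051), 39.3, tolerance = 0.01)
  expect_error(fold_change(-1, 1), "positive")
})

test_that("c-value diagnostic matches the design window", {
  cv <- c_value(binding_params(1, 0.051, -8000), itc_protocol())
  expect_equal(cv$c, 20 / 0.051, tolerance = 1e-9)
  expect_true(cv$fittable)
  expect_equal(c_value(binding_params(2, 20, 0), itc_protocol())$c, 2)
  expect_false(c_value(binding_params(1, 1e-4, 0), itc_protocol())$fittable)
})

test_that("thermograms round-trip through TSV", {
  tg <- simulate_titration(binding_params(1, 0.051, -8000), itc_protocol())
  p <- tempfile(fileext = ".tsv")
  write_thermogram(tg, p)
  back <- read_thermogram(p)
  expect_equal(back$heat_ucal, tg$heat_ucal, tolerance = 1e-9)
})
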