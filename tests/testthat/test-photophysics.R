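test_that("binding isotherm identities hold on parameter grids", {
  for (Kd in c(0.5, 5.3, 25.2, 80)) {
    for (Fmin in c(0.2, 1, 3)) {
      for (Fmax in c(0.05, 0.5, 2)) {
        # half-saturation midpoint
        expect_equal(binding_isotherm(Kd, Kd, Fmin, Fmax),
                     (Fmin + Fmax) / 2, tolerance = 1e-12)
        expect_equal(binding_isotherm(0, Kd, Fmin, Fmax), Fmin)
        # monotone with direction sign(Fmax - Fmin)
        x <- seq(0, 200, length.out = 50)
        y <- binding_isotherm(x, Kd, Fmin, Fmax)
        expect_true(all(sign(diff(y)) == sign(Fmax - Fmin) | diff(y) == 0))
      }
    }
  }
})

test_that("noise-free fits recover parameters exactly for random draws", {
  for (s in 1:100) {
    set.seed(s)
    Kd <- runif(1, 1, 80)
    Fmin <- runif(1, 0.5, 2)
    Fmax <- runif(1, 0.05, 0.45)
    tc <- gen_titration(Kd = Kd, Fmin = Fmin, Fmax = Fmax, noise_sd = 0,
                        seed = s)
    fit <- fit_binding_isotherm(tc)
    expect_equal(fit$Kd, Kd, tolerance = 1e-4, info = paste("seed", s))
    expect_equal(fit$Fmin, Fmin, tolerance = 1e-6)
    expect_equal(fit$Fmax, Fmax, tolerance = 1e-4)
  }
})

test_that("noisy titrations still localize Kd (median relative error <= 10%)", {
  errs <- vapply(1:100, function(s) {
    tc <- gen_titration(Kd = 25.2, Fmin = 1, Fmax = 0.2,
                        noise_sd = 0.02 * 0.8, n_replicates = 3, seed = s)
    abs(fit_binding_isotherm(tc)$Kd - 25.2) / 25.2
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})

test_that("flat curves are rejected as non-saturable (the gluconate case)", {
  tc <- gen_titration("gluconate", noise_sd = 0.005, n_replicates = 3,
                      seed = 2)
  expect_error(fit_binding_isotherm(tc), "no saturable response")
  tc0 <- gen_titration(Kd = 25, Fmin = 1, Fmax = 0.2, noise_sd = 0,
                       concentrations = c(0, 5, 25), seed = 1)
  expect_error(fit_binding_isotherm(tc0), "4 distinct")
})

test_that("50%-retention pKa estimator interpolates correctly", {
  # two-point linear case
  curve <- data.frame(pH = c(4, 6), normalized = c(0, 1))
  expect_equal(estimate_pka_50pct(curve), 5.0)
  # ideal curve (already on the 0..1 fraction scale) recovers the planted
  # pKa to interpolation accuracy anywhere on the grid
  for (pka in seq(3.5, 7.5, by = 0.25)) {
    ph <- seq(3.5, 8, 0.25)
    ideal <- data.frame(pH = ph, normalized = 1 / (1 + 10^(pka - ph)))
    expect_lte(abs(estimate_pka_50pct(ideal) - pka), 0.05,
               label = paste("pKa", pka))
  }
  # min/max-normalized measured curves agree near the middle of the grid,
  # where both asymptotes are observed
  for (pka in c(4.9, 5.2, 6.0)) {
    pc <- gen_ph_curve(pka, seed = 1)
    expect_lte(abs(estimate_pka_50pct(pc) - pka), 0.05,
               label = paste("pKa", pka))
  }
  # monotone series never reaching 0.5 errors
  expect_error(estimate_pka_50pct(data.frame(pH = 4:8,
                                             normalized = seq(.6, 1, .1))),
               "never crosses")
  # multiple crossings warn and report the first from high pH
  wavy <- data.frame(pH = c(3, 4, 5, 6, 7),
                     normalized = c(0, 1, 0.2, 0.9, 1))
  expect_warning(est <- estimate_pka_50pct(wavy), "multiple")
  expect_true(est > 5 && est < 6)
})

test_that("fold change, extinction coefficients and quantum yield follow their formulas", {
  expect_equal(fold_change(100, 50), 0.5)
  expect_equal(fold_change(7, 7), 1.0)
  expect_error(fold_change(0, 5), "positive")
  # quench factor recovered from a synthetic turn-off titration
  tc <- gen_titration("chloride", Fmin = 1, Fmax = 0.2, noise_sd = 0,
                      concentrations = c(0, 1, 2.5, 5, 10, 25, 50, 1e6),
                      seed = 1)
  Fbar <- rowMeans(tc$intensities)
  expect_equal(fold_change(Fbar[1], Fbar[length(Fbar)]), 0.2,
               tolerance = 1e-3)

  expect_equal(extinction_from_sequence("WWYYY"), 2 * 5500 + 3 * 1490)
  expect_equal(extinction_from_sequence("AGLKPDS"), 0)
  expect_error(extinction_from_sequence("AXW"), "invalid")
  # brute-force residue counting on random sequences
  for (s in 1:25) {
    set.seed(s)
    sq <- paste(sample(c("A", "W", "Y", "C", "G"), 50, replace = TRUE),
                collapse = "")
    chars <- strsplit(sq, "")[[1]]
    expect_equal(extinction_from_sequence(sq, oxidized = TRUE),
                 5500 * sum(chars == "W") + 1490 * sum(chars == "Y") +
                   125 * (sum(chars == "C") %/% 2))
  }

  expect_equal(extinction_at_wavelength(37360, 0.5, 0.25), 18680)
  expect_equal(extinction_at_wavelength(37360, 0.4, 0.4), 37360)
  # applying the inverse ratio recovers the 280 nm coefficient
  e485 <- extinction_at_wavelength(37360, 0.5, 0.25)
  expect_equal(extinction_at_wavelength(e485, 0.25, 0.5), 37360)
  expect_error(extinction_at_wavelength(37360, 0, 0.3), "positive")

  expect_equal(relative_quantum_yield(2, 2, 0.91), 0.91)
  expect_equal(relative_quantum_yield(1.6, 2, 0.91), 0.8 * 0.91)
  expect_error(relative_quantum_yield(-1, 2, 0.91), "positive")
  # planted slopes through noisy linear data
  set.seed(3)
  A <- seq(0.01, 0.1, length.out = 8)
  phi_true <- 0.85
  slope_ref <- 5000
  em_s <- slope_ref * phi_true / 0.91 * A
  fit_s <- unname(coef(lm(em_s ~ A))[2])
  expect_equal(relative_quantum_yield(fit_s, slope_ref, 0.91), phi_true,
               tolerance = 1e-9)

  expect_equal(combine_batches(10, 0), c(mean = 10, sd = 0))
  expect_equal(combine_batches(c(10, 14), c(3, 4)), c(mean = 12, sd = 2.5))
  expect_error(combine_batches(numeric(0), numeric(0)), "at least one")
  for (s in 1:20) {
    set.seed(s)
    v <- rnorm(5); sd_ <- abs(rnorm(5))
    expect_equal(unname(combine_batches(v, sd_)),
                 c(mean(v), sqrt(sum(sd_^2)) / 5))
  }
})

test_that("fitted affinities reproduce the measured anion ordering", {
  kds <- vapply(c("iodide", "nitrate", "bromide", "chloride"), function(a) {
    fit_binding_isotherm(gen_titration(a, noise_sd = 0, seed = 1))$Kd
  }, numeric(1))
  # iodide binds tightest, chloride weakest
  expect_true(all(diff(kds) > 0))
})
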