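test_that("stress-strain transformation divides by area and exposed length", {
  ss <- to_stress_strain(c(0, 0.5), c(0, 100), 10, 0.61)
  expect_equal(ss$stress[2], 100 / 61)
  expect_equal(ss$strain[2], 0.05)
  ss0 <- to_stress_strain(c(0, 0.1, 0.2), c(0, 0, 0), 5, 1)
  expect_equal(ss0$stress, c(0, 0, 0))
})

test_that("stress-strain transformation is linear in load and inverse in lo", {
  d <- seq(0, 1, length.out = 20)
  l <- 50 * d
  base <- to_stress_strain(d, l, 10, 0.5)
  expect_equal(to_stress_strain(d, 2 * l, 10, 0.5)$stress, 2 * base$stress)
  expect_equal(to_stress_strain(d, l, 20, 0.5)$strain, base$strain / 2)
})

test_that("stress-strain transformation validates its inputs", {
  expect_error(to_stress_strain(c(0, 0.2, 0.1), c(0, 1, 2), 10, 0.5),
               "non-decreasing")
  expect_error(to_stress_strain(c(0, -0.1), c(0, 1), 10, 0.5), "non-negative")
  expect_error(to_stress_strain(c(0, 0.1), c(0, 1), 0, 0.5),
               "exposed_length_lo_mm")
  expect_error(to_stress_strain(c(0, 0.1), c(0, 1), 10, -1),
               "cross_section_area_cm2")
  expect_error(to_stress_strain(c(0, 0.1), c(0), 10, 1), "lengths differ")
})

test_that("modulus fit recovers the elastic slope of noiseless curves exactly", {
  lin <- data.frame(strain = seq(0, 0.05, length.out = 40))
  lin$stress <- 550 * lin$strain
  expect_equal(fit_modulus(lin)$modulus, 0.550, tolerance = 1e-12)
  bi <- bilinear_ss(550, 0.031, 0.05, 19.2)
  expect_equal(fit_modulus(bi)$modulus, 0.550, tolerance = 1e-9)
  # the winning window lies inside the elastic limb
  expect_lte(fit_modulus(bi)$window[2], 0.031 + 1e-12)
  # doubling stress doubles the modulus
  bi2 <- bi
  bi2$stress <- 2 * bi2$stress
  expect_equal(fit_modulus(bi2)$modulus, 2 * fit_modulus(bi)$modulus)
})

test_that("modulus fit rejects degenerate input", {
  lin <- data.frame(strain = seq(0, 0.05, length.out = 40),
                    stress = seq(0, 10, length.out = 40))
  expect_error(fit_modulus(lin[1:5, ]), "at least 10")
  expect_error(fit_modulus(lin, window_fraction = 0), "window_fraction")
  expect_error(fit_modulus(lin, window_fraction = 0.7), "window_fraction")
  flat <- data.frame(strain = rep(0.01, 12), stress = 1:12)
  expect_error(fit_modulus(flat), "zero strain range")
})

test_that("offset yield matches the analytic two-line intersection", {
  cases <- expand.grid(e = c(427.5, 550, 800), eps_y = c(0.02, 0.031),
                       hard_frac = c(0.1, 0.4), offset = c(0.002, 0.005))
  for (i in seq_len(nrow(cases))) {
    e <- cases$e[i]; eps_y <- cases$eps_y[i]
    eps_f <- eps_y + 0.02
    sigma_f <- e * eps_y + cases$hard_frac[i] * e * (eps_f - eps_y)
    ss <- bilinear_ss(e, eps_y, eps_f, sigma_f, n = 80)
    got <- detect_yield(ss, e / 1000, cases$offset[i])
    want <- bilinear_offset_yield(e, eps_y, eps_f, sigma_f, cases$offset[i])
    expect_true(got$found)
    expect_equal(got$yield_strain, unname(want["strain"]), tolerance = 1e-9)
    expect_equal(got$yield_stress, unname(want["stress"]), tolerance = 1e-9)
  }
})

test_that("zero-offset yield returns the kink point of a bilinear curve", {
  ss <- bilinear_ss(427.5, 0.04, 0.06, 21.3)
  got <- detect_yield(ss, 0.4275, offset = 0)
  expect_equal(got$yield_strain, 0.04, tolerance = 1e-12)
  expect_equal(got$yield_stress, 427.5 * 0.04, tolerance = 1e-12)
})

test_that("a purely elastic curve yields a no-yield signal, not an error", {
  lin <- data.frame(strain = seq(0, 0.05, length.out = 30))
  lin$stress <- 400 * lin$strain
  got <- detect_yield(lin, 0.4, offset = 0.002)
  expect_false(got$found)
  expect_true(is.na(got$yield_strain))
})

test_that("failure point is the ultimate stress with ties broken to smaller strain", {
  ss <- data.frame(strain = c(0, 0.01, 0.02, 0.03, 0.04),
                   stress = c(0, 8, 19.2, 15, 10))
  f <- detect_failure(ss)
  expect_equal(f$failure_stress, max(ss$stress))
  expect_equal(f$failure_strain, 0.02)
  rising <- data.frame(strain = seq(0, 0.05, length.out = 11),
                       stress = seq(0, 19.2, length.out = 11))
  expect_equal(detect_failure(rising)$failure_strain, 0.05)
  tied <- data.frame(strain = c(0, 0.01, 0.02, 0.03),
                     stress = c(0, 5, 5, 2))
  expect_equal(detect_failure(tied)$failure_strain, 0.01)
  expect_error(detect_failure(data.frame(strain = numeric(), stress = numeric())),
               "empty")
})

test_that("drop rule returns the running maximum before a 10% stress drop", {
  ss <- data.frame(strain = c(0, 0.01, 0.02, 0.03, 0.04, 0.05),
                   stress = c(0, 10, 15, 13, 16, 2))
  expect_equal(detect_failure(ss, "drop10")$failure_stress, 15)
  expect_equal(detect_failure(ss, "ultimate")$failure_stress, 16)
})

test_that("strain energy integrates piecewise-linear curves exactly", {
  ramp <- data.frame(strain = c(0, 0.02), stress = c(0, 10))
  expect_equal(strain_energy(ramp, 0.02), 0.1)
  expect_equal(strain_energy(ramp, 0), 0)
  # partial interval by interpolation: triangle of half base
  expect_equal(strain_energy(ramp, 0.01), 0.025)
  e <- 550; eps_y <- 0.031; eps_f <- 0.05; sf <- 19.2
  ss <- bilinear_ss(e, eps_y, eps_f, sf)
  expect_equal(strain_energy(ss, eps_f),
               bilinear_energy(e, eps_y, eps_f, sf, eps_f), tolerance = 1e-12)
  expect_error(strain_energy(ss, 0.08), "outside")
})

test_that("strain energy is additive over intervals and monotone in the limit", {
  ss <- bilinear_ss(550, 0.031, 0.05, 19.2, n = 37)
  lims <- seq(0.004, 0.05, length.out = 9)
  vals <- vapply(lims, function(u) strain_energy(ss, u), numeric(1))
  expect_true(all(diff(vals) > 0))
  # additivity: integral to the end = integral to a grid point + tail integral
  split <- 15L
  s0 <- ss$strain[split]
  tail_ss <- ss[split:nrow(ss), ]
  tail_ss$strain <- tail_ss$strain - s0
  expect_equal(strain_energy(ss, s0) + strain_energy(tail_ss, 0.05 - s0),
               strain_energy(ss, 0.05), tolerance = 1e-12)
})

test_that("summarize_mechanics runs the full chain on a constructed specimen", {
  e <- 550; eps_y <- 0.031; eps_f <- 0.05; sf <- 19.2
  lo <- 7.1; area <- 0.61
  curve <- bilinear_curve(e, eps_y, eps_f, sf, lo, area, n = 80)
  s <- summarize_mechanics(curve, lo, area, specimen_id = "bi")
  expect_equal(s$modulus, 0.550, tolerance = 1e-9)
  expect_equal(s$failure_stress, 19.2, tolerance = 1e-12)
  expect_equal(s$failure_strain, 0.05, tolerance = 1e-12)
  want <- bilinear_offset_yield(e, eps_y, eps_f, sf, 0.002)
  expect_equal(s$yield_stress, unname(want["stress"]), tolerance = 1e-6)
  expect_equal(s$post_yield_energy, s$energy_failure - s$energy_yield)
})

test_that("summarize_mechanics flags elastic-only specimens and names failing stages", {
  lin <- data.frame(displacement_mm = seq(0, 0.5, length.out = 20))
  lin$load_n <- 400 * lin$displacement_mm
  s <- summarize_mechanics(lin, 10, 0.5, specimen_id = "el")
  expect_false(s$yield_found)
  expect_true(is.na(s$yield_stress) && is.na(s$energy_yield))
  expect_false(is.na(s$failure_stress))
  expect_error(summarize_mechanics(lin, 10, -1, specimen_id = "el"),
               "stage stress-strain")
  expect_error(summarize_mechanics(lin[1:4, ], 10, 0.5, specimen_id = "el"),
               "at least 10")
})

test_that("cohort table reports field-wise mean, sample SD and n", {
  curve <- bilinear_curve(550, 0.031, 0.05, 19.2, 7, 0.6, n = 40)
  s1 <- summarize_mechanics(curve, 7, 0.6, specimen_id = "a")
  s2 <- s1; s2$specimen_id <- "b"
  tab <- cohort_table(rbind(s1, s2))
  expect_true(all(tab$sd == 0))
  mixed <- rbind(s1, s2)
  mixed$yield_stress <- c(17, 18)
  tab2 <- cohort_table(mixed)
  expect_equal(tab2$mean[tab2$parameter == "sigma_y"], 17.5)
  expect_equal(tab2$sd[tab2$parameter == "sigma_y"], sd(c(17, 18)))
  # a field with fewer than two values is unavailable
  mixed$yield_stress <- c(17, NA)
  tab3 <- cohort_table(mixed)
  expect_true(is.na(tab3$mean[tab3$parameter == "sigma_y"]))
  expect_equal(tab3$n[tab3$parameter == "sigma_y"], 1L)
})
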