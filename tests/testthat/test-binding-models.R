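test_that("rate/affinity identities hold exactly", {
  expect_equal(kd_from_rates(2.6e5, 1.2e-4), 1.2e-4 / 2.6e5)
  expect_equal(kd_from_rates(1e5, 0), 0)
  expect_error(kd_from_rates(0, 1e-4), "positive")
  expect_equal(koff_from_kd(0.26e-9, 8.1e5), 0.26e-9 * 8.1e5)
  p <- kinetic_params(1e5, 7e-4)
  expect_equal(p$K_D, 7e-9)
  expect_error(kinetic_params(1e5, 7e-4, K_D = 8e-9), "inconsistent")
})

test_that("equilibrium isotherm and depletion variant agree in the limit", {
  expect_equal(bound_fraction_equilibrium(1e-9, 1e-9), 0.5)
  expect_equal(bound_fraction_equilibrium(1, 1e-9), 1, tolerance = 1e-8)
  expect_equal(bound_fraction_equilibrium(0, 0), 0)
  # negligible target: depletion-corrected result matches the excess formula
  conc <- 10^seq(-10, -7, by = 0.5)
  excess <- bound_fraction_equilibrium(conc, 1e-9)
  depleted <- bound_fraction_equilibrium(conc, 1e-9, target_tot = 1e-15)
  expect_true(all(abs(excess - depleted) < 1e-6))
})

test_that("kinetic ELISA model obeys its closed-form limits", {
  p <- kinetic_params(1e5, 7e-4)
  g0 <- simulate_kinetic_elisa(p, c(1e-9, 1e-8), 0)
  expect_true(all(g0$od == 0))
  c0 <- 7e-9 # c = K_D
  tau <- 1 / (p$k_on * c0 + p$k_off)
  g1 <- simulate_kinetic_elisa(p, c0, tau, od_max = 2)
  expect_equal(g1$od, 2 * 0.5 * (1 - exp(-1)), tolerance = 1e-12)
  # long-time limit is the equilibrium isotherm
  concs <- 1e-6 / 5^(0:5)
  tmax <- 10 / (p$k_on * min(concs) + p$k_off)
  g2 <- simulate_kinetic_elisa(p, concs, tmax)
  expect_true(max(abs(g2$od - bound_fraction_equilibrium(concs, p$K_D))) < 1e-4)
  expect_error(simulate_kinetic_elisa(p, 1e-9, -5), "negative")
})

test_that("kinetic ELISA fitter requires an informative grid", {
  p <- kinetic_params(1e5, 7e-4)
  g <- simulate_kinetic_elisa(p, c(1e-9, 1e-8), c(60, 600))
  expect_error(fit_kinetic_elisa(g), "concentrations")
})

test_that("free-ligand mass balance matches the bisection oracle", {
  expect_equal(free_ligand_with_inhibitor(1e-12, 0, 1e-9), 1e-12)
  # excess inhibitor at I = K_I leaves half the ligand free
  expect_equal(free_ligand_with_inhibitor(1e-15, 1e-9, 1e-9), 0.5e-15,
               tolerance = 1e-3)
  set.seed(41)
  for (i in 1:200) {
    L <- 10^runif(1, -13, -7)
    I <- 10^runif(1, -13, -5)
    K <- 10^runif(1, -12, -6)
    expect_equal(free_ligand_with_inhibitor(L, I, K),
                 free_ligand_bisection(L, I, K),
                 tolerance = 1e-10)
  }
  # monotone decreasing in inhibitor
  lf <- free_ligand_with_inhibitor(1e-12, 10^seq(-12, -6, by = 0.25), 1e-9)
  expect_true(all(diff(lf) < 0))
})

test_that("inhibition fitting degenerates sensibly", {
  fx <- attr(generate_assay_fixture("inhibition"), "tables")
  flat <- fx$calibration
  flat$response <- 1
  expect_error(fit_inhibition(flat, fx$data, 2.6e-12), "flat")
  zero <- fx$data
  zero$inhibitor_M <- 0
  expect_error(fit_inhibition(fx$calibration, zero, 2.6e-12),
               "unidentifiable")
})

test_that("sensorgrams are continuous and vanish at zero analyte", {
  p <- kinetic_params(2.6e5, 1.2e-4)
  s <- simulate_sensorgram(p, 10e-9, 43)
  a_end <- s$ru[s$phase == "association"]
  d_start <- s$ru[s$phase == "dissociation"]
  expect_equal(a_end[length(a_end)], d_start[1] / exp(-1.2e-4), # one dt apart
               tolerance = 1e-3)
  s0 <- simulate_sensorgram(p, 0, 43)
  expect_true(all(s0$ru == 0))
  expect_error(simulate_sensorgram(p, 1e-9, 43, t_assoc = -1))
  one <- simulate_sensorgram(p, 1e-9, 43)
  expect_error(fit_sensorgrams(one), "2 analyte")
})

test_that("ITC heats follow the one-site model identities", {
  inj <- c(3e-6, rep(5e-6, 29))
  zero <- itc_one_site_heats(1, 1e-9, 0, 4.9e-6, 53.2e-6, inj)
  expect_true(all(zero$heat_J == 0))
  h <- itc_one_site_heats(1, 0.35e-9, -8e4, 4.9e-6, 53.2e-6, inj)
  expect_true(all(h$heat_J < 0)) # exothermic
  # saturating titration: early injections carry ~dH per mole injected
  ndh <- h$heat_J[3] / (53.2e-6 * 5e-6)
  expect_equal(ndh, -8e4, tolerance = 0.02)
  # dG at K_D = 0.35 nM and 30 C is about -54.9 kJ/mol
  expect_equal(8.31446261815324 * 303.15 * log(0.35e-9) / 1000, -54.9,
               tolerance = 1e-2)
})

test_that("thermodynamic identities hold for every ITC fit", {
  inj <- c(3e-6, rep(5e-6, 29))
  h <- itc_one_site_heats(1, 1e-8, -8e4, 4.9e-6, 53.2e-6, inj,
                          noise_sd = 3e-7, seed = 4)
  f <- fit_itc(h, 4.9e-6, 53.2e-6)
  expect_equal(f$params$dG, 8.31446261815324 * 303.15 * log(f$params$K_D),
               tolerance = 1e-12)
  expect_equal(f$params$dG, f$params$dH - 303.15 * f$params$dS,
               tolerance = 1e-9)
  # the reference geometry at subnanomolar K_D exceeds the identifiable
  # c-value window and must warn
  h2 <- itc_one_site_heats(1, 0.35e-9, -8e4, 4.9e-6, 53.2e-6, inj)
  expect_warning(fit_itc(h2, 4.9e-6, 53.2e-6), "c-value")
})

test_that("melt fitting finds the midpoint and flags missing transitions", {
  temp <- seq(30, 110, by = 1)
  k <- exp((temp - 70) / 2.5)
  sig <- (-20 - 2 * k) / (1 + k)
  f <- fit_melt_curve(temp, sig)
  expect_equal(f$params$Tm, 70, tolerance = 1e-6)
  expect_false(f$extrapolated)
  expect_error(fit_melt_curve(temp, rep(-10, length(temp))), "transition")
})

test_that("Tm extrapolation to zero denaturant is exact on a line", {
  ex <- extrapolate_tm(c(80, 70, 60, 50), c(3, 4, 5, 6))
  expect_equal(ex$slope, -10)
  expect_equal(ex$tm_at_zero, 110)
  ex2 <- extrapolate_tm(c(65, 65), c(3, 5))
  expect_equal(ex2$slope, 0)
  expect_equal(ex2$tm_at_zero, 65)
})

test_that("fit objects expose tidy, glance and autoplot methods", {
  p <- kinetic_params(1e5, 7e-4)
  g <- simulate_kinetic_elisa(p, 1e-6 / 5^(0:4), c(240, 3600, 86400))
  f <- fit_kinetic_elisa(g)
  td <- tidy(f)
  expect_true(all(c("K_D", "k_on", "k_off") %in% td$term))
  gl <- glance(f)
  expect_equal(gl$n, nrow(g))
  expect_s3_class(autoplot(f), "ggplot")
  ex <- plot_tm_extrapolation(c(80, 70, 60, 50), c(3, 4, 5, 6))
  expect_s3_class(ex, "ggplot")
})
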