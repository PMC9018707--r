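# Wright-Fisher sweep simulator: determinism, divergence, selection response,
# cohorts and EBV phenotypes

tiny_cfg <- function(.seed, ...) {
  sweep_sim_config(n_base = 60, n_sel = 50, n_unsel = 40, n_snps = 300,
                   asc_factor = 8, seed = .seed, cohort_decades = NULL,
                   trait_model = NULL, ...)
}

test_that("simulation output is bit-exact under the same config and seed", {
  s1 <- simulate_sweep(tiny_cfg(5))
  s2 <- simulate_sweep(tiny_cfg(5))
  expect_identical(s1$panel_sel$haplo, s2$panel_sel$haplo)
  expect_identical(s1$panel_unsel$haplo, s2$panel_unsel$haplo)
  expect_identical(s1$truth$traj_sel, s2$truth$traj_sel)
  # and a different seed changes the draw
  s3 <- simulate_sweep(tiny_cfg(6))
  expect_false(identical(s1$panel_sel$haplo, s3$panel_sel$haplo))
})

test_that("truth record frequencies match the emitted matrices exactly", {
  sim <- simulate_sweep(tiny_cfg(7))
  expect_identical(sim$truth$freq_sel, colMeans(sim$panel_sel$haplo))
  expect_identical(sim$truth$freq_unsel, colMeans(sim$panel_unsel$haplo))
})

test_that("no divergence at g_split = 0 and small Fst after a short split", {
  cf0 <- sweep_sim_config(n_base = 100, n_sel = 80, n_unsel = 60,
                          n_snps = 2000, s = 0, g_split = 0, g_sel = 0,
                          seed = 8, cohort_decades = NULL)
  sim0 <- simulate_sweep(cf0)
  f0 <- compute_fst(sim0$panel_sel, sim0$panel_unsel)
  expect_equal(attr(f0, "fst_genome"), 0)

  cf4 <- sweep_sim_config(n_base = 100, n_sel = 80, n_unsel = 60,
                          n_snps = 2000, s = 0, g_split = 4, g_sel = 0,
                          seed = 8, cohort_decades = NULL)
  sim4 <- simulate_sweep(cf4)
  f4 <- compute_fst(sim4$panel_sel, sim4$panel_unsel)
  expect_gt(attr(f4, "fst_genome"), 0)
  expect_lt(attr(f4, "fst_genome"), 0.05)
})

test_that("neutral-split Fst grows with divergence time", {
  gw <- sapply(c(4, 20, 80), function(g) {
    mean(sapply(1:3, function(sd) {
      cf <- sweep_sim_config(n_base = 80, n_sel = 60, n_unsel = 60,
                             n_snps = 500, asc_factor = 8, s = 0,
                             g_split = g, g_sel = 0, seed = 100 + sd,
                             cohort_decades = NULL)
      sim <- simulate_sweep(cf)
      attr(compute_fst(sim$panel_sel, sim$panel_unsel), "fst_genome")
    }))
  })
  expect_true(all(diff(gw) > 0))
})

test_that("selection drives the focal derived allele above the neutral branch", {
  wins <- sapply(1:12, function(sd) {
    sim <- simulate_sweep(sweep_sim_config(
      n_base = 60, n_sel = 200, n_unsel = 150, n_snps = 300, asc_factor = 8,
      seed = sd, s = 0.1, g_split = 40, g_sel = 40, focal_freq = 0.1,
      cohort_decades = NULL, trait_model = NULL))
    fs <- sim$truth$freq_sel[sim$truth$focal_index]
    fu <- sim$truth$freq_unsel[sim$truth$focal_index]
    dc <- sim$truth$derived_code[sim$truth$focal_index]
    if (dc == 0L) { fs <- 1 - fs; fu <- 1 - fu }
    fs > fu
  })
  expect_gte(sum(wins), 10)
})

test_that("the realized focal trajectory rises under selection", {
  sim <- simulate_sweep(tiny_cfg(9, s = 0.15))
  traj <- sim$truth$traj_sel
  expect_gte(tail(traj, 1), traj[1])
  # deterministic-selection oracle: expected final frequency from iterating
  # dp = s p q (p + h(q - p)) / wbar exceeds the start; realized should too
  p <- sim$truth$freq_onset_derived_focal
  for (i in seq_len(30)) {
    q <- 1 - p
    wbar <- 1 + sim$truth$s * (p^2 + 0.5 * 2 * p * q)
    p <- p + sim$truth$s * p * q * (p + 0.5 * (q - p)) / wbar
  }
  expect_gt(p, sim$truth$freq_onset_derived_focal)
})

test_that("cohort assignment draws later decades from later generations", {
  decades <- setNames(rep(10L, 4), c(1980, 1990, 2000, 2010))
  cf <- tiny_cfg(10)
  cf$cohort_decades <- decades
  sim <- simulate_sweep(cf)
  panel <- sim$panel_sel
  expect_equal(n_samples(panel), 40L)
  expect_equal(as.integer(table(panel$samples$cohort_decade)), rep(10L, 4))
  expect_false(anyDuplicated(panel$samples$sample_id) > 0)
  expect_equal(length(sim$truth$freq_by_decade), 4L)
  # single decade covering everything gives a constant label
  cf1 <- tiny_cfg(10)
  cf1$cohort_decades <- c("2000" = 30L)
  sim1 <- simulate_sweep(cf1)
  expect_equal(unique(sim1$panel_sel$samples$cohort_decade), 2000L)
  # asking for more samples than simulated errors
  expect_error(assign_cohorts(sim, setNames(rep(100L, 4), names(decades))),
               "larger")
})

test_that("focal derived frequency is non-decreasing over decades under
           strong selection in most seeds", {
  ok <- sapply(1:10, function(sd) {
    cf <- tiny_cfg(sd, s = 0.2)
    cf$cohort_decades <- setNames(rep(12L, 4), c(1980, 1990, 2000, 2010))
    sim <- simulate_sweep(cf)
    f <- sim$truth$freq_by_decade
    tail(f, 1) >= f[1]
  })
  expect_gte(mean(ok), 0.8)
})

test_that("EBV reliability, pure-noise and effect-recovery contracts hold", {
  decades <- setNames(rep(25L, 4), c(1980, 1990, 2000, 2010))
  cf <- sweep_sim_config(n_base = 60, n_sel = 100, n_unsel = 30, n_snps = 300,
                         asc_factor = 8, seed = 31, cohort_decades = decades,
                         trait_model = list(
                           CWT = list(n_qtl = 1, effect_sd = 0,
                                      reliability = 1, decade_gain = 0,
                                      include_focal = TRUE, focal_effect = 5,
                                      noise_sd = 1)))
  sim <- simulate_sweep(cf)
  # reliability 1: EBV equals the true breeding value exactly
  expect_equal(sim$panel_sel$samples$CWT, sim$truth$tbv$CWT)
  # OLS on the known design recovers the focal effect within 2 SE
  x <- dosage_matrix(sim$panel_sel, derived = TRUE)[, sim$truth$focal_index]
  fit <- suppressWarnings(summary(lm(sim$panel_sel$samples$CWT ~ x)))
  expect_lt(abs(fit$coefficients[2, 1] - 5), 2 * fit$coefficients[2, 2] + 1e-9)

  # zero effects: EBVs are pure noise with mean near zero
  sim0 <- simulate_ebv(sim, trait_model = list(
    FLAT = list(n_qtl = 0, effect_sd = 0, reliability = 0.8, decade_gain = 0,
                include_focal = FALSE, focal_effect = 0, noise_sd = 1)),
    seed = 4)
  ebv <- sim0$panel_sel$samples$FLAT
  expect_lt(abs(mean(ebv)), 3 * sd(ebv) / sqrt(length(ebv)))

  # invalid reliability errors
  expect_error(simulate_ebv(sim, trait_model = list(
    BAD = list(n_qtl = 1, effect_sd = 1, reliability = 1.2, decade_gain = 0,
               include_focal = FALSE, focal_effect = 0, noise_sd = 1)),
    seed = 1), "reliability")
})

test_that("configured per-decade genetic gain appears in cohort EBV means", {
  decades <- setNames(rep(40L, 4), c(1980, 1990, 2000, 2010))
  cf <- sweep_sim_config(n_base = 60, n_sel = 160, n_unsel = 30, n_snps = 300,
                         asc_factor = 8, seed = 32, cohort_decades = decades,
                         trait_model = list(
                           GAIN = list(n_qtl = 0, effect_sd = 0,
                                       reliability = 0.8, decade_gain = 6,
                                       include_focal = FALSE,
                                       focal_effect = 0, noise_sd = 1)))
  sim <- simulate_sweep(cf)
  tr <- cohort_trend(sim$panel_sel, sim$truth$focal_id, traits = "GAIN")
  diffs <- diff(tr$mean_GAIN)
  se <- sqrt(tr$se_GAIN[-1]^2 + tr$se_GAIN[-4]^2)
  expect_true(all(abs(diffs - 6) < 2 * se + 1e-9))
})

test_that("EBV reliability calibration: cor(EBV, TBV)^2 near the target", {
  decades <- setNames(rep(60L, 4), c(1980, 1990, 2000, 2010))
  cf <- sweep_sim_config(n_base = 60, n_sel = 240, n_unsel = 30, n_snps = 300,
                         asc_factor = 8, seed = 33, cohort_decades = decades,
                         trait_model = list(
                           CWT = list(n_qtl = 30, effect_sd = 1,
                                      reliability = 0.8, decade_gain = 0,
                                      include_focal = TRUE, focal_effect = 3,
                                      noise_sd = 1)))
  sim <- simulate_sweep(cf)
  r2 <- cor(sim$panel_sel$samples$CWT, sim$truth$tbv$CWT)^2
  expect_gt(r2, 0.65)
  expect_lt(r2, 0.92)
})
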