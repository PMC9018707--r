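# GRM construction, REML variance components, MLM-LOCO association

sim_geno_panel <- function(n, m, seed, n_chrom = 2) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  haplo <- matrix(rbinom(2 * n * m, 1, rep(p, each = 2 * n)), nrow = 2 * n)
  make_panel(haplo, pos_bp = rep(seq_len(m / n_chrom) * 50000L, n_chrom),
             chrom = rep(as.character(seq_len(n_chrom)), each = m / n_chrom))
}

test_that("GRM entries follow the frequency-standardized cross-product", {
  # single SNP, p = 0.5, individual with dosage 2: (2-1)^2 / (2*0.5*0.5) = 2
  haplo <- rbind(c(1L), c(1L), c(0L), c(0L), c(1L), c(0L), c(0L), c(1L))
  panel <- make_panel(haplo)      # dosages 2, 0, 1, 1 -> p = 0.5
  g <- compute_grm(panel)
  expect_equal(g$K[1, 1], 2)
  expect_equal(g$K[1, 2], -2)     # (2-1)(0-1)/0.5
  expect_true(isSymmetric(g$K, tol = 1e-12))
})

test_that("a duplicated individual has identical rows and A_jk = A_jj", {
  panel <- sim_geno_panel(20, 40, seed = 8)
  dup <- subset_panel(panel, samples = c(1, 1, 2:20))
  dup$samples$sample_id <- sprintf("s%03d", seq_len(21))
  g <- compute_grm(dup)
  expect_equal(g$K[1, 2], g$K[1, 1])
  expect_equal(g$K[1, ], g$K[2, ])
})

test_that("unrelated HWE individuals give near-zero mean off-diagonal and unit diagonal", {
  panel <- sim_geno_panel(60, 3000, seed = 9)
  g <- compute_grm(panel)
  off <- g$K[upper.tri(g$K)]
  expect_lt(abs(mean(off)), 0.02)
  expect_gt(mean(diag(g$K)), 0.8)
  expect_lt(mean(diag(g$K)), 1.3)
})

test_that("GRM permutation and LOCO-complement consistency hold", {
  panel <- sim_geno_panel(15, 60, seed = 10)
  g <- compute_grm(panel)
  perm <- sample(15)
  g_perm <- compute_grm(subset_panel(panel, samples = perm))
  expect_equal(g_perm$K, g$K[perm, perm], ignore_attr = TRUE)
  # excluding all chromosomes but one equals building from that one directly
  g1 <- compute_grm(panel, exclude_chrom = "2")
  g1_direct <- compute_grm(subset_panel(panel,
                                        variants = panel$variants$chrom == "1"))
  expect_equal(g1$K, g1_direct$K, tolerance = 1e-12)
})

test_that("REML recovers heritability and handles degenerate inputs", {
  set.seed(11)
  panel <- sim_geno_panel(300, 800, seed = 11)
  g <- compute_grm(panel)
  eg <- eigen(g$K, symmetric = TRUE)
  h2_hat <- replicate(4, {
    u <- rnorm(300, 0, sqrt(pmax(eg$values, 0)))
    gval <- as.vector(eg$vectors %*% u)
    y <- gval + rnorm(300, 0, sd(gval))   # h2 = 0.5
    fit <- fit_variance_components(y, g)
    fit$h2
  })
  expect_lt(abs(mean(h2_hat) - 0.5), 0.15)

  # constant phenotype -> both components zero
  fit0 <- fit_variance_components(rep(1.7, 300), g)
  expect_equal(fit0$sigma_g2, 0)
  expect_equal(fit0$sigma_e2, 0)

  # identity GRM: components non-identifiable, total variance recovered
  y <- rnorm(200)
  fit_id <- fit_variance_components(y, diag(200))
  expect_lt(abs((fit_id$sigma_g2 + fit_id$sigma_e2) - var(y)) / var(y), 0.05)
})

test_that("with sigma_g2 = 0 the mixed-model beta equals the OLS slope", {
  panel <- sim_geno_panel(50, 40, seed = 12)
  set.seed(12)
  panel$samples$trait <- rnorm(50)
  scan <- suppressWarnings(
    mlm_loco_scan(panel, trait = "trait",
                  varcomp = list(sigma_g2 = 0, sigma_e2 = 1)))
  x <- dosage_matrix(panel)[, 5]
  ols <- coef(lm(panel$samples$trait ~ x))[2]
  expect_equal(scan$beta[scan$id == panel$variants$id[5]], unname(ols),
               tolerance = 1e-10)
})

test_that("association p-values are invariant to adding a constant to y", {
  panel <- sim_geno_panel(40, 40, seed = 13)
  set.seed(13)
  panel$samples$trait <- rnorm(40)
  s1 <- mlm_loco_scan(panel, trait = "trait")
  panel$samples$trait <- panel$samples$trait + 100
  s2 <- mlm_loco_scan(panel, trait = "trait")
  expect_equal(s1$p, s2$p, tolerance = 1e-8)
})

test_that("mixed-model scan recovers a simulated focal effect within 2 SE", {
  set.seed(14)
  panel <- sim_geno_panel(250, 400, seed = 14)
  x <- dosage_matrix(panel)[, 100]
  beta_true <- 0.8
  g <- compute_grm(panel)
  eg <- eigen(g$K, symmetric = TRUE)
  gval <- as.vector(eg$vectors %*% rnorm(250, 0, sqrt(pmax(eg$values, 0))))
  panel$samples$trait <- beta_true * x + gval + rnorm(250)
  scan <- mlm_loco_scan(panel, trait = "trait")
  row <- scan[scan$id == panel$variants$id[100], ]
  expect_lt(abs(row$beta - beta_true), 2 * row$se)
})
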