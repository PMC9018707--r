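# EHHS/iES, Rsb, Fst and classical MDS

test_that("EHHS hand cases match the unbiased homozygosity formula", {
  # all haplotypes identical -> EHHS = 1 everywhere
  panel <- make_panel(matrix(1L, nrow = 4, ncol = 5))
  prof <- compute_ehhs(panel, 3)
  expect_true(all(prof$ehh == 1))

  # n = 4, core split 2/2 (h_core = 1/3); all distinct at the next marker
  haplo <- rbind(c(1L, 0L), c(1L, 1L), c(0L, 0L), c(0L, 1L))
  # core homozygosity: pairs (1,2) and (3,4) share the core allele -> 1/3
  # at marker 2 all four rows are distinct over the span -> h = 0
  panel2 <- make_panel(haplo)
  prof2 <- compute_ehhs(panel2, 1)
  right <- prof2[prof2$arm == "right", ]
  expect_equal(right$ehh, c(1, 0))
})

test_that("EHHS agrees with the brute-force homozygosity oracle", {
  for (seed in 40:55) {
    panel <- random_panel(n_hap = 2 * sample(3:15, 1), m = 20, seed = seed)
    core <- sample(20, 1)
    prof <- compute_ehhs(panel, core, cutoff = 0)
    for (arm in c("left", "right")) {
      a <- prof[prof$arm == arm, ]
      want <- vapply(a$variant, brute_ehhs, 0, haplo = panel$haplo,
                     core = core)
      expect_equal(a$ehh, want, tolerance = 1e-12)
    }
  }
})

test_that("identical panels give raw_rsb = 0; raw is ln of the iES ratio", {
  panel <- random_panel(20, 30, seed = 77)
  scan <- scan_rsb(panel, panel)
  expect_true(all(abs(scan$raw_rsb[scan$reason == "ok"]) < 1e-12))
  p2 <- random_panel(14, 30, seed = 78)
  s <- scan_rsb(panel, p2)
  ok <- s$reason == "ok"
  expect_equal(s$raw_rsb[ok], log(s$ies_pop1[ok] / s$ies_pop2[ok]))
  # a doubled iES moves raw_rsb by exactly ln 2
  expect_equal(log(2 * s$ies_pop2[ok] / s$ies_pop2[ok]), rep(log(2), sum(ok)))
})

test_that("Rsb is antisymmetric under population swap", {
  p1 <- random_panel(16, 40, seed = 101)
  p2 <- random_panel(20, 40, seed = 102)
  s12 <- scan_rsb(p1, p2)
  s21 <- scan_rsb(p2, p1)
  ok <- s12$reason == "ok" & s21$reason == "ok"
  expect_equal(s12$raw_rsb[ok], -s21$raw_rsb[ok], tolerance = 1e-12)
  expect_equal(s12$std_rsb[ok], -s21$std_rsb[ok], tolerance = 1e-9)
  # the tail transform is symmetric, so p_rsb is invariant to the swap
  expect_equal(s12$p_rsb[ok], s21$p_rsb[ok], tolerance = 1e-9)
  # median standardization holds
  expect_lt(abs(median(s12$std_rsb, na.rm = TRUE)), 1e-9)
})

test_that("Fst matches hand-computed heterozygosity cases", {
  mk <- function(p, n = 40) {
    cnt <- round(p * n)
    make_panel(matrix(rep(c(1L, 0L), c(cnt, n - cnt)), ncol = 1))
  }
  # p1 = p2 -> 0
  f0 <- compute_fst(mk(0.3), mk(0.3))
  expect_equal(f0$fst, 0)
  # fixed difference -> 1
  f1 <- compute_fst(mk(1), mk(0))
  expect_equal(f1$fst, 1)
  expect_equal(f1$h_t, 0.5)
  # p1 = 0.2, p2 = 0.8 -> H_S = 0.32, H_T = 0.5, Fst = 0.36
  f <- compute_fst(mk(0.2), mk(0.8))
  expect_equal(f$h_s, 0.32)
  expect_equal(f$h_t, 0.5)
  expect_equal(f$fst, 0.36)
  expect_equal(attr(f, "fst_genome"), 0.36)
})

test_that("monomorphic pooled sites are excluded from genome-wide Fst", {
  h1 <- cbind(rep(0L, 10), rep(c(0L, 1L), 5))
  h2 <- cbind(rep(0L, 10), rep(c(1L, 0L), 5))
  f <- compute_fst(make_panel(h1), make_panel(h2))
  expect_true(is.na(f$fst[1]))
  expect_equal(attr(f, "fst_genome"), 0)  # only the shared polymorphic SNP
})

test_that("classical MDS reproduces identical individuals and distances", {
  set.seed(31)
  base <- matrix(rbinom(2 * 30, 1, 0.5), nrow = 2)
  haplo <- rbind(base, base, matrix(rbinom(4 * 30, 1, 0.5), nrow = 4))
  panel <- make_panel(haplo)
  mds <- classical_mds(panel, dims = 2)
  expect_equal(unlist(mds[1, c("MDS1", "MDS2")]),
               unlist(mds[2, c("MDS1", "MDS2")]), tolerance = 1e-10)

  # three individuals embed exactly in dims = n - 1 = 2
  h <- rbind(rep(0L, 12), rep(0L, 12),                       # s1
             rep(c(1L, 0L), c(4, 8)), rep(c(1L, 0L), c(4, 8)),  # s2
             rep(c(1L, 0L), c(8, 4)), rep(c(1L, 0L), c(8, 4)))  # s3
  panel3 <- make_panel(h)
  d_true <- as.matrix(stats::dist(dosage_matrix(panel3),
                                  method = "manhattan")) / (2 * 12)
  mds3 <- suppressWarnings(classical_mds(panel3, dims = 2))
  emb <- as.matrix(mds3[, grep("^MDS", names(mds3))])
  expect_equal(as.matrix(stats::dist(emb)), d_true, tolerance = 1e-8,
               ignore_attr = TRUE)
  # s2 lies between s1 and s3, so the trio is collinear: second eigenvalue 0
  eig <- attr(mds3, "eig")
  expect_lt(abs(eig[2]), 1e-8 * eig[1])
})
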