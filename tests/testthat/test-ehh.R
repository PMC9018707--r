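# EHH profiles, iHH integration, bifurcation trees

test_that("identical carriers keep EHH = 1 to both chromosome ends", {
  haplo <- rbind(matrix(1L, nrow = 4, ncol = 9),
                 matrix(rep(c(0L, 1L), length.out = 9 * 2), nrow = 2,
                        byrow = TRUE))
  haplo[5:6, 5] <- 0L     # two non-carrier haplotypes at the core
  panel <- make_panel(haplo)
  prof <- compute_ehh(panel, 5, core_allele = "b")
  expect_true(all(prof$ehh == 1))
  expect_equal(attr(prof, "trunc_left"), "end")
  expect_equal(attr(prof, "trunc_right"), "end")
  # EHH == 1 over the full chromosome integrates to its bp length
  expect_equal(attr(prof, "ihh"),
               max(panel$variants$pos_bp) - min(panel$variants$pos_bp))
})

test_that("four carriers splitting into two identical pairs give EHH = 1/3", {
  # brute force: C(4,2) = 6 pairs, 2 homozygous -> 1/3
  haplo <- rbind(c(1L, 1L, 0L), c(1L, 1L, 0L), c(1L, 1L, 1L), c(1L, 1L, 1L),
                 c(0L, 0L, 0L), c(0L, 0L, 1L))
  panel <- make_panel(haplo, pos_bp = c(1000, 2000, 3000))
  prof <- compute_ehh(panel, 2, core_allele = "b")
  right <- prof[prof$arm == "right" & prof$pos_bp == 3000, ]
  expect_equal(right$ehh, 1 / 3)
  expect_equal(right$ehh, brute_ehh(haplo, 2, 3, 1L))
})

test_that("all-distinct carriers truncate the arm immediately with EHH 0", {
  haplo <- rbind(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 0L, 0L), c(0L, 1L, 0L))
  panel <- make_panel(haplo, pos_bp = c(1000, 2000, 3000))
  prof <- compute_ehh(panel, 1, core_allele = "b")
  right <- prof[prof$arm == "right", ]
  expect_equal(right$ehh, c(1, 0))
  expect_equal(attr(prof, "trunc_right"), "cutoff")
})

test_that("fewer than two carriers or an unphased panel is an error", {
  haplo <- rbind(c(1L, 0L), c(0L, 0L), c(0L, 1L), c(0L, 1L))
  panel <- make_panel(haplo)
  expect_error(compute_ehh(panel, 1, core_allele = "b"), ">= 2 haplotypes")
  panel_u <- make_panel(haplo, phased = FALSE)
  expect_error(compute_ehh(panel_u, 1, core_allele = "a"), "phased")
})

test_that("iHH trapezoid matches hand-computed values", {
  # EHH points (0, 1.0), (1000, 0.5), (2000, 0.0) on one arm:
  # 1000 * 0.75 + 1000 * 0.25 = 1000
  prof <- tibble::tibble(arm = "right", variant = 1:3, id = letters[1:3],
                         pos_bp = c(0L, 1000L, 2000L),
                         ehh = c(1, 0.5, 0))
  expect_equal(integrate_ihh(prof), 1000)
  # single core point with immediate truncation integrates to 0
  prof1 <- prof[1, ]
  expect_equal(integrate_ihh(prof1), 0)
})

test_that("EHH agrees with the pair-enumeration oracle on random panels", {
  for (seed in 1:25) {
    panel <- random_panel(n_hap = 2 * sample(3:15, 1), m = 20, seed = seed)
    core <- sample(20, 1)
    for (allele in c(0L, 1L)) {
      if (sum(panel$haplo[, core] == allele) < 2) next
      prof <- compute_ehh(panel, core,
                          core_allele = if (allele == 0L) "a" else "b",
                          cutoff = 0)
      for (arm in c("left", "right")) {
        a <- prof[prof$arm == arm, ]
        want <- vapply(a$variant, brute_ehh, 0, haplo = panel$haplo,
                       core = core, allele = allele)
        expect_equal(a$ehh, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("EHH is non-increasing outward on every profile", {
  for (seed in 26:35) {
    panel <- random_panel(n_hap = 20, m = 15, seed = seed)
    for (core in c(1, 8, 15)) {
      for (al in c("a", "b")) {
        if (sum(panel$haplo[, core] == (al == "b")) < 2) next
        prof <- compute_ehh(panel, core, core_allele = al, cutoff = 0)
        for (arm in split(prof, prof$arm)) {
          ord <- order(abs(arm$pos_bp - attr(prof, "core_pos_bp")))
          expect_true(all(diff(arm$ehh[ord]) <= 1e-12))
        }
      }
    }
  }
})

test_that("max_extension_bp truncates the walk and flags the arm", {
  haplo <- matrix(1L, nrow = 4, ncol = 10)
  haplo[3:4, 5] <- 0L
  panel <- make_panel(haplo)
  prof <- compute_ehh(panel, 5, core_allele = "b", max_extension_bp = 2500)
  expect_equal(attr(prof, "trunc_right"), "max_extension")
  expect_true(all(abs(prof$pos_bp - attr(prof, "core_pos_bp")) <= 2500))
})

test_that("bifurcation trees conserve carrier counts and order children 0<1", {
  set.seed(7)
  panel <- random_panel(n_hap = 24, m = 12, seed = 7)
  tree <- bifurcation_tree(panel, 6, core_allele = "b", max_markers = 5)
  root <- tree$count[tree$level == 0]
  expect_equal(root, sum(panel$haplo[, 6] == 1L))
  for (lv in unique(tree$level)) {
    expect_equal(sum(tree$count[tree$level == lv]), root)
  }
  lv1 <- tree[tree$level == 1, ]
  expect_equal(lv1$path, sort(lv1$path))
  # single carrier gives a branchless path
  one <- make_panel(rbind(c(1L, 0L, 1L), c(0L, 1L, 0L)))
  path <- bifurcation_tree(one, 1, core_allele = "b", max_markers = 2)
  expect_true(all(path$count == 1))
  expect_equal(nrow(path), 3L)
})

test_that("zero-recombination panels have no more leaves than founders", {
  cf <- sweep_sim_config(n_base = 30, n_sel = 40, n_unsel = 20, n_snps = 60,
                         g_burn = 30, rho_per_bp = 0, s = 0, asc_factor = 4,
                         cohort_decades = NULL, seed = 11)
  sim <- simulate_sweep(cf)
  f <- colMeans(sim$panel_sel$haplo)
  core <- which.min(abs(f - 0.5))
  tree <- bifurcation_tree(sim$panel_sel, core, core_allele = "b",
                           max_markers = 30)
  n_leaves <- sum(tree$level == max(tree$level))
  expect_lte(n_leaves, sim$truth$n_founder_hap)
})
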