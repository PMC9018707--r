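#' Hardy-Weinberg exact test
#'
#' Exact two-sided test on genotype counts, summing the probabilities of all
#' heterozygote counts whose conditional probability (given allele counts) does
#' not exceed that of the observed count — the enumeration PLINK uses for its
#' HWE filter. Probabilities come from the recurrence
#' `P(het = h-2) / P(het = h) = h(h-1) / (4 (hom_r+1)(hom_c+1))`.
#'
#' @param n_aa,n_ab,n_bb genotype counts (vectors recycle together).
#' @return Vector of exact p-values in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  mapply(function(haa, hab, hbb) {
    n <- haa + hab + hbb
    if (n == 0L) return(NA_real_)
    n_rare <- 2L * min(haa, hbb) + hab
    # possible het counts share parity with n_rare
    hets <- seq(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
    if (length(hets) == 1L) return(1)
    # unnormalized probabilities by recurrence from the smallest het count
    lp <- numeric(length(hets))
    for (k in seq_along(hets)[-1L]) {
      h <- hets[k]
      hom_r <- (n_rare - h) / 2
      hom_c <- n - h - hom_r
      # moving h-2 -> h: P(h)/P(h-2) = 4 hom_r' hom_c' / (h (h-1)) with
      # hom_r' = hom_r + 1 etc. at the previous state
      lp[k] <- lp[k - 1L] + log(4 * (hom_r + 1) * (hom_c + 1)) -
        log(h) - log(h - 1)
    }
    p <- exp(lp - max(lp))
    p <- p / sum(p)
    obs <- p[match(hab, hets)]
    min(1, sum(p[p <= obs * (1 + 1e-12)]))
  }, n_aa, n_ab, n_bb)
}

#' Genotype counts per variant
#'
#' @param panel a [hap_panel()].
#' @return Tibble with columns `id`, `n_aa`, `n_ab`, `n_bb`, `n_missing`
#'   (counts of the allele_b dosage classes 0/1/2 over complete genotypes).
#' @export
genotype_counts <- function(panel) {
  d <- dosage_matrix(panel)
  tibble::tibble(
    id = panel$variants$id,
    n_aa = colSums(d == 0L, na.rm = TRUE),
    n_ab = colSums(d == 1L, na.rm = TRUE),
    n_bb = colSums(d == 2L, na.rm = TRUE),
    n_missing = colSums(is.na(d))
  )
}

#' Quality-control filter
#'
#' Applies, in order: per-individual missingness (> `max_missing` drops the
#' sample), per-SNP call rate (< `min_call` drops the SNP), Hardy-Weinberg
#' exact-test p (< `hwe_p` drops the SNP; tested within each population
#' present, a SNP failing in any population is removed), and minor-allele
#' frequency (< `min_maf` drops the SNP). Each SNP is charged to the first
#' filter that removes it, so the report's removals and the kept count add up
#' to the input count.
#'
#' @param panel a [hap_panel()].
#' @param hwe_p Hardy-Weinberg exact-test p-value threshold (default `1e-4`).
#' @param min_call minimum per-SNP call rate (default 0.90).
#' @param max_missing maximum per-individual missingness (default 0.10).
#' @param min_maf minimum minor-allele frequency (default 0.01).
#' @return List with elements `panel` (the filtered [hap_panel()]) and
#'   `report` (a `qc_report` tibble: one row per filter with `n_removed`,
#'   plus attributes `n_input`, `n_kept`, `n_samples_removed`, `thresholds`).
#' @export
qc_filter <- function(panel, hwe_p = 1e-4, min_call = 0.90,
                      max_missing = 0.10, min_maf = 0.01) {
  n_input <- n_variants(panel)
  d <- dosage_matrix(panel)
  ind_miss <- rowMeans(is.na(d))
  keep_samples <- ind_miss <= max_missing
  n_samples_removed <- sum(!keep_samples)
  if (n_samples_removed > 0L)
    panel <- subset_panel(panel, samples = keep_samples)

  d <- dosage_matrix(panel)
  call_rate <- colMeans(!is.na(d))
  fail_call <- call_rate < min_call

  pops <- unique(panel$samples$population)
  hwe_min <- rep(Inf, n_variants(panel))
  for (pp in pops) {
    gc <- genotype_counts(subset_panel(panel,
                                       samples = panel$samples$population == pp))
    hwe_min <- pmin(hwe_min, hwe_exact_test(gc$n_aa, gc$n_ab, gc$n_bb),
                    na.rm = TRUE)
  }
  fail_hwe <- !fail_call & is.finite(hwe_min) & hwe_min < hwe_p

  p <- colMeans(panel$haplo, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  fail_maf <- !fail_call & !fail_hwe & maf < min_maf

  keep <- !(fail_call | fail_hwe | fail_maf)
  if (!any(keep))
    stop("no variants survive QC", call. = FALSE)
  out <- subset_panel(panel, variants = keep)

  report <- tibble::tibble(
    filter = c("call_rate", "hwe", "maf"),
    threshold = c(min_call, hwe_p, min_maf),
    n_removed = c(sum(fail_call), sum(fail_hwe), sum(fail_maf))
  )
  attr(report, "n_input") <- n_input
  attr(report, "n_kept") <- sum(keep)
  attr(report, "n_samples_removed") <- n_samples_removed
  attr(report, "thresholds") <- list(hwe_p = hwe_p, min_call = min_call,
                                     max_missing = max_missing,
                                     min_maf = min_maf)
  class(report) <- c("qc_report", class(report))
  list(panel = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", attr(x, "n_input"), " variants in, ",
      attr(x, "n_kept"), " kept; ", attr(x, "n_samples_removed"),
      " sample(s) removed for missingness\n", sep = "")
  NextMethod()
}
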