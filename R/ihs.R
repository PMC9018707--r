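#' Genome-wide iHS scan
#'
#' For every eligible SNP, integrates EHH for the ancestral and the derived
#' allele (iHH_a, iHH_d), takes `raw_ihs = ln(iHH_a / iHH_d)` and standardizes
#' it to mean 0, sd 1 within derived-allele-frequency bins, so scores are
#' comparable across frequencies. Large negative standardized scores mark
#' unusually extended derived-allele haplotypes (the footprint of recent
#' positive selection); large positive scores mark extended ancestral
#' haplotypes. `pihs` is the -log10 two-sided Gaussian tail of the
#' standardized score ([pihs_transform()]).
#'
#' SNPs with unknown ancestral state, minor-allele frequency below `min_maf`,
#' fewer than two carriers of either allele, or a zero iHH are emitted with
#' `NA` scores and a `reason` code rather than dropped.
#'
#' @param panel a phased [hap_panel()] with ancestral annotations
#'   ([attach_ancestral()] or simulator truth).
#' @param min_maf minimum minor-allele frequency (default 0.01).
#' @param cutoff EHH cutoff passed to the walks (default 0.05).
#' @param freq_bin width of the derived-allele-frequency standardization bins
#'   (default 0.025).
#' @param max_extension_bp maximum arm extension in bp.
#' @param keep_end_truncated keep SNPs whose walk reached a chromosome end
#'   before crossing the cutoff (default TRUE; such arms integrate to the
#'   end and are flagged in `end_truncated`).
#' @param threshold significance threshold on `pihs` (strict `>`).
#' @return An `ihs_scan` tibble: `chrom`, `pos_bp`, `id`, `freq_derived`,
#'   `ihh_a`, `ihh_d`, `raw_ihs`, `std_ihs`, `pihs`, `allele_class`,
#'   `significant`, `end_truncated`, `reason`.
#' @export
scan_ihs <- function(panel, min_maf = 0.01, cutoff = 0.05, freq_bin = 0.025,
                     max_extension_bp = Inf, keep_end_truncated = TRUE,
                     threshold = 6) {
  if (!panel$phased) stop("iHS requires a phased panel", call. = FALSE)
  v <- panel$variants
  per_chrom <- lapply(split_by_chrom(panel), function(sub) {
    f <- colMeans(sub$haplo)
    eligible <- pmin(f, 1 - f) >= min_maf & !is.na(sub$variants$ancestral)
    res <- cpp_scan_ihh(sub$haplo, as.numeric(sub$variants$pos_bp), cutoff,
                        max_extension_bp, eligible)
    tibble::tibble(id = sub$variants$id, ihh0 = res$ihh0, ihh1 = res$ihh1,
                   end0 = res$end0, end1 = res$end1)
  })
  raw <- dplyr::bind_rows(per_chrom)
  raw <- raw[match(v$id, raw$id), ]

  anc_is_a <- v$ancestral == "a"
  out <- tibble::tibble(
    chrom = v$chrom, pos_bp = v$pos_bp, id = v$id,
    freq_derived = allele_freq(panel, "derived"),
    ihh_a = ifelse(anc_is_a, raw$ihh0, raw$ihh1),
    ihh_d = ifelse(anc_is_a, raw$ihh1, raw$ihh0),
    end_truncated = (raw$end0 | raw$end1) %in% TRUE
  )
  maf <- pmin(out$freq_derived, 1 - out$freq_derived)
  out$reason <- dplyr::case_when(
    is.na(v$ancestral) ~ "unknown_ancestral",
    is.na(maf) | maf < min_maf ~ "low_maf",
    is.na(out$ihh_a) | is.na(out$ihh_d) ~ "few_carriers",
    out$ihh_a == 0 | out$ihh_d == 0 ~ "zero_ihh",
    !keep_end_truncated & out$end_truncated ~ "end_truncated",
    TRUE ~ "ok"
  )
  if (!any(out$reason == "ok"))
    stop("no SNP eligible for iHS", call. = FALSE)
  out$raw_ihs <- ifelse(out$reason == "ok", log(out$ihh_a / out$ihh_d),
                        NA_real_)
  out$std_ihs <- standardize_in_bins(out$raw_ihs, out$freq_derived, freq_bin)
  out$reason[out$reason == "ok" & is.na(out$std_ihs)] <- "degenerate_bin"
  out$pihs <- pihs_transform(out$std_ihs)
  out <- structure(out, class = c("ihs_scan", class(out)),
                   cutoff = cutoff, freq_bin = freq_bin, min_maf = min_maf,
                   threshold = threshold)
  call_significant(out, threshold = threshold)
}

# mean-0 / sd-1 within frequency bins; NA for bins that cannot be standardized
standardize_in_bins <- function(x, freq, freq_bin) {
  bins <- cut(freq, breaks = seq(0, 1, by = freq_bin), include.lowest = TRUE)
  std <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  for (b in levels(bins)) {
    i <- which(ok & bins == b)
    if (length(i) < 2L) next
    s <- stats::sd(x[i])
    if (!is.finite(s) || s == 0) next
    std[i] <- (x[i] - mean(x[i])) / s
  }
  std
}

#' Two-sided Gaussian tail transform (piHS / pRsb scale)
#'
#' `-log10(1 - 2|Phi(x) - 0.5|)`, computed through the upper-tail complement
#' `2 * Q(|x|)` directly so it stays accurate far into the tails (|x| up to 8
#' and beyond). Symmetric in the sign of `x`; 0 at `x = 0`.
#'
#' @param x standardized scores (finite; NA propagates).
#' @return Non-negative transformed values.
#' @export
pihs_transform <- function(x) {
  -log10(2 * stats::pnorm(abs(x), lower.tail = FALSE))
}

#' Flag significant SNPs in a scan
#'
#' Significance is strict: the -log10 tail score must exceed `threshold`.
#' For iHS scans the allele class is set from the sign of the standardized
#' score (negative = derived, positive = ancestral; exactly zero = undefined
#' and never significant).
#'
#' @param scan an `ihs_scan` or `rsb_scan` tibble (or any tibble with a
#'   `pihs` or `p_rsb` column and, for classification, `std_ihs`).
#' @param threshold strict significance threshold (default 6).
#' @return The scan with `significant` (and `allele_class` where applicable)
#'   filled in.
#' @export
call_significant <- function(scan, threshold = 6) {
  pcol <- if ("pihs" %in% names(scan)) "pihs" else if
    ("p_rsb" %in% names(scan)) "p_rsb" else
    stop("scan has neither a 'pihs' nor a 'p_rsb' column", call. = FALSE)
  p <- scan[[pcol]]
  if ("std_ihs" %in% names(scan)) {
    s <- scan$std_ihs
    scan$allele_class <- dplyr::case_when(
      is.na(s) | s == 0 ~ NA_character_,
      s < 0 ~ "derived",
      TRUE ~ "ancestral"
    )
    scan$significant <- !is.na(p) & p > threshold & !is.na(scan$allele_class)
  } else {
    scan$significant <- !is.na(p) & p > threshold
  }
  attr(scan, "threshold") <- threshold
  scan
}

#' Reported significant iHS hits from the motivating cattle scan
#'
#' The published table of genome-wide-significant standardized iHS scores
#' (with their -log10 tail values) for the selected Korean beef-cattle
#' population genotyped on the BovineSNP50 chip; shipped as a plain-text
#' fixture for validating the piHS transform and the sign/threshold
#' classification rules.
#'
#' @return Tibble: `chrom`, `pos_bp`, `id`, `rsid`, `std_ihs`,
#'   `pihs_reported`.
#' @export
reported_ihs_hits <- function() {
  path <- system.file("extdata", "kpn_ihs_reported.tsv",
                      package = "sweepscan", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c"))
}
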