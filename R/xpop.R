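#' Cross-population Rsb scan
#'
#' At every SNP present and polymorphic in both panels, integrates site EHH
#' (iES, [compute_ehhs()]) within each population and takes
#' `raw_rsb = ln(iES_pop1 / iES_pop2)`. Scores are standardized by
#' subtracting the genome-wide median (robust to the extreme scores the scan
#' is looking for) and dividing by the ordinary standard deviation; `p_rsb`
#' is the -log10 two-sided Gaussian tail. Positive standardized scores point
#' to longer haplotypes (candidate selection) in the numerator population,
#' negative in the denominator population.
#'
#' @param panel1,panel2 phased [hap_panel()]s; `panel1` is the numerator.
#' @param cutoff EHHS cutoff (default 0.05).
#' @param max_extension_bp maximum arm extension in bp.
#' @param threshold significance threshold on `p_rsb` (strict `>`).
#' @return An `rsb_scan` tibble: `chrom`, `pos_bp`, `id`, `ies_pop1`,
#'   `ies_pop2`, `raw_rsb`, `std_rsb`, `p_rsb`, `significant`, `reason`;
#'   attributes `pop1`/`pop2` record the orientation.
#' @export
scan_rsb <- function(panel1, panel2, cutoff = 0.05, max_extension_bp = Inf,
                     threshold = 6) {
  if (!panel1$phased || !panel2$phased)
    stop("Rsb requires phased panels", call. = FALSE)
  shared <- intersect(panel1$variants$id, panel2$variants$id)
  if (!length(shared)) stop("panels share no markers", call. = FALSE)
  p1 <- subset_panel(panel1, variants = match(shared, panel1$variants$id))
  p2 <- subset_panel(panel2, variants = match(shared, panel2$variants$id))
  poly <- function(p) {
    f <- colMeans(p$haplo)
    f > 0 & f < 1
  }
  keep <- poly(p1) & poly(p2)
  p1 <- subset_panel(p1, variants = keep)
  p2 <- subset_panel(p2, variants = keep)

  ies_scan <- function(p) {
    per_chrom <- lapply(split_by_chrom(p), function(sub) {
      res <- cpp_scan_ies(sub$haplo, as.numeric(sub$variants$pos_bp), cutoff,
                          max_extension_bp, rep(TRUE, ncol(sub$haplo)))
      tibble::tibble(id = sub$variants$id, ies = res$ies)
    })
    dplyr::bind_rows(per_chrom)
  }
  i1 <- ies_scan(p1); i2 <- ies_scan(p2)
  stopifnot(identical(i1$id, i2$id))
  v <- p1$variants[match(i1$id, p1$variants$id), ]
  out <- tibble::tibble(
    chrom = v$chrom, pos_bp = v$pos_bp, id = v$id,
    ies_pop1 = i1$ies, ies_pop2 = i2$ies
  )
  out$reason <- dplyr::case_when(
    is.na(out$ies_pop1) | is.na(out$ies_pop2) ~ "too_few_haplotypes",
    out$ies_pop1 == 0 | out$ies_pop2 == 0 ~ "zero_ies",
    TRUE ~ "ok"
  )
  out$raw_rsb <- ifelse(out$reason == "ok",
                        log(out$ies_pop1 / out$ies_pop2), NA_real_)
  med <- stats::median(out$raw_rsb, na.rm = TRUE)
  s <- stats::sd(out$raw_rsb, na.rm = TRUE)
  out$std_rsb <- if (is.finite(s) && s > 0) (out$raw_rsb - med) / s else
    NA_real_
  out$p_rsb <- pihs_transform(out$std_rsb)
  out <- structure(out, class = c("rsb_scan", class(out)),
                   pop1 = panel1$samples$population[1],
                   pop2 = panel2$samples$population[1],
                   cutoff = cutoff, threshold = threshold)
  call_significant(out, threshold = threshold)
}

#' Per-SNP and genome-wide Fst between two populations
#'
#' Heterozygosity-based fixation index `(H_T - H_S)/H_T`, where `H_S` is the
#' mean expected heterozygosity (2pq) of the two populations and `H_T` the
#' expected heterozygosity at the unweighted mean allele frequency
#' (populations, not individuals, are the units). The genome-wide value is
#' the ratio of sums for numerical stability at low-MAF SNPs; per-SNP values
#' allow either summary to be recomputed.
#'
#' @param panel1,panel2 [hap_panel()]s sharing marker ids (alleles are
#'   harmonized by id; a marker whose allele pair differs is dropped).
#' @return An `fst_result` tibble: `chrom`, `pos_bp`, `id`, `p1`, `p2`,
#'   `h_t`, `h_s`, `fst` (NA where the pooled site is monomorphic), with
#'   attribute `fst_genome`.
#' @export
compute_fst <- function(panel1, panel2) {
  shared <- intersect(panel1$variants$id, panel2$variants$id)
  if (!length(shared)) stop("panels share no markers", call. = FALSE)
  i1 <- match(shared, panel1$variants$id)
  i2 <- match(shared, panel2$variants$id)
  v1 <- panel1$variants[i1, ]; v2 <- panel2$variants[i2, ]
  same <- v1$allele_a == v2$allele_a & v1$allele_b == v2$allele_b
  swapped <- v1$allele_a == v2$allele_b & v1$allele_b == v2$allele_a
  keep <- same | swapped
  p1 <- colMeans(panel1$haplo[, i1[keep], drop = FALSE], na.rm = TRUE)
  p2 <- colMeans(panel2$haplo[, i2[keep], drop = FALSE], na.rm = TRUE)
  p2 <- ifelse(swapped[keep], 1 - p2, p2)
  pbar <- (p1 + p2) / 2
  h_t <- 2 * pbar * (1 - pbar)
  h_s <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  fst <- ifelse(h_t > 0, (h_t - h_s) / h_t, NA_real_)
  out <- tibble::tibble(
    chrom = v1$chrom[keep], pos_bp = v1$pos_bp[keep], id = v1$id[keep],
    p1 = p1, p2 = p2, h_t = h_t, h_s = h_s, fst = fst
  )
  ok <- !is.na(fst)
  gw <- if (any(ok)) (sum(h_t[ok]) - sum(h_s[ok])) / sum(h_t[ok]) else
    NA_real_
  structure(out, class = c("fst_result", class(out)), fst_genome = gw)
}

#' Classical MDS on identity-by-state distances
#'
#' Pairwise distance `1 - IBS` (mean shared-allele proportion per genotype
#' pair), double-centered and eigendecomposed via [stats::cmdscale()].
#'
#' @param panels a [hap_panel()] or list of panels (pooled).
#' @param dims number of coordinates to return (default 4; silently limited
#'   to the positive-eigenvalue rank, with a warning when fewer are
#'   available).
#' @return An `mds_result` tibble: `sample_id`, `population`, `MDS1..MDSk`;
#'   attribute `eig` holds the eigenvalues.
#' @export
classical_mds <- function(panels, dims = 4) {
  if (inherits(panels, "hap_panel")) panels <- list(panels)
  shared <- Reduce(intersect, lapply(panels, function(p) p$variants$id))
  if (!length(shared)) stop("panels share no markers", call. = FALSE)
  d <- do.call(rbind, lapply(panels, function(p)
    dosage_matrix(subset_panel(p, variants = match(shared, p$variants$id)))))
  meta <- dplyr::bind_rows(lapply(panels, function(p)
    p$samples[, c("sample_id", "population")]))
  if (anyNA(d)) stop("MDS requires complete genotypes (run QC first)",
                     call. = FALSE)
  dd <- stats::dist(d, method = "manhattan") / (2 * ncol(d))
  k <- min(dims, nrow(d) - 1L)
  fit <- stats::cmdscale(dd, k = k, eig = TRUE)
  n_pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  if (n_pos < dims)
    warning("only ", n_pos, " positive dimensions available (", dims,
            " requested)", call. = FALSE)
  coords <- tibble::as_tibble(fit$points, .name_repair = "minimal")
  names(coords) <- paste0("MDS", seq_len(ncol(coords)))
  out <- dplyr::bind_cols(meta, coords)
  structure(out, class = c("mds_result", class(out)), eig = fit$eig)
}
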