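#' Decadal cohort trends of allele frequencies and breeding values
#'
#' For each decade cohort and each requested SNP: haplotype counts and
#' ancestral/derived allele frequencies; for each requested trait: the
#' cohort's mean EBV with its standard error. Decades are returned in
#' ascending order; an empty decade yields an all-NA row.
#'
#' @param panel a [hap_panel()] whose samples carry `cohort_decade` (and EBV
#'   columns for `traits`).
#' @param snp_ids marker ids to summarize (ancestral state must be known).
#' @param traits character vector of phenotype column names (default none).
#' @return A `cohort_trend` tibble: `decade`, `id`, `n_hap`,
#'   `freq_ancestral`, `freq_derived`, then `mean_<trait>` / `se_<trait>`
#'   columns.
#' @export
cohort_trend <- function(panel, snp_ids, traits = character(0)) {
  s <- panel$samples
  if (all(is.na(s$cohort_decade)))
    stop("panel samples have no cohort_decade labels", call. = FALSE)
  idx <- match(snp_ids, panel$variants$id)
  if (anyNA(idx))
    stop("unknown marker id: ", paste(snp_ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  if (any(is.na(panel$variants$ancestral[idx])))
    stop("ancestral state unknown for requested SNP(s)", call. = FALSE)
  decades <- sort(unique(s$cohort_decade))
  derived_code <- ifelse(panel$variants$ancestral[idx] == "a", 1L, 0L)
  hap_decade <- rep(s$cohort_decade, each = 2L)

  rows <- list()
  for (dec in decades) {
    hrows <- which(hap_decade == dec)
    srows <- which(s$cohort_decade == dec)
    for (k in seq_along(idx)) {
      fd <- if (length(hrows)) mean(panel$haplo[hrows, idx[k]] ==
                                      derived_code[k]) else NA_real_
      row <- tibble::tibble(decade = dec, id = snp_ids[k],
                            n_hap = length(hrows),
                            freq_ancestral = 1 - fd, freq_derived = fd)
      for (tr in traits) {
        vals <- s[[tr]][srows]
        row[[paste0("mean_", tr)]] <-
          if (length(vals)) mean(vals) else NA_real_
        row[[paste0("se_", tr)]] <-
          if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals)) else
            NA_real_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("cohort_trend", class(out)), traits = traits)
}

#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Exact two-locus haplotype counts (no EM needed on phased data) give
#' `D = p_AB - p_A p_B`, `r2 = D^2 / (p_A q_A p_B q_B)` and the normalized
#' `D' = D / D_max`. Pairs farther apart than `max_dist_bp` (default 500 kb)
#' are skipped; pairs involving a monomorphic marker get NA.
#'
#' @param panel a phased [hap_panel()].
#' @param marker_ids markers to include (default: all), taken in map order;
#'   inter-chromosome pairs are skipped.
#' @param max_dist_bp maximum pair distance in bp (default 500000).
#' @return An `ld_matrix` tibble (upper triangle): `id1`, `id2`, `dist_bp`,
#'   `d`, `d_prime`, `r2`.
#' @export
ld_matrix <- function(panel, marker_ids = NULL, max_dist_bp = 5e5) {
  if (!panel$phased) stop("haplotype LD requires a phased panel",
                          call. = FALSE)
  v <- panel$variants
  idx <- if (is.null(marker_ids)) seq_len(nrow(v)) else {
    i <- match(marker_ids, v$id)
    if (anyNA(i)) stop("unknown marker id", call. = FALSE)
    sort(i)
  }
  h <- panel$haplo[, idx, drop = FALSE]
  p <- unname(colMeans(h))
  rows <- list()
  for (a in seq_along(idx)[-length(idx)]) {
    for (b in seq((a + 1L), length(idx))) {
      if (v$chrom[idx[a]] != v$chrom[idx[b]]) next
      dist <- abs(v$pos_bp[idx[b]] - v$pos_bp[idx[a]])
      if (dist > max_dist_bp) next
      pa <- p[a]; pb <- p[b]
      if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
        D <- NA_real_; dp <- NA_real_; r2 <- NA_real_
      } else {
        pab <- mean(h[, a] == 1L & h[, b] == 1L)
        D <- pab - pa * pb
        r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
        dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb) else
          min(pa * pb, (1 - pa) * (1 - pb))
        dp <- if (dmax > 0) D / dmax else 0
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id1 = v$id[idx[a]], id2 = v$id[idx[b]], dist_bp = dist,
        d = D, d_prime = dp, r2 = r2)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(id1 = character(0), id2 = character(0),
                   dist_bp = numeric(0), d = numeric(0),
                   d_prime = numeric(0), r2 = numeric(0))
  structure(out, class = c("ld_matrix", class(out)),
            max_dist_bp = max_dist_bp)
}
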