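#' Haplotype panel
#'
#' The substrate of every statistic in the package: an allele matrix with two
#' rows per diploid sample, a variant map, and per-sample metadata. Alleles are
#' coded 0 (`allele_a`) and 1 (`allele_b`); `NA` marks a missing genotype and
#' is only permitted while `phased = FALSE`.
#'
#' @param haplo integer matrix, `2 * nrow(samples)` rows by `nrow(variants)`
#'   columns, entries in `{0, 1, NA}`.
#' @param variants tibble with columns `chrom`, `pos_bp` (1-based physical
#'   position), `id`, `allele_a`, `allele_b`, and `ancestral` (`"a"`, `"b"` or
#'   `NA` for unknown).
#' @param samples tibble with columns `sample_id`, `population`, and optionally
#'   `cohort_decade` plus one numeric column per phenotype (EBV, real units).
#' @param phased logical; `TRUE` promises complete, phase-resolved rows.
#'
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(haplo, variants, samples, phased = FALSE) {
  haplo <- as.matrix(haplo)
  storage.mode(haplo) <- "integer"
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)
  if (!"ancestral" %in% names(variants)) variants$ancestral <- NA_character_
  if (!"cohort_decade" %in% names(samples)) samples$cohort_decade <- NA_integer_
  panel <- structure(
    list(haplo = haplo, variants = variants, samples = samples,
         phased = isTRUE(phased)),
    class = "hap_panel"
  )
  validate_hap_panel(panel)
  panel
}

#' Validate a haplotype panel
#'
#' Enforces the structural invariants: two haplotype rows per sample, matching
#' column count, sorted strictly increasing positions within chromosome,
#' distinct alleles, allele codes in `{0, 1}` and completeness when phased.
#'
#' @param panel a [hap_panel()].
#' @return The panel, invisibly, or an error describing the violation.
#' @export
validate_hap_panel <- function(panel) {
  h <- panel$haplo; v <- panel$variants; s <- panel$samples
  if (nrow(h) != 2L * nrow(s))
    stop("haplotype matrix must have 2 rows per sample (", nrow(h),
         " rows for ", nrow(s), " samples)", call. = FALSE)
  if (ncol(h) != nrow(v))
    stop("haplotype matrix has ", ncol(h), " columns but ", nrow(v),
         " variants", call. = FALSE)
  if (anyDuplicated(v$id))
    stop("duplicate marker id: ",
         paste(unique(v$id[duplicated(v$id)]), collapse = ", "), call. = FALSE)
  if (any(v$pos_bp < 1L))
    stop("variant positions must be >= 1 bp (1-based physical)", call. = FALSE)
  bad_order <- v |>
    dplyr::mutate(.idx = dplyr::row_number()) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::filter(dplyr::row_number() > 1L & diff(c(NA, .data$pos_bp)) <= 0)
  if (nrow(bad_order) > 0L)
    stop("positions not strictly increasing within chromosome at marker ",
         bad_order$id[1L], call. = FALSE)
  if (any(v$allele_a == v$allele_b))
    stop("allele_a == allele_b at marker ",
         v$id[which(v$allele_a == v$allele_b)[1L]], call. = FALSE)
  codes <- unique(as.vector(h))
  if (!all(codes %in% c(0L, 1L, NA)))
    stop("haplotype entries must be 0, 1 or NA", call. = FALSE)
  if (panel$phased && anyNA(h))
    stop("phased panel contains missing alleles", call. = FALSE)
  if (!all(is.na(v$ancestral) | v$ancestral %in% c("a", "b")))
    stop("ancestral must be 'a', 'b' or NA", call. = FALSE)
  invisible(panel)
}

#' @export
print.hap_panel <- function(x, ...) {
  cat("<hap_panel> ", nrow(x$samples), " samples (", nrow(x$haplo),
      " haplotypes) x ", nrow(x$variants), " variants, ",
      if (x$phased) "phased" else "unphased", "\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$variants$chrom), collapse = ", "),
      "\n", sep = "")
  pops <- table(x$samples$population)
  cat("  populations: ",
      paste(names(pops), pops, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of samples / variants in a panel
#' @param panel a [hap_panel()].
#' @return Integer count.
#' @export
n_samples <- function(panel) nrow(panel$samples)

#' @rdname n_samples
#' @export
n_variants <- function(panel) nrow(panel$variants)

#' Genotype dosage matrix
#'
#' Collapses the two haplotype rows of each sample into a 0/1/2 count of the
#' `allele_b` (code 1) allele, or of the derived allele when
#' `derived = TRUE` (columns with unknown ancestral state are `NA`).
#'
#' @param panel a [hap_panel()].
#' @param derived count derived-allele copies instead of allele_b copies.
#' @return samples x variants integer matrix (NA where a genotype is missing).
#' @export
dosage_matrix <- function(panel, derived = FALSE) {
  h <- panel$haplo
  idx <- seq_len(n_samples(panel))
  d <- h[2L * idx - 1L, , drop = FALSE] + h[2L * idx, , drop = FALSE]
  rownames(d) <- panel$samples$sample_id
  colnames(d) <- panel$variants$id
  if (derived) {
    anc <- panel$variants$ancestral
    flip <- which(anc == "b")     # derived is allele_a -> dosage 2 - d
    unknown <- which(is.na(anc))
    if (length(flip)) d[, flip] <- 2L - d[, flip, drop = FALSE]
    if (length(unknown)) d[, unknown] <- NA_integer_
  }
  d
}

#' Allele frequencies per variant
#'
#' @param panel a [hap_panel()].
#' @param allele `"b"` (code 1, default), `"a"`, or `"derived"` (NA where the
#'   ancestral state is unknown).
#' @return Numeric vector, one frequency per variant, computed over non-missing
#'   haplotype entries.
#' @export
allele_freq <- function(panel, allele = c("b", "a", "derived")) {
  allele <- match.arg(allele)
  p <- colMeans(panel$haplo, na.rm = TRUE)
  if (allele == "a") return(1 - p)
  if (allele == "derived") {
    # ancestral "a" means the derived allele is allele_b (code 1)
    anc <- panel$variants$ancestral
    p <- ifelse(is.na(anc), NA_real_, ifelse(anc == "a", p, 1 - p))
  }
  p
}

#' Subset a panel by variants and/or samples
#'
#' @param panel a [hap_panel()].
#' @param variants integer or logical index into the variant table, or NULL.
#' @param samples integer or logical index into the sample table, or NULL.
#' @return A new [hap_panel()] with the retained rows/columns.
#' @export
subset_panel <- function(panel, variants = NULL, samples = NULL) {
  v_idx <- if (is.null(variants)) seq_len(n_variants(panel)) else
    seq_len(n_variants(panel))[variants]
  s_idx <- if (is.null(samples)) seq_len(n_samples(panel)) else
    seq_len(n_samples(panel))[samples]
  row_idx <- as.vector(rbind(2L * s_idx - 1L, 2L * s_idx))
  hap_panel(panel$haplo[row_idx, v_idx, drop = FALSE],
            panel$variants[v_idx, , drop = FALSE],
            panel$samples[s_idx, , drop = FALSE],
            phased = panel$phased)
}

#' Split a panel by chromosome
#' @param panel a [hap_panel()].
#' @return Named list of single-chromosome panels, in order of appearance.
#' @export
split_by_chrom <- function(panel) {
  chroms <- unique(panel$variants$chrom)
  out <- lapply(chroms, function(cc)
    subset_panel(panel, variants = panel$variants$chrom == cc))
  names(out) <- as.character(chroms)
  out
}
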