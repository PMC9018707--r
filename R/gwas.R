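#' Genomic relationship matrix
#'
#' VanRaden-form GRM: `A_jk = (1/N) sum_i (x_ij - 2p_i)(x_ik - 2p_i) /
#' (2 p_i (1 - p_i))` over the N included SNPs, with dosages `x` counting
#' the allele_b allele and in-sample frequencies `p_i`. Monomorphic SNPs are
#' skipped (count reported via message).
#'
#' @param panel a [hap_panel()] with complete genotypes.
#' @param exclude_chrom chromosome label(s) to leave out (LOCO), or `NULL`.
#' @return A `grm` object: `K` (n x n symmetric matrix), `sample_id`,
#'   `chromosomes_included`, `p` (frequencies used), `n_snps`.
#' @export
compute_grm <- function(panel, exclude_chrom = NULL) {
  v <- panel$variants
  keep <- !(v$chrom %in% exclude_chrom)
  d <- dosage_matrix(subset_panel(panel, variants = keep))
  if (anyNA(d)) stop("GRM requires complete genotypes", call. = FALSE)
  p <- colMeans(d) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    message(sum(mono), " monomorphic SNP(s) skipped in GRM")
    d <- d[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  if (ncol(d) == 0L) stop("no polymorphic SNPs left for the GRM",
                          call. = FALSE)
  z <- sweep(d, 2L, 2 * p, `-`)
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), `/`)
  K <- tcrossprod(z) / ncol(z)
  structure(list(K = K, sample_id = panel$samples$sample_id,
                 chromosomes_included = setdiff(unique(v$chrom),
                                                exclude_chrom),
                 p = p, n_snps = ncol(z)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm> ", nrow(x$K), " x ", nrow(x$K), " from ", x$n_snps,
      " SNPs on chromosomes ",
      paste(x$chromosomes_included, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.grm <- function(x, ...) {
  n <- nrow(x$K)
  idx <- which(upper.tri(x$K, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(sample_1 = x$sample_id[idx[, 1L]],
                 sample_2 = x$sample_id[idx[, 2L]],
                 relationship = x$K[idx])
}

#' REML variance components for a single-GRM mixed model
#'
#' Model `y = 1 mu + g + e`, `g ~ N(0, sigma_g2 K)`, `e ~ N(0, sigma_e2 I)`.
#' One eigendecomposition of the GRM reduces REML to an exact 1-D profile
#' search over the variance ratio, optimized to relative tolerance 1e-8.
#' Numerically negative GRM eigenvalues are clipped at zero with a warning.
#'
#' @param y numeric phenotype vector (length n).
#' @param grm a `grm` from [compute_grm()] (or a bare symmetric matrix).
#' @return An `mlm_varcomp` list: `sigma_g2`, `sigma_e2`, `h2`, `loglik`,
#'   `n`, plus the rotation (`U`, `d`) reused by the association scan.
#' @export
fit_variance_components <- function(y, grm) {
  K <- if (inherits(grm, "grm")) grm$K else as.matrix(grm)
  stopifnot(length(y) == nrow(K))
  if (stats::var(y) == 0)
    return(structure(list(sigma_g2 = 0, sigma_e2 = 0, h2 = NA_real_,
                          loglik = NA_real_, n = length(y),
                          U = NULL, d = NULL), class = "mlm_varcomp"))
  eg <- eigen(K, symmetric = TRUE)
  d <- eg$values
  if (any(d < -1e-8 * max(abs(d))))
    warning("GRM not numerically PSD; clipping negative eigenvalues at 0",
            call. = FALSE)
  d <- pmax(d, 0)
  U <- eg$vectors
  ys <- crossprod(U, y)
  xs <- crossprod(U, rep(1, length(y)))
  n <- length(y)

  reml_ll <- function(log_gamma) {
    g <- exp(log_gamma)            # sigma_g2 / sigma_e2
    w <- g * d + 1                 # V = sigma_e2 * diag(w) after rotation
    wi <- 1 / w
    xtvx <- sum(wi * xs^2)
    beta <- sum(wi * xs * ys) / xtvx
    r <- ys - xs * beta
    rss <- sum(wi * r^2)
    s2 <- rss / (n - 1)
    -0.5 * ((n - 1) * log(s2) + sum(log(w)) + log(xtvx) + (n - 1))
  }
  opt <- stats::optimize(reml_ll, interval = c(-14, 14), maximum = TRUE,
                         tol = 1e-8)
  g <- exp(opt$maximum)
  w <- g * d + 1
  wi <- 1 / w
  xtvx <- sum(wi * xs^2)
  beta <- sum(wi * xs * ys) / xtvx
  rss <- sum(wi * (ys - xs * beta)^2)
  sigma_e2 <- rss / (n - 1)
  sigma_g2 <- g * sigma_e2
  # boundary polish: compare against the no-genetic-variance model
  if (reml_ll(-14) >= opt$objective) {
    sigma_g2 <- 0
    sigma_e2 <- stats::var(y)
  }
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 h2 = sigma_g2 / (sigma_g2 + sigma_e2),
                 loglik = opt$objective, n = n, U = U, d = d),
            class = "mlm_varcomp")
}

#' @export
print.mlm_varcomp <- function(x, ...) {
  cat("<mlm_varcomp> sigma_g2 = ", signif(x$sigma_g2, 4),
      ", sigma_e2 = ", signif(x$sigma_e2, 4),
      ", h2 = ", signif(x$h2, 3), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @export
glance.mlm_varcomp <- function(x, ...) {
  tibble::tibble(sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2, h2 = x$h2,
                 loglik = x$loglik, n = x$n)
}

#' Mixed-linear-model association scan with LOCO polygenic control
#'
#' Per chromosome c: a GRM excluding c is built, variance components are
#' re-estimated by REML, and every SNP on c is tested by exact generalized
#' least squares of `y = a + b x` under covariance
#' `sigma_g2 * K_loco + sigma_e2 * I` (leave-one-chromosome-out avoids the
#' tested SNP contributing to its own polygenic control). The per-SNP test
#' is a 1-df Wald chi-square on the allele-substitution effect `b`.
#'
#' @param panel a [hap_panel()] with complete genotypes.
#' @param pheno phenotype source: `NULL` to use a column of
#'   `panel$samples`, or a data frame with `sample_id` and trait columns.
#' @param trait name of the trait column.
#' @param varcomp optional forced variance components, a list with
#'   `sigma_g2` and `sigma_e2` (skips REML; `sigma_g2 = 0` reduces every fit
#'   to ordinary least squares).
#' @param alpha significance level for the Bonferroni-adjusted flag.
#' @return A `gwas_scan` tibble: `chrom`, `pos_bp`, `id`, `freq`, `beta`,
#'   `se`, `wald_chi2`, `p`, `neglog10p`, `p_bonf`, `significant`,
#'   `sigma_g2`, `sigma_e2` (components of the LOCO set used for that SNP).
#' @export
mlm_loco_scan <- function(panel, pheno = NULL, trait, varcomp = NULL,
                          alpha = 0.05) {
  if (is.null(pheno)) {
    if (!trait %in% names(panel$samples))
      stop("trait '", trait, "' not found in sample metadata", call. = FALSE)
    y_all <- panel$samples[[trait]]
  } else {
    pheno <- tibble::as_tibble(pheno)
    y_all <- pheno[[trait]][match(panel$samples$sample_id, pheno$sample_id)]
  }
  keep <- !is.na(y_all)
  if (!all(keep)) panel <- subset_panel(panel, samples = keep)
  y <- y_all[keep]
  n <- length(y)
  chroms <- unique(panel$variants$chrom)
  dos_all <- dosage_matrix(panel)
  if (anyNA(dos_all)) stop("GWAS requires complete genotypes", call. = FALSE)

  res <- lapply(chroms, function(cc) {
    on_c <- panel$variants$chrom == cc
    p_c <- colMeans(dos_all[, on_c, drop = FALSE]) / 2
    if (all(p_c <= 0 | p_c >= 1)) {
      warning("chromosome ", cc, " has no polymorphic SNP; skipped",
              call. = FALSE)
      return(NULL)
    }
    if (length(chroms) == 1L) {
      warning("single-chromosome panel: polygenic term uses that chromosome",
              call. = FALSE)
      grm_loco <- compute_grm(panel)
    } else {
      grm_loco <- compute_grm(panel, exclude_chrom = cc)
    }
    if (is.null(varcomp)) {
      vc <- fit_variance_components(y, grm_loco)
      U <- vc$U; d <- vc$d
      sg <- vc$sigma_g2; se2 <- vc$sigma_e2
    } else {
      eg <- eigen(grm_loco$K, symmetric = TRUE)
      U <- eg$vectors; d <- pmax(eg$values, 0)
      sg <- varcomp$sigma_g2; se2 <- varcomp$sigma_e2
    }
    w <- 1 / (sg * d + se2)
    ys <- as.vector(crossprod(U, y))
    os <- as.vector(crossprod(U, rep(1, n)))
    Xs <- crossprod(U, dos_all[, on_c, drop = FALSE])
    s11 <- sum(w * os^2)
    s1y <- sum(w * os * ys)
    sx1 <- as.vector(crossprod(Xs, w * os))
    sxy <- as.vector(crossprod(Xs, w * ys))
    sxx <- as.vector(crossprod(Xs^2, w))
    det <- s11 * sxx - sx1^2
    beta <- (s11 * sxy - sx1 * s1y) / det
    var_beta <- s11 / det
    poly_ok <- p_c > 0 & p_c < 1
    beta[!poly_ok] <- NA_real_
    se_b <- sqrt(var_beta)
    se_b[!poly_ok] <- NA_real_
    chi2 <- (beta / se_b)^2
    pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    tibble::tibble(
      chrom = cc,
      pos_bp = panel$variants$pos_bp[on_c],
      id = panel$variants$id[on_c],
      freq = p_c,
      beta = beta, se = se_b, wald_chi2 = chi2, p = pval,
      neglog10p = -log10(pval),
      sigma_g2 = sg, sigma_e2 = se2
    )
  })
  out <- dplyr::bind_rows(res)
  out$p_bonf <- stats::p.adjust(out$p, method = "bonferroni")
  out$significant <- !is.na(out$p_bonf) & out$p_bonf < alpha
  structure(out, class = c("gwas_scan", class(out)), trait = trait,
            alpha = alpha, n = n)
}

#' @export
glance.gwas_scan <- function(x, ...) {
  tibble::tibble(trait = attr(x, "trait"), n_snps = nrow(x),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 min_p = min(x$p, na.rm = TRUE),
                 top_id = x$id[which.min(x$p)])
}
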