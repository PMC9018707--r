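#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_segment geom_errorbar facet_wrap labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot an EHH (or EHHS) decay curve
#' @param object an `ehh_profile`.
#' @param ... unused.
#' @return A ggplot: EHH against position, one line per arm, core at the peak.
#' @export
autoplot.ehh_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$pos_bp / 1e6, y = .data$ehh,
                     group = .data$arm)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "position (Mb)", y = "EHH",
         title = paste0("EHH decay around ", attr(object, "core_id"),
                        " (", attr(object, "core_allele"), " allele)")) +
    theme_minimal()
}

manhattan_plot <- function(df, ycol, threshold, ylab, colour = NULL) {
  p <- ggplot(df, aes(x = .data$pos_bp / 1e6, y = .data[[ycol]]))
  p <- if (is.null(colour)) p + geom_point(size = 0.6, alpha = 0.7) else
    p + geom_point(aes(colour = .data[[colour]]), size = 0.6, alpha = 0.7)
  p + geom_hline(yintercept = threshold, linetype = "dashed") +
    facet_wrap(~chrom, scales = "free_x", nrow = 1) +
    labs(x = "position (Mb)", y = ylab) +
    theme_minimal()
}

#' Manhattan-style plot of an iHS scan (piHS scale)
#' @param object an `ihs_scan`.
#' @param ... unused.
#' @return A ggplot of piHS by position, coloured by allele class, with the
#'   significance threshold dashed.
#' @export
autoplot.ihs_scan <- function(object, ...) {
  manhattan_plot(dplyr::filter(object, !is.na(.data$pihs)), "pihs",
                 attr(object, "threshold") %||% 6, "piHS", "allele_class")
}

#' Manhattan-style plot of an Rsb scan
#' @param object an `rsb_scan`.
#' @param ... unused.
#' @return A ggplot of pRsb by position with the significance threshold.
#' @export
autoplot.rsb_scan <- function(object, ...) {
  manhattan_plot(dplyr::filter(object, !is.na(.data$p_rsb)), "p_rsb",
                 attr(object, "threshold") %||% 6, "pRsb")
}

#' Manhattan plot of a mixed-model GWAS scan
#' @param object a `gwas_scan`.
#' @param ... unused.
#' @return A ggplot of -log10 p by position.
#' @export
autoplot.gwas_scan <- function(object, ...) {
  thr <- -log10(attr(object, "alpha") / nrow(object))
  manhattan_plot(dplyr::filter(object, !is.na(.data$p)), "neglog10p", thr,
                 paste0("-log10 p (", attr(object, "trait"), ")"))
}

#' Per-SNP Fst plot
#' @param object an `fst_result`.
#' @param ... unused.
#' @return A ggplot of per-SNP Fst with the genome-wide value dashed.
#' @export
autoplot.fst_result <- function(object, ...) {
  manhattan_plot(dplyr::filter(object, !is.na(.data$fst)), "fst",
                 attr(object, "fst_genome"), "Fst")
}

#' MDS scatter of the first two coordinates
#' @param object an `mds_result`.
#' @param ... unused.
#' @return A ggplot coloured by population.
#' @export
autoplot.mds_result <- function(object, ...) {
  ggplot(object, aes(x = .data$MDS1, y = .data$MDS2,
                     colour = .data$population)) +
    geom_point(alpha = 0.7) +
    labs(x = "MDS 1", y = "MDS 2") +
    theme_minimal()
}

#' Decadal trend plot: derived-allele frequency and EBV means
#' @param object a `cohort_trend`.
#' @param ... unused.
#' @return A ggplot of derived-allele frequency across decades (one line per
#'   SNP).
#' @export
autoplot.cohort_trend <- function(object, ...) {
  ggplot(object, aes(x = .data$decade, y = .data$freq_derived,
                     group = .data$id, colour = .data$id)) +
    geom_line() + geom_point() +
    labs(x = "decade", y = "derived-allele frequency") +
    theme_minimal()
}

#' Haplotype bifurcation diagram
#' @param object a `bifurcation_tree`.
#' @param ... unused.
#' @return A ggplot with branch thickness proportional to haplotype count.
#' @export
autoplot.bifurcation_tree <- function(object, ...) {
  # vertical placement: order paths within each level, weight by count
  df <- object |>
    dplyr::group_by(.data$level) |>
    dplyr::arrange(.data$path, .by_group = TRUE) |>
    dplyr::mutate(y = (cumsum(.data$count) - .data$count / 2) /
                    sum(.data$count)) |>
    dplyr::ungroup()
  seg <- df |>
    dplyr::filter(.data$level > 0) |>
    dplyr::left_join(df |>
                       dplyr::select("level", "path", py = "y") |>
                       dplyr::mutate(level = .data$level + 1L),
                     by = c("level", "parent_path" = "path"))
  ggplot() +
    geom_segment(data = seg,
                 aes(x = .data$level - 1L, xend = .data$level,
                     y = .data$py, yend = .data$y,
                     linewidth = .data$count), lineend = "round") +
    ggplot2::scale_linewidth(range = c(0.2, 4)) +
    labs(x = paste0("markers from core (", attr(object, "direction"), ")"),
         y = NULL,
         title = paste0("bifurcation at ", attr(object, "core_id"), " (",
                        attr(object, "core_allele"), ")")) +
    theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
glance.fst_result <- function(x, ...) {
  tibble::tibble(fst_genome = attr(x, "fst_genome"),
                 n_snps = sum(!is.na(x$fst)),
                 fst_mean = mean(x$fst, na.rm = TRUE))
}

#' @export
glance.ihs_scan <- function(x, ...) {
  tibble::tibble(n_snps = nrow(x), n_tested = sum(!is.na(x$std_ihs)),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 n_derived = sum(x$significant &
                                   x$allele_class == "derived", na.rm = TRUE),
                 n_ancestral = sum(x$significant &
                                     x$allele_class == "ancestral",
                                   na.rm = TRUE))
}

#' @export
glance.rsb_scan <- function(x, ...) {
  tibble::tibble(n_snps = nrow(x), n_tested = sum(!is.na(x$std_rsb)),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 pop1 = attr(x, "pop1"), pop2 = attr(x, "pop2"))
}
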