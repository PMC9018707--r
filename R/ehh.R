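#' Extended haplotype homozygosity around a core SNP
#'
#' For the haplotypes carrying `core_allele` at the core marker, EHH at a
#' marker x is the probability that two randomly drawn carriers are identical
#' at every marker between the core and x (pair-counting form
#' `sum n_h(n_h-1) / (n_c(n_c-1))`). The walk proceeds outward on the core's
#' chromosome until EHH falls below `cutoff` (the first sub-cutoff marker is
#' kept), the chromosome ends, or `max_extension_bp` is exceeded.
#'
#' @param panel a phased, complete [hap_panel()].
#' @param core core marker: its id (character) or variant index (numeric).
#' @param core_allele `"derived"`, `"ancestral"` (require a known ancestral
#'   state), `"a"`, or `"b"`.
#' @param cutoff EHH value at which the walk stops (default 0.05).
#' @param max_extension_bp maximum arm length in bp (default unlimited).
#' @return An `ehh_profile` tibble (`arm`, `variant`, `id`, `pos_bp`, `ehh`)
#'   with attributes `core_id`, `core_pos_bp`, `core_allele`, `n_carriers`,
#'   `trunc_left`, `trunc_right` (`"cutoff"`, `"end"` or `"max_extension"`),
#'   and `ihh` (trapezoidal integral over both arms, bp x EHH).
#' @export
compute_ehh <- function(panel, core, core_allele = "derived", cutoff = 0.05,
                        max_extension_bp = Inf) {
  prof <- ehh_walk(panel, core, core_allele, cutoff, max_extension_bp,
                   site = FALSE)
  prof
}

#' Site EHH (EHHS) around a core SNP
#'
#' Tang-style site version pooling both core alleles: haplotype homozygosity
#' over the interval core..x among *all* haplotypes, with the unbiased (n-1)
#' correction, normalized by its value at the core so EHHS(core) = 1. Its
#' integral (iES) is the per-population ingredient of Rsb.
#'
#' @inheritParams compute_ehh
#' @return An `ehh_profile` tibble as in [compute_ehh()]; the `ihh` attribute
#'   holds the iES.
#' @export
compute_ehhs <- function(panel, core, cutoff = 0.05, max_extension_bp = Inf) {
  ehh_walk(panel, core, "site", cutoff, max_extension_bp, site = TRUE)
}

resolve_core <- function(panel, core) {
  idx <- if (is.character(core)) match(core, panel$variants$id) else
    as.integer(core)
  if (is.na(idx) || idx < 1L || idx > n_variants(panel))
    stop("core marker '", core, "' not found in panel", call. = FALSE)
  idx
}

resolve_allele_code <- function(panel, idx, core_allele) {
  anc <- panel$variants$ancestral[idx]
  switch(core_allele,
    a = 0L, b = 1L,
    ancestral = {
      if (is.na(anc)) stop("ancestral state unknown at marker ",
                           panel$variants$id[idx], call. = FALSE)
      if (anc == "a") 0L else 1L
    },
    derived = {
      if (is.na(anc)) stop("ancestral state unknown at marker ",
                           panel$variants$id[idx], call. = FALSE)
      if (anc == "a") 1L else 0L
    },
    stop("core_allele must be 'derived', 'ancestral', 'a' or 'b'",
         call. = FALSE)
  )
}

trunc_label <- function(code) c("cutoff", "end", "max_extension")[code + 1L]

ehh_walk <- function(panel, core, core_allele, cutoff, max_extension_bp,
                     site) {
  if (!panel$phased) stop("EHH requires a phased panel", call. = FALSE)
  idx <- resolve_core(panel, core)
  chrom <- panel$variants$chrom[idx]
  on_chrom <- which(panel$variants$chrom == chrom)
  sub <- panel$haplo[, on_chrom, drop = FALSE]
  pos <- as.numeric(panel$variants$pos_bp[on_chrom])
  core_local <- match(idx, on_chrom)
  allele_code <- if (site) -1L else resolve_allele_code(panel, idx, core_allele)
  res <- cpp_ehh_profile(sub, pos, core_local - 1L, allele_code, cutoff,
                         max_extension_bp)
  arm_tbl <- function(which_idx, which_ehh, arm) {
    loc <- res[[which_idx]] + 1L
    tibble::tibble(arm = arm,
                   variant = on_chrom[loc],
                   id = panel$variants$id[on_chrom[loc]],
                   pos_bp = panel$variants$pos_bp[on_chrom[loc]],
                   ehh = res[[which_ehh]])
  }
  out <- dplyr::bind_rows(arm_tbl("left_idx", "left_ehh", "left"),
                          arm_tbl("right_idx", "right_ehh", "right"))
  class(out) <- c("ehh_profile", class(out))
  attr(out, "core_id") <- panel$variants$id[idx]
  attr(out, "core_pos_bp") <- panel$variants$pos_bp[idx]
  attr(out, "core_allele") <- if (site) "site" else core_allele
  attr(out, "n_carriers") <- res$n_carriers
  attr(out, "cutoff") <- cutoff
  attr(out, "trunc_left") <- trunc_label(res$left_trunc)
  attr(out, "trunc_right") <- trunc_label(res$right_trunc)
  attr(out, "ihh") <- integrate_ihh(out)
  out
}

#' Integrate an EHH profile into an iHH (or iES) value
#'
#' Trapezoidal rule over physical distance on each arm, core to the last
#' emitted point (the first sub-cutoff marker closes a truncated arm with its
#' actual EHH value; nothing is extrapolated), arms summed.
#'
#' @param profile an `ehh_profile` from [compute_ehh()] or [compute_ehhs()].
#' @return Non-negative scalar, bp x EHH units.
#' @export
integrate_ihh <- function(profile) {
  arms <- split(profile, profile$arm)
  sum(vapply(arms, function(a) {
    if (nrow(a) < 2L) return(0)
    d <- abs(diff(as.numeric(a$pos_bp)))
    sum(0.5 * (a$ehh[-1] + a$ehh[-nrow(a)]) * d)
  }, 0))
}

#' Haplotype bifurcation tree
#'
#' Roots the carriers of a core allele at the core marker and splits them at
#' each successive marker outward by the allele carried, so branch thickness
#' traces how haplotype homozygosity breaks down with distance.
#'
#' @inheritParams compute_ehh
#' @param direction `"right"` (increasing bp) or `"left"`.
#' @param max_markers number of markers to descend (truncated at the
#'   chromosome end).
#' @return A `bifurcation_tree` tibble: `level` (0 = root at the core), `id`,
#'   `pos_bp`, `path` (allele string from the core), `parent_path`, `count`.
#'   At every level the child counts sum to the root count; children are
#'   ordered allele 0 before allele 1.
#' @export
bifurcation_tree <- function(panel, core, core_allele = "derived",
                             direction = c("right", "left"),
                             max_markers = 10L) {
  direction <- match.arg(direction)
  if (!panel$phased) stop("bifurcation requires a phased panel", call. = FALSE)
  idx <- resolve_core(panel, core)
  allele_code <- resolve_allele_code(panel, idx, core_allele)
  carriers <- which(panel$haplo[, idx] == allele_code)
  if (length(carriers) < 1L)
    stop("no carriers of the requested core allele", call. = FALSE)
  chrom <- panel$variants$chrom[idx]
  on_chrom <- which(panel$variants$chrom == chrom)
  step <- if (direction == "right") 1L else -1L
  walk <- idx + step * seq_len(max_markers)
  walk <- walk[walk %in% on_chrom]
  paths <- rep("", length(carriers))
  nodes <- list(tibble::tibble(level = 0L, id = panel$variants$id[idx],
                               pos_bp = panel$variants$pos_bp[idx],
                               path = "", parent_path = NA_character_,
                               count = length(carriers)))
  for (k in seq_along(walk)) {
    j <- walk[k]
    paths <- paste0(paths, panel$haplo[carriers, j])
    tab <- sort(table(paths))    # deterministic: lexicographic 0 before 1
    tab <- tab[order(names(tab))]
    nodes[[k + 1L]] <- tibble::tibble(
      level = k,
      id = panel$variants$id[j],
      pos_bp = panel$variants$pos_bp[j],
      path = names(tab),
      parent_path = substr(names(tab), 1L, k - 1L),
      count = as.integer(tab))
  }
  out <- dplyr::bind_rows(nodes)
  class(out) <- c("bifurcation_tree", class(out))
  attr(out, "core_id") <- panel$variants$id[idx]
  attr(out, "core_allele") <- core_allele
  attr(out, "direction") <- direction
  out
}
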