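#' Read PLINK text PED/MAP files
#'
#' Parses whitespace-delimited PED/MAP into an unphased [hap_panel()]. The
#' missing-allele code `"0"` becomes `NA`; `allele_a`/`allele_b` are assigned
#' alphabetically from the alleles observed at each marker (a marker where only
#' one allele is seen gets the placeholder `"N"` as its second allele).
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @return An unphased [hap_panel()]; the two PED allele columns of a sample
#'   fill its two haplotype rows (phase is *not* implied by column order).
#' @export
read_ped_map <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map_lines <- readLines(map_path)
  map_fields <- strsplit(trimws(map_lines), "\\s+")
  nf <- lengths(map_fields)
  if (any(nf < 4L))
    stop("malformed MAP line ", which(nf < 4L)[1L], ": expected 4 fields",
         call. = FALSE)
  variants <- tibble::tibble(
    chrom = vapply(map_fields, `[[`, "", 1L),
    id = vapply(map_fields, `[[`, "", 2L),
    pos_bp = as.integer(vapply(map_fields, `[[`, "", 4L))
  )
  m <- nrow(variants)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_fields <- strsplit(trimws(ped_lines), "\\s+")
  expected <- 6L + 2L * m
  bad <- which(lengths(ped_fields) != expected)
  if (length(bad))
    stop("malformed PED line ", bad[1L], ": expected ", expected,
         " fields, found ", lengths(ped_fields)[bad[1L]], call. = FALSE)
  n <- length(ped_fields)
  sample_id <- vapply(ped_fields, `[[`, "", 2L)
  al <- matrix("", nrow = 2L * n, ncol = m)
  for (i in seq_len(n)) {
    g <- ped_fields[[i]][-(1:6)]
    al[2L * i - 1L, ] <- g[seq(1L, 2L * m, by = 2L)]
    al[2L * i, ] <- g[seq(2L, 2L * m, by = 2L)]
  }
  al[al == "0"] <- NA_character_

  allele_a <- character(m); allele_b <- character(m)
  haplo <- matrix(NA_integer_, nrow = 2L * n, ncol = m)
  for (j in seq_len(m)) {
    obs <- sort(unique(al[, j]))
    obs <- obs[!is.na(obs)]
    if (length(obs) > 2L)
      stop("marker ", variants$id[j], " has >2 alleles: ",
           paste(obs, collapse = ","), call. = FALSE)
    allele_a[j] <- if (length(obs) >= 1L) obs[1L] else "N"
    allele_b[j] <- if (length(obs) == 2L) obs[2L] else "N2"
    haplo[, j] <- ifelse(is.na(al[, j]), NA_integer_,
                         ifelse(al[, j] == allele_a[j], 0L, 1L))
  }
  variants$allele_a <- allele_a
  variants$allele_b <- allele_b
  samples <- tibble::tibble(sample_id = sample_id,
                            population = vapply(ped_fields, `[[`, "", 1L))
  hap_panel(haplo, variants, samples, phased = FALSE)
}

#' Write a phased panel as a TSV trio
#'
#' Writes `<prefix>.hap.tsv` (columns `sample_id`, `hap` in 1:2, then one
#' nucleotide column per marker id), `<prefix>.var.tsv` (the variant map) and
#' `<prefix>.sam.tsv` (sample metadata). The round trip through
#' [read_phased_panel()] is bit-exact.
#'
#' @param panel a phased [hap_panel()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_phased_panel <- function(panel, prefix) {
  if (!panel$phased) stop("panel must be phased", call. = FALSE)
  v <- panel$variants
  nuc <- matrix(ifelse(panel$haplo == 0L, rep(v$allele_a, each = nrow(panel$haplo)),
                       rep(v$allele_b, each = nrow(panel$haplo))),
                nrow = nrow(panel$haplo))
  hap_tbl <- tibble::as_tibble(as.data.frame(nuc, stringsAsFactors = FALSE),
                               .name_repair = "minimal")
  names(hap_tbl) <- v$id
  hap_tbl <- dplyr::bind_cols(
    tibble::tibble(sample_id = rep(panel$samples$sample_id, each = 2L),
                   hap = rep(1:2, n_samples(panel))),
    hap_tbl)
  readr::write_tsv(hap_tbl, paste0(prefix, ".hap.tsv"))
  readr::write_tsv(v, paste0(prefix, ".var.tsv"))
  readr::write_tsv(panel$samples, paste0(prefix, ".sam.tsv"))
  invisible(prefix)
}

#' Read a phased panel from a TSV trio
#'
#' Counterpart of [write_phased_panel()]. Every sample must contribute exactly
#' two haplotype rows and every allele must match the marker's
#' `allele_a`/`allele_b`; anything else is an error (phased input may not
#' contain missing alleles).
#'
#' @param prefix path prefix used by [write_phased_panel()].
#' @return A phased [hap_panel()].
#' @export
read_phased_panel <- function(prefix) {
  v <- readr::read_tsv(paste0(prefix, ".var.tsv"), show_col_types = FALSE,
                       col_types = readr::cols(chrom = "c", pos_bp = "i",
                                               .default = "c"))
  s <- readr::read_tsv(paste0(prefix, ".sam.tsv"), show_col_types = FALSE)
  hap_tbl <- readr::read_tsv(paste0(prefix, ".hap.tsv"), show_col_types = FALSE,
                             col_types = readr::cols(.default = "c"))
  per_sample <- table(hap_tbl$sample_id)
  if (any(per_sample != 2L))
    stop("sample ", names(per_sample)[per_sample != 2L][1L],
         " has ", per_sample[per_sample != 2L][1L],
         " haplotype rows; exactly 2 required", call. = FALSE)
  nuc <- as.matrix(hap_tbl[, v$id, drop = FALSE])
  haplo <- matrix(NA_integer_, nrow = nrow(nuc), ncol = ncol(nuc))
  for (j in seq_len(ncol(nuc))) {
    ok_a <- nuc[, j] == v$allele_a[j]
    ok_b <- nuc[, j] == v$allele_b[j]
    if (!all(ok_a | ok_b))
      stop("allele '", nuc[which(!(ok_a | ok_b))[1L], j], "' at marker ",
           v$id[j], " matches neither allele_a nor allele_b", call. = FALSE)
    haplo[, j] <- ifelse(ok_a, 0L, 1L)
  }
  # order haplotype rows to follow the sample table
  ord <- order(match(hap_tbl$sample_id, s$sample_id), hap_tbl$hap)
  hap_panel(haplo[ord, , drop = FALSE], v, s, phased = TRUE)
}

#' Read phased genotypes from a VCF
#'
#' Minimal reader for phased diploid VCF `GT` fields. Separators must be `|`;
#' an unphased `/` separator is an error, as are missing alleles.
#'
#' @param path path to an uncompressed VCF file.
#' @param population population label stored for every sample.
#' @return A phased [hap_panel()].
#' @export
read_phased_vcf <- function(path, population = "pop1") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("no #CHROM header line in VCF", call. = FALSE)
  cols <- strsplit(lines[hdr], "\t")[[1]]
  sample_id <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[!startsWith(body, "#")]
  rows <- strsplit(body, "\t")
  m <- length(rows)
  variants <- tibble::tibble(
    chrom = vapply(rows, `[[`, "", 1L),
    pos_bp = as.integer(vapply(rows, `[[`, "", 2L)),
    id = vapply(rows, `[[`, "", 3L),
    allele_a = vapply(rows, `[[`, "", 4L),
    allele_b = vapply(rows, `[[`, "", 5L)
  )
  n <- length(sample_id)
  haplo <- matrix(NA_integer_, nrow = 2L * n, ncol = m)
  for (j in seq_len(m)) {
    fmt <- strsplit(rows[[j]][9L], ":")[[1]]
    gt_i <- which(fmt == "GT")
    if (!length(gt_i)) stop("no GT field at VCF record ", j, call. = FALSE)
    gts <- vapply(rows[[j]][-(1:9)],
                  function(x) strsplit(x, ":")[[1]][gt_i], "",
                  USE.NAMES = FALSE)
    if (any(grepl("/", gts, fixed = TRUE)))
      stop("unphased genotype separator '/' at marker ", variants$id[j],
           "; phased '|' required", call. = FALSE)
    parts <- strsplit(gts, "|", fixed = TRUE)
    if (any(lengths(parts) != 2L) || any(unlist(parts) == "."))
      stop("missing or non-diploid GT at marker ", variants$id[j],
           call. = FALSE)
    a <- as.integer(unlist(parts))
    if (any(a > 1L)) stop("multi-allelic site at marker ", variants$id[j],
                          "; biallelic input required", call. = FALSE)
    haplo[, j] <- a
  }
  samples <- tibble::tibble(sample_id = sample_id, population = population)
  hap_panel(haplo, variants, samples, phased = TRUE)
}

#' Attach ancestral-allele annotations
#'
#' Joins a marker-to-ancestral-nucleotide table onto the panel's variant map.
#' Markers absent from the table, and markers whose annotated nucleotide
#' matches neither observed allele (warned), are flagged unknown; unknown
#' markers are skipped by the iHS scan but still usable for Rsb.
#'
#' @param panel a [hap_panel()].
#' @param ancestral a tibble/data.frame with columns `marker_id` and
#'   `ancestral_allele`, or the path of a TSV with those columns.
#' @return The panel with `variants$ancestral` filled in.
#' @export
attach_ancestral <- function(panel, ancestral) {
  if (is.character(ancestral) && length(ancestral) == 1L)
    ancestral <- readr::read_tsv(ancestral, show_col_types = FALSE)
  ancestral <- tibble::as_tibble(ancestral)
  stopifnot(all(c("marker_id", "ancestral_allele") %in% names(ancestral)))
  v <- panel$variants
  idx <- match(v$id, ancestral$marker_id)
  nuc <- ancestral$ancestral_allele[idx]
  status <- dplyr::case_when(
    is.na(nuc) ~ NA_character_,
    nuc == v$allele_a ~ "a",
    nuc == v$allele_b ~ "b",
    TRUE ~ "mismatch"
  )
  n_bad <- sum(status == "mismatch", na.rm = TRUE)
  if (n_bad > 0L) {
    warning(n_bad, " marker(s) with ancestral nucleotide matching neither ",
            "allele; flagged unknown", call. = FALSE)
    status[status == "mismatch"] <- NA_character_
  }
  panel$variants$ancestral <- status
  panel
}
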