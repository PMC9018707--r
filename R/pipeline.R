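#' Default end-to-end run configuration
#'
#' Thresholds default to the standard chip-QC and significance settings used
#' throughout the package: Hardy-Weinberg exact p < 1e-4, call rate >= 0.90,
#' per-individual missingness <= 0.10, MAF >= 0.01, piHS/pRsb > 6, EHH
#' cutoff 0.05, standardization bin width 0.025.
#'
#' @param sim a [sweep_sim_config()] describing the simulated input.
#' @param out_dir output directory for stage TSVs and the JSON manifest.
#' @param traits GWAS traits to scan.
#' @param seed seed controlling every stochastic stage.
#' @param ... overrides for any threshold field.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sweep_sim_config(), out_dir = tempfile("sweepscan_run_"),
                       traits = "CWT", seed = 1L, ...) {
  cfg <- list(
    sim = sim, out_dir = out_dir, traits = traits, seed = seed,
    hwe_p = 1e-4, min_call = 0.90, max_missing = 0.10, min_maf = 0.01,
    ehh_cutoff = 0.05, freq_bin = 0.025, pihs_threshold = 6,
    prsb_threshold = 6, ld_max_dist_bp = 5e5, mds_dims = 4
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

write_stage <- function(tbl, dir, name, manifest) {
  path <- file.path(dir, paste0(name, ".tsv"))
  readr::write_tsv(tibble::as_tibble(tbl), path)
  manifest$outputs[[name]] <- list(
    path = basename(path), n_rows = nrow(tbl),
    md5 = unname(tools::md5sum(path)))
  manifest
}

#' Run the full simulate-QC-scan pipeline
#'
#' Stages: sweep simulation, per-population QC, iHS scans of both
#' populations, Rsb (selected vs unselected), Fst, MDS, MLM-LOCO GWAS per
#' trait, and decadal cohort trends at the top iHS SNP. Every stage writes a
#' TSV into `out_dir`; a JSON manifest records thresholds, seeds, row counts
#' and md5 checksums, so a rerun with the same config and seed is
#' bit-identical.
#'
#' @param config a [run_config()].
#' @return The manifest (invisibly a list), with `out_dir` attached.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("sweepscan")),
    seed = config$seed,
    thresholds = config[c("hwe_p", "min_call", "max_missing", "min_maf",
                          "ehh_cutoff", "freq_bin", "pihs_threshold",
                          "prsb_threshold", "ld_max_dist_bp", "mds_dims")],
    outputs = list()
  )

  stage <- "sim"
  res <- tryCatch({
    config$sim$seed <- config$seed
    sim <- simulate_sweep(config$sim)
    message("[sim] focal ", sim$truth$focal_id, " on chrom ",
            sim$truth$focal_chrom)

    stage <- "qc"
    qc_sel <- qc_filter(sim$panel_sel, hwe_p = config$hwe_p,
                        min_call = config$min_call,
                        max_missing = config$max_missing,
                        min_maf = config$min_maf)
    qc_unsel <- qc_filter(sim$panel_unsel, hwe_p = config$hwe_p,
                          min_call = config$min_call,
                          max_missing = config$max_missing,
                          min_maf = config$min_maf)
    message("[qc] selected ", attr(qc_sel$report, "n_kept"), "/",
            attr(qc_sel$report, "n_input"), "; unselected ",
            attr(qc_unsel$report, "n_kept"), "/",
            attr(qc_unsel$report, "n_input"), " SNPs kept")
    manifest <- write_stage(qc_sel$report, config$out_dir, "qc_selected",
                            manifest)
    manifest <- write_stage(qc_unsel$report, config$out_dir, "qc_unselected",
                            manifest)

    stage <- "ihs"
    ihs_sel <- scan_ihs(qc_sel$panel, min_maf = config$min_maf,
                        cutoff = config$ehh_cutoff,
                        freq_bin = config$freq_bin,
                        threshold = config$pihs_threshold)
    ihs_unsel <- scan_ihs(qc_unsel$panel, min_maf = config$min_maf,
                          cutoff = config$ehh_cutoff,
                          freq_bin = config$freq_bin,
                          threshold = config$pihs_threshold)
    message("[ihs] significant: selected ", sum(ihs_sel$significant),
            ", unselected ", sum(ihs_unsel$significant))
    manifest <- write_stage(ihs_sel, config$out_dir, "ihs_selected", manifest)
    manifest <- write_stage(ihs_unsel, config$out_dir, "ihs_unselected",
                            manifest)

    stage <- "rsb"
    rsb <- scan_rsb(qc_sel$panel, qc_unsel$panel,
                    cutoff = config$ehh_cutoff,
                    threshold = config$prsb_threshold)
    manifest <- write_stage(rsb, config$out_dir, "rsb", manifest)

    stage <- "fst"
    fst <- compute_fst(qc_sel$panel, qc_unsel$panel)
    message("[fst] genome-wide = ", signif(attr(fst, "fst_genome"), 4))
    manifest <- write_stage(fst, config$out_dir, "fst", manifest)
    manifest$fst_genome <- attr(fst, "fst_genome")

    stage <- "mds"
    mds <- classical_mds(list(qc_sel$panel, qc_unsel$panel),
                         dims = config$mds_dims)
    manifest <- write_stage(mds, config$out_dir, "mds", manifest)

    stage <- "gwas"
    for (tr in config$traits) {
      if (!tr %in% names(qc_sel$panel$samples)) next
      gw <- mlm_loco_scan(qc_sel$panel, trait = tr)
      manifest <- write_stage(gw, config$out_dir, paste0("gwas_", tr),
                              manifest)
    }

    stage <- "trends"
    if (!all(is.na(qc_sel$panel$samples$cohort_decade))) {
      eligible <- which(!is.na(ihs_sel$std_ihs))
      top <- eligible[which.max(abs(ihs_sel$std_ihs[eligible]))]
      traits_avail <- intersect(config$traits,
                                names(qc_sel$panel$samples))
      tr_tbl <- cohort_trend(qc_sel$panel, ihs_sel$id[top],
                             traits = traits_avail)
      manifest <- write_stage(tr_tbl, config$out_dir, "trends", manifest)
    }
    manifest
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(res, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(res, "out_dir") <- config$out_dir
  invisible(res)
}
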