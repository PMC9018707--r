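#' Configuration for the two-population sweep simulator
#'
#' Forward Wright-Fisher simulation of a burn-in population that splits into a
#' selected and an unselected descendant. Defaults emulate a ~50k-chip scan of
#' a 30-year cattle breeding program: 667 selected vs 362 unselected animals,
#' one SNP per ~55 kb, a clean split 40 generations ago with directional
#' selection at one focal derived allele over the final 30 generations, and
#' four decade cohorts with rising breeding values.
#'
#' @param n_base diploid size of the burn-in population. The burn-in runs for
#'   `g_burn` generations (default `4 * n_base`) so linkage disequilibrium
#'   approaches drift equilibrium at the marker density.
#' @param n_sel,n_unsel diploid sizes of the selected / unselected populations.
#' @param n_snps markers per chromosome.
#' @param n_chrom number of chromosomes (freely recombining).
#' @param spacing_bp mean adjacent-marker distance in bp; gaps are exponential.
#' @param rho_per_bp per-generation crossover probability per bp.
#' @param s selection coefficient of the focal derived allele in the selected
#'   population (genotype fitnesses 1, 1+hs, 1+s).
#' @param h dominance coefficient in (0, 1].
#' @param focal_index marker index of the selected allele, or `NULL` (the
#'   default) to introduce the favored derived allele as a recent
#'   single-origin mutation at the end of the burn-in: one template
#'   haplotype's window of `focal_span_bp` is copied onto a fraction
#'   `focal_freq` of all haplotypes, which receive the derived allele at the
#'   central marker of chromosome 1. This constructs the classic hard-sweep
#'   configuration — one young haplotype rising in frequency — that
#'   haplotype-based scans are built to detect.
#' @param focal_freq derived-allele frequency at the start of the split
#'   phase (the planted frequency when `focal_index` is `NULL`).
#' @param focal_span_bp identical span of the planted young haplotype in bp
#'   (default 2.5 Mb, consistent with an allele roughly as old as the
#'   divergence of the two populations: age about `2 / (rho_per_bp *
#'   focal_span_bp)` generations).
#' @param g_split generations since the populations diverged.
#' @param g_sel generations of selection (final `g_sel` of the split phase;
#'   must be `<= g_split`).
#' @param g_burn burn-in generations (default `4 * n_base`).
#' @param asc_maf chip-ascertainment threshold: the marker panel is chosen at
#'   the end of the burn-in among loci with minor-allele frequency
#'   `>= asc_maf`, the way chip content is ascertained on a modern
#'   population. Initial candidate frequencies are Beta(0.5, 0.5) truncated
#'   to the same minor-allele frequency (a U-shaped neutral-SFS proxy).
#' @param asc_factor candidate loci simulated per retained marker; the
#'   burn-in runs on `asc_factor * n_snps` loci per chromosome so that
#'   `n_snps` of them still segregate above `asc_maf` after `g_burn`
#'   generations of drift.
#' @param burn_rho_scale multiplier on `rho_per_bp` applied during the
#'   burn-in only. Scaling the recombination rate while holding `n_base`
#'   fixed emulates the haplotype diversity of an ancestral population
#'   `burn_rho_scale` times larger (the usual `Ne x rho` rescaling), so the
#'   deep history carries realistically many haplotype lineages per Mb while
#'   the recent split and selection phases run at the true map rate.
#' @param cohort_decades named integer vector of per-decade sample counts for
#'   the selected population (names are decade labels, e.g. `"1980"`), or
#'   `NULL` for no cohort structure. Counts must sum to at most `n_sel`.
#' @param trait_model list of per-trait models for [simulate_ebv()]; see that
#'   function. `NULL` uses its defaults.
#' @param seed RNG seed (mandatory; all randomness flows from it).
#'
#' @return A `sweep_sim_config` list.
#' @export
sweep_sim_config <- function(n_base = 700, n_sel = 667, n_unsel = 362,
                             n_snps = 2000, n_chrom = 1, spacing_bp = 55000,
                             rho_per_bp = 1e-8, s = 0.15, h = 0.5,
                             focal_index = NULL, focal_freq = 0.35,
                             focal_span_bp = 2.5e6,
                             g_split = 40, g_sel = 30, g_burn = 4 * n_base,
                             asc_maf = 0.05, asc_factor = 10,
                             burn_rho_scale = 4,
                             cohort_decades = default_cohorts(n_sel),
                             trait_model = NULL, seed = 1L) {
  stopifnot(s >= 0, h > 0, h <= 1, g_sel <= g_split, g_sel >= 0,
            n_base >= 2, n_sel >= 1, n_unsel >= 1, n_snps >= 2,
            spacing_bp > 0, rho_per_bp >= 0, focal_freq > 0, focal_freq < 1)
  if (!is.null(focal_index))
    stopifnot(focal_index >= 1, focal_index <= n_snps * n_chrom)
  if (!is.null(cohort_decades)) {
    stopifnot(all(cohort_decades > 0), sum(cohort_decades) <= n_sel,
              !is.null(names(cohort_decades)))
  }
  structure(as.list(environment()), class = "sweep_sim_config")
}

#' Equal-sized decade cohorts 1980s-2010s
#' @param n total number of selected animals to spread over the four decades.
#' @return Named integer vector of per-decade counts.
#' @export
default_cohorts <- function(n) {
  base <- n %/% 4L
  counts <- rep(base, 4L) + c(rep(1L, n %% 4L), rep(0L, 4L - n %% 4L))
  stats::setNames(counts, c("1980", "1990", "2000", "2010"))
}

# switch intensity per gap giving exactly p_gap = rho * gap per meiosis
gap_lambda <- function(gaps_bp, rho_per_bp) {
  p <- pmin(rho_per_bp * gaps_bp, 0.5 - 1e-12)
  -0.5 * log(1 - 2 * p)
}

# wrap a haplotype matrix as a phased panel
panel_from_matrix <- function(hap, variants, population, id_prefix) {
  n <- nrow(hap) / 2L
  samples <- tibble::tibble(
    sample_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    population = population
  )
  hap_panel(hap, variants, samples, phased = TRUE)
}

#' Simulate a selected/unselected population pair
#'
#' Burn-in to drift equilibrium, split, neutral divergence, then directional
#' selection at the focal locus in the selected population only. Ancestral
#' alleles are the major alleles at the start of the burn-in (known truth).
#' If `cohort_decades` is set, decade cohorts are assigned from generation
#' snapshots ([assign_cohorts()]) and, if a trait model applies, EBV-like
#' phenotypes are attached ([simulate_ebv()]).
#'
#' @param config a [sweep_sim_config()].
#' @return A `sweep_sim` list: `panel_sel`, `panel_unsel` (phased
#'   [hap_panel()]s), `truth` (focal locus, selection trajectory, realized
#'   frequencies, founder count), `snapshots` (per-decade haplotype matrices),
#'   and `config`.
#' @export
simulate_sweep <- function(config) {
  stopifnot(inherits(config, "sweep_sim_config"))
  cf <- config
  set.seed(cf$seed)

  # candidate loci: denser than the chip so that, after the burn-in fixes a
  # large fraction by drift, n_snps per chromosome still segregate
  n_cand_chrom <- as.integer(ceiling(cf$asc_factor * cf$n_snps))
  m_cand <- n_cand_chrom * cf$n_chrom
  cand_spacing <- cf$spacing_bp * cf$n_snps / n_cand_chrom
  chrom <- rep(as.character(seq_len(cf$n_chrom)), each = n_cand_chrom)
  pos <- unlist(lapply(seq_len(cf$n_chrom), function(cc) {
    gaps <- pmax(1, round(stats::rexp(n_cand_chrom, 1 / cand_spacing)))
    cumsum(gaps)
  }))
  chrom_start <- c(TRUE, chrom[-1] != chrom[-m_cand])
  lam <- ifelse(chrom_start[-1], 0,
                gap_lambda(diff(pos), cf$rho_per_bp * cf$burn_rho_scale))

  # candidate frequencies: truncated-Beta neutral-SFS proxy, linkage
  # equilibrium start (LD builds up by drift during the burn-in)
  p0 <- stats::rbeta(m_cand, 0.5, 0.5)
  redraw <- pmin(p0, 1 - p0) < cf$asc_maf
  while (any(redraw)) {
    p0[redraw] <- stats::rbeta(sum(redraw), 0.5, 0.5)
    redraw <- pmin(p0, 1 - p0) < cf$asc_maf
  }
  founders <- matrix(stats::rbinom(2L * cf$n_base * m_cand, 1L,
                                   rep(p0, each = 2L * cf$n_base)),
                     nrow = 2L * cf$n_base)
  storage.mode(founders) <- "integer"
  f_init_cand <- colMeans(founders)

  burn <- cpp_wf_evolve(founders, lam, chrom_start, cf$n_base, cf$g_burn,
                        0, cf$h, -1L, 0L, integer(0))

  # chip-style ascertainment at the end of the burn-in: keep n_snps evenly
  # spaced loci per chromosome with MAF >= asc_maf in the panel-design
  # population (dropped candidates still contributed recombination distance,
  # exactly like untyped sites between chip markers)
  f_burn <- colMeans(burn$hap)
  keep <- unlist(lapply(unique(chrom), function(cc) {
    on_c <- which(chrom == cc)
    elig <- on_c[pmin(f_burn[on_c], 1 - f_burn[on_c]) >= cf$asc_maf]
    if (length(elig) < cf$n_snps) {
      message("chromosome ", cc, ": only ", length(elig),
              " of the requested ", cf$n_snps,
              " markers segregate above the ascertainment MAF")
      elig
    } else {
      elig[round(seq(1, length(elig), length.out = cf$n_snps))]
    }
  }))
  chrom <- chrom[keep]
  pos <- pos[keep]
  m_total <- length(keep)
  chrom_start <- c(TRUE, chrom[-1] != chrom[-m_total])
  lam <- ifelse(chrom_start[-1], 0, gap_lambda(diff(pos), cf$rho_per_bp))
  burn$hap <- burn$hap[, keep, drop = FALSE]
  f_init <- f_init_cand[keep]

  variants <- tibble::tibble(
    chrom = chrom, pos_bp = as.integer(pos),
    id = sprintf("snp%s_%05d", chrom,
                 unlist(lapply(split(seq_along(chrom), chrom)[unique(chrom)],
                               seq_along))),
    allele_a = "A", allele_b = "G",
    # ancestral allele = major allele at simulation start (known truth)
    ancestral = ifelse(f_init >= 0.5, "b", "a")
  )
  derived_code <- ifelse(variants$ancestral == "a", 1L, 0L)

  focal <- cf$focal_index
  if (is.null(focal)) {
    # plant the focal derived allele as a recent single-origin mutation at
    # the end of the burn-in: one template haplotype's window of
    # focal_span_bp is copied onto 2N * focal_freq randomly chosen
    # haplotypes, which receive the derived allele at the central marker.
    # This constructs the present-day signature of a young favored
    # haplotype (age ~ 2 / (rho * focal_span_bp) generations, i.e. around
    # the founding of the breeding program at the defaults) without
    # having to condition a forward path on an improbable drift ascent.
    on_c1 <- which(chrom == chrom[1L])
    focal <- on_c1[which.min(abs(pos[on_c1] -
                                   (pos[on_c1[1L]] + pos[max(on_c1)]) / 2))]
    win <- which(abs(pos - pos[focal]) <= cf$focal_span_bp / 2 &
                   chrom == chrom[focal])
    n_hap_base <- nrow(burn$hap)
    n_carr <- max(2L, round(n_hap_base * cf$focal_freq))
    carriers <- sample.int(n_hap_base, n_carr)
    template <- burn$hap[carriers[1L], win]
    burn$hap[carriers, win] <- rep(template, each = n_carr)
    burn$hap[, focal] <- 1L - derived_code[focal]
    burn$hap[carriers, focal] <- derived_code[focal]
    f_init[focal] <- mean(burn$hap[, focal])
  }

  # unselected branch: pure drift for g_split generations
  unsel <- cpp_wf_evolve(burn$hap, lam, chrom_start, cf$n_unsel, cf$g_split,
                         0, cf$h, -1L, 0L, integer(0))

  # selected branch: neutral pre-phase, then selection with decade snapshots
  g_pre <- cf$g_split - cf$g_sel
  pre <- cpp_wf_evolve(burn$hap, lam, chrom_start, cf$n_sel, g_pre,
                       0, cf$h, -1L, 0L, integer(0))

  freq_onset_derived <- ifelse(derived_code == 1L,
                               colMeans(pre$hap), 1 - colMeans(pre$hap))
  # conditioning on segregation: resample the pre-split branch if the focal
  # derived allele was lost by drift
  attempts <- 0L
  while (freq_onset_derived[focal] == 0 && attempts < 20L) {
    attempts <- attempts + 1L
    message("focal derived allele lost before selection; resampling (",
            attempts, ")")
    pre <- cpp_wf_evolve(burn$hap, lam, chrom_start, cf$n_sel, max(g_pre, 1L),
                         0, cf$h, -1L, 0L, integer(0))
    freq_onset_derived <- ifelse(derived_code == 1L, colMeans(pre$hap),
                                 1 - colMeans(pre$hap))
  }
  if (freq_onset_derived[focal] == 0)
    stop("focal derived allele irrecoverably lost during burn-in/pre-phase",
         call. = FALSE)

  n_decades <- if (is.null(cf$cohort_decades)) 0L else length(cf$cohort_decades)
  snap_gens <- if (n_decades > 0L && cf$g_sel > 0L)
    as.integer(ceiling(seq_len(n_decades) * cf$g_sel / n_decades)) else integer(0)
  selp <- cpp_wf_evolve(pre$hap, lam, chrom_start, cf$n_sel, cf$g_sel,
                        cf$s, cf$h, focal - 1L, derived_code[focal],
                        unique(snap_gens))
  snapshots <- selp$snapshots
  if (length(snap_gens))
    snapshots <- selp$snapshots[match(snap_gens, unique(snap_gens))]

  panel_sel <- panel_from_matrix(selp$hap, variants, "selected", "SEL")
  panel_unsel <- panel_from_matrix(unsel$hap, variants, "unselected", "USP")

  truth <- list(
    focal_index = focal,
    focal_id = variants$id[focal],
    focal_chrom = variants$chrom[focal],
    focal_pos_bp = variants$pos_bp[focal],
    s = cf$s,
    derived_code = derived_code,
    freq_init = f_init,
    freq_onset_derived_focal = freq_onset_derived[focal],
    traj_sel = selp$traj,
    freq_sel = colMeans(panel_sel$haplo),
    freq_unsel = colMeans(panel_unsel$haplo),
    n_founder_hap = 2L * cf$n_base,
    snap_gens = snap_gens,
    resample_events = attempts
  )
  out <- structure(list(panel_sel = panel_sel, panel_unsel = panel_unsel,
                        truth = truth, snapshots = snapshots, config = cf),
                   class = "sweep_sim")
  if (n_decades > 0L) {
    out <- assign_cohorts(out, cf$cohort_decades, seed = cf$seed + 1L)
    out <- simulate_ebv(out, cf$trait_model, seed = cf$seed + 2L)
  }
  out
}

#' @export
print.sweep_sim <- function(x, ...) {
  cat("<sweep_sim> focal ", x$truth$focal_id, " (chrom ", x$truth$focal_chrom,
      ", ", x$truth$focal_pos_bp, " bp), s = ", x$truth$s, "\n", sep = "")
  cat("  derived freq: onset ",
      signif(x$truth$freq_onset_derived_focal, 3), " -> final ",
      signif(focal_derived_freq(x$panel_sel, x$truth), 3),
      " (selected), ", signif(focal_derived_freq(x$panel_unsel, x$truth), 3),
      " (unselected)\n", sep = "")
  invisible(x)
}

focal_derived_freq <- function(panel, truth) {
  f <- mean(panel$haplo[, truth$focal_index])
  if (truth$derived_code[truth$focal_index] == 1L) f else 1 - f
}

#' Assign decade cohorts from generation snapshots
#'
#' Rebuilds the selected panel so that each decade's samples are drawn,
#' without replacement, from the generation snapshot of that decade (later
#' decades from later generations), setting `cohort_decade` on each sample.
#'
#' @param sim a `sweep_sim` from [simulate_sweep()].
#' @param cohort_decades named vector of per-decade sample counts (names are
#'   decade labels in ascending order of time).
#' @param seed RNG seed for the within-snapshot sampling.
#' @return The `sweep_sim` with `panel_sel` replaced by the cohort panel.
#' @export
assign_cohorts <- function(sim, cohort_decades, seed = 1L) {
  stopifnot(inherits(sim, "sweep_sim"))
  if (length(sim$snapshots) != length(cohort_decades))
    stop("simulation stored ", length(sim$snapshots),
         " snapshots but ", length(cohort_decades), " decades requested; ",
         "set cohort_decades in the config before simulating", call. = FALSE)
  n_avail <- vapply(sim$snapshots, function(h) nrow(h) / 2L, 0)
  if (any(cohort_decades > n_avail))
    stop("decade cohort larger than the simulated population (",
         max(cohort_decades), " > ", min(n_avail), ")", call. = FALSE)
  set.seed(seed)
  pieces <- vector("list", length(cohort_decades))
  for (k in seq_along(cohort_decades)) {
    hap <- sim$snapshots[[k]]
    pick <- sort(sample.int(nrow(hap) / 2L, cohort_decades[k]))
    rows <- as.vector(rbind(2L * pick - 1L, 2L * pick))
    pieces[[k]] <- hap[rows, , drop = FALSE]
  }
  hap <- do.call(rbind, pieces)
  panel <- panel_from_matrix(hap, sim$panel_sel$variants, "selected", "SEL")
  panel$samples$cohort_decade <-
    rep(as.integer(names(cohort_decades)), cohort_decades)
  sim$panel_sel <- panel
  sim$truth$freq_sel <- colMeans(panel$haplo)
  sim$truth$freq_by_decade <- vapply(
    split(seq_len(nrow(hap)),
          rep(as.integer(names(cohort_decades)), 2L * cohort_decades)),
    function(r) mean(hap[r, sim$truth$focal_index] ==
                       sim$truth$derived_code[sim$truth$focal_index]),
    0)
  sim
}

#' Default trait models for the breeding-objective traits
#'
#' Carcass weight (CWT, kg) carries the focal QTL and the strongest decadal
#' gain; eye muscle area (EMA, cm^2) and marbling score (MS) rise more gently;
#' backfat thickness (BFT, mm) drifts slightly downward. Reliability 0.8
#' matches high-accuracy progeny-test EBVs.
#'
#' @param focal_effect allele-substitution effect (trait units per derived
#'   copy) of the focal QTL on CWT.
#' @return Named list of per-trait models (`n_qtl`, `effect_sd`,
#'   `reliability`, `decade_gain`, `include_focal`, `focal_effect`,
#'   `noise_sd`).
#' @export
default_trait_model <- function(focal_effect = 8) {
  list(
    CWT = list(n_qtl = 50, effect_sd = 2.0, reliability = 0.8,
               decade_gain = 8, include_focal = TRUE,
               focal_effect = focal_effect, noise_sd = 5),
    EMA = list(n_qtl = 50, effect_sd = 0.6, reliability = 0.8,
               decade_gain = 2, include_focal = FALSE, focal_effect = 0,
               noise_sd = 2),
    BFT = list(n_qtl = 50, effect_sd = 0.12, reliability = 0.8,
               decade_gain = -0.3, include_focal = FALSE, focal_effect = 0,
               noise_sd = 0.5),
    MS = list(n_qtl = 50, effect_sd = 0.15, reliability = 0.8,
              decade_gain = 0.5, include_focal = FALSE, focal_effect = 0,
              noise_sd = 0.5)
  )
}

#' Attach EBV-like phenotypes to the selected panel
#'
#' True breeding value = sum of QTL effects times derived-allele dosage, plus
#' the per-decade polygenic gain; the EBV adds Gaussian noise scaled so that
#' `cor(EBV, TBV)^2` equals the configured reliability.
#'
#' @param sim a `sweep_sim`.
#' @param trait_model named list of trait models (see
#'   [default_trait_model()]); `NULL` uses the defaults.
#' @param seed RNG seed.
#' @return The `sweep_sim` with phenotype columns on `panel_sel$samples` and
#'   true breeding values in `truth$tbv`.
#' @export
simulate_ebv <- function(sim, trait_model = NULL, seed = 1L) {
  stopifnot(inherits(sim, "sweep_sim"))
  if (is.null(trait_model)) trait_model <- default_trait_model()
  set.seed(seed)
  panel <- sim$panel_sel
  dos <- dosage_matrix(panel, derived = TRUE)
  m <- ncol(dos)
  decade <- panel$samples$cohort_decade
  decade_rank <- if (all(is.na(decade))) rep(0L, nrow(dos)) else
    match(decade, sort(unique(decade))) - 1L
  tbv_all <- list()
  for (trait in names(trait_model)) {
    tm <- trait_model[[trait]]
    if (is.null(tm$reliability) || tm$reliability <= 0 || tm$reliability > 1)
      stop("reliability must be in (0, 1] for trait ", trait, call. = FALSE)
    qtl <- sort(sample.int(m, min(tm$n_qtl, m)))
    effects <- stats::rnorm(length(qtl), 0, tm$effect_sd)
    if (isTRUE(tm$include_focal)) {
      if (!(sim$truth$focal_index %in% qtl)) {
        qtl[1L] <- sim$truth$focal_index
        ord <- order(qtl); qtl <- qtl[ord]; effects <- effects[ord]
      }
      effects[qtl == sim$truth$focal_index] <- tm$focal_effect
    }
    tbv <- as.vector(dos[, qtl, drop = FALSE] %*% effects) +
      tm$decade_gain * decade_rank
    v <- stats::var(tbv)
    noise_var <- if (v > 0) v * (1 - tm$reliability) / tm$reliability
      else tm$noise_sd^2
    ebv <- if (tm$reliability == 1 && v > 0) tbv else
      tbv + stats::rnorm(length(tbv), 0, sqrt(noise_var))
    panel$samples[[trait]] <- ebv
    tbv_all[[trait]] <- tbv
  }
  sim$panel_sel <- panel
  sim$truth$tbv <- tbv_all
  sim$truth$trait_model <- trait_model
  sim
}
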