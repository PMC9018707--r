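# Small panel constructors and independent brute-force oracles used across
# the test files.

# wrap a 0/1 haplotype matrix (2 rows per sample) as a phased panel
make_panel <- function(haplo, pos_bp = NULL, chrom = "1", ancestral = "a",
                       population = "pop1", phased = TRUE) {
  haplo <- as.matrix(haplo)
  m <- ncol(haplo)
  if (is.null(pos_bp)) pos_bp <- seq_len(m) * 1000L
  variants <- tibble::tibble(
    chrom = rep(chrom, length.out = m),
    pos_bp = as.integer(pos_bp),
    id = sprintf("m%03d", seq_len(m)),
    allele_a = "A", allele_b = "G",
    ancestral = rep(ancestral, length.out = m)
  )
  n <- nrow(haplo) / 2L
  samples <- tibble::tibble(sample_id = sprintf("s%03d", seq_len(n)),
                            population = population)
  hap_panel(haplo, variants, samples, phased = phased)
}

random_panel <- function(n_hap, m, seed) {
  set.seed(seed)
  # condition every marker on being polymorphic-ish to exercise real paths
  haplo <- matrix(rbinom(n_hap * m, 1, runif(m, 0.2, 0.8)),
                  nrow = n_hap, byrow = TRUE)
  pos <- sort(sample.int(m * 5000L, m))
  make_panel(haplo, pos_bp = pos)
}

# brute-force EHH: probability that two random carriers of `allele` at `core`
# are identical at every marker between core and x (inclusive)
brute_ehh <- function(haplo, core, x, allele) {
  carriers <- which(haplo[, core] == allele)
  nc <- length(carriers)
  if (nc < 2) return(NA_real_)
  span <- min(core, x):max(core, x)
  pairs <- utils::combn(carriers, 2)
  hom <- apply(pairs, 2, function(pr)
    all(haplo[pr[1], span] == haplo[pr[2], span]))
  mean(hom)
}

# brute-force site EHH (Tang): unbiased homozygosity over the span divided by
# its value at the core
brute_ehhs <- function(haplo, core, x) {
  n <- nrow(haplo)
  hom <- function(span) {
    keys <- apply(haplo[, span, drop = FALSE], 1, paste, collapse = "")
    cnt <- table(keys)
    sum(cnt * (cnt - 1)) / (n * (n - 1))
  }
  hom(min(core, x):max(core, x)) / hom(core)
}

# brute-force HWE exact test: enumerate every heterozygote count compatible
# with the allele counts, weight by the conditional (hypergeometric-type)
# probability, and sum probabilities <= the observed one
brute_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nr <- 2 * min(n_aa, n_bb) + n_ab
  hets <- seq(nr %% 2, min(nr, 2 * n - nr), by = 2)
  logw <- vapply(hets, function(h) {
    hom_r <- (nr - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2)
  }, 0)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  obs <- w[match(n_ab, hets)]
  min(1, sum(w[w <= obs * (1 + 1e-12)]))
}
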