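# Generators for testable inputs: direct Ks samples from a peak mixture, and
# transcriptomes with paralog pairs planted at known synonymous depths.

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a Ks peak mixture
#'
#' Describes a mixture of Gaussian Ks peaks plus a uniform background, the
#' structure a paralog-age distribution takes when a transcriptome records a
#' burst of recent duplicates and several older duplication events. The
#' defaults emulate a seven-peak distribution with modes at 0.01, 0.022,
#' 0.05, 0.12, 0.27, 0.51 and 0.91, peak widths broadening with age, heavier
#' weight on the recent-duplicate excess near zero, and a 10% diffuse
#' background over `[0, ks_max]`.
#'
#' @param means Component means (Ks units).
#' @param sds Component standard deviations (> 0).
#' @param weights Component weights (must sum to 1).
#' @param background_fraction Fraction of draws from the uniform background.
#' @param ks_max Upper end of the background support.
#' @param n Sample size.
#' @param seed Integer seed.
#' @return List of class `ks_mixture_spec`.
#' @export
ks_mixture_spec <- function(means = c(0.01, 0.022, 0.05, 0.12, 0.27, 0.51, 0.91),
                            sds = c(0.005, 0.008, 0.015, 0.03, 0.05, 0.08, 0.12),
                            weights = c(0.25, 0.10, 0.10, 0.10, 0.20, 0.15, 0.10),
                            background_fraction = 0.10, ks_max = 1.5,
                            n = 4383L, seed = 1L) {
  if (length(means) != length(sds) || length(means) != length(weights)) {
    stop("means, sds and weights must have equal length")
  }
  if (any(sds <= 0)) stop("sds must be positive")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (background_fraction < 0 || background_fraction >= 1) {
    stop("background_fraction must be in [0, 1)")
  }
  structure(list(means = means, sds = sds, weights = weights,
                 background_fraction = background_fraction, ks_max = ks_max,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "ks_mixture_spec")
}

#' Draw a Ks sample from a peak-mixture specification
#'
#' Each draw comes from the uniform background with probability
#' `background_fraction` and otherwise from a mixture component; negative
#' mixture draws are resampled so the sample is non-negative. The same spec
#' (including seed) always yields the same sample.
#'
#' @param spec A [ks_mixture_spec()].
#' @return Numeric vector of length `spec$n`.
#' @export
sample_ks <- function(spec) {
  stopifnot(inherits(spec, "ks_mixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    from_bg <- runif(n) < spec$background_fraction
    out <- numeric(n)
    out[from_bg] <- runif(sum(from_bg), 0, spec$ks_max)
    n_mix <- sum(!from_bg)
    comp <- sample.int(length(spec$means), n_mix, replace = TRUE,
                       prob = spec$weights)
    draws <- rnorm(n_mix, spec$means[comp], spec$sds[comp])
    while (any(draws < 0)) {
      bad <- which(draws < 0)
      draws[bad] <- rnorm(length(bad), spec$means[comp[bad]],
                          spec$sds[comp[bad]])
    }
    out[!from_bg] <- draws
    out
  })
}

# per-codon single-base neighbour lists, split by effect
codon_neighbour_lists <- function() {
  if (!is.null(.ng_cache$neighbours)) return(.ng_cache$neighbours)
  syn <- list(); nonsyn <- list()
  for (codon in SENSE_CODONS) {
    nbs <- codon_neighbours(codon)
    sense <- nbs[!(nbs %in% STOP_CODONS)]
    aa <- GENETIC_CODE_1[[codon]]
    syn[[codon]] <- sense[GENETIC_CODE_1[sense] == aa]
    nonsyn[[codon]] <- sense[GENETIC_CODE_1[sense] != aa]
  }
  .ng_cache$neighbours <- list(syn = syn, nonsyn = nonsyn)
  .ng_cache$neighbours
}

# random stop-free CDS starting with ATG, as a codon vector
random_cds_codons <- function(n_codons) {
  body <- sample(setdiff(SENSE_CODONS, "ATG"), n_codons - 1L, replace = TRUE)
  c("ATG", body)
}

#' Simulate a transcriptome with paralog pairs planted at known Ks depths
#'
#' For every family and every depth an independent ancestral coding sequence
#' (stop-free, starting ATG) is duplicated into two copies. The copies are
#' then separated by planting substitutions until the pairwise synonymous
#' difference proportion matches the Jukes-Cantor inversion of the target
#' depth, `p_s = (3/4)(1 - exp(-4 d / 3))`; synonymous changes are placed
#' only where a single-base change is synonymous so Nei-Gojobori counting
#' sees them exactly, and nonsynonymous changes are added at relative rate
#' `omega`. Ancestors are independent across (family, depth) combinations,
#' so the only detectable paralogy is the planted one and the truth table is
#' exact.
#'
#' @param n_families Families per depth.
#' @param depths Target pairwise Ks depths (>= 0).
#' @param codons_per_gene Gene length in codons (>= 50).
#' @param omega Nonsynonymous changes per synonymous change (default 0.2).
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @return List with `records` (transcript data frame, two copies per pair)
#'   and `truth` (data frame: `family`, `id_a`, `id_b`, `planted_ks`,
#'   `realized_ps`, `realized_ks`, `length_codons`).
#' @export
simulate_duplicated_transcriptome <- function(n_families = 150L,
                                              depths = c(0.27, 0.51, 0.91),
                                              codons_per_gene = 500L,
                                              omega = 0.2, seed = 1L) {
  if (any(depths < 0)) stop("depths must be non-negative")
  if (codons_per_gene < 50L) stop("codons_per_gene must be at least 50")
  tb <- ng_tables()
  nbl <- codon_neighbour_lists()
  with_seed(seed, {
    recs <- list(); truth <- list(); row <- 0L
    for (di in seq_along(depths)) {
      d <- depths[di]
      ps_target <- 0.75 * (1 - exp(-4 * d / 3))
      if (ps_target >= 0.75) stop("unattainable under Jukes-Cantor")
      for (f in seq_len(n_families)) {
        anc <- random_cds_codons(codons_per_gene)
        S_anc <- sum(tb$syn_sites[anc])
        n_syn <- round(ps_target * S_anc)
        syn_ok <- which(lengths(nbl$syn[anc]) > 0L)
        nonsyn_ok <- setdiff(which(lengths(nbl$nonsyn[anc]) > 0L), 1L)
        if (n_syn > length(syn_ok)) stop("unattainable under Jukes-Cantor")
        copy <- anc
        if (n_syn > 0L) {
          at <- sample(syn_ok, n_syn)
          for (p in at) {
            opts <- nbl$syn[[anc[p]]]
            copy[p] <- opts[sample.int(length(opts), 1L)]
          }
        } else {
          at <- integer(0L)
        }
        n_nonsyn <- round(omega * n_syn)
        if (n_nonsyn > 0L) {
          pool <- setdiff(nonsyn_ok, at)
          at2 <- sample(pool, min(n_nonsyn, length(pool)))
          for (p in at2) {
            opts <- nbl$nonsyn[[anc[p]]]
            copy[p] <- opts[sample.int(length(opts), 1L)]
          }
        }
        # realized pairwise counts straight from the Nei-Gojobori tables
        S_pair <- sum((tb$syn_sites[anc] + tb$syn_sites[copy]) / 2)
        idx <- cbind(match(anc, SENSE_CODONS), match(copy, SENSE_CODONS))
        ps_real <- sum(tb$sd[idx]) / S_pair
        row <- row + 1L
        fam <- sprintf("fam%04d_d%d", f, di)
        id_a <- paste0(fam, "_a"); id_b <- paste0(fam, "_b")
        recs[[2L * row - 1L]] <- c(id_a, paste(anc, collapse = ""))
        recs[[2L * row]] <- c(id_b, paste(copy, collapse = ""))
        truth[[row]] <- data.frame(
          family = fam, id_a = id_a, id_b = id_b, planted_ks = d,
          realized_ps = ps_real, realized_ks = jc_correct(ps_real),
          length_codons = codons_per_gene, stringsAsFactors = FALSE)
      }
    }
    records <- data.frame(
      id = vapply(recs, `[[`, character(1L), 1L),
      seq = vapply(recs, `[[`, character(1L), 2L),
      desc = "", stringsAsFactors = FALSE)
    list(records = records,
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}
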