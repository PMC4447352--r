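# Nei-Gojobori machinery: per-codon synonymous site fractions and pairwise
# synonymous/nonsynonymous difference counts averaged over mutational
# pathways. Tables over the 61 sense codons are built once per session.

.ng_cache <- new.env(parent = emptyenv())

# All 9 single-base neighbours of a codon.
codon_neighbours <- function(codon) {
  bases <- c("A", "C", "G", "T")
  out <- character(0L)
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      nb <- codon
      substr(nb, pos, pos) <- b
      out <- c(out, nb)
    }
  }
  out
}

# Synonymous site count of one codon: sum over positions of the fraction of
# the 3 possible changes that preserve the amino acid. Changes to stop codons
# count as nonsynonymous.
codon_syn_sites <- function(codon) {
  aa <- GENETIC_CODE_1[[codon]]
  nbs <- codon_neighbours(codon)
  sum(GENETIC_CODE_1[nbs] == aa) / 3
}

# Synonymous/nonsynonymous differences between two sense codons, averaged
# over all orderings of the differing positions; pathways passing through a
# stop codon are discarded (all-blocked pairs fall back to every pathway).
codon_pair_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- permutations_of(pos)
  step_counts <- function(order_, allow_stops) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in order_) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stops && nxt %in% STOP_CODONS) return(NULL)
      if (GENETIC_CODE_1[[cur]] == GENETIC_CODE_1[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- lapply(perms, step_counts, allow_stops = FALSE)
  res <- res[!vapply(res, is.null, logical(1L))]
  if (length(res) == 0L) res <- lapply(perms, step_counts, allow_stops = TRUE)
  colMeans(do.call(rbind, res))
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

# Lazy lookup tables: syn-site vector (length 61) and 61x61 sd/nd matrices.
ng_tables <- function() {
  if (!is.null(.ng_cache$tables)) return(.ng_cache$tables)
  codons <- SENSE_CODONS
  syn_sites <- vapply(codons, codon_syn_sites, numeric(1L))
  n <- length(codons)
  sd_mat <- matrix(0, n, n, dimnames = list(codons, codons))
  nd_mat <- sd_mat
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      dd <- codon_pair_diffs(codons[i], codons[j])
      sd_mat[i, j] <- sd_mat[j, i] <- dd[["sd"]]
      nd_mat[i, j] <- nd_mat[j, i] <- dd[["nd"]]
    }
  }
  .ng_cache$tables <- list(syn_sites = syn_sites, sd = sd_mat, nd = nd_mat)
  .ng_cache$tables
}
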