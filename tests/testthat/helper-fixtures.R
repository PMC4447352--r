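# shared fixture builders (all generated in code, seeded by the caller)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# stop-free random CDS starting ATG, length in codons
random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  codons[1] <- "ATG"
  for (i in 2:n_codons) {
    repeat {
      cd <- random_dna(3)
      if (!cd %in% stops) break
    }
    codons[i] <- cd
  }
  paste(codons, collapse = "")
}

# copy of a sequence with point substitutions at a given per-base rate
mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

records_df <- function(ids, seqs) {
  data.frame(id = ids, seq = seqs, desc = "", stringsAsFactors = FALSE)
}

tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  write_fasta(records, path)
  path
}

# independent oracle: Nei-Gojobori counts for ONE codon pair by explicit
# recursive pathway enumeration (distinct code path from the package tables)
oracle_codon_pair <- function(c1, c2) {
  code <- ksdup:::GENETIC_CODE_1
  stops <- names(code)[code == "*"]
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  walk <- function(cur, remaining, allow_stop) {
    if (length(remaining) == 0) return(list(c(s = 0, n = 0)))
    out <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && nxt %in% stops) next
      step <- if (code[[cur]] == code[[nxt]]) c(s = 1, n = 0) else c(s = 0, n = 1)
      for (tail in walk(nxt, setdiff(remaining, p), allow_stop)) {
        out[[length(out) + 1]] <- step + tail
      }
    }
    out
  }
  paths <- walk(c1, diff_pos, allow_stop = FALSE)
  if (length(paths) == 0) paths <- walk(c1, diff_pos, allow_stop = TRUE)
  avg <- Reduce(`+`, paths) / length(paths)
  # site fractions: per position, fraction of the 3 changes that are
  # synonymous, averaged over the two codons
  syn_sites_of <- function(cd) {
    tot <- 0
    for (p in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(cd, p, p))) {
        alt <- cd
        substr(alt, p, p) <- b
        if (code[[alt]] == code[[cd]]) tot <- tot + 1 / 3
      }
    }
    tot
  }
  S <- (syn_sites_of(c1) + syn_sites_of(c2)) / 2
  c(S = S, N = 3 - S, Sd = unname(avg["s"]), Nd = unname(avg["n"]))
}

# package-side counts for one codon pair via the public operation
pkg_codon_pair <- function(c1, c2) {
  cnt <- ng_site_counts(list(aligned_a = c1, aligned_b = c2))
  c(S = cnt$S, N = cnt$N_sites, Sd = cnt$Sd, Nd = cnt$Nd)
}

# exact local-alignment oracle via Biostrings (independent implementation)
oracle_local_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = 5, gap_ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_ext,
                                      type = "local")
  Biostrings::score(pa)
}

# brute-force mutual-edge scan over a directed hit list
oracle_reciprocal_pairs <- function(hits, max_evalue) {
  keep <- hits[hits$evalue <= max_evalue & hits$query_id != hits$subject_id, ]
  found <- character(0)
  for (i in seq_len(nrow(keep))) {
    q <- keep$query_id[i]; s <- keep$subject_id[i]
    back <- any(keep$query_id == s & keep$subject_id == q)
    if (back) found <- c(found, paste(min(q, s), max(q, s), sep = "|"))
  }
  sort(unique(found))
}
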