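#' Locate the longest open reading frame across six frames
#'
#' Scans all three frames of the forward strand and of the reverse complement
#' for the longest run of stop-free codons and returns the corresponding
#' in-frame nucleotide subsequence. Ties are broken toward the forward strand,
#' then the lowest frame. Transcriptome assemblies are unoriented, so both
#' strands must be considered.
#'
#' @param seq Nucleotide string.
#' @param min_codons Minimum ORF length in codons (default 30).
#' @return List with `orf` (in-frame nucleotide string), `strand` (`"+"` or
#'   `"-"`) and `frame` (0, 1 or 2).
#' @export
find_orf <- function(seq, min_codons = 30L) {
  s_fwd <- toupper(seq)
  s_rev <- revcomp(s_fwd)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") s_fwd else s_rev
    for (frame in 0:2) {
      n_codons <- (nchar(s) - frame) %/% 3L
      if (n_codons < 1L) next
      starts <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
      codons <- substring(s, starts, starts + 2L)
      is_stop <- codons %in% STOP_CODONS
      runs <- rle(is_stop)
      ends <- cumsum(runs$lengths)
      begins <- ends - runs$lengths + 1L
      open <- which(!runs$values)
      if (length(open) == 0L) next
      len <- runs$lengths[open]
      k <- open[which.max(len)]
      run_len <- runs$lengths[k]
      if (is.null(best) || run_len > best$len) {
        orf <- substr(s, starts[begins[k]], starts[ends[k]] + 2L)
        best <- list(orf = orf, strand = strand, frame = frame, len = run_len)
      }
    }
  }
  if (is.null(best) || best$len < min_codons) stop("no usable ORF")
  best[c("orf", "strand", "frame")]
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1L]]), collapse = ""),
                character(1L), USE.NAMES = FALSE))
}

#' Protein-guided pairwise codon alignment
#'
#' Each coding sequence is first trimmed to its longest open reading frame
#' (six-frame scan), the two translations are aligned globally under a
#' BLOSUM62 substitution matrix with affine gap costs, and the protein
#' alignment is back-mapped to nucleotides so that every residue gap becomes
#' a 3-nt gap. This keeps the downstream site counting in frame.
#'
#' @param cds_a,cds_b Nucleotide sequences (need not be pre-oriented).
#' @param min_codons Minimum usable ORF length in codons.
#' @return List of class `codon_alignment` with `aligned_a`, `aligned_b`
#'   (equal-length gapped nucleotide strings) and `n_codon_columns` (gap-free,
#'   N-free, stop-free codon columns).
#' @export
protein_guided_codon_align <- function(cds_a, cds_b, min_codons = 30L) {
  orf_a <- find_orf(cds_a, min_codons)$orf
  orf_b <- find_orf(cds_b, min_codons)$orf
  prot_a <- translate_nt(orf_a)
  prot_b <- translate_nt(orf_b)
  if (grepl("\\*", substr(prot_a, 1L, nchar(prot_a) - 1L)) ||
      grepl("\\*", substr(prot_b, 1L, nchar(prot_b) - 1L))) {
    stop("internal stop codon within chosen ORF")
  }
  al <- cpp_codon_align(prot_a, prot_b, orf_a, orf_b, get_blosum62(),
                        10, 0.5)
  structure(list(aligned_a = al$aligned_a, aligned_b = al$aligned_b,
                 n_codon_columns = count_clean_columns(al$aligned_a,
                                                       al$aligned_b)),
            class = "codon_alignment")
}

get_blosum62 <- function() {
  if (is.null(.ng_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .ng_cache$blosum62 <- e$BLOSUM62
  }
  .ng_cache$blosum62
}

count_clean_columns <- function(nt_a, nt_b) {
  ca <- codon_split(nt_a)
  cb <- codon_split(nt_b)
  sum(clean_codon_mask(ca, cb))
}

codon_split <- function(s) {
  n <- nchar(s) %/% 3L
  substring(s, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
}

clean_codon_mask <- function(ca, cb) {
  !grepl("[-N]", ca) & !grepl("[-N]", cb) &
    !(ca %in% STOP_CODONS) & !(cb %in% STOP_CODONS)
}

#' Nei-Gojobori site and difference counts for a codon alignment
#'
#' Counts synonymous and nonsynonymous sites and differences over the
#' gap-free, N-free, stop-free codon columns of a codon alignment. Sites are
#' the pathway-unweighted Nei-Gojobori fractions (per codon, each position
#' contributes the fraction of its three possible changes that are
#' synonymous, averaged over the two sequences); differences between codons
#' differing at d positions are averaged over all d! single-step pathways,
#' discarding pathways through stop codons.
#'
#' @param aln A `codon_alignment` (or list with `aligned_a`, `aligned_b`).
#' @return Named list `S`, `N_sites`, `Sd`, `Nd`.
#' @export
ng_site_counts <- function(aln) {
  ca <- codon_split(aln$aligned_a)
  cb <- codon_split(aln$aligned_b)
  keep <- clean_codon_mask(ca, cb)
  if (!any(keep)) stop("too_few_sites: no countable codon columns")
  ca <- ca[keep]; cb <- cb[keep]
  tb <- ng_tables()
  S <- sum((tb$syn_sites[ca] + tb$syn_sites[cb]) / 2)
  N_sites <- 3 * length(ca) - S
  idx <- cbind(match(ca, SENSE_CODONS), match(cb, SENSE_CODONS))
  Sd <- sum(tb$sd[idx])
  Nd <- sum(tb$nd[idx])
  list(S = S, N_sites = N_sites, Sd = Sd, Nd = Nd)
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`. Proportions at or beyond the model's
#' saturation point (p >= 3/4) are not correctable and return `NA` (callers
#' report them as saturated).
#'
#' @param p Observed difference proportion in `[0, 1]`.
#' @return Corrected distance, or `NA_real_` when saturated.
#' @export
jc_correct <- function(p) {
  stopifnot(is.numeric(p), p >= 0, p <= 1)
  ifelse(p < 0.75, -0.75 * log(1 - (4 / 3) * p), NA_real_)
}

#' Estimate pairwise synonymous divergence (Ks) for two coding sequences
#'
#' Composes ORF detection, protein-guided codon alignment, Nei-Gojobori
#' counting and Jukes-Cantor correction. Pairs whose synonymous difference
#' proportion reaches the Jukes-Cantor saturation point (ps >= 3/4) are
#' rejected as too divergent, and pairs with fewer than `min_sites`
#' synonymous sites are rejected as uninformative.
#'
#' @param cds_a,cds_b Nucleotide coding sequences.
#' @param min_sites Minimum synonymous sites required (default 10).
#' @param min_codons Minimum ORF length in codons.
#' @return List of class `ks_result` with fields `S`, `N_sites`, `Sd`, `Nd`,
#'   `ps`, `ks` (`NA` when rejected) and `reject_reason` (one of `"none"`,
#'   `"saturated"`, `"too_few_sites"`).
#' @export
estimate_ks <- function(cds_a, cds_b, min_sites = 10, min_codons = 30L) {
  aln <- protein_guided_codon_align(cds_a, cds_b, min_codons = min_codons)
  ks_from_codon_alignment(aln, min_sites)
}

# shared composition step: codon alignment -> KsResult
ks_from_codon_alignment <- function(aln, min_sites) {
  counts <- tryCatch(ng_site_counts(aln), error = function(e) NULL)
  if (is.null(counts)) {
    return(ks_result(S = 0, N_sites = 0, Sd = 0, Nd = 0, ps = NA_real_,
                     ks = NA_real_, reject_reason = "too_few_sites"))
  }
  ps <- counts$Sd / counts$S
  if (counts$S < min_sites) {
    return(ks_result(counts$S, counts$N_sites, counts$Sd, counts$Nd, ps,
                     NA_real_, "too_few_sites"))
  }
  ks <- jc_correct(ps)
  if (is.na(ks)) {
    return(ks_result(counts$S, counts$N_sites, counts$Sd, counts$Nd, ps,
                     NA_real_, "saturated"))
  }
  ks_result(counts$S, counts$N_sites, counts$Sd, counts$Nd, ps, ks, "none")
}

ks_result <- function(S, N_sites, Sd, Nd, ps, ks, reject_reason) {
  structure(list(S = S, N_sites = N_sites, Sd = Sd, Nd = Nd, ps = ps,
                 ks = ks, reject_reason = reject_reason),
            class = "ks_result")
}

#' Per-pair Ks table for a set of paralog pairs
#'
#' Applies [estimate_ks()] to every pair and returns one row per pair with
#' counts, `ps`, `ks` and a `status` column (`"ok"` or the rejection reason).
#' Pairs supplied with `strand == "-"` are rejected up front as antisense
#' artifacts (codon alignment requires sense-strand CDS on both sides).
#'
#' @param records Transcript set (as from [read_fasta()]).
#' @param pairs Data frame with columns `id_a`, `id_b` and optionally
#'   `strand`.
#' @param min_sites,min_codons Passed to [estimate_ks()].
#' @return Data frame: `id_a`, `id_b`, `S`, `N_sites`, `Sd`, `Nd`, `ps`,
#'   `ks`, `status`.
#' @export
ks_table <- function(records, pairs, min_sites = 10, min_codons = 30L) {
  validate_records(records)
  seqs <- setNames(records$seq, records$id)
  n <- nrow(pairs)
  if (n == 0L) {
    return(data.frame(id_a = character(), id_b = character(), S = numeric(),
                      N_sites = numeric(), Sd = numeric(), Nd = numeric(),
                      ps = numeric(), ks = numeric(), status = character(),
                      stringsAsFactors = FALSE))
  }
  antisense <- if (is.null(pairs$strand)) rep(FALSE, n) else
    !is.na(pairs$strand) & pairs$strand == "-"
  # ORFs and translations once per transcript, not once per pair
  need <- unique(c(pairs$id_a[!antisense], pairs$id_b[!antisense]))
  orfs <- lapply(setNames(need, need), function(id)
    tryCatch(find_orf(seqs[[id]], min_codons)$orf, error = function(e) NULL))
  prots <- lapply(orfs, function(o) if (is.null(o)) NULL else translate_nt(o))
  ok_orf <- !vapply(orfs, is.null, logical(1L))
  alignable <- !antisense &
    ok_orf[match(pairs$id_a, need)] & ok_orf[match(pairs$id_b, need)]
  alignable[is.na(alignable)] <- FALSE
  results <- vector("list", n)
  if (any(alignable)) {
    blosum <- get_blosum62()
    for (i in which(alignable)) {
      ia <- pairs$id_a[i]; ib <- pairs$id_b[i]
      al <- cpp_codon_align(prots[[ia]], prots[[ib]], orfs[[ia]], orfs[[ib]],
                            blosum, 10, 0.5)
      aln <- list(aligned_a = al$aligned_a, aligned_b = al$aligned_b)
      results[[i]] <- ks_from_codon_alignment(aln, min_sites)
    }
  }
  for (i in which(!alignable)) {
    reason <- if (antisense[i]) "antisense" else "no_orf"
    results[[i]] <- list(S = NA_real_, N_sites = NA_real_, Sd = NA_real_,
                         Nd = NA_real_, ps = NA_real_, ks = NA_real_,
                         reject_reason = reason)
  }
  data.frame(
    id_a = pairs$id_a, id_b = pairs$id_b,
    S = vapply(results, function(r) r$S, numeric(1L)),
    N_sites = vapply(results, function(r) r$N_sites, numeric(1L)),
    Sd = vapply(results, function(r) r$Sd, numeric(1L)),
    Nd = vapply(results, function(r) r$Nd, numeric(1L)),
    ps = vapply(results, function(r) r$ps, numeric(1L)),
    ks = vapply(results, function(r) r$ks, numeric(1L)),
    status = vapply(results, function(r)
      if (r$reject_reason == "none") "ok" else r$reject_reason,
      character(1L)),
    stringsAsFactors = FALSE)
}
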