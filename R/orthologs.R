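#' Three-way reciprocal-best-hit ortholog triples
#'
#' A triple (a, b, c), one transcript per sample, is reported when each of
#' the three cross-sample relations a-b, b-c and a-c is a reciprocal BEST
#' hit at the e-value ceiling: each member is the other's top-scoring match
#' (lowest e-value, ties broken by bitscore) in both directions.
#'
#' @param set_a,set_b,set_c Transcript sets (as from [read_fasta()]).
#' @param max_evalue E-value ceiling.
#' @param ... Passed to [cross_hits()].
#' @return Data frame with `id_a`, `id_b`, `id_c` and the three pairwise
#'   best e-values; zero rows when no consistent triple exists.
#' @export
three_way_rbh <- function(set_a, set_b, set_c, max_evalue = 1e-20, ...) {
  rbh_ab <- rbh_map(set_a, set_b, max_evalue, ...)
  rbh_bc <- rbh_map(set_b, set_c, max_evalue, ...)
  rbh_ac <- rbh_map(set_a, set_c, max_evalue, ...)
  out <- list()
  for (i in seq_len(nrow(rbh_ab))) {
    a <- rbh_ab$id_x[i]; b <- rbh_ab$id_y[i]
    c_from_b <- rbh_bc$id_y[match(b, rbh_bc$id_x)]
    c_from_a <- rbh_ac$id_y[match(a, rbh_ac$id_x)]
    if (is.na(c_from_b) || is.na(c_from_a) || c_from_b != c_from_a) next
    out[[length(out) + 1L]] <- data.frame(
      id_a = a, id_b = b, id_c = c_from_a,
      evalue_ab = rbh_ab$evalue[i],
      evalue_bc = rbh_bc$evalue[match(b, rbh_bc$id_x)],
      evalue_ac = rbh_ac$evalue[match(a, rbh_ac$id_x)],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(id_a = character(), id_b = character(),
                      id_c = character(), evalue_ab = numeric(),
                      evalue_bc = numeric(), evalue_ac = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# reciprocal best hits between two sets: one row per mutual best pair
rbh_map <- function(set_x, set_y, max_evalue, ...) {
  fwd <- cross_hits(set_x, set_y, max_evalue = max_evalue, ...)
  rev <- cross_hits(set_y, set_x, max_evalue = max_evalue, ...)
  bx <- best_hit_per_query(fwd)
  by <- best_hit_per_query(rev)
  keep <- !is.na(by$subject_id[match(bx$subject_id, by$query_id)]) &
    by$subject_id[match(bx$subject_id, by$query_id)] == bx$query_id
  keep[is.na(keep)] <- FALSE
  data.frame(id_x = bx$query_id[keep], id_y = bx$subject_id[keep],
             evalue = bx$evalue[keep], stringsAsFactors = FALSE)
}

best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  h <- hits[order(hits$query_id, hits$evalue, -hits$bitscore), , drop = FALSE]
  h[!duplicated(h$query_id), c("query_id", "subject_id", "evalue")]
}

#' Majority-vote consensus of a gapped alignment
#'
#' Per column, the most frequent symbol wins, counting the gap as a symbol;
#' ties are broken by the fixed order A < C < G < T < gap (then any other
#' symbol), which makes the consensus independent of sequence order.
#'
#' @param aligned Character vector of equal-length gapped sequences (>= 2).
#' @return The consensus string.
#' @export
consensus_majority <- function(aligned) {
  if (length(aligned) < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(aligned))) != 1L) {
    stop("aligned sequences must have equal length")
  }
  mat <- do.call(rbind, strsplit(toupper(aligned), ""))
  prio <- c(A = 1, C = 2, G = 3, T = 4, "-" = 5, N = 6)
  cons <- apply(mat, 2L, function(col) {
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    top[order(ifelse(is.na(prio[top]), 99, prio[top]))][1L]
  })
  paste(cons, collapse = "")
}

#' Merge three sequences into one alignment anchored on the first
#'
#' Pairwise global nucleotide alignments of the second and third sequences
#' against the anchor are merged on the anchor's coordinates: insertion
#' columns relative to the anchor from either alignment become columns with
#' gaps in the other two rows. This anchor-merge construction is exact when
#' indels are rare and keeps the result reproducible, unlike interactive
#' multiple aligners.
#'
#' @param seqs Named character vector of 3 nucleotide sequences; the first
#'   is the anchor.
#' @return Named character vector of 3 equal-length gapped sequences.
#' @export
align_triple <- function(seqs) {
  stopifnot(length(seqs) == 3L)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                  baseOnly = FALSE)
  align_to_anchor <- function(anchor, other) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(anchor), Biostrings::DNAString(other),
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 1,
      type = "global")
    list(a = strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]],
         o = strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]])
  }
  al1 <- align_to_anchor(seqs[[1L]], seqs[[2L]])
  al2 <- align_to_anchor(seqs[[1L]], seqs[[3L]])
  n_anchor <- nchar(seqs[[1L]])
  idx1 <- which(al1$a != "-"); idx2 <- which(al2$a != "-")
  out_a <- character(0L); out_b <- character(0L); out_c <- character(0L)
  pos1 <- 1L; pos2 <- 1L
  emit <- function(a, b, c) {
    out_a <<- c(out_a, a); out_b <<- c(out_b, b); out_c <<- c(out_c, c)
  }
  for (i in seq_len(n_anchor + 1L)) {
    # insertions (gap in anchor) preceding anchor position i
    stop1 <- if (i <= n_anchor) idx1[i] else length(al1$a) + 1L
    while (pos1 < stop1) {
      if (al1$a[pos1] == "-") emit("-", al1$o[pos1], "-")
      pos1 <- pos1 + 1L
    }
    stop2 <- if (i <= n_anchor) idx2[i] else length(al2$a) + 1L
    while (pos2 < stop2) {
      if (al2$a[pos2] == "-") emit("-", "-", al2$o[pos2])
      pos2 <- pos2 + 1L
    }
    if (i <= n_anchor) {
      emit(al1$a[idx1[i]], al1$o[idx1[i]], al2$o[idx2[i]])
      pos1 <- idx1[i] + 1L
      pos2 <- idx2[i] + 1L
    }
  }
  out <- c(paste(out_a, collapse = ""), paste(out_b, collapse = ""),
           paste(out_c, collapse = ""))
  names(out) <- names(seqs)
  out
}

#' SNP and deletion report for an aligned ortholog group
#'
#' Compares every sequence of a gapped alignment against the majority-vote
#' consensus. A SNP is a column where the sequence's base differs from the
#' consensus base and neither is a gap; each SNP is classified synonymous or
#' nonsynonymous by substituting the observed base into the consensus codon
#' (framing anchored on `frame_anchor`'s first aligned base). Deletions are
#' maximal runs of gap columns in a sequence opposite consensus bases,
#' flagged in-frame when their length is divisible by 3. When `pair` names
#' two sequences, nonsynonymous SNP columns where both carry the same
#' variant base are counted as shared, the rest as unique per sequence.
#'
#' @param aligned Named character vector of equal-length gapped sequences.
#' @param frame_anchor Name of the sequence whose first aligned base defines
#'   codon position 0.
#' @param pair Optional names of two sequences for the shared/unique
#'   nonsynonymous breakdown.
#' @return List of class `variant_report`: `consensus`, `snp_counts` (named
#'   integer vector), `variants` (data frame: `seq_id`, `column`,
#'   `consensus_base`, `observed_base`, `codon_index`, `class`), `deletions`
#'   (data frame: `seq_id`, `column`, `length_nt`, `in_frame`,
#'   `length_codons`), and when `pair` is given `shared_nonsyn`,
#'   `unique_nonsyn`.
#' @export
variant_report <- function(aligned, frame_anchor = names(aligned)[1L],
                           pair = NULL) {
  if (is.null(names(aligned)) || any(!nzchar(names(aligned)))) {
    stop("aligned sequences must be named")
  }
  if (!frame_anchor %in% names(aligned)) {
    stop("frame_anchor '", frame_anchor, "' not found in alignment")
  }
  cons <- consensus_majority(aligned)
  cons_chars <- strsplit(cons, "")[[1L]]
  ncol_aln <- length(cons_chars)
  # consensus-coordinate of every column (NA at consensus-gap columns)
  cons_pos <- cumsum(cons_chars != "-")
  cons_pos[cons_chars == "-"] <- NA_integer_
  # frame offset: consensus position of the anchor's first aligned base
  anchor_chars <- strsplit(aligned[[frame_anchor]], "")[[1L]]
  first_col <- which(anchor_chars != "-")[1L]
  offset <- cons_pos[first_col]
  if (is.na(offset)) offset <- min(cons_pos[!is.na(cons_pos) &
                                              seq_len(ncol_aln) >= first_col])
  cons_seq <- gsub("-", "", cons)
  codon_of <- function(cp) (cp - offset) %/% 3L  # 0-based codon index
  classify <- function(cp, base) {
    ci <- codon_of(cp)
    if (is.na(ci) || ci < 0L) return(NA_character_)
    start <- offset + 3L * ci
    codon <- substr(cons_seq, start, start + 2L)
    if (nchar(codon) < 3L || grepl("[^ACGT]", codon)) return(NA_character_)
    variant <- codon
    substr(variant, cp - start + 1L, cp - start + 1L) <- base
    if (grepl("[^ACGT]", variant)) return(NA_character_)
    if (GENETIC_CODE_1[[codon]] == GENETIC_CODE_1[[variant]])
      "synonymous" else "nonsynonymous"
  }
  variants <- list(); deletions <- list()
  for (sid in names(aligned)) {
    chars <- strsplit(aligned[[sid]], "")[[1L]]
    is_snp <- chars != cons_chars & chars != "-" & cons_chars != "-"
    for (col in which(is_snp)) {
      variants[[length(variants) + 1L]] <- data.frame(
        seq_id = sid, column = col, consensus_base = cons_chars[col],
        observed_base = chars[col], codon_index = codon_of(cons_pos[col]),
        class = classify(cons_pos[col], chars[col]),
        stringsAsFactors = FALSE)
    }
    # deletion runs: gap in sequence opposite consensus base
    del <- chars == "-" & cons_chars != "-"
    runs <- rle(del)
    ends <- cumsum(runs$lengths)
    for (k in which(runs$values)) {
      len <- runs$lengths[k]
      deletions[[length(deletions) + 1L]] <- data.frame(
        seq_id = sid, column = ends[k] - len + 1L, length_nt = len,
        in_frame = len %% 3L == 0L,
        length_codons = if (len %% 3L == 0L) len %/% 3L else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(variants) > 0L) {
    do.call(rbind, c(variants, list(make.row.names = FALSE)))
  } else {
    data.frame(seq_id = character(), column = integer(),
               consensus_base = character(), observed_base = character(),
               codon_index = integer(), class = character(),
               stringsAsFactors = FALSE)
  }
  deletions <- if (length(deletions) > 0L) {
    do.call(rbind, c(deletions, list(make.row.names = FALSE)))
  } else {
    data.frame(seq_id = character(), column = integer(),
               length_nt = integer(), in_frame = logical(),
               length_codons = integer(), stringsAsFactors = FALSE)
  }
  snp_counts <- vapply(names(aligned), function(sid)
    sum(variants$seq_id == sid), integer(1L))
  out <- list(consensus = cons, snp_counts = snp_counts, variants = variants,
              deletions = deletions)
  if (!is.null(pair)) {
    stopifnot(length(pair) == 2L, all(pair %in% names(aligned)))
    ns <- variants[!is.na(variants$class) &
                     variants$class == "nonsynonymous", , drop = FALSE]
    v1 <- ns[ns$seq_id == pair[1L], ]
    v2 <- ns[ns$seq_id == pair[2L], ]
    key1 <- paste(v1$column, v1$observed_base)
    key2 <- paste(v2$column, v2$observed_base)
    shared <- length(intersect(key1, key2))
    out$shared_nonsyn <- shared
    out$unique_nonsyn <- setNames(
      c(length(key1) - shared, length(key2) - shared), pair)
  }
  structure(out, class = "variant_report")
}

#' @export
print.variant_report <- function(x, ...) {
  cat("Variant report vs majority consensus\n")
  cat("SNP counts:\n")
  print(x$snp_counts)
  if (nrow(x$deletions) > 0L) {
    cat("Deletions:\n")
    print(x$deletions)
  }
  if (!is.null(x$shared_nonsyn)) {
    cat(sprintf("Shared nonsynonymous: %d\n", x$shared_nonsyn))
  }
  invisible(x)
}
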