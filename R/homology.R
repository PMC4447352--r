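#' All-vs-all nucleotide similarity search within a transcript set
#'
#' Built-in seed-and-extend search: every ordered pair of distinct
#' transcripts sharing an exact `word_size` nucleotide word is a candidate;
#' candidates whose best ungapped X-drop extension reaches a trigger score
#' are aligned with an exact affine-gap local alignment, and alignments are
#' converted to e-values by the Karlin-Altschul formula
#' `E = K * m * n * exp(-lambda * S)` with `n` the total residue count of the
#' set. Self-hits are suppressed, and the reverse complement of every subject
#' is also searched so antisense matches are detected (reported with
#' `strand == "-"`).
#'
#' Default scoring is match +1, mismatch -2, gap of length L costing
#' `5 + 2 L`, with the published Karlin-Altschul parameters for these scores
#' (`lambda` 1.28, `K` 0.46).
#'
#' @param records Transcript set (as from [read_fasta()]); at least 2 rows.
#' @param max_evalue Maximum e-value to report (default `1e-20`, the
#'   paralog-screen ceiling used downstream).
#' @param word_size Exact-match seed length (default 11).
#' @param match,mismatch,gap_open,gap_ext Alignment scores.
#' @param lambda,K Karlin-Altschul parameters for the scoring scheme.
#' @param x_drop X-drop for the ungapped pre-filter extension.
#' @param trigger_score Ungapped score required before the full gapped
#'   alignment is computed.
#' @param band_pad Diagonal padding around the pair's seed diagonals for the
#'   banded gapped alignment; the band always contains every seed diagonal.
#' @param search_rc Also search reverse-complemented subjects.
#' @return Data frame of directed hits: `query_id`, `subject_id`, `evalue`,
#'   `bitscore`, `identity`, `q_start`, `q_end`, `s_start`, `s_end` (0-based
#'   half-open, forward-strand coordinates), `aligned_length`, `score`,
#'   `strand`.
#' @export
all_vs_all_hits <- function(records, max_evalue = 1e-20, word_size = 11L,
                            match = 1, mismatch = -2, gap_open = 5,
                            gap_ext = 2, lambda = 1.28, K = 0.46,
                            x_drop = 20, trigger_score = 25,
                            search_rc = TRUE, band_pad = 64L) {
  validate_records(records, min_n = 2L)
  if (word_size < 4L) stop("word_size must be at least 4")
  raw <- cpp_similarity_search(records$seq, records$seq, TRUE,
                               as.integer(word_size), max_evalue,
                               match, mismatch, gap_open, gap_ext,
                               lambda, K, x_drop, trigger_score, search_rc,
                               as.integer(band_pad))
  finish_hits(raw, records$id, records$id)
}

#' Similarity search of one transcript set against another
#'
#' Same engine as [all_vs_all_hits()] but with distinct query and subject
#' sets (used for cross-sample ortholog detection). Hits are directed
#' query -> subject only; call twice with the sets swapped for reciprocal
#' analysis.
#'
#' @inheritParams all_vs_all_hits
#' @param query,subject Transcript sets.
#' @return Data frame of directed hits (see [all_vs_all_hits()]).
#' @export
cross_hits <- function(query, subject, max_evalue = 1e-20, word_size = 11L,
                       match = 1, mismatch = -2, gap_open = 5, gap_ext = 2,
                       lambda = 1.28, K = 0.46, x_drop = 20,
                       trigger_score = 25, search_rc = TRUE,
                       band_pad = 64L) {
  validate_records(query)
  validate_records(subject)
  raw <- cpp_similarity_search(query$seq, subject$seq, FALSE,
                               as.integer(word_size), max_evalue,
                               match, mismatch, gap_open, gap_ext,
                               lambda, K, x_drop, trigger_score, search_rc,
                               as.integer(band_pad))
  finish_hits(raw, query$id, subject$id)
}

finish_hits <- function(raw, query_ids, subject_ids) {
  out <- data.frame(
    query_id = query_ids[raw$q_idx],
    subject_id = subject_ids[raw$s_idx],
    evalue = raw$evalue, bitscore = raw$bitscore, identity = raw$identity,
    q_start = raw$q_start, q_end = raw$q_end,
    s_start = raw$s_start, s_end = raw$s_end,
    aligned_length = raw$aligned_length, score = raw$score,
    strand = ifelse(raw$strand == 0L, "+", "-"),
    stringsAsFactors = FALSE)
  out[order(out$query_id, out$evalue, -out$bitscore), , drop = FALSE]
}

#' Read similarity hits from 12-column tabular format
#'
#' Parses the de facto standard 12-column tab-separated hit format (qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore; 1-based inclusive coordinates). Coordinates are
#' converted to 0-based half-open; subject spans with `sstart > send`
#' (minus-strand matches) are normalised to forward coordinates with
#' `strand == "-"`.
#'
#' @param path Path to the tabular file.
#' @return Data frame of hits in the same layout as [all_vs_all_hits()]
#'   (without `score`).
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(empty_hits())
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != 12L)
  if (length(bad) > 0L) {
    stop(sprintf("expected 12 tab-separated columns but found %d at line %d",
                 nf[bad[[1L]]], bad[[1L]]))
  }
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- tryCatch(
    read.table(path, sep = "\t", quote = "", comment.char = "",
               col.names = cols,
               colClasses = c("character", "character", rep("numeric", 10L))),
    error = function(e) stop("unparsable numeric field: ", conditionMessage(e)))
  minus <- df$sstart > df$send
  s_lo <- ifelse(minus, df$send, df$sstart)
  s_hi <- ifelse(minus, df$sstart, df$send)
  data.frame(
    query_id = df$qseqid, subject_id = df$sseqid,
    evalue = df$evalue, bitscore = df$bitscore,
    identity = df$pident / 100,
    q_start = df$qstart - 1L, q_end = df$qend,
    s_start = s_lo - 1L, s_end = s_hi,
    aligned_length = df$length,
    strand = ifelse(minus, "-", "+"),
    stringsAsFactors = FALSE)
}

#' Write similarity hits in 12-column tabular format
#'
#' Inverse of [read_tabular_hits()]: 1-based inclusive coordinates, subject
#' span reversed for minus-strand hits. Mismatch and gap-open counts are
#' reconstructed approximately from identity and aligned length.
#'
#' @param hits Hit data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  minus <- hits$strand == "-"
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = round(hits$identity * 100, 2),
    length = hits$aligned_length,
    mismatch = round((1 - hits$identity) * hits$aligned_length),
    gapopen = 0L,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = ifelse(minus, hits$s_end, hits$s_start + 1L),
    send = ifelse(minus, hits$s_start + 1L, hits$s_end),
    evalue = hits$evalue, bitscore = hits$bitscore)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             evalue = numeric(), bitscore = numeric(), identity = numeric(),
             q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), aligned_length = numeric(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Extract reciprocal paralog pairs from a self-search hit list
#'
#' An unordered pair `{A, B}` qualifies if and only if both directed hits
#' `A -> B` and `B -> A` exist at `evalue <= max_evalue` with `A != B`.
#' All qualifying pairs are retained, not only reciprocal best hits, so one
#' transcript can contribute several potential paralog pairs. Pairs whose
#' qualifying hits are exclusively minus-strand are flagged
#' (`strand == "-"`) so downstream Ks estimation can exclude them as
#' antisense artifacts.
#'
#' @param hits Directed hits from a set searched against itself.
#' @param max_evalue E-value ceiling (default `1e-20`).
#' @return Data frame with `id_a < id_b` (lexicographic canonical order),
#'   `best_evalue` and `strand`.
#' @export
reciprocal_paralog_pairs <- function(hits, max_evalue = 1e-20) {
  empty <- data.frame(id_a = character(), id_b = character(),
                      best_evalue = numeric(), strand = character(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  h <- hits[hits$evalue <= max_evalue & hits$query_id != hits$subject_id, ,
            drop = FALSE]
  if (nrow(h) == 0L) return(empty)
  strand <- if (is.null(h$strand)) rep("+", nrow(h)) else h$strand
  key_dir <- paste(h$query_id, h$subject_id, sep = "\r")
  pair_of <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  key_pair <- pair_of(h$query_id, h$subject_id)
  # reciprocal: the opposite direction must also be present
  rev_key <- paste(h$subject_id, h$query_id, sep = "\r")
  recip <- rev_key %in% key_dir
  h <- h[recip, , drop = FALSE]
  strand <- strand[recip]
  key_pair <- key_pair[recip]
  if (nrow(h) == 0L) return(empty)
  best_e <- tapply(h$evalue, key_pair, min)
  any_plus <- tapply(strand == "+", key_pair, any)
  ids <- strsplit(names(best_e), "\r", fixed = TRUE)
  out <- data.frame(
    id_a = vapply(ids, `[[`, character(1L), 1L),
    id_b = vapply(ids, `[[`, character(1L), 2L),
    best_evalue = as.numeric(best_e),
    strand = ifelse(as.logical(any_plus), "+", "-"),
    stringsAsFactors = FALSE)
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
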