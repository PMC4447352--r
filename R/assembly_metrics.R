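#' N50 of a set of scaffold lengths
#'
#' The largest length L such that scaffolds of length >= L together contain
#' at least half the total assembly length (cumulative-sum convention:
#' sort descending, accumulate, report the length at which the running total
#' first reaches half the grand total).
#'
#' @param lengths Positive integer scaffold lengths.
#' @return The N50 length.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(s)
  s[which(cs >= sum(s) / 2)[1L]]
}

#' Assembly-quality statistics for one scaffold set
#'
#' Computes the metrics used to compare candidate assemblies: scaffold
#' count, N50, and the number of scaffolds strictly longer than a threshold
#' together with their total length (the threshold is exclusive, matching
#' the "> 800 bp" convention).
#'
#' @param records Scaffold set (as from [read_fasta()]); non-empty.
#' @param label Assembly label (e.g. the k-mer length).
#' @param threshold Length threshold in bp (default 800, strict).
#' @return One-row data frame of class `assembly_stats`: `label`,
#'   `n_scaffolds`, `n50`, `n_over_threshold`, `bp_over_threshold`,
#'   `threshold`.
#' @export
scaffold_stats <- function(records, label, threshold = 800L) {
  validate_records(records)
  len <- nchar(records$seq)
  over <- len > threshold
  out <- data.frame(label = as.character(label),
                    n_scaffolds = length(len),
                    n50 = n50(len),
                    n_over_threshold = sum(over),
                    bp_over_threshold = sum(len[over]),
                    threshold = threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("assembly_stats", class(out))
  out
}

#' Select the best assembly from candidate statistics
#'
#' Lexicographic rule: maximise N50, break ties by fewest scaffolds, then by
#' candidate order. This operationalises the usual judgement that the best
#' k-mer sweep assembly combines the greatest N50 with the fewest scaffolds.
#'
#' @param candidates A data frame of stacked [scaffold_stats()] rows (or a
#'   list of them).
#' @return The winning one-row statistics.
#' @export
select_best_assembly <- function(candidates) {
  if (is.list(candidates) && !is.data.frame(candidates)) {
    candidates <- do.call(rbind, candidates)
  }
  if (is.null(candidates) || nrow(candidates) == 0L) {
    stop("empty candidate list")
  }
  ord <- order(-candidates$n50, candidates$n_scaffolds, seq_len(nrow(candidates)))
  candidates[ord[1L], , drop = FALSE]
}

#' Score a set of assembly FASTA files
#'
#' Convenience wrapper: reads each FASTA, computes [scaffold_stats()]
#' (labelled by file name unless labels are given) and returns the stacked
#' table, optionally written as TSV.
#'
#' @param paths FASTA file paths.
#' @param labels Optional labels (defaults to base file names).
#' @param threshold Length threshold in bp.
#' @param out_tsv Optional output TSV path.
#' @return Data frame with one row per assembly.
#' @export
assembly_stats_table <- function(paths, labels = NULL, threshold = 800L,
                                 out_tsv = NULL) {
  if (is.null(labels)) labels <- basename(paths)
  stats <- do.call(rbind, Map(function(p, l)
    scaffold_stats(read_fasta(p), l, threshold), paths, labels))
  rownames(stats) <- NULL
  if (!is.null(out_tsv)) {
    write.table(stats, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stats
}
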