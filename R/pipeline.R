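#' End-to-end duplication scan of a transcriptome
#'
#' Runs the full pipeline: all-vs-all similarity search, reciprocal paralog
#' pairing, per-pair Ks estimation (with rejection logging), BIC-selected
#' Gaussian-mixture peak detection, SiZer significance mapping, and
#' molecular-clock dating of the ancient peaks. All stage outputs are
#' written to `out_dir` as TSV/JSON and a machine-readable summary is
#' returned.
#'
#' @param input A FASTA path or a transcript data frame (see [read_fasta()]).
#' @param out_dir Output directory (created if missing); `NULL` skips file
#'   output.
#' @param max_evalue Similarity-search and pairing e-value ceiling.
#' @param min_sites Minimum synonymous sites per pair.
#' @param k_min,k_max Mixture component range.
#' @param recent_cutoff Ks boundary between recent and ancient peaks.
#' @param rate Synonymous substitution rate per site per year.
#' @param per_lineage Use the per-lineage dating convention `ks / (2 rate)`.
#' @param alpha SiZer significance level.
#' @param seed Integer seed (mixture restarts; recorded in the summary).
#' @param word_size Seed word length for the similarity search.
#' @return List of class `dupscan_report`: `summary` (counts, Ks
#'   quantiles, peaks, intervals, ages, config), `pairs`, `ks`, `mixture`,
#'   `sizer`, `peaks_dated`. Zero viable pairs yield a report with empty
#'   downstream sections and `summary$status == "no_viable_pairs"`.
#' @export
run_duplication_scan <- function(input, out_dir = NULL, max_evalue = 1e-20,
                                 min_sites = 10, k_min = 1L, k_max = 10L,
                                 recent_cutoff = 0.1, rate = 1.5e-8,
                                 per_lineage = FALSE, alpha = 0.05,
                                 seed = 1L, word_size = 11L) {
  records <- if (is.character(input)) read_fasta(input) else input
  validate_records(records, min_n = 2L)
  config <- list(max_evalue = max_evalue, min_sites = min_sites,
                 k_min = k_min, k_max = k_max, recent_cutoff = recent_cutoff,
                 rate = rate, per_lineage = per_lineage, alpha = alpha,
                 seed = seed, word_size = word_size,
                 n_records = nrow(records))
  message("similarity search over ", nrow(records), " transcripts")
  hits <- all_vs_all_hits(records, max_evalue = max_evalue,
                          word_size = word_size)
  pairs <- reciprocal_paralog_pairs(hits, max_evalue = max_evalue)
  message(nrow(pairs), " reciprocal pairs (",
          sum(pairs$strand == "-"), " antisense-only)")
  ks_tab <- ks_table(records, pairs, min_sites = min_sites)
  viable <- ks_tab[ks_tab$status == "ok", , drop = FALSE]
  rejects <- table(ks_tab$status[ks_tab$status != "ok"])
  if (length(rejects) > 0L) {
    message("rejections: ",
            paste(names(rejects), as.integer(rejects), collapse = ", "))
  }
  summary <- list(
    status = if (nrow(viable) > 0L) "ok" else "no_viable_pairs",
    n_hits = nrow(hits), n_pairs = nrow(pairs),
    n_pairs_viable = nrow(viable),
    rejections = as.list(setNames(as.integer(rejects), names(rejects))),
    config = config)
  mixture <- NULL; szr <- NULL; intervals <- NULL; dated <- NULL
  recent <- numeric(0L); ancient <- numeric(0L)
  if (nrow(viable) > 0L) {
    ksv <- viable$ks
    summary$ks_min <- min(ksv)
    summary$ks_median <- stats::median(ksv)
    summary$ks_max <- max(ksv)
    if (nrow(viable) >= 5L) {
      mixture <- select_mixture(ksv, k_min = k_min, k_max = k_max,
                                seed = seed)
      cls <- classify_peaks(mixture, recent_cutoff)
      recent <- cls$recent; ancient <- cls$ancient
      summary$k_selected <- mixture$k
      summary$peaks <- mixture$means
      summary$recent_peaks <- recent
      summary$ancient_peaks <- ancient
    }
    if (length(ksv) >= 50L) {
      szr <- sizer_map(ksv, alpha = alpha)
      intervals <- significant_peaks(szr)
      summary$significant_intervals <- intervals
    }
    dated <- date_report(ancient, rate = rate, per_lineage = per_lineage)
    summary$ancient_ages_myr <- dated$age_myr
  }
  report <- structure(list(summary = summary, pairs = pairs, ks = ks_tab,
                           mixture = mixture, sizer = szr,
                           peaks_dated = dated),
                      class = "dupscan_report")
  if (!is.null(out_dir)) write_dupscan_outputs(report, out_dir)
  report
}

write_dupscan_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(report$pairs, "pairs.tsv")
  tsv(report$ks, "ks.tsv")
  if (!is.null(report$mixture)) {
    tsv(report$mixture$bic_table, "bic_table.tsv")
    mix <- report$mixture
    jsonlite::write_json(
      list(k = mix$k, weights = mix$weights, means = mix$means,
           sds = mix$sds, loglik = mix$loglik, bic = mix$bic,
           recent_peaks = report$summary$recent_peaks,
           ancient_peaks = report$summary$ancient_peaks),
      file.path(out_dir, "mixture.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$sizer)) tsv(sizer_table(report$sizer), "sizer.tsv")
  if (!is.null(report$peaks_dated)) tsv(report$peaks_dated, "dated_peaks.tsv")
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.dupscan_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Duplication scan: %d transcripts, %d reciprocal pairs, %d viable Ks\n",
              s$config$n_records, s$n_pairs, s$n_pairs_viable))
  if (s$status == "ok") {
    cat(sprintf("Ks range %.4f - %.4f (median %.4f)\n",
                s$ks_min, s$ks_max, s$ks_median))
    if (!is.null(s$k_selected)) {
      cat(sprintf("Mixture k = %d; ancient peaks: %s\n", s$k_selected,
                  paste(sprintf("%.3f", s$ancient_peaks), collapse = ", ")))
    }
    if (!is.null(x$peaks_dated) && nrow(x$peaks_dated) > 0L) {
      cat("Dated ancient peaks (Myr): ",
          paste(sprintf("%.1f", x$peaks_dated$age_myr), collapse = ", "), "\n")
    }
  } else {
    cat("No viable paralog pairs.\n")
  }
  invisible(x)
}

#' Cross-sample ortholog scan over three transcriptomes
#'
#' Finds three-way reciprocal-best-hit ortholog triples, aligns each triple
#' (anchor-merge on the first member), and produces a variant report per
#' triple (SNP counts vs the majority consensus, synonymous/nonsynonymous
#' classes, deletion records).
#'
#' @param input_a,input_b,input_c FASTA paths or transcript data frames.
#' @param out_dir Optional output directory for per-triple TSVs.
#' @param max_evalue E-value ceiling for the searches.
#' @param pair Optional pair of sample labels (subset of `c("a","b","c")`)
#'   for the shared/unique nonsynonymous breakdown (default the first two).
#' @return List with `triples` (data frame) and `reports` (one
#'   `variant_report` per triple). No triples yields empty elements with a
#'   warning.
#' @export
run_ortholog_scan <- function(input_a, input_b, input_c, out_dir = NULL,
                              max_evalue = 1e-20, pair = c("a", "b")) {
  load1 <- function(x) if (is.character(x)) read_fasta(x) else x
  set_a <- load1(input_a); set_b <- load1(input_b); set_c <- load1(input_c)
  triples <- three_way_rbh(set_a, set_b, set_c, max_evalue = max_evalue)
  if (nrow(triples) == 0L) {
    warning("no consistent three-way reciprocal best hits found")
    return(list(triples = triples, reports = list()))
  }
  seq_of <- function(set, id) set$seq[match(id, set$id)]
  reports <- vector("list", nrow(triples))
  for (i in seq_len(nrow(triples))) {
    seqs <- c(a = seq_of(set_a, triples$id_a[i]),
              b = seq_of(set_b, triples$id_b[i]),
              c = seq_of(set_c, triples$id_c[i]))
    aligned <- align_triple(seqs)
    reports[[i]] <- variant_report(aligned, frame_anchor = "a", pair = pair)
  }
  names(reports) <- triples$id_a
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(triples, file.path(out_dir, "triples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    all_var <- do.call(rbind, lapply(seq_along(reports), function(i)
      cbind(triple = triples$id_a[i], reports[[i]]$variants)))
    all_del <- do.call(rbind, lapply(seq_along(reports), function(i)
      cbind(triple = triples$id_a[i], reports[[i]]$deletions)))
    write.table(all_var, file.path(out_dir, "variants.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(all_del, file.path(out_dir, "deletions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(triples = triples, reports = reports)
}
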