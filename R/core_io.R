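#' Read a nucleotide FASTA file into a transcript set
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a data frame
#' of transcript records. The record id is the first whitespace-delimited
#' token of the header; the remainder is kept as a description. Sequences are
#' uppercase-normalised and must be over the alphabet A, C, G, T, N.
#'
#' @param path Path to an existing FASTA file.
#' @return A `data.frame` with columns `id`, `seq`, `desc` (one row per
#'   record, input order preserved).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) stop("duplicate id ", dup[[1L]])
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("zero-length sequence for id ", ids[nchar(seqs) == 0L][[1L]])
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[[1L]]
    stop(sprintf("non-IUPAC character '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  data.frame(id = ids, seq = seqs, desc = desc, stringsAsFactors = FALSE)
}

#' Write a transcript set to FASTA
#'
#' Sequences are wrapped at 60 columns. `read_fasta(write_fasta(x, f))`
#' recovers `x` exactly.
#'
#' @param records Data frame with columns `id` and `seq` (optionally `desc`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  validate_records(records, allow_empty = TRUE)
  if (nrow(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(records$seq)
  desc <- if ("desc" %in% names(records)) records$desc else ""
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# shared record validation for operations taking a transcript set
validate_records <- function(records, allow_empty = FALSE, min_n = 0L) {
  if (!is.data.frame(records) || !all(c("id", "seq") %in% names(records))) {
    stop("records must be a data.frame with columns 'id' and 'seq'")
  }
  if (!allow_empty && nrow(records) == 0L) stop("empty record set")
  if (nrow(records) < min_n) stop("insufficient records: need at least ", min_n)
  if (anyDuplicated(records$id)) {
    stop("duplicate id ", records$id[duplicated(records$id)][[1L]])
  }
  invisible(records)
}

#' Translate a nucleotide sequence in a given frame
#'
#' Standard genetic code. The trailing partial codon (after the frame offset)
#' is dropped; stop codons are rendered `*`; codons containing `N` are
#' rendered `X`.
#'
#' @param seq Nucleotide string over A, C, G, T, N (case-insensitive).
#' @param frame Frame offset 0, 1 or 2.
#' @return Amino-acid string of length `floor((nchar(seq) - frame) / 3)`.
#' @export
translate_nt <- function(seq, frame = 0L) {
  stopifnot(length(seq) == 1L, frame %in% 0:2)
  s <- toupper(seq)
  n <- nchar(s)
  if (n - frame < 3L) return("")
  n_codons <- (n - frame) %/% 3L
  starts <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(s, starts, starts + 2L)
  aa <- GENETIC_CODE_1[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Standard genetic code (table 1), indexed by codon string; used by the
# translator, the Nei-Gojobori tables and the sequence simulator.
GENETIC_CODE_1 <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1L]]
  codons <- unlist(lapply(bases, function(b1)
    as.vector(vapply(bases, function(b2)
      paste0(b1, b2, bases), character(4L)))))
  setNames(aa, codons)
})

STOP_CODONS <- names(GENETIC_CODE_1)[GENETIC_CODE_1 == "*"]
SENSE_CODONS <- names(GENETIC_CODE_1)[GENETIC_CODE_1 != "*"]
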