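test_that("Nei-Gojobori counts match the pathway-enumeration oracle", {
  # spec-anchored single-codon cases
  expect_equal(pkg_codon_pair("TTT", "TTT"), c(S = 1 / 3, N = 8 / 3, Sd = 0, Nd = 0))
  expect_equal(unname(pkg_codon_pair("TTT", "TTC")[c("Sd", "Nd")]), c(1, 0))
  # two-position difference averaged over both pathway orders
  expect_equal(pkg_codon_pair("TTT", "GTA"), oracle_codon_pair("TTT", "GTA"))
  # random sample of sense-codon pairs against the oracle (full sweep is in
  # the acceptance suite)
  codons <- ksdup:::SENSE_CODONS
  withr::with_seed(8, {
    for (rep in 1:150) {
      c1 <- sample(codons, 1); c2 <- sample(codons, 1)
      expect_equal(pkg_codon_pair(c1, c2), oracle_codon_pair(c1, c2),
                   tolerance = 1e-12)
    }
  })
})

test_that("site fractions conserve S + N = 3 per codon column", {
  codons <- ksdup:::SENSE_CODONS
  withr::with_seed(9, {
    for (rep in 1:40) {
      ca <- paste(sample(codons, 20, replace = TRUE), collapse = "")
      cb <- paste(sample(codons, 20, replace = TRUE), collapse = "")
      cnt <- ng_site_counts(list(aligned_a = ca, aligned_b = cb))
      expect_equal(cnt$S + cnt$N_sites, 60, tolerance = 1e-9)
    }
  })
  # gap and N columns are excluded entirely
  cnt <- ng_site_counts(list(aligned_a = "TTT---ATGNNN",
                             aligned_b = "TTTAAAATGAAA"))
  expect_equal(cnt$S + cnt$N_sites, 6, tolerance = 1e-9)
  expect_error(ng_site_counts(list(aligned_a = "---", aligned_b = "AAA")),
               "too_few_sites")
})

test_that("Jukes-Cantor correction matches its closed form and saturates", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.3), -0.75 * log(1 - 0.4), tolerance = 1e-12)
  expect_equal(jc_correct(0.3), 0.3831192, tolerance = 1e-6)
  expect_true(is.na(jc_correct(0.75)))
  expect_true(is.na(jc_correct(0.8)))
  # d >= p on (0, 3/4), growing without bound near saturation
  p <- seq(0.01, 0.74, by = 0.01)
  expect_true(all(jc_correct(p) >= p))
  expect_gt(jc_correct(0.7499), 5)
})

test_that("ORF scan picks the longest stop-free frame on either strand", {
  withr::with_seed(10, cds <- random_cds(60))
  orf <- find_orf(cds)
  expect_equal(orf$orf, cds)
  expect_equal(orf$strand, "+")
  # reverse-complemented input is recovered on the minus strand
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(cds, "")[[1]]), collapse = ""))
  orf_rc <- find_orf(rc)
  expect_equal(orf_rc$orf, cds)
  expect_equal(orf_rc$strand, "-")
  # too-short ORFs are rejected
  withr::with_seed(11, short <- random_cds(20))
  expect_error(find_orf(short), "no usable ORF")
})

test_that("codon alignment is gap-free on identical input, 3-nt gapped on indels", {
  withr::with_seed(12, cds <- random_cds(80))
  aln <- protein_guided_codon_align(cds, cds)
  expect_equal(aln$aligned_a, aln$aligned_b)
  expect_equal(aln$n_codon_columns, 80)
  # one extra internal codon becomes one 3-nt gap
  ins <- paste0(substr(cds, 1, 120), "GCA", substr(cds, 121, nchar(cds)))
  aln2 <- protein_guided_codon_align(cds, ins)
  expect_equal(nchar(aln2$aligned_a), nchar(cds) + 3)
  expect_equal(gsub("-", "", aln2$aligned_a), cds)
  expect_equal(gsub("-", "", aln2$aligned_b), ins)
  expect_match(aln2$aligned_a, "---")
  # protein-level score agrees with the independent global aligner
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(translate_nt(cds)),
    Biostrings::AAString(translate_nt(ins)),
    substitutionMatrix = ksdup:::get_blosum62(),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  al <- ksdup:::cpp_codon_align(translate_nt(cds), translate_nt(ins),
                                cds, ins, ksdup:::get_blosum62(), 10, 0.5)
  expect_equal(al$score, Biostrings::score(pa))
})

test_that("Ks estimation recovers planted synonymous divergence", {
  cds0 <- withr::with_seed(17, random_cds(120))
  expect_equal(estimate_ks(cds0, cds0)$ks, 0)
  # planted synonymous-only changes at ps = 0.2 over 300 codons
  withr::with_seed(13, {
    sim <- simulate_duplicated_transcriptome(
      n_families = 1, depths = jc_correct(0.2), codons_per_gene = 300,
      omega = 0, seed = 99)
  })
  r <- estimate_ks(sim$records$seq[1], sim$records$seq[2])
  expect_equal(r$ks, jc_correct(0.2), tolerance = 0.03)
  # symmetry
  r2 <- estimate_ks(sim$records$seq[2], sim$records$seq[1])
  expect_lt(abs(r$ks - r2$ks), 1e-9)
})

test_that("unrelated codon sequences are rejected as saturated", {
  withr::with_seed(14, {
    a <- random_cds(200)
    b <- random_cds(200)
  })
  cnt <- ng_site_counts(list(aligned_a = a, aligned_b = b))
  expect_gt(cnt$Sd / cnt$S, 0.75)
  r <- ksdup:::ks_from_codon_alignment(list(aligned_a = a, aligned_b = b),
                                       min_sites = 10)
  expect_equal(r$reject_reason, "saturated")
  expect_true(is.na(r$ks))
})

test_that("ks is monotone along a nested synonymous-mutation ladder", {
  withr::with_seed(15, {
    depths <- c(0.05, 0.15, 0.3, 0.5, 0.8)
    ks_vals <- vapply(seq_along(depths), function(i) {
      sim <- simulate_duplicated_transcriptome(
        n_families = 1, depths = depths[i], codons_per_gene = 400,
        omega = 0, seed = 500)
      estimate_ks(sim$records$seq[1], sim$records$seq[2])$ks
    }, numeric(1))
  })
  expect_true(all(diff(ks_vals) > 0))
})

test_that("ks_table batches pairs and logs rejection reasons", {
  withr::with_seed(16, {
    cds <- random_cds(100)
    recs <- records_df(c("a", "b", "c"), c(cds, cds, random_cds(100)))
  })
  pairs <- data.frame(id_a = c("a", "a", "a"), id_b = c("b", "c", "c"),
                      strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  tab <- ks_table(recs, pairs)
  expect_equal(tab$status, c("ok", "saturated", "antisense"))
  expect_equal(tab$ks[1], 0)
  expect_equal(nrow(ks_table(recs, pairs[0, ])), 0)
})
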