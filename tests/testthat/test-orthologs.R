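test_that("majority consensus follows the documented tie order", {
  expect_equal(consensus_majority(c("A", "A", "G")), "A")
  expect_equal(consensus_majority(c("A", "C", "G")), "A")  # 3-way tie
  expect_equal(consensus_majority(c("-", "-", "-")), "-")
  expect_equal(consensus_majority(c("ACGT", "ACGT", "ACGT")), "ACGT")
  # order-free by construction
  seqs <- c("ACG-", "A-GT", "TCGT")
  expect_equal(consensus_majority(seqs), consensus_majority(rev(seqs)))
  expect_error(consensus_majority(c("AC", "ACG")), "equal length")
  expect_error(consensus_majority("ACGT"), "at least 2")
})

test_that("variant report classifies hand-built SNPs against the consensus", {
  # consensus is seq2/seq3 agreement; seq1 differs at two columns:
  # col 3 (codon 1 pos 3, TTT->TTC synonymous) and col 4 (codon 2 pos 1,
  # AAA->GAA nonsynonymous)
  aligned <- c(s1 = "TTCGAAGGG", s2 = "TTTAAAGGG", s3 = "TTTAAAGGG")
  rep <- variant_report(aligned, frame_anchor = "s2")
  expect_equal(unname(rep$snp_counts), c(2, 0, 0))
  v <- rep$variants
  expect_equal(v$class[v$column == 3], "synonymous")
  expect_equal(v$class[v$column == 4], "nonsynonymous")
  expect_equal(v$codon_index, c(0, 1))
  # identical sequences: no SNPs anywhere
  same <- c(a = "ATGATG", b = "ATGATG", c = "ATGATG")
  expect_true(all(variant_report(same)$snp_counts == 0))
})

test_that("a 6-nt gap run is one in-frame two-codon deletion record", {
  aligned <- c(anchor = "ATGAAACCCGGGTTT",
               short  = "ATG------GGGTTT",
               other  = "ATGAAACCCGGGTTT")
  rep <- variant_report(aligned, frame_anchor = "anchor")
  del <- rep$deletions
  expect_equal(nrow(del), 1)
  expect_equal(del$seq_id, "short")
  expect_equal(del$length_nt, 6)
  expect_true(del$in_frame)
  expect_equal(del$length_codons, 2)
  # out-of-frame deletion is flagged accordingly
  aligned2 <- c(a = "ATGAAACCC", b = "ATGAA--CC", c = "ATGAAACCC")
  del2 <- variant_report(aligned2, frame_anchor = "a")$deletions
  expect_false(del2$in_frame)
})

test_that("shared and unique nonsynonymous sites split correctly", {
  # both s1 and s2 carry the same nonsynonymous variant at col 1 (AAA->CAA);
  # s1 additionally has a private nonsynonymous change at col 7 (GGG->AGG)
  aligned <- c(s1 = "CAATTTAGG", s2 = "CAATTTGGG", s3 = "AAATTTGGG",
               s4 = "AAATTTGGG")
  rep <- variant_report(aligned, frame_anchor = "s3", pair = c("s1", "s2"))
  expect_equal(rep$shared_nonsyn, 1)
  expect_equal(unname(rep$unique_nonsyn), c(1, 0))
})

test_that("SNP counts are bounded by the column count", {
  withr::with_seed(50, {
    seqs <- c(a = random_dna(30), b = random_dna(30), c = random_dna(30))
  })
  rep <- variant_report(seqs, frame_anchor = "a")
  expect_true(all(rep$snp_counts <= 30))
})

test_that("anchor-merge alignment recovers a planted 3-nt indel", {
  withr::with_seed(51, base <- random_cds(60))
  with_ins <- paste0(substr(base, 1, 90), "GCT", substr(base, 91, nchar(base)))
  aligned <- align_triple(c(x = base, y = with_ins, z = base))
  expect_equal(unique(nchar(aligned)), nchar(with_ins))
  expect_equal(gsub("-", "", aligned[["y"]]), with_ins)
  expect_equal(gsub("-", "", aligned[["x"]]), base)
})

test_that("three-way reciprocal best hits recover planted ortholog sets", {
  withr::with_seed(52, {
    n_genes <- 12
    base <- vapply(rep(120, n_genes), random_cds, "")
    set_a <- records_df(paste0("a", 1:n_genes), base)
    set_b <- records_df(paste0("b", 1:n_genes),
                        vapply(base, mutate_seq, "", rate = 0.05))
    set_c <- records_df(paste0("c", 1:n_genes),
                        vapply(base, mutate_seq, "", rate = 0.05))
  })
  triples <- three_way_rbh(set_a, set_b, set_c, max_evalue = 1e-20)
  expect_equal(nrow(triples), n_genes)
  expect_equal(sub("a", "", triples$id_a), sub("b", "", triples$id_b))
  expect_equal(sub("a", "", triples$id_a), sub("c", "", triples$id_c))
  # a sample whose best hit points elsewhere breaks the triple
  expect_equal(nrow(three_way_rbh(set_a[1, , drop = FALSE],
                                  set_b[2, , drop = FALSE],
                                  set_c[3, , drop = FALSE])), 0)
})

test_that("ortholog scan reports planted substitution counts exactly", {
  withr::with_seed(53, {
    n_genes <- 5
    base <- vapply(rep(150, n_genes), random_cds, "")
    # plant a known number of substitutions in each b copy; c stays ancestral
    n_subs <- c(3, 7, 2, 9, 5)
    mutated <- vapply(seq_len(n_genes), function(i) {
      chars <- strsplit(base[i], "")[[1]]
      pos <- sample(seq_along(chars), n_subs[i])
      for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                chars[p]), 1)
      paste(chars, collapse = "")
    }, "")
    set_a <- records_df(paste0("g", 1:n_genes, "_a"), base)
    set_b <- records_df(paste0("g", 1:n_genes, "_b"), mutated)
    set_c <- records_df(paste0("g", 1:n_genes, "_c"), base)
  })
  scan <- run_ortholog_scan(set_a, set_b, set_c)
  expect_equal(nrow(scan$triples), n_genes)
  got <- vapply(scan$reports, function(r) unname(r$snp_counts["b"]),
                numeric(1))
  ord <- match(scan$triples$id_a, paste0("g", 1:n_genes, "_a"))
  expect_equal(unname(got), n_subs[ord])
  # identical sets: zero SNPs everywhere
  scan0 <- run_ortholog_scan(set_a, set_a, set_a)
  expect_true(all(vapply(scan0$reports, function(r) sum(r$snp_counts),
                         numeric(1)) == 0))
  # disjoint random sets: no triples, with a warning
  withr::with_seed(54, {
    r1 <- records_df("x", random_dna(300))
    r2 <- records_df("y", random_dna(300))
    r3 <- records_df("z", random_dna(300))
  })
  expect_warning(empty <- run_ortholog_scan(r1, r2, r3), "no consistent")
  expect_equal(nrow(empty$triples), 0)
})
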