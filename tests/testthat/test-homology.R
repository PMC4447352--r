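test_that("identical sequences give reciprocal near-zero e-value hits", {
  withr::with_seed(1, s <- random_dna(500))
  recs <- records_df(c("a", "b"), c(s, s))
  hits <- all_vs_all_hits(recs)
  expect_setequal(paste(hits$query_id, hits$subject_id),
                  c("a b", "b a"))
  expect_true(all(hits$evalue < 1e-100))
  expect_true(all(hits$identity == 1))
  expect_true(all(hits$strand == "+"))
  # spans cover the full sequences (0-based half-open)
  expect_true(all(hits$q_start == 0 & hits$q_end == 500))
})

test_that("unrelated random sequences produce no hits at 1e-20", {
  withr::with_seed(2, {
    recs <- records_df(c("x", "y"), c(random_dna(300), random_dna(300)))
  })
  expect_equal(nrow(all_vs_all_hits(recs)), 0)
})

test_that("a 5% substituted copy is found with matching identity", {
  withr::with_seed(3, {
    s <- random_dna(600)
    s2 <- mutate_seq(s, 0.05)
  })
  recs <- records_df(c("a", "b"), c(s, s2))
  hits <- all_vs_all_hits(recs)
  expect_equal(nrow(hits), 2)
  expect_true(all(abs(hits$identity - 0.95) < 0.02))
})

test_that("reported score equals the exact local-alignment oracle", {
  withr::with_seed(4, {
    for (rep in 1:6) {
      L <- sample(150:400, 1)
      s <- random_dna(L)
      s2 <- mutate_seq(s, runif(1, 0.02, 0.12))
      # direct exact-pair interface
      direct <- ksdup:::cpp_sw_pair(s, s2, 1, -2, 5, 2)
      expect_equal(direct$score, oracle_local_score(s, s2))
      # search-engine path (banded around seeds) reproduces the same score
      recs <- records_df(c("a", "b"), c(s, s2))
      hits <- all_vs_all_hits(recs, max_evalue = 10)
      expect_gte(nrow(hits), 1)
      expect_equal(max(hits$score), direct$score)
    }
  })
})

test_that("antisense duplicates are reported on the minus strand", {
  withr::with_seed(5, s <- random_dna(400))
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  recs <- records_df(c("f", "r"), c(s, rc))
  hits <- all_vs_all_hits(recs)
  expect_gte(nrow(hits), 2)
  expect_true(all(hits$strand == "-"))
  pairs <- reciprocal_paralog_pairs(hits)
  expect_equal(pairs$strand, "-")
})

test_that("tabular hit files round-trip with coordinate conversion", {
  path <- tempfile()
  writeLines(paste(c("a", "b", "95.0", "200", "10", "0",
                     "1", "200", "1", "200", "1e-50", "370"),
                   collapse = "\t"), path)
  h <- read_tabular_hits(path)
  expect_equal(h$query_id, "a")
  expect_equal(h$evalue, 1e-50)
  expect_equal(h$identity, 0.95)
  expect_equal(c(h$q_start, h$q_end), c(0, 200))
  expect_equal(h$strand, "+")
  # minus-strand subject span normalised
  writeLines(paste(c("a", "b", "90", "100", "10", "0",
                     "1", "100", "150", "51", "1e-30", "180"),
                   collapse = "\t"), path)
  h2 <- read_tabular_hits(path)
  expect_equal(h2$strand, "-")
  expect_equal(c(h2$s_start, h2$s_end), c(50, 150))
  # empty file -> empty frame; wrong column count -> located error
  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(read_tabular_hits(empty)), 0)
  bad <- tempfile()
  writeLines(c(paste(rep("1", 12), collapse = "\t"),
               paste(rep("1", 11), collapse = "\t")), bad)
  expect_error(read_tabular_hits(bad), "line 2")
  # write/read round trip on real hits
  withr::with_seed(6, {
    s <- random_dna(300); recs <- records_df(c("a", "b"), c(s, mutate_seq(s, 0.04)))
  })
  hits <- all_vs_all_hits(recs)
  out <- tempfile()
  write_tabular_hits(hits, out)
  back <- read_tabular_hits(out)
  expect_equal(back$query_id, hits$query_id)
  expect_equal(back$q_start, hits$q_start)
  expect_equal(back$evalue, hits$evalue, tolerance = 1e-6)
})

test_that("reciprocal pair extraction equals brute-force mutual-edge scan", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      ids <- paste0("g", seq_len(sample(20:100, 1)))
      n <- sample(50:400, 1)
      hits <- data.frame(
        query_id = sample(ids, n, replace = TRUE),
        subject_id = sample(ids, n, replace = TRUE),
        evalue = 10^runif(n, -40, 0),
        strand = "+", stringsAsFactors = FALSE)
      got <- reciprocal_paralog_pairs(hits, max_evalue = 1e-20)
      expect_setequal(paste(got$id_a, got$id_b, sep = "|"),
                      oracle_reciprocal_pairs(hits, 1e-20))
      # monotonicity: lowering the ceiling never adds pairs
      tighter <- reciprocal_paralog_pairs(hits, max_evalue = 1e-30)
      expect_true(all(paste(tighter$id_a, tighter$id_b) %in%
                        paste(got$id_a, got$id_b)))
    }
  })
})

test_that("self-hits and one-directional hits never form pairs", {
  hits <- data.frame(query_id = c("A", "A"), subject_id = c("A", "B"),
                     evalue = c(0, 1e-30), strand = "+",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(reciprocal_paralog_pairs(hits)), 0)
  both <- rbind(hits, data.frame(query_id = "B", subject_id = "A",
                                 evalue = 1e-25, strand = "+"))
  pairs <- reciprocal_paralog_pairs(both)
  expect_equal(pairs$id_a, "A")
  expect_equal(pairs$id_b, "B")
  expect_equal(pairs$best_evalue, 1e-30)
})
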