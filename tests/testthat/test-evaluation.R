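test_that("levenshtein agrees with a textbook DP oracle", {
  expect_equal(levenshtein("ACGT", "ACGT"), 0L)
  expect_equal(levenshtein("ACGT", ""), 4L)
  expect_equal(levenshtein("", "ACGT"), 4L)
  set.seed(17)
  for (i in 1:100) {
    a <- random_dna(sample(0:15, 1))
    b <- random_dna(sample(0:15, 1))
    expect_equal(levenshtein(a, b), lev_dp(a, b))
  }
})

test_that("distance metrics are symmetric, zero on identity, and the edit
           distance respects the triangle inequality", {
  set.seed(19)
  for (i in 1:25) {
    a <- random_dna(sample(4:20, 1)); b <- random_dna(sample(4:20, 1))
    c <- random_dna(sample(4:20, 1))
    expect_equal(levenshtein(a, b), levenshtein(b, a))
    expect_equal(kmer_distance(a, b), kmer_distance(b, a))
    expect_equal(levenshtein(a, a), 0L)
    expect_equal(kmer_distance(a, a), 0)
    expect_lte(levenshtein(a, c), levenshtein(a, b) + levenshtein(b, c))
  }
})

test_that("k-mer frequencies normalize overlapping counts", {
  f <- kmer_frequency("AAAAA")
  expect_equal(unname(f["AAAA"]), 1)
  expect_equal(sum(f), 1)
  expect_warning(f0 <- kmer_frequency("ACG"), "shorter")
  expect_equal(sum(f0), 0)
})

test_that("k-mer distance agrees with dictionary-counting brute force", {
  set.seed(23)
  for (i in 1:50) {
    a <- random_dna(sample(4:30, 1)); b <- random_dna(sample(4:30, 1))
    expect_equal(kmer_distance(a, b), kmer_dist_brute(a, b),
                 tolerance = 1e-9)
  }
})

test_that("gc_content is (G+C)/length", {
  expect_equal(gc_content(c("GGCC", "AATT", "ACGT")), c(1, 0, 0.5))
  expect_error(gc_content(""), "empty")
})

test_that("nearest-neighbour distributions match brute-force minima", {
  set.seed(29)
  q <- vapply(rep(10, 20), random_dna, character(1))
  t <- vapply(rep(10, 20), random_dna, character(1))
  got <- nn_distance_distribution(q, t, "levenshtein")
  brute <- vapply(q, function(a) min(vapply(t, function(b) lev_dp(a, b),
                                            numeric(1))), numeric(1))
  expect_equal(as.numeric(got), unname(brute))

  gotk <- nn_distance_distribution(q, t, "kmer")
  brutek <- vapply(q, function(a) {
    min(vapply(t, function(b) kmer_dist_brute(a, b), numeric(1)))
  }, numeric(1))
  expect_equal(as.numeric(gotk), unname(brutek), tolerance = 1e-9)

  # self-comparison baseline requires excluding exact matches
  expect_equal(as.numeric(nn_distance_distribution(c("AAAA"),
                                                   c("AAAT", "CCCC"),
                                                   "levenshtein")), 1)
  expect_message(
    v <- nn_distance_distribution("ACGT", "ACGT", "levenshtein",
                                  exclude_identical = TRUE),
    "excluded")
  expect_length(v, 0)
  expect_equal(attr(v, "excluded"), 1L)

  # natural-vs-natural: identical to dropping self-matches only
  self <- nn_distance_distribution(q, q, "levenshtein",
                                   exclude_identical = TRUE)
  expect_gt(min(self), 0)
})

test_that("MFE delegates to the backend, caches, and never fabricates", {
  calls <- 0L
  stub <- mfe_backend_stub(function(seqs) {
    calls <<- calls + length(seqs)
    -0.5 * nchar(seqs)
  })
  expect_equal(mfe("ACGUACGU", stub), -4, ignore_attr = TRUE)
  expect_equal(calls, 1L)
  # cached: second query does not re-fold
  expect_equal(mfe("ACGUACGU", stub), -4, ignore_attr = TRUE)
  expect_equal(calls, 1L)
  # monotone stub distribution is exactly the length transform
  set.seed(31)
  seqs <- vapply(sample(5:30, 10), random_dna, character(1))
  expect_equal(mfe(seqs, stub), -0.5 * nchar(seqs), ignore_attr = TRUE)
})

test_that("RNAfold backend returns negative energies for structured RNA", {
  skip_if(Sys.which("RNAfold") == "", "RNAfold not on PATH")
  be <- mfe_backend_rnafold()
  # a strong hairpin folds with negative energy; a homopolymer does not
  v <- mfe(c("GGGGGGCCCCAAAACGGGGCCCCCC", "AAAAAAAAAAAAAAAA"), be)
  expect_lt(v[1], 0)
  expect_equal(v[2], 0)
})

test_that("uORF scanning counts ATGs with in-frame stops", {
  u <- scan_uorfs("ATGTAA")
  expect_equal(u$count, 1L)
  expect_equal(u$spans$start, 0L)
  expect_equal(u$spans$end, 6L)
  expect_equal(scan_uorfs("ATGAAA")$count, 0L)
  # out-of-frame stop does not terminate
  expect_equal(scan_uorfs("ATGATAAC")$count, 0L)
  set.seed(37)
  for (i in 1:100) {
    s <- random_dna(sample(6:60, 1), gc = 0.35)
    expect_equal(scan_uorfs(s)$count, uorf_count_brute(s))
  }
})

test_that("G-quadruplex scanning matches an independent regex engine", {
  expect_equal(scan_g_quadruplex("GGGAGGGAGGGAGGG")$count, 1L)
  expect_equal(scan_g_quadruplex("ATATATAT")$count, 0L)
  g <- scan_g_quadruplex("GGGAGGGAGGGAGGG")
  expect_equal(g$spans$start, 0L)
  expect_equal(g$spans$end, 15L)
  set.seed(41)
  for (i in 1:60) {
    s <- random_dna(sample(15:80, 1), gc = 0.8)
    expect_equal(scan_g_quadruplex(s)$count, g4_count_brute(s))
  }
})

test_that("Kozak similarity is position-wise identity to the consensus", {
  hit <- kozak_similarity("AAGCCGCCACCATGGTT")
  expect_equal(hit$score, 1)
  expect_equal(hit$position, 2L)
  # count matching positions of poly-A against GCCGCCACCATGG directly
  cons <- strsplit("GCCGCCACCATGG", "")[[1]]
  expect_equal(kozak_similarity(strrep("A", 13))$score,
               mean(cons == "A"))
  # reversal breaks position-wise identity
  rev_cons <- paste(rev(cons), collapse = "")
  expect_lt(kozak_similarity(rev_cons)$score, 1)
  expect_warning(na <- kozak_similarity("ACGT"), "shorter")
  expect_true(is.na(na$score))
})

test_that("compare_sets runs a two-sample KS test and flags degeneracy", {
  set.seed(43)
  a <- rnorm(100)
  res <- compare_sets(a, a + 100)
  expect_equal(res$statistic, 1)
  same <- compare_sets(a, a)
  expect_gt(same$p_value, 0.99)
  # agreement with a direct call on fixed vectors
  b <- rnorm(80, 0.3)
  ref <- suppressWarnings(stats::ks.test(a, b))
  got <- compare_sets(a, b)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  deg <- compare_sets(rep(1, 5), rep(1, 7))
  expect_true(deg$degenerate)
})

test_that("evaluate_utrs assembles the per-sequence metric table", {
  set.seed(47)
  gen <- simulate_utrs(30, seed = 101)
  nat <- simulate_utrs(40, seed = 102)
  stub <- mfe_backend_stub(function(s) -0.1 * nchar(s))
  rep_ <- evaluate_utrs(gen, natural = nat, mfe_backend = stub)
  expect_s3_class(tidy(rep_), "tbl_df")
  expect_equal(nrow(rep_$per_seq), 30L)
  expect_true(all(c("gc", "levenshtein_nn", "kmer_nn", "mfe", "uorf_count",
                    "g4_count", "kozak_best") %in% names(rep_$per_seq)))
  expect_true(all(rep_$per_seq$gc >= 0 & rep_$per_seq$gc <= 1))
  expect_true(all(rep_$per_seq$levenshtein_nn >= 0))
  expect_equal(rep_$mfe_backend, "stub")
  g <- glance(rep_)
  expect_equal(g$n, 30L)
})
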