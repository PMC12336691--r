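test_that("productive clonality matches hand-computed entropy fixtures", {
  expect_equal(productive_clonality(mk_rep(c(2L, 2L, 2L, 2L))), 0)
  expect_equal(productive_clonality(mk_rep(5L)), 1)
  # templates (3, 1): H = -(0.75 log 0.75 + 0.25 log 0.25) = 0.5623
  r <- mk_rep(c(3L, 1L))
  H <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(productive_clonality(r), 1 - H / log(2))
  expect_equal(round(productive_clonality(r), 4), 0.1887)
  empty <- mk_rep(integer(0))
  expect_error(productive_clonality(empty), "undefined")
})

test_that("clonality is invariant to frequency-preserving rescaling", {
  r1 <- mk_rep(c(10L, 5L, 5L, 20L))
  r2 <- mk_rep(c(30L, 15L, 15L, 60L))
  expect_equal(productive_clonality(r1), productive_clonality(r2))
  expect_true(productive_clonality(r1) >= 0 &&
                productive_clonality(r1) <= 1)
})

test_that("expansion calls respect the top-k boundary and definition", {
  baseline <- mk_rep(c(5L, 5L), nt = c("BASE1", "BASE2"))
  # treated: 100 old high-count clones + 1 new at rank 50 + 1 new at 101
  nt_old <- sprintf("OLD%03d", 1:100)
  treated <- repertoire(data.frame(
    nucleotide_seq = c("BASE1", nt_old, "NEWMID", "NEWLOW"),
    junction_aa = "CASSF", v_gene = "TRBV05-06", j_gene = "TRBJ02-07",
    templates = c(1000L, seq(300L, 201L), 250L, 1L),
    productive = TRUE), sample_id = "s1")
  ex <- detect_expansions(baseline, treated, k = 100)
  expect_true("NEWMID" %in% ex$nucleotide_seq)
  expect_false("NEWLOW" %in% ex$nucleotide_seq)     # rank 102
  expect_false("BASE1" %in% ex$nucleotide_seq)      # present at baseline
  expect_true(all(ex$treated_rank <= 100))
  expect_error(detect_expansions(baseline, treated, k = 0), "k")
})

test_that("tie-breaking at the boundary is deterministic and lexicographic", {
  baseline <- mk_rep(1L, nt = "ZZZZ")
  # two tied new clones at the k-th position; only the lexicographically
  # smaller one is within k
  treated <- repertoire(data.frame(
    nucleotide_seq = c("AAA", "TIEA", "TIEB"),
    junction_aa = "CASSF", v_gene = "TRBV05-06", j_gene = "TRBJ02-07",
    templates = c(10L, 5L, 5L), productive = TRUE), sample_id = "s1")
  ex <- detect_expansions(baseline, treated, k = 2)
  expect_equal(ex$nucleotide_seq, c("AAA", "TIEA"))
  # row order of the input does not matter
  shuf <- treated
  shuf$rearrangements <- shuf$rearrangements[c(3, 1, 2), ]
  ex2 <- detect_expansions(baseline, repertoire(shuf$rearrangements, "s1"),
                           k = 2)
  expect_equal(ex, ex2)
})

test_that("pattern scoring agrees with a brute-force double loop", {
  set.seed(21)
  cfg <- small_config()
  pool <- gen_key_pool(cfg, seed = 3)
  r <- gen_repertoire(list(sample_id = "b", ga_exposed = TRUE,
                           carrier_A = TRUE, carrier_B = TRUE),
                      pool, cfg, seed = 13)
  idx <- sample(nrow(pool), 25)
  jn <- pool$junction_aa[idx]
  # wildcard half of them at a random interior position
  wild <- seq_along(jn) %% 2 == 0
  jn[wild] <- vapply(jn[wild], function(s) {
    p <- sample(seq(2, nchar(s) - 1), 1)
    substr(s, p, p) <- "x"
    s
  }, character(1))
  pat <- es_pattern(jn, pool$v_gene[idx], pool$j_gene[idx])

  sc <- score_pattern(r, pat)
  re <- r$rearrangements[r$rearrangements$productive, ]
  hit_brute <- vapply(seq_len(nrow(re)), function(i) {
    any(vapply(seq_len(nrow(pat)), function(k) {
      if (re$v_gene[i] != pat$v_gene[k] || re$j_gene[i] != pat$j_gene[k])
        return(FALSE)
      a <- strsplit(re$junction_aa[i], "")[[1]]
      b <- strsplit(pat$junction_aa[k], "")[[1]]
      length(a) == length(b) && all(a == b | b == "x")
    }, logical(1)))
  }, logical(1))
  expect_equal(sc$n_matched, sum(hit_brute))
  expect_equal(sc$breadth, sum(hit_brute) / r$R_unique)
  expect_equal(sc$depth, sum(re$templates[hit_brute]) / r$T_total)
  expect_equal(sc$breadth_per_1e6, sc$breadth * 1e6)
})

test_that("a one-wildcard motif matches its member clonotype", {
  r <- mk_rep(4L, junction = "CASSSHGGEQYF")
  m <- score_pattern(r, es_pattern("CASSxHGGEQYF", "TRBV05-06",
                                   "TRBJ02-07"))
  expect_equal(m$n_matched, 1L)
  # same junction, wrong V gene: no match
  r2 <- mk_rep(4L, junction = "CASSSHGGEQYF", v = "TRBV09")
  expect_equal(score_pattern(r2, es_pattern("CASSxHGGEQYF", "TRBV05-06",
                                            "TRBJ02-07"))$n_matched, 0L)
  expect_error(score_pattern(r, pat = es_pattern(character(),
                                                 character(),
                                                 character())), "empty")
  expect_error(es_pattern("CAxxSF", "TRBV05-06", "TRBJ02-07"),
               "one wildcard")
})

test_that("breadth arithmetic works at repertoire scale", {
  # 2 matching of 1e5 unique -> 20 per million
  n <- 1e5L
  df <- data.frame(nucleotide_seq = sprintf("N%06d", seq_len(n)),
                   junction_aa = c("CASSAAF", "CASSAAF",
                                   sprintf("CQ%05dF", seq_len(n - 2))),
                   v_gene = "TRBV05-06", j_gene = "TRBJ02-07",
                   templates = 1L, productive = TRUE)
  r <- repertoire(df, "big")
  sc <- score_pattern(r, es_pattern("CASSAAF", "TRBV05-06", "TRBJ02-07"))
  expect_equal(sc$breadth_per_1e6, 20)
})
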