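test_that("FET enrichment equals the exhaustive hypergeometric oracle", {
  # exhaustive sweep over all tables with small margins
  for (n1 in c(2L, 5L, 8L)) for (n2 in c(3L, 7L)) {
    for (a in 0:n1) for (b in 0:n2) {
      expect_equal(fet_enrichment(a, n1, b, n2), fet_oracle(a, n1, b, n2),
                   tolerance = 1e-12)
    }
  }
  # spot checks at study-like margins against fisher.test
  cases <- list(c(5, 58, 2, 211), c(12, 75, 3, 234), c(9, 71, 40, 978))
  for (cs in cases) {
    ft <- stats::fisher.test(matrix(c(cs[1], cs[2] - cs[1], cs[3],
                                      cs[4] - cs[3]), 2),
                             alternative = "greater")$p.value
    expect_equal(fet_enrichment(cs[1], cs[2], cs[3], cs[4]), ft,
                 tolerance = 1e-10)
  }
  # presence only in controls is never enrichment in cases
  expect_equal(fet_enrichment(0, 10, 5, 20), 1)
  # all cases present, no controls: tail is the single point mass
  expect_equal(fet_enrichment(4, 4, 0, 6),
               stats::dhyper(4, 4, 6, 4), tolerance = 1e-12)
  expect_error(fet_enrichment(-1, 5, 0, 5), "nonnegative")
})

make_toy_cohort <- function(presence_mat, is_case) {
  # presence_mat: samples x keys logical with key_id colnames
  pairs <- which(presence_mat, arr.ind = TRUE)
  keys <- colnames(presence_mat)
  parts <- data.table::tstrsplit(keys, "|", fixed = TRUE)
  pres <- data.table::data.table(sample = unname(pairs[, 1]))
  pres[, key := unname(pairs[, 2])]
  structure(list(
    keys = tibble::tibble(key_id = keys, junction_aa = parts[[1]],
                          v_gene = parts[[2]], j_gene = parts[[3]]),
    presence = pres,
    sample_ids = sprintf("s%02d", seq_len(nrow(presence_mat))),
    is_case = is_case), class = "trb_cohort")
}

test_that("presence matrices aggregate nucleotide variants per key", {
  reps <- list(
    s1 = repertoire(data.frame(
      nucleotide_seq = c("AAA", "CCC", "GGG"),
      junction_aa = c("CASSF", "CASSF", "CASQF"),
      v_gene = "TRBV05-06", j_gene = "TRBJ02-07",
      templates = 1L, productive = c(TRUE, TRUE, FALSE)), "s1"),
    s2 = mk_rep(2L, junction = "CASQF"))
  names(reps) <- c("s1", "s2")
  meta <- tibble::tibble(sample_id = c("s1", "s2"),
                         ga_exposed = c(TRUE, FALSE))
  ch <- trb_cohort(reps, meta)
  pm <- presence_matrix(ch)
  # two nucleotide variants of CASSF in s1 collapse to one TRUE entry;
  # the non-productive CASQF row in s1 is excluded
  expect_equal(dim(pm), c(2L, 2L))
  expect_equal(sum(pm["s1", ]), 1L)
  expect_equal(Matrix::rowSums(pm),
               c(s1 = 1, s2 = 1))
})

test_that("wildcard motifs require strict improvement over members", {
  # 14 cases / 20 controls in both cohorts; two member keys that are
  # individually weak but jointly strong
  n_case <- 14L; n_ctrl <- 20L
  keyA <- "CASSAHGGEQYF|TRBV05-06|TRBJ02-07"
  keyB <- "CASSTHGGEQYF|TRBV05-06|TRBJ02-07"
  lone <- "CQQQQQQF|TRBV09|TRBJ01-01"
  mk <- function(seed) {
    set.seed(seed)
    m <- matrix(FALSE, n_case + n_ctrl, 3,
                dimnames = list(NULL, c(keyA, keyB, lone)))
    m[1:7, keyA] <- TRUE           # cases 1-7
    m[8:14, keyB] <- TRUE          # cases 8-14
    m[1:10, lone] <- TRUE          # a strong single key
    make_toy_cohort(m, c(rep(TRUE, n_case), rep(FALSE, n_ctrl)))
  }
  cohorts <- list(c1 = mk(1), c2 = mk(2))
  es <- discover_enhanced_sequences(cohorts, discovery_config())
  # each member alone: 7/14 vs 0/20; union: 14/14 vs 0/20
  p_member <- fet_enrichment(7, n_case, 0, n_ctrl)
  p_union <- fet_enrichment(14, n_case, 0, n_ctrl)
  expect_lt(p_member, 1e-3)   # members are seeds
  expect_gt(p_member, 1e-4)   # members fail the motif bar alone
  expect_lt(p_union, 1e-4)
  expect_true("CASSxHGGEQYF" %in% es$motifs$pattern)
  mo <- es$motifs[es$motifs$pattern == "CASSxHGGEQYF", ]
  expect_setequal(mo$members[[1]], c(keyA, keyB))
  expect_equal(unname(mo$p[[1]]["c1"]), p_union)
  # the lone strong key is an ES key, and its motifs (single-member)
  # cannot strictly improve on it, so no motif is seeded from it
  expect_true(lone %in% es$keys$key_id)
  expect_false(any(grepl("^CQ", es$motifs$pattern)))
})

test_that("wildcards are restricted to interior positions by default", {
  seeds <- "CASSF|TRBV05-06|TRBJ02-07"
  pmat <- matrix(0.5, 1, 2, dimnames = list(seeds, c("c1", "c2")))
  kt <- gatrb:::key_table(seeds)
  m <- matrix(TRUE, 4, 1, dimnames = list(NULL, seeds))
  ch <- make_toy_cohort(m, c(TRUE, TRUE, FALSE, FALSE))
  mot <- expand_wildcards(seeds, list(c1 = ch, c2 = ch), pmat, kt,
                          discovery_config(min_replicated_cohorts = 0L))
  if (nrow(mot)) {
    pos <- regexpr("x", mot$pattern, fixed = TRUE)
    expect_true(all(pos > 1 & pos < nchar(mot$pattern)))
  }
  succeed()
})

test_that("the replication filter keeps only multi-cohort candidates", {
  sig <- matrix(c(TRUE, TRUE, FALSE,
                  TRUE, FALSE, FALSE,
                  TRUE, TRUE, TRUE), nrow = 3, byrow = TRUE,
                dimnames = list(c("k1", "k2", "k3"),
                                c("c1", "c2", "c3")))
  rf <- replicate_filter(sig, 2L)
  expect_setequal(rf$id, c("k1", "k3"))
  expect_setequal(rf$cohorts[["k1"]], c("c1", "c2"))
  expect_length(rf$cohorts[["k3"]], 3L)
  expect_error(replicate_filter(sig[, 1, drop = FALSE], 2L), "exceeds")
})

test_that("discovery output is invariant to sample and key order", {
  cfg <- small_config()
  pool <- gen_key_pool(cfg, seed = 31)
  dc <- gen_discovery_cohorts(pool, cfg, seed = 31)
  es1 <- discover_enhanced_sequences(dc$cohorts)
  perm <- lapply(dc$cohorts, function(ch) {
    set.seed(99)
    ps <- sample(length(ch$sample_ids))
    pk <- sample(nrow(ch$keys))
    inv_k <- order(pk)
    pres <- data.table::data.table(sample = order(ps)[ch$presence$sample])
    pres[, key := inv_k[ch$presence$key]]
    structure(list(
      keys = ch$keys[pk, ],
      presence = pres,
      sample_ids = ch$sample_ids[ps], is_case = ch$is_case[ps]),
      class = "trb_cohort")
  })
  es2 <- discover_enhanced_sequences(perm)
  expect_setequal(es1$keys$key_id, es2$keys$key_id)
  expect_setequal(es1$candidates$key_id, es2$candidates$key_id)
})

test_that("dropping a cohort never adds a replicated key", {
  cfg <- generator_config(
    repertoire = list(mean_unique = 400, pool_size = 6000),
    cohorts = list(
      list(name = "c1", n_cases = 30L, n_controls = 90L,
           hla = list(freq_A = 0.31, freq_B = 0.48, dprime = 0.31)),
      list(name = "c2", n_cases = 30L, n_controls = 90L,
           hla = list(freq_A = 0.33, freq_B = 0.44, dprime = 0.27)),
      list(name = "c3", n_cases = 30L, n_controls = 90L,
           hla = list(freq_A = 0.49, freq_B = 0.47, dprime = 0.10))))
  pool <- gen_key_pool(cfg, seed = 32)
  dc <- gen_discovery_cohorts(pool, cfg, seed = 32)
  es_all <- discover_enhanced_sequences(dc$cohorts)
  for (drop in 1:3) {
    es_sub <- discover_enhanced_sequences(dc$cohorts[-drop])
    expect_true(all(es_sub$keys$key_id %in% es_all$keys$key_id))
  }
})

test_that("the null yields discovery counts within binomial bounds", {
  # no planted signal: exposure has no effect on any key
  cfg <- small_config(planted = list(p_exposed_carrier = 0.02,
                                     synergy = 1))
  for (s in 1:2) {
    pool <- gen_key_pool(cfg, seed = 40 + s)
    dc <- gen_discovery_cohorts(pool, cfg, seed = 40 + s)
    es <- discover_enhanced_sequences(dc$cohorts)
    n_keys <- max(vapply(dc$cohorts, function(ch) nrow(ch$keys),
                         integer(1)))
    # per-cohort candidates are bounded by the binomial upper tail at
    # p = 0.001 (FET is conservative under discreteness)
    expect_lte(nrow(es$candidates),
               stats::qbinom(0.9999, 2L * n_keys, 0.001))
    expect_equal(nrow(es$keys), 0L)
  }
})

test_that("Hamming clustering groups near-identical junctions", {
  hc <- hamming_clusters(c("CASSSHGGEQYF", "CASSTHGGEQYF", "CASSLGF"))
  cl <- hc$clusters$cluster
  expect_equal(cl[1], cl[2])
  expect_false(cl[3] == cl[1])          # different length: never clustered
  cons <- hc$consensus$consensus[hc$consensus$size == 2]
  expect_equal(cons, "CASSxHGGEQYF")
  # published pair one Hamming step apart
  hc2 <- hamming_clusters(c("CASSLGQGAGGYTF", "CASSSGQGAGGYTF"))
  expect_equal(hc2$clusters$cluster[1], hc2$clusters$cluster[2])
  expect_error(hamming_clusters(character()), "no keys")
})
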