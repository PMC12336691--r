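# Small in-code fixtures shared across test files.

mk_rep <- function(templates, productive = rep(TRUE, length(templates)),
                   junction = NULL, v = "TRBV05-06", j = "TRBJ02-07",
                   nt = NULL, id = "s1") {
  n <- length(templates)
  if (is.null(junction)) junction <- sprintf("CASS%02dF", seq_len(n))
  if (is.null(nt)) nt <- sprintf("ACGT%04d", seq_len(n))
  repertoire(data.frame(nucleotide_seq = nt, junction_aa = junction,
                        v_gene = rep_len(v, n), j_gene = rep_len(j, n),
                        templates = templates, productive = productive),
             sample_id = id)
}

# compact generator settings for fast tests
small_config <- function(...) {
  generator_config(
    repertoire = list(mean_unique = 400, pool_size = 6000),
    cohorts = list(
      list(name = "c1", n_cases = 30L, n_controls = 90L,
           hla = list(freq_A = 0.31, freq_B = 0.48, dprime = 0.31)),
      list(name = "c2", n_cases = 30L, n_controls = 90L,
           hla = list(freq_A = 0.33, freq_B = 0.44, dprime = 0.27))),
    ...)
}

# exhaustive one-sided hypergeometric tail oracle
fet_oracle <- function(a, n1, b, n2) {
  m <- a + b
  sum(vapply(a:min(n1, m), function(k)
    stats::dhyper(k, n1, n2, m), numeric(1)))
}

# AUC by exhaustive case/control pair counting with midrank ties
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
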