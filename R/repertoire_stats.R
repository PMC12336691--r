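#' Define a sequence pattern (set of clonotype keys and one-wildcard motifs)
#'
#' A pattern is the unit against which clonal breadth and depth are scored:
#' a set of exact clonotype keys (CDR3 amino-acid junction + V + J) and/or
#' one-wildcard motifs, where the wildcard character `x` matches any single
#' amino acid at that position.
#'
#' @param junction_aa Character vector of junctions; at most one `x` each.
#' @param v_gene,j_gene Character vectors (recycled if length 1).
#' @return Tibble of class `gatrb_pattern` with an `is_motif` column.
#' @export
es_pattern <- function(junction_aa, v_gene, j_gene) {
  n_wild <- lengths(regmatches(junction_aa, gregexpr("x", junction_aa,
                                                     fixed = TRUE)))
  if (any(n_wild > 1L)) stopf("at most one wildcard 'x' per pattern element")
  out <- tibble::tibble(junction_aa = junction_aa,
                        v_gene = rep_len(v_gene, length(junction_aa)),
                        j_gene = rep_len(j_gene, length(junction_aa)),
                        is_motif = n_wild == 1L)
  class(out) <- c("gatrb_pattern", class(out))
  out
}

#' Productive clonality of a repertoire
#'
#' One minus the normalized Shannon entropy of the productive rearrangement
#' frequency distribution: `1 - H / ln(R_unique)` with
#' `H = -sum(f_i ln f_i)`, `f_i = templates_i / T_total`. 0 indicates a
#' maximally even repertoire, 1 a monoclonal one. By convention a repertoire
#' with a single productive rearrangement has clonality 1.
#'
#' @param rep A [repertoire()] object.
#' @return Clonality in `[0, 1]`.
#' @export
productive_clonality <- function(rep) {
  stopifnot(inherits(rep, "trb_repertoire"))
  if (rep$R_unique == 0L) stopf("clonality undefined for empty repertoire")
  if (rep$R_unique == 1L) return(1)
  f <- rep$rearrangements$templates[rep$rearrangements$productive] /
    rep$T_total
  H <- -sum(f * log(f))
  1 - H / log(rep$R_unique)
}

#' Detect treatment-driven clonal expansions
#'
#' An expansion is a nucleotide-level rearrangement absent from the baseline
#' sample but ranked within the top `k` most prevalent rearrangements of the
#' treated sample. Ranking is by descending template count with ties broken
#' by lexicographic nucleotide sequence, and exactly `k` rows are eligible.
#'
#' @param baseline,treated [repertoire()] objects from the same subject.
#' @param k Size of the prevalence window (default 100).
#' @param productive_only If `TRUE`, restrict eligibility to productive
#'   rearrangements; the default keeps both, since the rule is defined at
#'   nucleotide level.
#' @return Tibble with `nucleotide_seq`, `junction_aa`, `treated_rank`,
#'   `treated_templates`, one row per expansion.
#' @export
detect_expansions <- function(baseline, treated, k = 100L,
                              productive_only = FALSE) {
  stopifnot(inherits(baseline, "trb_repertoire"),
            inherits(treated, "trb_repertoire"))
  if (k < 1L) stopf("k must be >= 1")
  re <- treated$rearrangements
  if (productive_only) re <- re[re$productive, ]
  ord <- order(-re$templates, re$nucleotide_seq)
  re <- re[ord, ]
  re$treated_rank <- seq_len(nrow(re))
  top <- re[seq_len(min(k, nrow(re))), ]
  new <- !top$nucleotide_seq %in% baseline$rearrangements$nucleotide_seq
  out <- top[new, c("nucleotide_seq", "junction_aa", "treated_rank",
                    "templates")]
  names(out)[4] <- "treated_templates"
  tibble::as_tibble(out)
}

#' Score a repertoire against a sequence pattern (clonal breadth and depth)
#'
#' Breadth is the number of unique productive rearrangements matching the
#' pattern as a fraction of all unique productive rearrangements; depth is
#' the number of matching templates as a fraction of all productive
#' templates. A rearrangement matches an exact key if its
#' (junction, V, J) triple equals it, and matches a motif if it has the
#' same V, J and junction length and agrees at every non-wildcard position.
#'
#' @param rep A [repertoire()] object.
#' @param pattern An [es_pattern()].
#' @return One-row tibble: `sample_id`, `n_matched`, `breadth`, `depth`,
#'   `breadth_per_1e6`.
#' @export
score_pattern <- function(rep, pattern) {
  stopifnot(inherits(rep, "trb_repertoire"))
  if (NROW(pattern) == 0L) stopf("empty pattern")
  re <- rep$rearrangements[rep$rearrangements$productive, ]
  if (nrow(re) == 0L)
    return(tibble::tibble(sample_id = rep$sample_id, n_matched = 0L,
                          breadth = 0, depth = 0, breadth_per_1e6 = 0))
  hit <- matches_pattern(re$junction_aa, re$v_gene, re$j_gene, pattern)
  n_m <- sum(hit)
  breadth <- n_m / rep$R_unique
  depth <- sum(re$templates[hit]) / rep$T_total
  tibble::tibble(sample_id = rep$sample_id, n_matched = n_m,
                 breadth = breadth, depth = depth,
                 breadth_per_1e6 = breadth * 1e6)
}

# Logical vector: does each (junction, v, j) match any pattern element?
matches_pattern <- function(junction_aa, v_gene, j_gene, pattern) {
  hit <- rep(FALSE, length(junction_aa))
  exact <- pattern[!pattern$is_motif, ]
  if (nrow(exact))
    hit <- key_id(junction_aa, v_gene, j_gene) %in%
      key_id(exact$junction_aa, exact$v_gene, exact$j_gene)
  motifs <- pattern[pattern$is_motif, ]
  for (i in seq_len(nrow(motifs))) {
    cand <- !hit & v_gene == motifs$v_gene[i] & j_gene == motifs$j_gene[i] &
      nchar(junction_aa) == nchar(motifs$junction_aa[i])
    if (any(cand)) {
      rx <- paste0("^", gsub("x", ".", motifs$junction_aa[i], fixed = TRUE),
                   "$")
      hit[cand] <- grepl(rx, junction_aa[cand])
    }
  }
  hit
}

#' Score many repertoires against named patterns
#'
#' @param repertoires List of [repertoire()] objects.
#' @param patterns Named list of [es_pattern()] objects.
#' @return Tibble of per-sample, per-pattern scores with a `pattern_id`
#'   column.
#' @export
score_patterns <- function(repertoires, patterns) {
  stopifnot(length(patterns) > 0, !is.null(names(patterns)))
  out <- lapply(names(patterns), function(pid) {
    sc <- dplyr::bind_rows(lapply(repertoires, score_pattern,
                                  pattern = patterns[[pid]]))
    sc$pattern_id <- pid
    sc
  })
  dplyr::bind_rows(out)[, c("sample_id", "pattern_id", "n_matched",
                            "breadth", "depth", "breadth_per_1e6")]
}
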