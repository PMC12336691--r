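#' Compact cohort representation for clonotype discovery
#'
#' The discovery layer operates on presence/absence of clonotype keys per
#' sample. `trb_cohort()` reduces a list of repertoires plus metadata to a
#' key table and a sample-by-key presence pair list; several nucleotide
#' variants of one amino-acid key collapse to a single presence entry.
#'
#' @param repertoires Named list of [repertoire()] objects.
#' @param meta Tibble with `sample_id` and logical `ga_exposed` marking
#'   cases.
#' @return Object of class `trb_cohort`: list with `keys` (tibble of unique
#'   keys), `presence` (data.table of `sample`/`key` integer pairs),
#'   `sample_ids`, `is_case`.
#' @export
trb_cohort <- function(repertoires, meta) {
  stopifnot(all(meta$sample_id %in% names(repertoires)))
  is_case <- as.logical(meta$ga_exposed)
  if (!any(is_case) || all(is_case))
    stopf("cohort needs at least one case and one control")
  pairs <- data.table::rbindlist(lapply(seq_len(nrow(meta)), function(i) {
    re <- repertoires[[meta$sample_id[i]]]$rearrangements
    re <- re[re$productive, ]
    data.table::data.table(
      sample = i,
      key_id = unique(key_id(re$junction_aa, re$v_gene, re$j_gene)))
  }))
  keys <- unique(pairs$key_id)
  pairs[, key := match(key_id, keys)]
  parts <- data.table::tstrsplit(keys, "|", fixed = TRUE)
  structure(list(
    keys = tibble::tibble(key_id = keys, junction_aa = parts[[1]],
                          v_gene = parts[[2]], j_gene = parts[[3]]),
    presence = pairs[, c("sample", "key")],
    sample_ids = meta$sample_id, is_case = is_case),
    class = "trb_cohort")
}

# Fast path used by the generator: pool-index presence lists.
trb_cohort_from_indices <- function(index_list, pool, sample_ids, is_case) {
  used <- sort(unique(unlist(index_list)))
  pairs <- data.table::data.table(
    sample = rep(seq_along(index_list), lengths(index_list)),
    pool_idx = unlist(index_list))
  # collapse nucleotide variants of one amino-acid key
  kid <- pool$key_id[used]
  ukeys <- unique(kid)
  remap <- match(pool$key_id, ukeys)
  pairs[, key := remap[pool_idx]]
  pairs <- unique(pairs[, c("sample", "key")])
  ki <- match(ukeys, pool$key_id)
  structure(list(
    keys = tibble::tibble(key_id = ukeys,
                          junction_aa = pool$junction_aa[ki],
                          v_gene = pool$v_gene[ki], j_gene = pool$j_gene[ki]),
    presence = pairs, sample_ids = sample_ids,
    is_case = as.logical(is_case)), class = "trb_cohort")
}

#' @export
print.trb_cohort <- function(x, ...) {
  cat(sprintf("<trb_cohort> %d samples (%d cases / %d controls), %d keys\n",
              length(x$sample_ids), sum(x$is_case), sum(!x$is_case),
              nrow(x$keys)))
  invisible(x)
}

#' Sample-by-key presence matrix
#'
#' @param cohort A [trb_cohort()].
#' @return Sparse logical [Matrix::sparseMatrix()] (samples x keys), with
#'   sample ids and key ids as dimnames. An entry is `TRUE` iff the sample
#'   contains at least one productive rearrangement with that exact
#'   (junction, V, J).
#' @export
presence_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "trb_cohort"))
  Matrix::sparseMatrix(
    i = cohort$presence$sample, j = cohort$presence$key,
    x = TRUE,
    dims = c(length(cohort$sample_ids), nrow(cohort$keys)),
    dimnames = list(cohort$sample_ids, cohort$keys$key_id))
}

#' One-sided Fisher exact enrichment p-value
#'
#' Upper hypergeometric tail probability `P[X >= cases_present]` for
#' enrichment of a clonotype in cases, given fixed margins. Vectorized over
#' tables.
#'
#' @param cases_present,controls_present Samples containing the key.
#' @param cases_total,controls_total Group sizes.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
fet_enrichment <- function(cases_present, cases_total,
                           controls_present, controls_total) {
  if (any(c(cases_present, cases_total, controls_present,
            controls_total) < 0))
    stopf("counts must be nonnegative")
  if (any(cases_present > cases_total) ||
      any(controls_present > controls_total))
    stopf("present counts exceed group sizes")
  phyper(cases_present - 1, cases_present + controls_present,
         cases_total + controls_total - cases_present - controls_present,
         cases_total, lower.tail = FALSE)
}

#' Discovery configuration
#'
#' @param p_seq Per-cohort significance threshold for exact keys (default
#'   0.001).
#' @param p_motif Combined-p threshold for one-wildcard motifs (default
#'   0.0001); a motif must also beat the best individual member p-value.
#' @param min_replicated_cohorts Cohorts a candidate must be significant in
#'   (default 2).
#' @param interior_only If `TRUE` (default) wildcards are restricted to
#'   interior junction positions, preserving the conserved C/F flanks.
#' @param fdr `"none"` (default, relying on the threshold + replication
#'   dual filter) or `"BH"` to additionally report Benjamini-Hochberg
#'   adjusted per-cohort p-values.
#' @return List of class `gatrb_discovery_config`.
#' @export
discovery_config <- function(p_seq = 1e-3, p_motif = 1e-4,
                             min_replicated_cohorts = 2L,
                             interior_only = TRUE,
                             fdr = c("none", "BH")) {
  fdr <- match.arg(fdr)
  if (p_seq <= 0 || p_seq >= 1 || p_motif <= 0 || p_motif >= 1)
    stopf("thresholds must lie in (0, 1)")
  structure(list(p_seq = p_seq, p_motif = p_motif,
                 min_replicated_cohorts = as.integer(min_replicated_cohorts),
                 interior_only = interior_only, fdr = fdr),
            class = "gatrb_discovery_config")
}

# per-cohort presence counts for every key observed in the cohort
cohort_key_counts <- function(cohort) {
  dt <- data.table::as.data.table(cohort$presence)
  dt[, case := cohort$is_case[sample]]
  cnt <- dt[, list(a = sum(case), b = sum(!case)), by = "key"]
  cnt[, key_id := cohort$keys$key_id[key]]
  cnt
}

#' Discover Enhanced Sequences across cohorts
#'
#' Implements case/control clonotype discovery: per-cohort one-sided Fisher
#' exact enrichment of every observed key, one-wildcard motif expansion
#' seeded from significant keys, and a multi-cohort replication filter. No
#' multiplicity correction is applied by default; stringency comes from the
#' dual filter of a low p threshold plus replication in at least
#' `min_replicated_cohorts` cohorts.
#'
#' @param cohorts Named list of [trb_cohort()] objects (>= 2).
#' @param config A [discovery_config()].
#' @return List of class `gatrb_es_set`: `keys` and `motifs` tibbles of
#'   replicated Enhanced Sequences (per-cohort 2x2 counts and p-values,
#'   replication record), plus `candidates` (all per-cohort significant
#'   keys before replication) and the config.
#' @export
discover_enhanced_sequences <- function(cohorts,
                                        config = discovery_config()) {
  stopifnot(length(cohorts) >= 1, all(vapply(cohorts, inherits,
                                             logical(1), "trb_cohort")))
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  if (length(cohorts) < config$min_replicated_cohorts)
    stopf("min_replicated_cohorts (%d) exceeds number of cohorts (%d)",
          config$min_replicated_cohorts, length(cohorts))

  counts <- lapply(cohorts, cohort_key_counts)
  n_case <- vapply(cohorts, function(ch) sum(ch$is_case), integer(1))
  n_ctrl <- vapply(cohorts, function(ch) sum(!ch$is_case), integer(1))
  for (i in seq_along(counts))
    counts[[i]][, p := fet_enrichment(a, n_case[i], b, n_ctrl[i])]

  all_keys <- unique(unlist(lapply(counts, `[[`, "key_id")))
  pmat <- matrix(1, nrow = length(all_keys), ncol = length(cohorts),
                 dimnames = list(all_keys, names(cohorts)))
  amat <- bmat <- matrix(0L, nrow = length(all_keys), ncol = length(cohorts),
                         dimnames = list(all_keys, names(cohorts)))
  for (i in seq_along(counts)) {
    ix <- match(counts[[i]]$key_id, all_keys)
    pmat[ix, i] <- counts[[i]]$p
    amat[ix, i] <- counts[[i]]$a
    bmat[ix, i] <- counts[[i]]$b
  }
  sig <- pmat < config$p_seq
  seed_keys <- all_keys[rowSums(sig) >= 1L]

  key_tab <- key_table(all_keys)
  motifs <- expand_wildcards(seed_keys, cohorts, pmat, key_tab, config)

  rep_keys <- replicate_filter(sig, config$min_replicated_cohorts)
  keys_out <- key_tab[match(rep_keys$id, key_tab$key_id), ]
  keys_out$p <- lapply(match(rep_keys$id, all_keys), function(i)
    setNames(pmat[i, ], names(cohorts)))
  keys_out$cases_present <- lapply(match(rep_keys$id, all_keys),
                                   function(i) amat[i, ])
  keys_out$controls_present <- lapply(match(rep_keys$id, all_keys),
                                      function(i) bmat[i, ])
  keys_out$replicated_cohorts <- rep_keys$cohorts
  keys_out$n_replicated <- lengths(rep_keys$cohorts)

  cand <- key_tab[match(seed_keys, key_tab$key_id), ]
  cand$min_p <- apply(pmat[match(seed_keys, all_keys), , drop = FALSE],
                      1, min)
  if (config$fdr == "BH") {
    padj <- apply(pmat, 2, p.adjust, method = "BH")
    keys_out$p_adj <- lapply(match(rep_keys$id, all_keys), function(i)
      setNames(padj[i, ], names(cohorts)))
  }
  structure(list(keys = keys_out, motifs = motifs, candidates = cand,
                 cohort_sizes = tibble::tibble(
                   cohort = names(cohorts), n_cases = n_case,
                   n_controls = n_ctrl),
                 config = config), class = "gatrb_es_set")
}

#' @export
print.gatrb_es_set <- function(x, ...) {
  cat(sprintf("<gatrb_es_set> %d replicated keys, %d replicated motifs (%d candidate keys)\n",
              nrow(x$keys), nrow(x$motifs), nrow(x$candidates)))
  invisible(x)
}

key_table <- function(key_ids) {
  parts <- data.table::tstrsplit(key_ids, "|", fixed = TRUE)
  tibble::tibble(key_id = key_ids, junction_aa = parts[[1]],
                 v_gene = parts[[2]], j_gene = parts[[3]])
}

#' Expand significant keys into one-wildcard motifs
#'
#' For every seed key and every eligible junction position, forms the
#' one-wildcard motif, collects all observed member keys (same V, J and
#' length, equal at non-wildcard positions), and computes the motif's
#' combined p-value per cohort as a one-sided Fisher exact test on the
#' union presence of its members. A motif is significant in a cohort when
#' its combined p is below `p_motif` and strictly below the p-value of
#' every individual member in that cohort; motifs significant in at least
#' `min_replicated_cohorts` cohorts are retained.
#'
#' @param seed_keys Character vector of key ids (`junction|V|J`).
#' @param cohorts Named list of [trb_cohort()] objects.
#' @param pmat Per-key, per-cohort p-value matrix (rownames = key ids).
#' @param key_tab Tibble of all observed keys (from the same cohorts).
#' @param config A [discovery_config()].
#' @return Tibble of motifs with members, per-cohort p-values and the
#'   replication record.
#' @export
expand_wildcards <- function(seed_keys, cohorts, pmat, key_tab,
                             config = discovery_config()) {
  empty <- tibble::tibble(pattern = character(), v_gene = character(),
                          j_gene = character(), members = list(),
                          p = list(), replicated_cohorts = list(),
                          n_replicated = integer())
  if (length(seed_keys) == 0L) return(empty)
  seeds <- key_table(seed_keys)
  mask_at <- function(s, p) {
    substr(s, p, p) <- "x"
    s
  }
  cand <- data.table::rbindlist(lapply(seq_len(nrow(seeds)), function(i) {
    jn <- seeds$junction_aa[i]
    L <- nchar(jn)
    pos <- if (config$interior_only) seq(2L, L - 1L) else seq_len(L)
    data.table::data.table(pattern = vapply(pos, mask_at, "", s = jn),
                           v_gene = seeds$v_gene[i],
                           j_gene = seeds$j_gene[i])
  }))
  cand <- unique(cand)

  # one-wildcard masked variants of every observed key of a relevant
  # length, joined against the candidate motifs to get the member map
  kt <- data.table::as.data.table(key_tab)
  kt[, len := nchar(junction_aa)]
  lens <- unique(nchar(cand$pattern))
  masked <- data.table::rbindlist(lapply(lens, function(L) {
    sub <- kt[len == L]
    if (nrow(sub) == 0L) return(NULL)
    pos <- if (config$interior_only) seq(2L, L - 1L) else seq_len(L)
    data.table::rbindlist(lapply(pos, function(p)
      data.table::data.table(pattern = mask_at(sub$junction_aa, p),
                             v_gene = sub$v_gene, j_gene = sub$j_gene,
                             key_id = sub$key_id)))
  }))
  mm <- masked[cand, on = c("pattern", "v_gene", "j_gene"), nomatch = 0L]
  if (nrow(mm) == 0L) return(empty)
  mm[, mid := paste(pattern, v_gene, j_gene, sep = "|")]
  mids <- unique(mm$mid)

  n_case <- vapply(cohorts, function(ch) sum(ch$is_case), integer(1))
  n_ctrl <- vapply(cohorts, function(ch) sum(!ch$is_case), integer(1))
  pv <- matrix(1, nrow = length(mids), ncol = length(cohorts),
               dimnames = list(mids, names(cohorts)))
  ok <- matrix(FALSE, nrow = length(mids), ncol = length(cohorts),
               dimnames = list(mids, names(cohorts)))
  for (ci in seq_along(cohorts)) {
    ch <- cohorts[[ci]]
    mc <- mm[, list(mid, key_id)]
    mc[, key := match(key_id, ch$keys$key_id)]
    mc <- mc[!is.na(key)]
    if (nrow(mc) == 0L) next
    px <- merge(ch$presence, mc[, list(mid, key)], by = "key",
                allow.cartesian = TRUE)
    hits <- unique(px[, list(mid, sample)])
    hits[, case := ch$is_case[sample]]
    cnt <- hits[, list(a = sum(case), b = sum(!case)), by = "mid"]
    pci <- fet_enrichment(cnt$a, n_case[ci], cnt$b, n_ctrl[ci])
    pv[cnt$mid, ci] <- pci
    # strict improvement over every member's individual p in this cohort
    mp <- data.table::data.table(key_id = rownames(pmat), p = pmat[, ci])
    minp <- merge(mm[, list(mid, key_id)], mp, by = "key_id")[
      , list(minp = min(p)), by = "mid"]
    ok[minp$mid, ci] <- pv[minp$mid, ci] < config$p_motif &
      pv[minp$mid, ci] < minp$minp
  }
  keep <- rowSums(ok) >= config$min_replicated_cohorts
  if (!any(keep)) return(empty)
  members_by_mid <- split(mm$key_id, mm$mid)
  out <- lapply(which(keep), function(i) {
    mid <- mids[i]
    parts <- strsplit(mid, "|", fixed = TRUE)[[1]]
    tibble::tibble(pattern = parts[1], v_gene = parts[2],
                   j_gene = parts[3],
                   members = list(unique(members_by_mid[[mid]])),
                   p = list(pv[i, ]),
                   replicated_cohorts = list(names(cohorts)[ok[i, ]]),
                   n_replicated = sum(ok[i, ]))
  })
  dplyr::bind_rows(out)
}

#' Replication filter
#'
#' Retains candidates significant in at least `min_replicated` cohorts and
#' records which cohorts replicated each.
#'
#' @param sig Logical matrix candidates x cohorts (dimnames required).
#' @param min_replicated Minimum replicating cohorts.
#' @return List with `id` (retained rownames) and `cohorts` (list of
#'   replicating cohort names per retained candidate).
#' @export
replicate_filter <- function(sig, min_replicated = 2L) {
  if (ncol(sig) < min_replicated)
    stopf("min_replicated (%d) exceeds number of cohorts (%d)",
          min_replicated, ncol(sig))
  keep <- rowSums(sig) >= min_replicated
  list(id = rownames(sig)[keep],
       cohorts = apply(sig[keep, , drop = FALSE], 1, function(r)
         colnames(sig)[r], simplify = FALSE))
}

#' Hamming-distance clustering of clonotype junctions
#'
#' Connected components of the graph joining same-length junctions at
#' Hamming distance at most `d`, with a per-cluster consensus string
#' carrying `x` at non-unanimous positions.
#'
#' @param keys Tibble with a `junction_aa` column (e.g. the `keys` element
#'   of a discovery result), or a character vector of junctions.
#' @param d Maximum Hamming distance for an edge (default 1).
#' @return List with `clusters` (tibble: `junction_aa`, `cluster`) and
#'   `consensus` (tibble: `cluster`, `size`, `consensus`).
#' @export
hamming_clusters <- function(keys, d = 1L) {
  jn <- if (is.character(keys)) keys else keys$junction_aa
  if (length(jn) == 0L) stopf("no keys to cluster")
  jn <- unique(jn)
  edges <- list()
  by_len <- split(seq_along(jn), nchar(jn))
  for (grp in by_len) {
    if (length(grp) < 2L) next
    chars <- do.call(rbind, strsplit(jn[grp], ""))
    for (i in seq_len(length(grp) - 1L)) {
      dh <- rowSums(chars[(i + 1L):length(grp), , drop = FALSE] !=
                      matrix(chars[i, ], nrow = length(grp) - i,
                             ncol = ncol(chars), byrow = TRUE))
      hit <- which(dh <= d)
      if (length(hit))
        edges[[length(edges) + 1L]] <-
          cbind(grp[i], grp[i + hit])
    }
  }
  g <- igraph::make_empty_graph(n = length(jn), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  cons <- vapply(split(jn, comp), function(members) {
    if (length(members) == 1L) return(members)
    chars <- do.call(rbind, strsplit(members, ""))
    apply(chars, 2, function(col)
      if (length(unique(col)) == 1L) col[1] else "x") |>
      paste(collapse = "")
  }, character(1))
  list(clusters = tibble::tibble(junction_aa = jn, cluster = unname(comp)),
       consensus = tibble::tibble(cluster = as.integer(names(cons)),
                                  size = as.integer(table(comp)),
                                  consensus = unname(cons)))
}

#' @importFrom stats p.adjust
NULL
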