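#' Per-sample presence of candidate clonotype keys
#'
#' @param repertoires List of [repertoire()] objects.
#' @param keys Tibble with `junction_aa`, `v_gene`, `j_gene` (exact keys).
#' @return Logical matrix, samples x keys; rownames are sample ids.
#' @export
feature_presence <- function(repertoires, keys) {
  kid <- key_id(keys$junction_aa, keys$v_gene, keys$j_gene)
  out <- matrix(FALSE, nrow = length(repertoires), ncol = length(kid),
                dimnames = list(vapply(repertoires, `[[`, "", "sample_id"),
                                kid))
  for (i in seq_along(repertoires)) {
    re <- repertoires[[i]]$rearrangements
    re <- re[re$productive, ]
    out[i, ] <- kid %in% key_id(re$junction_aa, re$v_gene, re$j_gene)
  }
  out
}

# Mann-Whitney AUC via midranks.
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stopf("both classes required")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train an HLA carrier imputation model from repertoire features
#'
#' Fits the two-covariate logistic model for carriage of one HLA allele:
#' the count of allele-associated feature clonotypes present in the
#' repertoire, and the log of the number of unique productive
#' rearrangements (which controls for repertoire sampling depth). Feature
#' clonotypes are selected among the candidates by one-sided Fisher exact
#' carrier enrichment at `select_p`. Performance is reported as the
#' cross-validated AUROC over `folds` folds (feature selection repeated
#' inside each training fold).
#'
#' @param presence Logical matrix samples x candidate keys (see
#'   [feature_presence()]), or a list of [repertoire()] objects together
#'   with `candidate_keys`.
#' @param r_unique Integer vector of unique productive rearrangement counts
#'   per sample (computed from the repertoires when those are supplied).
#' @param carrier Logical vector of known carrier status.
#' @param allele Allele name stored in the model.
#' @param candidate_keys Tibble of candidate keys when `presence` is a
#'   repertoire list.
#' @param folds Number of cross-validation folds (default 5).
#' @param select_p Feature-selection FET threshold (default 1e-4).
#' @param seed Optional seed for fold assignment.
#' @return Object of class `hla_model`: allele, selected `feature_keys`,
#'   coefficients (`intercept`, `coef_count`, `coef_logR`), and `cv_auroc`.
#' @export
train_hla_model <- function(presence, carrier, r_unique = NULL,
                            allele = "allele", candidate_keys = NULL,
                            folds = 5L, select_p = 1e-4, seed = NULL) {
  if (is.list(presence) && !is.matrix(presence)) {
    reps <- presence
    if (is.null(candidate_keys)) stopf("candidate_keys required with repertoires")
    r_unique <- vapply(reps, `[[`, integer(1), "R_unique")
    presence <- feature_presence(reps, candidate_keys)
  }
  presence <- as.matrix(presence) > 0
  carrier <- as.logical(carrier)
  if (length(unique(carrier)) < 2L) stopf("both carriers and non-carriers required")
  if (is.null(r_unique) || length(r_unique) != nrow(presence))
    stopf("r_unique must be given for every sample")
  if (any(r_unique < 1L)) stopf("r_unique must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  select_features <- function(rows) {
    a <- colSums(presence[rows & carrier, , drop = FALSE])
    b <- colSums(presence[rows & !carrier, , drop = FALSE])
    p <- fet_enrichment(a, sum(rows & carrier), b, sum(rows & !carrier))
    which(p < select_p)
  }
  fit_on <- function(rows, feats) {
    df <- data.frame(y = carrier[rows],
                     n_feat = rowSums(presence[rows, feats, drop = FALSE]),
                     logR = log(r_unique[rows]))
    suppressWarnings(glm(y ~ n_feat + logR, family = binomial(), data = df))
  }

  fold <- sample(rep(seq_len(folds), length.out = nrow(presence)))
  cv_pred <- rep(NA_real_, nrow(presence))
  for (f in seq_len(folds)) {
    tr <- fold != f
    feats <- select_features(tr)
    if (length(feats) == 0L) { cv_pred[!tr] <- 0.5; next }
    m <- fit_on(tr, feats)
    nd <- data.frame(n_feat = rowSums(presence[!tr, feats, drop = FALSE]),
                     logR = log(r_unique[!tr]))
    cv_pred[!tr] <- predict(m, newdata = nd, type = "response")
  }
  cv_auroc <- rank_auc(cv_pred, carrier)

  feats <- select_features(rep(TRUE, nrow(presence)))
  if (length(feats) == 0L) stopf("no feature keys pass selection at p < %g",
                                 select_p)
  m <- fit_on(rep(TRUE, nrow(presence)), feats)
  co <- coef(m)
  structure(list(
    allele = allele,
    feature_keys = colnames(presence)[feats],
    intercept = unname(co[1]), coef_count = unname(co["n_feat"]),
    coef_logR = unname(co["logR"]),
    cv_auroc = cv_auroc, n_train = nrow(presence)),
    class = "hla_model")
}

#' @export
print.hla_model <- function(x, ...) {
  cat(sprintf(
    "<hla_model> %s: %d feature keys; logit = %.3f + %.3f*count + %.3f*logR; CV AUROC %.3f\n",
    x$allele, length(x$feature_keys), x$intercept, x$coef_count,
    x$coef_logR, x$cv_auroc))
  invisible(x)
}

#' Impute HLA carrier status for a repertoire
#'
#' @param model An [train_hla_model()] fit.
#' @param rep A [repertoire()] object, or a list with `n_feat` (feature
#'   keys present) and `r_unique`.
#' @param threshold Probability cut for the positive label (default 0.5).
#' @return List with `carrier` (logical) and `probability`.
#' @export
impute_hla <- function(model, rep, threshold = 0.5) {
  stopifnot(inherits(model, "hla_model"))
  if (inherits(rep, "trb_repertoire")) {
    if (rep$R_unique == 0L) stopf("imputation undefined for empty repertoire")
    re <- rep$rearrangements[rep$rearrangements$productive, ]
    n_feat <- sum(model$feature_keys %in%
                    key_id(re$junction_aa, re$v_gene, re$j_gene))
    r_unique <- rep$R_unique
  } else {
    n_feat <- rep$n_feat; r_unique <- rep$r_unique
    if (any(r_unique < 1L)) stopf("imputation undefined for empty repertoire")
  }
  pr <- plogis(model$intercept + model$coef_count * n_feat +
                 model$coef_logR * log(r_unique))
  list(carrier = pr >= threshold, probability = pr)
}

#' Serialize / restore an HLA model as JSON
#'
#' @param model An `hla_model`.
#' @param path Output (or input) JSON path.
#' @return `write_hla_model` returns `path` invisibly; `read_hla_model`
#'   returns the model.
#' @export
write_hla_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hla_model
#' @export
read_hla_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "hla_model")
}

#' Assign discovered Enhanced Sequences to HLA alleles
#'
#' Each ES key is tested against each allele label (typed or imputed) with
#' a one-sided Fisher exact test of presence in carriers vs non-carriers;
#' the minimal-p allele is selected. Motifs take the most significant
#' allele among their member keys. Categories: `assigned` (p < `p_assigned`),
#' `uncertain` (p < `p_uncertain`), otherwise `unassigned`. Ties in the
#' minimal p are reported (comma-separated), not broken silently.
#'
#' @param es A `gatrb_es_set` from [discover_enhanced_sequences()], or a
#'   tibble of keys with `key_id`, `junction_aa`, `v_gene`, `j_gene`.
#' @param cohort A [trb_cohort()] covering the samples used for assignment.
#' @param hla_labels Tibble: `sample_id` plus one logical column per allele
#'   (no missing values; typed labels should override imputed ones
#'   upstream).
#' @param p_assigned,p_uncertain Category thresholds (1e-4, 1e-3).
#' @return Tibble with `target`, `type`, `allele`, `p`, `category`.
#' @export
assign_hla <- function(es, cohort, hla_labels,
                       p_assigned = 1e-4, p_uncertain = 1e-3) {
  stopifnot(inherits(cohort, "trb_cohort"))
  alleles <- setdiff(names(hla_labels), "sample_id")
  if (length(alleles) == 0L) stopf("hla_labels needs allele columns")
  ix <- match(cohort$sample_ids, hla_labels$sample_id)
  if (anyNA(ix))
    stopf("unlabelled sample(s): %s",
          paste(cohort$sample_ids[is.na(ix)], collapse = ", "))
  lab <- as.matrix(hla_labels[ix, alleles, drop = FALSE])
  if (anyNA(lab)) stopf("hla_labels contains missing values")

  keys <- if (inherits(es, "gatrb_es_set")) es$keys else es
  motifs <- if (inherits(es, "gatrb_es_set")) es$motifs else NULL

  key_p <- function(kid) {
    ki <- match(kid, cohort$keys$key_id)
    present <- logical(length(cohort$sample_ids))
    if (!is.na(ki))
      present[cohort$presence$sample[cohort$presence$key == ki]] <- TRUE
    vapply(alleles, function(al) {
      carr <- lab[, al]
      fet_enrichment(sum(present & carr), sum(carr),
                     sum(present & !carr), sum(!carr))
    }, numeric(1))
  }

  assign_one <- function(pv) {
    pmin_ <- min(pv)
    winners <- alleles[pv == pmin_]
    category <- if (pmin_ < p_assigned) "assigned"
      else if (pmin_ < p_uncertain) "uncertain" else "unassigned"
    if (length(winners) > 1L && category == "assigned") category <- "uncertain"
    tibble::tibble(allele = paste(winners, collapse = ","), p = pmin_,
                   category = category)
  }

  out <- list()
  for (i in seq_len(NROW(keys))) {
    res <- assign_one(key_p(keys$key_id[i]))
    out[[length(out) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(target = keys$key_id[i], type = "key"), res)
  }
  for (i in seq_len(NROW(motifs))) {
    member_p <- do.call(rbind, lapply(motifs$members[[i]], key_p))
    pv <- apply(member_p, 2, min)
    res <- assign_one(pv)
    out[[length(out) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(target = key_id(motifs$pattern[i], motifs$v_gene[i],
                                     motifs$j_gene[i]), type = "motif"), res)
  }
  dplyr::bind_rows(out)
}
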