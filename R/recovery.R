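#' Build trial subject metadata from arm-by-HLA group sizes
#'
#' Allocates subjects to treatment arms with fixed HLA-A carrier counts per
#' arm (the design of the published trial re-analyses), draws the second
#' allele conditionally on the first to honour the configured carrier
#' linkage disequilibrium, and attaches subject covariates.
#'
#' @param arms Named list of `c(n_Aneg, n_Apos)` pairs, names taken as
#'   treatment arms (e.g. `list(IFN = c(165, 74), GA = c(64, 32))`).
#' @param config A [generator_config()].
#' @param seed Optional seed.
#' @return Subject tibble suitable for [gen_clinical()].
#' @export
gen_trial_meta <- function(arms, config = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(arms), function(arm) {
    n <- arms[[arm]]
    tibble::tibble(treatment_arm = arm,
                   carrier_A = rep(c(FALSE, TRUE), n))
  })
  meta <- dplyr::bind_rows(rows)
  n <- nrow(meta)
  fA <- config$hla$freq_A; fB <- config$hla$freq_B
  pAB <- feasible_carrier_joint(fA, fB, config$hla$dprime)
  pB_given_A <- pAB / fA
  pB_given_notA <- (fB - pAB) / (1 - fA)
  meta$carrier_B <- runif(n) < ifelse(meta$carrier_A, pB_given_A,
                                      pB_given_notA)
  meta$subject_id <- sprintf("subj%04d", seq_len(n))
  dplyr::bind_cols(meta, gen_covariates(n))
}

#' Simulate and refit treatment-by-HLA interaction hazard ratios
#'
#' Parameter-recovery experiment for the clinical interaction models:
#' relapse data are generated at the configured effect sizes and arm
#' allocation, the corresponding Cox model is refitted with the full
#' covariate set, and the estimated interaction hazard ratio is collected
#' per replicate.
#'
#' @param arms Arm allocation as in [gen_trial_meta()].
#' @param config A [generator_config()]; the planted interaction hazard
#'   ratios live in `config$clinical`.
#' @param model `"ag"` fits the Andersen-Gill recurrent-event model;
#'   `"first"` fits the time-to-first-event Cox model.
#' @param term Coefficient whose hazard ratio is collected. Defaults to the
#'   GA-by-HLA-A interaction for `"first"` and the (GA+IFN)-by-HLA-A
#'   interaction for `"ag"`.
#' @param n_reps Number of simulation replicates.
#' @param seed Integer seed (fanned out per replicate).
#' @return Tibble with one row per replicate: `rep`, `hr`, `se`,
#'   `ci_lower`, `ci_upper`, `covered` (does the 95% CI contain the planted
#'   value).
#' @export
recover_interaction_hr <- function(arms, config = generator_config(),
                                   model = c("ag", "first"),
                                   term = NULL, n_reps = 50L, seed = 1L) {
  model <- match.arg(model)
  has_gaifn <- "GA+IFN" %in% names(arms)
  base_cov <- c("age_norm", "sexmTRUE", "ga", "carrier_A", "carrier_B",
                "duration_norm")
  if (is.null(term))
    term <- if (model == "ag" && has_gaifn) "gaifnTRUE:carrier_ATRUE"
      else "gaTRUE:carrier_ATRUE"
  planted <- if (term == "gaifnTRUE:carrier_ATRUE")
    config$clinical$hr_inter_gaifn_A else config$clinical$hr_inter_ga_A

  covs <- c("age_norm", "sexm", "duration_norm", "ga")
  if (has_gaifn) covs <- c(covs, "gaifn")
  covs <- c(covs, "carrier_A", "carrier_B", "ga:carrier_A", "ga:carrier_B")
  if (has_gaifn) covs <- c(covs, "gaifn:carrier_A", "gaifn:carrier_B")

  out <- lapply(seq_len(n_reps), function(r) {
    meta <- gen_trial_meta(arms, config, seed = child_seed(seed, r))
    sim <- gen_clinical(meta, config)
    cov <- sim$covariates
    fit <- if (model == "ag") {
      d <- dplyr::inner_join(sim$recurrent, cov, by = "subject_id")
      fit_cox_ag(d, covs)
    } else {
      d <- dplyr::inner_join(sim$first_event, cov, by = "subject_id")
      fit_cox(d, covs)
    }
    co <- fit$coefficients
    i <- match(term, co$term)
    if (is.na(i)) stopf("term %s not in fitted model (have: %s)", term,
                        paste(co$term, collapse = ", "))
    tibble::tibble(rep = r, hr = co$hr[i], se = co$se[i],
                   ci_lower = co$hr_lower[i], ci_upper = co$hr_upper[i],
                   covered = co$hr_lower[i] <= planted &
                     planted <= co$hr_upper[i])
  })
  res <- dplyr::bind_rows(out)
  attr(res, "planted_hr") <- planted
  attr(res, "term") <- term
  res
}

#' Holdout benchmark of the HLA imputation model
#'
#' Simulates labeled repertoires at the configured carrier frequency and
#' feature-key presence rates, trains the two-covariate logistic model on a
#' training split with 5-fold cross-validation, and evaluates AUROC on the
#' held-out subjects. Candidate features are the planted allele-associated
#' keys plus background decoys, so feature selection is part of what is
#' benchmarked.
#'
#' @param n Total subjects (default 600).
#' @param n_train Training subjects (default 480; the rest are held out).
#' @param frac_carrier Carrier fraction (default 0.4).
#' @param n_decoys Background decoy candidate keys (default 400).
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return List: `holdout_auroc`, `cv_auroc`, `model`, `n_holdout`,
#'   `planted_keys` (ids of the planted allele-associated keys).
#' @export
hla_imputation_benchmark <- function(n = 600L, n_train = 480L,
                                     frac_carrier = 0.4, n_decoys = 400L,
                                     config = generator_config(),
                                     seed = 1L) {
  set.seed(seed)
  pool <- gen_key_pool(config, seed = child_seed(seed, 101L))
  carrier <- runif(n) < frac_carrier
  if (length(unique(carrier)) < 2L) stopf("need both classes; increase n")
  feat_idx <- which(pool$role == "hla_A")
  decoy_idx <- sample(which(pool$role == "background"), n_decoys)
  cand_idx <- c(feat_idx, decoy_idx)

  presence <- matrix(FALSE, n, length(cand_idx))
  r_unique <- integer(n)
  for (i in seq_len(n)) {
    idx <- sample_pool_indices(FALSE, carrier[i], FALSE, pool, config)
    presence[i, ] <- cand_idx %in% idx$productive
    r_unique[i] <- length(idx$productive)
  }
  colnames(presence) <- pool$key_id[cand_idx]
  rownames(presence) <- sprintf("s%04d", seq_len(n))

  tr <- seq_len(n) <= n_train
  model <- train_hla_model(presence[tr, ], carrier[tr],
                           r_unique = r_unique[tr],
                           allele = config$hla$allele_A,
                           seed = child_seed(seed, 102L))
  ho_prob <- impute_hla(model, list(
    n_feat = rowSums(presence[!tr, model$feature_keys, drop = FALSE]),
    r_unique = r_unique[!tr]))$probability
  list(holdout_auroc = rank_auc(ho_prob, carrier[!tr]),
       cv_auroc = model$cv_auroc, model = model, n_holdout = sum(!tr),
       planted_keys = pool$key_id[feat_idx])
}
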