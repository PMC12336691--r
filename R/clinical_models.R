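#' Carrier-level normalized linkage disequilibrium D'
#'
#' Normalized D' computed on carrier (phenotype) frequencies: with
#' `fA = nA/n`, `fB = nB/n`, `fAB = nAB/n`, the raw disequilibrium is
#' `D = fAB - fA*fB`, scaled by its maximum attainable magnitude given the
#' margins (`min(fA(1-fB), (1-fA)fB)` for positive D,
#' `min(fA*fB, (1-fA)(1-fB))` for negative D). The absolute value is
#' returned. Vectorized over tables.
#'
#' @param n Total subjects.
#' @param nA,nB Carriers of allele A / allele B.
#' @param nAB Double carriers.
#' @return Normalized D' in `[0, 1]`.
#' @export
#' @examples
#' carrier_dprime(405, 125, 193, 80)  # 0.31
carrier_dprime <- function(n, nA, nB, nAB) {
  if (any(nAB > pmin(nA, nB)) || any(nA + nB - nAB > n))
    stopf("inconsistent carrier table")
  fA <- nA / n; fB <- nB / n; fAB <- nAB / n
  if (any(fA %in% c(0, 1)) || any(fB %in% c(0, 1)))
    stopf("D' undefined for degenerate margins")
  D <- fAB - fA * fB
  dmax <- ifelse(D >= 0, pmin(fA * (1 - fB), (1 - fA) * fB),
                 pmin(fA * fB, (1 - fA) * (1 - fB)))
  out <- abs(D) / dmax
  out[D == 0] <- 0
  out
}

#' Published cohort HLA carrier counts
#'
#' Carrier counts of HLA-A*03:01 and HLA-DRB1*15:01 (and their overlap) in
#' six multiple-sclerosis cohorts, as published; the inputs for the
#' carrier-level linkage-disequilibrium computation.
#'
#' @return Tibble with `cohort`, `n`, `nA` (A*03:01 carriers), `nB`
#'   (DRB1*15:01 carriers), `nAB` (double carriers).
#' @export
cohort_carrier_counts <- function() {
  path <- system.file("extdata", "cohort_hla_carrier_counts.csv",
                      package = "gatrb", mustWork = TRUE)
  tibble::as_tibble(data.table::fread(path, showProgress = FALSE))
}

#' Exact matching of two groups on categorical strata
#'
#' Retains subjects in strata (exact on the categorical variables, with age
#' binned by quantiles) that contain members of both groups, the standard
#' pre-processing step before comparing a treated with an untreated group
#' in a cross-sectional cohort.
#'
#' @param meta Tibble of subjects.
#' @param group Name of the logical grouping column.
#' @param vars Matching variables; `age` is binned, others matched exactly.
#' @param age_bins Number of quantile bins for age (default 4).
#' @return List with `matched` (retained rows, including a `stratum`
#'   column and matching `weight`s: 1 for the group of interest, the
#'   within-stratum group ratio for the comparison group, so that weighted
#'   margins of the matching variables balance exactly), `strata`
#'   (per-stratum group counts) and `n_discarded`.
#' @export
exact_match <- function(meta, group,
                        vars = c("age", "sex", "carrier_A", "carrier_B"),
                        age_bins = 4L) {
  miss <- setdiff(c(group, vars), names(meta))
  if (length(miss)) stopf("missing matching column(s): %s",
                          paste(miss, collapse = ", "))
  m <- meta
  if ("age" %in% vars) {
    br <- unique(quantile(m$age, probs = seq(0, 1, length.out = age_bins + 1),
                          na.rm = TRUE))
    m$age_bin <- cut(m$age, breaks = br, include.lowest = TRUE)
    vars <- c(setdiff(vars, "age"), "age_bin")
  }
  stratum <- interaction(m[vars], drop = TRUE)
  g <- as.logical(m[[group]])
  keep_strata <- names(which(tapply(g, stratum, function(x)
    any(x) && any(!x))))
  keep <- stratum %in% keep_strata
  if (!any(keep)) {
    warnf("no overlapping strata; empty matched set")
    return(list(matched = meta[0, ], strata = tibble::tibble(),
                n_discarded = nrow(meta)))
  }
  strata_tab <- tibble::as_tibble(as.data.frame(table(
    stratum = droplevels(stratum[keep]), group = g[keep])))
  matched <- meta[keep, ]
  ms <- droplevels(stratum[keep]); mg <- g[keep]
  n_t <- tapply(mg, ms, sum); n_c <- tapply(!mg, ms, sum)
  ratio <- (n_t / n_c)[as.character(ms)]
  matched$stratum <- as.character(ms)
  matched$weight <- ifelse(mg, 1, unname(ratio))
  list(matched = matched, strata = strata_tab,
       n_discarded = sum(!keep))
}

# Tidy a coxph or lm fit into the package's model_fit container.
new_model_fit <- function(fit, coefs, type) {
  structure(list(fit = fit, coefficients = coefs, type = type,
                 loglik = tryCatch(as.numeric(logLik(fit)),
                                   error = function(e) NA_real_)),
            class = "gatrb_model_fit")
}

#' @export
print.gatrb_model_fit <- function(x, ...) {
  cat(sprintf("<gatrb_model_fit> %s\n", x$type))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Linear model with treatment-by-HLA interaction terms
#'
#' Ordinary least squares for a continuous clinical outcome with the
#' standard covariate set: min-max-normalized age and disease duration,
#' sex, treatment indicator(s), HLA carrier indicators, and
#' treatment-by-HLA interactions.
#'
#' @param data Tibble with the outcome, `age`, `sex`, `disease_duration`,
#'   and the treatment/HLA columns named below.
#' @param outcome Name of the outcome column.
#' @param treatment Name(s) of logical treatment indicator column(s).
#' @param hla Name(s) of logical HLA carrier column(s).
#' @return A `gatrb_model_fit` with coefficient tibble (`term`, `estimate`,
#'   `se`, `p`).
#' @export
fit_linear_interaction <- function(data, outcome, treatment = "ga",
                                   hla = c("carrier_A", "carrier_B")) {
  d <- as.data.frame(data)
  d$age_norm <- min_max_scale(d$age)
  d$duration_norm <- min_max_scale(d$disease_duration)
  d$sexm <- d$sex == "m"
  inter <- unlist(lapply(treatment, function(tr)
    paste0(tr, ":", hla)))
  rhs <- paste(c("age_norm", "sexm", "duration_norm", treatment, hla,
                 inter), collapse = " + ")
  f <- as.formula(paste(outcome, "~", rhs))
  mm <- model.matrix(f, d)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm))
    stopf("rank-deficient design; collinear column(s): %s",
          paste(colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]],
                collapse = ", "))
  m <- lm(f, data = d)
  s <- summary(m)$coefficients
  coefs <- tibble::tibble(term = rownames(s), estimate = s[, 1],
                          se = s[, 2], p = s[, 4])
  new_model_fit(m, coefs, sprintf("linear (%s)", outcome))
}

cox_coef_table <- function(m) {
  s <- summary(m)
  co <- s$coefficients
  se_col <- if ("robust se" %in% colnames(co)) "robust se" else "se(coef)"
  est <- co[, "coef"]; se <- co[, se_col]
  tibble::tibble(
    term = rownames(co), estimate = est, se = se,
    hr = exp(est), hr_lower = exp(est - 1.96 * se),
    hr_upper = exp(est + 1.96 * se),
    p = 2 * pnorm(-abs(est / se)))
}

check_cox_covariates <- function(d, covariates) {
  const <- covariates[vapply(covariates, function(v)
    length(unique(d[[v]])) < 2L, logical(1))]
  if (length(const))
    stopf("covariate(s) constant across subjects: %s",
          paste(const, collapse = ", "))
}

#' Cox proportional-hazards model for time to first event
#'
#' Maximum partial likelihood with Efron tie handling (via
#' [survival::coxph()]); hazard ratios with Wald 95% confidence intervals.
#'
#' @param data Tibble with `time`, `status` and the covariate columns.
#' @param covariates Character vector of covariate terms; interactions may
#'   be written as `"a:b"`.
#' @return A `gatrb_model_fit` with coefficient tibble including `hr`,
#'   `hr_lower`, `hr_upper`.
#' @export
fit_cox <- function(data, covariates) {
  d <- as.data.frame(data)
  if (sum(d$status) < 1L) stopf("no events")
  check_cox_covariates(d, setdiff(covariates, grep(":", covariates,
                                                   value = TRUE)))
  f <- as.formula(paste("survival::Surv(time, status) ~",
                        paste(covariates, collapse = " + ")))
  m <- survival::coxph(f, data = d, ties = "efron",
                       control = survival::coxph.control(iter.max = 50,
                                                         eps = 1e-9))
  if (!is.null(m$info) && grepl("infinite", paste(m$info, collapse = " ")))
    warnf("possible monotone likelihood (separation) detected")
  new_model_fit(m, cox_coef_table(m), "cox (first event)")
}

#' Andersen-Gill recurrent-event Cox model
#'
#' Cox partial likelihood over counting-process `(start, stop]` risk
#' intervals with robust sandwich standard errors clustered by subject,
#' the standard model for recurrent relapse data.
#'
#' @param data Tibble in counting-process form: `start`, `stop`, `event`,
#'   `subject_id`, plus covariate columns (constant within subject).
#' @param covariates Character vector of covariate terms.
#' @param cluster Column defining the robust-variance cluster (default
#'   `"subject_id"`).
#' @return A `gatrb_model_fit`; `se` in the coefficient tibble is the
#'   robust clustered standard error (`naive_se` also reported).
#' @export
fit_cox_ag <- function(data, covariates, cluster = "subject_id") {
  d <- as.data.frame(data)
  if (any(d$start >= d$stop)) stopf("intervals must satisfy start < stop")
  ov <- vapply(split(d, d[[cluster]]), function(s) {
    s <- s[order(s$start), ]
    nrow(s) > 1L && any(s$start[-1] < s$stop[-nrow(s)])
  }, logical(1))
  if (any(ov)) stopf("overlapping intervals within subject(s): %s",
                     paste(names(ov)[ov], collapse = ", "))
  check_cox_covariates(d, setdiff(covariates, grep(":", covariates,
                                                   value = TRUE)))
  f <- as.formula(paste("survival::Surv(start, stop, event) ~",
                        paste(covariates, collapse = " + ")))
  m <- survival::coxph(f, data = d, ties = "efron", robust = TRUE,
                       cluster = d[[cluster]],
                       control = survival::coxph.control(iter.max = 50,
                                                         eps = 1e-9))
  coefs <- cox_coef_table(m)
  coefs$naive_se <- summary(m)$coefficients[, "se(coef)"]
  new_model_fit(m, coefs, "cox (Andersen-Gill)")
}

#' Schoenfeld residuals of a fitted Cox model
#'
#' Per-event, per-covariate residuals (observed minus risk-set-weighted
#' expected covariate), the standard proportional-hazards diagnostic.
#' Residual columns sum to ~0 at the maximum partial likelihood estimate.
#'
#' @param fit A `gatrb_model_fit` from [fit_cox()] or [fit_cox_ag()].
#' @return Tibble with `time` and one residual column per covariate.
#' @export
schoenfeld_residuals <- function(fit) {
  stopifnot(inherits(fit, "gatrb_model_fit"))
  r <- residuals(fit$fit, type = "schoenfeld")
  if (is.null(dim(r))) r <- matrix(r, dimnames = list(names(r),
                                                      fit$coefficients$term[1]))
  tibble::as_tibble(cbind(time = as.numeric(rownames(r)),
                          as.data.frame(r)))
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimate with Greenwood variance (via
#' [survival::survfit()]).
#'
#' @param data Tibble with `time`, `status` and the grouping column.
#' @param group Name of the grouping column (`NULL` for a single curve).
#' @return Tibble of step coordinates: `group`, `time`, `n_risk`,
#'   `n_event`, `surv`, `se`, `lower`, `upper`.
#' @export
kaplan_meier <- function(data, group = NULL) {
  d <- as.data.frame(data)
  f <- if (is.null(group)) survival::Surv(time, status) ~ 1
    else as.formula(paste("survival::Surv(time, status) ~", group))
  sf <- survival::survfit(f, data = d, conf.type = "log")
  s <- summary(sf, censored = TRUE)
  grp <- if (is.null(s$strata)) "all" else sub("^.*=", "",
                                               as.character(s$strata))
  tibble::tibble(group = grp, time = s$time, n_risk = s$n.risk,
                 n_event = s$n.event, surv = s$surv, se = s$std.err,
                 lower = s$lower, upper = s$upper)
}
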