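#' Generator configuration for synthetic TRB cohorts
#'
#' Returns the full configuration driving the synthetic multi-cohort
#' generator. Defaults emulate the study conditions the analysis layers
#' assume: three discovery cohorts with 58/211, 75/234 and 71/978
#' case/control splits, each carrying its published HLA carrier
#' frequencies and carrier-level linkage disequilibrium (0.31/0.48 at
#' D' = 0.31; 0.33/0.44 at D' = 0.27; 0.49/0.47 at D' = 0.10 for
#' HLA-A*03:01 / HLA-DRB1*15:01), with 0.31/0.48/0.31 as the global
#' default for subjects generated outside a cohort;
#' 65 + 35 + 5 planted treatment-associated public clonotypes on the A, B
#' and unrestricted backgrounds, present at 0.02 in unexposed repertoires
#' and 0.30 in exposed carriers (with a 1.5x synergy on the A pattern in
#' double carriers); 100 imputation feature clonotypes per allele at
#' 0.30 carrier / 0.015 non-carrier presence; and clinical outcomes
#' generated under treatment-by-HLA interaction effects (hazard ratios
#' 0.66/0.67 for recurrent relapse, 0.37 for first relapse, linear
#' interaction effects -0.34 for annual EDSS change and -1.34 for MSSS).
#'
#' @param ... Named overrides, matching the structure of the returned list
#'   (e.g. `repertoire = list(mean_unique = 500)` merges into the
#'   repertoire block).
#' @return A nested list of class `gatrb_config`.
#' @export
generator_config <- function(...) {
  cfg <- list(
    seed = 1L,
    cohorts = list(
      list(name = "cohortA", n_cases = 58L, n_controls = 211L,
           hla = list(freq_A = 0.31, freq_B = 0.48, dprime = 0.31)),
      list(name = "cohortB", n_cases = 75L, n_controls = 234L,
           hla = list(freq_A = 0.33, freq_B = 0.44, dprime = 0.27)),
      list(name = "cohortC", n_cases = 71L, n_controls = 978L,
           hla = list(freq_A = 0.49, freq_B = 0.47, dprime = 0.10))
    ),
    repertoire = list(
      mean_unique = 3000, dispersion = 12, clone_exponent = 2.0,
      max_templates = 50000L, pool_size = 60000L, frac_nonproductive = 0.12,
      min_unique = 200L
    ),
    hla = list(
      allele_A = "A*03:01", allele_B = "DRB1*15:01",
      freq_A = 0.31, freq_B = 0.48, dprime = 0.31
    ),
    planted = list(
      n_A = 65L, n_B = 35L, n_none = 5L,
      p_background = 0.02, p_exposed_carrier = 0.30, synergy = 1.5
    ),
    hla_features = list(
      n_per_allele = 100L, p_carrier = 0.30, p_noncarrier = 0.015
    ),
    longitudinal = list(n_expansions = 12L),
    clinical = list(
      baseline_hazard = 0.3,           # recurrent events per year
      baseline_hazard_first = 1.0,     # first-relapse intensity per year
      followup_recurrent = 3,          # years
      followup_first = 1,              # years
      hr_ga = 0.9, hr_gaifn = 0.85,
      hr_A = 1.2, hr_B = 1.0,
      hr_inter_ga_A = 0.66, hr_inter_gaifn_A = 0.67,
      hr_inter_ga_B = 1.0, hr_inter_gaifn_B = 1.0,
      hr_age = 0.8, hr_sexm = 1.1, hr_duration = 0.9,
      beta_edss = c(intercept = 0.15, ga = -0.03, A = 0.08, inter_ga_A = -0.34),
      sd_edss = 0.9,
      beta_msss = c(intercept = 5.5, ga = -0.2, A = 0.3, inter_ga_A = -1.34),
      sd_msss = 2.0
    )
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (nm != "cohorts" && is.list(cfg[[nm]]) && is.list(overrides[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], overrides[[nm]])
    else cfg[[nm]] <- overrides[[nm]]  # cohorts replaced wholesale
  }
  validate_generator_config(cfg)
  structure(cfg, class = "gatrb_config")
}

validate_generator_config <- function(cfg) {
  p <- c(cfg$planted$p_background, cfg$planted$p_exposed_carrier,
         cfg$hla_features$p_carrier, cfg$hla_features$p_noncarrier,
         cfg$hla$freq_A, cfg$hla$freq_B, cfg$hla$dprime)
  if (any(p < 0 | p > 1)) stopf("probabilities and D' must lie in [0, 1]")
  if (any(c(cfg$planted$n_A, cfg$planted$n_B, cfg$planted$n_none) < 0))
    stopf("planted key counts must be nonnegative")
  feasible_carrier_joint(cfg$hla$freq_A, cfg$hla$freq_B, cfg$hla$dprime)
  invisible(cfg)
}

# Joint double-carrier probability implied by (fA, fB, D') under the
# carrier-level D' convention; errors if infeasible.
feasible_carrier_joint <- function(freqA, freqB, dprime) {
  if (any(c(freqA, freqB, dprime) < 0) || any(c(freqA, freqB, dprime) > 1))
    stopf("freqA, freqB and dprime must lie in [0, 1]")
  dmax <- min(freqA * (1 - freqB), (1 - freqA) * freqB)
  pAB <- freqA * freqB + dprime * dmax
  if (pAB > min(freqA, freqB) + 1e-12 || pAB < 0)
    stopf("infeasible (freqA, freqB, dprime) triple")
  pAB
}

#' Draw carrier genotypes for two linked HLA alleles
#'
#' Subject-level carrier status for two alleles is drawn from the 2x2
#' carrier distribution implied by the marginal carrier frequencies and the
#' carrier-level normalized D' (the convention of [carrier_dprime()]).
#'
#' @param n Number of subjects.
#' @param freqA,freqB Carrier frequencies in `[0, 1]`.
#' @param dprime Target carrier-level normalized D' in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Tibble with logical columns `carrier_A`, `carrier_B`.
#' @export
assign_genotypes <- function(n, freqA, freqB, dprime, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pAB <- feasible_carrier_joint(freqA, freqB, dprime)
  probs <- c(AB = pAB, A = freqA - pAB, B = freqB - pAB,
             none = 1 - freqA - freqB + pAB)
  if (any(probs < -1e-12)) stopf("infeasible (freqA, freqB, dprime) triple")
  cell <- sample.int(4L, n, replace = TRUE, prob = pmax(probs, 0))
  tibble::tibble(carrier_A = cell %in% c(1L, 2L),
                 carrier_B = cell %in% c(1L, 3L))
}

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_strings <- function(n, len, alphabet) {
  cols <- lapply(seq_len(len), function(i)
    sample(alphabet, n, replace = TRUE))
  do.call(paste0, cols)
}

#' Generate the shared public clonotype pool
#'
#' Builds the pool of public clonotypes from which all synthetic repertoires
#' draw: planted treatment-associated keys on each HLA background, HLA
#' imputation feature keys, and background keys. Planted treatment keys are
#' skewed towards TRBV05-06 to emulate the V-gene bias of real
#' treatment-associated patterns.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return Tibble of class `gatrb_pool` with columns `junction_aa`,
#'   `v_gene`, `j_gene`, `nucleotide_seq`, `role` (one of `ga_A`, `ga_B`,
#'   `ga_none`, `hla_A`, `hla_B`, `background`) and `key_id`.
#' @export
gen_key_pool <- function(config = generator_config(), seed = config$seed) {
  set.seed(seed)
  n <- config$repertoire$pool_size
  n_special <- with(config, planted$n_A + planted$n_B + planted$n_none +
                      2L * hla_features$n_per_allele)
  if (n <= n_special) stopf("pool_size must exceed the planted key count")
  len <- sample(11:17, n, replace = TRUE,
                prob = c(0.08, 0.15, 0.22, 0.22, 0.18, 0.10, 0.05))
  mid <- rand_strings(n, 12L, .aa20)
  junction <- paste0("CASS", substring(mid, 1L, len - 5L), "F")
  v_panel <- c("TRBV05-06", "TRBV02-01", "TRBV04-01", "TRBV06-05",
               "TRBV07-09", "TRBV09-01", "TRBV12-03", "TRBV19-01",
               "TRBV20-01", "TRBV28-01")
  j_panel <- c("TRBJ01-01", "TRBJ01-02", "TRBJ01-05", "TRBJ02-01",
               "TRBJ02-03", "TRBJ02-05", "TRBJ02-07")
  v_gene <- sample(v_panel, n, replace = TRUE,
                   prob = c(0.15, rep(0.85 / 9, 9)))
  j_gene <- sample(j_panel, n, replace = TRUE)
  role <- rep("background", n)
  idx <- 1L
  for (blk in list(c("ga_A", config$planted$n_A),
                   c("ga_B", config$planted$n_B),
                   c("ga_none", config$planted$n_none),
                   c("hla_A", config$hla_features$n_per_allele),
                   c("hla_B", config$hla_features$n_per_allele))) {
    k <- as.integer(blk[2])
    if (k > 0) role[idx:(idx + k - 1L)] <- blk[1]
    idx <- idx + k
  }
  ga_idx <- which(role %in% c("ga_A", "ga_B", "ga_none"))
  v_gene[ga_idx] <- ifelse(runif(length(ga_idx)) < 0.6, "TRBV05-06",
                           v_gene[ga_idx])
  nt <- rand_strings(n, 48L, c("A", "C", "G", "T"))
  pool <- tibble::tibble(junction_aa = junction, v_gene = v_gene,
                         j_gene = j_gene, nucleotide_seq = nt, role = role,
                         key_id = key_id(junction, v_gene, j_gene))
  class(pool) <- c("gatrb_pool", class(pool))
  pool
}

# Per-key inclusion probabilities for one sample's special keys, and the
# sampled productive pool indices for the whole repertoire.
sample_pool_indices <- function(ga_exposed, carrier_A, carrier_B, pool,
                                config) {
  rp <- config$repertoire; pl <- config$planted; hf <- config$hla_features
  r_target <- max(rp$min_unique,
                  rnbinom(1L, mu = rp$mean_unique, size = rp$dispersion))
  role <- pool$role
  special <- which(role != "background")
  p <- rep(pl$p_background, length(special))
  sp_role <- role[special]
  if (isTRUE(ga_exposed)) {
    if (isTRUE(carrier_A)) {
      pa <- pl$p_exposed_carrier
      if (isTRUE(carrier_B)) pa <- min(pa * pl$synergy, 0.95)
      p[sp_role == "ga_A"] <- pa
    }
    if (isTRUE(carrier_B)) p[sp_role == "ga_B"] <- pl$p_exposed_carrier
    p[sp_role == "ga_none"] <- pl$p_exposed_carrier
  }
  p[sp_role == "hla_A"] <- if (isTRUE(carrier_A)) hf$p_carrier else hf$p_noncarrier
  p[sp_role == "hla_B"] <- if (isTRUE(carrier_B)) hf$p_carrier else hf$p_noncarrier
  inc_special <- special[runif(length(special)) < p]
  n_bg <- max(r_target - length(inc_special), 0L)
  bg_pool <- which(role == "background")
  inc_bg <- sample(bg_pool, min(n_bg, length(bg_pool)))
  list(productive = c(inc_special, inc_bg),
       nonproductive = sample(bg_pool,
                              round(rp$frac_nonproductive * r_target)))
}

power_law_templates <- function(n, exponent, cap) {
  t <- floor(runif(n)^(-1 / (exponent - 1)))
  as.integer(pmin(pmax(t, 1), cap))
}

#' Generate one synthetic repertoire
#'
#' Draws a repertoire for one sample given its exposure and HLA carrier
#' status. Unique rearrangement counts follow a negative-binomial size law;
#' template counts follow a discrete power law; planted treatment keys,
#' HLA-imputation feature keys and background keys are included with the
#' probabilities set in the configuration (see [generator_config()]).
#'
#' @param meta A one-row data frame or list with `sample_id`, `subject_id`,
#'   `ga_exposed`, `carrier_A`, `carrier_B` (and optionally `timepoint`).
#' @param pool A [gen_key_pool()] pool.
#' @param config A [generator_config()].
#' @param seed Optional integer seed.
#' @return A [repertoire()] object.
#' @export
gen_repertoire <- function(meta, pool, config = generator_config(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(pool) == 0) stopf("empty key pool")
  idx <- sample_pool_indices(meta$ga_exposed, meta$carrier_A, meta$carrier_B,
                             pool, config)
  build_repertoire_from_indices(idx, meta, pool, config)
}

build_repertoire_from_indices <- function(idx, meta, pool, config) {
  all_idx <- c(idx$productive, setdiff(idx$nonproductive, idx$productive))
  n_prod <- length(idx$productive)
  productive <- c(rep(TRUE, n_prod), rep(FALSE, length(all_idx) - n_prod))
  dt <- data.table::data.table(
    nucleotide_seq = pool$nucleotide_seq[all_idx],
    junction_aa = pool$junction_aa[all_idx],
    v_gene = pool$v_gene[all_idx],
    j_gene = pool$j_gene[all_idx],
    templates = power_law_templates(length(all_idx),
                                    config$repertoire$clone_exponent,
                                    config$repertoire$max_templates),
    productive = productive)
  repertoire(dt, sample_id = as.character(meta$sample_id),
             subject_id = as.character(meta[["subject_id"]] %||%
                                         meta[["sample_id"]]),
             timepoint = as.character(meta[["timepoint"]] %||% "single"))
}

#' Generate subject-level covariates
#'
#' Age, sex and disease duration with distributions typical of an adult
#' relapsing MS trial population.
#'
#' @param n Number of subjects.
#' @return Tibble with `age` (years), `sex` (`"f"`/`"m"`),
#'   `disease_duration` (years).
#' @export
gen_covariates <- function(n) {
  tibble::tibble(
    age = pmin(pmax(rnorm(n, 38, 10), 18), 65),
    sex = ifelse(runif(n) < 0.7, "f", "m"),
    disease_duration = pmin(rexp(n, 1 / 5), 30))
}

#' Generate a synthetic case/control cohort
#'
#' @param name Cohort name.
#' @param n_cases,n_controls Exposed / unexposed sample counts.
#' @param pool A [gen_key_pool()] pool.
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @param as `"repertoire"` returns full [repertoire()] objects;
#'   `"cohort"` returns the compact [trb_cohort()] presence representation
#'   used by the discovery layer (much lighter for large cohorts).
#' @param cohort_hla Optional list overriding `config$hla` (e.g. the
#'   per-cohort `hla` entry of a cohort in [generator_config()]).
#' @return A list with `meta` (tibble) and either `repertoires` or `cohort`.
#' @export
gen_cohort <- function(name, n_cases, n_controls,
                       pool, config = generator_config(), seed = config$seed,
                       as = c("repertoire", "cohort"), cohort_hla = NULL) {
  as <- match.arg(as)
  set.seed(seed)
  n <- n_cases + n_controls
  hla <- modifyList(config$hla, cohort_hla %||% list())
  geno <- assign_genotypes(n, hla$freq_A, hla$freq_B, hla$dprime)
  meta <- tibble::tibble(
    sample_id = sprintf("%s_s%04d", name, seq_len(n)),
    subject_id = sprintf("%s_p%04d", name, seq_len(n)),
    cohort_id = name,
    ga_exposed = c(rep(TRUE, n_cases), rep(FALSE, n_controls)),
    treatment_arm = c(rep("GA", n_cases), rep("none", n_controls)),
    carrier_A = geno$carrier_A, carrier_B = geno$carrier_B,
    hla_genotype = hla_genotype_string(geno, config))
  meta <- dplyr::bind_cols(meta, gen_covariates(n))
  if (as == "repertoire") {
    reps <- lapply(seq_len(n), function(i)
      gen_repertoire(meta[i, ], pool, config))
    names(reps) <- meta$sample_id
    list(meta = meta, repertoires = reps)
  } else {
    pres <- lapply(seq_len(n), function(i)
      sample_pool_indices(meta$ga_exposed[i], meta$carrier_A[i],
                          meta$carrier_B[i], pool, config)$productive)
    ch <- trb_cohort_from_indices(pres, pool, meta$sample_id,
                                  is_case = meta$ga_exposed)
    list(meta = meta, cohort = ch)
  }
}

#' Generate all configured discovery cohorts
#'
#' Convenience wrapper generating every cohort in `config$cohorts` (compact
#' presence form) from one shared key pool.
#'
#' @param pool A [gen_key_pool()] pool.
#' @param config A [generator_config()].
#' @param seed Integer seed, fanned out per cohort.
#' @return List with `cohorts` (named list of [trb_cohort()]) and `metas`
#'   (named list of metadata tibbles).
#' @export
gen_discovery_cohorts <- function(pool, config = generator_config(),
                                  seed = config$seed) {
  cohorts <- list(); metas <- list()
  for (i in seq_along(config$cohorts)) {
    cs <- config$cohorts[[i]]
    g <- gen_cohort(cs$name, cs$n_cases, cs$n_controls, pool, config,
                    seed = child_seed(seed, 10L + i), as = "cohort",
                    cohort_hla = cs$hla)
    cohorts[[cs$name]] <- g$cohort
    metas[[cs$name]] <- g$meta
  }
  list(cohorts = cohorts, metas = metas)
}

hla_genotype_string <- function(geno, config) {
  a <- ifelse(geno$carrier_A, config$hla$allele_A, NA)
  b <- ifelse(geno$carrier_B, config$hla$allele_B, NA)
  out <- mapply(function(x, y) paste(na.omit(c(x, y)), collapse = ";"), a, b)
  ifelse(nzchar(out), out, "none")
}

#' Generate a pre/post-treatment repertoire pair with planted expansions
#'
#' The treated repertoire contains `config$longitudinal$n_expansions` new
#' nucleotide rearrangements absent at baseline and placed within the top
#' 100 by template count, emulating treatment-driven clonal expansion.
#'
#' @inheritParams gen_repertoire
#' @param meta One-row metadata with `ga_exposed = TRUE`.
#' @return List with `baseline` and `treated` [repertoire()] objects.
#' @export
gen_longitudinal_pair <- function(meta, pool, config = generator_config(),
                                  seed = NULL) {
  if (!isTRUE(meta$ga_exposed)) stopf("gen_longitudinal_pair needs ga_exposed = TRUE")
  if (!is.null(seed)) set.seed(seed)
  base_meta <- meta; base_meta$ga_exposed <- FALSE
  base_meta$timepoint <- "baseline"
  baseline <- gen_repertoire(base_meta, pool, config)

  # the treated repertoire is the baseline repertoire under resampling
  # (templates re-drawn, a small fraction of clones lost), plus: planted
  # pattern keys newly recruited under exposure, a little background
  # churn (both entering at small clone sizes), and the designated
  # expansion clones pushed into the top 100
  re <- data.table::as.data.table(baseline$rearrangements)
  keep <- runif(nrow(re)) > 0.05
  re <- re[keep]
  re[, templates := power_law_templates(nrow(re),
                                        config$repertoire$clone_exponent,
                                        config$repertoire$max_templates)]
  base_idx <- match(baseline$rearrangements$nucleotide_seq,
                    pool$nucleotide_seq)
  idx <- sample_pool_indices(TRUE, meta$carrier_A, meta$carrier_B, pool,
                             config)
  new_planted <- setdiff(idx$productive[pool$role[idx$productive] !=
                                          "background"], base_idx)
  n_churn <- max(1L, round(0.05 * nrow(re)))
  free <- setdiff(which(pool$role == "background"),
                  c(base_idx, new_planted))
  churn <- sample(free, n_churn)
  n_exp <- config$longitudinal$n_expansions
  exp_idx <- sample(setdiff(free, churn), n_exp)
  small <- c(new_planted, churn)
  add <- data.table::data.table(
    nucleotide_seq = pool$nucleotide_seq[c(small, exp_idx)],
    junction_aa = pool$junction_aa[c(small, exp_idx)],
    v_gene = pool$v_gene[c(small, exp_idx)],
    j_gene = pool$j_gene[c(small, exp_idx)],
    templates = rep(1L, length(small) + n_exp),
    productive = TRUE)
  re <- rbind(re, add)
  top <- sort(re$templates, decreasing = TRUE)[min(100L, nrow(re))]
  hit <- re$nucleotide_seq %in% pool$nucleotide_seq[exp_idx]
  re[hit, templates := as.integer(top + sample.int(1000L, sum(hit)))]
  treated <- repertoire(re, as.character(meta$sample_id),
                        as.character(meta[["subject_id"]] %||%
                                       meta[["sample_id"]]),
                        "treated")
  list(baseline = baseline, treated = treated)
}

#' Generate clinical outcomes under treatment-by-HLA interaction effects
#'
#' Recurrent relapse times follow a Poisson (Andersen-Gill) intensity with
#' multiplicative covariate effects; first-relapse times are exponential
#' with administrative censoring; continuous outcomes follow linear models
#' with Gaussian noise. All effect sizes come from the configuration.
#'
#' @param meta Tibble with one row per subject: `subject_id`,
#'   `treatment_arm` (`"IFN"`, `"GA"`, `"GA+IFN"`, `"none"`), `carrier_A`,
#'   `carrier_B`, `age`, `sex`, `disease_duration`.
#' @param config A [generator_config()].
#' @param seed Optional integer seed.
#' @return List with `recurrent` (counting-process tibble: `subject_id`,
#'   `start`, `stop`, `event` in days), `first_event` (tibble with `time`
#'   in days and `status`), `continuous` (tibble with `delta_edss`, `msss`)
#'   and `covariates` (the design tibble used).
#' @export
gen_clinical <- function(meta, config = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cl <- config$clinical
  if (cl$followup_recurrent <= 0 || cl$followup_first <= 0)
    stopf("follow-up must be positive")
  ga <- meta$treatment_arm == "GA"
  gaifn <- meta$treatment_arm == "GA+IFN"
  A <- as.logical(meta$carrier_A); B <- as.logical(meta$carrier_B)
  age_n <- min_max_scale(meta$age)
  dur_n <- min_max_scale(meta$disease_duration)
  sexm <- meta$sex == "m"
  lp <- log(cl$hr_ga) * ga + log(cl$hr_gaifn) * gaifn +
    log(cl$hr_A) * A + log(cl$hr_B) * B +
    log(cl$hr_inter_ga_A) * (ga & A) + log(cl$hr_inter_gaifn_A) * (gaifn & A) +
    log(cl$hr_inter_ga_B) * (ga & B) + log(cl$hr_inter_gaifn_B) * (gaifn & B) +
    log(cl$hr_age) * age_n + log(cl$hr_sexm) * sexm +
    log(cl$hr_duration) * dur_n
  rate <- cl$baseline_hazard * exp(lp)           # events / year

  fu_days <- round(cl$followup_recurrent * 365.25)
  rec <- lapply(seq_len(nrow(meta)), function(i) {
    k <- rpois(1L, rate[i] * cl$followup_recurrent)
    times <- sort(round(runif(k) * fu_days))
    times <- unique(times[times > 0 & times < fu_days])
    stops <- c(times, fu_days)
    data.table::data.table(subject_id = meta$subject_id[i],
                           start = c(0, times), stop = stops,
                           event = c(rep(1L, length(times)), 0L))
  })
  recurrent <- tibble::as_tibble(data.table::rbindlist(rec))

  fu1 <- round(cl$followup_first * 365.25)
  rate1 <- cl$baseline_hazard_first * exp(lp)
  t_exp <- rexp(nrow(meta), rate1 / 365.25)
  first_event <- tibble::tibble(
    subject_id = meta$subject_id,
    time = pmin(ceiling(t_exp), fu1),
    status = as.integer(t_exp <= fu1))

  be <- cl$beta_edss; bm <- cl$beta_msss
  continuous <- tibble::tibble(
    subject_id = meta$subject_id,
    delta_edss = be["intercept"] + be["ga"] * ga + be["A"] * A +
      be["inter_ga_A"] * (ga & A) + rnorm(nrow(meta), 0, cl$sd_edss),
    msss = bm["intercept"] + bm["ga"] * ga + bm["A"] * A +
      bm["inter_ga_A"] * (ga & A) + rnorm(nrow(meta), 0, cl$sd_msss))

  covariates <- tibble::tibble(
    subject_id = meta$subject_id, ga = ga, gaifn = gaifn,
    carrier_A = A, carrier_B = B, age_norm = age_n, sexm = sexm,
    duration_norm = dur_n)
  list(recurrent = recurrent, first_event = first_event,
       continuous = continuous, covariates = covariates)
}
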