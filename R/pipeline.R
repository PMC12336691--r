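#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), checks the schema and
#' cross-field feasibility (probabilities, carrier D' compatibility,
#' replication requirement vs cohort count), fills documented defaults and
#' echoes them, and flags unknown keys as warnings rather than errors.
#'
#' @param config Path to a YAML file, or a named list.
#' @return List with `config` (a merged [generator_config()]), `discovery`
#'   (a [discovery_config()]), `pipeline` (validation-cohort and arm
#'   settings), and `issues` (character vector of filled defaults and
#'   unknown-key warnings).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  issues <- character()
  known <- c("seed", "cohorts", "repertoire", "hla", "planted",
             "hla_features", "longitudinal", "clinical", "discovery",
             "validation", "arms", "io")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    issues <- c(issues, sprintf("unknown key(s) ignored: %s",
                                paste(unknown, collapse = ", ")))
    warnf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed)) {
    issues <- c(issues, "seed missing; default 1 used")
    config$seed <- 1L
  }
  gen_args <- config[intersect(names(config),
                               c("seed", "cohorts", "repertoire", "hla",
                                 "planted", "hla_features", "longitudinal",
                                 "clinical"))]
  if (!is.null(gen_args$cohorts))
    gen_args$cohorts <- lapply(gen_args$cohorts, function(ch)
      list(name = ch$name, n_cases = as.integer(ch$n_cases),
           n_controls = as.integer(ch$n_controls), hla = ch$hla))
  gcfg <- do.call(generator_config, gen_args)
  disc <- do.call(discovery_config, config$discovery %||% list())
  if (disc$min_replicated_cohorts > length(gcfg$cohorts))
    stopf("min_replicated_cohorts (%d) exceeds number of cohorts (%d)",
          disc$min_replicated_cohorts, length(gcfg$cohorts))
  pipeline <- modifyList(list(
    validation = list(n_cases = 60L, n_controls = 60L),
    arms = list(IFN = c(112L, 56L), GA = c(112L, 60L),
                `GA+IFN` = c(258L, 95L)),
    io = list(write_repertoires = FALSE)),
    config[intersect(names(config), c("validation", "arms", "io"))])
  list(config = gcfg, discovery = disc, pipeline = pipeline,
       issues = issues)
}

write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  path
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes simulate, discover, map-hla, score, classify and model in
#' order, writing one artifact per stage under `out_dir` plus a run
#' manifest (config hash, seed, per-stage timing and row counts).
#' Re-running with an identical configuration and seed reproduces the
#' stage outputs. Each stage is also available as a standalone function
#' ([gen_cohort()], [discover_enhanced_sequences()], [train_hla_model()] /
#' [assign_hla()], [score_patterns()], [predict_exposure()],
#' [fit_cox_ag()] and friends).
#'
#' @param config Path to a YAML config, or a list (see
#'   [validate_config()]).
#' @param seed Global seed; fanned out deterministically into per-stage
#'   child seeds so stages can be re-run in isolation.
#' @param out_dir Output directory (created if needed).
#' @return The run manifest, invisibly.
#' @export
run_ga_pipeline <- function(config = list(), seed = NULL, out_dir) {
  vc <- validate_config(config)
  cfg <- vc$config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = rlang::hash(list(vc$config, vc$discovery,
                                                  vc$pipeline, cfg$seed)),
                   seed = cfg$seed,
                   version = as.character(utils::packageVersion("gatrb")),
                   stages = list())
  t_all <- proc.time()[3]
  stage <- function(name, fun) {
    t0 <- proc.time()[3]
    res <- tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, sprintf("FAILED_%s", name)))
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- c(list(seconds = round(proc.time()[3] - t0,
                                                       2)), res$info)
    message(sprintf("[gatrb] %-10s %6.1fs  %s", name,
                    proc.time()[3] - t0,
                    paste(names(res$info), unlist(res$info),
                          collapse = ", ", sep = "=")))
    res$value
  }

  ## simulate ---------------------------------------------------------
  sim <- stage("simulate", function() {
    pool <- gen_key_pool(cfg, seed = child_seed(cfg$seed, 1L))
    cohorts <- list(); metas <- list()
    for (i in seq_along(cfg$cohorts)) {
      cs <- cfg$cohorts[[i]]
      g <- gen_cohort(cs$name, cs$n_cases, cs$n_controls, pool, cfg,
                      seed = child_seed(cfg$seed, 10L + i), as = "cohort",
                      cohort_hla = cs$hla)
      cohorts[[cs$name]] <- g$cohort
      metas[[cs$name]] <- g$meta
    }
    vset <- vc$pipeline$validation
    val <- gen_cohort("validation", vset$n_cases, vset$n_controls, pool,
                      cfg, seed = child_seed(cfg$seed, 20L),
                      as = "repertoire")
    meta <- dplyr::bind_rows(c(metas, list(validation = val$meta)))
    data.table::fwrite(meta, file.path(out_dir, "metadata.csv"))
    if (isTRUE(vc$pipeline$io$write_repertoires)) {
      rdir <- file.path(out_dir, "repertoires")
      dir.create(rdir, showWarnings = FALSE)
      for (r in val$repertoires)
        write_repertoire(r, file.path(rdir, paste0(r$sample_id, ".tsv")))
    }
    list(value = list(pool = pool, cohorts = cohorts, metas = metas,
                      validation = val),
         info = list(n_samples = nrow(meta),
                     output = "metadata.csv"))
  })

  ## discover ---------------------------------------------------------
  es <- stage("discover", function() {
    es <- discover_enhanced_sequences(sim$cohorts, vc$discovery)
    out <- list(keys = es$keys[, c("key_id", "junction_aa", "v_gene",
                                   "j_gene", "n_replicated")],
                motifs = if (nrow(es$motifs))
                  es$motifs[, c("pattern", "v_gene", "j_gene",
                                "n_replicated")] else list(),
                cohort_sizes = es$cohort_sizes)
    write_stage_json(out, file.path(out_dir, "es.json"))
    list(value = es, info = list(n_keys = nrow(es$keys),
                                 n_motifs = nrow(es$motifs),
                                 output = "es.json"))
  })

  ## map-hla ----------------------------------------------------------
  hla <- stage("map_hla", function() {
    # typed genotypes of the discovery samples are the assignment labels
    meta_all <- dplyr::bind_rows(sim$metas)
    pooled <- pool_cohorts(sim$cohorts)
    labels <- tibble::tibble(sample_id = meta_all$sample_id)
    labels[[cfg$hla$allele_A]] <- meta_all$carrier_A
    labels[[cfg$hla$allele_B]] <- meta_all$carrier_B
    assign <- assign_hla(es, pooled, labels)
    data.table::fwrite(assign, file.path(out_dir, "hla_assignments.csv"))
    # imputation models trained on the largest discovery cohort
    big <- which.max(vapply(sim$cohorts, function(ch)
      length(ch$sample_ids), integer(1)))
    models <- lapply(c(A = "carrier_A", B = "carrier_B"), function(col) {
      train_hla_model_from_cohort(
        sim$cohorts[[big]], sim$metas[[big]][[col]],
        allele = if (col == "carrier_A") cfg$hla$allele_A else
          cfg$hla$allele_B,
        seed = child_seed(cfg$seed, 30L))
    })
    write_stage_json(lapply(models, unclass),
                     file.path(out_dir, "hla_models.json"))
    list(value = list(assignments = assign, models = models),
         info = list(n_assigned = sum(assign$category == "assigned"),
                     cv_auroc_A = round(models$A$cv_auroc, 3),
                     output = "hla_assignments.csv"))
  })

  ## score ------------------------------------------------------------
  scores <- stage("score", function() {
    pats <- assignment_patterns(es, hla$assignments,
                                c(cfg$hla$allele_A, cfg$hla$allele_B))
    if (!length(pats) && nrow(es$keys)) {
      # no confident HLA split (e.g. small runs): score the pooled ES set
      jn <- c(es$keys$junction_aa,
              if (nrow(es$motifs)) es$motifs$pattern)
      pats <- list(ES = es_pattern(
        jn, c(es$keys$v_gene, if (nrow(es$motifs)) es$motifs$v_gene),
        c(es$keys$j_gene, if (nrow(es$motifs)) es$motifs$j_gene)))
    }
    sc <- if (length(pats))
      score_patterns(sim$validation$repertoires, pats)
    else tibble::tibble(sample_id = character(), pattern_id = character(),
                        n_matched = integer(), breadth = numeric(),
                        depth = numeric(), breadth_per_1e6 = numeric())
    data.table::fwrite(sc, file.path(out_dir, "scores.csv"))
    list(value = list(scores = sc, patterns = pats),
         info = list(n_rows = nrow(sc), output = "scores.csv"))
  })

  ## classify ---------------------------------------------------------
  roc <- stage("classify", function() {
    vmeta <- sim$validation$meta
    strata <- c(cfg$hla$allele_A, cfg$hla$allele_B)
    names(strata) <- c("carrier_A", "carrier_B")
    out <- list()
    for (col in names(strata)) {
      al <- strata[[col]]
      if (!al %in% scores$scores$pattern_id) next
      sc <- scores$scores[scores$scores$pattern_id == al, ]
      pe <- predict_exposure(sc, vmeta, stratum = col)
      out[[al]] <- list(breadth_auc = pe$breadth$auc,
                        breadth_ci = unname(pe$breadth$ci95),
                        depth_auc = pe$depth$auc,
                        depth_ci = unname(pe$depth$ci95), n = pe$n)
    }
    if (!length(out) && "ES" %in% scores$scores$pattern_id) {
      sc <- scores$scores[scores$scores$pattern_id == "ES", ]
      pe <- predict_exposure(sc, vmeta, stratum = NULL)
      out[["ES"]] <- list(breadth_auc = pe$breadth$auc,
                          breadth_ci = unname(pe$breadth$ci95),
                          depth_auc = pe$depth$auc,
                          depth_ci = unname(pe$depth$ci95), n = pe$n)
    }
    write_stage_json(out, file.path(out_dir, "roc.json"))
    list(value = out,
         info = list(n_patterns = length(out), output = "roc.json"))
  })

  ## model ------------------------------------------------------------
  fits <- stage("model", function() {
    meta <- gen_trial_meta(vc$pipeline$arms, cfg,
                           seed = child_seed(cfg$seed, 40L))
    sim_cl <- gen_clinical(meta, cfg, seed = child_seed(cfg$seed, 41L))
    cov <- sim_cl$covariates
    has_gaifn <- any(cov$gaifn)
    covs <- c("age_norm", "sexm", "duration_norm", "ga",
              if (has_gaifn) "gaifn", "carrier_A", "carrier_B",
              "ga:carrier_A", "ga:carrier_B",
              if (has_gaifn) c("gaifn:carrier_A", "gaifn:carrier_B"))
    ag <- fit_cox_ag(dplyr::inner_join(sim_cl$recurrent, cov,
                                       by = "subject_id"), covs)
    fe <- fit_cox(dplyr::inner_join(sim_cl$first_event, cov,
                                    by = "subject_id"), covs)
    lin_dat <- dplyr::inner_join(sim_cl$continuous, meta,
                                 by = "subject_id")
    lin_dat$ga <- lin_dat$treatment_arm == "GA"
    lin <- fit_linear_interaction(lin_dat, "delta_edss", treatment = "ga")
    out <- list(andersen_gill = as.list(ag$coefficients),
                cox_first_event = as.list(fe$coefficients),
                linear_delta_edss = as.list(lin$coefficients))
    write_stage_json(out, file.path(out_dir, "models.json"))
    list(value = list(ag = ag, first = fe, linear = lin),
         info = list(output = "models.json"))
  })

  manifest$total_seconds <- round(proc.time()[3] - t_all, 2)
  write_stage_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

# Merge several trb_cohorts (disjoint samples) into one, for HLA
# assignment across the full discovery set.
pool_cohorts <- function(cohorts) {
  keys <- unique(unlist(lapply(cohorts, function(ch) ch$keys$key_id)))
  offs <- 0L
  pres <- list(); ids <- character(); case <- logical()
  for (ch in cohorts) {
    remap <- match(ch$keys$key_id, keys)
    p <- data.table::data.table(sample = ch$presence$sample + offs)
    p[, key := remap[ch$presence$key]]
    pres[[length(pres) + 1L]] <- p
    ids <- c(ids, ch$sample_ids)
    case <- c(case, ch$is_case)
    offs <- offs + length(ch$sample_ids)
  }
  structure(list(keys = key_table(keys),
                 presence = data.table::rbindlist(pres),
                 sample_ids = ids, is_case = case), class = "trb_cohort")
}

# Train an imputation model from a compact cohort: candidates are keys
# present in >= 5 samples, presence/R_unique derived from the pair table.
train_hla_model_from_cohort <- function(cohort, carrier, allele,
                                        min_presence = 5L, seed = NULL) {
  tab <- tabulate(cohort$presence$key, nbins = nrow(cohort$keys))
  cand <- which(tab >= min_presence)
  pm <- presence_matrix(cohort)[, cand, drop = FALSE]
  r_unique <- Matrix::rowSums(presence_matrix(cohort))
  train_hla_model(as.matrix(pm), carrier, r_unique = r_unique,
                  allele = allele, seed = seed)
}

# Patterns (keys + motifs) per allele from an assignment table.
assignment_patterns <- function(es, assignments, alleles) {
  pats <- list()
  for (al in alleles) {
    tg <- assignments$target[assignments$allele == al &
                               assignments$category %in%
                               c("assigned", "uncertain")]
    if (length(tg) == 0L) next
    kt <- key_table(tg)
    pats[[al]] <- es_pattern(kt$junction_aa, kt$v_gene, kt$j_gene)
  }
  pats
}
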