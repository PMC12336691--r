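#' Construct a TRB repertoire
#'
#' A repertoire is one sample's set of unique nucleotide-level rearrangements
#' with template counts. Summary denominators (`R_unique`, unique productive
#' rearrangements; `T_total`, productive templates) are always recomputed from
#' the rows, never trusted from input.
#'
#' @param rearrangements Data frame with columns `nucleotide_seq`,
#'   `junction_aa`, `v_gene`, `j_gene`, `templates`, `productive`.
#' @param sample_id,subject_id Sample / subject identifiers.
#' @param timepoint One of `"baseline"`, `"treated"`, `"single"`.
#' @return An object of class `trb_repertoire`: a list with the rearrangement
#'   tibble and recomputed `R_unique` and `T_total`.
#' @details Duplicate `nucleotide_seq` rows are merged with summed templates
#'   (with a warning); non-productive rows are retained but excluded from
#'   `R_unique` and `T_total`.
#' @export
repertoire <- function(rearrangements, sample_id, subject_id = sample_id,
                       timepoint = c("single", "baseline", "treated")) {
  timepoint <- match.arg(timepoint)
  req <- c("nucleotide_seq", "junction_aa", "v_gene", "j_gene",
           "templates", "productive")
  miss <- setdiff(req, names(rearrangements))
  if (length(miss)) stopf("missing rearrangement column(s): %s",
                          paste(miss, collapse = ", "))
  dt <- data.table::as.data.table(rearrangements)[, req, with = FALSE]
  dt[, templates := as.integer(templates)]
  dt[, productive := as.logical(productive)]
  if (nrow(dt) && any(dt$templates < 1L, na.rm = TRUE))
    stopf("templates must be >= 1")
  if (anyDuplicated(dt$nucleotide_seq)) {
    warnf("sample %s: duplicate nucleotide_seq rows merged (templates summed)",
          sample_id)
    dt <- dt[, list(junction_aa = junction_aa[1L], v_gene = v_gene[1L],
                    j_gene = j_gene[1L], templates = sum(templates),
                    productive = productive[1L]),
             by = "nucleotide_seq"]
  }
  bad <- dt$productive & (!nzchar(dt$junction_aa) | is.na(dt$junction_aa) |
                            is.na(dt$v_gene) | is.na(dt$j_gene))
  if (any(bad)) stopf("sample %s: %d productive row(s) lack junction/V/J",
                      sample_id, sum(bad))
  prod <- dt[dt$productive]
  structure(list(
    sample_id = as.character(sample_id),
    subject_id = as.character(subject_id),
    timepoint = timepoint,
    rearrangements = tibble::as_tibble(dt),
    R_unique = nrow(prod),
    T_total = if (nrow(prod)) sum(prod$templates) else 0L
  ), class = "trb_repertoire")
}

#' @export
print.trb_repertoire <- function(x, ...) {
  cat(sprintf(
    "<trb_repertoire> sample %s (subject %s, %s)\n  %d rearrangements; R_unique = %d, T_total = %d\n",
    x$sample_id, x$subject_id, x$timepoint, nrow(x$rearrangements),
    x$R_unique, x$T_total))
  invisible(x)
}

.airr_cols <- c(sequence = "nucleotide_seq", junction_aa = "junction_aa",
                v_call = "v_gene", j_call = "j_gene",
                duplicate_count = "templates", productive = "productive")
.iseq_cols <- c(nucleotide = "nucleotide_seq", aminoAcid = "junction_aa",
                vGeneName = "v_gene", jGeneName = "j_gene",
                "count (templates/reads)" = "templates",
                sequenceStatus = "productive")

#' Read a rearrangement table into a repertoire
#'
#' Reads an AIRR Community rearrangement TSV (columns `sequence`,
#' `junction_aa`, `v_call`, `j_call`, `duplicate_count`, `productive`) or an
#' immunoSEQ-style export (`nucleotide`, `aminoAcid`, `vGeneName`,
#' `jGeneName`, `count (templates/reads)` or `templates`, `sequenceStatus`).
#' Gene calls are canonicalized with [canonicalize_gene()].
#'
#' @param path Path to a TSV file.
#' @param dialect `"airr"` or `"immunoseq"`.
#' @param sample_id Sample identifier; defaults to the file name.
#' @inheritParams repertoire
#' @return A [repertoire()] object.
#' @export
read_repertoire <- function(path, dialect = c("airr", "immunoseq"),
                            sample_id = sub("\\.[^.]*$", "", basename(path)),
                            subject_id = sample_id, timepoint = "single") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", showProgress = FALSE,
                          data.table = TRUE)
  map <- if (dialect == "airr") .airr_cols else .iseq_cols
  if (dialect == "immunoseq" && !"count (templates/reads)" %in% names(dt)) {
    map[["count (templates/reads)"]] <- NULL
    map["templates"] <- "templates"
  }
  miss <- setdiff(names(map), names(dt))
  if (length(miss)) stopf("%s: missing required column(s) for dialect '%s': %s",
                          path, dialect, paste(miss, collapse = ", "))
  dt <- dt[, names(map), with = FALSE]
  data.table::setnames(dt, names(map), unname(map))
  for (cc in c("nucleotide_seq", "junction_aa", "v_gene", "j_gene"))
    dt[, (cc) := as.character(dt[[cc]])]
  dt[, productive := if (dialect == "airr")
    toupper(as.character(productive)) %in% c("T", "TRUE", "1")
    else as.character(productive) == "In"]
  dt[, v_gene := canonicalize_gene(v_gene)]
  dt[, j_gene := canonicalize_gene(j_gene)]
  repertoire(dt, sample_id = sample_id, subject_id = subject_id,
             timepoint = timepoint)
}

#' Write a repertoire as an AIRR rearrangement TSV
#'
#' Round-trips exactly through [read_repertoire()] with `dialect = "airr"`.
#'
#' @param rep A [repertoire()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path) {
  stopifnot(inherits(rep, "trb_repertoire"))
  dt <- data.table::as.data.table(rep$rearrangements)
  data.table::setnames(dt, unname(.airr_cols), names(.airr_cols))
  dt[, productive := ifelse(productive, "T", "F")]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a cohort: metadata plus one repertoire file per sample
#'
#' @param metadata_path CSV with at least `sample_id`; recognised columns
#'   include `subject_id`, `cohort_id`, `ga_exposed`, `treatment_arm`,
#'   `hla_genotype` (semicolon-separated allele names, empty/`unknown` for
#'   untyped), `age`, `sex`, `disease_duration`.
#' @param repertoire_dir Directory holding `<sample_id>.tsv` files.
#' @param dialect Passed to [read_repertoire()].
#' @return A list with `repertoires` (named list of [repertoire()] objects,
#'   aligned to metadata order), `meta` (tibble) and `report` (extra files
#'   present in the directory but absent from the metadata).
#' @export
read_cohort <- function(metadata_path, repertoire_dir,
                        dialect = c("airr", "immunoseq")) {
  dialect <- match.arg(dialect)
  meta <- tibble::as_tibble(data.table::fread(metadata_path,
                                              showProgress = FALSE))
  if (!"sample_id" %in% names(meta)) stopf("metadata lacks sample_id column")
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) stopf("duplicate sample_id in metadata")
  if ("hla_genotype" %in% names(meta)) {
    g <- as.character(meta$hla_genotype)
    meta$hla_genotype <- ifelse(is.na(g) | !nzchar(g) |
                                  tolower(g) == "unknown", NA_character_, g)
  }
  paths <- file.path(repertoire_dir, paste0(meta$sample_id, ".tsv"))
  missing <- meta$sample_id[!file.exists(paths)]
  if (length(missing))
    stopf("no repertoire file for sample(s): %s",
          paste(missing, collapse = ", "))
  reps <- lapply(seq_len(nrow(meta)), function(i)
    read_repertoire(paths[i], dialect = dialect,
                    sample_id = meta$sample_id[i],
                    subject_id = as.character(
                      meta$subject_id[i] %||% meta$sample_id[i])))
  names(reps) <- meta$sample_id
  extra <- setdiff(sub("\\.tsv$", "", list.files(repertoire_dir,
                                                 pattern = "\\.tsv$")),
                   meta$sample_id)
  list(repertoires = reps, meta = meta,
       report = list(extra_files = extra))
}

#' Does a metadata row carry a given HLA allele?
#'
#' @param hla_genotype Character vector of semicolon-separated allele sets
#'   (`NA` = untyped).
#' @param allele Allele name, e.g. `"A*03:01"`.
#' @return Logical vector (`NA` where untyped).
#' @export
carries_allele <- function(hla_genotype, allele) {
  vapply(strsplit(as.character(hla_genotype), ";"), function(g) {
    if (length(g) == 1L && is.na(g[1])) return(NA)
    allele %in% trimws(g)
  }, logical(1))
}
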