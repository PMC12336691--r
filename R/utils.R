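#' @importFrom stats glm lm coef predict phyper rbinom rnbinom rpois runif
#'   rnorm rexp binomial plogis quantile setNames sd as.formula pnorm vcov
#'   logLik model.matrix na.omit residuals
#' @importFrom utils head modifyList
NULL

.datatable.aware <- TRUE

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonical clonotype key identifier
#'
#' Collapses a CDR3 amino-acid junction plus V and J gene into the single
#' string used throughout the package to identify a clonotype.
#'
#' @param junction_aa Character vector of CDR3 amino-acid junctions.
#' @param v_gene,j_gene Character vectors of canonical gene names.
#' @return Character vector of `junction|V|J` identifiers.
#' @export
key_id <- function(junction_aa, v_gene, j_gene) {
  paste(junction_aa, v_gene, j_gene, sep = "|")
}

#' Canonicalize a TRB gene call
#'
#' Normalizes V/J gene calls across sequencing dialects to the zero-padded,
#' allele-stripped form used for cross-cohort clonotype matching
#' (e.g. `TRBV5-6*01`, `TCRBV05-06` and `TRBV5-6` all map to `TRBV05-06`).
#'
#' @param x Character vector of gene calls. Allele suffixes (`*01`) and
#'   anything after a comma or slash (multi-call ambiguity) are dropped;
#'   family and gene numbers are zero-padded to two digits.
#' @return Character vector of canonical names; calls that do not look like
#'   TRB genes (e.g. `unresolved`) are returned as `NA`.
#' @export
#' @examples
#' canonicalize_gene(c("TRBV5-6*01", "TCRBJ02-07", "TRBV28", "unresolved"))
canonicalize_gene <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- sub("[,/].*$", "", x)     # first call of an ambiguous list
  x <- sub("\\*.*$", "", x)      # strip allele
  x <- sub("^TCRB", "TRB", x)
  m <- regmatches(x, regexec("^TRB([VDJ])0*([0-9]+)(?:-0*([0-9]+))?$", x))
  vapply(m, function(g) {
    if (length(g) == 0L) return(NA_character_)
    out <- sprintf("TRB%s%02d", g[2], as.integer(g[3]))
    if (nzchar(g[4])) out <- sprintf("%s-%02d", out, as.integer(g[4]))
    out
  }, character(1))
}

#' Min-max scale a numeric vector
#'
#' Rescales to `[0, 1]` within the analysis dataset, the normalization used
#' for age and disease duration in the clinical interaction models.
#'
#' @param x Numeric vector.
#' @return Rescaled vector; constant input returns all zeros.
#' @export
min_max_scale <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (diff(r) == 0) return(rep(0, length(x)))
  (x - r[1]) / diff(r)
}

# Deterministic fan-out of one global seed into per-stage child seeds.
# Uses a fixed LCG step so stage k's seed does not depend on how many draws
# earlier stages consumed. Values kept strictly below 2^31.
child_seed <- function(seed, stage) {
  s <- (as.numeric(seed) * 48271 + 11 * as.numeric(stage)) %% 2147483629
  as.integer(s) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
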