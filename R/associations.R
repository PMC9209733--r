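#' Construct study metadata for a GWAS source
#'
#' Describes the cohort behind one summary-statistics file: a label, the
#' trait, its type, and sample sizes. Case/control counts may be left `NA`
#' when the source publication does not report them; when both are given,
#' `n` must equal their sum.
#'
#' @param label Cohort/source name (e.g. `"FinnGen"`).
#' @param trait Trait label (e.g. `"NAFLD"`).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n Total sample size in persons (`NA` if unknown).
#' @param n_cases,n_controls Case/control counts for binary traits
#'   (`NA` if unknown; 0 for quantitative traits).
#' @return A list of class `study_meta`.
#' @examples
#' study_meta("non-FinnGen", "NAFLD", "binary",
#'            n_cases = 1483, n_controls = 17781)
#' @export
study_meta <- function(label, trait, trait_type = c("quantitative", "binary"),
                       n = NA_real_, n_cases = NA_real_,
                       n_controls = NA_real_) {
  trait_type <- match.arg(trait_type)
  if (trait_type == "quantitative") {
    if (is.na(n_cases)) n_cases <- 0
    if (is.na(n_controls)) n_controls <- 0
  }
  if (trait_type == "binary" && !is.na(n_cases) && !is.na(n_controls)) {
    if (n_cases < 1 || n_controls < 1)
      stop("binary trait requires n_cases >= 1 and n_controls >= 1")
    if (is.na(n)) n <- n_cases + n_controls
    if (n != n_cases + n_controls)
      stop("n must equal n_cases + n_controls")
  }
  structure(list(label = label, trait = trait, trait_type = trait_type,
                 n = n, n_cases = n_cases, n_controls = n_controls),
            class = "study_meta")
}

# Canonical field names of an association table.
.assoc_fields <- c("rsid", "effect_allele", "other_allele", "eaf", "beta",
                   "se", "pvalue", "n", "n_cases", "n_controls", "trait",
                   "trait_type")

#' Assemble an association table from vectors
#'
#' Builds a validated data frame of per-variant summary associations (one
#' row per variant) in the canonical layout used throughout the package.
#'
#' @param rsid Variant identifiers.
#' @param effect_allele,other_allele Single-base alleles (A/C/G/T); the
#'   beta refers to the effect allele. Lower case is accepted and
#'   normalized to upper case.
#' @param eaf Effect-allele frequency in (0,1); `NA` if unavailable.
#' @param beta Per-allele effect (SD units for quantitative traits,
#'   log-odds for binary traits).
#' @param se Standard error of `beta` (> 0).
#' @param pvalue Association p-value in (0, 1]; `NA` if unavailable.
#' @param meta A [study_meta()] supplying trait label/type and sample sizes.
#' @return A `data.frame` with columns `rsid`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`, `n_cases`,
#'   `n_controls`, `trait`, `trait_type`.
#' @export
association_table <- function(rsid, effect_allele, other_allele, eaf, beta,
                              se, pvalue = NA_real_, meta) {
  stopifnot(inherits(meta, "study_meta"))
  k <- length(rsid)
  if (length(pvalue) == 1) pvalue <- rep(pvalue, k)
  df <- data.frame(
    rsid = as.character(rsid),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    eaf = as.numeric(eaf), beta = as.numeric(beta), se = as.numeric(se),
    pvalue = as.numeric(pvalue),
    n = rep(meta$n, k), n_cases = rep(meta$n_cases, k),
    n_controls = rep(meta$n_controls, k),
    trait = rep(meta$trait, k), trait_type = rep(meta$trait_type, k),
    stringsAsFactors = FALSE
  )
  validate_associations(df, mode = "strict")
}

# Per-row validation; returns character(0) when the row is valid, otherwise
# the names of the offending fields.
.row_problems <- function(row) {
  bad <- character(0)
  ok_allele <- function(a) !is.na(a) && nchar(a) == 1 && a %in% c("A", "C", "G", "T")
  if (is.na(row$rsid) || !nzchar(row$rsid)) bad <- c(bad, "rsid")
  if (!ok_allele(row$effect_allele)) bad <- c(bad, "effect_allele")
  if (!ok_allele(row$other_allele)) bad <- c(bad, "other_allele")
  if (ok_allele(row$effect_allele) && ok_allele(row$other_allele) &&
      row$effect_allele == row$other_allele)
    bad <- c(bad, "effect_allele")
  if (!is.na(row$eaf) && (row$eaf <= 0 || row$eaf >= 1)) bad <- c(bad, "eaf")
  if (is.na(row$beta)) bad <- c(bad, "beta")
  if (is.na(row$se) || row$se <= 0) bad <- c(bad, "se")
  if (!is.na(row$pvalue) && (row$pvalue <= 0 || row$pvalue > 1))
    bad <- c(bad, "pvalue")
  if (identical(row$trait_type, "binary") &&
      !is.na(row$n_cases) && !is.na(row$n_controls)) {
    if (row$n_cases < 1 || row$n_controls < 1) bad <- c(bad, "n_cases")
    if (!is.na(row$n) && row$n != row$n_cases + row$n_controls)
      bad <- c(bad, "n")
  }
  unique(bad)
}

#' Validate an association table
#'
#' Checks every row against the field invariants (positive SE, frequency
#' strictly inside (0,1), single distinct A/C/G/T alleles, p in (0,1],
#' consistent case/control counts). In `strict` mode the first invalid row
#' aborts with an error naming the row and field; in `lenient` mode invalid
#' rows are dropped with a message and recorded in the `"rejections"`
#' attribute of the result.
#'
#' @param assocs Data frame in the canonical association layout.
#' @param mode `"strict"` or `"lenient"`.
#' @param quiet Suppress per-row messages in lenient mode.
#' @return The validated (possibly reduced) data frame.
#' @export
validate_associations <- function(assocs, mode = c("strict", "lenient"),
                                  quiet = FALSE) {
  mode <- match.arg(mode)
  missing_cols <- setdiff(.assoc_fields, names(assocs))
  if (length(missing_cols))
    stop("association table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  assocs$effect_allele <- toupper(assocs$effect_allele)
  assocs$other_allele <- toupper(assocs$other_allele)
  keep <- rep(TRUE, nrow(assocs))
  rejections <- list()
  for (i in seq_len(nrow(assocs))) {
    bad <- .row_problems(assocs[i, ])
    if (length(bad)) {
      if (mode == "strict")
        stop(sprintf("invalid value in row %d, field '%s'", i, bad[1]))
      keep[i] <- FALSE
      rejections[[length(rejections) + 1L]] <-
        data.frame(row = i, rsid = assocs$rsid[i],
                   fields = paste(bad, collapse = ";"),
                   stringsAsFactors = FALSE)
      if (!quiet)
        message(sprintf("dropping row %d (%s): invalid %s",
                        i, assocs$rsid[i], paste(bad, collapse = ", ")))
    }
  }
  out <- assocs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- if (length(rejections))
    do.call(rbind, rejections)
  else
    data.frame(row = integer(0), rsid = character(0), fields = character(0))
  out
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a headered, tab-separated summary-statistics file into the
#' canonical association layout. Source files from different consortia use
#' different headers, so a `column_map` translates canonical field names to
#' the file's column names. Fields not covered by the map (`eaf`, `pvalue`)
#' are filled with `NA`; sample sizes and trait labels come from
#' `trait_meta` unless the file itself carries mapped `n`/`n_cases`/
#' `n_controls` columns.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param trait_meta A [study_meta()] describing the cohort and trait.
#' @param column_map Named character vector mapping canonical names
#'   (`rsid`, `effect_allele`, `other_allele`, `beta`, `se`, and optionally
#'   `eaf`, `pvalue`, `n`, `n_cases`, `n_controls`) to the file's column
#'   names. Defaults to the identity map for the required fields.
#' @param mode Validation mode, `"strict"` (default: any bad row is an
#'   error) or `"lenient"` (bad rows are skipped and logged).
#' @param sep Field separator (default tab).
#' @return Validated association data frame; row order of the file is
#'   preserved. Rejected rows (lenient mode) are recorded in the
#'   `"rejections"` attribute.
#' @examples
#' p <- system.file("extdata", "il6_exposure.tsv", package = "targetmr")
#' m <- study_meta("IL-6 GWAS", "IL-6", "quantitative", n = 30000)
#' read_associations(p, m, column_map = c(
#'   rsid = "SNP", effect_allele = "A1", other_allele = "A2",
#'   eaf = "EAF", beta = "BETA", se = "SE", pvalue = "P"))
#' @export
read_associations <- function(path, trait_meta, column_map = NULL,
                              mode = c("strict", "lenient"), sep = "\t") {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(inherits(trait_meta, "study_meta"))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  if (is.null(column_map))
    column_map <- stats::setNames(required, required)
  for (f in required) {
    if (!f %in% names(column_map))
      stop("column_map must cover field '", f, "'")
  }
  missing <- setdiff(unname(column_map), names(raw))
  if (length(missing))
    stop("mapped column(s) not present in file: ",
         paste(missing, collapse = ", "))
  pick <- function(f, default = NA_real_) {
    if (f %in% names(column_map)) raw[[column_map[[f]]]]
    else rep(default, nrow(raw))
  }
  k <- nrow(raw)
  df <- data.frame(
    rsid = as.character(pick("rsid")),
    effect_allele = toupper(as.character(pick("effect_allele"))),
    other_allele = toupper(as.character(pick("other_allele"))),
    eaf = as.numeric(pick("eaf")),
    beta = as.numeric(pick("beta")),
    se = as.numeric(pick("se")),
    pvalue = as.numeric(pick("pvalue")),
    n = as.numeric(pick("n", trait_meta$n)),
    n_cases = as.numeric(pick("n_cases", trait_meta$n_cases)),
    n_controls = as.numeric(pick("n_controls", trait_meta$n_controls)),
    trait = rep(trait_meta$trait, k),
    trait_type = rep(trait_meta$trait_type, k),
    stringsAsFactors = FALSE
  )
  if (nrow(df) == 0) {
    attr(df, "rejections") <-
      data.frame(row = integer(0), rsid = character(0), fields = character(0))
    return(df)
  }
  validate_associations(df, mode = mode)
}

# Normalize an MR estimate or meta-analysis result into the fixed results
# header. CI columns are on the odds scale for binary outcomes and on the
# beta scale otherwise.
.as_results_row <- function(x) {
  if ("model" %in% names(x)) {          # meta-analysis result
    binary <- !is.na(x$odds_ratio)
    data.frame(
      exposure = x$exposure, outcome = x$outcome,
      method = paste0("meta_", x$model), nsnp = NA_real_,
      beta = x$beta, se = x$se,
      or = x$odds_ratio,
      ci_low = if (binary) x$or_ci_low else x$ci_low,
      ci_high = if (binary) x$or_ci_high else x$ci_high,
      pvalue = x$pvalue, q = x$q, i2 = x$i2,
      stringsAsFactors = FALSE
    )
  } else {
    binary <- !is.na(x$odds_ratio)
    data.frame(
      exposure = x$exposure, outcome = x$outcome,
      method = x$method, nsnp = x$n_snps,
      beta = x$beta, se = x$se,
      or = x$odds_ratio,
      ci_low = if (binary) x$or_ci_low else x$ci_low,
      ci_high = if (binary) x$or_ci_high else x$ci_high,
      pvalue = x$pvalue, q = NA_real_, i2 = NA_real_,
      stringsAsFactors = FALSE
    )
  }
}

#' Write MR and meta-analysis results to a tab-separated table
#'
#' Emits a TSV with the fixed header `exposure, outcome, method, nsnp,
#' beta, se, or, ci_low, ci_high, pvalue, q, i2`. Odds ratios and their
#' confidence bounds are rendered with a configurable number of decimals
#' (default 2, the reporting precision conventional for odds ratios);
#' `beta`, `se` and `pvalue` keep full precision. For quantitative
#' outcomes `or` is `NA` and `ci_low`/`ci_high` are on the beta scale.
#'
#' @param results A single estimate/meta result (one-row data frame from
#'   [wald_ratio()], [ivw()], [pool_fixed()], [pool_random()]) or a list of
#'   them; an empty list yields a header-only file.
#' @param path Output file path.
#' @param or_digits Decimals for `or`, `ci_low`, `ci_high`.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path, or_digits = 2) {
  if (is.data.frame(results)) results <- list(results)
  header <- c("exposure", "outcome", "method", "nsnp", "beta", "se", "or",
              "ci_low", "ci_high", "pvalue", "q", "i2")
  if (length(results) == 0) {
    tab <- as.data.frame(stats::setNames(
      replicate(length(header), character(0), simplify = FALSE), header))
  } else {
    tab <- do.call(rbind, lapply(results, .as_results_row))
    for (col in c("or", "ci_low", "ci_high")) {
      tab[[col]] <- ifelse(is.na(tab[[col]]), NA,
                           formatC(tab[[col]], digits = or_digits,
                                   format = "f"))
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
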