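#' Test whether an allele pair is palindromic
#'
#' A palindromic (ambiguous-strand) SNP has alleles that are reverse
#' complements of each other — A/T or C/G — so the strand of a reported
#' association cannot be resolved from the alleles alone.
#'
#' @param effect_allele,other_allele Single-base alleles (A/C/G/T),
#'   vectorized.
#' @return Logical vector.
#' @examples
#' is_palindromic("A", "T")  # TRUE
#' is_palindromic("C", "A")  # FALSE
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  a1 <- toupper(effect_allele)
  a2 <- toupper(other_allele)
  bad <- !(a1 %in% c("A", "C", "G", "T")) | !(a2 %in% c("A", "C", "G", "T"))
  if (any(bad))
    stop("non-ACGT allele: ",
         paste(unique(c(a1[bad], a2[bad])), collapse = ", "))
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

.complement <- function(a) {
  chartr("ACGT", "TGCA", toupper(a))
}

#' Selection criteria for genetic instruments
#'
#' Thresholds for instrument selection: genome-wide significance on the
#' exposure, a minor-allele-frequency floor, an LD r-squared ceiling for
#' greedy pruning, and whether palindromic variants are removed outright.
#' Defaults are the conventional cis-instrument choices (p < 5e-8,
#' MAF > 0.01, r^2 < 0.3, drop palindromes).
#'
#' @param p_max Exposure p-value must be strictly below this.
#' @param maf_min Minor-allele frequency `min(eaf, 1-eaf)` must be strictly
#'   above this.
#' @param ld_r2_max Candidates with r^2 at or above this against any kept
#'   variant are pruned.
#' @param drop_palindromic Remove A/T and C/G variants before pruning.
#' @return A list of class `selection_criteria`.
#' @export
selection_criteria <- function(p_max = 5e-8, maf_min = 0.01,
                               ld_r2_max = 0.3, drop_palindromic = TRUE) {
  stopifnot(p_max > 0, p_max < 1, maf_min >= 0, maf_min < 0.5,
            ld_r2_max >= 0, ld_r2_max <= 1, is.logical(drop_palindromic))
  structure(list(p_max = p_max, maf_min = maf_min, ld_r2_max = ld_r2_max,
                 drop_palindromic = drop_palindromic),
            class = "selection_criteria")
}

#' Construct a pairwise LD matrix
#'
#' Stores squared correlations (r-squared) between variant dosages, keyed
#' by rsID. The matrix must be symmetric with unit diagonal and values in
#' \[0, 1\].
#'
#' @param r2 Square numeric matrix of squared correlations.
#' @param rsids Variant identifiers (defaults to `rownames(r2)`).
#' @return A list of class `ld_matrix` with elements `rsids` and `r2`.
#' @export
ld_matrix <- function(r2, rsids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(rsids)) stop("rsids required (or set rownames on r2)")
  rsids <- as.character(rsids)
  stopifnot(nrow(r2) == ncol(r2), length(rsids) == nrow(r2))
  if (any(r2 < 0 | r2 > 1)) stop("LD r2 values must lie in [0, 1]")
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("LD matrix diagonal must be 1")
  if (any(abs(r2 - t(r2)) > 1e-8)) stop("LD matrix must be symmetric")
  dimnames(r2) <- list(rsids, rsids)
  structure(list(rsids = rsids, r2 = r2), class = "ld_matrix")
}

#' Read a pairwise LD matrix from a tab-separated file
#'
#' Accepts either a wide square matrix with rsID row/column labels, or a
#' long format with columns `rsid_a`, `rsid_b`, `r2` (unlisted pairs
#' default to r^2 = 0; the diagonal is implied).
#'
#' @param path Path to the TSV.
#' @return An [ld_matrix()].
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("rsid_a", "rsid_b", "r2") %in% names(raw))) {
    ids <- sort(unique(c(raw$rsid_a, raw$rsid_b)))
    m <- diag(length(ids))
    dimnames(m) <- list(ids, ids)
    for (i in seq_len(nrow(raw))) {
      m[raw$rsid_a[i], raw$rsid_b[i]] <- raw$r2[i]
      m[raw$rsid_b[i], raw$rsid_a[i]] <- raw$r2[i]
    }
    return(ld_matrix(m, ids))
  }
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  ld_matrix(m, ids)
}

subset_ld <- function(ld, rsids) {
  stopifnot(inherits(ld, "ld_matrix"))
  missing <- setdiff(rsids, ld$rsids)
  if (length(missing))
    stop("rsid(s) missing from LD matrix: ", paste(missing, collapse = ", "))
  ld_matrix(ld$r2[rsids, rsids, drop = FALSE], rsids)
}

#' Select genetic instruments for the exposure
#'
#' Applies the selection filters in order: exposure p-value below
#' `criteria$p_max`, minor-allele frequency above `criteria$maf_min`,
#' optional removal of palindromic variants, then greedy LD pruning —
#' survivors are ranked by ascending p-value (ties broken by rsID), the
#' best is kept, and any later candidate with r^2 at or above
#' `criteria$ld_r2_max` against a kept variant is dropped. Every decision
#' is recorded in the selection log.
#'
#' @param exposure_assocs Association table for the exposure.
#' @param criteria A [selection_criteria()].
#' @param ld An [ld_matrix()] covering every candidate that survives the
#'   p-value and MAF filters.
#' @return A list of class `instrument_set` with elements `assocs` (the
#'   retained exposure rows, in p-value order), `ld` (restricted to the
#'   retained rsIDs) and `selection_log` (one row per candidate with
#'   `retained` and `reason`).
#' @export
select_instruments <- function(exposure_assocs,
                               criteria = selection_criteria(), ld) {
  stopifnot(inherits(criteria, "selection_criteria"))
  a <- exposure_assocs
  log <- data.frame(rsid = character(0), retained = logical(0),
                    reason = character(0), stringsAsFactors = FALSE)
  note <- function(rsid, retained, reason) {
    rbind(log, data.frame(rsid = rsid, retained = retained, reason = reason,
                          stringsAsFactors = FALSE))
  }
  if (nrow(a) == 0) {
    empty_ld <- ld_matrix(matrix(numeric(0), 0, 0), character(0))
    return(structure(list(assocs = a, ld = empty_ld, selection_log = log),
                     class = "instrument_set"))
  }
  status <- rep(NA_character_, nrow(a))
  status[!(a$pvalue < criteria$p_max)] <- "pvalue >= threshold"
  maf <- pmin(a$eaf, 1 - a$eaf)
  status[is.na(status) & !(maf > criteria$maf_min)] <- "MAF <= threshold"
  if (criteria$drop_palindromic) {
    pal <- is_palindromic(a$effect_allele, a$other_allele)
    status[is.na(status) & pal] <- "palindromic"
  }
  survivors <- which(is.na(status))
  # greedy prune by ascending p, ties by rsid
  ord <- survivors[order(a$pvalue[survivors], a$rsid[survivors])]
  if (length(ord)) {
    ld_sub <- subset_ld(ld, a$rsid[ord])   # errors if a candidate is absent
    kept <- integer(0)
    for (i in ord) {
      if (length(kept)) {
        r2s <- ld_sub$r2[a$rsid[i], a$rsid[kept]]
        if (any(r2s >= criteria$ld_r2_max)) {
          clash <- a$rsid[kept][which(r2s >= criteria$ld_r2_max)[1]]
          status[i] <- sprintf("LD r2 >= %g with %s", criteria$ld_r2_max,
                               clash)
          next
        }
      }
      kept <- c(kept, i)
      status[i] <- "retained"
    }
  } else {
    kept <- integer(0)
  }
  for (i in seq_len(nrow(a)))
    log <- note(a$rsid[i], status[i] == "retained", status[i])
  retained <- a[kept, , drop = FALSE]
  rownames(retained) <- NULL
  ld_kept <- if (nrow(retained)) subset_ld(ld, retained$rsid)
             else ld_matrix(matrix(numeric(0), 0, 0), character(0))
  structure(list(assocs = retained, ld = ld_kept, selection_log = log),
            class = "instrument_set")
}

#' Harmonize an outcome association onto the exposure's effect allele
#'
#' Puts the exposure and outcome associations for one variant on a shared
#' effect allele. If the outcome reports the same allele pair the record
#' passes through; if the alleles are swapped the outcome beta is negated
#' and its frequency complemented; if the pair matches only after base
#' complementation a strand flip is recorded (and combined with a swap if
#' needed). Palindromic variants cannot be resolved from alleles: the
#' `drop` policy refuses them, while `infer_by_eaf` orients by comparing
#' allele frequencies and refuses when both frequencies sit inside the
#' ambiguity band around 0.5.
#'
#' @param exposure_rec,outcome_rec One-row association tables sharing an
#'   rsID.
#' @param palindromic_policy `"drop"` (default) or `"infer_by_eaf"`.
#' @param ambiguity_band Half-width of the frequency band around 0.5 inside
#'   which EAF-based inference is refused (default 0.08).
#' @return A one-row data frame (a harmonized pair) with the shared allele
#'   orientation, exposure and outcome betas/SEs/frequencies, a
#'   `palindromic` flag, the `orientation_action` taken, and the outcome
#'   trait labels.
#' @export
harmonize_pair <- function(exposure_rec, outcome_rec,
                           palindromic_policy = c("drop", "infer_by_eaf"),
                           ambiguity_band = 0.08) {
  palindromic_policy <- match.arg(palindromic_policy)
  e <- as.list(exposure_rec[1, ])
  o <- as.list(outcome_rec[1, ])
  if (!identical(e$rsid, o$rsid))
    stop("rsid mismatch: ", e$rsid, " vs ", o$rsid)
  pal <- is_palindromic(e$effect_allele, e$other_allele)
  action <- NULL
  if (pal) {
    if (!setequal(c(o$effect_allele, o$other_allele),
                  c(e$effect_allele, e$other_allele)))
      stop("incompatible alleles for palindromic variant ", e$rsid)
    if (palindromic_policy == "drop")
      stop("ambiguous palindromic variant ", e$rsid,
           " (policy 'drop'); use infer_by_eaf or remove it")
    if (is.na(e$eaf) || is.na(o$eaf))
      stop("infer_by_eaf requires both allele frequencies for ", e$rsid)
    if (abs(e$eaf - 0.5) <= ambiguity_band &&
        abs(o$eaf - 0.5) <= ambiguity_band)
      stop("cannot orient palindromic variant ", e$rsid,
           ": both allele frequencies within ", ambiguity_band, " of 0.5")
    same_side <- sign(e$eaf - 0.5) == sign(o$eaf - 0.5)
    if (sign(e$eaf - 0.5) == 0 || sign(o$eaf - 0.5) == 0)
      stop("cannot orient palindromic variant ", e$rsid,
           ": allele frequency exactly 0.5")
    if (same_side) {
      action <- "none"
    } else {
      action <- "allele_swap"
      o$beta <- -o$beta
      o$eaf <- 1 - o$eaf
    }
  } else if (o$effect_allele == e$effect_allele &&
             o$other_allele == e$other_allele) {
    action <- "none"
  } else if (o$effect_allele == e$other_allele &&
             o$other_allele == e$effect_allele) {
    action <- "allele_swap"
    o$beta <- -o$beta
    o$eaf <- 1 - o$eaf
  } else {
    oc_e <- .complement(o$effect_allele)
    oc_o <- .complement(o$other_allele)
    if (oc_e == e$effect_allele && oc_o == e$other_allele) {
      action <- "strand_flip"
    } else if (oc_e == e$other_allele && oc_o == e$effect_allele) {
      action <- "strand_flip_and_swap"
      o$beta <- -o$beta
      o$eaf <- 1 - o$eaf
    } else {
      stop("allele sets incompatible after complementation for ", e$rsid,
           ": exposure ", e$effect_allele, "/", e$other_allele,
           ", outcome ", outcome_rec$effect_allele[1], "/",
           outcome_rec$other_allele[1])
    }
  }
  data.frame(
    rsid = e$rsid,
    effect_allele = e$effect_allele, other_allele = e$other_allele,
    exposure_beta = e$beta, exposure_se = e$se, exposure_eaf = e$eaf,
    outcome_beta = o$beta, outcome_se = o$se, outcome_eaf = o$eaf,
    palindromic = pal, orientation_action = action,
    exposure = e$trait, outcome = o$trait, outcome_type = o$trait_type,
    stringsAsFactors = FALSE
  )
}

#' Harmonize all shared variants between two association tables
#'
#' Applies [harmonize_pair()] to every rsID present in both tables,
#' preserving the exposure table's order.
#'
#' @inheritParams harmonize_pair
#' @param exposure_assocs,outcome_assocs Association tables.
#' @return A data frame of harmonized pairs (zero rows if no rsID is
#'   shared).
#' @export
harmonize <- function(exposure_assocs, outcome_assocs,
                      palindromic_policy = c("drop", "infer_by_eaf"),
                      ambiguity_band = 0.08) {
  palindromic_policy <- match.arg(palindromic_policy)
  shared <- intersect(exposure_assocs$rsid, outcome_assocs$rsid)
  rows <- lapply(shared, function(id) {
    harmonize_pair(exposure_assocs[exposure_assocs$rsid == id, ][1, ],
                   outcome_assocs[outcome_assocs$rsid == id, ][1, ],
                   palindromic_policy, ambiguity_band)
  })
  if (!length(rows))
    return(data.frame())
  do.call(rbind, rows)
}

#' Align harmonized pairs to the exposure-increasing allele
#'
#' Re-orients each pair so the effect allele is the one that raises the
#' exposure: rows with a negative exposure beta have both betas negated,
#' allele labels swapped, and both frequencies complemented. The Wald
#' ratio is invariant under this operation; applying it twice equals
#' applying it once.
#'
#' @param pairs Harmonized pairs from [harmonize()] / [harmonize_pair()].
#' @return The pairs with `exposure_beta >= 0` everywhere.
#' @export
align_to_increasing <- function(pairs) {
  if (nrow(pairs) == 0) return(pairs)
  flip <- pairs$exposure_beta < 0
  if (any(flip)) {
    ea <- pairs$effect_allele[flip]
    pairs$effect_allele[flip] <- pairs$other_allele[flip]
    pairs$other_allele[flip] <- ea
    pairs$exposure_beta[flip] <- -pairs$exposure_beta[flip]
    pairs$outcome_beta[flip] <- -pairs$outcome_beta[flip]
    pairs$exposure_eaf[flip] <- 1 - pairs$exposure_eaf[flip]
    pairs$outcome_eaf[flip] <- 1 - pairs$outcome_eaf[flip]
  }
  pairs
}
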