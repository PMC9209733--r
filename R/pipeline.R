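#' Read a pipeline run configuration from a YAML file
#'
#' The configuration mirrors the arguments of [run_pipeline()]: an
#' `exposure` block (`file`, `label`, `trait`, `trait_type`, sample
#' sizes, optional `column_map`), a list of `outcomes` blocks of the same
#' shape, `ld_file`, an optional `criteria` block ([selection_criteria()]
#' fields), `se_method`, `ci_level`, `primary_instrument`,
#' `report_per_snp`, `meta_model` (`auto`/`fixed`/`random`), an optional
#' `external_estimates_file` (TSV with `cohort`, `outcome`, `or`,
#' `ci_low`, `ci_high`, optional `n_snps` — published per-cohort results
#' to include in the meta-analysis), `power_scenarios`, and
#' `output_dir`. Relative paths are resolved against the YAML file's
#' directory.
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n:` key as the boolean FALSE; restore it.
  fix_n <- function(x) {
    if (is.list(x)) {
      names(x)[names(x) %in% c("FALSE", "no")] <- "n"
      lapply(x, fix_n)
    } else x
  }
  cfg <- fix_n(cfg)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  cfg$exposure$file <- resolve(cfg$exposure$file)
  cfg$outcomes <- lapply(cfg$outcomes, function(o) {
    o$file <- resolve(o$file)
    o
  })
  cfg$ld_file <- resolve(cfg$ld_file)
  cfg$external_estimates_file <- resolve(cfg$external_estimates_file)
  validate_run_config(cfg)
}

#' Validate a pipeline run configuration
#'
#' @param cfg Configuration list (see [read_run_config()]).
#' @return The list, classed `run_config`, with defaults filled in.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$exposure) || is.null(cfg$exposure$file))
    stop("config error: exposure block with a file is required")
  if (is.null(cfg$outcomes) || !length(cfg$outcomes))
    stop("config error: at least one outcome block is required")
  if (is.null(cfg$ld_file))
    stop("config error: ld_file is required")
  for (f in c(cfg$exposure$file, vapply(cfg$outcomes, `[[`, "", "file"),
              cfg$ld_file, cfg$external_estimates_file))
    if (!file.exists(f)) stop("config error: file not found: ", f)
  labels <- vapply(cfg$outcomes, function(o) o$label %||% o$trait, "")
  if (anyDuplicated(labels))
    stop("config error: outcome labels must be unique")
  cfg$se_method <- cfg$se_method %||% "first_order"
  cfg$ci_level <- cfg$ci_level %||% 0.95
  cfg$meta_model <- cfg$meta_model %||% "auto"
  cfg$report_per_snp <- isTRUE(cfg$report_per_snp)
  cfg$criteria <- do.call(selection_criteria, cfg$criteria %||% list())
  structure(cfg, class = c("run_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.meta_from_block <- function(block) {
  study_meta(block$label %||% block$trait, block$trait,
             block$trait_type %||% "binary",
             n = block$n %||% NA_real_,
             n_cases = block$n_cases %||% NA_real_,
             n_controls = block$n_controls %||% NA_real_)
}

.read_block <- function(block, mode = "strict") {
  cm <- if (!is.null(block$column_map)) unlist(block$column_map) else NULL
  read_associations(block$file, .meta_from_block(block), column_map = cm,
                    mode = mode)
}

#' Run the full target-MR analysis pipeline
#'
#' Executes the stages in order: read summary statistics, select
#' instruments ([select_instruments()]), harmonize each outcome onto the
#' exposure's effect allele and align to the exposure-increasing allele
#' ([harmonize()], [align_to_increasing()]), estimate per-cohort causal
#' effects ([wald_ratio()] with one instrument, [ivw()] with several, plus
#' per-instrument and primary-instrument estimates when requested), pool
#' estimates sharing an outcome trait across cohorts — including published
#' per-cohort results supplied via `external_estimates_file` — with the
#' configured model policy ([pool_estimates()]), tabulate instrument F
#' statistics ([f_statistic()]) and power scenarios ([power_table()]).
#' Each stage writes a TSV into the output directory, plus a combined
#' results table and a run log recording every selection and model
#' decision. Any stage error aborts the run, names the stage, and removes
#' partial outputs. Re-running an unchanged configuration is
#' bit-identical.
#'
#' @param config A `run_config` list (from [read_run_config()] or
#'   [validate_run_config()]).
#' @param output_dir Overrides `config$output_dir`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `instruments`, `harmonized`,
#'   `estimates`, `meta`, `f_statistics`, `power`, `log`, and the output
#'   file paths.
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  out_dir <- output_dir %||% config$output_dir
  if (is.null(out_dir)) stop("config error: output_dir is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
    invisible(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, path)
    path
  }

  # -- read inputs ---------------------------------------------------------
  exposure <- stage("read", .read_block(config$exposure))
  ld <- stage("read", read_ld(config$ld_file))
  outcome_blocks <- config$outcomes
  outcomes <- stage("read", lapply(outcome_blocks, .read_block))
  say("read %d exposure variants, %d outcome source(s)", nrow(exposure),
      length(outcomes))

  # -- instrument selection ------------------------------------------------
  instruments <- stage("select",
                       select_instruments(exposure, config$criteria, ld))
  for (i in seq_len(nrow(instruments$selection_log)))
    say("selection: %s -> %s", instruments$selection_log$rsid[i],
        instruments$selection_log$reason[i])
  if (nrow(instruments$assocs) == 0)
    stage("select", stop("no instruments retained"))
  emit(instruments$selection_log, "selection.tsv")

  # -- harmonization -------------------------------------------------------
  harmonized <- stage("harmonize", {
    hl <- lapply(seq_along(outcomes), function(i) {
      h <- harmonize(instruments$assocs, outcomes[[i]])
      if (nrow(h)) {
        h <- align_to_increasing(h)
        h$cohort <- outcome_blocks[[i]]$label %||% outcome_blocks[[i]]$trait
      }
      h
    })
    do.call(rbind, hl[vapply(hl, nrow, 0L) > 0])
  })
  if (is.null(harmonized) || nrow(harmonized) == 0)
    stage("harmonize", stop("no variant shared between exposure and any outcome"))
  say("harmonized %d exposure-outcome pairs", nrow(harmonized))
  emit(harmonized, "harmonized.tsv")

  # -- per-cohort estimation ----------------------------------------------
  est <- stage("estimate", {
    rows <- list()
    meta_rows <- list()
    for (cohort in unique(harmonized$cohort)) {
      pairs <- harmonized[harmonized$cohort == cohort, , drop = FALSE]
      headline <- if (nrow(pairs) == 1)
        wald_ratio(pairs, config$se_method, config$ci_level)
      else
        ivw(pairs, config$ci_level)
      headline$cohort <- cohort
      rows[[length(rows) + 1]] <- headline
      say("estimate [%s]: %s over %d instrument(s), beta %.4f (se %.4f)",
          cohort, headline$method, headline$n_snps, headline$beta,
          headline$se)
      chosen <- headline
      if (!is.null(config$primary_instrument) &&
          config$primary_instrument %in% pairs$rsid && nrow(pairs) > 1) {
        prim <- wald_ratio(pairs[pairs$rsid == config$primary_instrument, ],
                           config$se_method, config$ci_level)
        prim$cohort <- cohort
        rows[[length(rows) + 1]] <- prim
        chosen <- prim
        say("estimate [%s]: primary instrument %s, beta %.4f", cohort,
            config$primary_instrument, prim$beta)
      }
      if (config$report_per_snp && nrow(pairs) > 1) {
        for (j in seq_len(nrow(pairs))) {
          wr <- wald_ratio(pairs[j, ], config$se_method, config$ci_level)
          wr$method <- paste0("wald_ratio[", pairs$rsid[j], "]")
          wr$cohort <- cohort
          rows[[length(rows) + 1]] <- wr
        }
      }
      meta_rows[[length(meta_rows) + 1]] <- chosen
    }
    list(rows = rows, meta_rows = meta_rows)
  })
  estimates <- do.call(rbind, est$rows)
  emit(estimates, "estimates.tsv")

  # -- meta-analysis across cohorts ---------------------------------------
  meta_input <- do.call(rbind, est$meta_rows)
  if (!is.null(config$external_estimates_file)) {
    ext <- stage("meta", {
      tab <- utils::read.table(config$external_estimates_file, header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
      do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
        r <- reconstruct_estimate(
          tab$or[i], tab$ci_low[i], tab$ci_high[i],
          ci_level = config$ci_level,
          exposure = config$exposure$trait, outcome = tab$outcome[i],
          method = "reconstructed",
          n_snps = if ("n_snps" %in% names(tab)) tab$n_snps[i] else NA)
        r$cohort <- tab$cohort[i]
        r
      }))
    })
    say("loaded %d external per-cohort estimate(s)", nrow(ext))
    meta_input <- rbind(meta_input, ext)
  }
  meta <- stage("meta", {
    out <- list()
    for (tr in unique(meta_input$outcome)) {
      grp <- meta_input[meta_input$outcome == tr, , drop = FALSE]
      grp$cohort <- NULL
      model <- config$meta_model
      if (model == "auto") {
        model <- decide_model(grp)
        say("meta [%s]: k = %d, model '%s' chosen by heterogeneity rule",
            tr, nrow(grp), model)
      }
      out[[tr]] <- pool_estimates(grp, model, config$ci_level)
    }
    do.call(rbind, out)
  })
  emit(meta, "meta.tsv")

  # -- F statistics and power ---------------------------------------------
  f_tab <- data.frame(rsid = instruments$assocs$rsid,
                      f = unname(f_statistic(instruments$assocs)),
                      stringsAsFactors = FALSE)
  emit(f_tab, "f_statistics.tsv")
  power <- NULL
  if (!is.null(config$power_scenarios)) {
    power <- stage("power", {
      scen <- do.call(rbind, lapply(config$power_scenarios, function(s) {
        r2 <- s[["r2"]]              # [[ avoids partial match on r2_from
        if (is.null(r2)) {
          ids <- s[["r2_from"]] %||% instruments$assocs$rsid
          sel <- instruments$assocs[instruments$assocs$rsid %in% ids, ]
          r2 <- instrument_r2(sel$eaf, sel$beta)
        }
        power_scenario(n = s$n, case_fraction = s$case_fraction,
                       or_per_sd = s$or_per_sd, r2 = r2,
                       alpha = s$alpha %||% 0.05,
                       label = s$label %||% NA_character_)
      }))
      power_table(scen)
    })
    emit(power, "power.tsv")
  }

  # -- combined reporting table -------------------------------------------
  combined <- c(
    lapply(seq_len(nrow(estimates)), function(i) estimates[i, ]),
    lapply(seq_len(nrow(meta)), function(i) meta[i, ])
  )
  res_path <- file.path(out_dir, "results.tsv")
  write_results_table(combined, res_path,
                      or_digits = config$or_digits %||% 2)
  written <- c(written, res_path)
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  written <- c(written, log_path)
  ok <- TRUE
  invisible(list(instruments = instruments, harmonized = harmonized,
                 estimates = estimates, meta = meta, f_statistics = f_tab,
                 power = power, log = log_lines, files = unique(written)))
}
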