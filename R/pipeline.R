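DEFAULT_THRESHOLDS <- list(p_instrument = 5e-8, r2_clump = 0.001,
                           alpha_primary = 0.0125, alpha_nominal = 0.05,
                           palindrome_window = 0.08)

#' Build a study configuration
#'
#' A `study_config` names the GWAS tables of a study (exposures, outcomes,
#' optional mediators and covariates), the LD source, the analysis
#' thresholds, and the seeds. `tables` is a named list; each entry needs
#' `path` and may set `trait_units`, `is_binary`, `sex`, `per_unit_decrease`,
#' `column_map` and `n`. Thresholds default to genome-wide instrument
#' selection at `5e-8`, clumping at `r2 < 0.001`, a Bonferroni-style primary
#' significance level of `0.0125` (four exposures per outcome, fixed by
#' design rather than recomputed) and a nominal level of `0.05`.
#'
#' @param x a list with fields `tables`, `exposures`, `outcomes`,
#'   `mediators`, `covariates`, `ld_path`, `thresholds`, `seed`, `out_dir`,
#'   or a path to a JSON file holding one.
#' @return a validated `study_config`.
#' @export
study_config <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop_mr("mr_io_error", "config file not found: %s", x)
    x <- jsonlite::read_json(x, simplifyVector = TRUE)
    if (is.data.frame(x$tables)) x$tables <- split(x$tables, seq_len(nrow(x$tables)))
  }
  stopifnot(is.list(x))
  cfg <- list(tables = x$tables %||% list(),
              exposures = as.character(x$exposures %||% character()),
              outcomes = as.character(x$outcomes %||% character()),
              mediators = as.character(x$mediators %||% character()),
              covariates = as.character(x$covariates %||% character()),
              ld_path = x$ld_path %||% NULL,
              thresholds = utils::modifyList(DEFAULT_THRESHOLDS,
                                             as.list(x$thresholds %||% list())),
              seed = as.integer(x$seed %||% 1L),
              out_dir = x$out_dir %||% NULL)
  th <- cfg$thresholds
  if (th$alpha_primary > th$alpha_nominal) {
    stop_mr("mr_validation_error",
            "alpha_primary (%g) must not exceed alpha_nominal (%g)",
            th$alpha_primary, th$alpha_nominal)
  }
  referenced <- c(cfg$exposures, cfg$outcomes, cfg$mediators, cfg$covariates)
  missing_tbl <- setdiff(referenced, names(cfg$tables))
  if (length(missing_tbl)) {
    stop_mr("mr_validation_error", "config references unknown table(s): %s",
            paste(missing_tbl, collapse = ", "))
  }
  structure(cfg, class = "study_config")
}

#' Load every table referenced by a study configuration
#'
#' @param config a `study_config` (or anything [study_config()] accepts).
#' @return a `study` object: the config, named `gwas_table`s, and the
#'   `ld_matrix` (empty when no `ld_path` is given).
#' @export
load_study <- function(config) {
  cfg <- if (inherits(config, "study_config")) config else study_config(config)
  tables <- lapply(names(cfg$tables), function(nm) {
    spec <- cfg$tables[[nm]]
    read_gwas(spec$path,
              column_map = spec$column_map %||% NULL,
              trait_name = nm,
              trait_units = spec$trait_units %||% "unit",
              is_binary = isTRUE(spec$is_binary),
              sex = spec$sex %||% "both",
              n = spec$n %||% NA_real_)
  })
  names(tables) <- names(cfg$tables)
  ld <- if (!is.null(cfg$ld_path)) read_ld(cfg$ld_path) else ld_matrix()
  structure(list(config = cfg, tables = tables, ld = ld), class = "mr_study")
}

per_unit_decrease <- function(cfg, name) {
  isTRUE(cfg$tables[[name]]$per_unit_decrease)
}

# shared select -> harmonize -> clump front end; returns the instrument set
# and the conservation audit (#selected = #retained + sum(dropped-by-action))
fit_pair <- function(study, exp_name, out_name) {
  cfg <- study$config
  th <- cfg$thresholds
  ins <- select_instruments(study$tables[[exp_name]], th$p_instrument)
  h <- harmonize(ins, study$tables[[out_name]], th$palindrome_window)
  hc <- clump(h, study$ld, th$r2_clump)
  cts <- attr(h, "counts")
  strength <- tryCatch({
    ins_kept <- gwas_subset(ins, match(hc$snp, ins$snp))
    suppressWarnings(overall_strength(ins_kept))
  }, error = function(e) NULL)
  audit <- data.frame(
    exposure = exp_name, outcome = out_name,
    n_selected = nrow(ins),
    n_absent_in_outcome = cts$absent_in_outcome,
    n_dropped_palindrome = cts$dropped_palindrome,
    n_dropped_incompatible = cts$dropped_incompatible,
    n_harmonized = nrow(h),
    n_clumped_away = nrow(h) - nrow(hc),
    n_retained = nrow(hc),
    f_overall = if (is.null(strength)) NA_real_ else strength$f_overall,
    r2_total = if (is.null(strength)) NA_real_ else strength$r2_total,
    stringsAsFactors = FALSE)
  list(h = hc, audit = audit)
}

result_row <- function(r, exposure, outcome, adjusted_for = "none", extra = list()) {
  row <- data.frame(exposure = exposure, outcome = outcome,
                    method = r$method, n_snp = r$n_snp,
                    estimate = r$estimate, se = r$se,
                    or = r$or %||% NA_real_,
                    ci_low = r$ci_low, ci_high = r$ci_high, pval = r$pval,
                    adjusted_for = adjusted_for, stringsAsFactors = FALSE)
  if (length(extra)) for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  row
}

#' Primary IVW analyses for every exposure-outcome pair
#'
#' For each pair: instrument selection, harmonization, clumping, IVW with
#' multiplicative random effects (Wald ratio when a single instrument
#' survives), and conversion to the odds-ratio reporting scale for binary
#' outcomes, honouring each exposure's `per_unit_decrease` flag.
#' Significance is flagged at both the primary (Bonferroni 0.0125) and
#' nominal (0.05) levels. Pair-level failures are logged, not fatal.
#'
#' @param study an `mr_study` from [load_study()].
#' @return list with `results` (data frame, one row per pair), `audit`
#'   (instrument bookkeeping per pair) and `failures`.
#' @export
run_primary <- function(study) {
  cfg <- study$config
  th <- cfg$thresholds
  results <- list(); audits <- list(); failures <- character(0)
  for (ex in cfg$exposures) for (ou in cfg$outcomes) {
    key <- paste(ex, ou, sep = " -> ")
    got <- tryCatch({
      fp <- fit_pair(study, ex, ou)
      r <- ivw(fp$h)
      if (!is.null(r$or)) r <- to_odds_ratio(r, per_unit_decrease(cfg, ex))
      row <- result_row(r, ex, ou, extra = list(
        or_low = r$or_low %||% NA_real_, or_high = r$or_high %||% NA_real_,
        q_stat = r$q_stat %||% NA_real_, phi = r$phi %||% NA_real_,
        primary_significant = r$pval < th$alpha_primary,
        nominal_significant = r$pval < th$alpha_nominal))
      list(row = row, audit = fp$audit)
    }, error = function(e) e)
    if (inherits(got, "error")) {
      failures[[key]] <- conditionMessage(got)
      mr_log("WARN", "primary %s failed: %s", key, conditionMessage(got))
    } else {
      results[[key]] <- got$row
      audits[[key]] <- got$audit
    }
  }
  list(results = rbind_fill(results),
       audit = rbind_fill(audits),
       failures = failures)
}

#' Sensitivity suite: weighted median, MR-Egger, MR-PRESSO
#'
#' Reuses the harmonized, clumped instrument set of each pair. Methods whose
#' preconditions fail (fewer than 3 SNPs for the median and Egger, fewer
#' than 4 for MR-PRESSO) are skipped with a logged reason. Seeds derive from
#' the study seed, so the whole table is reproducible.
#'
#' @param study an `mr_study`.
#' @param n_boot bootstrap replicates for the weighted median SE.
#' @param n_sim simulation replicates for MR-PRESSO.
#' @return list with `results` (rows per pair and method, including the Egger
#'   intercept and the PRESSO global/distortion p-values), `skips`, `failures`.
#' @export
run_sensitivity <- function(study, n_boot = 1000, n_sim = 1000) {
  cfg <- study$config
  results <- list(); skips <- character(0); failures <- character(0)
  seed <- cfg$seed
  for (ex in cfg$exposures) for (ou in cfg$outcomes) {
    key <- paste(ex, ou, sep = " -> ")
    fp <- tryCatch(fit_pair(study, ex, ou), error = function(e) e)
    if (inherits(fp, "error")) {
      failures[[key]] <- conditionMessage(fp)
      next
    }
    h <- fp$h
    pud <- per_unit_decrease(cfg, ex)
    orify <- function(r) if (!is.null(r$or)) to_odds_ratio(r, pud) else r
    if (nrow(h) >= 3) {
      wm <- orify(weighted_median(h, n_boot = n_boot, seed = seed))
      results[[paste(key, "wm")]] <- result_row(wm, ex, ou)
      eg <- tryCatch(egger(h), error = function(e) e)
      if (inherits(eg, "error")) {
        skips[[paste(key, "egger")]] <- conditionMessage(eg)
      } else {
        slope <- orify(eg$slope)
        results[[paste(key, "egger")]] <- result_row(
          slope, ex, ou,
          extra = list(egger_intercept = eg$intercept$estimate,
                       egger_intercept_se = eg$intercept$se,
                       egger_intercept_pval = eg$intercept$pval))
      }
    } else {
      skips[[paste(key, "wm")]] <- sprintf("%d SNP(s) < 3", nrow(h))
      skips[[paste(key, "egger")]] <- sprintf("%d SNP(s) < 3", nrow(h))
    }
    if (nrow(h) >= 4) {
      pr <- mr_presso(h, n_sim = n_sim, seed = seed)
      results[[paste(key, "presso")]] <- result_row(
        orify(pr$corrected), ex, ou,
        extra = list(presso_global_pval = pr$global_pval,
                     presso_n_outliers = nrow(pr$outliers),
                     presso_distortion_pval = pr$distortion_pval))
    } else {
      skips[[paste(key, "presso")]] <- sprintf("%d SNP(s) < 4", nrow(h))
    }
    seed <- seed + 1L
  }
  list(results = rbind_fill(results),
       skips = skips, failures = failures)
}

nominal_pairs <- function(primary) {
  res <- primary$results
  if (!nrow(res)) return(res[0, c("exposure", "outcome")])
  res[res$nominal_significant, c("exposure", "outcome"), drop = FALSE]
}

#' Bidirectional (reverse-direction) MR
#'
#' For pairs passing the nominal gate on primary analysis, swaps the
#' exposure and outcome roles and reruns the univariable pipeline. Reverse
#' results are reported as beta coefficients with SEs — never odds ratios —
#' because the reversed outcome is the original (continuous) exposure.
#'
#' @param study an `mr_study`.
#' @param primary output of [run_primary()] (pairs are re-derived from it).
#' @return list with `results`, `skips`.
#' @export
run_bidirectional <- function(study, primary) {
  pairs <- nominal_pairs(primary)
  results <- list(); skips <- character(0)
  for (i in seq_len(nrow(pairs))) {
    ex <- pairs$outcome[i]; ou <- pairs$exposure[i]   # reversed roles
    key <- paste(ex, ou, sep = " -> ")
    got <- tryCatch({
      fp <- fit_pair(study, ex, ou)
      r <- ivw(fp$h)
      r$or <- r$or_low <- r$or_high <- NULL           # beta/SE reporting scale
      result_row(r, ex, ou, extra = list(direction = "reverse"))
    }, error = function(e) e)
    if (inherits(got, "error")) skips[[key]] <- conditionMessage(got)
    else results[[key]] <- got
  }
  list(results = rbind_fill(results), skips = skips)
}

#' Covariate-adjusted (multivariable) analyses
#'
#' Runs [mvmr_ivw()] with the covariate as co-exposure for every pair that
#' passed the nominal gate, mirroring covariate adjustment for educational
#' attainment. Adjusted estimates are reported next to the unadjusted ones.
#'
#' @param study an `mr_study`.
#' @param primary output of [run_primary()].
#' @param covariate name of a table in the config (defaults to the first
#'   entry of `covariates`).
#' @return list with `results`, `skips`.
#' @export
run_adjusted <- function(study, primary, covariate = NULL) {
  cfg <- study$config
  covariate <- covariate %||% cfg$covariates[1]
  if (is.null(covariate) || is.na(covariate)) {
    stop_mr("mr_validation_error", "no covariate configured")
  }
  th <- cfg$thresholds
  pairs <- nominal_pairs(primary)
  results <- list(); skips <- character(0)
  for (i in seq_len(nrow(pairs))) {
    ex <- pairs$exposure[i]; ou <- pairs$outcome[i]
    key <- paste(ex, ou, sep = " -> ")
    got <- tryCatch({
      mv <- mvmr_ivw(stats::setNames(list(study$tables[[ex]],
                                          study$tables[[covariate]]),
                                     c(ex, covariate)),
                     study$tables[[ou]], study$ld,
                     th$p_instrument, th$r2_clump, th$palindrome_window)
      eff <- mv$effects[1, ]
      unadj <- primary$results[primary$results$exposure == ex &
                                 primary$results$outcome == ou, ]
      est <- eff$estimate; ci <- c(eff$ci_low, eff$ci_high)
      if (mv$outcome_binary && per_unit_decrease(cfg, ex)) {
        est <- -est; ci <- rev(-ci)
      }
      data.frame(exposure = ex, outcome = ou, method = "mvmr_ivw",
                 n_snp = mv$n_snp, estimate = est, se = eff$se,
                 or = if (mv$outcome_binary) exp(est) else NA_real_,
                 ci_low = ci[1], ci_high = ci[2], pval = eff$pval,
                 adjusted_for = covariate,
                 conditional_F = mv$conditional_F[1],
                 unadjusted_estimate = unadj$estimate[1],
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(got, "error")) skips[[key]] <- conditionMessage(got)
    else results[[key]] <- got
  }
  list(results = rbind_fill(results), skips = skips)
}

#' Step-wise mediation for every configured pathway
#'
#' @param study an `mr_study`.
#' @return list with `results` (Table-3-shaped data frame: per pair the
#'   unadjusted total effect followed by one mediator-adjusted row per
#'   carried-forward mediator), `reports` (the `mediation_report` objects)
#'   and `failures`.
#' @export
run_mediation <- function(study) {
  cfg <- study$config
  th <- cfg$thresholds
  meds <- stats::setNames(lapply(cfg$mediators, function(m) study$tables[[m]]),
                          cfg$mediators)
  rows <- list(); reports <- list(); failures <- character(0)
  for (ex in cfg$exposures) for (ou in cfg$outcomes) {
    key <- paste(ex, ou, sep = " -> ")
    reps <- tryCatch(
      mediate(study$tables[[ex]], study$tables[[ou]], meds, study$ld,
              screen_alpha = th$alpha_nominal, p_threshold = th$p_instrument,
              r2_clump = th$r2_clump, palindrome_window = th$palindrome_window),
      error = function(e) e)
    if (inherits(reps, "error")) {
      failures[[key]] <- conditionMessage(reps)
      next
    }
    fails <- attr(reps, "failures")
    if (length(fails)) {
      for (nm in names(fails)) failures[[paste(key, nm)]] <- fails[[nm]]
    }
    total <- attr(reps, "total")
    if (!is.null(total) && length(reps)) {
      rows[[paste(key, "total")]] <- result_row(total, ex, ou, "none")
      for (rp in reps) {
        rows[[paste(key, rp$mediator)]] <- data.frame(
          exposure = ex, outcome = ou, method = "mvmr_ivw",
          n_snp = rp$mvmr$n_snp, estimate = rp$direct$estimate,
          se = rp$direct$se, or = rp$direct$or %||% NA_real_,
          ci_low = rp$direct$ci_low, ci_high = rp$direct$ci_high,
          pval = rp$direct$pval, adjusted_for = rp$mediator,
          attenuation = rp$attenuation, stringsAsFactors = FALSE)
      }
    }
    reports[[key]] <- reps
  }
  list(results = rbind_fill(rows),
       reports = reports, failures = failures)
}

#' Run the complete study and write all outputs
#'
#' Orchestrates primary, sensitivity, bidirectional, covariate-adjusted and
#' mediation analyses, writes each fragment as TSV under the output
#' directory together with the instrument audit and a reproducibility
#' manifest (config hash, seed, package version).
#'
#' @param config a `study_config`, config list, or JSON path.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @param n_boot,n_sim Monte-Carlo sizes passed to the sensitivity suite.
#' @return a `study_report` list with all fragments, invisibly writing TSVs.
#' @export
run_study <- function(config, out_dir = NULL, n_boot = 1000, n_sim = 1000) {
  study <- if (inherits(config, "mr_study")) config else load_study(config)
  cfg <- study$config
  out_dir <- out_dir %||% cfg$out_dir
  primary <- run_primary(study)
  sensitivity <- run_sensitivity(study, n_boot = n_boot, n_sim = n_sim)
  bidirectional <- run_bidirectional(study, primary)
  adjusted <- if (length(cfg$covariates)) run_adjusted(study, primary) else NULL
  mediation <- if (length(cfg$mediators)) run_mediation(study) else NULL
  report <- structure(list(primary = primary, sensitivity = sensitivity,
                           bidirectional = bidirectional, adjusted = adjusted,
                           mediation = mediation, config = cfg),
                      class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    frag <- function(df, name) {
      if (!is.null(df) && nrow(df)) write_tsv_full(df, file.path(out_dir, name))
    }
    frag(primary$results, "primary.tsv")
    frag(primary$audit, "instrument_audit.tsv")
    frag(sensitivity$results, "sensitivity.tsv")
    frag(bidirectional$results, "bidirectional.tsv")
    if (!is.null(adjusted)) frag(adjusted$results, "adjusted.tsv")
    if (!is.null(mediation)) frag(mediation$results, "mediation.tsv")
    manifest <- list(package = "mrkit",
                     version = as.character(utils::packageVersion("mrkit")),
                     seed = cfg$seed,
                     thresholds = cfg$thresholds,
                     config_hash = config_hash(cfg),
                     r_version = R.version.string)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(tmp))
}
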