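#' Analysis configuration
#'
#' Thresholds and options for the adaptive per-region ANCOVA pipeline.
#'
#' @param screen_p Covariate screening p threshold (default 0.05, strict).
#' @param screen_r Covariate screening |r| threshold (default 0.4, strict).
#' @param interaction_p Interaction screening p threshold (default 0.05).
#' @param fdr_q Significance threshold on q-values (default 0.05).
#' @param pi0 Fixed pi0 for the q-value step, or `NULL` (default) to let
#'   [qvalue_family()] decide (spline estimate for families of at least
#'   `min_m_spline` tests, pi0 = 1 below that).
#' @param min_m_spline Small-family cutoff for the pi0 spline (default 20).
#' @param seed Seed recorded in reports for provenance.
#' @return An object of class `ahglm_config`.
#' @export
ahglm_config <- function(screen_p = 0.05, screen_r = 0.4,
                         interaction_p = 0.05, fdr_q = 0.05, pi0 = NULL,
                         min_m_spline = 20L, seed = NULL) {
  structure(list(screen_p = screen_p, screen_r = screen_r,
                 interaction_p = interaction_p, fdr_q = fdr_q, pi0 = pi0,
                 min_m_spline = as.integer(min_m_spline), seed = seed),
            class = "ahglm_config")
}

#' Read an analysis configuration from YAML
#'
#' Recognised keys match the arguments of [ahglm_config()]; unknown keys
#' produce a warning and are ignored.
#'
#' @param path YAML file.
#' @return An [ahglm_config()].
#' @export
read_ahglm_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(ahglm_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    warning("ignoring unknown config key(s): ", paste(extra, collapse = ", "))
  do.call(ahglm_config, vals[intersect(names(vals), known)])
}

#' Relative group difference in percent
#'
#' `(mean_med - mean_ctrl) * 100 / mean_ctrl` — the convention used for all
#' tabulated group contrasts.
#'
#' @param mean_ctrl Control-group mean (must be positive).
#' @param mean_med Meditator-group mean.
#' @return Percent difference.
#' @export
relative_difference <- function(mean_ctrl, mean_med) {
  if (any(mean_ctrl <= 0)) stop("control mean must be positive")
  (mean_med - mean_ctrl) * 100 / mean_ctrl
}

#' Share of a volume difference relative to the whole-brain difference
#'
#' @param part_ml Summed difference over a set of regions, mL (or mm^3 —
#'   any unit, as long as both arguments share it).
#' @param whole_ml Whole-brain group difference in the same unit; must be
#'   nonzero.
#' @return `part * 100 / whole`, percent.
#' @export
share_of_difference <- function(part_ml, whole_ml) {
  if (any(whole_ml == 0)) stop("whole-brain difference must be nonzero")
  part_ml * 100 / whole_ml
}

#' Run the adaptive ANCOVA over one family of regions
#'
#' For every region: screen age and TIV, screen the permitted interactions,
#' classify the zone, fit the zone model, and run the assumption
#' diagnostics. Nominal p-values are then converted to q-values within the
#' family, and the family summaries are computed from the raw group means:
#' the summed significant difference, its share of the whole-brain
#' difference (when a whole-brain reference is available), and the
#' mean ± SD relative difference across all regions. A region whose fit
#' fails is recorded with a flag and the rest of the family continues.
#'
#' @param table A [roi_volume_table()].
#' @param family Label for the report (default `"all"`); the family is the
#'   set of columns of `table`.
#' @param config An [ahglm_config()].
#' @param whole_brain_diff_ml Reference group difference for
#'   [share_of_difference()]. Default `NULL` uses the region named
#'   `whole_brain` (or `Whole brain GMV`) if the table has one.
#' @return An object of class `family_report`: a `results` data frame (one
#'   row per region), the `qvalue_result`, the set of significant regions,
#'   the family summaries, and the per-region fit objects.
#' @export
run_family <- function(table, family = "all", config = ahglm_config(),
                       whole_brain_diff_ml = NULL) {
  stopifnot(inherits(table, "roi_volume_table"),
            inherits(config, "ahglm_config"))
  regions <- table$regions
  fits <- vector("list", length(regions))
  names(fits) <- regions
  rows <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    r <- regions[i]
    rows[[i]] <- tryCatch({
      zone <- screen_region(table, r, config)
      fit <- fit_region(table, r, zone)
      fit$diagnostics <- run_diagnostics(fit)
      fits[[i]] <- fit
      data.frame(
        region = r, zone = zone$zone_code, F = fit$F_med,
        p_nominal = fit$p_nominal, q = NA_real_,
        mean_ctrl = fit$group_mean_ctrl, sd_ctrl = fit$group_sd_ctrl,
        mean_med = fit$group_mean_med, sd_med = fit$group_sd_med,
        relative_diff_pct = fit$relative_diff_pct,
        eta2_partial = fit$eta2_partial,
        flags = paste(fit$diagnostics$flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("region '", r, "' failed: ", conditionMessage(e))
      data.frame(region = r, zone = NA_character_, F = NA_real_,
                 p_nominal = NA_real_, q = NA_real_, mean_ctrl = NA_real_,
                 sd_ctrl = NA_real_, mean_med = NA_real_, sd_med = NA_real_,
                 relative_diff_pct = NA_real_, eta2_partial = NA_real_,
                 flags = paste0("fit-error:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
  }
  results <- do.call(rbind, rows)
  ok <- !is.na(results$p_nominal)
  qres <- qvalue_family(results$p_nominal[ok], min_m_spline =
                          config$min_m_spline, pi0 = config$pi0)
  results$q[ok] <- qres$qvals
  sig <- results$region[ok][results$q[ok] < config$fdr_q]

  diff_ml <- results$mean_med - results$mean_ctrl
  sum_sig <- sum(diff_ml[results$region %in% sig], na.rm = TRUE)
  if (is.null(whole_brain_diff_ml)) {
    wb <- match(c("whole_brain", "Whole brain GMV", "whole brain"),
                results$region)
    wb <- wb[!is.na(wb)][1]
    if (!is.na(wb)) whole_brain_diff_ml <- diff_ml[wb]
  }
  share <- if (!is.null(whole_brain_diff_ml) &&
               isTRUE(whole_brain_diff_ml != 0))
    share_of_difference(sum_sig, whole_brain_diff_ml) else NA_real_
  mixed <- length(sig) > 1 &&
    length(unique(sign(diff_ml[results$region %in% sig]))) > 1

  structure(
    list(family = family, results = results, qvalue = qres,
         significant = sig,
         summaries = list(
           sum_sig_diff_ml = sum_sig,
           whole_brain_diff_ml = whole_brain_diff_ml,
           share_of_wholebrain_pct = share,
           mean_relative_diff_pct = mean(results$relative_diff_pct,
                                         na.rm = TRUE),
           sd_relative_diff_pct = stats::sd(results$relative_diff_pct,
                                            na.rm = TRUE),
           mixed_signs = mixed),
         fits = fits, config = config),
    class = "family_report"
  )
}

#' @export
print.family_report <- function(x, ...) {
  cat(sprintf(
    "<family_report> '%s': %d regions, %d significant at q < %.2g (pi0 = %.3f, %s)\n",
    x$family, nrow(x$results), length(x$significant), x$config$fdr_q,
    x$qvalue$pi0, x$qvalue$method_note))
  if (length(x$significant))
    cat("  significant:", paste(x$significant, collapse = ", "), "\n")
  cat(sprintf("  mean relative difference %.2f ± %.2f %%\n",
              x$summaries$mean_relative_diff_pct,
              x$summaries$sd_relative_diff_pct))
  invisible(x)
}

#' Write a family report to disk
#'
#' Writes two tab-separated files: `<path>` with values rounded the way the
#' regional tables are printed (2 decimals for F, volumes and percents; 4
#' for p, q and partial eta-squared) and `<stem>_full.tsv` with full
#' precision for machine consumption. Before writing, the tabulated
#' identities are re-verified on every row: partial eta-squared must equal
#' `F / (F + df_error)` and the relative difference must equal its defining
#' formula on the tabulated means.
#'
#' @param report A [run_family()] report.
#' @param path Output TSV path.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "family_report"))
  res <- report$results
  for (i in seq_len(nrow(res))) {
    if (is.na(res$F[i])) next
    fit <- report$fits[[res$region[i]]]
    stopifnot(abs(res$eta2_partial[i] -
                    res$F[i] / (res$F[i] + fit$df_error)) < 1e-8,
              abs(res$relative_diff_pct[i] -
                    relative_difference(res$mean_ctrl[i],
                                        res$mean_med[i])) < 1e-8)
  }
  full_path <- sub("\\.tsv$", "_full.tsv", path)
  if (identical(full_path, path)) full_path <- paste0(path, "_full.tsv")
  utils::write.table(res, full_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rounded <- res
  for (col in c("F", "mean_ctrl", "sd_ctrl", "mean_med", "sd_med",
                "relative_diff_pct"))
    rounded[[col]] <- round(rounded[[col]], 2)
  for (col in c("p_nominal", "q", "eta2_partial"))
    rounded[[col]] <- round(rounded[[col]], 4)
  utils::write.table(rounded, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, full_path))
}

#' @rdname write_report
#' @param full Read the full-precision companion (default `TRUE`) when
#'   present.
#' @export
read_report <- function(path, full = TRUE) {
  full_path <- sub("\\.tsv$", "_full.tsv", path)
  if (full && file.exists(full_path)) path <- full_path
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Group-balance audit of the cohort covariates
#'
#' Two-sample pooled t-tests of age and TIV between groups, the
#' Table-1-style sanity check that the groups are matched. Advisory only;
#' not part of the inference path.
#'
#' @param subjects Subject covariate data frame.
#' @return Data frame with one row per covariate.
#' @export
group_balance_audit <- function(subjects) {
  subjects <- validate_subjects(subjects)
  one <- function(v, nm) {
    tt <- stats::t.test(v ~ subjects$med, var.equal = TRUE)
    data.frame(variable = nm,
               mean_ctrl = unname(tt$estimate[1]),
               mean_med = unname(tt$estimate[2]),
               t = -unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }
  rbind(one(subjects$age, "age"), one(subjects$tiv_ml, "tiv_ml"))
}
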