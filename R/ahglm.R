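#' Screen a covariate for inclusion in a region's model
#'
#' A covariate (age or TIV) enters a region's ANCOVA only when its pooled
#' Pearson correlation with the regional volume is both significant and
#' substantial: `p < p_threshold` and `|r| > r_threshold`, strict
#' inequalities. The p-value is the usual t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`, two-sided. The correlation is taken
#' over the pooled sample (both groups together): the screen asks whether a
#' linear covariate relationship exists at all, not whether it differs by
#' group. The magnitude rule uses `|r|` because the age relationship is
#' typically negative.
#'
#' @param gmv Numeric vector of regional volumes (mL).
#' @param covariate Numeric vector, same length (years or mL).
#' @param name Covariate label carried into reports (`"Age"` or `"TIV"`).
#' @param p_threshold,r_threshold Screening thresholds (defaults 0.05, 0.4).
#' @return An object of class `screen_result` with fields `covariate`, `r`,
#'   `p`, `passes` and `flag`.
#' @export
screen_covariate <- function(gmv, covariate, name = "covariate",
                             p_threshold = 0.05, r_threshold = 0.4) {
  stopifnot(length(gmv) == length(covariate))
  if (length(gmv) < 4L)
    stop("need at least 4 observations to screen a covariate")
  if (anyNA(gmv) || anyNA(covariate))
    stop("missing values in screening inputs")
  flag <- character(0)
  if (stats::sd(gmv) == 0 || stats::sd(covariate) == 0) {
    return(structure(list(covariate = name, r = NA_real_, p = NA_real_,
                          passes = FALSE, flag = "zero-variance"),
                     class = "screen_result"))
  }
  n <- length(gmv)
  r <- stats::cor(gmv, covariate)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  structure(list(covariate = name, r = r, p = p,
                 passes = (p < p_threshold) && (abs(r) > r_threshold),
                 flag = flag),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %s: r = %.3f, p = %.4g -> %s\n",
              x$covariate, x$r, x$p, if (x$passes) "include" else "exclude"))
  invisible(x)
}

#' Screen a group-by-covariate interaction
#'
#' Only reached when the covariate itself passed screening. Fits
#' `GMV ~ 1 + Med + cov + Med:cov` by least squares and returns the two-sided
#' p-value of the interaction coefficient; the interaction is included when
#' `p < p_threshold`.
#'
#' @param gmv,covariate Numeric vectors.
#' @param med 0/1 group indicator.
#' @param p_threshold Inclusion threshold (default 0.05).
#' @return List with `p` and `include` (plus `flag` when the design is
#'   singular, in which case the interaction is excluded).
#' @export
screen_interaction <- function(gmv, covariate, med, p_threshold = 0.05) {
  stopifnot(length(gmv) == length(covariate), length(gmv) == length(med))
  d <- data.frame(gmv = gmv, cov = covariate, med = med)
  fit <- stats::lm(gmv ~ med * cov, data = d)
  cf <- summary(fit)$coefficients
  if (!("med:cov" %in% rownames(cf)) || anyNA(stats::coef(fit))) {
    return(list(p = NA_real_, include = FALSE, flag = "singular-design"))
  }
  p <- cf["med:cov", "Pr(>|t|)"]
  list(p = p, include = p < p_threshold)
}

# zone code as a pure function of the four inclusion flags
.zone_table <- function(age, tiv, int_age, int_tiv) {
  if (!age && !tiv) return("1")
  if (tiv && !age) return(if (int_tiv) "2C" else "2A")
  if (age && !tiv) return(if (int_age) "2D" else "2B")
  # both covariates in
  if (!int_age && !int_tiv) return("3A")
  if (int_tiv && !int_age) return("3B")
  if (int_age && !int_tiv) return("3C")
  "3D"
}

#' Classify a region into a model zone
#'
#' The zone code names which terms the region's ANCOVA carries, from Zone 1
#' (group only, a plain two-sample comparison) to Zone 3D (both covariates
#' and both group-by-covariate interactions, the full model). An interaction
#' may be included only when its covariate is; inconsistent flags are a hard
#' error.
#'
#' Zone table: 1 = no covariates; 2A = TIV; 2B = Age; 2C = TIV + Med:TIV;
#' 2D = Age + Med:Age; 3A = Age + TIV; 3B = 3A + Med:TIV; 3C = 3A + Med:Age;
#' 3D = full model.
#'
#' @param screen_age,screen_tiv `screen_result` objects (or logicals).
#' @param int_age,int_tiv Interaction screen results from
#'   [screen_interaction()] (or logicals); ignored unless the matching
#'   covariate passed.
#' @return An object of class `zone_classification`.
#' @export
classify_zone <- function(screen_age, screen_tiv, int_age = NULL,
                          int_tiv = NULL) {
  as_flag <- function(x, field) {
    if (is.null(x)) return(FALSE)
    if (inherits(x, "screen_result")) return(isTRUE(x$passes))
    if (is.list(x)) return(isTRUE(x[[field]]))
    isTRUE(as.logical(x))
  }
  a <- as_flag(screen_age, "passes")
  t <- as_flag(screen_tiv, "passes")
  ia <- as_flag(int_age, "include")
  it <- as_flag(int_tiv, "include")
  if ((ia && !a) || (it && !t))
    stop("inconsistent flags: an interaction requires its covariate")
  pick_p <- function(x) if (is.list(x) && !is.null(x$p)) x$p else NA_real_
  structure(
    list(zone_code = .zone_table(a, t, ia, it),
         include_age = a, include_tiv = t,
         include_med_x_age = ia, include_med_x_tiv = it,
         screens = list(age = if (inherits(screen_age, "screen_result"))
                          screen_age else NULL,
                        tiv = if (inherits(screen_tiv, "screen_result"))
                          screen_tiv else NULL),
         interaction_p = c(age = pick_p(int_age), tiv = pick_p(int_tiv))),
    class = "zone_classification"
  )
}

#' @export
print.zone_classification <- function(x, ...) {
  terms <- c("Med",
             if (x$include_age) "Age", if (x$include_tiv) "TIV",
             if (x$include_med_x_age) "Med:Age",
             if (x$include_med_x_tiv) "Med:TIV")
  cat(sprintf("<zone %s> GMV ~ %s\n", x$zone_code,
              paste(c("1", terms), collapse = " + ")))
  invisible(x)
}

#' Zone inclusion flags from a zone code
#'
#' Inverse of the zone table in [classify_zone()].
#'
#' @param zone_code One of `"1"`, `"2A"`..`"2D"`, `"3A"`..`"3D"`.
#' @return A `zone_classification` with the four inclusion flags set.
#' @export
zone_from_code <- function(zone_code) {
  codes <- list("1"  = c(FALSE, FALSE, FALSE, FALSE),
                "2A" = c(FALSE, TRUE,  FALSE, FALSE),
                "2B" = c(TRUE,  FALSE, FALSE, FALSE),
                "2C" = c(FALSE, TRUE,  FALSE, TRUE),
                "2D" = c(TRUE,  FALSE, TRUE,  FALSE),
                "3A" = c(TRUE,  TRUE,  FALSE, FALSE),
                "3B" = c(TRUE,  TRUE,  FALSE, TRUE),
                "3C" = c(TRUE,  TRUE,  TRUE,  FALSE),
                "3D" = c(TRUE,  TRUE,  TRUE,  TRUE))
  zone_code <- as.character(zone_code)
  if (!zone_code %in% names(codes))
    stop("unknown zone code: ", zone_code)
  f <- codes[[zone_code]]
  classify_zone(f[1], f[2], f[3], f[4])
}

# design matrix for a zone: sum-to-zero group coding (-1/2, +1/2) and
# mean-centred covariates, so interaction columns leave the group main
# effect interpretable at average covariate values
.zone_design <- function(subjects, zone) {
  med_c <- ifelse(subjects$med == 1, 0.5, -0.5)
  age_c <- subjects$age - mean(subjects$age)
  tiv_c <- subjects$tiv_ml - mean(subjects$tiv_ml)
  X <- cbind(`(Intercept)` = 1, Med = med_c)
  if (zone$include_age) X <- cbind(X, Age = age_c)
  if (zone$include_tiv) X <- cbind(X, TIV = tiv_c)
  if (zone$include_med_x_age) X <- cbind(X, `Med:Age` = med_c * age_c)
  if (zone$include_med_x_tiv) X <- cbind(X, `Med:TIV` = med_c * tiv_c)
  X
}

#' Fit a region's zone-specific ANCOVA
#'
#' Ordinary least squares on the zone's design (sum-to-zero group coding,
#' mean-centred covariates). The group test is the partial F comparing the
#' zone model against the same model with the group column removed (1
#' numerator df); the effect size is partial eta-squared,
#' `SS_med / (SS_med + SS_error)`, which for a 1-df effect equals
#' `F / (F + df_error)`. Group means, SDs and the relative difference are
#' raw (covariate-unadjusted) per-group statistics, matching how regional
#' volumes are tabulated.
#'
#' @param table A [roi_volume_table()].
#' @param region Region name (a column of the table).
#' @param zone A `zone_classification` or zone code string.
#' @return An object of class `region_fit`.
#' @export
fit_region <- function(table, region, zone) {
  stopifnot(inherits(table, "roi_volume_table"))
  if (!region %in% table$regions)
    stop("region '", region, "' not in the volume table")
  if (is.character(zone)) zone <- zone_from_code(zone)
  stopifnot(inherits(zone, "zone_classification"))
  y <- table$volumes[, region]
  subj <- table$subjects
  n0 <- sum(subj$med == 0); n1 <- sum(subj$med == 1)
  if (n0 < 3L || n1 < 3L)
    stop("need at least 3 subjects per group (have ", n0, " / ", n1, ")")

  X <- .zone_design(subj, zone)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  n <- length(y); k <- ncol(X)
  df_error <- n - k
  if (df_error <= 0L) stop("no error degrees of freedom (n = ", n,
                           ", parameters = ", k, ")")
  fit <- stats::lm.fit(X, y)
  beta <- stats::setNames(fit$coefficients, colnames(X))
  sse_full <- sum(fit$residuals^2)

  X0 <- X[, colnames(X) != "Med", drop = FALSE]
  sse_red <- sum(stats::lm.fit(X0, y)$residuals^2)
  ss_med <- sse_red - sse_full
  F_med <- (ss_med / 1) / (sse_full / df_error)
  p_nom <- stats::pf(F_med, 1, df_error, lower.tail = FALSE)
  eta2 <- ss_med / (ss_med + sse_full)

  m0 <- mean(y[subj$med == 0]); m1 <- mean(y[subj$med == 1])
  structure(
    list(region_name = region, zone = zone, beta = beta,
         F_med = F_med, df1 = 1L, df_error = df_error,
         p_nominal = p_nom, eta2_partial = eta2,
         group_mean_ctrl = m0, group_sd_ctrl = stats::sd(y[subj$med == 0]),
         group_mean_med = m1, group_sd_med = stats::sd(y[subj$med == 1]),
         relative_diff_pct = relative_difference(m0, m1),
         n = n, residuals = unname(fit$residuals),
         fitted = unname(fit$fitted.values),
         design = X, response = unname(y), subjects = subj,
         diagnostics = NULL),
    class = "region_fit"
  )
}

#' @export
print.region_fit <- function(x, ...) {
  cat(sprintf(
    "<region_fit> %s (zone %s): F(1,%d) = %.2f, p = %.4g, eta2p = %.3f\n",
    x$region_name, x$zone$zone_code, x$df_error, x$F_med, x$p_nominal,
    x$eta2_partial))
  cat(sprintf("  control %.2f ± %.2f mL, meditator %.2f ± %.2f mL (%+.2f%%)\n",
              x$group_mean_ctrl, x$group_sd_ctrl, x$group_mean_med,
              x$group_sd_med, x$relative_diff_pct))
  invisible(x)
}

#' Post-fit assumption diagnostics
#'
#' Advisory checks on a fitted region model; failures raise flags but never
#' change the fitted model. Residuals are internally standardised
#' (studentised with the hat leverage) before testing:
#' * Shapiro-Wilk normality of the standardised residuals;
#' * Levene's test (median-centred) of residual spread across the two groups;
#' * count of observations with |standardised residual| > 3;
#' * homogeneity-of-regression-slopes p per included covariate, from the
#'   interaction-augmented model (for zones already carrying the interaction
#'   this is the interaction coefficient's own p).
#'
#' @param fit A [fit_region()] result.
#' @return An object of class `diagnostics_report`; also attached to the
#'   returned copy of the fit under `$diagnostics`.
#' @export
run_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "region_fit"))
  X <- fit$design
  h <- stats::hat(X)
  sigma <- sqrt(sum(fit$residuals^2) / fit$df_error)
  rstd <- if (sigma > 0)
    fit$residuals / (sigma * sqrt(pmax(1 - h, .Machine$double.eps)))
  else rep(0, length(fit$residuals))  # perfect fit: nothing to standardise
  flags <- character(0)

  shapiro_p <- NA_real_
  if (length(rstd) >= 3L && stats::sd(rstd) > 0) {
    shapiro_p <- stats::shapiro.test(rstd)$p.value
    if (shapiro_p <= 0.05) flags <- c(flags, "residual-non-normality")
  } else flags <- c(flags, "shapiro-not-computable")

  grp <- factor(ifelse(fit$subjects$med == 1, "meditator", "control"))
  lev <- car::leveneTest(fit$residuals, grp, center = stats::median)
  levene_p <- lev[["Pr(>F)"]][1]
  if (is.finite(levene_p) && levene_p <= 0.05)
    flags <- c(flags, "variance-heterogeneity")

  n_out <- sum(abs(rstd) > 3)
  if (n_out > 0) flags <- c(flags, "outliers")

  slope_p <- c(Age = NA_real_, TIV = NA_real_)
  subj <- fit$subjects
  for (cv in c("Age", "TIV")) {
    inc <- if (cv == "Age") fit$zone$include_age else fit$zone$include_tiv
    if (!inc) next
    covv <- if (cv == "Age") subj$age else subj$tiv_ml
    si <- screen_interaction(fit$response, covv, subj$med)
    slope_p[cv] <- si$p
    if (is.finite(si$p) && si$p <= 0.05) {
      already <- if (cv == "Age") fit$zone$include_med_x_age
                 else fit$zone$include_med_x_tiv
      if (!already)
        flags <- c(flags, paste0("slope-heterogeneity-", tolower(cv)))
    }
  }

  structure(
    list(shapiro_p = shapiro_p, levene_p = levene_p, n_outliers = n_out,
         slope_homogeneity_p = slope_p, flags = flags),
    class = "diagnostics_report"
  )
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf(
    "<diagnostics> Shapiro p = %.3f, Levene p = %.3f, outliers = %d%s\n",
    x$shapiro_p, x$levene_p, x$n_outliers,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
    else ""))
  invisible(x)
}

#' Screen and classify one region
#'
#' Runs the full model-selection path for a single region: covariate screens
#' for age and TIV, interaction screens where permitted, and the zone
#' classification.
#'
#' @param table A [roi_volume_table()].
#' @param region Region name.
#' @param config An [ahglm_config()].
#' @return A `zone_classification`.
#' @export
screen_region <- function(table, region, config = ahglm_config()) {
  stopifnot(inherits(table, "roi_volume_table"))
  y <- table$volumes[, region]
  subj <- table$subjects
  sa <- screen_covariate(y, subj$age, "Age",
                         config$screen_p, config$screen_r)
  st <- screen_covariate(y, subj$tiv_ml, "TIV",
                         config$screen_p, config$screen_r)
  ia <- if (sa$passes)
    screen_interaction(y, subj$age, subj$med, config$interaction_p) else NULL
  it <- if (st$passes)
    screen_interaction(y, subj$tiv_ml, subj$med, config$interaction_p)
    else NULL
  classify_zone(sa, st, ia, it)
}
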