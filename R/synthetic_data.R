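#' Cohort specification for the synthetic-data generator
#'
#' Describes a two-group cross-sectional morphometry cohort: group sizes, the
#' female/male split within each group, the age range (ages are drawn
#' uniformly over it), and sex-specific total-intracranial-volume (TIV)
#' means. The defaults emulate a 23 + 23 cohort with 17 F / 6 M per group,
#' ages 21-63 y, and a strong sex difference in TIV — strong enough that the
#' pooled two-sample sex-on-TIV t-test comes out below 1e-4 in the large
#' majority of draws, which is the generator's built-in audit property.
#'
#' @param n_per_group Subjects per group (default 23).
#' @param sex_counts Named vector `c(F = , M = )` per group (default 17/6).
#' @param age_range Two increasing values, years (default `c(21, 63)`).
#' @param tiv_mean_by_sex Named vector `c(F = , M = )` of mean TIV in mL
#'   (default `c(F = 1370, M = 1600)`).
#' @param tiv_sd Within-sex TIV standard deviation, mL (default 100).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 23L,
                        sex_counts = c(F = 17L, M = 6L),
                        age_range = c(21, 63),
                        tiv_mean_by_sex = c(F = 1370, M = 1600),
                        tiv_sd = 100) {
  stopifnot(n_per_group >= 1, all(sex_counts >= 0),
            sum(sex_counts) == n_per_group,
            length(age_range) == 2, age_range[1] < age_range[2],
            all(c("F", "M") %in% names(tiv_mean_by_sex)), tiv_sd >= 0)
  structure(list(n_per_group = as.integer(n_per_group),
                 sex_counts = sex_counts, age_range = age_range,
                 tiv_mean_by_sex = tiv_mean_by_sex, tiv_sd = tiv_sd),
            class = "cohort_spec")
}

#' Generate subject covariates for a two-group cohort
#'
#' Ages are uniform over the spec's range; TIV is normal around the
#' sex-specific mean. Both groups share the same covariate distributions
#' (groups are matched on age and sex), so any group difference in regional
#' volumes comes from the region model, not the covariates.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return Data frame with columns `id`, `med`, `age`, `sex`, `tiv_ml`,
#'   `group`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  one_group <- function(med, prefix) {
    sex <- rep(c("F", "M"), times = c(spec$sex_counts[["F"]],
                                      spec$sex_counts[["M"]]))
    n <- length(sex)
    data.frame(
      id = sprintf("%s%02d", prefix, seq_len(n)),
      med = med,
      age = stats::runif(n, spec$age_range[1], spec$age_range[2]),
      sex = sex,
      tiv_ml = stats::rnorm(n, spec$tiv_mean_by_sex[sex], spec$tiv_sd),
      group = if (med == 1) "meditator" else "control",
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(one_group(0, "C"), one_group(1, "M"))
  rownames(out) <- NULL
  out
}

#' Region specification: the generative counterpart of the zone models
#'
#' One region's volumes are drawn as
#' `baseline * (1 + effect_pct/100 * Med) + age_slope * (Age - mean Age) +
#'  tiv_slope * (TIV - mean TIV) + interaction terms * Med + N(0, noise_sd)`.
#'
#' @param name Region name.
#' @param baseline_ml Control-group mean volume, mL.
#' @param effect_pct Group difference as percent of baseline (default 0).
#' @param age_slope mL per year (typically negative).
#' @param tiv_slope mL per mL of TIV.
#' @param interaction_age,interaction_tiv Extra slope for the meditator group
#'   (mL/year, mL/mL).
#' @param noise_sd_ml Residual SD, mL.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, baseline_ml, effect_pct = 0, age_slope = 0,
                        tiv_slope = 0, interaction_age = 0,
                        interaction_tiv = 0, noise_sd_ml = 1) {
  stopifnot(baseline_ml > 0, noise_sd_ml > 0)
  structure(list(name = name, baseline_ml = baseline_ml,
                 effect_pct = effect_pct, age_slope = age_slope,
                 tiv_slope = tiv_slope, interaction_age = interaction_age,
                 interaction_tiv = interaction_tiv,
                 noise_sd_ml = noise_sd_ml),
            class = "region_spec")
}

#' Default whole-brain region specification
#'
#' Calibrated so a default cohort gives a control-group total SD near
#' 74.6 mL with pooled correlations r(GMV, TIV) about 0.65 and
#' r(GMV, Age) about 0.5 — a region that screens into Zone 3A — and a
#' meditator excess of 6.93%.
#'
#' @return A [region_spec()].
#' @export
whole_brain_spec <- function() {
  region_spec("whole_brain", baseline_ml = 611, effect_pct = 6.93,
              age_slope = -3.0, tiv_slope = 0.35, noise_sd_ml = 42)
}

# scale the whole-brain calibration down to a region of given baseline:
# slopes and residual SD shrink proportionally, so relative volume spread
# and the pooled covariate correlations are preserved
.scaled_spec <- function(name, baseline, effect_pct = 0) {
  f <- baseline / 611
  region_spec(name, baseline, effect_pct,
              age_slope = -3.0 * f, tiv_slope = 0.35 * f,
              noise_sd_ml = 42 * f)
}

#' Lobar (16-region) study preset
#'
#' Sixteen lobe-level regions (frontal, temporal, parietal, occipital,
#' limbic, sublobar, brainstem, cerebellum, each hemisphere). Four regions
#' carry a true group effect — right temporal (9.02%), right frontal
#' (9.36%), left frontal (9.02%) and right brainstem (19.68%) — the rest are
#' null. Cortical regions carry the age/TIV covariate structure (Zone
#' 3A-like); the brainstem regions carry none (Zone 1-like).
#'
#' @return List of [region_spec()]s.
#' @export
lobar16_specs <- function() {
  cort <- function(name, base, eff = 0) .scaled_spec(name, base, eff)
  stem <- function(name, base, eff = 0)
    region_spec(name, base, eff, noise_sd_ml = 0.28 * base / 1.67)
  list(
    cort("R.frontal",    78.35, 9.36), cort("L.frontal",   76.57, 9.02),
    cort("R.temporal",   46.65, 9.02), cort("L.temporal",  45.50),
    cort("R.parietal",   40.00),       cort("L.parietal",  39.50),
    cort("R.occipital",  25.00),       cort("L.occipital", 25.00),
    cort("R.limbic",     15.50),       cort("L.limbic",    15.00),
    cort("R.sublobar",   24.50),       cort("L.sublobar",  24.00),
    stem("R.brainstem",   1.67, 19.68), stem("L.brainstem",  1.60),
    cort("R.cerebellum", 52.00),       cort("L.cerebellum", 51.00)
  )
}

#' Hemisphere / whole-brain (3-region) study preset
#'
#' Right hemisphere (284.92 mL, +7.03%), left hemisphere (276.62 mL,
#' +6.72%) and whole brain (611 mL, +6.93%), all with the scaled Zone
#' 3A-like covariate structure.
#'
#' @return List of [region_spec()]s.
#' @export
hemi3_specs <- function() {
  list(.scaled_spec("R.hemisphere", 284.92, 7.03),
       .scaled_spec("L.hemisphere", 276.62, 6.72),
       whole_brain_spec())
}

#' Generate a subject-by-region volume table from region specifications
#'
#' @param cohort Subject data frame from [generate_cohort()].
#' @param regions List of [region_spec()]s (or a single one).
#' @param seed Integer seed.
#' @return A [roi_volume_table()]. Values are clipped at zero (with a
#'   warning) in the rare event a draw goes negative.
#' @export
generate_volumes <- function(cohort, regions, seed = 1L) {
  if (inherits(regions, "region_spec")) regions <- list(regions)
  stopifnot(all(vapply(regions, inherits, logical(1), "region_spec")))
  n <- nrow(cohort)  # force the cohort before touching the RNG state
  set.seed(seed)
  age_c <- cohort$age - mean(cohort$age)
  tiv_c <- cohort$tiv_ml - mean(cohort$tiv_ml)
  med <- cohort$med
  vols <- vapply(regions, function(rs) {
    rs$baseline_ml * (1 + rs$effect_pct / 100 * med) +
      rs$age_slope * age_c + rs$tiv_slope * tiv_c +
      rs$interaction_age * med * age_c + rs$interaction_tiv * med * tiv_c +
      stats::rnorm(n, 0, rs$noise_sd_ml)
  }, numeric(n))
  colnames(vols) <- vapply(regions, `[[`, character(1), "name")
  if (any(vols < 0)) {
    warning(sum(vols < 0), " generated volume(s) were negative; clipped to 0")
    vols[vols < 0] <- 0
  }
  roi_volume_table(cohort, vols)
}

#' Build NIfTI-style tissue maps and an atlas that reproduce a volume table
#'
#' Constructs an atlas of disjoint axis-aligned blocks (one label per region)
#' on a small grid and, per subject, a grey-matter map whose within-block
#' totals times the voxel volume equal the table entries exactly (each
#' region's volume is spread uniformly over its block). Round-tripping
#' through [extract_roi_table()] recovers the table to floating-point
#' accuracy, which makes this the fixture generator for the volumetrics
#' stage.
#'
#' @param table A [roi_volume_table()].
#' @param grid Grid shape (default `c(12, 12, 12)`), 1 mm isotropic voxels.
#' @param block Edge length of each region block in voxels (default 3).
#' @param family Family name recorded in the label table (default
#'   `"synthetic"`).
#' @param seed Seed controlling the (shuffled) assignment of regions to
#'   blocks.
#' @return List with `gm_maps` (named list of [tissue_map()]s), `atlas` (an
#'   [atlas_definition()]) and `labels` (the label table).
#' @export
generate_nifti_fixture <- function(table, grid = c(12L, 12L, 12L),
                                   block = 3L, family = "synthetic",
                                   seed = 1L) {
  stopifnot(inherits(table, "roi_volume_table"))
  nb <- prod(grid %/% block)
  regions <- table$regions
  if (length(regions) > nb)
    stop("grid too small: ", nb, " blocks available for ",
         length(regions), " regions")
  set.seed(seed)
  block_ids <- sample(nb, length(regions))

  label_img <- array(0L, grid)
  bdim <- grid %/% block
  block_voxels <- vector("list", length(regions))
  for (r in seq_along(regions)) {
    b <- block_ids[r] - 1L
    i <- b %% bdim[1]; j <- (b %/% bdim[1]) %% bdim[2]
    k <- b %/% (bdim[1] * bdim[2])
    ix <- (i * block + 1L):(i * block + block)
    iy <- (j * block + 1L):(j * block + block)
    iz <- (k * block + 1L):(k * block + block)
    label_img[ix, iy, iz] <- r
    block_voxels[[r]] <- list(ix = ix, iy = iy, iz = iz)
  }
  labels <- data.frame(label_id = seq_along(regions),
                       region_name = regions, family = family,
                       stringsAsFactors = FALSE)
  atlas <- atlas_definition(label_img, labels, voxel_volume_mm3 = 1)

  nvox <- block^3
  gm_maps <- lapply(seq_len(nrow(table$subjects)), function(s) {
    arr <- array(0, grid)
    for (r in seq_along(regions)) {
      bv <- block_voxels[[r]]
      # mL -> mm^3, spread uniformly over the block's voxels (1 mm^3 each)
      arr[bv$ix, bv$iy, bv$iz] <- table$volumes[s, r] * 1000 / nvox
    }
    tissue_map(arr, voxel_volume_mm3 = 1)
  })
  names(gm_maps) <- table$subjects$id
  list(gm_maps = gm_maps, atlas = atlas, labels = labels)
}

#' Sex-on-TIV audit
#'
#' Pooled-variance two-sample t-test of TIV between the sexes. In cohorts of
#' this design the effect should be highly significant; the pipeline reports
#' it as a dataset audit because including TIV in the region models is what
#' intrinsically controls for sex (sex itself is never a model term).
#'
#' @param subjects Subject covariate data frame.
#' @return List with `t`, `df`, `p` and the per-sex means.
#' @export
sex_tiv_audit <- function(subjects) {
  subjects <- validate_subjects(subjects)
  tt <- stats::t.test(tiv_ml ~ sex, data = subjects, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       mean_f = unname(tt$estimate[1]), mean_m = unname(tt$estimate[2]))
}
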