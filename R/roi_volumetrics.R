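#' Tissue map: a modulated tissue-probability volume on a voxel grid
#'
#' Wraps a 3D array of modulated tissue densities (dimensionless, as produced
#' by VBM-style segmentation + modulation) together with the volume of one
#' voxel in cubic millimetres. Regional volumes are obtained by summing voxel
#' values over a mask and multiplying by the voxel volume: modulation
#' preserves total tissue amounts, so no thresholding is applied anywhere.
#'
#' @param values 3D numeric array of voxel values. Must be finite.
#' @param voxel_volume_mm3 Volume of one voxel in mm^3. Ignored when `affine`
#'   is given.
#' @param affine Optional 4x4 voxel-to-world matrix; the voxel volume is the
#'   absolute determinant of its 3x3 spatial part (the product of the voxel
#'   dimensions for axis-aligned grids).
#' @return An object of class `tissue_map`.
#' @export
tissue_map <- function(values, voxel_volume_mm3 = 1, affine = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!all(is.finite(values)))
    stop("tissue map contains non-finite voxel values")
  if (any(values < 0))
    warning("tissue map contains negative voxel values; ",
            "modulated tissue densities are expected to be non-negative")
  if (!is.null(affine)) {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)))
      stop("`affine` must be a 4x4 matrix")
    voxel_volume_mm3 <- abs(det(affine[1:3, 1:3]))
  }
  if (!is.numeric(voxel_volume_mm3) || length(voxel_volume_mm3) != 1L ||
      !is.finite(voxel_volume_mm3) || voxel_volume_mm3 <= 0)
    stop("`voxel_volume_mm3` must be a single positive number")
  structure(
    list(values = values,
         grid_shape = dim(values),
         voxel_volume_mm3 = voxel_volume_mm3),
    class = "tissue_map"
  )
}

#' @export
print.tissue_map <- function(x, ...) {
  cat(sprintf("<tissue_map> grid %s, voxel %.4g mm^3, total %.3f mL\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_volume_mm3,
              total_volume(x)))
  invisible(x)
}

#' Read a NIfTI-1 volume as a tissue map
#'
#' The voxel volume is derived from the image geometry (absolute determinant
#' of the 3x3 spatial part of the voxel-to-world transform).
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a single 3D volume.
#' @return A [tissue_map()].
#' @export
read_tissue_map <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  if (length(dim(arr)) != 3L)
    stop("expected a single 3D volume in ", path)
  tissue_map(arr, affine = RNifti::xform(img))
}

#' Write a tissue map as a NIfTI-1 volume
#'
#' @param map A [tissue_map()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_tissue_map <- function(map, path) {
  stopifnot(inherits(map, "tissue_map"))
  s <- map$voxel_volume_mm3^(1 / 3)  # isotropic grid carrying the voxel volume
  img <- RNifti::asNifti(map$values, pixdim = c(s, s, s))
  RNifti::writeNifti(img, path)
  invisible(path)
}

.check_same_grid <- function(a, b, what = "mask") {
  if (!identical(as.integer(a$grid_shape), as.integer(dim(b))))
    stop(sprintf("grid mismatch: map is %s but %s is %s",
                 paste(a$grid_shape, collapse = "x"), what,
                 paste(dim(b), collapse = "x")))
}

#' Total tissue volume within a mask
#'
#' Sum of voxel values inside the mask times the voxel volume, in mL. This is
#' the standard total-volume computation for modulated tissue maps: no voxel
#' is thresholded or weighted.
#'
#' @param map A [tissue_map()].
#' @param mask Logical (or 0/1) array on the same grid; `NULL` sums the whole
#'   image.
#' @return Volume in mL.
#' @export
total_volume <- function(map, mask = NULL) {
  stopifnot(inherits(map, "tissue_map"))
  if (!all(is.finite(map$values)))
    stop("tissue map contains non-finite voxel values")
  if (is.null(mask)) {
    s <- sum(map$values)
  } else {
    .check_same_grid(map, mask)
    s <- sum(map$values[as.logical(mask)])
  }
  s * map$voxel_volume_mm3 / 1000
}

#' Total intracranial volume from the three tissue classes
#'
#' TIV = whole-image GM + WM + CSF volume, in mL. The three maps must share a
#' grid and geometry; no resampling is attempted.
#'
#' @param gm,wm,csf [tissue_map()] objects for grey matter, white matter and
#'   cerebrospinal fluid.
#' @return TIV in mL.
#' @export
compute_tiv <- function(gm, wm, csf) {
  stopifnot(inherits(gm, "tissue_map"), inherits(wm, "tissue_map"),
            inherits(csf, "tissue_map"))
  for (m in list(wm, csf)) {
    .check_same_grid(gm, m$values, what = "companion map")
    if (abs(m$voxel_volume_mm3 - gm$voxel_volume_mm3) >
        1e-6 * gm$voxel_volume_mm3)
      stop("voxel geometry differs between tissue maps")
  }
  total_volume(gm) + total_volume(wm) + total_volume(csf)
}

#' Atlas definition: integer label image plus label table
#'
#' @param label_image 3D integer array; 0 is background.
#' @param labels Data frame with columns `label_id` (positive integer,
#'   unique), `region_name` and `family`. Families are disjoint sets of
#'   labels (e.g. a lobar and a fine parcellation live in different images).
#' @param voxel_volume_mm3,affine Geometry, as for [tissue_map()].
#' @return An object of class `atlas_definition`.
#' @export
atlas_definition <- function(label_image, labels, voxel_volume_mm3 = 1,
                             affine = NULL) {
  if (!is.array(label_image) || length(dim(label_image)) != 3L)
    stop("`label_image` must be a 3D array")
  storage.mode(label_image) <- "integer"
  req <- c("label_id", "region_name", "family")
  if (!all(req %in% names(labels)))
    stop("label table must have columns: ", paste(req, collapse = ", "))
  labels$label_id <- as.integer(labels$label_id)
  if (anyDuplicated(labels$label_id))
    stop("duplicate label_id in label table")
  if (any(labels$label_id <= 0L))
    stop("label_id values must be positive integers")
  present <- setdiff(unique(as.vector(label_image)), 0L)
  unknown <- setdiff(present, labels$label_id)
  if (length(unknown))
    stop("label image contains ids absent from the label table: ",
         paste(unknown, collapse = ", "))
  if (!is.null(affine)) {
    affine <- as.matrix(affine)
    voxel_volume_mm3 <- abs(det(affine[1:3, 1:3]))
  }
  structure(
    list(label_image = label_image, labels = labels,
         voxel_volume_mm3 = voxel_volume_mm3),
    class = "atlas_definition"
  )
}

#' @export
print.atlas_definition <- function(x, ...) {
  cat(sprintf("<atlas_definition> grid %s, %d labels, families: %s\n",
              paste(dim(x$label_image), collapse = "x"), nrow(x$labels),
              paste(unique(x$labels$family), collapse = ", ")))
  invisible(x)
}

#' Read an atlas label table
#'
#' Tab-separated file with header `label_id  region_name  family`. Unknown
#' columns produce a warning; missing required columns are fatal.
#'
#' @param path Path to the TSV.
#' @return Data frame with the three required columns.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  req <- c("label_id", "region_name", "family")
  missing <- setdiff(req, names(tab))
  if (length(missing))
    stop("label table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(tab), req)
  if (length(extra))
    warning("ignoring unknown label-table column(s): ",
            paste(extra, collapse = ", "))
  tab <- tab[req]
  if (anyDuplicated(tab$label_id))
    stop("duplicate label_id in ", path)
  tab$label_id <- as.integer(tab$label_id)
  tab
}

#' @rdname read_label_table
#' @param labels Data frame as returned by [read_label_table()].
#' @export
write_label_table <- function(labels, path) {
  utils::write.table(labels[c("label_id", "region_name", "family")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an atlas (label image + label table)
#'
#' @param image_path NIfTI label image.
#' @param labels_path Label-table TSV (see [read_label_table()]).
#' @return An [atlas_definition()].
#' @export
read_atlas <- function(image_path, labels_path) {
  img <- RNifti::readNifti(image_path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  atlas_definition(round(arr), read_label_table(labels_path),
                   affine = RNifti::xform(img))
}

#' Subject-by-region volume table
#'
#' The central container for regional grey-matter volumes: one row per
#' subject, one column per region, values in mL, plus the subject covariates
#' (group, age, sex, TIV) that the per-region models use.
#'
#' @param subjects Data frame with columns `id`, `med` (0 control /
#'   1 meditator), `age` (years), `sex` (`"F"`/`"M"`) and `tiv_ml`.
#' @param volumes Numeric matrix, subjects x regions, in mL. Column names are
#'   the region names; row order matches `subjects`.
#' @return An object of class `roi_volume_table`.
#' @export
roi_volume_table <- function(subjects, volumes) {
  subjects <- validate_subjects(subjects)
  volumes <- as.matrix(volumes)
  if (nrow(volumes) != nrow(subjects))
    stop("`volumes` has ", nrow(volumes), " rows but there are ",
         nrow(subjects), " subjects")
  if (is.null(colnames(volumes)))
    stop("`volumes` must have region names as column names")
  if (any(!is.finite(volumes)))
    stop("volume table contains non-finite values")
  if (any(volumes < 0))
    stop("volumes must be non-negative")
  rownames(volumes) <- subjects$id
  structure(
    list(subjects = subjects, regions = colnames(volumes), volumes = volumes),
    class = "roi_volume_table"
  )
}

#' @export
print.roi_volume_table <- function(x, ...) {
  cat(sprintf("<roi_volume_table> %d subjects x %d regions (mL)\n",
              nrow(x$volumes), ncol(x$volumes)))
  invisible(x)
}

validate_subjects <- function(subjects) {
  subjects <- as.data.frame(subjects)
  req <- c("id", "med", "age", "sex", "tiv_ml")
  missing <- setdiff(req, names(subjects))
  if (length(missing))
    stop("subject table lacks column(s): ", paste(missing, collapse = ", "))
  subjects$id <- as.character(subjects$id)
  if (anyDuplicated(subjects$id))
    stop("duplicated subject ids: ",
         paste(unique(subjects$id[duplicated(subjects$id)]), collapse = ", "))
  if (!all(subjects$med %in% c(0, 1)))
    stop("`med` must be 0 (control) or 1 (meditator)")
  if (!all(subjects$sex %in% c("F", "M")))
    stop("`sex` must be 'F' or 'M'")
  drop <- !stats::complete.cases(subjects[req]) |
    !is.finite(subjects$age) | !is.finite(subjects$tiv_ml)
  if (any(drop)) {
    warning("dropping ", sum(drop), " subject(s) with missing covariates: ",
            paste(subjects$id[drop], collapse = ", "))
    subjects <- subjects[!drop, , drop = FALSE]
  }
  if (any(subjects$age <= 0) || any(subjects$tiv_ml <= 0))
    stop("age and tiv_ml must be positive")
  rownames(subjects) <- NULL
  subjects
}

#' Extract a subject-by-region volume table from tissue maps and an atlas
#'
#' For every subject and every region in the requested atlas family, sums the
#' subject's modulated grey-matter map over the voxels carrying that region's
#' label and converts to mL. The label image is used as-is (exact integer
#' equality, no binarisation threshold); maps and atlas must share the grid.
#'
#' @param gm_maps Named list of [tissue_map()]s, one per subject id.
#' @param atlas An [atlas_definition()].
#' @param family Family id selecting rows of the atlas label table.
#' @param subjects Subject covariate data frame (see [roi_volume_table()]).
#' @return A [roi_volume_table()]; region order follows the label table.
#' @export
extract_roi_table <- function(gm_maps, atlas, family, subjects) {
  stopifnot(inherits(atlas, "atlas_definition"))
  subjects <- validate_subjects(subjects)
  lab <- atlas$labels[atlas$labels$family == family, , drop = FALSE]
  if (nrow(lab) == 0L)
    stop("family '", family, "' not present in the atlas label table")
  missing_maps <- setdiff(subjects$id, names(gm_maps))
  if (length(missing_maps))
    stop("missing grey-matter map(s) for subject(s): ",
         paste(missing_maps, collapse = ", "))
  present <- unique(as.vector(atlas$label_image))
  vols <- matrix(0, nrow(subjects), nrow(lab),
                 dimnames = list(subjects$id, lab$region_name))
  for (j in seq_len(nrow(subjects))) {
    map <- gm_maps[[subjects$id[j]]]
    stopifnot(inherits(map, "tissue_map"))
    .check_same_grid(map, atlas$label_image, what = "atlas label image")
    if (abs(map$voxel_volume_mm3 - atlas$voxel_volume_mm3) >
        1e-6 * atlas$voxel_volume_mm3)
      stop("voxel geometry differs between map and atlas")
    for (r in seq_len(nrow(lab))) {
      if (!(lab$label_id[r] %in% present)) {
        if (j == 1L)
          warning("label ", lab$label_id[r], " (", lab$region_name[r],
                  ") absent from the label image; recording zero volume")
        next
      }
      vols[j, r] <- total_volume(map, atlas$label_image == lab$label_id[r])
    }
  }
  roi_volume_table(subjects, vols)
}

#' Read / write subject covariates
#'
#' TSV/CSV with header `id  group  age  sex  tiv_ml`; `group` may be
#' `control`/`meditator` or `0`/`1`. The delimiter is inferred from the file
#' extension (`.csv` = comma, otherwise tab).
#'
#' @param path File path.
#' @return Data frame with columns `id`, `med`, `age`, `sex`, `tiv_ml`
#'   (plus `group` kept as a factor-like string).
#' @export
read_subjects <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("id", "group", "age", "sex", "tiv_ml")
  missing <- setdiff(req, names(tab))
  if (length(missing))
    stop("subject file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(tab), req)
  if (length(extra))
    warning("ignoring unknown subject column(s): ",
            paste(extra, collapse = ", "))
  grp <- as.character(tab$group)
  med <- ifelse(grp %in% c("meditator", "1"), 1,
                ifelse(grp %in% c("control", "0"), 0, NA))
  if (anyNA(med))
    stop("unrecognised group value(s): ",
         paste(unique(grp[is.na(med)]), collapse = ", "))
  validate_subjects(data.frame(id = tab$id, med = med, age = tab$age,
                               sex = tab$sex, tiv_ml = tab$tiv_ml,
                               group = ifelse(med == 1, "meditator", "control"),
                               stringsAsFactors = FALSE))
}

#' @rdname read_subjects
#' @param subjects Subject covariate data frame.
#' @export
write_subjects <- function(subjects, path) {
  subjects <- validate_subjects(subjects)
  out <- data.frame(id = subjects$id,
                    group = ifelse(subjects$med == 1, "meditator", "control"),
                    age = subjects$age, sex = subjects$sex,
                    tiv_ml = subjects$tiv_ml)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a wide subject-by-region volume table
#'
#' First column `id`, remaining columns one region each, values in mL —
#' the layout of per-subject regional GMV supplementary tables.
#'
#' @param path File path (TSV, or CSV by extension).
#' @param subjects Optional covariate data frame to attach; when supplied the
#'   result is a full [roi_volume_table()], otherwise a bare data frame.
#' @return A [roi_volume_table()] or data frame.
#' @export
read_volume_table <- function(path, subjects = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "id")
    stop("volume table ", path, " must have 'id' as its first column")
  if (anyDuplicated(tab$id))
    stop("duplicated subject ids in ", path)
  vols <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vols) <- tab$id
  if (is.null(subjects)) return(tab)
  subjects <- validate_subjects(subjects)
  missing <- setdiff(subjects$id, tab$id)
  if (length(missing))
    stop("volume table lacks row(s) for subject(s): ",
         paste(missing, collapse = ", "))
  roi_volume_table(subjects, vols[subjects$id, , drop = FALSE])
}

#' @rdname read_volume_table
#' @param table A [roi_volume_table()].
#' @export
write_volume_table <- function(table, path) {
  stopifnot(inherits(table, "roi_volume_table"))
  out <- data.frame(id = table$subjects$id, table$volumes,
                    check.names = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
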