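#' Write a grid or mask to a NIfTI volume file
#'
#' Values, spacing and origin round-trip exactly. Masks are stored as 0/1
#' integers. The affine stored on disk is diagonal with the package's LPS
#' axis order mapped directly onto the file axes.
#'
#' @param grid a [dose_grid()], [image_grid()] or [organ_mask()].
#' @param path output path; `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  if (!inherits(grid, "volume_grid")) stop("grid must be a volume grid")
  vals <- grid$values
  if (is.logical(vals)) vals <- array(as.integer(vals), dim = dim(vals))
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- grid$spacing
  m <- diag(4)
  diag(m)[1:3] <- grid$spacing
  m[1:3, 4] <- grid$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a grid or mask from a NIfTI volume file
#'
#' @param path file written by [write_volume()] (or any 3D NIfTI with a
#'   diagonal affine).
#' @param type `"dose"`, `"image"` or `"mask"`.
#' @param laterality for masks, passed to [organ_mask()].
#' @return the corresponding volume object.
#' @export
read_volume <- function(path, type = c("dose", "image", "mask"),
                        laterality = "unassigned") {
  type <- match.arg(type)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L) stop("expected a 3D volume: ", path)
  vals <- array(as.numeric(vals), dim(vals))  # strip NIfTI attributes
  xf <- RNifti::xform(img)
  spacing <- abs(diag(xf[1:3, 1:3, drop = FALSE]))
  if (all(spacing == 0)) spacing <- RNifti::pixdim(img)[1:3]
  origin <- xf[1:3, 4]
  switch(type,
    dose = dose_grid(vals, spacing, origin),
    image = image_grid(vals, spacing, origin),
    mask = organ_mask(vals != 0, spacing, origin, laterality = laterality))
}

#' Read a cohort from delimited text tables
#'
#' @param patients_path CSV with header `id, age, sex` (sex coded
#'   `female`/`male`).
#' @param followups_path CSV with header `id, time_months, grade`.
#' @return a [cohort()].
#' @export
read_cohort <- function(patients_path, followups_path) {
  pat <- utils::read.csv(patients_path, stringsAsFactors = FALSE)
  fup <- utils::read.csv(followups_path, stringsAsFactors = FALSE)
  need <- function(df, cols, path) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop("missing column(s) ", paste(miss, collapse = ", "),
                           " in ", path)
  }
  need(pat, c("id", "age", "sex"), patients_path)
  need(fup, c("id", "time_months", "grade"), followups_path)
  cohort(pat, fup)
}

#' Write a cohort to delimited text tables
#' @param x a [cohort()].
#' @param patients_path,followups_path output CSV paths.
#' @export
write_cohort <- function(x, patients_path, followups_path) {
  utils::write.csv(x$patients, patients_path, row.names = FALSE)
  utils::write.csv(x$followups, followups_path, row.names = FALSE)
  invisible(x)
}

#' Write a wide-format feature table
#'
#' Wide format: one row per patient, first column `patient_id`, one column
#' per feature. The long format has header
#' `patient_id, side, group, feature, value`.
#'
#' @param table data.frame with `patient_id` and feature columns.
#' @param path output path.
#' @param format `"wide"` or `"long"`.
#' @export
write_feature_table <- function(table, path, format = c("wide", "long")) {
  format <- match.arg(format)
  # 17 significant digits make the numeric round trip bit-exact
  fmt17 <- function(df) {
    for (cn in names(df)) if (is.double(df[[cn]]))
      df[[cn]] <- formatC(df[[cn]], digits = 17, format = "g")
    df
  }
  if (format == "wide") {
    utils::write.csv(fmt17(table), path, row.names = FALSE, quote = FALSE)
  } else {
    feats <- setdiff(names(table), "patient_id")
    ann <- annotate_features(feats)
    long <- do.call(rbind, lapply(seq_along(feats), function(i) {
      data.frame(patient_id = table$patient_id,
                 side = ann$side[i], group = ann$group[i],
                 feature = feats[i], value = table[[feats[i]]],
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(fmt17(long), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path input path.
#' @param format `"wide"` or `"long"`.
#' @return wide-format data.frame.
#' @export
read_feature_table <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "wide") return(df)
  ids <- unique(df$patient_id)
  feats <- unique(df$feature)
  wide <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (f in feats) {
    sub <- df[df$feature == f, ]
    wide[[f]] <- sub$value[match(ids, sub$patient_id)]
  }
  wide
}
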