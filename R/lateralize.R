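#' Lateralize a patient's volumes into ipsi- and contralateral glands
#'
#' Spatial dose features are defined with respect to the treated (higher-dose,
#' "ipsilateral") side rather than anatomical left/right. To make features
#' side-consistent across patients, the volumes are flipped through the
#' sagittal plane whenever the mean dose to the right parotid gland exceeds
#' the mean dose to the left one; after the (optional) flip the
#' higher-mean-dose gland is labeled ipsilateral. Ties ("strictly higher" not
#' met) do not flip and label the left gland ipsilateral.
#'
#' @param dose a [dose_grid()].
#' @param left,right [organ_mask()]s of the left and right parotid glands,
#'   nonempty, same lattice as `dose`.
#' @param image optional [image_grid()] flipped alongside.
#' @return an object of class `"lateralization"`: a list with `dose`, `image`,
#'   `ipsi_mask`, `contra_mask`, `flipped`, `mean_ipsi`, `mean_contra`.
#' @export
lateralize <- function(dose, left, right, image = NULL) {
  stopifnot_same_geometry(dose, left, "dose and left mask")
  stopifnot_same_geometry(dose, right, "dose and right mask")
  if (!any(left$values)) stop("left mask is empty")
  if (!any(right$values)) stop("right mask is empty")
  if (!is.null(image)) stopifnot_same_geometry(dose, image, "dose and image")
  m_left <- mean_dose(dose, left)
  m_right <- mean_dose(dose, right)
  flipped <- m_right > m_left
  if (flipped) {
    dose <- flip_sagittal(dose)
    left <- flip_sagittal(left)
    right <- flip_sagittal(right)
    if (!is.null(image)) image <- flip_sagittal(image)
    ipsi <- right; contra <- left
  } else {
    ipsi <- left; contra <- right
  }
  ipsi$role <- "ipsi"
  contra$role <- "contra"
  structure(list(dose = dose, image = image,
                 ipsi_mask = ipsi, contra_mask = contra,
                 flipped = flipped,
                 mean_ipsi = mean_dose(dose, ipsi),
                 mean_contra = mean_dose(dose, contra)),
            class = "lateralization")
}

#' @export
print.lateralization <- function(x, ...) {
  cat(sprintf(
    "<lateralization> flipped=%s, ipsi=%s gland (mean %.2f Gy), contra=%s gland (mean %.2f Gy)\n",
    x$flipped, x$ipsi_mask$laterality, x$mean_ipsi,
    x$contra_mask$laterality, x$mean_contra))
  invisible(x)
}
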