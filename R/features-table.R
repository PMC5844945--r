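#' Feature group vocabulary
#'
#' The nine feature groups used by the group-selection step of the
#' multivariate workflow.
#' @return character vector of group names.
#' @export
feature_group_names <- function() {
  c("demographics", "parotid shape", "DVH", "subvolume mean dose",
    "spatial dose gradient", "spatial dose spread", "spatial dose correlation",
    "spatial dose skewness", "spatial dose coskewness")
}

# Registry of per-gland base feature names by group.
gland_feature_registry <- function() {
  list(
    "parotid shape" = c("volume", "area", "sphericity", "eccentricity",
                        "compactness", "lambda1", "lambda2", "lambda3"),
    "DVH" = c("mean", "spread", "skewness",
              paste0("D", c(2, 98, seq(10, 90, by = 10))),
              paste0("V", seq(10, 45, by = 5)), "entropy", "uniformity"),
    "subvolume mean dose" = paste0("s", rep(c("x", "y", "z"), each = 3), 1:3),
    "spatial dose gradient" = c("gradient_x", "gradient_y", "gradient_z"),
    "spatial dose spread" = c("eta200", "eta020", "eta002"),
    "spatial dose correlation" = c("eta110", "eta101", "eta011"),
    "spatial dose skewness" = c("eta300", "eta030", "eta003"),
    "spatial dose coskewness" = c("eta012", "eta021", "eta120",
                                  "eta102", "eta210", "eta201", "eta111"))
}

#' Annotate feature names with group and gland side
#'
#' Feature columns are named `<base>_i` (ipsilateral gland), `<base>_c`
#' (contralateral gland), or a patient-level name (`age`, `sex`,
#' `time_months`).
#'
#' @param features character vector of feature column names.
#' @return data.frame with columns `feature`, `base`, `side`, `group`.
#' @export
annotate_features <- function(features) {
  reg <- gland_feature_registry()
  base2group <- unlist(lapply(names(reg), function(g)
    stats::setNames(rep(g, length(reg[[g]])), reg[[g]])))
  side <- rep("patient-level", length(features))
  base <- features
  ipsi <- grepl("_i$", features)
  contra <- grepl("_c$", features)
  side[ipsi] <- "ipsi"; side[contra] <- "contra"
  base[ipsi | contra] <- sub("_[ic]$", "", base[ipsi | contra])
  group <- unname(base2group[base])
  group[base %in% c("age", "sex")] <- "demographics"
  group[base == "time_months"] <- "demographics"
  group[is.na(group)] <- "other"
  data.frame(feature = features, base = base, side = side, group = group,
             stringsAsFactors = FALSE)
}

#' Extract all per-gland features
#'
#' Runs shape, DVH, subvolume, gradient and moment extraction on one gland.
#'
#' @param dose a [dose_grid()].
#' @param mask an [organ_mask()] on the same lattice.
#' @return named numeric vector of 60 features.
#' @export
extract_gland_features <- function(dose, mask) {
  sf <- shape_features(mask)
  c(unlist(sf[c("volume", "area", "sphericity", "eccentricity", "compactness",
                "lambda1", "lambda2", "lambda3")]),
    dvh_features(dose, mask),
    subvolume_mean_doses(dose, mask),
    dose_gradients(dose, mask),
    dose_moments(dose, mask))
}

#' Extract the full feature vector for one patient
#'
#' Lateralizes the volumes (sagittal flip toward the higher-dose gland being
#' ipsilateral), optionally resamples to isotropic resolution first, then
#' extracts per-gland features suffixed `_i` / `_c`.
#'
#' @param dose a [dose_grid()].
#' @param left,right parotid [organ_mask()]s.
#' @param age,sex patient-level covariates (`sex` coded `"female"`/`"male"`;
#'   stored as 0/1 male indicator).
#' @param resample_to optional isotropic spacing (mm), e.g. 1; `NULL` keeps
#'   the native lattice.
#' @return named numeric vector (120 gland features + age + sex).
#' @export
extract_patient_features <- function(dose, left, right, age = NA, sex = NA,
                                     resample_to = NULL) {
  if (!is.null(resample_to)) {
    dose <- resample_to_isotropic(dose, resample_to)
    left <- resample_to_isotropic(left, resample_to)
    right <- resample_to_isotropic(right, resample_to)
  }
  lat <- lateralize(dose, left, right)
  fi <- extract_gland_features(lat$dose, lat$ipsi_mask)
  fc <- extract_gland_features(lat$dose, lat$contra_mask)
  names(fi) <- paste0(names(fi), "_i")
  names(fc) <- paste0(names(fc), "_c")
  sex_num <- if (is.character(sex) || is.factor(sex))
    as.numeric(as.character(sex) == "male") else as.numeric(sex)
  c(age = as.numeric(age), sex = sex_num, fi, fc)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation between two feature vectors; the
#' ordinal-association measure behind the redundancy filter.
#'
#' @param x,y numeric vectors of equal length >= 2, neither constant.
#' @return tau in \[-1, 1\].
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Kendall tau is undefined for constant input")
  stats::cor(x, y, method = "kendall")
}

#' Concordance probability of a Kendall correlation
#'
#' The probability that two features rank a random pair of observations the
#' same way, `(1 + tau) / 2`. At the redundancy-filter threshold `tau = 0.5`
#' this is 75%.
#'
#' @param tau Kendall correlation in \[-1, 1\].
#' @return probability in \[0, 1\].
#' @export
concordance_probability <- function(tau) {
  if (any(!is.finite(tau)) || any(tau < -1) || any(tau > 1))
    stop("tau must lie in [-1, 1]")
  (1 + tau) / 2
}

#' Default simplicity ranking of base features
#'
#' When two features are flagged as redundant, the conceptually and
#' computationally simpler one is kept: demographics first, then mean dose
#' (over any `Dx`/`Vx`), volume (over derived shape descriptors), simple
#' spread/skewness, gradients, subvolume means, and finally the more derived
#' quantities. Position = priority (earlier wins).
#'
#' @return character vector of base feature names, highest priority first.
#' @export
default_feature_priority <- function() {
  reg <- gland_feature_registry()
  c("age", "sex", "time_months",
    "mean", "volume", "spread", "skewness",
    "gradient_x", "gradient_y", "gradient_z",
    reg[["subvolume mean dose"]],
    "area", "sphericity", "eccentricity", "compactness",
    "lambda1", "lambda2", "lambda3",
    paste0("D", c(2, 98, seq(10, 90, by = 10))),
    paste0("V", seq(10, 45, by = 5)),
    "entropy", "uniformity",
    reg[["spatial dose spread"]], reg[["spatial dose correlation"]],
    reg[["spatial dose skewness"]], reg[["spatial dose coskewness"]])
}

#' Kendall-tau redundancy filter
#'
#' Flags a pair of base features as highly correlated when `|tau| >
#' threshold` in BOTH glands (for pairs where both members are per-gland
#' features) or in their single shared column (patient-level pairs), and
#' drops the lower-priority member of each flagged pair.
#'
#' @param table wide feature table (data.frame; a `patient_id` column is
#'   ignored); per-gland features as `<base>_i` / `<base>_c` columns.
#' @param threshold absolute Kendall tau above which a pair is redundant.
#' @param priority ordered character vector of base names, simplest first;
#'   must cover every feature involved in a drop.
#' @return list with `table` (reduced, both gland columns of dropped bases
#'   removed), `dropped` (data.frame logging `dropped`, `kept`, `tau_ipsi`,
#'   `tau_contra`).
#' @export
redundancy_filter <- function(table, threshold = 0.5,
                              priority = default_feature_priority()) {
  feats <- setdiff(names(table), "patient_id")
  ann <- annotate_features(feats)
  bases <- unique(ann$base)
  rank_of <- function(b) {
    r <- match(b, priority)
    if (is.na(r)) NA_integer_ else r
  }
  tau_of <- function(a, b) {
    # returns c(tau_ipsi, tau_contra) or a single shared tau for
    # patient-level pairs
    col <- function(base, side) {
      hit <- ann$feature[ann$base == base & ann$side == side]
      if (length(hit)) table[[hit[1]]] else NULL
    }
    ai <- col(a, "ipsi"); ac <- col(a, "contra"); ap <- col(a, "patient-level")
    bi <- col(b, "ipsi"); bc <- col(b, "contra"); bp <- col(b, "patient-level")
    safe_tau <- function(x, y)
      tryCatch(kendall_tau(x, y), error = function(e) NA_real_)
    if (!is.null(ap) || !is.null(bp)) {
      xa <- if (!is.null(ap)) ap else ai
      xb <- if (!is.null(bp)) bp else bi
      t1 <- safe_tau(xa, xb)
      c(t1, t1)
    } else {
      c(safe_tau(ai, bi), safe_tau(ac, bc))
    }
  }
  dropped <- character(0)
  log <- data.frame(dropped = character(0), kept = character(0),
                    tau_ipsi = numeric(0), tau_contra = numeric(0),
                    stringsAsFactors = FALSE)
  if (length(bases) >= 2) {
    for (i in seq_len(length(bases) - 1)) {
      for (j in (i + 1):length(bases)) {
        a <- bases[i]; b <- bases[j]
        if (a %in% dropped || b %in% dropped) next
        tt <- tau_of(a, b)
        if (any(is.na(tt)) || !all(abs(tt) > threshold)) next
        ra <- rank_of(a); rb <- rank_of(b)
        if (is.na(ra) || is.na(rb))
          stop("priority ranking is missing feature ",
               if (is.na(ra)) a else b)
        loser <- if (ra <= rb) b else a
        winner <- if (ra <= rb) a else b
        dropped <- c(dropped, loser)
        log <- rbind(log, data.frame(dropped = loser, kept = winner,
                                     tau_ipsi = tt[1], tau_contra = tt[2],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  keep <- !(ann$base %in% dropped)
  cols <- c(intersect("patient_id", names(table)), ann$feature[keep])
  list(table = table[, cols, drop = FALSE], dropped = log)
}
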