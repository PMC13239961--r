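#' Radiomic feature vector (first-order + 3D shape)
#'
#' Resamples the volume and mask to the configured isotropic spacing and
#' extracts the 18 first-order and 14 shape descriptors from the original
#' (unfiltered) volume: 32 features.
#'
#' @param volume a [dose_volume()] (or image volume in the same container).
#' @param mask a [structure_mask()].
#' @param config an [extraction_config()] (image defaults: 1 mm spacing,
#'   bin width 25).
#' @return named numeric vector of length 32.
#' @export
extract_radiomics <- function(volume, mask,
                              config = extraction_config(bin_width = 25)) {
  rs <- resample_pair(volume, mask, config)
  c(first_order_features(rs$volume, rs$mask, config, prefix = "original"),
    shape_features(rs$mask, prefix = "original"))
}

#' Dosiomic feature vector (first-order + texture + wavelet)
#'
#' Extracts, from the resampled and discretized dose volume: 18 first-order
#' features, 75 texture features (GLCM 24, GLRLM 16, GLSZM 16, GLDM 14,
#' NGTDM 5), and the same 93 first-order + texture features from each of
#' the 8 wavelet subbands (744), for 837 features in total. Shape features
#' are not re-extracted (they are identical to the imaging ones by
#' construction). The default mask is the whole dose field (`dose > 0`).
#'
#' @param dose_volume a [dose_volume()].
#' @param mask optional [structure_mask()]; `NULL` uses the whole field.
#' @param config an [extraction_config()] (dose defaults: 1 Gy bins).
#' @return named numeric vector (837 with all categories enabled).
#' @export
extract_dosiomics <- function(dose_volume, mask = NULL,
                              config = extraction_config(bin_width = 1)) {
  vol <- if (!is.null(config$resample_spacing_mm)) {
    resample_volume(dose_volume, config$resample_spacing_mm)
  } else {
    dose_volume
  }
  mgrid <- if (is.null(mask)) {
    vol$grid > 0
  } else {
    resample_mask_grid(mask, vol)
  }
  if (!any(mgrid)) mgrid <- array(TRUE, dim = dim(vol$grid))

  cats <- config$enabled_categories
  tex_cats <- intersect(c("glcm", "glrlm", "glszm", "gldm", "ngtdm"), cats)
  extract_one <- function(arr, prefix) {
    fo <- if ("firstorder" %in% cats) {
      first_order_features(arr, mgrid, config, prefix = prefix)
    } else NULL
    lev <- discretize(arr, mgrid, config$bin_width)
    tex <- unlist(lapply(tex_cats, function(cat) {
      texture_features(lev, cat, prefix = prefix)
    }))
    c(fo, tex)
  }

  out <- extract_one(vol$grid, "original")
  if ("wavelet" %in% cats) {
    bands <- wavelet_bands(vol$grid)
    for (b in names(bands)) {
      out <- c(out, extract_one(bands[[b]], paste0("wavelet-", b)))
    }
  }
  out
}

# resample a volume and its mask onto the configured isotropic grid
resample_pair <- function(volume, mask, config) {
  if (is.null(config$resample_spacing_mm)) {
    return(list(volume = volume, mask = mask))
  }
  vol <- resample_volume(volume, config$resample_spacing_mm)
  list(volume = vol,
       mask = structure_mask(resample_mask_grid(mask, vol), vol$spacing,
                             vol$origin, mask$label))
}

# trilinear-resample a mask as an indicator field, threshold at 0.5
resample_mask_grid <- function(mask, target_vol) {
  mv <- dose_volume(array(as.double(mask$grid), dim = dim(mask$grid)),
                    mask$spacing, mask$origin,
                    isocenter = mask$origin, prescription_dose = 1)
  dims <- dim(target_vol$grid)
  ax <- lapply(1:3, function(a) {
    target_vol$origin[a] + (seq_len(dims[a]) - 1) * target_vol$spacing[a]
  })
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  array(sample_volume(mv, pts) >= 0.5, dim = dims)
}

#' Feature table for a simulated cohort
#'
#' Extracts one radiomic + dosiomic feature row per plan (features are
#' plan-level: they describe the reference volume, while rotations vary
#' per record).
#'
#' @param cohort a [simulate_cohort()] result with volumes kept.
#' @param radiomics_config,dosiomics_config [extraction_config()]s.
#' @return data.frame with `plan_id` and one column per feature.
#' @export
cohort_features <- function(cohort,
                            radiomics_config = extraction_config(
                              resample_spacing_mm = NULL, bin_width = 25),
                            dosiomics_config = extraction_config(
                              resample_spacing_mm = NULL, bin_width = 1)) {
  if (length(cohort$plans) == 0) {
    stop_rotqa("cohort was simulated without volumes", "rotqa_invalid_input")
  }
  rows <- lapply(names(cohort$plans), function(pid) {
    pl <- cohort$plans[[pid]]
    rad <- extract_radiomics(pl$volume, pl$mask, radiomics_config)
    dos <- extract_dosiomics(pl$volume, mask = NULL, dosiomics_config)
    c(setNames(rad, paste0("radiomics_", names(rad))),
      setNames(dos, paste0("dosiomics_", names(dos))))
  })
  feat <- do.call(rbind, rows)
  df <- data.frame(plan_id = names(cohort$plans), feat, check.names = FALSE,
                   row.names = NULL)
  df
}

#' Write / read a feature table CSV
#'
#' @param table data.frame from [cohort_features()] (or metrics join).
#' @param path CSV path.
#' @return `path` invisibly (write); data.frame (read).
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop_rotqa("feature table is empty or truncated", "rotqa_parse_error")
  }
  df
}
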