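#' 2D dose plane container
#'
#' A square (after standardization) matrix of planar dose samples with a
#' uniform pixel pitch, as produced by a planar detector array.
#'
#' @param matrix 2D numeric matrix of dose values, all non-negative.
#' @param spacing_mm scalar inter-sample pitch in mm.
#' @param mode `"absolute_Gy"` (values in Gy) or `"relative_fraction"`
#'   (values scaled to a reference maximum, max <= 1 + tolerance).
#' @return an object of class `dose_plane`.
#' @export
dose_plane <- function(matrix, spacing_mm, mode = c("absolute_Gy",
                                                    "relative_fraction")) {
  mode <- match.arg(mode)
  if (!is.matrix(matrix)) stop_rotqa("`matrix` must be a matrix",
                                     "rotqa_invalid_spec")
  if (anyNA(matrix) || any(!is.finite(matrix))) {
    stop_rotqa("plane contains non-finite values", "rotqa_invalid_input")
  }
  if (any(matrix < 0)) stop_rotqa("dose values must be >= 0",
                                  "rotqa_invalid_spec")
  check_number(spacing_mm, "spacing_mm", 0, strict = TRUE)
  # relative planes self-normalized to their own max have max == 1; a plane
  # normalized to a shared reference max may slightly exceed 1, so the mode
  # flag is informative rather than a hard bound
  structure(list(matrix = matrix, spacing_mm = as.double(spacing_mm),
                 mode = mode, max_dose = max(matrix)),
            class = "dose_plane")
}

#' @export
print.dose_plane <- function(x, ...) {
  cat(sprintf("<dose_plane> %dx%d, pitch %.4g mm, max %.4g (%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$spacing_mm, x$max_dose,
              x$mode))
  invisible(x)
}

#' Write / read a dose plane as CSV matrix + JSON sidecar
#'
#' @param plane a [dose_plane()].
#' @param prefix path prefix; writes `<prefix>.csv` (matrix, no header) and
#'   `<prefix>.json` (spacing and mode).
#' @return `prefix` invisibly (write); a [dose_plane()] (read).
#' @export
write_plane <- function(plane, prefix) {
  utils::write.table(plane$matrix, paste0(prefix, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(spacing_mm = plane$spacing_mm, mode = plane$mode),
                       paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_plane
#' @export
read_plane <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (is.null(side$spacing_mm) || is.null(side$mode)) {
    stop_rotqa("plane sidecar missing `spacing_mm` or `mode`",
               "rotqa_parse_error")
  }
  m <- as.matrix(read.csv(paste0(prefix, ".csv"), header = FALSE))
  dimnames(m) <- NULL
  if (anyNA(m)) stop_rotqa("plane CSV is ragged or non-numeric",
                           "rotqa_parse_error")
  dose_plane(m, side$spacing_mm, side$mode)
}
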