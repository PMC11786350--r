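#' Spot geometry: coordinates and optional histology intensity
#'
#' Container for per-spot planar coordinates and, optionally, a grey-scale
#' histology intensity per spot. The intensity `z` is the median grey value of
#' a small pixel window around each spot center (see [spot_intensity()]) and
#' feeds the fused spot distance of [squared_distance_matrix()].
#'
#' @param spot_ids character vector of unique spot identifiers (length M).
#' @param x,y numeric planar coordinates per spot (platform array units).
#' @param z optional numeric grey-scale intensity per spot, typically in
#'   `[0, 1]`; `NULL` when no histology image is available.
#' @return An object of class `spot_geometry`: a list with elements
#'   `spot_ids`, `x`, `y`, `z` (possibly `NULL`) and `n_spots`.
#' @examples
#' geom <- spot_geometry(c("s1", "s2"), x = c(0, 3), y = c(0, 4))
#' geom$n_spots
#' @export
spot_geometry <- function(spot_ids, x, y, z = NULL) {
  spot_ids <- as.character(spot_ids)
  m <- length(spot_ids)
  if (anyDuplicated(spot_ids)) {
    stop("duplicated spot_ids: ",
         paste(unique(spot_ids[duplicated(spot_ids)]), collapse = ", "))
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != m || length(y) != m) {
    stop("x and y must have the same length as spot_ids (", m, ")")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite spot coordinates")
  }
  if (!is.null(z)) {
    z <- as.numeric(z)
    if (length(z) != m) stop("z must have length ", m)
    if (!all(is.finite(z))) stop("non-finite intensity values in z")
  }
  structure(list(spot_ids = spot_ids, x = x, y = y, z = z, n_spots = m),
            class = "spot_geometry")
}

#' @export
print.spot_geometry <- function(x, ...) {
  cat("spot_geometry:", x$n_spots, "spots;",
      if (is.null(x$z)) "no histology intensity" else "with histology intensity",
      "\n")
  invisible(x)
}

#' Median grey-scale intensity around spot centers
#'
#' For each spot, takes the median of the grey-scale image values inside a
#' `window` x `window` pixel square centered on the spot's pixel coordinates,
#' clipping the window at the image boundary, then divides by `max_intensity`
#' to put values on a `[0, 1]` scale.
#'
#' @param image numeric matrix of grey-scale intensities (rows = pixel rows).
#'   For RGB arrays convert first with [rgb_to_grey()].
#' @param centers two-column matrix or data frame of per-spot pixel
#'   coordinates `(row, col)`, 1-based.
#' @param window odd integer window side length (default 5).
#' @param max_intensity value to divide medians by. The default 1 leaves
#'   already-normalized images (e.g. `png::readPNG()` output) unchanged; pass
#'   255 (or 65535) for 8-bit (16-bit) integer images.
#' @return numeric vector of per-spot median intensities, length `nrow(centers)`.
#' @examples
#' img <- matrix(0.7, 10, 10)
#' spot_intensity(img, cbind(5, 5))  # 0.7
#' @export
spot_intensity <- function(image, centers, window = 5L, max_intensity = 1) {
  if (!is.matrix(image) || length(image) == 0L) {
    stop("image must be a non-empty 2-D matrix")
  }
  if (!all(is.finite(image))) stop("image contains non-finite values")
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be an odd integer >= 1")
  centers <- as.matrix(centers)
  if (ncol(centers) != 2L) stop("centers must have two columns (row, col)")
  nr <- nrow(image); nc <- ncol(image)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(nrow(centers)), function(i) {
    r <- centers[i, 1L]; c <- centers[i, 2L]
    if (r < 1 || r > nr || c < 1 || c > nc) {
      stop("spot ", i, " center (", r, ", ", c, ") lies outside the image")
    }
    rows <- max(1L, r - half):min(nr, r + half)
    cols <- max(1L, c - half):min(nc, c + half)
    stats::median(image[rows, cols]) / max_intensity
  }, numeric(1))
}

#' Convert an RGB histology image to grey-scale
#'
#' Standard luminance weighting `0.2126 R + 0.7152 G + 0.0722 B`. Arrays with
#' an alpha channel ignore it; a 2-D matrix is returned unchanged.
#'
#' @param img numeric matrix (already grey) or 3-D array with 3 or 4 channels.
#' @return numeric matrix of grey intensities.
#' @export
rgb_to_grey <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) != 3L || dim(img)[3] < 3L) {
    stop("img must be a matrix or an array with >= 3 channels")
  }
  0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
}

#' Read a spot coordinate table
#'
#' Expects a delimited file with header columns `spot_id`, `x`, `y` and
#' optionally `pixel_row`, `pixel_col` (pixel centers on the histology image).
#'
#' @param path file path; comma- or tab-delimited, chosen by extension
#'   (`.csv` vs anything else).
#' @return data frame with the columns above.
#' @export
read_spot_coords <- function(path) {
  if (!file.exists(path)) stop("coordinates file not found: ", path)
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("spot_id", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("coordinates file missing columns: ",
                         paste(miss, collapse = ", "))
  df
}
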