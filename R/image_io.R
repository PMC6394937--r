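#' Read an 8-bit grayscale image
#'
#' Reads a PNG or TIFF file and returns its pixel grid as an integer matrix
#' with values in \[0, 255\], rows indexing image rows from the top. Shoulder
#' ultrasound exports are 8-bit grayscale; color files whose channels are
#' identical (a common workstation export artifact) are collapsed to one
#' channel, any other color content is rejected, as are higher bit depths.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer matrix (height x width) of gray levels in \[0, 255\].
#' @export
read_gray_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("image file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (PNG or TIFF expected): ",
         path, call. = FALSE)
  )
  mat <- .collapse_channels(img, path)
  vals <- mat * 255
  ivals <- round(vals)
  if (max(abs(vals - ivals)) > 1e-6) {
    stop("not an 8-bit image (gray levels are not multiples of 1/255): ",
         path, call. = FALSE)
  }
  storage.mode(ivals) <- "integer"
  ivals
}

# readPNG/readTIFF return values in [0,1]; 2D = gray, 3rd dim = channels.
.collapse_channels <- function(img, path) {
  if (length(dim(img)) == 2L) return(img)
  if (length(dim(img)) != 3L) {
    stop("unsupported image layout in ", path, call. = FALSE)
  }
  nch <- dim(img)[3]
  if (nch == 2L) {           # gray + alpha
    if (any(img[, , 2] != 1)) {
      stop("image has non-trivial alpha channel: ", path, call. = FALSE)
    }
    return(img[, , 1])
  }
  if (nch %in% c(3L, 4L)) {
    if (nch == 4L && any(img[, , 4] != 1)) {
      stop("image has non-trivial alpha channel: ", path, call. = FALSE)
    }
    if (any(img[, , 1] != img[, , 2]) || any(img[, , 1] != img[, , 3])) {
      stop("color image with distinct channels is not a grayscale export: ",
           path, call. = FALSE)
    }
    return(img[, , 1])
  }
  stop("unsupported channel count (", nch, ") in ", path, call. = FALSE)
}

#' Write an 8-bit grayscale image
#'
#' Inverse of [read_gray_image()]; used by the phantom generator and in
#' round-trip tests.
#'
#' @param image Integer matrix with values in \[0, 255\].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  stopifnot(is.matrix(image), all(image >= 0), all(image <= 255))
  ext <- tolower(tools::file_ext(path))
  norm <- image / 255
  switch(ext,
    png = png::writePNG(norm, target = path),
    tif = ,
    tiff = tiff::writeTIFF(norm, where = path, bits.per.sample = 8L),
    stop("unsupported output format '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Rasterize a lesion polygon to a binary mask
#'
#' Vertices are 0-based `(row, col)` pixel coordinates; the continuous polygon
#' connects the centers of those pixels, and pixel `(r, c)` occupies center
#' `(r + 0.5, c + 0.5)`. A pixel belongs to the mask iff its center is inside
#' the polygon under the even-odd rule, with centers lying exactly on the
#' boundary counted as inside, so a rectangle with corners `(0,0)` and `(3,3)`
#' covers the full 4 x 4 block of pixels.
#'
#' @param vertices Numeric matrix (or data.frame) with two columns `(row, col)`
#'   and at least 3 rows.
#' @param dims Integer vector `c(height, width)`.
#' @return Logical matrix of dimension `dims`.
#' @export
rasterize_polygon <- function(vertices, dims) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) {
    stop("a polygon needs at least 3 vertices, got ", nrow(vertices),
         call. = FALSE)
  }
  if (ncol(vertices) != 2L || !is.numeric(vertices)) {
    stop("`vertices` must be an n x 2 numeric (row, col) matrix", call. = FALSE)
  }
  dims <- as.integer(dims)
  if (length(dims) != 2L || any(dims < 1L)) {
    stop("`dims` must be positive c(height, width)", call. = FALSE)
  }
  if (any(vertices < 0) || any(vertices[, 1] > dims[1] - 1) ||
      any(vertices[, 2] > dims[2] - 1)) {
    stop("polygon vertices fall outside the image bounds", call. = FALSE)
  }
  # polygon in pixel-center coordinates
  py <- vertices[, 1] + 0.5
  px <- vertices[, 2] + 0.5
  cy <- rep(seq_len(dims[1]) - 0.5, times = dims[2])
  cx <- rep(seq_len(dims[2]) - 0.5, each  = dims[1])

  n <- length(py)
  inside <- logical(length(cy))
  on_edge <- logical(length(cy))
  eps <- 1e-9
  j <- n
  for (i in seq_len(n)) {
    y1 <- py[j]; x1 <- px[j]; y2 <- py[i]; x2 <- px[i]
    crosses <- (y1 > cy) != (y2 > cy)
    if (any(crosses)) {
      xin <- x1 + (cy[crosses] - y1) * (x2 - x1) / (y2 - y1)
      hit <- cx[crosses] < xin
      inside[crosses][hit] <- !inside[crosses][hit]
    }
    # boundary: point on segment (y1,x1)-(y2,x2)
    dy <- y2 - y1; dx <- x2 - x1
    len2 <- dy * dy + dx * dx
    if (len2 > 0) {
      cross <- dx * (cy - y1) - dy * (cx - x1)
      tpar <- (dy * (cy - y1) + dx * (cx - x1)) / len2
      on_edge <- on_edge |
        (abs(cross) < eps * sqrt(len2) & tpar >= -eps & tpar <= 1 + eps)
    }
    j <- i
  }
  matrix(inside | on_edge, nrow = dims[1], ncol = dims[2])
}

#' Collect lesion pixels in row-major order
#'
#' @param image Integer matrix of gray levels.
#' @param mask Logical matrix of the same dimensions; `TRUE` marks lesion.
#' @return Integer vector of the masked intensities, scanned row by row
#'   (fixed order for reproducibility).
#' @export
masked_pixels <- function(image, mask) {
  if (!identical(dim(image), dim(mask))) {
    stop("image (", paste(dim(image), collapse = "x"),
         ") and mask (", paste(dim(mask), collapse = "x"),
         ") dimensions differ", call. = FALSE)
  }
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  as.integer(t(image)[t(mask)])
}

#' Read a lesion ROI file
#'
#' Two on-disk forms are supported: a CSV of `row,col` polygon vertices
#' (rasterized against the image dimensions) or a mask image in which any
#' nonzero pixel is inside the lesion.
#'
#' @param path ROI file (`.csv` vertex list, or `.png`/`.tif` mask).
#' @param dims `c(height, width)` of the image the ROI belongs to.
#' @return Logical mask matrix of dimension `dims`.
#' @export
read_roi <- function(path, dims) {
  if (!file.exists(path)) stop("ROI file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    verts <- utils::read.csv(path, header = TRUE)
    if (ncol(verts) < 2L) {
      stop("vertex CSV must have columns row,col: ", path, call. = FALSE)
    }
    return(rasterize_polygon(as.matrix(verts[, 1:2]), dims))
  }
  m <- read_gray_image(path)
  if (!identical(dim(m), as.integer(dims))) {
    stop("mask image dimensions do not match the image: ", path, call. = FALSE)
  }
  m > 0L
}

#' Assemble labelled case records from a manifest
#'
#' The manifest is a CSV with header
#' `case_id,patient_id,image_file,roi_file,label`; file columns are resolved
#' relative to `image_dir` and labels must be `"tendinopathy"` or `"tear"`.
#'
#' @param csv_path Manifest file.
#' @param image_dir Directory holding the referenced image and ROI files.
#' @return List of case records; each is a list with elements `case_id`,
#'   `patient_id`, `image`, `mask`, `label` and class `"case_record"`.
#' @export
load_manifest <- function(csv_path, image_dir = dirname(csv_path)) {
  if (!file.exists(csv_path)) {
    stop("manifest not found: ", csv_path, call. = FALSE)
  }
  man <- utils::read.csv(csv_path, colClasses = "character")
  needed <- c("case_id", "patient_id", "image_file", "roi_file", "label")
  missing_cols <- setdiff(needed, names(man))
  if (length(missing_cols)) {
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(man$label), c("tendinopathy", "tear"))
  if (length(bad)) {
    stop("unknown label(s) in manifest: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(man)), function(i) {
    image <- read_gray_image(file.path(image_dir, man$image_file[i]))
    mask <- read_roi(file.path(image_dir, man$roi_file[i]), dim(image))
    case_record(man$case_id[i], man$patient_id[i], image, mask, man$label[i])
  })
}

#' Construct a labelled case record
#'
#' @param case_id,patient_id Identifier strings.
#' @param image Integer gray-level matrix.
#' @param mask Logical lesion mask of the same dimensions.
#' @param label `"tendinopathy"` or `"tear"`.
#' @return A list with class `"case_record"`.
#' @export
case_record <- function(case_id, patient_id, image, mask, label) {
  label <- match.arg(label, c("tendinopathy", "tear"))
  if (!identical(dim(image), dim(mask))) {
    stop("image/mask dimension mismatch for case ", case_id, call. = FALSE)
  }
  if (!any(mask)) stop("empty lesion mask for case ", case_id, call. = FALSE)
  structure(
    list(case_id = as.character(case_id),
         patient_id = as.character(patient_id),
         image = image, mask = mask, label = label),
    class = "case_record"
  )
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case %s | patient %s | %s | %dx%d px | lesion %d px>\n",
              x$case_id, x$patient_id, x$label,
              nrow(x$image), ncol(x$image), sum(x$mask)))
  invisible(x)
}
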