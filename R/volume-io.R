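#' Read a volumetric stack (multipage TIFF or NRRD)
#'
#' Reads a gray-level or label stack into a [voxel_grid()]. NRRD files carry
#' their own spacing (and optionally origin); plain TIFF stacks do not, so a
#' `spacing_override` is required for them. The TIFF page index becomes the z
#' index (section axis).
#'
#' @param path file path; format chosen by extension (`.nrrd`/`.nhdr` or
#'   `.tif`/`.tiff`).
#' @param spacing_override optional length-3 nm spacing used when the file
#'   carries none (always the case for TIFF). When both are present the file
#'   metadata wins.
#' @return A [voxel_grid()].
#' @seealso [write_volume()], [extract_labels()], [threshold_segment()]
#' @export
read_volume <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("nrrd", "nhdr")) {
    g <- read_nrrd(path)
    if (is.null(g$spacing)) {
      if (is.null(spacing_override))
        stop("no spacing: NRRD header carries none and no spacing_override given")
      g$spacing <- as.numeric(spacing_override)
    }
    voxel_grid(g$values, g$spacing, g$origin %||% c(0, 0, 0))
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1L]  # first channel of RGB(A)
      t(p)  # readTIFF returns [row=y, col=x]; we index [x, y]
    })
    if (is.null(spacing_override))
      stop("no spacing: TIFF carries no voxel spacing; pass spacing_override")
    vals <- array(0, c(dim(pages[[1L]]), length(pages)))
    for (k in seq_along(pages)) vals[, , k] <- pages[[k]]
    voxel_grid(vals, as.numeric(spacing_override))
  } else {
    stop("unsupported volume format: .", ext, " (use NRRD or TIFF)")
  }
}

#' Write a volumetric stack
#'
#' Writes a [voxel_grid()] or [binary_mask()] to NRRD (preferred: spacing and
#' origin travel with the file) or multipage TIFF (16-bit; requires integer
#' values in 0..65535, spacing is lost).
#'
#' @param grid a [voxel_grid()] or [binary_mask()].
#' @param path destination; extension selects the format.
#' @param encoding for NRRD: `"raw"` (little-endian binary, default) or
#'   `"text"` (portable ASCII).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, encoding = c("raw", "text")) {
  encoding <- match.arg(encoding)
  if (inherits(grid, "binary_mask"))
    grid <- voxel_grid(array(as.integer(grid$voxels), dim(grid$voxels)),
                       grid$spacing, grid$origin)
  if (!inherits(grid, "voxel_grid")) stop("'grid' must be a voxel_grid")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("nrrd", "nhdr")) {
    write_nrrd(grid, path, encoding)
  } else if (ext %in% c("tif", "tiff")) {
    v <- grid$values
    if (any(v != round(v)) || min(v) < 0 || max(v) > 65535)
      stop("TIFF export needs integer values in 0..65535; use NRRD instead")
    pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    stop("unsupported volume format: .", ext)
  }
  invisible(path)
}

# -- minimal NRRD0004 reader/writer ------------------------------------------
# Fields understood: sizes, type, encoding (raw | ascii/text/txt), endian,
# spacings, space directions (axis-aligned), axis mins, space origin.

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    hdr <- c(hdr, line)
  }
  hdr <- hdr[!grepl("^#", hdr)]
  kv <- strsplit(hdr, ":\\s*")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = ": "), "")
  getf <- function(k) if (k %in% keys) vals[match(k, keys)] else NULL

  sizes <- as.integer(strsplit(trimws(getf("sizes")), "\\s+")[[1L]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported")
  type <- trimws(getf("type") %||% "double")
  enc <- tolower(trimws(getf("encoding") %||% "raw"))
  endian <- tolower(trimws(getf("endian") %||% "little"))

  spacing <- NULL
  if (!is.null(getf("spacings"))) {
    spacing <- as.numeric(strsplit(trimws(getf("spacings")), "\\s+")[[1L]])
  } else if (!is.null(getf("space directions"))) {
    dirs <- regmatches(getf("space directions"),
                       gregexpr("\\(([^)]*)\\)", getf("space directions")))[[1L]]
    m <- t(vapply(dirs, function(d)
      as.numeric(strsplit(gsub("[()]", "", d), ",")[[1L]]), numeric(3)))
    spacing <- sqrt(rowSums(m^2))
  }
  origin <- NULL
  if (!is.null(getf("axis mins"))) {
    origin <- as.numeric(strsplit(trimws(getf("axis mins")), "\\s+")[[1L]])
  } else if (!is.null(getf("space origin"))) {
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       trimws(getf("space origin"))), ",")[[1L]])
  }

  n <- prod(sizes)
  rtype <- switch(type,
    "signed char" = , "int8" = , "int8_t" = list(what = "integer", size = 1L),
    "uchar" = , "unsigned char" = , "uint8" = , "uint8_t" =
      list(what = "integer", size = 1L, signed = FALSE),
    "short" = , "int16" = , "signed short" = list(what = "integer", size = 2L),
    "ushort" = , "unsigned short" = , "uint16" =
      list(what = "integer", size = 2L, signed = FALSE),
    "int" = , "int32" = , "signed int" = list(what = "integer", size = 4L),
    "float" = list(what = "numeric", size = 4L),
    "double" = list(what = "numeric", size = 8L),
    stop("unsupported NRRD type: ", type))
  if (enc == "raw") {
    data <- readBin(con, rtype$what, n = n, size = rtype$size,
                    signed = rtype$signed %||% TRUE,
                    endian = if (endian == "big") "big" else "little")
  } else if (enc %in% c("ascii", "text", "txt")) {
    data <- scan(con, what = double(), n = n, quiet = TRUE)
  } else {
    stop("unsupported NRRD encoding: ", enc)
  }
  if (length(data) != n) stop("NRRD data truncated: got ", length(data),
                              " of ", n, " values")
  list(values = array(as.numeric(data), sizes), spacing = spacing,
       origin = origin)
}

write_nrrd <- function(grid, path, encoding = "raw") {
  v <- grid$values
  integral <- all(v == round(v)) && max(abs(v)) < 2^31
  type <- if (integral) "int32" else "double"
  hdr <- c(
    "NRRD0004",
    "# generated by sasmorph",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(v), collapse = " ")),
    paste0("encoding: ", if (encoding == "raw") "raw" else "text"),
    "endian: little",
    paste0("spacings: ", paste(format(grid$spacing, digits = 15), collapse = " ")),
    paste0("axis mins: ", paste(format(grid$origin, digits = 15), collapse = " ")),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (encoding == "raw") {
    if (integral) writeBin(as.integer(v), con, size = 4L, endian = "little")
    else writeBin(as.numeric(v), con, size = 8L, endian = "little")
  } else {
    writeLines(paste(format(as.numeric(v), digits = 17), collapse = " "), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a label volume into per-junction masks
#'
#' One [binary_mask()] per distinct nonzero label, each cropped to its
#' bounding box plus a 2-voxel background pad (so the distance transform sees
#' background on every side), with the origin adjusted so physical coordinates
#' are preserved.
#'
#' @param grid a [voxel_grid()] of non-negative integer labels (0 = background).
#' @return List of [binary_mask()] objects, ordered by label value; empty list
#'   for an all-zero grid.
#' @export
extract_labels <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  v <- grid$values
  if (any(v < 0) || any(v != round(v)))
    stop("label grid must contain non-negative integers")
  labs <- sort(unique(v[v > 0]))
  lapply(labs, function(l) crop_mask(v == l, grid, as.integer(l)))
}

# crop a logical array to its foreground bbox + pad, preserving physical coords
crop_mask <- function(logical_array, grid, label_id, pad = 2L) {
  idx <- which(logical_array, arr.ind = TRUE)
  d <- dim(logical_array)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  # guarantee the pad even at the array border by growing the target array
  lo_t <- apply(idx, 2, min) - pad
  hi_t <- apply(idx, 2, max) + pad
  out <- array(FALSE, hi_t - lo_t + 1L)
  out[(lo[1] - lo_t[1] + 1):(hi[1] - lo_t[1] + 1),
      (lo[2] - lo_t[2] + 1):(hi[2] - lo_t[2] + 1),
      (lo[3] - lo_t[3] + 1):(hi[3] - lo_t[3] + 1)] <-
    logical_array[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  binary_mask(out, grid$spacing,
              origin = grid$origin + (lo_t - 1) * grid$spacing,
              label_id = label_id)
}

#' Threshold segmentation of a gray stack
#'
#' Convenience segmentation in the spirit of threshold-based EM tools: an
#' optional Gaussian blur (to suppress noisy pixels), a gray-level threshold,
#' then 26-connected component labeling with a minimum-size filter. This is
#' deliberately minimal; production segmentations normally come from a
#' dedicated tool and enter through [read_volume()] + [extract_labels()].
#'
#' @param grid a gray-level [voxel_grid()].
#' @param gray_threshold voxels with value >= threshold become foreground.
#' @param blur_sigma optional physical blur sigma in nm (converted per axis to
#'   voxel units); `NULL` for no blur.
#' @param min_size drop components with fewer voxels than this (default 50).
#' @return List of [binary_mask()] (possibly empty). A threshold outside the
#'   grid's value range yields an empty list with a warning.
#' @export
threshold_segment <- function(grid, gray_threshold, blur_sigma = NULL,
                              min_size = 50L) {
  stopifnot(inherits(grid, "voxel_grid"))
  v <- grid$values
  if (gray_threshold > max(v)) {
    warning("threshold ", gray_threshold, " above the stack maximum ",
            max(v), "; nothing segmented")
    return(list())
  }
  if (!is.null(blur_sigma) && blur_sigma > 0) {
    sm <- cpp_gauss_blur3(as.numeric(v), dim(v), blur_sigma / grid$spacing)
    v <- array(sm, dim(v))
  }
  fg <- v >= gray_threshold
  if (!any(fg)) return(list())
  lab <- array(cpp_label26(as.logical(fg), dim(fg)), dim(fg))
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts >= min_size)
  lapply(seq_along(keep), function(i)
    crop_mask(lab == keep[i], grid, label_id = i))
}
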