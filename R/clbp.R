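# Completed Local Binary Pattern (CLBP) texture descriptors.
#
# The descriptor decomposes each local neighbourhood into three complementary
# components: the sign and the magnitude of the radial differences
# d_p = g_p - g_c between a centre pixel and its P circular neighbours, and a
# binary code for the centre intensity itself. Sign and magnitude patterns
# are reduced with the rotation-invariant uniform ("riu2") mapping and the
# three components are combined in one joint histogram, which makes the
# descriptor insensitive to image orientation and to affine changes of
# illumination -- both hard to control in scanning electron microscopy.

#' CLBP configuration
#'
#' @param P number of circular neighbours (>= 4). The default 24 together
#'   with `R = 3` gives the 1,352-dimensional joint descriptor
#'   `(P + 2)^2 * 2`.
#' @param R neighbourhood radius in pixels (> 0).
#' @param interpolation `"bilinear"` (default, robust under arbitrary
#'   rotation) or `"nearest"` (exact under 90-degree rotations; used by the
#'   rotation tests).
#' @return an object of class `clbp_config`.
#' @export
#' @examples
#' feature_length(clbp_config()) # 1352
clbp_config <- function(P = 24L, R = 3, interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  assert_that(length(P) == 1 && is.finite(P) && P >= 4 && P == round(P),
              "P must be a single integer >= 4")
  assert_that(length(R) == 1 && is.finite(R) && R > 0, "R must be > 0")
  structure(list(P = as.integer(P), R = as.numeric(R),
                 interpolation = interpolation),
            class = "clbp_config")
}

#' Length of the CLBP feature vector
#'
#' The joint histogram over (sign bin, magnitude bin, centre bit) has
#' `(P + 2) * (P + 2) * 2` cells: `P + 2` riu2 bins for each of the sign and
#' magnitude components and 2 centre states.
#'
#' @param config a [clbp_config()].
#' @return integer feature length.
#' @export
feature_length <- function(config = clbp_config()) {
  stopifnot(inherits(config, "clbp_config"))
  as.integer((config$P + 2L)^2 * 2L)
}

#' Validate a grayscale image matrix
#'
#' @param pixels numeric matrix of intensities in `[0, 1]` (values outside
#'   are allowed for the purpose of illumination-invariance checks; they must
#'   simply be finite).
#' @return the matrix, invisibly classed as `gray_image`.
#' @export
as_gray_image <- function(pixels) {
  assert_that(is.matrix(pixels) && is.numeric(pixels),
              "image must be a numeric matrix")
  assert_that(all(is.finite(pixels)), "image contains non-finite pixels")
  structure(pixels, class = c("gray_image", "matrix", "array"))
}

#' Read an image file as a grayscale matrix
#'
#' PNG and TIFF, 8- or 16-bit, single- or 3-channel. Colour images are
#' converted by the ITU-R 601 luminance weights (0.299, 0.587, 0.114), fixed
#' for reproducibility.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return a `gray_image` matrix with intensities in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) {
    ct_stop(sprintf("cannot read image file '%s'", path), "coraltex_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch({
    if (ext == "png") {
      png::readPNG(path)
    } else if (ext %in% c("tif", "tiff")) {
      tiff::readTIFF(path)
    } else {
      ct_stop(sprintf("unsupported image format '%s' for '%s'", ext, path),
              "coraltex_io_error")
    }
  }, error = function(e) {
    if (inherits(e, "coraltex_error")) stop(e)
    ct_stop(sprintf("cannot read image file '%s': %s", path,
                    conditionMessage(e)), "coraltex_io_error")
  })
  as_gray_image(luminance(arr))
}

# ITU-R 601 grayscale conversion; drops an alpha channel if present.
luminance <- function(arr) {
  if (length(dim(arr)) == 2) return(arr)
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    if (nc == 1) return(arr[, , 1])
    if (nc >= 3) {
      return(0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3])
    }
    if (nc == 2) return(arr[, , 1]) # gray + alpha
  }
  ct_stop("unsupported image array shape", "coraltex_validation_error")
}

# Sample the P circular neighbours of every valid pixel. Returns a list of
# difference matrices d_p = g_p - g_c, one per neighbour, over the valid
# (border-excluded) region.
circular_differences <- function(pixels, config) {
  P <- config$P; R <- config$R
  b <- as.integer(ceiling(R))
  h <- nrow(pixels); w <- ncol(pixels)
  if (h < 2 * R + 1 || w < 2 * R + 1) {
    ct_stop(sprintf("image %dx%d smaller than 2R+1 = %g for radius R = %g",
                    h, w, 2 * R + 1, R), "coraltex_size_error")
  }
  assert_that(all(is.finite(pixels)), "image contains non-finite pixels")
  rows <- (b + 1L):(h - b); cols <- (b + 1L):(w - b)
  centre <- pixels[rows, cols, drop = FALSE]
  diffs <- vector("list", P)
  for (p in seq_len(P) - 1L) {
    th <- 2 * pi * p / P
    offr <- -R * sin(th)
    offc <- R * cos(th)
    if (config$interpolation == "nearest") {
      nb <- pixels[rows + round(offr), cols + round(offc), drop = FALSE]
    } else {
      fr <- floor(offr); dr <- offr - fr
      fc <- floor(offc); dc <- offc - fc
      # snap near-integer offsets so zero-weight corners never index
      # outside the border margin
      if (dr > 1 - 1e-9) { fr <- fr + 1; dr <- 0 }
      if (dc > 1 - 1e-9) { fc <- fc + 1; dc <- 0 }
      if (dr < 1e-9) dr <- 0
      if (dc < 1e-9) dc <- 0
      frr <- fr + (dr > 0); fcc <- fc + (dc > 0)
      nb <- (1 - dr) * (1 - dc) * pixels[rows + fr,  cols + fc,  drop = FALSE]
      if (dc > 0) nb <- nb + (1 - dr) * dc *
          pixels[rows + fr,  cols + fcc, drop = FALSE]
      if (dr > 0) nb <- nb + dr * (1 - dc) *
          pixels[rows + frr, cols + fc,  drop = FALSE]
      if (dr > 0 && dc > 0) nb <- nb + dr * dc *
          pixels[rows + frr, cols + fcc, drop = FALSE]
    }
    diffs[[p + 1L]] <- nb - centre
  }
  list(diffs = diffs, rows = rows, cols = cols, centre = centre, border = b)
}

# riu2-reduce a list of P binary matrices without materialising 2^P codes.
bits_to_riu2 <- function(bits) {
  P <- length(bits)
  s <- Reduce(`+`, bits)
  trans <- abs(bits[[1L]] - bits[[P]])
  for (p in 2:P) trans <- trans + abs(bits[[p]] - bits[[p - 1L]])
  out <- s
  out[trans > 2] <- P + 1L
  out
}

#' Rotation-invariant uniform (riu2) mapping of a binary pattern
#'
#' A pattern is "uniform" when its circular sequence of bits has at most two
#' 0/1 transitions; uniform patterns map to their bit sum (0..P), all others
#' to the single non-uniform bin `P + 1`.
#'
#' @param pattern a vector of exactly P bits (0/1 or logical).
#' @return integer bin index in `[0, P + 1]`.
#' @export
#' @examples
#' riu2_map(c(0, 0, 0, 0, 1, 1, 1, 1)) # 4
#' riu2_map(rep(c(0, 1), 4))           # 9, non-uniform
riu2_map <- function(pattern) {
  assert_that(length(pattern) >= 4 && all(pattern %in% c(0, 1)),
              "pattern must be a vector of >= 4 bits")
  b <- as.integer(pattern)
  P <- length(b)
  u <- abs(b[P] - b[1L]) + sum(abs(diff(b)))
  if (u <= 2) sum(b) else P + 1L
}

#' Decompose an image into CLBP sign/magnitude/centre codes
#'
#' For every pixel at least `ceiling(R)` from the border the P circular
#' neighbours are sampled and the differences `d_p = g_p - g_c` decomposed
#' into a sign bit `[d_p >= 0]` and a magnitude bit `[|d_p| >= c]`, where the
#' threshold `c` is the mean of `|d_p|` over all valid pixels and neighbours.
#' The centre bit is `[g_c >= c_I]` with `c_I` the mean intensity over valid
#' pixels. Ties use the `>=` convention throughout. Both P-bit patterns are
#' then reduced with the riu2 mapping.
#'
#' @param image a `gray_image` or plain numeric matrix.
#' @param config a [clbp_config()].
#' @return an object of class `clbp_codes` with riu2 bin matrices
#'   (`sign_bin`, `magnitude_bin`), the `center_bit` matrix, packed P-bit
#'   codes (`sign_code`, `magnitude_code`, values `sum b_p 2^p`), the
#'   thresholds `c` and `c_I`, the valid-pixel mask and the config.
#' @export
clbp_decompose <- function(image, config = clbp_config()) {
  if (!inherits(image, "gray_image")) image <- as_gray_image(image)
  P <- config$P
  cd <- circular_differences(image, config)
  absd <- lapply(cd$diffs, abs)
  c_thr <- mean(vapply(absd, mean, numeric(1)))
  sign_bits <- lapply(cd$diffs, function(d) (d >= 0) + 0L)
  mag_bits <- lapply(absd, function(a) (a >= c_thr) + 0L)
  pow <- 2^(seq_len(P) - 1L)
  pack <- function(bits) Reduce(`+`, Map(`*`, bits, pow))
  c_int <- mean(cd$centre)
  mask <- matrix(FALSE, nrow(image), ncol(image))
  mask[cd$rows, cd$cols] <- TRUE
  structure(list(
    sign_bin = bits_to_riu2(sign_bits),
    magnitude_bin = bits_to_riu2(mag_bits),
    center_bit = (cd$centre >= c_int) + 0L,
    sign_code = pack(sign_bits),
    magnitude_code = pack(mag_bits),
    c = c_thr, c_I = c_int,
    valid_mask = mask,
    config = config
  ), class = "clbp_codes")
}

#' Joint CLBP histogram
#'
#' Bins every valid pixel by (sign bin, magnitude bin, centre bit) into a
#' 3-D histogram of shape `(P + 2, P + 2, 2)`, flattened row-major (centre
#' fastest, sign slowest) and L1-normalised over the valid pixels.
#'
#' @param codes a `clbp_codes` object from [clbp_decompose()].
#' @param metadata optional named list (sample id, colony id, species, scale)
#'   carried through to the feature.
#' @return an object of class `texture_feature`: `histogram` (probability
#'   vector of length `(P + 2)^2 * 2`), `config`, `metadata`.
#' @export
joint_histogram <- function(codes, metadata = list()) {
  stopifnot(inherits(codes, "clbp_codes"))
  P <- codes$config$P
  n <- length(codes$sign_bin)
  if (n == 0) ct_stop("no valid pixels to histogram", "coraltex_degenerate_image_error")
  idx <- (as.vector(codes$sign_bin) * (P + 2L) + as.vector(codes$magnitude_bin)) * 2L +
    as.vector(codes$center_bit) + 1L
  h <- tabulate(idx, nbins = (P + 2L)^2 * 2L) / n
  structure(list(histogram = h, config = codes$config, metadata = metadata),
            class = "texture_feature")
}

#' Compute the CLBP feature of one image
#'
#' Convenience wrapper: [clbp_decompose()] followed by [joint_histogram()].
#'
#' @inheritParams clbp_decompose
#' @inheritParams joint_histogram
#' @return a `texture_feature`.
#' @export
clbp_features <- function(image, config = clbp_config(), metadata = list()) {
  joint_histogram(clbp_decompose(image, config), metadata = metadata)
}

#' Extract CLBP features for a manifest of images
#'
#' @param manifest data frame with columns `sample_id`, `colony_id`,
#'   `species`, `scale` and either `path` (image files, resolved against
#'   `dir`) or nothing if `images` is given.
#' @param config a [clbp_config()].
#' @param dir optional directory that relative `path`s are resolved against.
#' @param images optional named list of in-memory `gray_image` matrices keyed
#'   by `sample_id`, bypassing file I/O (the synthetic generator returns
#'   datasets in this form).
#' @return list of `texture_feature`, one per manifest row, in manifest
#'   order.
#' @export
extract_features <- function(manifest, config = clbp_config(), dir = NULL,
                             images = NULL) {
  need <- c("sample_id", "colony_id", "species", "scale")
  assert_that(is.data.frame(manifest) && all(need %in% names(manifest)),
              "manifest must have columns sample_id, colony_id, species, scale")
  if (nrow(manifest) == 0) return(list())
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    img <- if (!is.null(images)) {
      im <- images[[as.character(row$sample_id)]]
      assert_that(!is.null(im),
                  sprintf("manifest sample '%s' missing from images list",
                          row$sample_id))
      im
    } else {
      assert_that("path" %in% names(manifest),
                  "manifest needs a 'path' column when no images are supplied")
      p <- as.character(row$path)
      if (!is.null(dir)) p <- file.path(dir, p)
      read_gray_image(p)
    }
    clbp_features(img, config,
                  metadata = list(sample_id = as.character(row$sample_id),
                                  colony_id = as.character(row$colony_id),
                                  species = as.character(row$species),
                                  scale = as.character(row$scale)))
  })
}

#' Stack texture features into a matrix plus metadata table
#'
#' @param features list of `texture_feature`.
#' @return list with `x` (numeric matrix, one row per feature, columns
#'   `h_0000`...) and `meta` (data frame of the metadata fields).
#' @export
features_to_matrix <- function(features) {
  assert_that(length(features) > 0, "no features supplied")
  len <- length(features[[1]]$histogram)
  x <- t(vapply(features, function(f) f$histogram, numeric(len)))
  colnames(x) <- sprintf("h_%04d", seq_len(len) - 1L)
  meta <- do.call(rbind, lapply(features, function(f) {
    m <- f$metadata
    data.frame(sample_id = m$sample_id %||% NA_character_,
               colony_id = m$colony_id %||% NA_character_,
               species = m$species %||% NA_character_,
               scale = m$scale %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  list(x = x, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a feature table as CSV
#'
#' One row per image: the metadata columns, then `h_0000 ...`. The header
#' comment line records P and R so a reader can validate the configuration.
#'
#' @param features list of `texture_feature`.
#' @param path output CSV path.
#' @export
write_features_csv <- function(features, path) {
  fm <- features_to_matrix(features)
  cfg <- features[[1]]$config
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# CLBP P=%d R=%g", cfg$P, cfg$R), con)
  utils::write.csv(cbind(fm$meta, as.data.frame(fm$x)), con, row.names = FALSE)
}

#' @rdname write_features_csv
#' @param path CSV path written by [write_features_csv()].
#' @return list with `x`, `meta` and `config` as in [features_to_matrix()].
#' @export
read_features_csv <- function(path) {
  header <- readLines(path, n = 1)
  cfg <- NULL
  if (grepl("^# CLBP", header)) {
    P <- as.integer(sub(".*P=(\\d+).*", "\\1", header))
    R <- as.numeric(sub(".*R=([0-9.]+).*", "\\1", header))
    cfg <- clbp_config(P = P, R = R)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  hcols <- grep("^h_", names(df))
  list(x = as.matrix(df[, hcols, drop = FALSE]),
       meta = df[, setdiff(seq_along(df), hcols), drop = FALSE],
       config = cfg)
}
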