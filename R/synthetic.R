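# Synthetic pseudo-corallite data.
#
# The texture generator renders Voronoi tessellations whose parameters map
# interpretably onto skeletal anatomy: cell density stands for corallite
# density (inverse corallite diameter), radial ridges per cell for septa,
# darker cell boundaries for the theca, and a bright central bump for the
# columella. Colonies are the unit of biological replication: each colony
# draws its own parameter perturbation once, and all of its images (3 per
# magnification scale, 2 scales) share it. Per-image illumination is a
# random global gain/offset, which the CLBP descriptor should cancel
# exactly. A colony-coherent label-noise operator emulates tentative field
# identifications.

#' Texture class parameters
#'
#' @param cell_density expected corallites per 10^4 pixels at colony scale
#'   (> 0); corallite-scale images render ~1/16 of this density so a single
#'   cell fills most of the frame.
#' @param ridges_per_cell mean radial ridge (septa) count per cell.
#' @param wall_thickness theca wall thickness in pixels.
#' @param noise_sd additive Gaussian pixel noise SD.
#' @param illumination_amplitude per-image global gain/offset amplitude: the
#'   rendered image is transformed `gain * I + offset` with
#'   `gain = 1 + a u`, `offset = a v`, `u, v ~ U(-1, 1)`.
#' @param within_colony_jitter SD of the per-cell ridge-count jitter.
#' @param between_colony_sd SD of the colony-level log-normal perturbation
#'   applied to density and ridge count.
#' @return a `texture_class_params` list.
#' @export
texture_class_params <- function(cell_density = 8, ridges_per_cell = 36,
                                 wall_thickness = 2.5, noise_sd = 0.04,
                                 illumination_amplitude = 0.2,
                                 within_colony_jitter = 1.5,
                                 between_colony_sd = 0.05) {
  p <- list(cell_density = cell_density, ridges_per_cell = ridges_per_cell,
            wall_thickness = wall_thickness, noise_sd = noise_sd,
            illumination_amplitude = illumination_amplitude,
            within_colony_jitter = within_colony_jitter,
            between_colony_sd = between_colony_sd)
  assert_that(all(unlist(p) >= 0) && cell_density > 0,
              "texture parameters must be >= 0, density > 0")
  structure(p, class = "texture_class_params")
}

#' Default three-class texture parameter sets
#'
#' Three species-like classes separated mainly by corallite density and
#' septa count, with colony-level variability narrower than the class gaps
#' (distinct textures), standing in for the small/medium/large-corallite
#' species of a confusing congeneric complex.
#'
#' @return named list of [texture_class_params()].
#' @export
default_texture_classes <- function() {
  list(
    spA = texture_class_params(cell_density = 16, ridges_per_cell = 24,
                               wall_thickness = 3.6, noise_sd = 0.015,
                               between_colony_sd = 0.02),
    spB = texture_class_params(cell_density = 4, ridges_per_cell = 48,
                               wall_thickness = 1.4, noise_sd = 0.015,
                               between_colony_sd = 0.02),
    spC = texture_class_params(cell_density = 8.5, ridges_per_cell = 36,
                               wall_thickness = 2.5, noise_sd = 0.015,
                               between_colony_sd = 0.02)
  )
}

#' Render one pseudo-corallite texture image
#'
#' Voronoi tessellation at the given cell density; per-cell radial ridges
#' (count jittered per cell) darkened theca walls where the first and second
#' nearest-centre distances nearly tie, a bright columella bump at each cell
#' centre, additive Gaussian noise, and finally a random global gain/offset
#' "illumination" transform. Deterministic given the seed.
#'
#' @param params a [texture_class_params()] (colony-level values; apply any
#'   colony perturbation before calling).
#' @param seed per-image RNG seed.
#' @param scale `"colony"` (many corallites) or `"corallite"` (~1 cell).
#' @param size image side length in pixels (default 256).
#' @return a `gray_image` matrix. Intensities are not clipped, so the
#'   illumination transform remains exactly affine.
#' @export
generate_colony_texture <- function(params, seed = 1L,
                                    scale = c("colony", "corallite"),
                                    size = 256L) {
  scale <- match.arg(scale)
  stopifnot(inherits(params, "texture_class_params"))
  # corallite scale is a 3x linear magnification: 1/9 the cell density and
  # all anatomical lengths (walls, columella, ridge profile) 3x larger in
  # px, so a frame still shows the theca walls of neighbouring corallites
  mag <- if (scale == "corallite") 3 else 1
  dens <- params$cell_density / mag^2
  ncell <- max(1L, round(dens * size^2 / 1e4))
  assert_that(size >= 16, "image size too small for one cell")
  with_seed(seed, {
    cx <- stats::runif(ncell, 0, size)
    cy <- stats::runif(ncell, 0, size)
    kc <- pmax(3, round(stats::rnorm(ncell, params$ridges_per_cell,
                                     params$within_colony_jitter)))
    phase <- stats::runif(ncell, 0, 2 * pi)
    px <- rep(seq_len(size) - 0.5, times = size)  # row coordinate
    py <- rep(seq_len(size) - 0.5, each = size)   # column coordinate
    d1 <- rep(Inf, size^2); d2 <- rep(Inf, size^2); i1 <- rep(1L, size^2)
    for (k in seq_len(ncell)) {
      d <- (px - cx[k])^2 + (py - cy[k])^2
      d2 <- pmin(d2, pmax(d, d1))
      nb <- d < d1
      i1[nb] <- k
      d1 <- pmin(d1, d)
    }
    r1 <- sqrt(d1)
    ang <- atan2(py - cy[i1], px - cx[i1])
    img <- 0.55 +
      0.18 * cos(kc[i1] * (ang - phase[i1])) * (r1 / (r1 + 2 * mag)) -
      0.32 * pmax(0, 1 - (sqrt(d2) - r1) /
                    max(params$wall_thickness * mag, 1e-6)) +
      0.22 * exp(-(r1 / (2.5 * mag))^2) +
      stats::rnorm(size^2, 0, params$noise_sd)
    a <- params$illumination_amplitude
    gain <- 1 + a * stats::runif(1, -1, 1)
    offset <- a * stats::runif(1, -1, 1)
    as_gray_image(matrix(gain * img + offset, size, size))
  })
}

#' Synthetic texture dataset specification
#'
#' @param classes named list of [texture_class_params()] (>= 2 classes).
#' @param colonies_per_class colonies per class (default 20).
#' @param images_per_colony_per_scale images per colony at each of the two
#'   magnification scales (default 3, i.e. 6 images per colony).
#' @param size image side in pixels (default 256).
#' @param label_noise_rate colony-level label flip probability in `[0, 0.5)`.
#' @param confusable optional named map class -> confusable class; default
#'   maps each class to the next one cyclically.
#' @param seed master seed.
#' @return a `synthetic_dataset_spec` list.
#' @export
synthetic_dataset_spec <- function(classes = default_texture_classes(),
                                   colonies_per_class = 20L,
                                   images_per_colony_per_scale = 3L,
                                   size = 256L, label_noise_rate = 0,
                                   confusable = NULL, seed = 1L) {
  assert_that(length(classes) >= 2 && !is.null(names(classes)),
              "need >= 2 named classes")
  assert_that(label_noise_rate >= 0 && label_noise_rate < 0.5,
              "label_noise_rate must lie in [0, 0.5)")
  if (is.null(confusable)) {
    cls <- names(classes)
    confusable <- stats::setNames(cls[c(seq_along(cls)[-1], 1)], cls)
  }
  structure(list(classes = classes,
                 colonies_per_class = as.integer(colonies_per_class),
                 images_per_colony_per_scale = as.integer(images_per_colony_per_scale),
                 size = as.integer(size),
                 label_noise_rate = label_noise_rate,
                 confusable = confusable, seed = as.integer(seed)),
            class = "synthetic_dataset_spec")
}

#' Colony-coherent label noise
#'
#' Each colony's label flips to its designated confusable class with
#' probability `rho`; all images of a colony flip together (noise operates
#' on the colony vector, which the caller propagates to images).
#'
#' @param labels character vector of one label per colony.
#' @param rho flip probability in `[0, 0.5)`.
#' @param confusable named map class -> confusable class covering every
#'   label.
#' @param seed RNG seed.
#' @return character vector of noisy labels.
#' @export
apply_label_noise <- function(labels, rho, confusable, seed = 1L) {
  assert_that(rho >= 0 && rho < 0.5, "rho must lie in [0, 0.5)")
  labels <- as.character(labels)
  assert_that(all(labels %in% names(confusable)),
              "confusable map must cover every class")
  if (rho == 0) return(labels)
  with_seed(seed, {
    flip <- stats::runif(length(labels)) < rho
    labels[flip] <- unname(confusable[labels[flip]])
    labels
  })
}

#' Generate a synthetic texture dataset
#'
#' Draws colony-level parameter perturbations from the class parameters,
#' renders `2 * images_per_colony_per_scale` images per colony (both
#' magnification scales), applies colony-coherent label noise, and returns
#' the images in memory together with a manifest and a colony parameter log.
#'
#' @param spec a [synthetic_dataset_spec()].
#' @param dir optional directory: when given, images are also written as
#'   8-bit PNGs (intensities clipped to `[0, 1]`) and the manifest gains a
#'   `path` column.
#' @return list with `images` (named list of `gray_image` keyed by sample
#'   id), `manifest` (data frame: `sample_id`, `colony_id`, `species` =
#'   post-noise label, `true_species`, `scale`, optionally `path`) and
#'   `params_log` (one row per colony).
#' @export
generate_texture_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_dataset_spec"))
  cls <- names(spec$classes)
  colonies <- expand.grid(colony = seq_len(spec$colonies_per_class),
                          species = cls, stringsAsFactors = FALSE)
  colonies$colony_id <- sprintf("%s_c%02d", colonies$species, colonies$colony)
  # colony-level multiplicative perturbations
  pert <- lapply(seq_len(nrow(colonies)), function(i) {
    p <- spec$classes[[colonies$species[i]]]
    with_seed(seed_stream(spec$seed, 1L, i), {
      z <- stats::rnorm(2, 0, p$between_colony_sd)
      p$cell_density <- p$cell_density * exp(z[1])
      p$ridges_per_cell <- p$ridges_per_cell * exp(z[2])
      p
    })
  })
  noisy <- apply_label_noise(colonies$species, spec$label_noise_rate,
                             spec$confusable,
                             seed = seed_stream(spec$seed, 2L))
  scales <- c("colony", "corallite")
  rows <- list(); images <- list()
  for (i in seq_len(nrow(colonies))) {
    for (s in seq_along(scales)) {
      for (rep_i in seq_len(spec$images_per_colony_per_scale)) {
        sid <- sprintf("%s_%s%d", colonies$colony_id[i],
                       substr(scales[s], 1, 3), rep_i)
        images[[sid]] <- generate_colony_texture(
          pert[[i]], seed = seed_stream(spec$seed, 3L, i, s, rep_i),
          scale = scales[s], size = spec$size)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, colony_id = colonies$colony_id[i],
          species = noisy[i], true_species = colonies$species[i],
          scale = scales[s], stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  params_log <- cbind(colonies[, c("colony_id", "species")],
                      do.call(rbind, lapply(pert, function(p)
                        as.data.frame(unclass(p)))))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    manifest$path <- paste0(manifest$sample_id, ".png")
    for (i in seq_len(nrow(manifest))) {
      img <- pmin(pmax(images[[manifest$sample_id[i]]], 0), 1)
      png::writePNG(img, file.path(dir, manifest$path[i]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(params_log, file.path(dir, "params_log.csv"),
                     row.names = FALSE)
  }
  list(images = images, manifest = manifest, params_log = params_log)
}

# ---- morphometric tables ----------------------------------------------------

#' Morphometric class parameters
#'
#' @param means named numeric vector of class means for the five measured
#'   characters `corallite_diameter`, `columella_diameter`,
#'   `mean_septal_thickness`, `mean_septal_length`, `n_septa` (mm / counts).
#' @param sds residual SDs for the same characters.
#' @param binary_probs named Bernoulli probabilities for the binary
#'   characters (`cycle4_present` ... `septal_continuity`; completeness
#'   probabilities are conditional on presence).
#' @param colony_sd SD of the additive colony-level random effect, expressed
#'   as a fraction of each character's mean.
#' @param columella_points integer range (length 2) of corallite centres
#'   digitised per colony.
#' @return a `morpho_class_params` list.
#' @export
morpho_class_params <- function(means, sds, binary_probs, colony_sd = 0.08,
                                columella_points = c(6L, 28L)) {
  cont <- c("corallite_diameter", "columella_diameter",
            "mean_septal_thickness", "mean_septal_length", "n_septa")
  bin <- c("cycle4_present", "cycle4_complete", "cycle5_present",
           "cycle5_complete", "cycle6_present", "cycle6_complete",
           "intratentacular_budding", "septal_continuity")
  assert_that(all(cont %in% names(means)) && all(cont %in% names(sds)),
              "means/sds must name all five continuous characters")
  assert_that(all(bin %in% names(binary_probs)),
              "binary_probs must name all eight binary characters")
  assert_that(all(sds >= 0) && all(binary_probs >= 0 & binary_probs <= 1),
              "sds >= 0 and probabilities in [0, 1] required")
  structure(list(means = means[cont], sds = sds[cont],
                 binary_probs = binary_probs[bin], colony_sd = colony_sd,
                 columella_points = as.integer(columella_points)),
            class = "morpho_class_params")
}

#' Default three-class morphometric parameters with heavy overlap
#'
#' Continuous characters overlap strongly across the classes (class mean
#' gaps well under one within-class SD plus colony effect), emulating the
#' published ranges of the confusable congeners; one binary character
#' (intratentacular budding) is moderately diagnostic of the third class.
#'
#' @return named list of [morpho_class_params()] for classes spA/spB/spC.
#' @export
default_morpho_classes <- function() {
  base_bin <- c(cycle4_present = 0.5, cycle4_complete = 0.3,
                cycle5_present = 0.2, cycle5_complete = 0.1,
                cycle6_present = 0.05, cycle6_complete = 0.02,
                intratentacular_budding = 0.1, septal_continuity = 0.5)
  mk <- function(cd, nsep, bud, c4p) {
    bp <- base_bin
    bp["intratentacular_budding"] <- bud
    bp["cycle4_present"] <- c4p
    morpho_class_params(
      means = c(corallite_diameter = cd, columella_diameter = 0.35 * cd,
                mean_septal_thickness = 0.10, mean_septal_length = 0.42 * cd,
                n_septa = nsep),
      sds = c(corallite_diameter = 0.55, columella_diameter = 0.22,
              mean_septal_thickness = 0.035, mean_septal_length = 0.3,
              n_septa = 7),
      binary_probs = bp)
  }
  list(spA = mk(3.2, 33, 0.10, 0.40),
       spB = mk(3.9, 41, 0.12, 0.60),
       spC = mk(3.5, 37, 0.65, 0.45))
}

#' Generate a synthetic morphometric table
#'
#' One record per colony. Continuous values are class mean + colony random
#' effect + residual (truncated at a small positive floor); binary values
#' are Bernoulli with completeness bits coerced consistent with presence.
#' Min/max inter-columella distances are derived by generating a jittered
#' grid of columella centres per colony (spacing set by that colony's
#' corallite diameter) and passing it through
#' [columella_distance_range()].
#'
#' @param classes named list of [morpho_class_params()].
#' @param colonies_per_class colonies per class.
#' @param seed master seed.
#' @return data frame of `colony_id`, `species` and the
#'   [morpho_characters] columns.
#' @export
generate_morpho_table <- function(classes = default_morpho_classes(),
                                  colonies_per_class = 20L, seed = 1L) {
  assert_that(length(classes) >= 2 && !is.null(names(classes)),
              "need >= 2 named classes")
  rows <- list()
  ci <- 0L
  for (cl in names(classes)) {
    p <- classes[[cl]]
    for (k in seq_len(colonies_per_class)) {
      ci <- ci + 1L
      rec <- with_seed(seed_stream(seed, 20L, ci), {
        eff <- stats::rnorm(length(p$means), 0, p$colony_sd * abs(p$means))
        cont <- pmax(p$means + eff + stats::rnorm(length(p$means), 0, p$sds),
                     0.01)
        names(cont) <- names(p$means)
        cont["n_septa"] <- max(6, round(cont["n_septa"]))
        b <- stats::rbinom(length(p$binary_probs), 1, p$binary_probs)
        names(b) <- names(p$binary_probs)
        for (cyc in c("cycle4", "cycle5", "cycle6")) {
          if (b[paste0(cyc, "_present")] == 0) b[paste0(cyc, "_complete")] <- 0
        }
        npts <- sample(seq(p$columella_points[1], p$columella_points[2]), 1)
        sp <- cont["corallite_diameter"]
        side <- ceiling(sqrt(npts))
        g <- expand.grid(x = seq_len(side), y = seq_len(side))[seq_len(npts), ]
        pts <- data.frame(x = g$x * sp + stats::rnorm(npts, 0, 0.22 * sp),
                          y = g$y * sp + stats::rnorm(npts, 0, 0.22 * sp))
        rng <- tryCatch(columella_distance_range(pts),
                        coraltex_degenerate_geometry_error = function(e)
                          c(min = 0.8 * sp, max = 1.5 * sp))
        c(as.list(cont),
          as.list(b),
          list(min_columella_dist = unname(rng["min"]),
               max_columella_dist = unname(rng["max"])))
      })
      rows[[ci]] <- cbind(data.frame(colony_id = sprintf("%s_c%02d", cl, k),
                                     species = cl, stringsAsFactors = FALSE),
                          as.data.frame(rec))
    }
  }
  out <- do.call(rbind, rows)
  out[, c("colony_id", "species", morpho_characters)]
}
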