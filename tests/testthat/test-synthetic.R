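small_spec <- function(...) {
  synthetic_dataset_spec(colonies_per_class = 2,
                         images_per_colony_per_scale = 1,
                         size = 64, seed = 3, ...)
}

test_that("texture rendering is deterministic and seed-sensitive", {
  p <- texture_class_params()
  a <- generate_colony_texture(p, seed = 5, size = 64)
  b <- generate_colony_texture(p, seed = 5, size = 64)
  expect_identical(unclass(a), unclass(b))
  c2 <- generate_colony_texture(p, seed = 6, size = 64)
  expect_false(identical(unclass(a), unclass(c2)))
  expect_error(generate_colony_texture(p, size = 8),
               class = "coraltex_validation_error")
})

test_that("datasets have the promised shape and colony structure", {
  spec <- synthetic_dataset_spec(colonies_per_class = 10,
                                 images_per_colony_per_scale = 3,
                                 size = 32, seed = 2)
  ds <- generate_texture_dataset(spec)
  expect_identical(nrow(ds$manifest), 180L) # 3 classes x 10 colonies x 6
  expect_length(ds$images, 180L)
  expect_true(all(table(ds$manifest$colony_id) == 6))
  expect_true(all(table(ds$manifest$colony_id, ds$manifest$scale) == 3))
  # no noise: observed species equal true species
  expect_identical(ds$manifest$species, ds$manifest$true_species)
  # parameter log: one row per colony, constant within colony by construction
  expect_identical(nrow(ds$params_log), 30L)
  expect_true(all(c("cell_density", "ridges_per_cell") %in%
                    names(ds$params_log)))
  # rerun is bit-identical
  ds2 <- generate_texture_dataset(spec)
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$manifest, ds2$manifest)
})

test_that("PNG output round-trips through the manifest reader", {
  dir <- withr::local_tempdir()
  ds <- generate_texture_dataset(small_spec(), dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  feats <- extract_features(man, clbp_config(P = 8), dir = dir)
  expect_length(feats, nrow(man))
  expect_equal(sum(feats[[1]]$histogram), 1, tolerance = 1e-12)
})

test_that("label noise is colony-coherent with the nominal rate", {
  labels <- rep(c("a", "b"), each = 500)
  conf <- c(a = "b", b = "a")
  expect_identical(apply_label_noise(labels, 0, conf, seed = 1), labels)
  noisy <- apply_label_noise(labels, 0.2, conf, seed = 1)
  frac <- mean(noisy != labels)
  expect_lt(abs(frac - 0.2), 0.04) # binomial 3 sigma at n = 1000
  expect_identical(apply_label_noise(labels, 0.2, conf, seed = 1), noisy)
  expect_error(apply_label_noise(labels, 0.6, conf),
               class = "coraltex_validation_error")
  expect_error(apply_label_noise(labels, 0.1, c(a = "b"), seed = 1),
               class = "coraltex_validation_error")
  # within a generated dataset, all images of a colony share one label
  ds <- generate_texture_dataset(small_spec(label_noise_rate = 0.3))
  mixed <- tapply(ds$manifest$species, ds$manifest$colony_id,
                  function(s) length(unique(s)))
  expect_true(all(mixed == 1))
})

test_that("classes with distinct parameters are separated in feature space", {
  p1 <- texture_class_params(cell_density = 15, noise_sd = 0.03)
  p2 <- texture_class_params(cell_density = 5, noise_sd = 0.03)
  f <- function(p, s) clbp_features(generate_colony_texture(p, seed = s,
                                                            size = 96),
                                    clbp_config(P = 8))$histogram
  h1 <- lapply(1:4, function(s) f(p1, s))
  h2 <- lapply(1:4, function(s) f(p2, s + 100))
  within <- c(mapply(chi2_distance, h1[1:3], h1[2:4]),
              mapply(chi2_distance, h2[1:3], h2[2:4]))
  between <- as.vector(outer(1:4, 1:4, Vectorize(function(i, j)
    chi2_distance(h1[[i]], h2[[j]]))))
  expect_gt(mean(between), mean(within))
})

test_that("per-image illumination is exactly cancelled by the descriptor", {
  p0 <- texture_class_params(illumination_amplitude = 0)
  p1 <- texture_class_params(illumination_amplitude = 0.3)
  i0 <- generate_colony_texture(p0, seed = 9, size = 96)
  i1 <- generate_colony_texture(p1, seed = 9, size = 96)
  expect_false(identical(unclass(i0), unclass(i1)))
  h0 <- clbp_features(i0, clbp_config(P = 8))$histogram
  h1 <- clbp_features(i1, clbp_config(P = 8))$histogram
  expect_lt(sum(abs(h0 - h1)), 1e-6)
})

test_that("morphometric tables honour their parameters and invariants", {
  tab <- generate_morpho_table(colonies_per_class = 8, seed = 4)
  expect_identical(nrow(tab), 24L)
  expect_identical(names(tab), c("colony_id", "species", morpho_characters))
  expect_true(all(tab$min_columella_dist <= tab$max_columella_dist))
  for (cyc in c("cycle4", "cycle5", "cycle6")) {
    comp <- tab[[paste0(cyc, "_complete")]]
    pres <- tab[[paste0(cyc, "_present")]]
    expect_true(all(pres[comp == 1] == 1))
  }
  expect_identical(generate_morpho_table(colonies_per_class = 8, seed = 4),
                   tab)
  # zero-variance limit: continuous fields identical within a class
  cls <- default_morpho_classes()
  cls <- lapply(cls, function(p) {
    p$sds[] <- 0; p$colony_sd <- 0; p
  })
  cls <- lapply(cls, function(p) {
    morpho_class_params(p$means, p$sds, p$binary_probs, colony_sd = 0,
                        columella_points = p$columella_points)
  })
  tab0 <- generate_morpho_table(cls, colonies_per_class = 3, seed = 6)
  sdA <- tab0[tab0$species == "spA", "corallite_diameter"]
  expect_true(all(sdA == sdA[1]))
})

test_that("the default morphometric classes overlap heavily", {
  tab <- generate_morpho_table(colonies_per_class = 30, seed = 8)
  # normal-theory intervals of every continuous character overlap pairwise
  for (ch in c("corallite_diameter", "n_septa", "columella_diameter")) {
    stats <- tapply(tab[[ch]], tab$species, function(v) c(mean(v), sd(v)))
    cis <- lapply(stats, function(m) ci_interval(m[1], m[2]))
    expect_true(ci_overlap(cis$spA, cis$spB))
    expect_true(ci_overlap(cis$spB, cis$spC))
    expect_true(ci_overlap(cis$spA, cis$spC))
  }
})
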