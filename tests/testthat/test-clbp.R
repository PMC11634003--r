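test_that("riu2 mapping follows the uniformity rule", {
  expect_identical(riu2_map(rep(0, 8)), 0L)
  expect_identical(riu2_map(c(0, 0, 0, 0, 1, 1, 1, 1)), 4L)
  expect_identical(riu2_map(rep(c(0, 1), 4)), 9L)
  expect_identical(riu2_map(rep(1, 8)), 8L)
  # all 8-bit patterns land in [0, P+1] and uniform ones on their bit sum
  for (code in 0:255) {
    bits <- as.integer(intToBits(code))[1:8]
    bin <- riu2_map(bits)
    expect_true(bin >= 0 && bin <= 9)
    u <- abs(bits[8] - bits[1]) + sum(abs(diff(bits)))
    expect_identical(bin, if (u <= 2) sum(bits) else 9L)
  }
  expect_error(riu2_map(c(0, 1, 2, 0)), "bits")
})

test_that("feature length is (P+2)^2 * 2", {
  expect_identical(feature_length(clbp_config(P = 24)), 1352L)
  expect_identical(feature_length(clbp_config(P = 8)), 200L)
  expect_identical(feature_length(clbp_config(P = 16)), 648L)
})

test_that("constant image decomposes to the all-ones corner", {
  cfg <- clbp_config(P = 8, R = 1)
  codes <- clbp_decompose(matrix(0.4, 5, 5), cfg)
  expect_true(all(codes$sign_bin == 8))       # every d_p = 0 -> s_p = 1
  expect_true(all(codes$magnitude_bin == 8))  # c = 0, |d_p| >= 0 -> t_p = 1
  expect_true(all(codes$center_bit == 1))
  expect_identical(codes$c, 0)
  h <- joint_histogram(codes)$histogram
  idx <- (8 * 10 + 8) * 2 + 1 + 1 # sign bin 8, magnitude bin 8, centre 1
  expect_identical(h[idx], 1)
  expect_identical(sum(h), 1)
})

test_that("codes are invariant to global intensity shift and gain", {
  set.seed(41)
  img <- matrix(runif(30 * 30), 30, 30)
  cfg <- clbp_config(P = 8, R = 2)
  base <- clbp_decompose(img, cfg)
  shifted <- clbp_decompose(img + 0.2, cfg)
  expect_identical(base$sign_bin, shifted$sign_bin)
  expect_identical(base$magnitude_bin, shifted$magnitude_bin)
  expect_identical(base$center_bit, shifted$center_bit)
  affine <- clbp_decompose(1.7 * img - 0.3, cfg)
  expect_identical(base$sign_bin, affine$sign_bin)
  expect_identical(base$magnitude_bin, affine$magnitude_bin)
  expect_identical(base$center_bit, affine$center_bit)
  h0 <- joint_histogram(base)$histogram
  h1 <- joint_histogram(affine)$histogram
  expect_lt(sum(abs(h0 - h1)), 1e-9)
})

test_that("riu2 bin multisets are invariant under 90-degree rotation", {
  set.seed(7)
  img <- matrix(runif(32 * 32), 32, 32)
  for (P in c(8, 24)) {
    cfg <- clbp_config(P = P, R = 2, interpolation = "nearest")
    a <- clbp_decompose(img, cfg)
    b <- clbp_decompose(rotate90(img), cfg)
    expect_identical(sort(as.vector(a$sign_bin)), sort(as.vector(b$sign_bin)))
    expect_identical(sort(as.vector(a$magnitude_bin)),
                     sort(as.vector(b$magnitude_bin)))
  }
})

test_that("joint histograms stay close under rotation with bilinear sampling", {
  set.seed(8)
  # smooth random field: white noise blurred by a moving-average kernel
  raw <- matrix(runif(70 * 70), 70, 70)
  sm <- raw
  for (i in 1:2) {
    n <- nrow(sm)
    sm <- (sm[1:(n - 2), 1:(n - 2)] + sm[2:(n - 1), 2:(n - 1)] +
             sm[3:n, 3:n]) / 3
  }
  img <- sm[1:64, 1:64]
  f0 <- clbp_features(img, clbp_config(P = 8, R = 2))$histogram
  f90 <- clbp_features(rotate90(img), clbp_config(P = 8, R = 2))$histogram
  expect_lt(sum(abs(f0 - f90)), 0.05)
})

test_that("vectorised extraction matches the per-pixel brute-force reference", {
  set.seed(11)
  img <- matrix(runif(16 * 16), 16, 16)
  for (P in c(8, 24)) {
    cfg <- clbp_config(P = P, R = 2)
    expect_identical(clbp_features(img, cfg)$histogram,
                     brute_clbp_histogram(img, P = P, R = 2))
  }
  # nearest-neighbour sampling path
  cfg <- clbp_config(P = 8, R = 2, interpolation = "nearest")
  expect_identical(clbp_features(img, cfg)$histogram,
                   brute_clbp_histogram(img, P = 8, R = 2,
                                        interpolation = "nearest"))
})

test_that("histograms are probability vectors on random images", {
  set.seed(3)
  for (i in 1:5) {
    img <- matrix(runif(24 * 24), 24, 24)
    h <- clbp_features(img, clbp_config(P = 8, R = 3))$histogram
    expect_true(all(h >= 0))
    expect_equal(sum(h), 1, tolerance = 1e-12)
  }
})

test_that("size and validity preconditions are enforced", {
  expect_error(clbp_decompose(matrix(0.5, 6, 20), clbp_config(P = 8, R = 3)),
               class = "coraltex_size_error")
  img <- matrix(0.5, 20, 20); img[3, 3] <- NA
  expect_error(clbp_decompose(img, clbp_config(P = 8, R = 3)),
               class = "coraltex_validation_error")
})

test_that("extraction runs from files and from memory identically", {
  set.seed(5)
  dir <- withr::local_tempdir()
  img <- matrix(runif(24 * 24), 24, 24)
  png::writePNG(img, file.path(dir, "a.png"))
  manifest <- data.frame(sample_id = "a", colony_id = "c1", species = "sp1",
                         scale = "colony", path = "a.png")
  from_file <- extract_features(manifest, clbp_config(P = 8), dir = dir)
  from_mem <- extract_features(manifest, clbp_config(P = 8),
                               images = list(a = png::readPNG(file.path(dir, "a.png"))))
  expect_equal(from_file[[1]]$histogram, from_mem[[1]]$histogram)
  expect_identical(from_file[[1]]$metadata$colony_id, "c1")
  expect_identical(extract_features(manifest[0, ], clbp_config(P = 8)), list())
  manifest$path <- "missing.png"
  expect_error(extract_features(manifest, clbp_config(P = 8), dir = dir),
               "missing.png", class = "coraltex_io_error")
})

test_that("RGB input is converted by fixed luminance weights", {
  set.seed(6)
  dir <- withr::local_tempdir()
  arr <- array(runif(20 * 20 * 3), c(20, 20, 3))
  png::writePNG(arr, file.path(dir, "rgb.png"))
  gray <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  got <- read_gray_image(file.path(dir, "rgb.png"))
  expect_equal(unclass(got), gray, tolerance = 1e-2, ignore_attr = TRUE)
  # conversion is deterministic: luminance of the stored channels gives
  # identical CLBP features to the package's reader
  stored <- png::readPNG(file.path(dir, "rgb.png"))
  pre <- 0.299 * stored[, , 1] + 0.587 * stored[, , 2] + 0.114 * stored[, , 3]
  f1 <- clbp_features(got, clbp_config(P = 8))
  f2 <- clbp_features(pre, clbp_config(P = 8))
  expect_identical(f1$histogram, f2$histogram)
})

test_that("feature CSV round-trips with its configuration header", {
  set.seed(9)
  dir <- withr::local_tempdir()
  manifest <- data.frame(sample_id = c("s1", "s2"), colony_id = "c1",
                         species = "sp1", scale = c("colony", "corallite"))
  imgs <- list(s1 = matrix(runif(24^2), 24), s2 = matrix(runif(24^2), 24))
  feats <- extract_features(manifest, clbp_config(P = 8), images = imgs)
  p <- file.path(dir, "features.csv")
  write_features_csv(feats, p)
  back <- read_features_csv(p)
  expect_identical(back$config$P, 8L)
  expect_equal(back$x[1, ], feats[[1]]$histogram, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$meta$scale, c("colony", "corallite"))
})
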