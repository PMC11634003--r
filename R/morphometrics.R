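# Traditional morphometrics: the 15-character table measured on corallites
# (diameters, septal measurements, septal-cycle presence/completeness,
# Delaunay-based inter-columella distances, budding and septal continuity),
# encoded into the unit hypercube for the fuzzy classifier.

#' Fixed order of the 15 morphometric characters
#'
#' Continuous characters in mm (counts unscaled) and binary 0/1 characters,
#' in the conventional numbering: (1) corallite diameter, (2) columella
#' diameter, (3) mean first-cycle septal thickness, (4) mean first-cycle
#' septal length, (5) number of septa, (6/7) 4th septal cycle
#' present/complete, (8/9) 5th cycle present/complete, (10/11) 6th cycle
#' present/complete, (12/13) minimum/maximum inter-columella distance from
#' the colony's Delaunay mesh, (14) intratentacular budding, (15) septal
#' continuity between adjacent corallites.
#'
#' @format character vector of the 15 column names.
#' @export
morpho_characters <- c(
  "corallite_diameter", "columella_diameter", "mean_septal_thickness",
  "mean_septal_length", "n_septa",
  "cycle4_present", "cycle4_complete", "cycle5_present", "cycle5_complete",
  "cycle6_present", "cycle6_complete",
  "min_columella_dist", "max_columella_dist",
  "intratentacular_budding", "septal_continuity"
)

morpho_continuous <- morpho_characters[c(1:5, 12, 13)]
morpho_binary <- setdiff(morpho_characters, morpho_continuous)

#' Delaunay triangulation edges of columella centres
#'
#' Triangulates the XY positions of the columella centres of one colony and
#' returns the unique undirected edges with their Euclidean lengths. Used to
#' derive the minimum and maximum inter-columella distances.
#'
#' @param points matrix or data frame with columns `x` and `y` (mm, planar
#'   projection); at least 3 non-collinear points.
#' @return data frame with columns `i`, `j` (point indices, `i < j`) and
#'   `length`.
#' @export
#' @examples
#' delaunay_edges(cbind(x = c(0, 1, 0), y = c(0, 0, 1)))
delaunay_edges <- function(points) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  storage.mode(pts) <- "double"
  assert_that(all(is.finite(pts)), "coordinates must be finite")
  if (nrow(pts) < 3) {
    ct_stop("need at least 3 points to triangulate",
            "coraltex_degenerate_geometry_error")
  }
  # collinearity: all cross products of (p2-p1, pk-p1) within tolerance of 0
  v <- sweep(pts[-1, , drop = FALSE], 2, pts[1, ])
  cr <- v[1, 1] * v[, 2] - v[1, 2] * v[, 1]
  scale <- max(abs(pts)) + 1
  if (all(abs(cr) < 1e-10 * scale^2)) {
    ct_stop("points are collinear; no triangulation exists",
            "coraltex_degenerate_geometry_error")
  }
  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)
  seg <- dd$delsgs
  i <- pmin(seg$ind1, seg$ind2)
  j <- pmax(seg$ind1, seg$ind2)
  keep <- !duplicated(cbind(i, j))
  i <- i[keep]; j <- j[keep]
  # lengths from the original coordinates (deldir's segment table rounds)
  len <- sqrt((pts[i, 1] - pts[j, 1])^2 + (pts[i, 2] - pts[j, 2])^2)
  out <- data.frame(i = i, j = j, length = len)
  out[order(out$i, out$j), , drop = FALSE]
}

#' Minimum and maximum inter-columella distances of a colony
#'
#' The shortest and longest edge of the Delaunay mesh over the columella
#' centres — characters (12) and (13) of the morphometric table.
#'
#' @inheritParams delaunay_edges
#' @return named numeric vector `c(min = ..., max = ...)` in mm.
#' @export
columella_distance_range <- function(points) {
  e <- delaunay_edges(points)
  c(min = min(e$length), max = max(e$length))
}

#' Encode morphometric records as a classifier feature matrix
#'
#' Continuous characters are min-max scaled to `[0, 1]` (a constant column
#' scales to 0 with a warning); binary characters pass through unchanged, so
#' the encoding is idempotent on them. Column order follows
#' [morpho_characters]. The result lives in the unit hypercube as the
#' fuzzy classifier's equivalence measure requires.
#'
#' @param records data frame with the [morpho_characters] columns plus
#'   `colony_id` and `species`.
#' @param impute `"none"` (default: missing values are an error) or
#'   `"median"` (continuous NAs replaced by the column median, binary NAs by
#'   the column mode).
#' @return list with `x` (numeric matrix, 15 columns), `labels` (factor of
#'   species) and `colony_id`.
#' @export
encode_morpho_features <- function(records, impute = c("none", "median")) {
  impute <- match.arg(impute)
  assert_that(all(morpho_characters %in% names(records)),
              paste("records must contain columns:",
                    paste(setdiff(morpho_characters, names(records)),
                          collapse = ", ")))
  x <- as.matrix(records[, morpho_characters])
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    if (impute == "none") {
      ct_stop("missing values present; use impute = \"median\"",
              "coraltex_validation_error")
    }
    for (cc in morpho_characters) {
      col <- x[, cc]
      if (anyNA(col)) {
        fill <- if (cc %in% morpho_continuous) {
          stats::median(col, na.rm = TRUE)
        } else {
          round(mean(col, na.rm = TRUE))
        }
        x[is.na(col), cc] <- fill
      }
    }
  }
  bin <- x[, morpho_binary]
  assert_that(all(bin %in% c(0, 1)), "binary characters must be 0/1")
  for (cyc in c("cycle4", "cycle5", "cycle6")) {
    comp <- x[, paste0(cyc, "_complete")]
    pres <- x[, paste0(cyc, "_present")]
    assert_that(all(pres[comp == 1] == 1),
                sprintf("%s_complete = 1 requires %s_present = 1", cyc, cyc))
  }
  assert_that(all(x[, "min_columella_dist"] <= x[, "max_columella_dist"]),
              "min_columella_dist must be <= max_columella_dist")
  for (cc in morpho_continuous) {
    rng <- range(x[, cc])
    if (diff(rng) == 0) {
      warning(sprintf("constant continuous character '%s' scaled to 0", cc))
      x[, cc] <- 0
    } else {
      x[, cc] <- (x[, cc] - rng[1]) / diff(rng)
    }
  }
  list(x = x,
       labels = factor(records$species),
       colony_id = as.character(records$colony_id))
}

#' Normal-theory interval from a mean and standard deviation
#'
#' `mean - 1.96 sd` to `mean + 1.96 sd`: the interval covering ~95% of a
#' normal distribution with those moments, used to compare published
#' character ranges across morphometric studies.
#'
#' @param mean,sd numeric vectors (recycled); `sd >= 0`.
#' @return data frame with columns `low` and `high`.
#' @export
#' @examples
#' ci_interval(2, 0.5) # 1.02 .. 2.98
ci_interval <- function(mean, sd) {
  assert_that(all(is.finite(mean)) && all(is.finite(sd)),
              "mean and sd must be finite")
  assert_that(all(sd >= 0), "sd must be >= 0")
  data.frame(low = mean - 1.96 * sd, high = mean + 1.96 * sd)
}

#' Do two intervals overlap?
#'
#' @param a,b single-row data frames (or vectors) with `low`/`high`.
#' @return logical.
#' @export
ci_overlap <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  a$low <= b$high && b$low <= a$high
}

#' Read a morphometric record CSV / colony coordinate CSV
#'
#' @param path CSV with the [morpho_characters] columns plus `colony_id`,
#'   `species` (records), or `colony_id`, `x`, `y` triples (coordinates).
#' @return data frame.
#' @export
read_morpho_csv <- function(path) {
  if (!file.exists(path)) {
    ct_stop(sprintf("cannot read '%s'", path), "coraltex_io_error")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}
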