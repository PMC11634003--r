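# Independent reference implementations used as oracles. These are written
# per-pixel / per-threshold, deliberately ignoring the vectorised paths in
# the package.

# Brute-force CLBP: per-pixel loops, explicit bit vectors through
# riu2_map(), direct histogram counting.
brute_clbp_histogram <- function(img, P, R, interpolation = "bilinear") {
  b <- as.integer(ceiling(R))
  h <- nrow(img); w <- ncol(img)
  rows <- (b + 1):(h - b); cols <- (b + 1):(w - b)
  sample_at <- function(r, c) {
    if (interpolation == "nearest") return(img[round(r), round(c)])
    r0 <- floor(r); c0 <- floor(c)
    dr <- r - r0; dc <- c - c0
    if (dr > 1 - 1e-9) { r0 <- r0 + 1; dr <- 0 }
    if (dc > 1 - 1e-9) { c0 <- c0 + 1; dc <- 0 }
    if (dr < 1e-9) dr <- 0
    if (dc < 1e-9) dc <- 0
    r1 <- r0 + (dr > 0); c1 <- c0 + (dc > 0)
    (1 - dr) * (1 - dc) * img[r0, c0] +
      (1 - dr) * dc * img[r0, c1] +
      dr * (1 - dc) * img[r1, c0] +
      dr * dc * img[r1, c1]
  }
  diffs <- array(NA_real_, c(length(rows), length(cols), P))
  for (ii in seq_along(rows)) for (jj in seq_along(cols)) {
    for (p in 0:(P - 1)) {
      th <- 2 * pi * p / P
      diffs[ii, jj, p + 1] <- sample_at(rows[ii] - R * sin(th),
                                        cols[jj] + R * cos(th)) -
        img[rows[ii], cols[jj]]
    }
  }
  c_thr <- mean(abs(diffs))
  c_int <- mean(img[rows, cols])
  counts <- numeric((P + 2)^2 * 2)
  for (ii in seq_along(rows)) for (jj in seq_along(cols)) {
    d <- diffs[ii, jj, ]
    sb <- riu2_map(as.integer(d >= 0))
    mb <- riu2_map(as.integer(abs(d) >= c_thr))
    cb <- as.integer(img[rows[ii], cols[jj]] >= c_int)
    idx <- (sb * (P + 2) + mb) * 2 + cb + 1
    counts[idx] <- counts[idx] + 1
  }
  counts / sum(counts)
}

# Brute-force Delaunay edges via the empty-circumcircle property: keep every
# triangle whose circumcircle contains no other point, collect its edges.
brute_delaunay_edges <- function(pts) {
  n <- nrow(pts)
  circum <- function(a, b, c) {
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
             (sum(c^2)) * (a[2] - b[2])) / d
    uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
             (sum(c^2)) * (b[1] - a[1])) / d
    c(ux, uy)
  }
  edges <- NULL
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- circum(pts[i, ], pts[j, ], pts[k, ])
    if (is.null(cc)) next
    r2 <- sum((pts[i, ] - cc)^2)
    others <- setdiff(seq_len(n), c(i, j, k))
    if (all(rowSums(sweep(pts[others, , drop = FALSE], 2, cc)^2) >
              r2 + 1e-9)) {
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
    }
  }
  unique(as.data.frame(edges))
}

# Exhaustive PRC AUC: walk every distinct threshold, count from scratch.
brute_prc_auc <- function(labels, scores) {
  ts <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  rec <- 0; auc <- 0
  for (t in ts) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    auc <- auc + (tp / P - rec) * prec
    rec <- tp / P
  }
  auc
}

rotate90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
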