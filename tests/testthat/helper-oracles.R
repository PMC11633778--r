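# Independent oracles used to freeze expected values.

# brute-force type-7 quantile: sort + linear interpolation between order
# statistics, written without stats::quantile
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_lif <- function(x, k = 1.5) {
  q1 <- oracle_quantile7(x, 0.25)
  q3 <- oracle_quantile7(x, 0.75)
  q1 - k * (q3 - q1)
}

# Welch t statistic and two-tailed p from first principles
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# maximum bipartite matching size under a distance cap, by exhaustive
# recursion (for small n)
oracle_max_matching <- function(a, b, max_dist) {
  d <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2)
  ok <- d <= max_dist
  best <- 0
  recurse <- function(i, used_b, count) {
    if (count + (nrow(ok) - i + 1) <= best) return()
    if (i > nrow(ok)) { best <<- max(best, count); return() }
    recurse(i + 1, used_b, count)  # skip a_i
    for (j in which(ok[i, ] & !used_b)) {
      used_b[j] <- TRUE
      recurse(i + 1, used_b, count + 1)
      used_b[j] <- FALSE
    }
  }
  if (nrow(d) > 0 && ncol(d) > 0) recurse(1, rep(FALSE, ncol(d)), 0)
  best
}

# flat image with k planted Gaussian peaks (optionally at subpixel centers)
plant_spots <- function(centers, size = c(96, 96), bg = 100,
                        amplitude = 2000, sigma = 1.5, read_sd = 5,
                        seed = 1) {
  set.seed(seed)
  img <- matrix(bg, size[1], size[2])
  for (i in seq_len(nrow(centers))) {
    sr <- centers[i, 2]; sc <- centers[i, 1]  # (x, y) -> (col, row)
    rr <- max(1, round(sr) - 6):min(size[1], round(sr) + 6)
    cc <- max(1, round(sc) - 6):min(size[2], round(sc) + 6)
    g <- outer((rr - sr)^2, (cc - sc)^2, "+")
    img[rr, cc] <- img[rr, cc] + amplitude * exp(-g / (2 * sigma^2))
  }
  img + matrix(rnorm(length(img), 0, read_sd), size[1], size[2])
}

# small in-memory feature table for z-score oracles
toy_features <- function(n_sample = 88, n_nt = 8, seed = 1,
                         barcode = "T01", condition = "NoEGTA") {
  set.seed(seed)
  n <- n_sample + n_nt
  data.frame(
    barcode = barcode, well = sprintf("W%03d", seq_len(n)),
    condition = condition,
    gene = c(sprintf("g%03d", seq_len(n_sample)), rep("NT", n_nt)),
    role = c(rep("sample", n_sample), rep("NT", n_nt)),
    replicate = 1L,
    QC1_NoOfAnalysedCells = round(rnorm(n, 350, 30)),
    N1_NucNotch = rnorm(n, 100, 8),
    N3_MembNotch = rnorm(n, 600, 30),
    N4_CellNotch = rnorm(n, 100, 10),
    N5_PercentOfCellsWithSpots = pmax(0, rnorm(n, 4, 4)),
    N9_NoOfSpotsPerCell = pmax(0, rnorm(n, 0.3, 0.25)),
    stringsAsFactors = FALSE)
}
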