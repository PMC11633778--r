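test_that("%IntDens follows the ratio formula and its additivity", {
  expect_equal(percent_intdens(50, 200), 25)
  expect_equal(percent_intdens(200, 200), 100)
  expect_error(percent_intdens(10, 0), "is 0")
  # partition of a whole-cell ROI sums to 100
  set.seed(31)
  img <- matrix(runif(64^2, 10, 500), 64, 64)
  cell <- matrix(FALSE, 64, 64); cell[10:50, 10:50] <- TRUE
  parts <- list(a = cell & row(cell) < 25,
                b = cell & row(cell) >= 25 & col(cell) < 30,
                c = cell & row(cell) >= 25 & col(cell) >= 30)
  whole <- roi_intdens(img, cell)$int_dens
  pct <- vapply(parts, function(m)
    percent_intdens(roi_intdens(img, m)$int_dens, whole), numeric(1))
  expect_equal(sum(pct), 100, tolerance = 1e-6)
})

test_that("nested ROIs give monotone %IntDens on non-negative images", {
  set.seed(32)
  img <- matrix(runif(64^2), 64, 64)
  whole <- matrix(TRUE, 64, 64)
  w <- roi_intdens(img, whole)$int_dens
  last <- 0
  for (r in c(10, 20, 30)) {
    m <- matrix(FALSE, 64, 64); m[1:r, 1:r] <- TRUE
    p <- percent_intdens(roi_intdens(img, m)$int_dens, w)
    expect_gt(p, last)
    last <- p
  }
})

test_that("polygon ROIs rasterize consistently with masks", {
  img <- matrix(1, 32, 32)
  # axis-aligned square: x (col) 10..20, y (row) 5..15
  poly <- cbind(x = c(9.5, 20.5, 20.5, 9.5), y = c(4.5, 4.5, 15.5, 15.5))
  got <- roi_intdens(img, poly)
  expect_equal(got$area_px, 11 * 11)
  mask <- matrix(FALSE, 32, 32); mask[5:15, 10:20] <- TRUE
  expect_equal(got$int_dens, roi_intdens(img, mask)$int_dens)
})

test_that("identical and disjoint spot sets give fractions 1 and 0", {
  a <- data.frame(x = c(10, 20, 30), y = c(10, 20, 30))
  same <- colocalize(a, a, max_distance = 2)
  expect_equal(same$n_colocalized, 3)
  expect_equal(same$fraction_colocalized, 1)
  off <- colocalize(a, transform(a, x = x + 3), max_distance = 2)
  expect_equal(off$n_colocalized, 0)
  expect_equal(off$fraction_colocalized, 0)
})

test_that("colocalized counts are symmetric in the channel order", {
  set.seed(33)
  for (i in 1:10) {
    a <- data.frame(x = runif(15, 1, 100), y = runif(15, 1, 100))
    b <- data.frame(x = runif(25, 1, 100), y = runif(25, 1, 100))
    ab <- colocalize(a, b, 2)
    ba <- colocalize(b, a, 2)
    expect_equal(ab$n_colocalized, ba$n_colocalized)
    expect_lte(ab$n_colocalized, min(nrow(a), nrow(b)))
  }
})

test_that("greedy matching agrees with the exhaustive oracle on small sets", {
  set.seed(34)
  agree <- 0; trials <- 40
  for (i in seq_len(trials)) {
    a <- data.frame(x = runif(8, 1, 30), y = runif(8, 1, 30))
    b <- data.frame(x = runif(8, 1, 30), y = runif(8, 1, 30))
    got <- colocalize(a, b, max_distance = 2)$n_colocalized
    best <- oracle_max_matching(a, b, 2)
    expect_lte(got, best)
    if (got == best) agree <- agree + 1
  }
  expect_gte(agree / trials, 0.95)
})

test_that("replicate summaries enforce the five-ROI five-image rule", {
  m <- data.frame(condition = "kd", image = rep(1:5, each = 1),
                  value = c(10, 12, 11, 13, 9))
  s <- summarize_replicates(m)
  expect_true(s$valid)
  expect_equal(s$mean, mean(m$value))
  expect_equal(s$sd, sd(m$value))
  # four ROIs: invalid
  s4 <- summarize_replicates(m[1:4, ])
  expect_false(s4$valid)
  # five ROIs but four images: invalid
  m2 <- m; m2$image <- c(1, 1, 2, 3, 4)
  expect_false(summarize_replicates(m2)$valid)
})
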