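# Masked region means, global fitted image, SPF field and mask recursion.

test_that("region means recover piecewise-constant intensities", {
  ph <- disk_phantom(shape = c(96, 96), fg = 200, bg = 40, r = 20)
  rr <- matrix(seq_len(96), 96, 96)
  cc <- t(rr)
  d <- sqrt((rr - 48.5)^2 + (cc - 48.5)^2)
  # steep field, positive exactly on the disk: |phi| >> eps so the
  # regularized Heaviside is near-binary and the means are sharp
  phi <- 30 * (20 - d)
  mask <- matrix(TRUE, 96, 96)
  mask[c(1:3, 94:96), ] <- FALSE  # interior-of-frame mask
  mask[, c(1:3, 94:96)] <- FALSE
  rm <- region_means(ph$image, phi, mask)
  expect_false(rm$degenerate)
  expect_lt(abs(rm$c1 - 200) / 200, 0.02)
  expect_lt(abs(rm$c2 - 40) / 40, 0.02)
})

test_that("uniform image gives c1 = c2 = c", {
  img <- matrix(77, 20, 20)
  phi <- init_levelset(c(20, 20), margin = 3)
  rm <- region_means(img, phi, update_mask(phi))
  expect_equal(rm$c1, 77)
  expect_equal(rm$c2, 77)
})

test_that("region means match a brute-force double-sum oracle", {
  set.seed(11)
  img <- matrix(runif(256, 0, 255), 16, 16)
  phi <- matrix(rnorm(256, 0, 2), 16, 16)
  mask <- matrix(runif(256) > 0.3, 16, 16)
  eps <- 1.5
  # independent elementwise summation
  n1 <- d1 <- n2 <- d2 <- 0
  for (i in 1:16) {
    for (j in 1:16) {
      h <- 0.5 * (1 + (2 / pi) * atan(phi[i, j] / eps))
      m <- as.numeric(mask[i, j])
      n1 <- n1 + img[i, j] * h * m;       d1 <- d1 + h * m
      n2 <- n2 + img[i, j] * (1 - h) * m; d2 <- d2 + (1 - h) * m
    }
  }
  rm <- region_means(img, phi, mask, eps)
  expect_equal(rm$c1, n1 / d1, tolerance = 1e-10)
  expect_equal(rm$c2, n2 / d2, tolerance = 1e-10)
  # reduction to the unmasked two-phase means when M is all-TRUE
  all_m <- matrix(TRUE, 16, 16)
  rm_all <- region_means(img, phi, all_m, eps)
  h <- heaviside(phi, eps)
  expect_equal(rm_all$c1, sum(img * h) / sum(h), tolerance = 1e-12)
  expect_equal(rm_all$c2, sum(img * (1 - h)) / sum(1 - h),
               tolerance = 1e-12)
  # empty mask degenerates
  expect_true(region_means(img, phi, matrix(FALSE, 16, 16))$degenerate)
})

test_that("global fitted image interpolates between the region means", {
  stats <- list(c1 = 180, c2 = 20)
  phi <- matrix(c(1e6, 0, -1e6, 3), 2, 2)
  gfi <- global_fitted_image(stats, phi)
  expect_equal(gfi[1, 1], 180, tolerance = 1e-5)   # phi >> eps
  expect_equal(gfi[2, 1], (180 + 20) / 2)          # on the zero level
  expect_equal(gfi[1, 2], 20, tolerance = 1e-4)    # phi << -eps
  expect_true(all(gfi >= 20 & gfi <= 180))
  same <- global_fitted_image(list(c1 = 55, c2 = 55), phi)
  expect_equal(same, matrix(55, 2, 2))
})

test_that("spf matches the printed formula and its contract", {
  set.seed(23)
  img <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
  img[sample(256, 20)] <- 0
  phi <- matrix(rnorm(256, 0, 2), 16, 16)
  mask <- matrix(runif(256) > 0.25, 16, 16)
  rm <- region_means(img, phi, mask)
  gfi <- global_fitted_image(rm, phi)
  s <- spf(img, gfi, mask)
  # brute-force oracle
  d <- img - gfi
  mx <- 0
  for (k in seq_along(d)) mx <- max(mx, abs(d[k]))
  oracle <- matrix(0, 16, 16)
  for (i in 1:16) {
    for (j in 1:16) {
      oracle[i, j] <- if (img[i, j] == 0) 0 else
        d[i, j] * as.numeric(mask[i, j]) / mx
    }
  }
  expect_equal(unclass(s), oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(abs(s) <= 1))
  expect_true(all(s[img == 0] == 0))
  expect_true(all(s[!mask] == 0))
  expect_false(attr(s, "degenerate"))
})

test_that("spf is zero with a degenerate flag on a constant image", {
  img <- matrix(120, 10, 10)
  s <- spf(img, img, matrix(TRUE, 10, 10))
  expect_true(all(s == 0))
  expect_true(attr(s, "degenerate"))
})

test_that("spf has opposite signs inside a bright object and in the masked
           background, and attains |spf| = 1", {
  ph <- disk_phantom(shape = c(96, 96), fg = 220, bg = 30, r = 18)
  phi <- init_levelset(c(96, 96))
  mask <- update_mask(phi)
  rm <- region_means(ph$image, phi, mask)
  gfi <- global_fitted_image(rm, phi, 1.5)
  s <- spf(ph$image, gfi, mask)
  obj <- ph$truth[[1]]
  bg <- mask & !obj
  expect_true(all(s[obj] > 0))   # bright object: I above the fitted image
  expect_true(all(s[bg] < 0))    # masked dark background
  expect_equal(max(abs(s)), 1)
})

test_that("mask recursion is nested and partitions correctly", {
  phi <- init_levelset(c(30, 30), region = list(type = "circle",
                                                center = c(15, 15),
                                                radius = 10))
  m <- update_mask(phi)
  expect_true(m[15, 15])
  expect_false(m[1, 1])
  expect_false(any(update_mask(matrix(-2, 8, 8))))  # termination signal
  # outer region: annulus between two concentric disks
  phi2 <- init_levelset(c(30, 30), region = list(type = "circle",
                                                 center = c(15, 15),
                                                 radius = 6))
  m2 <- update_mask(phi2)
  ann <- outer_region(m, m2)
  expect_true(all(ann == (m & !m2)))
  expect_equal(sum(ann) + sum(m2), sum(m))        # partition identity
  expect_false(any(outer_region(m, m)))           # prev = curr -> empty
  # curr not a subset: intersected first, partition still holds
  shifted <- update_mask(init_levelset(c(30, 30),
                                       region = list(type = "circle",
                                                     center = c(10, 22),
                                                     radius = 7)))
  out <- outer_region(m, shifted)
  expect_equal(sum(out) + sum(shifted & m), sum(m))
})

test_that("subregion masks stay nested across a phantom run", {
  ph <- disk_phantom(shape = c(64, 64), r = 12)
  fit <- spf_segment(ph$image, config = seg_config(max_iters = 120))
  expect_true(all(diff(fit$history$area) <= 0))
  expect_true(all(fit$initial_mask[fit$final_mask]))  # final inside initial
})
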