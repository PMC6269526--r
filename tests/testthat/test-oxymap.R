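test_that("background subtraction is the exact additive inverse", {
  pair <- list(blue = matrix(2, 8, 8), red = matrix(2, 8, 8),
               blue_bg = matrix(2, 8, 8), red_bg = matrix(2, 8, 8))
  corr <- subtract_background(pair)
  expect_true(all(corr$blue == 0) && all(corr$red == 0))

  pair$blue_bg <- pair$red_bg <- matrix(0, 8, 8)
  corr <- subtract_background(pair)
  expect_equal(corr$blue, pair$blue)

  pair$red_bg <- matrix(0, 4, 4)
  expect_error(subtract_background(pair), "shape")

  # several background frames are averaged
  pair2 <- list(blue = matrix(5, 4, 4), red = matrix(5, 4, 4),
                blue_bg = list(matrix(1, 4, 4), matrix(3, 4, 4)),
                red_bg = matrix(0, 4, 4))
  expect_true(all(subtract_background(pair2)$blue == 3))
})

test_that("ratio map is gain-invariant and floors the red channel", {
  b <- matrix(4, 8, 8)
  r1 <- ratio_map(b, b, red_floor = 0.1)
  expect_true(all(r1$ratio[r1$valid] == 1))

  g <- 13.7
  blue <- matrix(runif(64, 1, 3), 8, 8)
  red <- matrix(runif(64, 1, 3), 8, 8)
  expect_equal(ratio_map(g * blue, g * red, red_floor = 0.1)$ratio,
               ratio_map(blue, red, red_floor = 0.1)$ratio)

  expect_error(ratio_map(blue, red, red_floor = 0), "red_floor")
  red[1, 1] <- 0.01
  rm2 <- ratio_map(blue, red, red_floor = 0.5)
  expect_false(rm2$valid[1, 1])
  expect_true(is.na(rm2$ratio[1, 1]))
})

test_that("Stern-Volmer inversion recovers the oxygen field exactly", {
  set.seed(21)
  po2 <- matrix(runif(400, 0, 2), 20, 20)
  ksv <- 1.3
  pair <- simulate_ratiometric_images(po2, ksv = ksv, noise_sd = 0)
  corr <- subtract_background(pair)
  ri <- ratio_map(corr$blue, corr$red, red_floor = 1e-6)
  # (ratio - ratio0)/ratio0 = ksv * pO2 with ratio0 = 1
  expect_lt(max(abs((ri$ratio - 1) / 1 - ksv * po2)), 1e-6)
  rec <- invert_stern_volmer(ri, ksv = ksv)
  expect_lt(max(abs(rec - po2) / pmax(po2, 1e-12)), 1e-6)
})

test_that("gray rendering is a monotone function of the ratio", {
  set.seed(22)
  blue <- matrix(runif(256, 1, 5), 16, 16)
  red <- matrix(runif(256, 1, 5), 16, 16)
  ri <- ratio_map(blue, red, red_floor = 0.1, gray_bounds = c(0.2, 5))
  o1 <- order(ri$ratio[ri$valid])
  expect_true(!is.unsorted(ri$gray[ri$valid][o1]))
})

test_that("mean gray averages the ROI and honours validity", {
  gray_val <- 0.37
  # build a ratio image whose gray is uniform 0.37
  blue <- matrix(1 + gray_val, 10, 10)
  red <- matrix(1, 10, 10)
  ri <- ratio_map(blue, red, red_floor = 0.1, gray_bounds = c(1, 2))
  roi <- matrix(TRUE, 10, 10)
  expect_equal(mean_gray(ri, roi), gray_val)

  # half-0 / half-1 checkerboard
  chk <- outer(1:10, 1:10, function(i, j) (i + j) %% 2 == 0)
  blue2 <- ifelse(chk, 2, 1)
  ri2 <- ratio_map(blue2, red, red_floor = 0.1, gray_bounds = c(1, 2))
  expect_equal(mean_gray(ri2, roi), 0.5)

  # invalid pixels outside the ROI do not change the value
  red3 <- red; red3[1, ] <- 0
  ri3 <- ratio_map(blue2, red3, red_floor = 0.1, gray_bounds = c(1, 2))
  roi3 <- roi; roi3[1, ] <- FALSE
  expect_equal(mean_gray(ri3, roi3), mean_gray(ri2, roi3))

  # ROI disjoint from valid pixels errors
  roi_bad <- matrix(FALSE, 10, 10); roi_bad[1, 1] <- TRUE
  expect_error(mean_gray(ri3, roi_bad), "valid")
})

test_that("relative oxygenation normalizes to the stated reference", {
  ser <- expand.grid(day = c(0, 3, 6), group = c("t", "c"), replicate = 1:4)
  ser$value <- 0.5
  out <- relative_oxygenation(ser, reference = 0.5)
  expect_true(all(out$mean_pct == 100))
  expect_error(relative_oxygenation(ser, reference = 0), "> 0")
  one <- ser[ser$replicate == 1, ]
  expect_true(all(is.na(relative_oxygenation(one, 0.5)$sem_pct)))
})

test_that("relieved quenching reads out as higher oxygenation every day", {
  days <- c(0, 3, 6)
  ser <- do.call(rbind, lapply(seq_len(4), function(rep) {
    do.call(rbind, lapply(seq_along(days), function(di) {
      base_po2 <- 0.4 + 0.1 * di
      do.call(rbind, lapply(c(treated = 2, control = 1), function(relief) {
        po2 <- matrix(base_po2 * relief, 24, 24)
        pair <- simulate_ratiometric_images(po2, ksv = 1,
                                            backgrounds = c(0.05, 0.05),
                                            noise_sd = 0.01,
                                            seed = rep * 100 + di * 10 +
                                              round(relief))
        corr <- subtract_background(pair)
        ri <- ratio_map(corr$blue, corr$red, red_floor = 0.05,
                        gray_bounds = c(1, 4))
        data.frame(day = days[di],
                   group = if (relief == 2) "treated" else "control",
                   replicate = rep,
                   value = mean_gray(ri, matrix(TRUE, 24, 24)))
      }))
    }))
  }))
  ref <- mean(ser$value[ser$day == 0 & ser$group == "control"])
  out <- relative_oxygenation(ser, reference = ref)
  for (d in days) {
    expect_gt(out$mean_pct[out$day == d & out$group == "treated"],
              out$mean_pct[out$day == d & out$group == "control"])
  }
})
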