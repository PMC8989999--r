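test_that("segmentation recovers planted non-overlapping rods", {
  sim <- simulate_images(image_spec(n_cells = 5, seed = 3))
  masks <- segment_cells(sim$image, 0.1)
  expect_length(masks, 5)
  expect_identical(segment_cells(matrix(0, 64, 64), 0.1), list())
})

test_that("rendered images are seed-deterministic", {
  spec <- image_spec(n_cells = 4, psf_sigma = 1, noise_model = "gaussian",
                     noise_sd = 2, seed = 17)
  expect_identical(simulate_images(spec), simulate_images(spec))
})

test_that("a single horizontal rod rasterizes to the expected extent", {
  # 3 um x 0.8 um at 0.1 um/px -> 30 x 8 px bounding box (+/- 1 px)
  spec <- image_spec(image_size = 64, n_cells = 1,
                     cell_length_range = c(3, 3),
                     cell_width_range = c(0.8, 0.8), seed = 2)
  sim <- simulate_images(spec)
  mask <- sim$image > 50
  pts <- which(mask, arr.ind = TRUE)
  ext <- c(diff(range(pts[, 1])), diff(range(pts[, 2]))) + 1
  th <- sim$cells$theta[1]
  # spherocylinder bounding box: (L - w)|cos|, (L - w)|sin| plus w caps
  expect_lt(abs(ext[2] - (22 * abs(cos(th)) + 8)), 2)
  expect_lt(abs(ext[1] - (22 * abs(sin(th)) + 8)), 2)
})

test_that("overcrowded placement errors out", {
  expect_error(simulate_images(image_spec(image_size = 64, n_cells = 60,
                                          seed = 1)),
               "overlap")
})

test_that("segmentation count survives Poisson noise at good SNR", {
  spec <- image_spec(n_cells = 5, fg = 200, bg = 10, psf_sigma = 1,
                     noise_model = "poisson", seed = 5)
  sim <- simulate_images(spec)
  expect_length(segment_cells(sim$image, 0.1), 5)
})

test_that("shape measures match planted geometry within 2 px", {
  tol <- 0.2  # 2 px at 0.1 um/px
  for (s in c(3, 10, 15)) {
    sim <- simulate_images(image_spec(n_cells = 5, seed = s))
    masks <- segment_cells(sim$image, 0.1)
    sh <- do.call(rbind, lapply(masks, measure_shape, pixel_size = 0.1))
    for (i in seq_len(nrow(sh))) {
      j <- which.min((sim$cells$x_px - sh$x_px[i])^2 +
                     (sim$cells$y_px - sh$y_px[i])^2)
      expect_lt(abs(sh$length[i] - sim$cells$length_um[j]), tol)
      expect_lt(abs(sh$width[i] - sim$cells$width_um[j]), tol)
    }
  }
})

test_that("hand-built masks give exact shape descriptors", {
  # 30 x 8 px rectangle at 0.1 um/px: area 2.4 um^2, straight axis
  m <- matrix(FALSE, 50, 50); m[20:27, 10:39] <- TRUE
  sh <- measure_shape(m, 0.1)
  expect_equal(sh$area, 2.4)
  expect_equal(sh$curvature, 0)
  expect_lt(abs(sh$length - 3.0), 0.2)
  # straight 1-px line: curvature and angularity exactly 0
  m2 <- matrix(FALSE, 20, 20); m2[10, 5:14] <- TRUE
  sh2 <- measure_shape(m2, 0.1)
  expect_equal(sh2$curvature, 0)
  expect_equal(sh2$angularity, 0)
  # semicircular arc: curvature ~ 1 - 2/pi = 0.363
  th <- seq(0, pi, length.out = 200)
  rr <- round(25 + 15 * sin(th)); cc <- round(25 + 15 * cos(th))
  m3 <- matrix(FALSE, 50, 50); m3[cbind(rr, cc)] <- TRUE
  expect_lt(abs(measure_shape(m3, 0.1)$curvature - (1 - 2 / pi)), 0.03)
  expect_error(measure_shape(matrix(c(TRUE, rep(FALSE, 24)), 5, 5), 0.1),
               "degenerate")
})

test_that("gates match brute-force interval evaluation", {
  gates <- shape_gates()
  mid <- data.frame(area = 2, length = 3, width = 0.8, curvature = 0.05,
                    angularity = 0.1)
  shapes <- rbind(mid,
                  transform(mid, length = 1.0),   # below 1.2 um
                  transform(mid, area = 0.05),    # below 0.1 um^2
                  transform(mid, width = 1.5))    # above 1 um
  kept <- apply_gates(shapes, gates)
  expect_equal(nrow(kept), 1)
  expect_equal(attr(kept, "rejections")[["length"]], 1)
  # brute force over every row and gate
  g <- unclass(gates)
  brute <- vapply(seq_len(nrow(shapes)), function(i)
    all(vapply(names(g), function(nm)
      shapes[[nm]][i] >= g[[nm]][1] && shapes[[nm]][i] <= g[[nm]][2],
      logical(1))), logical(1))
  expect_equal(nrow(kept), sum(brute))
})

test_that("gating is idempotent and monotone in gate width", {
  set.seed(4)
  shapes <- data.frame(area = runif(50, 0, 4), length = runif(50, 0.5, 6),
                       width = runif(50, 0, 1.5),
                       curvature = runif(50, 0, 0.3),
                       angularity = runif(50, 0, 0.4))
  g <- shape_gates()
  once <- apply_gates(shapes, g)
  twice <- apply_gates(once, g)
  expect_equal(nrow(once), nrow(twice))
  looser <- shape_gates(area_range = c(0, Inf), length_range = c(0, 10),
                        width_range = c(0, 2), curvature_range = c(0, 1),
                        angularity_range = c(0, 1))
  expect_true(all(rownames(once) %in% rownames(apply_gates(shapes, looser))))
})

test_that("intensity extraction averages over the mask", {
  m1 <- matrix(FALSE, 10, 10); m1[2:4, 2:4] <- TRUE
  m2 <- matrix(FALSE, 10, 10); m2[7:9, 7:9] <- TRUE
  uniform <- matrix(7, 10, 10)
  planted <- matrix(10, 10, 10); planted[m1] <- 100
  rec <- extract_intensities(list(m1, m2), list(gfp = uniform, mch = planted),
                             field = 2L)
  expect_equal(rec$gfp_raw, c(7, 7))
  expect_equal(rec$mch_raw, c(100, 10))
  expect_equal(names(rec), c("cell_id", "field", "gfp_raw", "mch_raw"))
  expect_error(extract_intensities(list(m1), list(g = matrix(0, 5, 5))),
               "dimensions")
})
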