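uniform_cutout <- function(px, mask = NULL) {
  mask <- mask %||% matrix(1, nrow(px), ncol(px))
  structure(list(pixels = px, mask = mask, offset = c(row = 1, col = 1),
                 rescaled = TRUE),
            class = "cutout_image")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("square_median matches the textbook median and a sort oracle", {
  cut <- uniform_cutout(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(as.numeric(square_median(cut, c(1, 1), 2)), 2.5)

  cut7 <- uniform_cutout(matrix(7, 10, 10))
  expect_equal(as.numeric(square_median(cut7, c(3, 3), 4)), 7)

  set.seed(14)
  px <- matrix(sample(0:65535, 400 * 400, replace = TRUE), 400, 400)
  cut <- uniform_cutout(px)
  for (k in 1:50) {
    corner <- c(sample(1:350, 1), sample(1:350, 1))
    v <- px[corner[1]:(corner[1] + 49), corner[2]:(corner[2] + 49)]
    s <- sort(as.vector(v))  # full-sort oracle
    oracle <- (s[1250] + s[1251]) / 2
    expect_identical(as.numeric(square_median(cut, corner, 50)), oracle)
  }
})

test_that("square_median excludes mask-background pixels and reports them", {
  px <- matrix(100, 6, 6)
  px[1:3, ] <- 0
  mask <- matrix(1, 6, 6); mask[1:3, ] <- 0
  cut <- uniform_cutout(px, mask)
  m <- square_median(cut, c(1, 1), 6)
  expect_equal(as.numeric(m), 100)
  expect_equal(attr(m, "n_excluded"), 18L)
  expect_error(square_median(cut, c(5, 5), 6),
               class = "ebtbr_placement_error")
})

make_placement <- function(cut, seed, side) {
  place_squares(cut, seed, define_roi(cut), side = side)
}

test_that("compute_tbr follows the normalized median ratio formula", {
  # quadrant-wise constant image: target 2000, background 1000, norms 500
  px <- matrix(500, 200, 200)
  px[1:100, 101:200] <- 2000   # upper right = target side
  px[1:100, 1:100] <- 1000     # upper left = background side
  cut <- uniform_cutout(px)
  sq <- make_placement(cut, c(30, 150), 20)
  res <- compute_tbr(cut, sq, animal_id = "x", group_label = "g")
  expect_equal(res$median_target, 2000)
  expect_equal(res$median_background, 1000)
  expect_equal(res$tbr, 2.0)
  # identity: tbr == (m_t * m_nc) / (m_b * m_ni)
  expect_equal(res$tbr,
               res$median_target * res$median_norm_contra /
                 (res$median_background * res$median_norm_ipsi))

  flat <- uniform_cutout(matrix(1234, 200, 200))
  expect_equal(compute_tbr(flat, make_placement(flat, c(30, 150), 20))$tbr, 1)
})

test_that("compute_tbr errors on zero medians, naming the square", {
  px <- matrix(1000, 200, 200)
  px[1:60, 101:200] <- 0   # zero target region (mask still foreground)
  cut <- uniform_cutout(px)
  sq <- make_placement(cut, c(30, 150), 20)
  err <- tryCatch(compute_tbr(cut, sq), error = identity)
  expect_s3_class(err, "ebtbr_degenerate_error")
  expect_match(conditionMessage(err), "target")
})

test_that("single-normalizer mode normalizes both sides by the ipsilateral square", {
  px <- matrix(500, 200, 200)
  px[101:200, 1:100] <- 250   # contralateral bottom darker
  px[1:100, 101:200] <- 2000
  px[1:100, 1:100] <- 1000
  cut <- uniform_cutout(px)
  sq <- make_placement(cut, c(30, 150), 20)
  per_side <- compute_tbr(cut, sq)
  single <- compute_tbr(cut, sq, single_normalizer = TRUE)
  expect_equal(per_side$tbr, (2000 / 500) / (1000 / 250))
  expect_equal(single$tbr, (2000 / 500) / (1000 / 500))
})

test_that("TBR is invariant under positive scaling of the cutout", {
  ph <- small_phantom(leak_ratio = 1.4, noise_sd = 500, seed = 6)
  a <- assess_phantom(ph)
  cut <- a$cutout
  sq <- a$placement
  base <- compute_tbr(cut, sq)$tbr
  for (k in c(0.5, 3)) {
    cut2 <- cut
    cut2$pixels <- cut$pixels * k
    expect_equal(compute_tbr(cut2, sq)$tbr, base, tolerance = 1e-12)
  }
})

test_that("pipeline recovers the constructed leak ratio on noiseless phantoms", {
  ph <- small_phantom(leak_ratio = 1.5, noise_sd = 0, seed = 5)
  a <- assess_phantom(ph)
  expect_equal(a$result$tbr, 1.5, tolerance = 1e-9)
})

test_that("swapping hemispheres inverts the TBR exactly (noiseless)", {
  ph <- small_phantom(leak_ratio = 1.8, noise_sd = 0, seed = 9)
  a <- assess_phantom(ph)
  # reading 1: mirrored image, seed kept at the same pixel coordinates ->
  # the target samples the contralateral tissue, so TBR inverts
  am <- assess_image(mirror_slice(ph$image), ph$truth$seed_point,
                     cfg = filter_config("intensity"), side = side_for(0.25))
  expect_lt(abs(a$result$tbr * am$result$tbr - 1), 1e-9)
  # reading 2: mirrored image AND co-mirrored seed -> the target follows
  # the leak, so TBR is unchanged
  cols <- dim(ph$image$pixels)[2]
  seed2 <- c(ph$truth$seed_point[1], cols - ph$truth$seed_point[2] + 1)
  am2 <- assess_image(mirror_slice(ph$image), seed2,
                      cfg = filter_config("intensity"),
                      side = side_for(0.25))
  expect_equal(am2$result$tbr, a$result$tbr, tolerance = 1e-9)
})

test_that("batch_tbr isolates per-row failures and is deterministic", {
  ph1 <- small_phantom(leak_ratio = 1.3, noise_sd = 800, seed = 2)
  ph2 <- small_phantom(leak_ratio = 1.0, noise_sd = 800, seed = 3)
  runs <- list(
    list(image = ph1$image, seed = ph1$truth$seed_point, id = "a",
         group = "g1"),
    list(path = "missing_file.tif", seed = c(10, 10), id = "broken",
         group = "g1"),
    list(image = ph2$image, seed = ph2$truth$seed_point, id = "b",
         group = "g2"))
  res <- batch_tbr(runs, cfg = filter_config("intensity"),
                   side = side_for(0.25))
  expect_equal(nrow(res), 3)
  expect_equal(res$animal_id, c("a", "broken", "b"))
  expect_true(is.na(res$error[1]) && is.na(res$error[3]))
  expect_false(is.na(res$error[2]))
  expect_true(is.na(res$tbr[2]))
  # same image listed twice -> identical values
  res2 <- batch_tbr(list(runs[[1]], runs[[1]]),
                    cfg = filter_config("intensity"), side = side_for(0.25))
  expect_identical(res2$tbr[1], res2$tbr[2])
})

test_that("a cohort batch yields one labelled row per animal", {
  shared <- phantom_params(rows = 104, cols = 140)
  cohort <- generate_cohort(shared = shared, seed = 4)
  runs <- lapply(cohort, function(e)
    list(image = e$image, seed = e$truth$seed_point, id = e$id,
         group = e$label))
  res <- batch_tbr(runs, cfg = filter_config("intensity"),
                   side = side_for(0.1))
  expect_equal(nrow(res), 26)
  expect_equal(as.vector(table(res$group)[c("DHC", "sham", "ET1", "SD")]),
               c(8, 6, 7, 5))
  expect_true(all(is.na(res$error)))
})
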