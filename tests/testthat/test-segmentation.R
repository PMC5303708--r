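test_that("perfectly separable point masses are thresholded exactly", {
  colors <- rbind(matrix(rep(c(100, 80, 60), each = 20), ncol = 3),
                  matrix(rep(c(40, 120, 50), each = 20), ncol = 3))
  is_soil <- rep(c(TRUE, FALSE), each = 20)
  for (space in c("HSV", "RGB")) {
    thr <- learn_soil_threshold(colors, is_soil, channel_space = space)
    x <- canopywtc:::.to_space(colors, space)
    inside <- x[, 1] >= thr$lower[1] & x[, 1] <= thr$upper[1] &
              x[, 2] >= thr$lower[2] & x[, 2] <= thr$upper[2] &
              x[, 3] >= thr$lower[3] & x[, 3] <= thr$upper[3]
    expect_true(all(inside == is_soil)) # 100% training accuracy
  }
})

test_that("disjoint color boxes are separated with >= 99% accuracy", {
  withr::with_seed(11, {
    soil <- cbind(runif(200, 90, 130), runif(200, 70, 100),
                  runif(200, 50, 80))
    plant <- cbind(runif(200, 30, 80), runif(200, 110, 160),
                   runif(200, 30, 70))
  })
  colors <- rbind(soil, plant)
  is_soil <- rep(c(TRUE, FALSE), each = 200)
  thr <- learn_soil_threshold(colors, is_soil, channel_space = "RGB")
  # brute-force check of every training pixel against the learned bounds
  inside <- apply(colors, 1, function(v)
    all(v >= thr$lower) && all(v <= thr$upper))
  accuracy <- mean(inside == is_soil)
  expect_gte(accuracy, 0.99)
})

test_that("single-class training sets raise a training error", {
  colors <- matrix(runif(30, 0, 255), ncol = 3)
  expect_error(learn_soil_threshold(colors, rep(TRUE, 10)), "both soil")
  expect_error(learn_soil_threshold(colors, rep(FALSE, 10)), "both soil")
})

test_that("remove_background matches a pixelwise bounds oracle", {
  sq <- make_square_scene()
  tp <- list(colors = rbind(matrix(rep(c(110, 85, 65), each = 30), ncol = 3),
                            matrix(rep(c(60, 120, 50), each = 30), ncol = 3)),
             is_soil = rep(c(TRUE, FALSE), each = 30))
  thr <- learn_soil_threshold(tp$colors, tp$is_soil)
  fg <- remove_background(sq$image, thr)
  expect_identical(fg, sq$in_square)

  # image entirely of the trained soil color -> all background
  soil_img <- rgb_image(array(rep(c(110, 85, 65), each = 25),
                              dim = c(5, 5, 3)))
  expect_false(any(remove_background(soil_img, thr)))

  # zero-width bounds matching no pixel -> all foreground
  thr0 <- soil_threshold(c(10, 10, 10), c(10, 10, 10),
                         channel_space = "RGB")
  expect_true(all(remove_background(sq$image, thr0)))
})

test_that("decorrelation stretch reduces channel correlations", {
  px <- array(0L, dim = c(10, 10, 3))
  cols <- rbind(matrix(rep(c(60, 100, 40), each = 50), ncol = 3),
                matrix(rep(c(80, 90, 50), each = 50), ncol = 3))
  # add mild jitter so the covariance has full rank
  cols <- withr::with_seed(3, pmin(pmax(cols + rnorm(300, 0, 2), 0), 255))
  for (ch in 1:3) px[, , ch] <- matrix(round(cols[, ch]), 10, 10)
  img <- rgb_image(px)
  fg <- matrix(TRUE, 10, 10)
  st <- stretch_colors(img, fg, method = "decorrelation")
  expect_false(isTRUE(st$params$fallback))
  pre <- abs(cor(cols))
  post_cols <- cbind(st$image$pixels[, , 1][fg], st$image$pixels[, , 2][fg],
                     st$image$pixels[, , 3][fg])
  post <- abs(cor(post_cols))
  for (i in 1:2) for (j in (i + 1):3)
    expect_lte(post[i, j], pre[i, j] + 1e-8)
  # each output channel spans the full range
  expect_true(all(apply(post_cols, 2, min) <= 1))
  expect_true(all(apply(post_cols, 2, max) >= 254))
})

test_that("rank-deficient covariance falls back to the percentile stretch", {
  ramp <- array(0L, dim = c(4, 16, 3))
  for (ch in 1:3) ramp[, , ch] <- matrix(rep(seq(40, 190, 10), each = 4),
                                         4, 16)
  img <- rgb_image(ramp) # R = G = B: perfectly correlated
  st <- stretch_colors(img, matrix(TRUE, 4, 16), method = "decorrelation")
  expect_true(st$params$fallback)
  expect_equal(st$params$method, "percentile")
  ref <- stretch_colors(img, matrix(TRUE, 4, 16), method = "percentile")
  expect_equal(st$image$pixels, ref$image$pixels)
})

test_that("constant-color foreground maps to the midpoint, no div by zero", {
  img <- rgb_image(array(rep(c(70, 90, 50), each = 9), dim = c(3, 3, 3)))
  st <- stretch_colors(img, matrix(TRUE, 3, 3), method = "percentile")
  expect_true(all(st$image$pixels == 128))
})

test_that("background pixels pass through the stretch unmodified", {
  sq <- make_square_scene()
  fg <- sq$in_square
  st <- stretch_colors(sq$image, fg, method = "percentile")
  for (ch in 1:3)
    expect_identical(st$image$pixels[, , ch][!fg],
                     sq$image$pixels[, , ch][!fg])
})

test_that("k-means closed forms hold at k = 1 and k = N", {
  withr::with_seed(5, x <- matrix(rnorm(60, 100, 30), ncol = 3))
  km1 <- kmeans_cluster(x, k = 1, seed = 2)
  expect_equal(as.numeric(km1$centroids), colMeans(x))
  expect_equal(km1$sse, sum(sweep(x, 2, colMeans(x))^2))

  kmN <- kmeans_cluster(x, k = nrow(x), seed = 2)
  expect_equal(kmN$sse, 0)
  expect_equal(sort(kmN$assignment), seq_len(nrow(x)))
})

test_that("planted 3-cluster partition is recovered and locally optimal", {
  centers <- rbind(c(30, 30, 30), c(120, 200, 90), c(180, 160, 60))
  withr::with_seed(8, {
    x <- do.call(rbind, lapply(1:3, function(i)
      sweep(matrix(runif(30, -2, 2), 10, 3), 2, centers[i, ], "+")))
  })
  planted <- rep(1:3, each = 10)
  km <- kmeans_cluster(x, k = 3, seed = 4)
  # partition equality up to label permutation
  expect_equal(length(unique(paste(km$assignment, planted))), 3)
  # oracle: no single-point relocation lowers the SSE
  sse_of <- function(assign) {
    sum(vapply(1:3, function(j) {
      pts <- x[assign == j, , drop = FALSE]
      if (!nrow(pts)) return(0)
      sum(sweep(pts, 2, colMeans(pts))^2)
    }, numeric(1)))
  }
  base <- sse_of(km$assignment)
  expect_equal(base, km$sse, tolerance = 1e-8)
  for (i in seq_len(nrow(x))) for (j in 1:3) {
    if (km$assignment[i] == j) next
    moved <- km$assignment
    moved[i] <- j
    expect_gte(sse_of(moved), base - 1e-9)
  }
})

test_that("k-means is deterministic and its SSE trace non-increasing", {
  withr::with_seed(21, x <- matrix(runif(900, 0, 255), ncol = 3))
  a <- kmeans_cluster(x, k = 4, seed = 13)
  b <- kmeans_cluster(x, k = 4, seed = 13)
  expect_identical(a$centroids, b$centroids)
  expect_identical(a$assignment, b$assignment)
  expect_true(all(diff(a$sse_trace) <= 1e-9))
  # every point sits with its nearest centroid (ties -> lowest index)
  d2 <- as.matrix(dist(rbind(x, a$centroids)))^2
  d2 <- d2[seq_len(nrow(x)), nrow(x) + seq_len(4)]
  expect_equal(a$assignment, max.col(-d2, ties.method = "first"))
})

test_that("k-means agrees with an independent implementation on SSE", {
  centers <- rbind(c(20, 20, 20), c(120, 180, 90), c(220, 60, 150))
  withr::with_seed(31, {
    x <- do.call(rbind, lapply(1:3, function(i)
      sweep(matrix(rnorm(45, 0, 4), 15, 3), 2, centers[i, ], "+")))
  })
  ours <- kmeans_cluster(x, k = 3, seed = 9)
  ref <- stats::kmeans(x, centers = 3, nstart = 25)
  # well-separated clusters: both reach the same global optimum
  expect_equal(ours$sse, ref$tot.withinss, tolerance = 1e-8)
})

test_that("k-means input contracts are enforced", {
  x <- matrix(1:12, ncol = 3)
  expect_error(kmeans_cluster(x, k = 5), "N >= k")
  x[1] <- NA
  expect_error(kmeans_cluster(x, k = 2), "non-finite")
})

test_that("cluster-to-class mapping follows the hand distance table", {
  centroids <- rbind(c(60, 120, 50),    # exactly green prototype
                     c(150, 135, 70),   # nearest dead
                     c(112, 88, 64),    # nearest background
                     c(70, 110, 55))    # nearest green
  protos <- list(class_prototype(CLASS_GREEN, c(60, 120, 50)),
                 class_prototype(CLASS_DEAD, c(160, 140, 60)),
                 class_prototype(CLASS_BACKGROUND, c(110, 85, 65)))
  # hand oracle: full 4 x 3 distance table
  pm <- rbind(c(60, 120, 50), c(160, 140, 60), c(110, 85, 65))
  expected_lab <- apply(centroids, 1, function(v)
    c(CLASS_GREEN, CLASS_DEAD, CLASS_BACKGROUND)[
      which.min(colSums((t(pm) - v)^2))])
  fg <- matrix(TRUE, 2, 2)
  km <- structure(list(k = 4, centroids = centroids, assignment = 1:4,
                       sse = 0, seed = 1), class = "kmeans_result")
  mask <- assign_classes(km, protos, fg)
  expect_equal(as.vector(mask$labels), expected_lab)
})

test_that("prototype ties resolve green before dead, and masks are forced
           to background outside the foreground", {
  protos <- list(class_prototype(CLASS_GREEN, c(0, 0, 0)),
                 class_prototype(CLASS_DEAD, c(100, 0, 0)))
  km <- structure(list(k = 1, centroids = matrix(c(50, 0, 0), 1),
                       assignment = rep(1L, 2), sse = 0, seed = 1),
                  class = "kmeans_result") # equidistant from both
  fg <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  mask <- assign_classes(km, protos, fg)
  expect_equal(mask$labels[fg], rep(CLASS_GREEN, 2))
  expect_equal(mask$labels[!fg], rep(CLASS_BACKGROUND, 2))
})

test_that("missing required prototypes raise a configuration error", {
  km <- kmeans_cluster(matrix(runif(30), ncol = 3), k = 2, seed = 1)
  expect_error(
    assign_classes(km, list(class_prototype(CLASS_GREEN, c(1, 2, 3))),
                   matrix(TRUE, 2, 5)),
    "green and dead")
})

test_that("segment_plant recovers known scene composition within 2 points", {
  run <- segment_synthetic_scene(scene_spec(seed = 17))
  truth <- to_percentages(run$scene$truth_counts)$of_image
  est <- run$result$percentages$of_image
  expect_lt(abs(est[["green"]] - truth[["green"]]), 2)
  expect_lt(abs(est[["dead"]] - truth[["dead"]]), 2)
})

test_that("an all-soil image yields 100% background with a warning flag", {
  spec <- scene_spec(n_green = 0, n_dead = 0, color_sd = 0, seed = 3)
  run <- segment_synthetic_scene(spec)
  expect_equal(run$result$percentages$of_image[["background"]], 100)
  expect_true("zero_foreground" %in% run$result$warnings)
  expect_true(all(is.na(run$result$percentages$of_plant)))
})

test_that("segmentation is a pure function of image, config and seed", {
  spec <- scene_spec(seed = 23)
  a <- segment_synthetic_scene(spec)
  b <- segment_synthetic_scene(spec)
  expect_identical(a$result$mask$labels, b$result$mask$labels)
})

test_that("pixel-cap subsampling still assigns every pixel exactly", {
  spec <- scene_spec(width = 64, height = 64, leaf_axes = c(8, 20),
                     seed = 5)
  sc <- generate_scene(spec)
  tp <- scene_training_pixels(spec, seed = 5)
  thr <- learn_soil_threshold(tp$colors, tp$is_soil)
  cfg_full <- segmentation_config(thr, seed = 2)
  cfg_cap <- segmentation_config(thr, seed = 2, pixel_cap = 500L)
  full <- segment_plant(sc$image, cfg_full)
  capped <- segment_plant(sc$image, cfg_cap)
  # counts conserve and all classes stay within the label set
  expect_equal(capped$counts$total_pixels, 64 * 64)
  truth <- to_percentages(sc$truth_counts)$of_image
  expect_lt(abs(capped$percentages$of_image[["green"]] - truth[["green"]]), 4)
  expect_identical(full$counts$total_pixels, capped$counts$total_pixels)
})

test_that("minimum-region cleanup removes speckles", {
  skip_if_not_installed("EBImage")
  sq <- make_square_scene(h = 30, w = 30, side = 10)
  px <- sq$image$pixels
  px[1, 1, ] <- c(60L, 120L, 50L) # single-pixel plant speckle
  img <- rgb_image(px)
  tp <- list(colors = rbind(matrix(rep(c(110, 85, 65), each = 30), ncol = 3),
                            matrix(rep(c(60, 120, 50), each = 30), ncol = 3)),
             is_soil = rep(c(TRUE, FALSE), each = 30))
  thr <- learn_soil_threshold(tp$colors, tp$is_soil)
  cfg <- segmentation_config(thr, k = 2, seed = 1, min_region_size = 5L,
    prototypes = list(class_prototype(CLASS_GREEN, c(60, 120, 50)),
                      class_prototype(CLASS_DEAD, c(160, 140, 60))))
  seg <- segment_plant(img, cfg)
  expect_equal(seg$mask$labels[1, 1], CLASS_BACKGROUND)
  expect_equal(seg$counts$pixels_green, 100)
})
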