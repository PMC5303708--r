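# Segmentation pipeline: background threshold -> color stretch -> seeded
# k-means -> prototype class assignment. Works on one overhead frame at a
# time (one plant per image).

.channel_range <- function(channel_space) {
  # HSV channels are kept on [0, 1] (grDevices::rgb2hsv convention);
  # RGB on [0, 255].
  if (channel_space == "HSV") c(0, 1) else c(0, 255)
}

# N x 3 matrix of RGB values (0-255) -> N x 3 in the working space
.to_space <- function(colors, channel_space) {
  if (channel_space == "RGB") return(colors)
  t(grDevices::rgb2hsv(t(colors), maxColorValue = 255))
}

#' Soil color-threshold model
#'
#' Per-channel inclusive bounds defining the color volume treated as soil /
#' background. A pixel is background iff every channel (after conversion to
#' `channel_space`) lies within its bounds.
#'
#' @param lower,upper numeric length-3 vectors of per-channel bounds
#'   (inclusive); `lower <= upper` channel-wise. RGB bounds live on
#'   \[0, 255\], HSV bounds on \[0, 1\].
#' @param channel_space `"HSV"` (default elsewhere; soil separates mainly by
#'   hue and saturation under varying field illumination) or `"RGB"`.
#' @return An object of class `soil_threshold`.
#' @export
soil_threshold <- function(lower, upper, channel_space = c("HSV", "RGB")) {
  channel_space <- match.arg(channel_space)
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L)
    stop("lower and upper must each have 3 channels", call. = FALSE)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower > upper))
    stop("bounds must be finite with lower <= upper per channel",
         call. = FALSE)
  rng <- .channel_range(channel_space)
  if (any(lower < rng[1]) || any(upper > rng[2]))
    stop("bounds outside the representable range for ", channel_space,
         call. = FALSE)
  structure(list(lower = lower, upper = upper,
                 channel_space = channel_space),
            class = "soil_threshold")
}

#' Learn a soil-background color threshold from labeled pixels
#'
#' Fits a per-channel percentile envelope (`trim` = \[p1, p99\] by default)
#' around the soil training pixels, then tightens each bound toward the soil
#' median until no plant pixel remains inside the volume or the bound would
#' cross a floor width. Each tightening step moves the one bound whose move
#' sacrifices the fewest soil training pixels.
#'
#' @param colors N x 3 matrix of RGB training colors (0-255).
#' @param is_soil logical vector of length N; `TRUE` for soil pixels.
#' @param channel_space working space for the threshold, `"HSV"` or `"RGB"`.
#' @param trim lower/upper percentiles of the initial soil envelope.
#' @param floor_width minimum per-channel box width retained during
#'   tightening, as a fraction of the initial envelope width.
#' @return A [soil_threshold()].
#' @export
learn_soil_threshold <- function(colors, is_soil,
                                 channel_space = c("HSV", "RGB"),
                                 trim = c(1, 99), floor_width = 0.1) {
  channel_space <- match.arg(channel_space)
  colors <- as.matrix(colors)
  if (nrow(colors) != length(is_soil))
    stop("colors and is_soil lengths differ", call. = FALSE)
  if (!any(is_soil) || all(is_soil))
    stop("training set must contain both soil and plant pixels",
         call. = FALSE)
  x <- .to_space(colors, channel_space)
  soil <- x[is_soil, , drop = FALSE]
  plant <- x[!is_soil, , drop = FALSE]

  lower <- apply(soil, 2, stats::quantile, probs = trim[1] / 100, names = FALSE)
  upper <- apply(soil, 2, stats::quantile, probs = trim[2] / 100, names = FALSE)
  med <- apply(soil, 2, stats::median)
  min_width <- pmax(upper - lower, .Machine$double.eps) * floor_width

  inside <- function(pts, lo, hi) {
    pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
    pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
    pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
  }

  # Greedy tightening: each step excludes at least one violating plant pixel
  # at the cheapest cost in enclosed soil pixels.
  eps <- 1e-9
  repeat {
    viol <- plant[inside(plant, lower, upper), , drop = FALSE]
    if (nrow(viol) == 0L) break
    best <- NULL
    for (ch in 1:3) {
      # raise lower bound just past the smallest violating value
      cand_lo <- min(viol[, ch]) + eps
      if (cand_lo <= med[ch] && (upper[ch] - cand_lo) >= min_width[ch]) {
        cost <- sum(soil[, ch] >= lower[ch] & soil[, ch] < cand_lo)
        if (is.null(best) || cost < best$cost)
          best <- list(cost = cost, ch = ch, side = "lo", val = cand_lo)
      }
      # lower upper bound just past the largest violating value
      cand_hi <- max(viol[, ch]) - eps
      if (cand_hi >= med[ch] && (cand_hi - lower[ch]) >= min_width[ch]) {
        cost <- sum(soil[, ch] <= upper[ch] & soil[, ch] > cand_hi)
        if (is.null(best) || cost < best$cost)
          best <- list(cost = cost, ch = ch, side = "hi", val = cand_hi)
      }
    }
    if (is.null(best)) break # floor reached; accept residual violations
    if (best$side == "lo") lower[best$ch] <- best$val else
      upper[best$ch] <- best$val
  }
  # relaxation pass: grow each bound back toward the soil extremes wherever
  # that admits no plant pixel, maximizing enclosed soil subject to
  # excluding plant where separable
  if (!any(inside(plant, lower, upper))) {
    for (pass in 1:2) for (ch in 1:3) {
      cand <- lower; cand[ch] <- min(soil[, ch])
      adm <- plant[inside(plant, cand, upper), ch]
      lower[ch] <- if (length(adm)) min(lower[ch], max(adm) + eps) else
        cand[ch]
      cand <- upper; cand[ch] <- max(soil[, ch])
      adm <- plant[inside(plant, lower, cand), ch]
      upper[ch] <- if (length(adm)) max(upper[ch], min(adm) - eps) else
        cand[ch]
    }
  }
  rng <- .channel_range(channel_space)
  soil_threshold(pmax(lower, rng[1]), pmin(upper, rng[2]), channel_space)
}

#' Remove the soil background from an image
#'
#' @param img an [rgb_image()].
#' @param model a [soil_threshold()].
#' @return A logical H x W matrix; `TRUE` marks foreground (plant) pixels,
#'   i.e. pixels whose color falls outside the soil volume.
#' @export
remove_background <- function(img, model) {
  stopifnot(inherits(img, "rgb_image"), inherits(model, "soil_threshold"))
  colors <- cbind(as.vector(img$pixels[, , 1]),
                  as.vector(img$pixels[, , 2]),
                  as.vector(img$pixels[, , 3]))
  x <- .to_space(colors, model$channel_space)
  bg <- x[, 1] >= model$lower[1] & x[, 1] <= model$upper[1] &
        x[, 2] >= model$lower[2] & x[, 2] <= model$upper[2] &
        x[, 3] >= model$lower[3] & x[, 3] <= model$upper[3]
  matrix(!bg, img$height, img$width)
}

# Affine color transform y = clip(x A + b); stretch parameters keep the
# transform explicit so class prototypes can be pushed through it.
.affine_params <- function(method, A, b, fallback = FALSE,
                           percentiles = NULL) {
  structure(list(method = method, A = A, b = b, fallback = fallback,
                 percentiles = percentiles),
            class = "stretch_params")
}

#' Apply fitted stretch parameters to a color matrix
#'
#' @param params a `stretch_params` object from [stretch_colors()].
#' @param colors N x 3 matrix of colors in the input space (0-255 RGB).
#' @return N x 3 matrix of stretched colors, clipped to \[0, 255\].
#' @export
apply_stretch <- function(params, colors) {
  stopifnot(inherits(params, "stretch_params"))
  y <- sweep(as.matrix(colors) %*% params$A, 2, params$b, "+")
  y[y < 0] <- 0
  y[y > 255] <- 255
  y
}

#' Stretch foreground colors to increase contrast
#'
#' Enhances subtle hue differences before clustering by building a "false
#' color" image. The default `"decorrelation"` method whitens the foreground
#' channel covariance (symmetric inverse-square-root) and rescales each
#' output channel to span \[0, 255\], so output channels are pairwise
#' uncorrelated over the foreground. `"percentile"` maps each channel's low /
#' high percentile to 0 / 255 linearly with clipping. A rank-deficient
#' foreground covariance makes decorrelation fall back to the percentile
#' stretch; the fallback is recorded in the returned parameters.
#'
#' Background pixels pass through unmodified.
#'
#' @param img an [rgb_image()].
#' @param foreground logical H x W foreground mask from
#'   [remove_background()].
#' @param method `"decorrelation"` or `"percentile"`.
#' @param percentiles length-2 low/high percentiles for the percentile
#'   stretch (also used by the fallback).
#' @return A list with `image` (the stretched [rgb_image()]) and `params`
#'   (the fitted `stretch_params`).
#' @export
stretch_colors <- function(img, foreground,
                           method = c("decorrelation", "percentile"),
                           percentiles = c(2, 98)) {
  method <- match.arg(method)
  stopifnot(inherits(img, "rgb_image"), is.matrix(foreground))
  if (!identical(dim(foreground), c(img$height, img$width)))
    stop("foreground mask shape does not match the image", call. = FALSE)
  if (!any(foreground))
    stop("no foreground pixels to stretch", call. = FALSE)
  fg_colors <- cbind(img$pixels[, , 1][foreground],
                     img$pixels[, , 2][foreground],
                     img$pixels[, , 3][foreground])

  percentile_params <- function() {
    lo <- apply(fg_colors, 2, stats::quantile, probs = percentiles[1] / 100,
                names = FALSE)
    hi <- apply(fg_colors, 2, stats::quantile, probs = percentiles[2] / 100,
                names = FALSE)
    gain <- ifelse(hi > lo, 255 / (hi - lo), 0)
    b <- ifelse(hi > lo, -lo * gain, 128) # zero-range channel -> midpoint
    .affine_params("percentile", diag(gain), b, percentiles = percentiles)
  }

  params <- if (method == "percentile") {
    percentile_params()
  } else {
    cv <- stats::cov(fg_colors)
    ev <- eigen(cv, symmetric = TRUE)
    if (nrow(fg_colors) < 4L || min(ev$values) < 1e-8 * max(ev$values, 1)) {
      p <- percentile_params()
      p$fallback <- TRUE
      p
    } else {
      W <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
      mu <- colMeans(fg_colors)
      z <- sweep(fg_colors, 2, mu) %*% W
      zmin <- apply(z, 2, min); zmax <- apply(z, 2, max)
      gain <- ifelse(zmax > zmin, 255 / (zmax - zmin), 0)
      # full affine: y = (x - mu) W diag(gain) - zmin * gain
      A <- W %*% diag(gain)
      b <- -as.numeric(mu %*% A) - zmin * gain + 0
      b <- ifelse(zmax > zmin, b, 128)
      .affine_params("decorrelation", A, b)
    }
  }

  out <- img$pixels
  stretched <- apply_stretch(params, fg_colors)
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[foreground] <- stretched[, ch]
    out[, , ch] <- plane
  }
  list(image = rgb_image(out, source_id = img$source_id), params = params)
}

#' Seeded Lloyd's k-means with k-means++ initialization
#'
#' Deterministic given (data order, seed): k-means++ seeding, Lloyd
#' iterations until the largest centroid movement drops below `tol` or
#' `max_iter` is reached. Each point is assigned to its nearest centroid by
#' Euclidean distance with ties broken toward the lowest centroid index; a
#' cluster emptied during an update is re-seeded to the point currently
#' farthest from its own centroid. The within-cluster sum of squares (SSE)
#' is non-increasing over iterations and its trace is returned.
#'
#' @param x N x d numeric matrix (pixel colors: d = 3).
#' @param k number of clusters, `1 <= k <= N`.
#' @param seed integer seed controlling the initialization.
#' @param max_iter maximum Lloyd iterations.
#' @param tol convergence tolerance on centroid movement (Euclidean).
#' @return An object of class `kmeans_result` with fields `k`, `centroids`
#'   (k x d), `assignment` (length N), `sse`, `sse_trace`, `iterations`,
#'   `seed`.
#' @export
kmeans_cluster <- function(x, k, seed = 1L, max_iter = 100L, tol = 1e-4) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (!all(is.finite(x))) stop("non-finite values in input", call. = FALSE)
  if (k < 1L || n < k) stop("need N >= k >= 1", call. = FALSE)

  dist2_to <- function(centers) {
    # N x k matrix of squared Euclidean distances
    matrix(rowSums(x^2), n, nrow(centers)) -
      2 * x %*% t(centers) +
      matrix(rowSums(centers^2), n, nrow(centers), byrow = TRUE)
  }

  centers <- withr::with_seed(as.integer(seed), {
    idx <- integer(k)
    idx[1] <- sample.int(n, 1L)
    if (k > 1L) for (j in 2:k) {
      d2 <- do.call(pmin, lapply(idx[seq_len(j - 1L)], function(i)
        rowSums(sweep(x, 2, x[i, ])^2)))
      d2[idx[seq_len(j - 1L)]] <- 0
      idx[j] <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else
        setdiff(seq_len(n), idx[seq_len(j - 1L)])[1]
    }
    x[idx, , drop = FALSE]
  })

  sse_trace <- numeric(0)
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to(centers)
    d2[d2 < 0] <- 0
    assign <- max.col(-d2, ties.method = "first")
    sse_trace <- c(sse_trace, sum(d2[cbind(seq_len(n), assign)]))
    agg <- rowsum(x, assign)
    cnt <- tabulate(assign, nbins = k)
    new_centers <- centers
    present <- as.integer(rownames(agg))
    new_centers[present, ] <- agg / cnt[present]
    for (j in which(cnt == 0L)) { # farthest-point re-seeding
      d_own <- d2[cbind(seq_len(n), assign)]
      far <- which.max(d_own)
      new_centers[j, ] <- x[far, ]
      assign[far] <- j
      d2[far, ] <- Inf; d2[far, j] <- 0
    }
    moved <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (moved < tol) break
  }
  # final consistent assignment against the converged centroids
  d2 <- dist2_to(centers)
  d2[d2 < 0] <- 0
  assign <- max.col(-d2, ties.method = "first")
  sse <- sum(d2[cbind(seq_len(n), assign)])
  structure(list(k = k, centroids = centers, assignment = assign,
                 sse = sse, sse_trace = c(sse_trace, sse),
                 iterations = it, seed = as.integer(seed)),
            class = "kmeans_result")
}

#' Class prototype in the working color space
#'
#' @param label one of `CLASS_GREEN`, `CLASS_DEAD`, `CLASS_BACKGROUND`.
#' @param centroid length-3 color vector.
#' @return An object of class `class_prototype`.
#' @export
class_prototype <- function(label, centroid) {
  label <- as.integer(label)
  if (!label %in% c(CLASS_GREEN, CLASS_DEAD, CLASS_BACKGROUND))
    stop("unknown class label", call. = FALSE)
  centroid <- as.numeric(centroid)
  if (length(centroid) != 3L || any(!is.finite(centroid)))
    stop("centroid must be a finite 3-vector", call. = FALSE)
  structure(list(label = label, centroid = centroid),
            class = "class_prototype")
}

#' Default class prototypes (raw RGB)
#'
#' Green leaf (60,120,50), dead/chlorotic leaf (160,140,60) and residual soil
#' (110,85,65): the same palette the synthetic scene generator uses. For real
#' imagery, supply prototypes sampled from the photographs at hand.
#'
#' @return A list of [class_prototype()] objects.
#' @export
default_prototypes <- function() {
  list(class_prototype(CLASS_GREEN, c(60, 120, 50)),
       class_prototype(CLASS_DEAD, c(160, 140, 60)),
       class_prototype(CLASS_BACKGROUND, c(110, 85, 65)))
}

# label priority used for prototype distance ties: GREEN < DEAD < BACKGROUND
.label_priority <- function(label) {
  match(label, c(CLASS_GREEN, CLASS_DEAD, CLASS_BACKGROUND))
}

#' Map k-means clusters to segmentation classes
#'
#' Each cluster centroid takes the label of its nearest prototype (Euclidean
#' distance in the working color space; exact ties resolve in the priority
#' order green, dead, background). Pixels outside the foreground mask are
#' forced to background regardless of their cluster.
#'
#' @param result a [kmeans_cluster()] result fitted on the foreground pixels,
#'   in foreground order (column-major order of `which(foreground)`).
#' @param prototypes list of [class_prototype()]; must include at least one
#'   green and one dead prototype.
#' @param foreground logical H x W foreground mask; `sum(foreground)` must
#'   equal the number of clustered pixels.
#' @param image_source_id identifier stored on the returned mask.
#' @return A [label_mask()].
#' @export
assign_classes <- function(result, prototypes, foreground,
                           image_source_id = "") {
  stopifnot(inherits(result, "kmeans_result"), is.matrix(foreground))
  labs <- vapply(prototypes, function(p) p$label, integer(1))
  if (!all(c(CLASS_GREEN, CLASS_DEAD) %in% labs))
    stop("prototypes must cover at least the green and dead classes",
         call. = FALSE)
  if (sum(foreground) != length(result$assignment))
    stop("foreground pixel count does not match the clustering",
         call. = FALSE)
  ord <- order(vapply(prototypes, function(p) .label_priority(p$label),
                      integer(1)))
  prototypes <- prototypes[ord]
  proto_mat <- t(vapply(prototypes, function(p) p$centroid, numeric(3)))
  proto_lab <- vapply(prototypes, function(p) p$label, integer(1))

  d2 <- matrix(rowSums(result$centroids^2), result$k, nrow(proto_mat)) -
    2 * result$centroids %*% t(proto_mat) +
    matrix(rowSums(proto_mat^2), result$k, nrow(proto_mat), byrow = TRUE)
  cluster_label <- proto_lab[max.col(-d2, ties.method = "first")]

  lab <- matrix(CLASS_BACKGROUND, nrow(foreground), ncol(foreground))
  lab[foreground] <- cluster_label[result$assignment]
  label_mask(lab, image_source_id = image_source_id)
}

#' Segmentation configuration
#'
#' Aggregates every tuning knob of the pipeline. Defaults: HSV soil
#' threshold (supplied by the user or learned), decorrelation stretch,
#' k = 4 clusters (green, dead, shadowed plant, residual soil) mapped onto 3
#' classes, seeded k-means++ with up to 100 iterations, no minimum-region
#' cleanup, and a 200,000-pixel cap on the sample used to fit centroids
#' (final assignment always covers every pixel).
#'
#' @param threshold_model a [soil_threshold()].
#' @param stretch_method `"decorrelation"` or `"percentile"`.
#' @param percentiles percentile pair for the percentile stretch / fallback.
#' @param k number of k-means clusters; must be at least the number of
#'   distinct prototype labels.
#' @param seed integer seed for k-means++ and pixel subsampling.
#' @param max_iter,tol k-means stopping rule.
#' @param prototypes list of [class_prototype()] in raw RGB; they are pushed
#'   through the fitted stretch before distances are measured.
#' @param min_region_size connected components of plant pixels smaller than
#'   this (8-connectivity) are relabeled background; 0 disables cleanup.
#' @param pixel_cap maximum number of foreground pixels used to fit
#'   centroids.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_model,
                                stretch_method = "decorrelation",
                                percentiles = c(2, 98),
                                k = 4L, seed = 1L,
                                max_iter = 100L, tol = 1e-3,
                                prototypes = default_prototypes(),
                                min_region_size = 0L,
                                pixel_cap = 200000L) {
  stopifnot(inherits(threshold_model, "soil_threshold"))
  k <- as.integer(k)
  n_labels <- length(unique(vapply(prototypes, function(p) p$label,
                                   integer(1))))
  if (k < n_labels)
    stop("k must be >= the number of distinct prototype labels",
         call. = FALSE)
  if (max_iter < 1L || tol < 0)
    stop("max_iter must be >= 1 and tol >= 0", call. = FALSE)
  structure(list(threshold_model = threshold_model,
                 stretch_method = match.arg(stretch_method,
                                            c("decorrelation", "percentile")),
                 percentiles = percentiles, k = k, seed = as.integer(seed),
                 max_iter = as.integer(max_iter), tol = tol,
                 prototypes = prototypes,
                 min_region_size = as.integer(min_region_size),
                 pixel_cap = as.integer(pixel_cap)),
            class = "segmentation_config")
}

.config_fingerprint <- function(config) {
  paste0("space=", config$threshold_model$channel_space,
         ";lo=", paste(signif(config$threshold_model$lower, 6), collapse = ","),
         ";hi=", paste(signif(config$threshold_model$upper, 6), collapse = ","),
         ";stretch=", config$stretch_method,
         ";k=", config$k, ";seed=", config$seed,
         ";max_iter=", config$max_iter, ";tol=", config$tol,
         ";min_region=", config$min_region_size,
         ";cap=", config$pixel_cap)
}

# drop plant components (8-connectivity) smaller than min_size pixels
.cleanup_mask <- function(labels, min_size) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    warning("EBImage not available; minimum-region cleanup skipped")
    return(labels)
  }
  plant <- labels != CLASS_BACKGROUND
  cc <- EBImage::imageData(EBImage::bwlabel(plant))
  sizes <- tabulate(cc[cc > 0])
  small <- which(sizes < min_size)
  labels[cc %in% small] <- CLASS_BACKGROUND
  labels
}

#' Segment one overhead plant image
#'
#' Runs the full pipeline: soil-threshold background removal, foreground
#' color stretch, seeded k-means clustering of foreground colors, prototype
#' class assignment, optional minimum-region cleanup, and pixel counting.
#' Deterministic: the same image, configuration and seed always produce the
#' identical mask.
#'
#' An image with zero foreground pixels after thresholding returns an
#' all-background result carrying a `"zero_foreground"` warning flag rather
#' than an error.
#'
#' @param img an [rgb_image()].
#' @param config a [segmentation_config()].
#' @return A `segmentation_result`: see [segmentation_result()].
#' @export
segment_plant <- function(img, config) {
  stopifnot(inherits(img, "rgb_image"),
            inherits(config, "segmentation_config"))
  fg <- remove_background(img, config$threshold_model)
  warnings <- character(0)
  if (!any(fg)) {
    mask <- label_mask(matrix(CLASS_BACKGROUND, img$height, img$width),
                       image_source_id = img$source_id)
    return(segmentation_result(mask, config,
                               warnings = "zero_foreground"))
  }

  st <- stretch_colors(img, fg, method = config$stretch_method,
                       percentiles = config$percentiles)
  if (isTRUE(st$params$fallback))
    warnings <- c(warnings, "stretch_fallback_percentile")
  fg_colors <- cbind(st$image$pixels[, , 1][fg],
                     st$image$pixels[, , 2][fg],
                     st$image$pixels[, , 3][fg])

  n_fg <- nrow(fg_colors)
  k <- min(config$k, n_fg)
  fit_idx <- if (n_fg > config$pixel_cap) {
    withr::with_seed(config$seed,
                     sort(sample.int(n_fg, config$pixel_cap)))
  } else seq_len(n_fg)
  km <- kmeans_cluster(fg_colors[fit_idx, , drop = FALSE], k = k,
                       seed = config$seed, max_iter = config$max_iter,
                       tol = config$tol)
  # exact assignment of every foreground pixel to the fitted centroids
  d2 <- matrix(rowSums(fg_colors^2), n_fg, k) -
    2 * fg_colors %*% t(km$centroids) +
    matrix(rowSums(km$centroids^2), n_fg, k, byrow = TRUE)
  full <- km
  full$assignment <- max.col(-d2, ties.method = "first")

  proto_stretched <- lapply(config$prototypes, function(p)
    class_prototype(p$label,
                    apply_stretch(st$params, matrix(p$centroid, 1))[1, ]))
  mask <- assign_classes(full, proto_stretched, fg,
                         image_source_id = img$source_id)
  if (config$min_region_size > 0L)
    mask <- label_mask(.cleanup_mask(mask$labels, config$min_region_size),
                       image_source_id = img$source_id)
  segmentation_result(mask, config, kmeans = km,
                      stretch_params = st$params, warnings = warnings)
}
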