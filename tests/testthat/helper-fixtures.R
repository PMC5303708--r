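# Shared fixtures and independent oracles, built in code at test time.

# small image with a centered square of plant color on a soil background
make_square_scene <- function(h = 20, w = 20, soil = c(110, 85, 65),
                              plant = c(60, 120, 50), side = 8) {
  px <- array(0L, dim = c(h, w, 3L))
  r0 <- (h - side) %/% 2 + 1; c0 <- (w - side) %/% 2 + 1
  sq_rows <- r0:(r0 + side - 1); sq_cols <- c0:(c0 + side - 1)
  for (ch in 1:3) {
    plane <- matrix(soil[ch], h, w)
    plane[sq_rows, sq_cols] <- plant[ch]
    px[, , ch] <- plane
  }
  in_square <- matrix(FALSE, h, w)
  in_square[sq_rows, sq_cols] <- TRUE
  list(image = rgb_image(px, "square"), in_square = in_square)
}

# a mask with exact class counts, pixels placed deterministically
make_counted_mask <- function(h, w, n_green, n_dead) {
  lab <- matrix(CLASS_BACKGROUND, h, w)
  lab[seq_len(n_green)] <- CLASS_GREEN
  lab[n_green + seq_len(n_dead)] <- CLASS_DEAD
  label_mask(lab)
}

# independent tally oracle: single-pass scan over the label matrix
oracle_counts <- function(mask) {
  g <- d <- b <- 0L
  for (v in as.vector(mask$labels)) {
    if (v == CLASS_GREEN) g <- g + 1L
    else if (v == CLASS_DEAD) d <- d + 1L
    else b <- b + 1L
  }
  c(green = g, dead = d, background = b)
}

# fixed protocol used for segmentation-recovery checks: calibrate the soil
# threshold from labeled samples of the scene's color model, then segment
segment_synthetic_scene <- function(spec, k = 4, seg_seed = spec$seed) {
  sc <- generate_scene(spec)
  tp <- scene_training_pixels(spec, n_per_class = 300, seed = spec$seed)
  thr <- learn_soil_threshold(tp$colors, tp$is_soil)
  cfg <- segmentation_config(thr, k = k, seed = seg_seed)
  list(scene = sc, result = segment_plant(sc$image, cfg), config = cfg)
}

# exhaustive pairwise check that letter sharing <=> |difference| <= LSD
check_letters_against_lsd <- function(lsd_result) {
  gr <- lsd_result$groups
  if (!lsd_result$significant) return(all(gr$letters == gr$letters[1]))
  ok <- TRUE
  for (i in seq_len(nrow(gr))) for (j in seq_len(nrow(gr))) {
    if (i == j) next
    share <- length(intersect(strsplit(gr$letters[i], "")[[1]],
                              strsplit(gr$letters[j], "")[[1]])) > 0
    within_lsd <- abs(gr$mean[i] - gr$mean[j]) <= lsd_result$lsd
    if (share != within_lsd) ok <- FALSE
  }
  ok
}

# closed-form two-sided p for a Pearson r at sample size n
pearson_p_closed_form <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}
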