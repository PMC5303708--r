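# Seeded synthetic inputs: overhead canopy scenes with pixel-exact ground
# truth, and genotype x treatment trait cohorts with controllable effect
# sizes and correlation structure. These stand in for field photographs and
# trial records so every other module is testable without field data.

#' Specification of a synthetic overhead canopy scene
#'
#' A soil-textured frame over which dead then green leaf ellipses are
#' composited (later strokes overwrite earlier: green canopy occludes dead
#' lower leaves, as seen from above on a senescing plant). Default class
#' colors — green (60,120,50), dead (160,140,60), soil (110,85,65), each
#' with sd 5 — are separable yet non-trivial fixture values.
#'
#' @param width,height frame size in pixels, >= 32.
#' @param soil_color,green_color,dead_color mean RGB 3-vectors per class;
#'   must be pairwise distinct.
#' @param color_sd per-pixel per-channel Gaussian color noise sd.
#' @param n_green,n_dead number of green / dead leaf ellipses, >= 0.
#' @param leaf_axes length-2 range of ellipse semi-axes, in pixels; the
#'   larger semi-axis must fit in the frame.
#' @param orientation_range length-2 range of ellipse orientations
#'   (radians).
#' @param illumination_gradient relative amplitude of a linear left-to-right
#'   illumination ramp (0 = flat).
#' @param seed integer seed; all randomness flows from it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 256L, height = 256L,
                       soil_color = c(110, 85, 65),
                       green_color = c(60, 120, 50),
                       dead_color = c(160, 140, 60),
                       color_sd = 5,
                       n_green = 6L, n_dead = 4L,
                       leaf_axes = c(15, 45),
                       orientation_range = c(0, pi),
                       illumination_gradient = 0,
                       seed = 1L) {
  if (width < 32L || height < 32L)
    stop("scene dimensions must be at least 32 pixels", call. = FALSE)
  if (color_sd < 0) stop("color_sd must be >= 0", call. = FALSE)
  if (n_green < 0L || n_dead < 0L)
    stop("leaf counts must be >= 0", call. = FALSE)
  cols <- rbind(soil_color, green_color, dead_color)
  if (anyDuplicated(cols))
    stop("class color means must be pairwise distinct", call. = FALSE)
  if (2 * max(leaf_axes) > min(width, height))
    stop("leaves larger than the frame", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 soil_color = soil_color, green_color = green_color,
                 dead_color = dead_color, color_sd = color_sd,
                 n_green = as.integer(n_green), n_dead = as.integer(n_dead),
                 leaf_axes = leaf_axes,
                 orientation_range = orientation_range,
                 illumination_gradient = illumination_gradient,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# paint one rotated filled ellipse onto labels (in place value `value`);
# returns the updated label matrix
.paint_ellipse <- function(labels, cx, cy, a, b, theta, value) {
  h <- nrow(labels); w <- ncol(labels)
  r <- ceiling(max(a, b))
  rows <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  sub <- labels[rows, cols, drop = FALSE]
  sub[inside] <- value
  labels[rows, cols] <- sub
  labels
}

#' Render a synthetic canopy scene with pixel-exact ground truth
#'
#' Seed-deterministic: identical spec and seed produce identical bytes. The
#' truth mask records the final visible class of every pixel and the truth
#' counts tally that mask exactly.
#'
#' @param spec a [scene_spec()].
#' @return A list with `image` ([rgb_image()]), `truth_mask`
#'   ([label_mask()]) and `truth_counts` (`class_counts`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height; w <- spec$width
  withr::with_seed(spec$seed, {
    labels <- matrix(CLASS_BACKGROUND, h, w)
    draw_leaves <- function(labels, n, value) {
      for (i in seq_len(n)) {
        cx <- stats::runif(1, 1, w)
        cy <- stats::runif(1, 1, h)
        a <- stats::runif(1, spec$leaf_axes[1], spec$leaf_axes[2])
        b <- stats::runif(1, spec$leaf_axes[1], spec$leaf_axes[2])
        theta <- stats::runif(1, spec$orientation_range[1],
                              spec$orientation_range[2])
        labels <- .paint_ellipse(labels, cx, cy, a, b, theta, value)
      }
      labels
    }
    labels <- draw_leaves(labels, spec$n_dead, CLASS_DEAD)
    labels <- draw_leaves(labels, spec$n_green, CLASS_GREEN)

    px <- array(0, dim = c(h, w, 3L))
    means <- list(spec$soil_color, spec$green_color, spec$dead_color)
    names(means) <- as.character(c(CLASS_BACKGROUND, CLASS_GREEN, CLASS_DEAD))
    ramp <- 1 + spec$illumination_gradient *
      (matrix(seq_len(w), h, w, byrow = TRUE) / w - 0.5)
    for (ch in 1:3) {
      plane <- matrix(0, h, w)
      for (cls in names(means))
        plane[labels == as.integer(cls)] <- means[[cls]][ch]
      plane <- plane * ramp + matrix(stats::rnorm(h * w, 0, spec$color_sd),
                                     h, w)
      px[, , ch] <- pmin(pmax(round(plane), 0), 255)
    }
    storage.mode(px) <- "integer"
    mask <- label_mask(labels,
                       image_source_id = sprintf("scene_seed%d", spec$seed))
    list(image = rgb_image(px, source_id = sprintf("scene_seed%d",
                                                   spec$seed)),
         truth_mask = mask,
         truth_counts = count_pixels(mask))
  })
}

#' Specification of a synthetic genotype x treatment trait cohort
#'
#' Emulates the structure of a waterlogging field trial: `n_genotypes`
#' genotypes with multiplicative genotype effects on shoot biomass,
#' `replicates` plants per genotype and treatment, a mean biomass reduction
#' under waterlogging, per-genotype dead-leaf sensitivity, and projected
#' green/dead areas linked to the corresponding biomass fractions by a
#' proportionality coefficient plus Gaussian noise. Defaults mirror the
#' trial scale this package targets: 22 genotypes, 6 replicates, control
#' shoot biomass around 700 g/plant, a 50% mean biomass reduction under
#' waterlogging.
#'
#' @param n_genotypes number of genotypes.
#' @param replicates replicates per genotype and treatment, >= 1.
#' @param base_shb mean control shoot biomass (g/plant).
#' @param genotype_sd sd of the log-normal genotype effect on biomass.
#' @param replicate_cv within-genotype replicate coefficient of variation.
#' @param reduction mean fractional biomass reduction under waterlogging,
#'   in \[0, 1\].
#' @param dead_frac_control,dead_frac_waterlogged mean dead-leaf fraction
#'   per treatment (per-genotype sensitivities scatter around the
#'   waterlogged value).
#' @param area_coef projected area (cm2) per gram of leaf biomass.
#' @param area_noise_sd sd of the area noise (cm2); alternatively set
#'   `target_area_cor` to calibrate it.
#' @param target_area_cor if non-`NULL`, the area noise sd is set so the
#'   planted correlation between green leaf biomass and projected green
#'   area equals this value (based on the realized biomass spread).
#' @param height_coef,height_base,height_noise_sd linear link from shoot
#'   biomass to plant height (cm).
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genotypes = 22L, replicates = 6L,
                        base_shb = 700, genotype_sd = 0.35,
                        replicate_cv = 0.25,
                        reduction = 0.5,
                        dead_frac_control = 0.05,
                        dead_frac_waterlogged = 0.35,
                        area_coef = 2.5,
                        area_noise_sd = 50,
                        target_area_cor = NULL,
                        height_coef = 0.03, height_base = 18,
                        height_noise_sd = 3,
                        seed = 1L) {
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (reduction < 0 || reduction > 1)
    stop("reduction must lie in [0, 1]", call. = FALSE)
  if (area_noise_sd < 0) stop("area_noise_sd must be >= 0", call. = FALSE)
  if (!is.null(target_area_cor) &&
      (target_area_cor <= 0 || target_area_cor > 1))
    stop("target_area_cor must lie in (0, 1]", call. = FALSE)
  structure(list(n_genotypes = as.integer(n_genotypes),
                 replicates = as.integer(replicates),
                 base_shb = base_shb, genotype_sd = genotype_sd,
                 replicate_cv = replicate_cv, reduction = reduction,
                 dead_frac_control = dead_frac_control,
                 dead_frac_waterlogged = dead_frac_waterlogged,
                 area_coef = area_coef, area_noise_sd = area_noise_sd,
                 target_area_cor = target_area_cor,
                 height_coef = height_coef, height_base = height_base,
                 height_noise_sd = height_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic trait cohort
#'
#' Draws genotype effects, applies the waterlogging reduction, splits shoot
#' biomass into green and dead leaf fractions, links projected areas to the
#' leaf biomass fractions (`area = coef * biomass + noise`, truncated at 0)
#' and heights to shoot biomass, and derives NDVI from the green fraction.
#' Seed-deterministic.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame of per-plant observations (columns `plant_id`,
#'   `genotype`, `treatment`, `replicate`, `shb_g`, `glb_g`, `dlb_g`,
#'   `pga_cm2`, `pda_cm2`, `height_cm`, `ndvi`) with the generating
#'   parameters attached as attribute `"true_params"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    G <- spec$n_genotypes; R <- spec$replicates
    gen_ids <- sprintf("G%02d", seq_len(G))
    gen_eff <- exp(stats::rnorm(G, 0, spec$genotype_sd))
    sens <- pmin(pmax(spec$dead_frac_waterlogged +
                        stats::rnorm(G, 0, 0.08), 0.02), 0.9)

    grid <- expand.grid(replicate = seq_len(R), genotype = seq_len(G),
                        treatment = c("CONTROL", "WATERLOGGED"),
                        stringsAsFactors = FALSE)
    n <- nrow(grid)
    mu <- spec$base_shb * gen_eff[grid$genotype] *
      ifelse(grid$treatment == "WATERLOGGED", 1 - spec$reduction, 1)
    shb <- pmax(mu * (1 + stats::rnorm(n, 0, spec$replicate_cv)), 1)
    dead_frac <- pmin(pmax(ifelse(grid$treatment == "WATERLOGGED",
                                  sens[grid$genotype],
                                  spec$dead_frac_control) +
                             stats::rnorm(n, 0, 0.03), 0), 0.95)
    glb <- shb * (1 - dead_frac)
    dlb <- shb * dead_frac

    noise_sd <- spec$area_noise_sd
    if (!is.null(spec$target_area_cor)) {
      r <- spec$target_area_cor
      noise_sd <- spec$area_coef * stats::sd(glb) * sqrt(1 / r^2 - 1)
    }
    pga <- pmax(spec$area_coef * glb + stats::rnorm(n, 0, noise_sd), 0)
    pda <- pmax(spec$area_coef * dlb + stats::rnorm(n, 0, noise_sd), 0)
    height <- pmax(spec$height_base + spec$height_coef * shb +
                     stats::rnorm(n, 0, spec$height_noise_sd), 1)
    green_frac <- 1 - dead_frac
    ndvi_val <- pmin(pmax(0.15 + 0.7 * green_frac +
                            stats::rnorm(n, 0, 0.03), -1), 1)

    out <- data.frame(
      plant_id = sprintf("%s_%s_r%d", gen_ids[grid$genotype],
                         substr(grid$treatment, 1, 1), grid$replicate),
      genotype = gen_ids[grid$genotype],
      treatment = grid$treatment,
      replicate = grid$replicate,
      shb_g = shb, glb_g = glb, dlb_g = dlb,
      pga_cm2 = pga, pda_cm2 = pda,
      height_cm = height, ndvi = ndvi_val,
      stringsAsFactors = FALSE
    )
    attr(out, "true_params") <- list(
      genotype_effect = stats::setNames(gen_eff, gen_ids),
      dead_sensitivity = stats::setNames(sens, gen_ids),
      reduction = spec$reduction, area_coef = spec$area_coef,
      area_noise_sd = noise_sd, seed = spec$seed
    )
    out
  })
}

#' Labeled training pixels from a scene's color model
#'
#' Draws soil- and plant-labeled color samples from the class color
#' distributions of a [scene_spec()] (Gaussian around each class mean with
#' the spec's color sd, clipped to 0-255). These emulate the hand-labeled
#' pixels an operator would sample to calibrate the soil threshold before
#' a batch run.
#'
#' @param spec a [scene_spec()].
#' @param n_per_class samples per class.
#' @param seed integer seed.
#' @return A list with `colors` (N x 3 RGB matrix) and `is_soil` (logical).
#' @export
scene_training_pixels <- function(spec, n_per_class = 300L, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(as.integer(seed), {
    draw <- function(mu) {
      m <- matrix(stats::rnorm(3L * n_per_class, rep(mu, each = n_per_class),
                               spec$color_sd), ncol = 3L)
      pmin(pmax(round(m), 0), 255)
    }
    colors <- rbind(draw(spec$soil_color), draw(spec$green_color),
                    draw(spec$dead_color))
    list(colors = colors,
         is_soil = rep(c(TRUE, FALSE, FALSE), each = n_per_class))
  })
}
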