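# Derived indices (WTC, projected WTC, NDVI) and trial statistics
# (genotype means, CV, Pearson correlation matrices, Fisher's protected
# LSD with letter groupings).

#' Waterlogging tolerance coefficient (WTC)
#'
#' The ratio of shoot biomass produced under waterlogging to that produced
#' under control (drained) conditions, in percent. Vectorized.
#'
#' @param shb_waterlogged shoot biomass under waterlogging (g/plant), >= 0.
#' @param shb_control shoot biomass under control conditions (g/plant), > 0.
#' @return `100 * shb_waterlogged / shb_control` (percent).
#' @export
compute_wtc <- function(shb_waterlogged, shb_control) {
  if (any(!is.finite(shb_control)) || any(shb_control <= 0))
    stop("control shoot biomass must be positive", call. = FALSE)
  if (any(!is.finite(shb_waterlogged)) || any(shb_waterlogged < 0))
    stop("waterlogged shoot biomass must be non-negative", call. = FALSE)
  100 * shb_waterlogged / shb_control
}

#' Projected WTC from image-derived green areas
#'
#' The image-based analogue of [compute_wtc()]: the ratio of projected green
#' area under waterlogging to that under control conditions, in percent.
#'
#' @param pga_waterlogged projected green area under waterlogging
#'   (cm2/plant), >= 0.
#' @param pga_control projected green area under control (cm2/plant), > 0.
#' @return `100 * pga_waterlogged / pga_control` (percent).
#' @export
compute_projected_wtc <- function(pga_waterlogged, pga_control) {
  if (any(!is.finite(pga_control)) || any(pga_control <= 0))
    stop("control projected green area must be positive", call. = FALSE)
  if (any(!is.finite(pga_waterlogged)) || any(pga_waterlogged < 0))
    stop("waterlogged projected green area must be non-negative",
         call. = FALSE)
  100 * pga_waterlogged / pga_control
}

#' Normalized difference vegetation index
#'
#' `(NIR - Red) / (NIR + Red)`: high for healthy green canopies, which
#' absorb red light and reflect near-infrared.
#'
#' @param nir near-infrared reflectance, >= 0.
#' @param red red reflectance, >= 0.
#' @return NDVI in \[-1, 1\]. Vectorized.
#' @export
ndvi <- function(nir, red) {
  if (any(!is.finite(nir)) || any(!is.finite(red)) ||
      any(nir < 0) || any(red < 0))
    stop("reflectances must be finite and non-negative", call. = FALSE)
  if (any(nir + red == 0))
    stop("nir + red must be positive", call. = FALSE)
  (nir - red) / (nir + red)
}

#' Percent decrease between treatment grand means
#'
#' @param mean_control grand mean under control conditions, > 0.
#' @param mean_treated grand mean under treatment.
#' @return `100 * (mean_control - mean_treated) / mean_control`.
#' @export
percent_change <- function(mean_control, mean_treated) {
  if (any(!is.finite(mean_control)) || any(mean_control <= 0))
    stop("control mean must be positive", call. = FALSE)
  100 * (mean_control - mean_treated) / mean_control
}

#' Genotype means for one trait under one treatment
#'
#' Arithmetic means per genotype over replicates (in a balanced design these
#' equal the least-square means), the grand mean of the genotype means, and
#' a coefficient of variation computed from the pooled within-genotype
#' standard deviation: `CV = 100 * sd_pooled / grand_mean`.
#'
#' @param observations data.frame of replicate-level records with columns
#'   `genotype`, `treatment` and the trait.
#' @param trait name of the trait column.
#' @param treatment treatment level to subset on, or `NULL` to use all rows.
#' @return A list with `means` (data.frame: genotype, mean, n), `grand_mean`,
#'   `cv` (percent; `NA` when no genotype has >= 2 replicates). Genotypes
#'   with no non-missing observation get `NA` means.
#' @export
genotype_means <- function(observations, trait, treatment = NULL) {
  stopifnot(is.data.frame(observations), trait %in% names(observations))
  df <- observations
  if (!is.null(treatment)) df <- df[df$treatment == treatment, , drop = FALSE]
  if (nrow(df) == 0L) stop("no observations selected", call. = FALSE)
  sp <- split(df[[trait]], df$genotype)
  means <- vapply(sp, function(v) mean(v, na.rm = TRUE), numeric(1))
  means[!vapply(sp, function(v) any(!is.na(v)), logical(1))] <- NA_real_
  n <- vapply(sp, function(v) sum(!is.na(v)), integer(1))
  grand <- mean(means, na.rm = TRUE)
  # pooled within-genotype SD over genotypes with >= 2 replicates
  ss <- vapply(sp, function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2L) sum((v - mean(v))^2) else NA_real_
  }, numeric(1))
  dfree <- n - 1L
  use <- !is.na(ss) & dfree >= 1L
  cv <- if (any(use) && grand != 0) {
    100 * sqrt(sum(ss[use]) / sum(dfree[use])) / grand
  } else NA_real_
  list(means = data.frame(genotype = names(sp), mean = unname(means),
                          n = unname(n), stringsAsFactors = FALSE),
       grand_mean = grand, cv = cv)
}

#' Pearson correlation with a two-sided t-test
#'
#' Pairwise deletion of incomplete pairs; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length.
#' @return A list with `r`, `p`, `n` (number of complete pairs used).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Significance stars for a p-value
#'
#' @param p p-value(s).
#' @param thresholds named-free numeric vector of strictly decreasing
#'   thresholds for one, two and three stars.
#' @return `"***"`, `"**"`, `"*"` or `"ns"`. Vectorized.
#' @export
star_annotation <- function(p, thresholds = c(0.05, 0.01, 0.001)) {
  thresholds <- sort(thresholds, decreasing = TRUE)
  ifelse(p < thresholds[3], "***",
         ifelse(p < thresholds[2], "**",
                ifelse(p < thresholds[1], "*", "ns")))
}

#' Pearson correlation matrix with significance stars
#'
#' Correlates every pair of trait columns with pairwise deletion, annotating
#' each cell with the conventional stars (default * P < 0.05, ** P < 0.01,
#' *** P < 0.001; ns otherwise). Cells whose correlation is undefined
#' (constant column, < 3 complete pairs) are `NA` with a warning.
#'
#' @param table data.frame or matrix of trait columns (rows = genotypes).
#' @param star_thresholds p-value thresholds for one, two, three stars.
#' @return An object of class `correlation_result`: `r`, `p`, `n` matrices
#'   and a character `stars` matrix, all symmetric with unit / empty
#'   diagonals.
#' @export
correlation_matrix <- function(table, star_thresholds = c(0.05, 0.01, 0.001)) {
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, logical(1))
  table <- table[, num, drop = FALSE]
  m <- ncol(table)
  if (m < 2L) stop("need at least 2 numeric trait columns", call. = FALSE)
  traits <- names(table)
  r <- p <- n <- matrix(NA_real_, m, m, dimnames = list(traits, traits))
  stars <- matrix("", m, m, dimnames = list(traits, traits))
  diag(r) <- 1
  failed <- character(0)
  for (i in seq_len(m)) {
    n[i, i] <- sum(!is.na(table[[i]]))
    for (j in seq_len(m)) {
      if (j <= i) next
      res <- tryCatch(pearson(table[[i]], table[[j]]), error = function(e) e)
      if (inherits(res, "error")) {
        failed <- c(failed, paste0(traits[i], "~", traits[j]))
        next
      }
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p
      n[i, j] <- n[j, i] <- res$n
      stars[i, j] <- stars[j, i] <- star_annotation(res$p, star_thresholds)
    }
  }
  if (length(failed))
    warning("correlation undefined for: ", paste(failed, collapse = ", "))
  structure(list(r = r, p = p, n = n, stars = stars,
                 star_thresholds = star_thresholds),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, digits = 2, ...) {
  disp <- matrix(paste0(format(round(x$r, digits)),
                        ifelse(x$stars == "" | x$stars == "ns", "",
                               x$stars)),
                 nrow(x$r), dimnames = dimnames(x$r))
  diag(disp) <- "-"
  print(disp, quote = FALSE)
  invisible(x)
}

# classic sweep: on means sorted descending with a common LSD, groups i and
# j (i < j) share a letter iff mean_i - mean_j <= LSD. Each maximal interval
# [i, f(i)] with f(i) = largest j still within the LSD of i gets one letter;
# keeping only non-nested intervals makes letter sharing exactly equivalent
# to |difference| <= LSD.
.lsd_letters <- function(means, lsd) {
  ord <- order(means, decreasing = TRUE)
  s <- means[ord]
  g <- length(s)
  f <- vapply(seq_len(g), function(i) max(which(s[i] - s <= lsd)),
              integer(1))
  starts <- which(seq_len(g) == 1L | f > c(0L, f[-g]))
  letters_sorted <- character(g)
  for (ri in seq_along(starts)) {
    iv <- starts[ri]:f[starts[ri]]
    letters_sorted[iv] <- paste0(letters_sorted[iv], letters[ri])
  }
  out <- character(g)
  out[ord] <- letters_sorted
  out
}

#' Fisher's protected LSD
#'
#' One-way ANOVA on replicate-level values; only if the overall F-test is
#' significant at `alpha` (the "protected" step) is the least significant
#' difference computed as `t(1 - alpha/2, df_error) * sqrt(2 * MSE / n)`,
#' with `n` the common replicate count (harmonic mean when unbalanced).
#' Letters are assigned by the standard sweep over means sorted descending:
#' two groups share a letter iff their means differ by at most the LSD.
#' When F is not significant every group shares one letter.
#'
#' @param values numeric vector of replicate-level observations.
#' @param groups group (genotype or treatment) of each observation.
#' @param alpha significance level for both the F-test and the LSD.
#' @return An object of class `lsd_result`: `alpha`, `df_error`, `lsd`
#'   (`NA` when F is not significant), `f_p_value`, `significant`, and a
#'   data.frame `groups` (group, mean, n, letters) sorted by descending
#'   mean.
#' @export
fisher_lsd <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  g <- nlevels(groups)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  n_per <- as.integer(table(groups))
  if (any(n_per < 2L))
    stop("need at least 2 replicates per group", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate design: all values identical", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  av <- stats::anova(fit)
  mse <- av["Residuals", "Mean Sq"]
  df_err <- av["Residuals", "Df"]
  f_p <- av["groups", "Pr(>F)"]
  means <- tapply(values, groups, mean)
  n_h <- g / sum(1 / n_per) # harmonic mean replicate count
  significant <- is.finite(f_p) && f_p <= alpha
  if (significant && mse > 0) {
    lsd <- stats::qt(1 - alpha / 2, df_err) * sqrt(2 * mse / n_h)
    letts <- .lsd_letters(as.numeric(means), lsd)
  } else {
    lsd <- NA_real_
    letts <- rep("a", g)
  }
  ord <- order(means, decreasing = TRUE)
  structure(list(alpha = alpha, df_error = df_err, lsd = lsd,
                 f_p_value = f_p, significant = significant,
                 groups = data.frame(group = names(means)[ord],
                                     mean = as.numeric(means)[ord],
                                     n = n_per[ord],
                                     letters = letts[ord],
                                     stringsAsFactors = FALSE)),
            class = "lsd_result")
}

#' @export
print.lsd_result <- function(x, ...) {
  cat(sprintf("Fisher's protected LSD (alpha = %g): F-test p = %.4g, %s\n",
              x$alpha, x$f_p_value,
              if (x$significant) sprintf("LSD = %.4g", x$lsd)
              else "not significant (single letter group)"))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Genotype-level means from a published waterlogging trial
#'
#' Genotype least-square means of shoot biomass (g/plant) and plant height
#' (cm) for 19 interspecific Brachiaria hybrids and three commercial check
#' cultivars grown under control and waterlogged field conditions, as
#' reported by the field trial this package's methodology reproduces.
#' Useful as a realistic worked example and for checking the summary
#' statistics.
#'
#' @return A data.frame with columns `genotype`, `shb_control`,
#'   `shb_waterlogged`, `height_control`, `height_waterlogged`,
#'   `ve_waterlogged`.
#' @export
brachiaria_trial_means <- function() {
  path <- system.file("extdata", "brachiaria_trial_means.csv",
                      package = "canopywtc", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
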