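#' Dominance analysis of a multiple regression
#'
#' Decomposes a regression's explained variance into per-predictor
#' contributions by refitting the model on every non-empty predictor subset
#' (`2^p - 1` models). A predictor's total dominance is its incremental
#' goodness-of-fit gain when added to a subset, averaged first within each
#' subset size and then across sizes; percent relative importance expresses
#' each total dominance as a percentage of their sum, which equals the
#' full-model fit. Gains are measured on adjusted R-squared by default (the
#' scale used to compare band contributions); unadjusted R-squared is
#' available for settings where exact additivity under orthogonal predictors
#' is wanted.
#'
#' @param target Numeric response vector.
#' @param predictors Numeric matrix, one column per predictor (p <= 12).
#' @param metric `"adjusted"` or `"unadjusted"` R-squared for the
#'   incremental gains.
#' @return A `dominance_result` list: `total_dominance`, `percent_importance`
#'   (sums to 100), `full_fit`, `n_models`, `subset_fit` (named by bitmask).
#' @export
dominance_analysis <- function(target, predictors,
                               metric = c("adjusted", "unadjusted")) {
  metric <- match.arg(metric)
  predictors <- as.matrix(predictors)
  p <- ncol(predictors)
  n <- length(target)
  if (nrow(predictors) != n) stop("target and predictors lengths differ", call. = FALSE)
  if (n <= 8) stop("need more than 8 observations", call. = FALSE)
  if (n < p + 2) stop("fewer observations than largest subset + 2", call. = FALSE)
  if (p > 12) stop("too many predictors for exhaustive enumeration", call. = FALSE)
  if (is.null(colnames(predictors))) {
    colnames(predictors) <- paste0("x", seq_len(p))
  }

  # centered cross-products let every subset model be solved from one pass
  xc <- scale(predictors, center = TRUE, scale = FALSE)
  yc <- target - mean(target)
  sxx <- crossprod(xc)
  sxy <- crossprod(xc, yc)
  syy <- sum(yc^2)
  subset_r2 <- function(idx) {
    if (length(idx) == 0) return(0)
    b <- tryCatch(solve(sxx[idx, idx, drop = FALSE], sxy[idx, , drop = FALSE]),
                  error = function(e) {
                    MASS::ginv(sxx[idx, idx, drop = FALSE]) %*%
                      sxy[idx, , drop = FALSE]
                  })
    drop(crossprod(sxy[idx, , drop = FALSE], b)) / syy
  }
  fit_metric <- function(idx) {
    r2 <- subset_r2(idx)
    if (metric == "adjusted") adjusted_r2(r2, n, length(idx)) else r2
  }

  n_models <- as.integer(2^p - 1)
  masks <- seq_len(n_models)
  members <- lapply(masks, function(m) which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0))
  fit <- vapply(members, fit_metric, numeric(1))
  names(fit) <- masks
  sizes <- lengths(members)

  total <- numeric(p)
  for (k in seq_len(p)) {
    bit <- 2^(k - 1)
    gains_by_size <- numeric(p)          # size of the subset k is added to: 0..p-1
    for (s in 0:(p - 1)) {
      without <- masks[sizes == s + 1 & bitwAnd(masks, bit) > 0] - bit
      base_fit <- ifelse(without == 0, 0, fit[as.character(without)])
      gains_by_size[s + 1] <- mean(fit[as.character(without + bit)] - base_fit)
    }
    total[k] <- mean(gains_by_size)
  }
  names(total) <- colnames(predictors)
  full <- fit[as.character(n_models)]
  pct <- if (abs(sum(total)) > 0) 100 * total / sum(total) else rep(NA_real_, p)
  structure(list(
    total_dominance = total, percent_importance = pct,
    full_fit = unname(full), n_models = n_models, subset_fit = fit,
    metric = metric
  ), class = "dominance_result")
}

#' Dominance analysis for every regional model
#'
#' Runs [dominance_analysis()] on each region's haemodynamic profile against
#' its six band profiles and summarizes the per-band percent relative
#' importance across the cortex.
#'
#' @inheritParams fit_regional_model
#' @param metric Passed to [dominance_analysis()].
#' @return A list: `results` (per-region `dominance_result`), `contributions`
#'   (N x 6 percent matrix), `total_dominance` (N x 6), `most_dominant`
#'   (factor of band names, ties broken by canonical band order),
#'   `full_adj_r2`.
#' @export
dominance_all_regions <- function(haemo, bands, metric = "adjusted") {
  check_band_set(bands)
  n <- nrow(haemo)
  results <- lapply(seq_len(n), function(i) {
    dominance_analysis(regional_profile(haemo, i),
                       band_profile_matrix(bands, i), metric = metric)
  })
  contributions <- t(vapply(results, `[[`, numeric(6), "percent_importance"))
  totals <- t(vapply(results, `[[`, numeric(6), "total_dominance"))
  colnames(contributions) <- colnames(totals) <- names(bands)
  ties <- apply(contributions, 1, function(x) sum(x == max(x)) > 1)
  if (any(ties)) {
    message(sum(ties), " region(s) had tied dominant bands; ",
            "ties broken by canonical band order")
  }
  most <- factor(names(bands)[apply(contributions, 1, which.max)],
                 levels = names(bands))
  list(results = results, contributions = contributions,
       total_dominance = totals, most_dominant = most,
       full_adj_r2 = vapply(results, `[[`, numeric(1), "full_fit"))
}

#' One-way ANOVA and pairwise contrasts of band contributions
#'
#' Treats each region's percent contribution as an observation and the six
#' bands as groups: a one-way ANOVA (between df = bands - 1, within
#' df = bands x regions - bands) followed by all pairwise two-sample pooled-
#' variance t tests, two-tailed p values Bonferroni-corrected by the number
#' of pairs (15 for 6 bands, capped at 1), and pooled-SD Cohen's d. Mean
#' differences are reported as absolute values.
#'
#' @param contributions Region x band matrix of percent contributions.
#' @return A `band_contrast` list: `f`, `df` (between, within), `p`,
#'   and `pairs`, a data frame with columns `pair`, `mean_diff`, `t`,
#'   `p_bonf`, `cohens_d`.
#' @export
band_contribution_anova <- function(contributions) {
  contributions <- as.matrix(contributions)
  n_band <- ncol(contributions)
  n_reg <- nrow(contributions)
  if (n_band < 2 || n_reg < 2) stop("need >= 2 bands and >= 2 regions", call. = FALSE)
  if (is.null(colnames(contributions))) {
    colnames(contributions) <- paste0("band", seq_len(n_band))
  }
  long <- data.frame(
    value = as.vector(contributions),
    band = factor(rep(colnames(contributions), each = n_reg),
                  levels = colnames(contributions))
  )
  av <- stats::anova(stats::lm(value ~ band, data = long))
  if (!is.finite(av[1, "F value"])) {
    stop("F undefined: zero within-group variance", call. = FALSE)
  }
  combos <- utils::combn(colnames(contributions), 2)
  n_pairs <- ncol(combos)
  pairs <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
    a <- contributions[, combos[1, k]]
    b <- contributions[, combos[2, k]]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    sp <- sqrt(((n_reg - 1) * stats::var(a) + (n_reg - 1) * stats::var(b)) /
                 (2 * n_reg - 2))
    data.frame(
      pair = paste(combos[1, k], combos[2, k], sep = "-"),
      mean_diff = abs(mean(a) - mean(b)),
      t = unname(tt$statistic),
      p_bonf = min(1, tt$p.value * n_pairs),
      cohens_d = if (sp > 0) abs(mean(a) - mean(b)) / sp else 0,
      stringsAsFactors = FALSE
    )
  }))
  structure(list(
    f = av[1, "F value"],
    df = c(between = av[1, "Df"], within = av[2, "Df"]),
    p = av[1, "Pr(>F)"],
    pairs = pairs
  ), class = "band_contrast")
}
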