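#' Distance-dependent train/test splits for one region's profile
#'
#' For region `i`, every other region in turn serves as the "source" of one
#' split: the `floor(train_frac * (N - 1))` regions closest to the source
#' (by Euclidean distance between parcel centroids, the source itself at
#' distance zero) form the train set and the remainder the test set. With
#' all `N - 1` candidate sources this yields `N - 1` unique splits, so the
#' procedure is deterministic.
#'
#' @param geometry Parcel geometry.
#' @param i Region whose profile is being split.
#' @param train_frac Fraction of profile entries assigned to training,
#'   in (0, 1).
#' @return A list of `N - 1` splits, each a list with `source`, `train`,
#'   `test` (region indices into `1..N`, excluding `i`).
#' @export
distance_dependent_splits <- function(geometry, i, train_frac = 0.75) {
  check_geometry(geometry)
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be in (0, 1)", call. = FALSE)
  }
  n <- nrow(geometry)
  if (i < 1 || i > n) stop("region index out of range", call. = FALSE)
  others <- setdiff(seq_len(n), i)
  d <- geometry_dist(geometry)[others, others, drop = FALSE]
  n_train <- floor(train_frac * (n - 1))
  lapply(seq_along(others), function(k) {
    ord <- order(d[k, ], seq_along(others))  # source ranks first at distance 0
    list(source = others[k],
         train = others[ord[seq_len(n_train)]],
         test = others[ord[(n_train + 1):(n - 1)]])
  })
}

#' Distance-dependent cross-validation of the regional models
#'
#' For every region and every split from [distance_dependent_splits()], fits
#' the six-band regional model on the train edges only, predicts the test
#' edges, and records the Pearson correlation between empirical and
#' predicted connectivity on both sets. Performance per region is the mean
#' correlation across splits.
#'
#' @inheritParams fit_regional_model
#' @param geometry Parcel geometry matching the matrices.
#' @param train_frac Training fraction, in (0, 1).
#' @return A `cv_result` list: `train` and `test` (length-N mean-correlation
#'   maps), `n_splits`.
#' @export
regional_cv <- function(haemo, bands, geometry, train_frac = 0.75) {
  check_band_set(bands)
  check_geometry(geometry)
  n <- nrow(haemo)
  if (nrow(geometry) != n) {
    stop("geometry and matrices disagree on parcellation size", call. = FALSE)
  }
  train_map <- test_map <- numeric(n)
  n_skipped <- 0L
  for (i in seq_len(n)) {
    y_full <- regional_profile(haemo, i)
    x_full <- band_profile_matrix(bands, i)
    splits <- distance_dependent_splits(geometry, i, train_frac)
    pos <- integer(n); pos[setdiff(seq_len(n), i)] <- seq_len(n - 1)
    tr <- te <- numeric(length(splits))
    ok <- logical(length(splits))
    for (k in seq_along(splits)) {
      it <- pos[splits[[k]]$train]
      is <- pos[splits[[k]]$test]
      if (stats::sd(y_full[is]) == 0 || stats::sd(y_full[it]) == 0) next
      fit <- stats::.lm.fit(cbind(1, x_full[it, , drop = FALSE]), y_full[it])
      coef <- fit$coefficients
      pred_tr <- y_full[it] - fit$residuals
      pred_te <- drop(cbind(1, x_full[is, , drop = FALSE]) %*% coef)
      if (stats::sd(pred_te) == 0 || stats::sd(pred_tr) == 0) next
      tr[k] <- stats::cor(y_full[it], pred_tr)
      te[k] <- stats::cor(y_full[is], pred_te)
      ok[k] <- TRUE
    }
    if (!all(ok)) n_skipped <- n_skipped + sum(!ok)
    train_map[i] <- mean(tr[ok])
    test_map[i] <- mean(te[ok])
  }
  if (n_skipped > 0) {
    warning(n_skipped, " degenerate split(s) skipped")
  }
  structure(list(train = train_map, test = test_map,
                 n_splits = as.integer(n - 1)),
            class = "cv_result")
}

#' Subject-level leave-one-out cross-validation
#'
#' For each held-out subject, fits the regional models on the mean matrices
#' of the remaining subjects and evaluates, per region, the Pearson
#' correlation between the held-out subject's empirical haemodynamic profile
#' and the profile predicted from that subject's own band profiles. Metrics
#' are averaged over folds.
#'
#' @param subjects List of per-subject data as returned by
#'   [make_subject_ensemble()]: each element has `haemo` and `bands`.
#' @return A `cv_result` list: `train` and `test` length-N maps (fold means),
#'   `n_folds`.
#' @export
subject_loo_cv <- function(subjects) {
  n_sub <- length(subjects)
  if (n_sub < 3) stop("need at least 3 subjects", call. = FALSE)
  n <- nrow(subjects[[1]]$haemo)
  n_band <- length(subjects[[1]]$bands)
  train_acc <- test_acc <- matrix(0, n_sub, n)
  for (s in seq_len(n_sub)) {
    rest <- setdiff(seq_len(n_sub), s)
    haemo_tr <- Reduce(`+`, lapply(subjects[rest], `[[`, "haemo")) / length(rest)
    bands_tr <- lapply(seq_len(n_band), function(b) {
      Reduce(`+`, lapply(subjects[rest], function(x) x$bands[[b]])) / length(rest)
    })
    names(bands_tr) <- names(subjects[[1]]$bands)
    class(bands_tr) <- "band_fc_set"
    fits <- fit_all_regions(haemo_tr, bands_tr)
    for (i in seq_len(n)) {
      fit <- fits$fits[[i]]
      train_acc[s, i] <- stats::cor(regional_profile(haemo_tr, i),
                                    fit$predicted_profile)
      x_te <- band_profile_matrix(subjects[[s]]$bands, i)
      pred <- drop(cbind(1, x_te) %*% fit$coefficients)
      test_acc[s, i] <- stats::cor(regional_profile(subjects[[s]]$haemo, i), pred)
    }
  }
  structure(list(train = colMeans(train_acc), test = colMeans(test_acc),
                 n_folds = n_sub),
            class = "cv_result")
}
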