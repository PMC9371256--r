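#' Configuration for an end-to-end analysis run
#'
#' @param synthetic A [synthetic_config()] describing the inputs to
#'   generate, or `NULL` to supply matrices via `haemo_path` /
#'   `band_paths` / `geometry_path`.
#' @param haemo_path,band_paths,geometry_path Paths to a haemodynamic
#'   matrix, six band matrices, and a geometry table (used when
#'   `synthetic` is `NULL`).
#' @param n_spin Number of spin-null repetitions.
#' @param alpha Significance / FDR level.
#' @param train_frac Training fraction for distance-dependent CV.
#' @param run_cv Logical; run the cross-validation stages (the slowest part).
#' @param seed Integer master seed; per-stage child seeds are derived from it.
#' @param out_dir Optional output directory for machine-readable results.
#' @return A validated `analysis_config` list.
#' @export
analysis_config <- function(synthetic = synthetic_config(),
                            haemo_path = NULL, band_paths = NULL,
                            geometry_path = NULL,
                            n_spin = 1000L, alpha = 0.05,
                            train_frac = 0.75, run_cv = TRUE,
                            seed = 42L, out_dir = NULL) {
  if (is.null(synthetic)) {
    paths <- c(haemo_path, band_paths, geometry_path)
    if (length(band_paths) != 6 || is.null(haemo_path) || is.null(geometry_path)) {
      stop("without a synthetic config, supply haemo_path, 6 band_paths, ",
           "and geometry_path", call. = FALSE)
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop("input file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  if (n_spin < 1) stop("n_spin must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)",
                                               call. = FALSE)
  structure(list(
    synthetic = synthetic, haemo_path = haemo_path, band_paths = band_paths,
    geometry_path = geometry_path, n_spin = as.integer(n_spin), alpha = alpha,
    train_frac = train_frac, run_cv = isTRUE(run_cv), seed = as.integer(seed),
    out_dir = out_dir
  ), class = "analysis_config")
}

#' Run the full cross-modal mapping pipeline
#'
#' Executes, in order: input generation (or loading), regional / global /
#' band-specific model fitting, dominance analysis with band contrasts,
#' distance-dependent and subject-level cross-validation, spin-null
#' inference on the correspondence map versus the functional gradient and
#' the synthetic hierarchy, and the microarchitectural context statistics
#' (structure-function coupling, depth profiles, gene expression). All
#' stages are seeded from `config$seed`. When `config$out_dir` is set,
#' results and provenance are written as delimited text and JSON.
#'
#' @param config An [analysis_config()].
#' @return A `results_bundle` list; see the individual stage functions for
#'   the element contracts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  stage_seed <- with_seed_(config$seed,
                           sample.int(.Machine$integer.max, 8))

  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    geometry <- make_geometry(sc$n_parcels, seed = stage_seed[1])
    bands <- make_band_fc_set(geometry, sc)
    truthed <- make_crossmodal_truth(bands, geometry, sc)
    haemo <- truthed$haemo
    truth <- truthed$truth
    context_in <- NULL  # built below against the fitted map's anchor
  } else {
    geometry <- read_geometry(config$geometry_path)
    haemo <- read_matrix(config$haemo_path)
    bands <- lapply(config$band_paths, read_matrix)
    names(bands) <- canonical_bands()$name
    class(bands) <- "band_fc_set"
    truth <- NULL
  }
  n <- nrow(haemo)

  regional <- fit_all_regions(haemo, bands)
  global <- fit_global_model(haemo, bands)
  band_specific <- fit_band_specific_models(haemo, bands)
  dom <- dominance_all_regions(haemo, bands)
  contrasts <- band_contribution_anova(dom$contributions)

  cv_regional <- cv_subject <- NULL
  if (config$run_cv) {
    cv_regional <- regional_cv(haemo, bands, geometry, config$train_frac)
    if (!is.null(config$synthetic)) {
      subjects <- make_subject_ensemble(haemo, bands,
                                        config$synthetic$n_subjects,
                                        config$synthetic$subject_noise_sd,
                                        seed = stage_seed[2])
      cv_subject <- subject_loo_cv(subjects)
    }
  }

  spins <- generate_spins(geometry, config$n_spin, seed = stage_seed[3])
  gradient <- principal_gradient(haemo,
                                 anchor = if (!is.null(truth)) truth$hierarchy)
  grad_test <- spin_pvalue(regional$adj_r2, gradient$scores, spins)
  hier_test <- if (!is.null(truth)) {
    spin_pvalue(regional$adj_r2, truth$hierarchy, spins)
  }

  context <- NULL
  if (!is.null(config$synthetic)) {
    maps <- make_context_maps(geometry, anchor_map = regional$adj_r2,
                              seed = stage_seed[4])
    coupling <- structure_function_coupling(maps$structural, haemo)
    depth <- depth_profile_association(regional$adj_r2, maps$depth_profiles,
                                       spins, alpha = config$alpha)
    expr <- expression_map_association(regional$adj_r2, maps$expression,
                                       "ANCHOR_GENE", spins)
    ok <- !is.na(coupling)
    coupling_test <- spin_pvalue(regional$adj_r2[ok], coupling[ok],
                                 subset_spins(spins, ok))
    context <- list(maps = maps, coupling = coupling,
                    coupling_test = coupling_test,
                    depth = depth, expression_test = expr)
  }

  bundle <- structure(list(
    config = config, geometry = geometry, truth = truth,
    regional = regional, global = global, band_specific = band_specific,
    dominance = dom, contrasts = contrasts,
    cv_regional = cv_regional, cv_subject = cv_subject,
    gradient = gradient, gradient_test = grad_test,
    hierarchy_test = hier_test, context = context,
    n_parcels = n
  ), class = "results_bundle")

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @keywords internal
#' @noRd
subset_spins <- function(spins, keep) {
  # restrict a spin ensemble to a subset of parcels: spun values falling on
  # dropped parcels are remapped to the nearest retained index order
  idx <- which(keep)
  sub <- spins[, idx, drop = FALSE]
  remap <- match(sub, idx)
  # a spun assignment may point at a dropped parcel; fall back to itself
  fallback <- matrix(rep(seq_along(idx), each = nrow(spins)), nrow(spins))
  remap[is.na(remap)] <- fallback[is.na(remap)]
  structure(matrix(remap, nrow(spins)), class = "spin_ensemble",
            seed = attr(spins, "seed"), n_spin = attr(spins, "n_spin"))
}

#' @keywords internal
#' @noRd
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(out_dir, ...)
  write_geometry(bundle$geometry, path("geometry.tsv"))
  maps <- data.frame(
    parcel = bundle$geometry$parcel,
    adj_r2 = bundle$regional$adj_r2,
    gradient = bundle$gradient$scores
  )
  if (!is.null(bundle$truth)) {
    maps$hierarchy <- bundle$truth$hierarchy
    maps$target_r2 <- bundle$truth$target_r2
  }
  if (!is.null(bundle$cv_regional)) {
    maps$cv_train <- bundle$cv_regional$train
    maps$cv_test <- bundle$cv_regional$test
  }
  utils::write.table(maps, path("maps.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(parcel = bundle$geometry$parcel, bundle$dominance$contributions,
               most_dominant = bundle$dominance$most_dominant),
    path("dominance.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$contrasts$pairs, path("band_contrasts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    seed = bundle$config$seed,
    n_parcels = bundle$n_parcels,
    n_spin = bundle$config$n_spin,
    global_adj_r2 = bundle$global$adj_r2,
    regional_adj_r2_range = range(bundle$regional$adj_r2),
    anova_f = bundle$contrasts$f,
    anova_df = as.list(bundle$contrasts$df),
    gradient_r = bundle$gradient_test$r,
    gradient_p_spin = bundle$gradient_test$p_spin
  )
  if (!is.null(bundle$hierarchy_test)) {
    summary$hierarchy_r <- bundle$hierarchy_test$r
    summary$hierarchy_p_spin <- bundle$hierarchy_test$p_spin
  }
  jsonlite::write_json(summary, path("summary.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(out_dir)
}
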