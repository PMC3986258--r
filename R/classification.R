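# Random-forest discrimination of fission vs fusion: 2000 trees with 3
# candidate features per split, out-of-bag error, permutation importance
# with per-tree SDs (overall and class-conditional), the class-error-vs-
# forest-size curve, and single-bifurcation decision stumps.

#' Train the fission/fusion random forest
#'
#' Fits a bagged ensemble of `config$n_trees` classification trees with
#' `config$rf_split_candidates` candidate features per split on the 11
#' morphological/positional features. Missing values (undefined neck width
#' or positional features) are imputed by the class-agnostic column median,
#' with a message. Class priors are taken from the data as observed; no
#' reweighting is applied, so the majority class is typically predicted
#' better.
#'
#' @param features Tibble with the 11 feature columns (see
#'   [mito_feature_names()]) and an `event_call` factor with levels
#'   `fission`, `fusion`. At least 50 rows and both classes required.
#' @param config A [run_config()]; `random_seed` seeds the forest.
#' @return An object of class `mito_forest`: the fitted
#'   [randomForest::randomForest] plus `oob_error` (overall OOB
#'   misclassification, the weighted mean of the class errors),
#'   `class_errors`, and the training matrix.
#' @export
train_forest <- function(features, config = run_config()) {
  dat <- .forest_data(features)
  .with_seed(config$random_seed, {
    fit <- randomForest::randomForest(
      x = dat$x, y = dat$y,
      ntree = config$n_trees,
      mtry = config$rf_split_candidates,
      importance = TRUE, keep.forest = TRUE, keep.inbag = TRUE)
    conf <- fit$confusion
    class_errors <- conf[, "class.error"]
    structure(list(fit = fit,
                   oob_error = unname(fit$err.rate[config$n_trees, "OOB"]),
                   class_errors = c(fission = unname(class_errors["fission"]),
                                    fusion = unname(class_errors["fusion"])),
                   x = dat$x, y = dat$y, config = config),
              class = "mito_forest")
  })
}

.forest_data <- function(features) {
  feats <- mito_feature_names()
  missing_cols <- setdiff(c(feats, "event_call"), names(features))
  if (length(missing_cols) > 0L) {
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(features) < 50L) {
    stop("need at least 50 events to train the forest", call. = FALSE)
  }
  y <- factor(features$event_call, levels = c("fission", "fusion"))
  if (any(table(y) == 0L)) {
    stop("both fission and fusion events are required", call. = FALSE)
  }
  x <- as.data.frame(features[, feats])
  n_imputed <- 0L
  for (nm in feats) {
    bad <- !is.finite(x[[nm]])
    if (any(bad)) {
      fill <- if (all(bad)) 0 else stats::median(x[[nm]][!bad])
      x[[nm]][bad] <- fill
      n_imputed <- n_imputed + sum(bad)
    }
  }
  if (all(vapply(x, function(v) length(unique(v)) == 1L, logical(1)))) {
    stop("all features are constant", call. = FALSE)
  }
  if (n_imputed > 0L) {
    message("imputed ", n_imputed,
            " missing feature values by the column median")
  }
  list(x = x, y = y)
}

#' @export
print.mito_forest <- function(x, ...) {
  cat(sprintf("<mito_forest> %d trees, mtry %d, OOB error %.3f (fission %.3f, fusion %.3f)\n",
              x$fit$ntree, x$fit$mtry, x$oob_error,
              x$class_errors["fission"], x$class_errors["fusion"]))
  invisible(x)
}

#' Feature importance ranking with uncertainties
#'
#' Permutation importance: the mean per-tree increase in out-of-bag
#' misclassification when a feature's values are permuted among the
#' out-of-bag samples, with the associated per-tree spread (SD of the
#' per-tree increases scaled by the tree count). Class-conditional columns
#' restrict the error to events of one true class. Features are ranked by
#' the overall importance, descending. With `config$importance_refit` the
#' importance is instead the OOB-error increase of a forest refitted without
#' the feature (no per-tree SD is defined for that variant).
#'
#' @param model A `mito_forest` from [train_forest()].
#' @return A tibble of class `mito_importance` with 11 rows: `rank`,
#'   `feature`, `importance_all`, `sd_all`, `importance_fission`,
#'   `sd_fission`, `importance_fusion`, `sd_fusion`.
#' @export
importance_ranking <- function(model) {
  stopifnot(inherits(model, "mito_forest"))
  if (isTRUE(model$config$importance_refit)) {
    return(.importance_refit(model))
  }
  imp <- randomForest::importance(model$fit, scale = FALSE)
  sds <- model$fit$importanceSD
  out <- tibble::tibble(
    feature = rownames(imp),
    importance_all = unname(imp[, "MeanDecreaseAccuracy"]),
    sd_all = unname(sds[, "MeanDecreaseAccuracy"]),
    importance_fission = unname(imp[, "fission"]),
    sd_fission = unname(sds[, "fission"]),
    importance_fusion = unname(imp[, "fusion"]),
    sd_fusion = unname(sds[, "fusion"]))
  out <- dplyr::arrange(out, dplyr::desc(.data$importance_all))
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
  class(out) <- c("mito_importance", class(out))
  out
}

.importance_refit <- function(model) {
  base <- model$oob_error
  cfg <- model$config
  rows <- purrr::map(mito_feature_names(), function(nm) {
    keep <- setdiff(mito_feature_names(), nm)
    fit <- .with_seed(cfg$random_seed, randomForest::randomForest(
      x = model$x[, keep], y = model$y, ntree = cfg$n_trees,
      mtry = min(cfg$rf_split_candidates, length(keep))))
    conf <- fit$confusion
    tibble::tibble(
      feature = nm,
      importance_all = unname(fit$err.rate[cfg$n_trees, "OOB"]) - base,
      sd_all = NA_real_,
      importance_fission = unname(conf["fission", "class.error"]) -
        unname(model$class_errors["fission"]),
      sd_fission = NA_real_,
      importance_fusion = unname(conf["fusion", "class.error"]) -
        unname(model$class_errors["fusion"]),
      sd_fusion = NA_real_)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows),
                        dplyr::desc(.data$importance_all))
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
  class(out) <- c("mito_importance", class(out))
  out
}

#' Class error as a function of forest size
#'
#' Out-of-bag class errors of the nested sub-ensembles formed by the first
#' `n` trees, for `n = 1 ... n_trees` — the curve that shows the error
#' stabilizing once the forest exceeds a hundred-odd trees.
#'
#' @param model A `mito_forest`.
#' @return A tibble with columns `n_trees`, `oob_error`, `fission_error`,
#'   `fusion_error`.
#' @export
class_error_curve <- function(model) {
  stopifnot(inherits(model, "mito_forest"))
  er <- model$fit$err.rate
  tibble::tibble(n_trees = seq_len(nrow(er)),
                 oob_error = unname(er[, "OOB"]),
                 fission_error = unname(er[, "fission"]),
                 fusion_error = unname(er[, "fusion"]))
}

#' Single-bifurcation decision boundary for one feature
#'
#' Trains the most basic unit of the forest — a depth-one classification
#' tree — on a single feature: the threshold minimizing the Gini impurity of
#' the two-way split, scanned over all midpoints between consecutive sorted
#' unique values, ties broken toward the smaller threshold. Each side is
#' labeled by its majority class.
#'
#' @param features Feature tibble with `event_call`, or a numeric vector.
#' @param feature Feature name (when `features` is a tibble).
#' @param labels Factor of `fission`/`fusion` (when `features` is a vector).
#' @return A one-row tibble: `feature`, `threshold`, `fission_side`
#'   (`"high"` or `"low"`), `gini`.
#' @export
stump_boundary <- function(features, feature = NULL, labels = NULL) {
  if (is.data.frame(features)) {
    stopifnot(!is.null(feature))
    x <- features[[feature]]
    y <- factor(features$event_call, levels = c("fission", "fusion"))
  } else {
    x <- as.numeric(features)
    y <- factor(labels, levels = c("fission", "fusion"))
    if (is.null(feature)) feature <- "x"
  }
  keep <- is.finite(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  ux <- sort(unique(x))
  if (length(ux) < 2L) stop("feature is constant", call. = FALSE)
  cuts <- (ux[-1] + ux[-length(ux)]) / 2
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  fis <- cumsum(y[ord] == "fission")
  tot <- seq_len(n)
  # left counts at each cut: number of x <= cut
  nl <- findInterval(cuts, xs)
  fl <- fis[nl]
  nr <- n - nl
  fr <- fis[n] - fl
  gini <- function(f, m) ifelse(m == 0, 0, 2 * (f / m) * (1 - f / m))
  score <- (nl / n) * gini(fl, nl) + (nr / n) * gini(fr, nr)
  best <- which(score <= min(score) + 1e-12)[1]  # tie -> smaller threshold
  thr <- cuts[best]
  p_fis_high <- (fis[n] - fis[findInterval(thr, xs)]) / (n - findInterval(thr, xs))
  p_fis_low <- fis[findInterval(thr, xs)] / findInterval(thr, xs)
  tibble::tibble(feature = feature, threshold = thr,
                 fission_side = if (p_fis_high >= p_fis_low) "high" else "low",
                 gini = score[best])
}

# ---- broom-style tidiers ---------------------------------------------------

#' Tidy a fitted mitochondrial forest
#'
#' `tidy()` returns the importance ranking (one row per feature);
#' `glance()` returns a one-row model summary.
#'
#' @param x A `mito_forest`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mito_forest
#' @export
tidy.mito_forest <- function(x, ...) {
  importance_ranking(x)
}

#' @rdname tidy.mito_forest
#' @method glance mito_forest
#' @export
glance.mito_forest <- function(x, ...) {
  tibble::tibble(n_trees = x$fit$ntree,
                 mtry = x$fit$mtry,
                 n_events = length(x$y),
                 n_fission = sum(x$y == "fission"),
                 n_fusion = sum(x$y == "fusion"),
                 oob_error = x$oob_error,
                 fission_error = unname(x$class_errors["fission"]),
                 fusion_error = unname(x$class_errors["fusion"]))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
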