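# Three-class random forest (BRCA1 / BRCA2 / none): feature selection,
# class resampling, grid search, repeated nested-CV blacklisting, final
# training, prediction and QC.

.CLASSES <- c("BRCA1", "BRCA2", "none")

.as_class_labels <- function(labels) {
  labels <- factor(as.character(labels), levels = .CLASSES)
  if (anyNA(labels)) stop("labels must be BRCA1, BRCA2 or none")
  labels
}

.as_feature_matrix <- function(features) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  x
}

#' Rank-based feature selection
#'
#' Retains features that are significantly higher in BRCA1/2-deficient than
#' in proficient samples by a one-tailed Wilcoxon rank-sum test
#' (deficient > proficient, p < 0.01 by default). The exact null
#' distribution is used for small untied samples and the normal
#' approximation with tie correction otherwise.
#'
#' @param features Samples-by-features numeric matrix.
#' @param labels Class labels (`"BRCA1"`, `"BRCA2"`, `"none"`); the two
#'   deficient classes are pooled for the test.
#' @param p_cutoff One-sided p-value threshold.
#' @return Character vector of selected feature names.
#' @export
select_features_wilcoxon <- function(features, labels, p_cutoff = 0.01) {
  features <- .as_feature_matrix(features)
  labels <- .as_class_labels(labels)
  deficient <- labels != "none"
  if (sum(deficient) < 2 || sum(!deficient) < 2) {
    stop("need at least 2 deficient and 2 proficient samples")
  }
  p <- apply(features, 2, function(x) {
    if (length(unique(x)) == 1) return(1)
    suppressWarnings(
      wilcox.test(x[deficient], x[!deficient], alternative = "greater")$p.value
    )
  })
  names(p)[p < p_cutoff]
}

#' Resampling parameter grid
#'
#' The class-resampling grid searched during training: down-sampling of the
#' "none" class by 1x (none), 2x or 4x, crossed with up-sampling of the
#' minority "BRCA1" class by 1x, 1.5x or 2x. Rows are in row-major order
#' (down-sampling outer), which fixes the deterministic tie-break: the first
#' row with the maximal cross-validated AUPRC wins.
#'
#' @return `data.frame` with columns `down_none` and `up_brca1` (9 rows).
#' @export
hrd_resampling_grid <- function() {
  g <- expand.grid(up_brca1 = c(1, 1.5, 2), down_none = c(1, 2, 4))
  data.frame(down_none = g$down_none, up_brca1 = g$up_brca1)
}

# Stratified k-fold assignment (per-class round-robin of shuffled indices)
.make_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Resampled training indices: "none" down-sampled without replacement,
# "BRCA1" up-sampled with replacement; "BRCA2" untouched.
.resample_indices <- function(labels, down_none, up_brca1, seed) {
  set.seed(seed)
  i_none <- which(labels == "none")
  i_b1 <- which(labels == "BRCA1")
  i_b2 <- which(labels == "BRCA2")
  keep_none <- if (down_none > 1) {
    sample(i_none, max(1L, floor(length(i_none) / down_none)))
  } else i_none
  extra_b1 <- if (up_brca1 > 1 && length(i_b1) > 0) {
    sample(i_b1, round(length(i_b1) * (up_brca1 - 1)), replace = TRUE)
  } else integer(0)
  c(i_b1, extra_b1, i_b2, keep_none)
}

.fit_forest <- function(x, y, ntree, seed, importance = FALSE) {
  set.seed(seed)
  randomForest::randomForest(x = x, y = y, ntree = ntree,
                             importance = importance)
}

# Out-of-fold HRD probabilities for one 10-fold CV round with fixed
# features and resampling parameters. Resampling touches training folds
# only, so evaluation folds contain only original samples.
.oof_p_hrd <- function(x, labels, fold, down_none, up_brca1, ntree, seed) {
  p_hrd <- rep(NA_real_, nrow(x))
  for (f in sort(unique(fold))) {
    tr <- which(fold != f)
    ri <- tr[.resample_indices(labels[tr], down_none, up_brca1,
                               seed = seed + 7L * f)]
    fit <- .fit_forest(x[ri, , drop = FALSE], droplevels(labels[ri]),
                       ntree, seed = seed + 13L * f)
    pr <- predict(fit, x[fold == f, , drop = FALSE], type = "prob")
    p1 <- if ("BRCA1" %in% colnames(pr)) pr[, "BRCA1"] else 0
    p2 <- if ("BRCA2" %in% colnames(pr)) pr[, "BRCA2"] else 0
    p_hrd[fold == f] <- p1 + p2
  }
  p_hrd
}

#' Choose class-resampling parameters by cross-validated grid search
#'
#' For each cell of the resampling grid, performs stratified 10-fold CV
#' (resampling applied within training folds only), scores the out-of-fold
#' HRD probabilities (positive class = BRCA1 or BRCA2 deficient) by AUPRC,
#' and returns the cell with the highest AUPRC (first cell in grid order on
#' ties).
#'
#' @inheritParams select_features_wilcoxon
#' @param grid Candidate parameters, see [hrd_resampling_grid()].
#' @param cv_folds Number of stratified CV folds.
#' @param seed Integer seed governing folding, resampling and forest fits.
#' @param ntree Trees per forest.
#' @return List with `down_none`, `up_brca1` and the per-cell `auprc`.
#' @export
grid_search_resampling <- function(features, labels,
                                   grid = hrd_resampling_grid(),
                                   cv_folds = 10, seed = 1, ntree = 500) {
  x <- .as_feature_matrix(features)
  labels <- .as_class_labels(labels)
  if (any(table(labels) == 0)) {
    stop("labels must contain all three classes")
  }
  fold <- .make_folds(labels, cv_folds, seed)
  positive <- labels != "none"
  auprc <- vapply(seq_len(nrow(grid)), function(ci) {
    p <- .oof_p_hrd(x, labels, fold, grid$down_none[ci], grid$up_brca1[ci],
                    ntree, seed = seed + 1000L * ci)
    .avg_precision(p, positive)
  }, numeric(1))
  best <- which.max(auprc)  # ties: first cell in row-major grid order
  list(down_none = grid$down_none[best], up_brca1 = grid$up_brca1[best],
       auprc = cbind(grid, auprc = auprc))
}

#' Core training: feature selection, resampling search, forest fit
#'
#' The core procedure behind [hrd_train()]: one-tailed Wilcoxon feature
#' selection, grid search over class-resampling parameters, resampling of
#' the full training set with the chosen parameters, and a final
#' three-class random forest fit. Use directly when blacklisting is not
#' wanted (e.g. on a pre-filtered training set).
#'
#' @inheritParams grid_search_resampling
#' @param p_cutoff Feature-selection p-value threshold.
#' @param cutoff HRD probability cutoff stored in the model.
#' @return A fitted model of class `hrdforest`.
#' @export
hrd_train_core <- function(features, labels, seed = 1, ntree = 500,
                           cv_folds = 10, p_cutoff = 0.01,
                           grid = hrd_resampling_grid(), cutoff = 0.5) {
  x <- .as_feature_matrix(features)
  labels <- .as_class_labels(labels)
  if (any(table(labels) < 2)) {
    stop("training needs at least 2 samples in each of the three classes")
  }
  sel <- select_features_wilcoxon(x, labels, p_cutoff)
  if (length(sel) < 2) stop("fewer than 2 features selected")
  xs <- x[, sel, drop = FALSE]
  gs <- grid_search_resampling(xs, labels, grid = grid, cv_folds = cv_folds,
                               seed = seed, ntree = ntree)
  ri <- .resample_indices(labels, gs$down_none, gs$up_brca1, seed = seed + 1L)
  forest <- .fit_forest(xs[ri, , drop = FALSE], labels[ri], ntree,
                        seed = seed + 2L, importance = TRUE)
  structure(list(forest = forest, features = sel,
                 resampling = list(down_none = gs$down_none,
                                   up_brca1 = gs$up_brca1,
                                   auprc = gs$auprc),
                 cutoff = cutoff, seed = seed, ntree = ntree,
                 classes = .CLASSES, blacklist = NULL,
                 n_train = nrow(x), call = match.call()),
            class = "hrdforest")
}

#' Blacklist inconsistently predicted training samples
#'
#' Repeated nested cross-validation: features and resampling parameters are
#' fixed once (computed on the full labeled set), then `repeats` rounds of
#' stratified 10-fold CV produce out-of-fold HRD calls for every sample.
#' Deficient-labeled (BRCA1/BRCA2) samples predicted HRD in fewer than
#' `hrd_min_frac` of the rounds, and "none"-labeled samples predicted HRD in
#' more than `hrp_max_frac` of the rounds, are blacklisted. With the default
#' 100 repeats these fractions reproduce the <60 / >40 call-count rule.
#'
#' @inheritParams hrd_train_core
#' @param repeats Number of repeated CV rounds (must be >= 1).
#' @param folds CV folds per round.
#' @param hrd_min_frac,hrp_max_frac Blacklisting fractions.
#' @return List with `blacklisted` (integer indices), `hrd_counts` (HRD
#'   calls per sample), `repeats`, and the fixed `features`/`resampling`.
#' @export
blacklist_samples <- function(features, labels, repeats = 100, folds = 10,
                              seed = 1, ntree = 500, p_cutoff = 0.01,
                              grid = hrd_resampling_grid(), cutoff = 0.5,
                              hrd_min_frac = 0.6, hrp_max_frac = 0.4) {
  if (repeats < 1) stop("repeats must be >= 1")
  x <- .as_feature_matrix(features)
  labels <- .as_class_labels(labels)
  sel <- select_features_wilcoxon(x, labels, p_cutoff)
  if (length(sel) < 2) stop("fewer than 2 features selected")
  xs <- x[, sel, drop = FALSE]
  gs <- grid_search_resampling(xs, labels, grid = grid, cv_folds = folds,
                               seed = seed, ntree = ntree)
  counts <- integer(nrow(x))
  for (r in seq_len(repeats)) {
    fold <- .make_folds(labels, folds, seed = seed + 100000L + r)
    p <- .oof_p_hrd(xs, labels, fold, gs$down_none, gs$up_brca1, ntree,
                    seed = seed + 200000L + 1000L * r)
    counts <- counts + (p >= cutoff)
  }
  deficient <- labels != "none"
  bl <- which((deficient & counts < hrd_min_frac * repeats) |
              (!deficient & counts > hrp_max_frac * repeats))
  list(blacklisted = bl, hrd_counts = counts, repeats = repeats,
       features = sel,
       resampling = list(down_none = gs$down_none, up_brca1 = gs$up_brca1))
}

#' Train the HRD random-forest classifier
#'
#' The full two-stage training procedure. Stage 1 blacklists training
#' samples whose out-of-fold predictions across repeated nested
#' cross-validation contradict their genetic label (deficient samples
#' rarely predicted HRD, e.g. after reversion of the biallelic hit;
#' proficient samples frequently predicted HRD, e.g. deficient in another
#' HR gene). Stage 2 reapplies the core procedure
#' ([hrd_train_core()]) to the filtered training set, yielding the final
#' model. The model predicts per-sample probabilities of BRCA1-type and
#' BRCA2-type deficiency; their sum is the HRD probability, thresholded at
#' `cutoff` (default 0.5).
#'
#' @inheritParams blacklist_samples
#' @return A fitted model of class `hrdforest` with methods
#'   [predict.hrdforest()], `print`, `summary` and `plot`.
#' @examples
#' sim <- simulate_cohort(n_brca1 = 12, n_brca2 = 12, n_none = 40, seed = 1)
#' fit <- hrd_train(sim$features, sim$labels, seed = 1, repeats = 2,
#'                  ntree = 50)
#' predict(fit, sim$features[1:3, ])
#' @export
hrd_train <- function(features, labels, seed = 1, repeats = 100, folds = 10,
                      ntree = 500, p_cutoff = 0.01,
                      grid = hrd_resampling_grid(), cutoff = 0.5,
                      hrd_min_frac = 0.6, hrp_max_frac = 0.4) {
  x <- .as_feature_matrix(features)
  labels <- .as_class_labels(labels)
  bl <- blacklist_samples(x, labels, repeats = repeats, folds = folds,
                          seed = seed, ntree = ntree, p_cutoff = p_cutoff,
                          grid = grid, cutoff = cutoff,
                          hrd_min_frac = hrd_min_frac,
                          hrp_max_frac = hrp_max_frac)
  keep <- setdiff(seq_len(nrow(x)), bl$blacklisted)
  fit <- hrd_train_core(x[keep, , drop = FALSE], labels[keep], seed = seed,
                        ntree = ntree, cv_folds = folds, p_cutoff = p_cutoff,
                        grid = grid, cutoff = cutoff)
  fit$blacklist <- list(indices = bl$blacklisted,
                        samples = rownames(x)[bl$blacklisted],
                        hrd_counts = bl$hrd_counts, repeats = repeats)
  fit$call <- match.call()
  fit
}

#' Predict HRD status for new samples
#'
#' Returns the forest's three class probabilities, the HRD probability
#' (`p_hrd = p_brca1 + p_brca2`), the HRD/HRP call (`HRD` when
#' `p_hrd >= cutoff`), and the HRD subtype (argmax of the two deficiency
#' probabilities when called HRD; an exact tie resolves to BRCA2-type, the
#' larger class).
#'
#' @param object A fitted `hrdforest` model.
#' @param newdata Samples-by-features matrix or data.frame containing at
#'   least the model's selected features (missing features are an error).
#' @param ... Unused.
#' @return `data.frame` with columns `sample`, `p_brca1`, `p_brca2`,
#'   `p_none`, `p_hrd`, `hr_status`, `hrd_type`.
#' @export
predict.hrdforest <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  newdata <- .as_feature_matrix(newdata)
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing)) {
    stop("missing features: ", paste(missing, collapse = ", "))
  }
  x <- newdata[, object$features, drop = FALSE]
  pr <- predict(object$forest, x, type = "prob")
  p1 <- pr[, "BRCA1"]; p2 <- pr[, "BRCA2"]; p0 <- pr[, "none"]
  p_hrd <- p1 + p2
  hrd <- p_hrd >= object$cutoff
  data.frame(
    sample = rownames(x),
    p_brca1 = unname(p1), p_brca2 = unname(p2), p_none = unname(p0),
    p_hrd = unname(p_hrd),
    hr_status = ifelse(hrd, "HRD", "HRP"),
    hrd_type = ifelse(!hrd, "none",
                      ifelse(p1 > p2, "BRCA1-type", "BRCA2-type")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Quality-control gate for HRD calls
#'
#' A reliable call requires absence of microsatellite instability, at least
#' `min_indels` indels in total, and — when the sample is predicted HRD —
#' at least `min_svs` SVs within the 16 SV contexts. Returns the failing
#' flags; an empty vector means the sample passes QC.
#'
#' @param profile A [extract_profile()] result.
#' @param prediction A row of [predict.hrdforest()] output, the string
#'   `"HRD"`/`"HRP"`, or `NULL` (treated as not predicted HRD).
#' @param min_indels,min_svs,msi_threshold QC thresholds.
#' @return Character vector, subset of `c("MSI", "LOW_INDEL", "LOW_SV")`.
#' @export
apply_qc <- function(profile, prediction = NULL, min_indels = 50,
                     min_svs = 30, msi_threshold = 14000) {
  flags <- character(0)
  if (detect_msi(profile, msi_threshold)) flags <- c(flags, "MSI")
  if (sum(profile[indel_context_keys()]) < min_indels) {
    flags <- c(flags, "LOW_INDEL")
  }
  is_hrd <- if (is.null(prediction)) {
    FALSE
  } else if (is.character(prediction)) {
    identical(prediction, "HRD")
  } else {
    identical(as.character(prediction$hr_status[1]), "HRD")
  }
  if (is_hrd && sum(profile[sv_context_keys()]) < min_svs) {
    flags <- c(flags, "LOW_SV")
  }
  flags
}

#' Feature importance of a fitted model
#'
#' Mean decrease in accuracy, overall or for one class (e.g. the BRCA1
#' column shows which features separate BRCA1-type deficiency from the
#' rest — dominated by 1-100 kb duplications).
#'
#' @param model A fitted `hrdforest`.
#' @param class `NULL` for overall importance, or one of `"BRCA1"`,
#'   `"BRCA2"`, `"none"`.
#' @return Named numeric vector sorted decreasingly.
#' @export
hrd_importance <- function(model, class = NULL) {
  imp <- randomForest::importance(model$forest, type = 1, scale = TRUE)
  if (!is.null(class)) {
    imp <- randomForest::importance(model$forest, scale = TRUE)[, class,
                                                                drop = FALSE]
  }
  sort(setNames(imp[, 1], rownames(imp)), decreasing = TRUE)
}

#' Persist / restore a fitted model
#'
#' Models are written as a small versioned archive (format tag, package
#' version, model object) so that a reloaded model reproduces identical
#' predictions.
#'
#' @param model A fitted `hrdforest`.
#' @param path File path.
#' @return `read_hrdforest()` returns the restored `hrdforest`.
#' @export
write_hrdforest <- function(model, path) {
  stopifnot(inherits(model, "hrdforest"))
  saveRDS(list(format = "hrdforest-model", format_version = 1L,
               package_version = as.character(packageVersion("hrdforest")),
               model = model), path)
  invisible(path)
}

#' @rdname write_hrdforest
#' @export
read_hrdforest <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "hrdforest-model")) {
    stop("not a persisted hrdforest model: ", path)
  }
  obj$model
}

#' @export
print.hrdforest <- function(x, ...) {
  cat("HRD random-forest classifier\n")
  cat("  classes:", paste(x$classes, collapse = " / "), "\n")
  cat("  trees:", x$ntree, " selected features:", length(x$features), "\n")
  cat("  resampling: none class down", paste0(x$resampling$down_none, "x,"),
      "BRCA1 class up", paste0(x$resampling$up_brca1, "x"), "\n")
  cat("  HRD cutoff:", x$cutoff, " seed:", x$seed, "\n")
  if (!is.null(x$blacklist)) {
    cat("  blacklisted during training:", length(x$blacklist$indices),
        "sample(s) over", x$blacklist$repeats, "repeats\n")
  }
  invisible(x)
}

#' @export
summary.hrdforest <- function(object, ...) {
  print(object)
  cat("\nTop features (mean decrease in accuracy):\n")
  imp <- hrd_importance(object)
  print(round(head(imp, 10), 2))
  invisible(object)
}

#' @export
plot.hrdforest <- function(x, n = 15, ...) {
  imp <- rev(head(hrd_importance(x), n))
  dotchart(imp, pch = 19, xlab = "Mean decrease in accuracy",
           main = "Feature importance", ...)
  invisible(x)
}
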