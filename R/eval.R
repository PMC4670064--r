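#' k-fold cross-validation assignments
#'
#' Random partition of `n` presences into `k` folds whose sizes differ by
#' at most one; the same seed reproduces the same folds.
#'
#' @param n number of presences (must be `>= k`).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return Integer vector of fold labels in `1..k`, length `n`.
#' @export
kfold_assign <- function(n, k = 10, seed = 1L) {
  if (n < k) stop_named("need at least k = %d presences, got %d", k, n)
  folds <- rep(seq_len(k), length.out = n)
  with_seed(seed, sample(folds))
}

#' Rank-based ROC AUC for presence-background scores
#'
#' Mann-Whitney estimator: the probability that a random presence scores
#' higher than a random background point, ties counted half. Background
#' points play the role of the negative class (the presence-background
#' convention).
#'
#' @param scores_presence,scores_background numeric score vectors.
#' @return AUC in `[0, 1]`; exactly 0.5 (with a warning) when all scores
#'   are identical.
#' @export
roc_auc <- function(scores_presence, scores_background) {
  n1 <- length(scores_presence); n0 <- length(scores_background)
  if (!n1 || !n0) stop_named("both score sets must be nonempty")
  all_scores <- c(scores_presence, scores_background)
  if (length(unique(all_scores)) == 1L) {
    warn_named("all scores identical; AUC = 0.5")
    return(0.5)
  }
  r <- rank(all_scores)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Partial-ROC ratio of a suitability prediction
#'
#' Bootstrap partial-ROC evaluation: the ROC curve is formed from the
#' cumulative suitability distribution of the prediction raster (x = the
#' proportion of the landscape predicted at or above a threshold) against
#' the sensitivity of the test presences (y = proportion of test points at
#' or above the threshold). Restricted to the region with sensitivity
#' `>= 1 - E`, the ratio compares the area under the model curve with the
#' area under the diagonal (the random expectation) over the same
#' x-interval; a ratio above 1 indicates better-than-random performance.
#' Per bootstrap replicate, `boot_prop` of the test points are resampled
#' with replacement; `p` is the fraction of replicate ratios `<= 1`.
#'
#' @param pred a [raster_grid()] of suitability, or the numeric vector of
#'   landscape suitability values.
#' @param test_points data frame of test coordinates (`x`/`y` or
#'   `longitude`/`latitude`) when `pred` is a raster, or a numeric vector
#'   of test-point suitability scores.
#' @param E allowed omission (default 0; must be `< 1`).
#' @param boot_prop proportion of test points resampled per replicate.
#' @param reps bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return List: `ratio` (full-data), `ratio_mean`, `ratio_sd`, `p`,
#'   and the replicate `ratios`.
#' @export
partial_roc <- function(pred, test_points, E = 0, boot_prop = 0.5,
                        reps = 1000, seed = 1L) {
  if (E >= 1 || E < 0) stop_named("E must be in [0, 1)")
  if (is_raster_grid(pred)) {
    vals <- as.vector(pred$values)
    vals <- vals[!is.na(vals)]
    if (is.numeric(test_points)) {
      test <- test_points
    } else {
      cell <- cell_from_xy(pred, test_points[[1L]], test_points[[2L]])
      test <- pred$values[cell]
      if (anyNA(test)) stop_named("test points fall on nodata or outside")
    }
  } else {
    vals <- pred[!is.na(pred)]
    test <- test_points
  }
  # landscape cumulative fraction >= t, evaluated on the threshold grid
  thr <- sort(unique(if (length(vals) > 4000L) {
    stats::quantile(vals, seq(0, 1, length.out = 4000L), names = FALSE)
  } else vals))
  sv <- sort(vals)
  x_area <- 1 - (findInterval(thr, sv, left.open = TRUE)) / length(sv)

  one_ratio <- function(scores) {
    ss <- sort(scores)
    y <- 1 - findInterval(thr, ss, left.open = TRUE) / length(ss)
    keep <- y >= 1 - E
    if (sum(keep) < 2L) return(NA_real_)
    xs <- x_area[keep]; ys <- y[keep]
    # interpolate the boundary crossing for a stable region edge
    last <- max(which(keep))
    if (last < length(thr) && E > 0) {
      y1 <- y[last]; y2 <- y[last + 1L]
      if (y1 > y2) {
        f <- (y1 - (1 - E)) / (y1 - y2)
        xs <- c(xs, x_area[last] + f * (x_area[last + 1L] - x_area[last]))
        ys <- c(ys, 1 - E)
      }
    }
    auc_model <- trapz(xs, ys)
    xr <- range(xs)
    auc_rand <- (xr[2L]^2 - xr[1L]^2) / 2
    if (auc_rand <= 0) return(NA_real_)
    auc_model / auc_rand
  }

  ratio_full <- one_ratio(test)
  nb <- max(1L, ceiling(boot_prop * length(test)))
  ratios <- with_seed(seed, vapply(seq_len(reps), function(r) {
    one_ratio(sample(test, nb, replace = TRUE))
  }, numeric(1L)))
  ratios_ok <- ratios[!is.na(ratios)]
  list(ratio = ratio_full,
       ratio_mean = mean(ratios_ok),
       ratio_sd = stats::sd(ratios_ok),
       p = mean(ratios_ok <= 1),
       ratios = ratios)
}

#' Training-omission thresholds and test sensitivity
#'
#' `omission_thresholds()` returns, for each omission rate `r`, the
#' `r`-quantile (type 1, an order statistic; 0% gives the minimum) of the
#' training presence scores. `omission_sensitivity()` is the fraction of
#' test presences scoring at or above a threshold; sensitivity is monotone
#' non-increasing in the threshold.
#'
#' @param train_scores training presence suitability scores (nonempty).
#' @param rates omission rates (default 0% and 10%).
#' @return Named numeric vector of thresholds.
#' @export
omission_thresholds <- function(train_scores, rates = c(0, 0.10)) {
  if (!length(train_scores)) stop_named("training scores are empty")
  thr <- stats::quantile(train_scores, rates, type = 1L, names = FALSE)
  names(thr) <- paste0(rates * 100, "%")
  thr
}

#' @rdname omission_thresholds
#' @param test_scores test presence suitability scores (nonempty).
#' @param threshold suitability threshold.
#' @export
omission_sensitivity <- function(test_scores, threshold) {
  if (!length(test_scores)) stop_named("test scores are empty")
  mean(test_scores >= threshold)
}

#' Cross-validated evaluation of a maximum-entropy model
#'
#' k-fold evaluation: per fold, the model is refitted on the training
#' presences (background fixed), and the held-out presences are scored
#' against the background for a test AUC. Omission thresholds come from the
#' training-fold scores and the corresponding held-out sensitivities (and
#' omission rates) are averaged over folds. The partial-ROC ratio is
#' computed from the full-data model on the landscape.
#'
#' @param presence,background raw environment tables.
#' @param landscape raw environment of the full calibration extent (for
#'   the partial-ROC curve); defaults to `background`.
#' @param classes,beta,n_hinge_knots,bg_weights,control passed to
#'   [maxent_sdm()].
#' @param k folds (default 10).
#' @param proc_reps,proc_E partial-ROC settings.
#' @param seed integer seed for folds and bootstrap.
#' @return Object of class `sdm_eval`: per-fold table, summary statistics
#'   (`auc_mean`, `auc_sd`, `pauc`), thresholds and sensitivities.
#' @export
evaluate_sdm <- function(presence, background, landscape = NULL,
                         classes = "lqh", beta = 1, k = 10,
                         n_hinge_knots = 50, bg_weights = NULL,
                         proc_reps = 1000, proc_E = 0, seed = 1L,
                         control = list()) {
  presence <- as.matrix(presence)
  landscape <- landscape %||% background
  folds <- kfold_assign(nrow(presence), k = k, seed = derive_seed(seed, "cv"))
  full <- maxent_sdm(presence, background, classes = classes, beta = beta,
                     n_hinge_knots = n_hinge_knots, bg_weights = bg_weights,
                     control = control)
  fold_control <- utils::modifyList(control, list(init = full$lambda))
  per_fold <- lapply(seq_len(k), function(f) {
    train <- presence[folds != f, , drop = FALSE]
    test <- presence[folds == f, , drop = FALSE]
    m <- maxent_sdm(train, background, classes = classes, beta = beta,
                    n_hinge_knots = n_hinge_knots, bg_weights = bg_weights,
                    control = fold_control)
    s_test <- predict(m, test)
    s_train <- predict(m, train)
    s_bg <- predict(m, as.matrix(background))
    thr <- omission_thresholds(s_train)
    data.frame(fold = f,
               auc = roc_auc(s_test, s_bg),
               thr0 = thr[[1L]], thr10 = thr[[2L]],
               sens0 = omission_sensitivity(s_test, thr[[1L]]),
               sens10 = omission_sensitivity(s_test, thr[[2L]]))
  })
  tab <- do.call(rbind, per_fold)
  proc <- partial_roc(predict(full, as.matrix(landscape)),
                      predict(full, presence), E = proc_E, reps = proc_reps,
                      seed = derive_seed(seed, "proc"))
  structure(list(folds = folds, per_fold = tab,
                 auc_mean = mean(tab$auc), auc_sd = stats::sd(tab$auc),
                 pauc = proc[c("ratio", "ratio_mean", "ratio_sd", "p")],
                 sens0_mean = mean(tab$sens0), sens10_mean = mean(tab$sens10),
                 omission0_mean = 1 - mean(tab$sens0),
                 omission10_mean = 1 - mean(tab$sens10),
                 model = full, seed = seed),
            class = "sdm_eval")
}

#' @export
print.sdm_eval <- function(x, ...) {
  cat("Cross-validated model evaluation\n")
  cat(sprintf("  test AUC (cv): %.3f +/- %.3f over %d folds\n",
              x$auc_mean, x$auc_sd, nrow(x$per_fold)))
  cat(sprintf("  pAUC ratio: %.3f +/- %.3f (p = %.3f)\n",
              x$pauc$ratio_mean, x$pauc$ratio_sd, x$pauc$p))
  cat(sprintf("  test sensitivity at 0%%/10%% training omission: %.3f / %.3f\n",
              x$sens0_mean, x$sens10_mean))
  cat(sprintf("  test omission at 0%%/10%% training omission: %.3f / %.3f\n",
              x$omission0_mean, x$omission10_mean))
  invisible(x)
}
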