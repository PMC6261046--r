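#' Z-score standardization
#'
#' Subtracts the mean and divides by the standard deviation.
#'
#' @param values Numeric vector with at least 2 values and nonzero variance.
#' @return Standardized vector (mean 0, sd 1).
#' @export
zscore <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to z-score")
  s <- stats::sd(values)
  if (s == 0) stop("cannot z-score a constant vector")
  (values - mean(values)) / s
}

#' Classifier evaluation configuration
#'
#' @param thresholds Posterior-probability thresholds; default the ten
#'   values 0.750, 0.775, ..., 0.975.
#' @param n_permutations Label permutations for the chance distribution
#'   (default 100).
#' @param alpha_z Significance level of the z-test against chance (default
#'   0.05).
#' @param alpha_sign Significance level of the cross-instance sign test
#'   (default 0.05).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(thresholds = seq(0.750, 0.975, by = 0.025),
                              n_permutations = 100L, alpha_z = 0.05,
                              alpha_sign = 0.05) {
  stopifnot(all(diff(thresholds) > 0), all(thresholds > 0.5),
            all(thresholds < 1), n_permutations >= 2)
  structure(list(thresholds = thresholds,
                 n_permutations = as.integer(n_permutations),
                 alpha_z = alpha_z, alpha_sign = alpha_sign),
            class = "classifier_config")
}

#' Train the connection-existence classifier on simulated data
#'
#' Support vector machine with a linear kernel on the two z-scored
#' structural measures (absolute density difference, distance), with class
#' weights inversely proportional to class frequencies (uniform prior
#' probabilities over the two classes) and Platt-type sigmoid calibration of
#' the decision score into a posterior probability that a connection is
#' present.
#'
#' @param features Data frame or matrix with two columns (absolute density
#'   difference, distance); z-scored internally per column.
#' @param exists Binary existence labels (both classes must occur).
#' @param config A [classifier_config()] (kept with the object).
#' @return Object of class `sim_classifier`.
#' @export
train_classifier <- function(features, exists,
                             config = classifier_config()) {
  y <- factor(as.integer(exists), levels = c(0L, 1L))
  if (any(table(y) == 0L)) stop("training data must contain both classes")
  X <- as.matrix(as.data.frame(lapply(as.data.frame(features), zscore)))
  wt <- as.numeric(length(y) / (2 * table(y)))
  names(wt) <- levels(y)
  fit <- e1071::svm(X, y, kernel = "linear", probability = TRUE,
                    class.weights = wt, scale = FALSE)
  structure(list(svm = fit, feature_names = colnames(X), config = config),
            class = "sim_classifier")
}

#' Posterior probability of connection presence
#'
#' @param object A `sim_classifier`.
#' @param newdata Matrix or data frame of (already z-scored) feature
#'   columns in the order used for training.
#' @param ... Unused.
#' @return Numeric vector of `p_present` in (0, 1).
#' @export
predict.sim_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  colnames(X) <- object$feature_names
  pred <- stats::predict(object$svm, X, probability = TRUE)
  probs <- attr(pred, "probabilities")
  as.numeric(probs[, "1"])
}

#' Dual-threshold classification rule
#'
#' Labels a pair `present` when `p_present > threshold`, `absent` when
#' `p_present < 1 - threshold`, and `unclassified` in the intermediate band
#' where the posterior is not confident enough.
#'
#' @param p_present Posterior probabilities.
#' @param threshold Threshold probability in (0.5, 1).
#' @return Factor with levels `absent`, `unclassified`, `present`.
#' @export
classify_with_threshold <- function(p_present, threshold) {
  stopifnot(threshold > 0.5, threshold < 1)
  out <- rep("unclassified", length(p_present))
  out[p_present > threshold] <- "present"
  out[p_present < 1 - threshold] <- "absent"
  factor(out, levels = c("absent", "unclassified", "present"))
}

#' Evaluate predictions at one threshold
#'
#' Accuracy is the fraction of correct predictions among classified rows;
#' the Youden index J = sensitivity + specificity - 1 (0 = chance, 1 =
#' perfect) additionally requires both truth classes among the classified
#' rows; `fraction_classified` is the share of rows given a label at all.
#'
#' @param predictions Factor from [classify_with_threshold()].
#' @param truth Binary ground-truth existence.
#' @return List with `accuracy`, `youden_j`, `fraction_classified`,
#'   `n_classified`; undefined metrics are `NA`.
#' @export
evaluate_threshold <- function(predictions, truth) {
  truth <- as.integer(truth)
  classified <- predictions != "unclassified"
  n_cls <- sum(classified)
  frac <- if (length(predictions)) n_cls / length(predictions) else NA_real_
  if (n_cls == 0L)
    return(list(accuracy = NA_real_, youden_j = NA_real_,
                fraction_classified = frac, n_classified = 0L))
  pred_bin <- as.integer(predictions[classified] == "present")
  tr <- truth[classified]
  acc <- mean(pred_bin == tr)
  youden <- if (all(tr == 1L) || all(tr == 0L)) NA_real_ else {
    sens <- mean(pred_bin[tr == 1L] == 1L)
    spec <- mean(pred_bin[tr == 0L] == 0L)
    sens + spec - 1
  }
  list(accuracy = acc, youden_j = youden, fraction_classified = frac,
       n_classified = n_cls)
}

#' Permutation-based chance distribution and z-test
#'
#' Randomly permutes the truth labels, re-evaluates accuracy and Youden J at
#' the threshold for each permutation, fits each chance distribution to a
#' normal, and returns the two-tailed z-test p-value for the observed
#' metrics against that distribution.
#'
#' @param truth Binary ground-truth existence.
#' @param p_present Posterior probabilities (fixed across permutations).
#' @param threshold Threshold probability.
#' @param n_permutations Number of label permutations (default 100).
#' @return List with, per metric (`accuracy`, `youden_j`): observed value,
#'   `chance_mean`, `chance_sd`, `z`, `p_value` (two-sided; for a degenerate
#'   chance distribution, 1 when the observation equals the constant and 0
#'   otherwise, flagged via `degenerate`).
#' @export
permutation_null <- function(truth, p_present, threshold,
                             n_permutations = 100L) {
  stopifnot(n_permutations >= 2)
  predictions <- classify_with_threshold(p_present, threshold)
  obs <- evaluate_threshold(predictions, truth)
  chance <- matrix(NA_real_, n_permutations, 2,
                   dimnames = list(NULL, c("accuracy", "youden_j")))
  for (b in seq_len(n_permutations)) {
    ev <- evaluate_threshold(predictions, sample(truth))
    chance[b, ] <- c(ev$accuracy, ev$youden_j)
  }
  one <- function(metric) {
    o <- obs[[metric]]
    v <- chance[, metric]
    v <- v[is.finite(v)]
    if (!is.finite(o) || length(v) < 2L)
      return(list(observed = o, chance_mean = NA_real_,
                  chance_sd = NA_real_, z = NA_real_, p_value = NA_real_,
                  degenerate = FALSE))
    m <- mean(v)
    s <- stats::sd(v)
    if (s == 0)
      return(list(observed = o, chance_mean = m, chance_sd = 0,
                  z = if (o == m) 0 else Inf * sign(o - m),
                  p_value = if (o == m) 1 else 0, degenerate = TRUE))
    z <- (o - m) / s
    list(observed = o, chance_mean = m, chance_sd = s, z = z,
         p_value = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
  }
  list(accuracy = one("accuracy"), youden_j = one("youden_j"))
}

#' Evaluate a trained classifier on an empirical-format dataset
#'
#' Applies the dual-threshold rule at every configured threshold, evaluates
#' accuracy, Youden J and fraction classified, runs the permutation analysis
#' per threshold, and aggregates to the per-instance summary: mean metrics
#' and the median z-test p-value across thresholds with defined metrics.
#'
#' @param classifier A [train_classifier()] result.
#' @param dataset An empirical-format dataset ([generate_fixture()] or
#'   [read_empirical_csv()]): columns `exists`, `differentiation`,
#'   `distance`. Measures are z-scored with the dataset's own mean and sd.
#' @param config A [classifier_config()].
#' @return List of class `instance_evaluation`: `per_threshold` data frame,
#'   `mean_accuracy`, `mean_youden`, `mean_fraction_classified`,
#'   `median_p_accuracy`, `median_p_youden`, `missing` (TRUE when no
#'   threshold produced a defined metric).
#' @export
evaluate_classifier <- function(classifier, dataset,
                                config = classifier_config()) {
  X <- cbind(zscore(dataset$differentiation), zscore(dataset$distance))
  p_present <- predict(classifier, X)
  truth <- as.integer(dataset$exists)
  rows <- lapply(config$thresholds, function(thr) {
    predictions <- classify_with_threshold(p_present, thr)
    ev <- evaluate_threshold(predictions, truth)
    pn <- permutation_null(truth, p_present, thr,
                           n_permutations = config$n_permutations)
    data.frame(threshold = thr, accuracy = ev$accuracy,
               youden_j = ev$youden_j,
               fraction_classified = ev$fraction_classified,
               p_accuracy = pn$accuracy$p_value,
               p_youden = pn$youden_j$p_value)
  })
  per_thr <- do.call(rbind, rows)
  mean_def <- function(v) if (any(is.finite(v))) mean(v[is.finite(v)])
                          else NA_real_
  med_def <- function(v) if (any(is.finite(v)))
                           stats::median(v[is.finite(v)]) else NA_real_
  structure(
    list(per_threshold = per_thr,
         mean_accuracy = mean_def(per_thr$accuracy),
         mean_youden = mean_def(per_thr$youden_j),
         mean_fraction_classified = mean_def(per_thr$fraction_classified),
         median_p_accuracy = med_def(per_thr$p_accuracy),
         median_p_youden = med_def(per_thr$p_youden),
         missing = !any(is.finite(per_thr$accuracy))),
    class = "instance_evaluation")
}

#' Aggregate instance evaluations for one layout
#'
#' Medians of the per-instance mean metrics plus the left-tailed sign test
#' of the per-instance median z-test p-values against `alpha_z`. Instances
#' whose metrics were undefined at every threshold are excluded and counted.
#'
#' @param evaluations List of [evaluate_classifier()] results.
#' @param config A [classifier_config()].
#' @return One-row data frame with medians, sign-test `z`/`p` per metric,
#'   and `n_missing`.
#' @export
aggregate_layout <- function(evaluations, config = classifier_config()) {
  stopifnot(length(evaluations) >= 1)
  missing <- vapply(evaluations, `[[`, logical(1), "missing")
  ev <- evaluations[!missing]
  med <- function(name) {
    v <- vapply(ev, `[[`, numeric(1), name)
    if (any(is.finite(v))) stats::median(v[is.finite(v)]) else NA_real_
  }
  st <- function(name) {
    v <- vapply(ev, `[[`, numeric(1), name)
    v <- v[is.finite(v)]
    if (!length(v)) return(list(z = NA_real_, p_value = NA_real_))
    sign_test_left(v, config$alpha_z)
  }
  st_acc <- st("median_p_accuracy")
  st_j <- st("median_p_youden")
  data.frame(
    n_instances = length(evaluations), n_missing = sum(missing),
    median_accuracy = med("mean_accuracy"),
    median_p_accuracy = med("median_p_accuracy"),
    sign_z_accuracy = st_acc$z, sign_p_accuracy = st_acc$p_value,
    median_youden = med("mean_youden"),
    median_p_youden = med("median_p_youden"),
    sign_z_youden = st_j$z, sign_p_youden = st_j$p_value,
    median_fraction_classified = med("mean_fraction_classified"))
}

#' Three-way ANOVA on classification performance
#'
#' Main-effects analysis of variance of a classification performance metric
#' over the factors species, growth mode and number of origins (the nine
#' realistically oriented layouts evaluated in two species), with estimated
#' marginal means for the origin levels and Bonferroni-corrected pairwise
#' post-hoc z-tests using the model residual variance.
#'
#' @param performance Data frame with columns `species`, `growth_mode`,
#'   `origins` (factors or coercible) and the metric column; the design must
#'   be balanced.
#' @param metric Name of the metric column (e.g. `"accuracy"`).
#' @param alpha_posthoc Per-comparison threshold after Bonferroni correction
#'   (default 0.05 / 3).
#' @return List of class `anova_origins` with `anova_table` (factor rows
#'   plus error: sum of squares, d.f., mean square, F, p), `marginal_means`
#'   (per origin level: estimate and standard error), `posthoc` (pairwise
#'   differences with z and p), `alpha_posthoc`.
#' @export
anova_origins <- function(performance, metric = "accuracy",
                          alpha_posthoc = 0.05 / 3) {
  for (f in c("species", "growth_mode", "origins"))
    performance[[f]] <- factor(performance[[f]])
  counts <- table(performance$species, performance$growth_mode,
                  performance$origins)
  if (length(unique(as.vector(counts))) != 1L)
    stop("design must be balanced across species x growth mode x origins")
  y <- performance[[metric]]
  fit <- stats::lm(y ~ species + growth_mode + origins, data = performance)
  at <- stats::anova(fit)
  rows <- rownames(at)
  anova_table <- data.frame(
    factor = c(rows[rows != "Residuals"], "Error"),
    sum_sq = at$`Sum Sq`[c(which(rows != "Residuals"),
                           which(rows == "Residuals"))],
    df = at$Df[c(which(rows != "Residuals"), which(rows == "Residuals"))],
    mean_sq = at$`Mean Sq`[c(which(rows != "Residuals"),
                             which(rows == "Residuals"))],
    F = c(at$`F value`[rows != "Residuals"], NA),
    p = c(at$`Pr(>F)`[rows != "Residuals"], NA))
  # estimated marginal means for origins: average model prediction over the
  # balanced grid of the remaining factors
  grid <- expand.grid(species = levels(performance$species),
                      growth_mode = levels(performance$growth_mode))
  V <- stats::vcov(fit)
  mm_rows <- lapply(levels(performance$origins), function(lev) {
    g <- data.frame(
      species = factor(grid$species, levels = levels(performance$species)),
      growth_mode = factor(grid$growth_mode,
                           levels = levels(performance$growth_mode)),
      origins = factor(lev, levels = levels(performance$origins)))
    L <- colMeans(stats::model.matrix(stats::delete.response(
      stats::terms(fit)), g))
    est <- sum(L * stats::coef(fit))
    se <- sqrt(drop(t(L) %*% V %*% L))
    list(L = L, est = est, se = se)
  })
  marginal_means <- data.frame(
    origins = levels(performance$origins),
    estimate = vapply(mm_rows, `[[`, numeric(1), "est"),
    se = vapply(mm_rows, `[[`, numeric(1), "se"))
  levs <- levels(performance$origins)
  combs <- utils::combn(seq_along(levs), 2)
  posthoc <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]
    j <- combs[2, k]
    L <- mm_rows[[i]]$L - mm_rows[[j]]$L
    diff <- mm_rows[[i]]$est - mm_rows[[j]]$est
    se <- sqrt(drop(t(L) %*% V %*% L))
    z <- diff / se
    data.frame(comparison = paste(levs[i], "vs", levs[j]),
               difference = diff, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  }))
  posthoc$significant <- posthoc$p < alpha_posthoc
  structure(list(anova_table = anova_table, marginal_means = marginal_means,
                 posthoc = posthoc, alpha_posthoc = alpha_posthoc,
                 metric = metric),
            class = "anova_origins")
}

#' @export
print.anova_origins <- function(x, ...) {
  cat(sprintf("<anova_origins> metric: %s\n", x$metric))
  print(x$anova_table)
  cat("Marginal means (origins):\n")
  print(x$marginal_means)
  cat("Post-hoc comparisons (Bonferroni alpha =",
      format(x$alpha_posthoc, digits = 3), "):\n")
  print(x$posthoc)
  invisible(x)
}
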