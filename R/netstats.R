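#' Analysis configuration
#'
#' @param alpha_spearman Significance threshold for per-instance Spearman
#'   rank correlations (default 0.05).
#' @param alpha_sign Significance threshold for cross-instance sign tests
#'   (default 0.05).
#' @param n_bins_max Maximum number of bins for relative-frequency binning
#'   (default 10).
#' @param n_instances Instances per layout used for aggregation (default
#'   100).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(alpha_spearman = 0.05, alpha_sign = 0.05,
                            n_bins_max = 10L, n_instances = 100L) {
  stopifnot(alpha_spearman > 0, alpha_spearman < 1,
            alpha_sign > 0, alpha_sign < 1, n_bins_max >= 1)
  structure(list(alpha_spearman = alpha_spearman, alpha_sign = alpha_sign,
                 n_bins_max = as.integer(n_bins_max),
                 n_instances = as.integer(n_instances)),
            class = "analysis_config")
}

#' Relative frequency of present connections per bin
#'
#' Divides the observed range of a structural measure into bins and computes
#' the fraction of present connections in each bin:
#' `relative_frequency = n_present / (n_present + n_absent)`. Measures with
#' at most `n_bins` distinct values (density-difference tiers) get one bin
#' per distinct value; continuous measures get `n_bins` equal-width bins
#' over the observed range. Empty bins carry an undefined (`NA`) frequency.
#'
#' @param values Structural measure per ordered area pair.
#' @param exists Binary existence per ordered area pair, aligned with
#'   `values`.
#' @param n_bins Maximum number of bins (<= 10).
#' @return Data frame of class `binned_frequency`: `bin_low`, `bin_high`,
#'   `bin_mid`, `n_present`, `n_absent`, `relative_frequency`; attribute
#'   `tiered` says whether distinct-value binning was used.
#' @export
bin_relative_frequency <- function(values, exists, n_bins = 10L) {
  stopifnot(length(values) == length(exists), n_bins >= 1, n_bins <= 10)
  # tier detection is robust to floating-point noise in tier differences
  vr <- signif(values, 8)
  ux <- sort(unique(vr))
  if (length(ux) <= n_bins) {
    idx <- match(vr, ux)
    lows <- highs <- mids <- ux
    k <- length(ux)
    tiered <- TRUE
  } else {
    rng <- range(values)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    idx <- findInterval(values, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    lows <- edges[-length(edges)]
    highs <- edges[-1]
    mids <- (lows + highs) / 2
    k <- n_bins
    tiered <- FALSE
  }
  pres <- tabulate(idx[exists == 1], nbins = k)
  abs_ <- tabulate(idx[exists == 0], nbins = k)
  out <- data.frame(bin_low = lows, bin_high = highs, bin_mid = mids,
                    n_present = pres, n_absent = abs_,
                    relative_frequency = ifelse(pres + abs_ > 0,
                                                pres / (pres + abs_), NA))
  attr(out, "tiered") <- tiered
  class(out) <- c("binned_frequency", "data.frame")
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation with average ranks for ties. For up to 7 paired
#' observations the two-sided p-value is computed by exhaustive enumeration
#' of all rank permutations (so that, e.g., a perfect correlation across 4
#' bins yields the minimum attainable p of 2/4! = 0.083); for larger samples
#' the t approximation is used. Pairs with non-finite entries are dropped.
#'
#' @param x,y Paired observations.
#' @return List of class `correlation_result` with `rho`, `p_value`, `n`,
#'   and `method` (`"exact"` or `"t-approximation"`); `rho` and `p_value`
#'   are `NA` for fewer than 3 points or zero variance.
#' @export
spearman_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  bad <- function() structure(list(rho = NA_real_, p_value = NA_real_,
                                   n = n, method = "undefined"),
                              class = "correlation_result")
  if (n < 3L) return(bad())
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(bad())
  rho <- stats::cor(rx, ry)
  if (n <= 7L) {
    perms <- .rank_permutations(n)
    rx_c <- rx - mean(rx)
    ry_c <- ry - mean(ry)
    denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
    permuted <- matrix(rx_c[perms], nrow(perms), n)
    rhos <- as.vector(permuted %*% ry_c) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 0))
    p <- if (is.finite(tt)) 2 * stats::pt(-abs(tt), n - 2) else 0
    method <- "t-approximation"
  }
  structure(list(rho = rho, p_value = p, n = n, method = method),
            class = "correlation_result")
}

# all permutations of centred x-ranks, cached per (n, rank multiset)
.perm_cache <- new.env(parent = emptyenv())
.rank_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  perm_idx <- .permutations(n)
  .perm_cache[[key]] <- perm_idx
  perm_idx
}

# matrix of all n! permutations of seq_len(n) (rows), recursive construction
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Left-tailed sign test against a reference level
#'
#' Tests whether the median of a group of p-values lies below a reference
#' significance threshold (H1: median < `alpha_ref`), using the normal
#' approximation with continuity correction: with `S` values above the
#' reference out of `n` non-tied values, `z = (2S - n + 1) / sqrt(n)` and
#' `p = pnorm(z)`. With 100 values all below the threshold this yields
#' z = -9.9, p = 2.08e-23.
#'
#' @param p_values Per-instance probabilities (non-finite entries dropped).
#' @param alpha_ref Reference threshold (default 0.05).
#' @return List with `z`, `p_value`, `n_above`, `n_below`, `n`.
#' @export
sign_test_left <- function(p_values, alpha_ref = 0.05) {
  p_values <- p_values[is.finite(p_values)]
  if (!length(p_values)) stop("no finite p-values supplied")
  above <- sum(p_values > alpha_ref)
  below <- sum(p_values < alpha_ref)
  n <- above + below  # ties at the threshold are discarded
  if (n == 0L)
    return(list(z = 0, p_value = 1, n_above = 0L, n_below = 0L, n = 0L))
  z <- (2 * above - n + 1) / sqrt(n)
  list(z = z, p_value = stats::pnorm(z), n_above = above, n_below = below,
       n = n)
}

#' Binary logistic regression for connection existence
#'
#' Maximum-likelihood logistic fit of connection existence on z-scored
#' structural predictors, without regularization. Predictor sets mirror the
#' four model variants: constant-only null, distance, absolute density
#' difference, or both.
#'
#' @param exists Binary outcomes over ordered area pairs.
#' @param predictors Data frame (or matrix) of predictor columns; `NULL` or
#'   zero columns fits the null model. Columns are z-scored internally.
#' @param predictor_set Label stored with the fit.
#' @return List of class `logistic_fit`: `coefficients`, `log_likelihood`,
#'   `predictor_set`, `converged`, `separation` (flag for quasi-perfect
#'   separation).
#' @export
fit_logistic <- function(exists, predictors = NULL,
                         predictor_set = "custom") {
  y <- as.integer(exists)
  if (length(unique(y)) < 2L)
    stop("outcomes must contain both classes")
  if (is.null(predictors) || NCOL(predictors) == 0L) {
    df <- data.frame(y = y)
    fml <- y ~ 1
  } else {
    X <- as.data.frame(lapply(as.data.frame(predictors), zscore))
    df <- cbind(y = y, X)
    fml <- stats::as.formula(paste("y ~", paste(names(X), collapse = " + ")))
  }
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df,
               control = list(maxit = 100)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  structure(list(coefficients = stats::coef(fit),
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 predictor_set = predictor_set,
                 converged = fit$converged, separation = warned),
            class = "logistic_fit")
}

#' McFadden's pseudo-R-squared
#'
#' Likelihood-based improvement of a logistic model over the constant-only
#' null model, `1 - LL_model / LL_null`. Interpretation bands: 0.10 and
#' above moderate, 0.15 adequate, 0.20 very high. `printed_formula = TRUE`
#' returns the bare likelihood ratio `LL_model / LL_null` instead (audit
#' mode).
#'
#' @param ll_model Log-likelihood of the fitted model (or a `logistic_fit`).
#' @param ll_null Log-likelihood of the null model (or a `logistic_fit`);
#'   must be negative.
#' @param printed_formula Return the raw ratio instead of one minus it.
#' @return Numeric scalar.
#' @export
mcfadden_r2 <- function(ll_model, ll_null, printed_formula = FALSE) {
  if (inherits(ll_model, "logistic_fit")) ll_model <- ll_model$log_likelihood
  if (inherits(ll_null, "logistic_fit")) ll_null <- ll_null$log_likelihood
  if (ll_null == 0) stop("null log-likelihood must be negative")
  ratio <- ll_model / ll_null
  if (printed_formula) ratio else 1 - ratio
}

#' Per-instance connectome analysis
#'
#' Computes, for one simulated instance, the full per-instance record:
#' relative-frequency Spearman correlations against distance (10 bins) and
#' absolute density difference (one bin per tier), the four logistic fits
#' and their three pseudo-R2 values, the degree-versus-density correlation,
#' and summary connectivity statistics.
#'
#' @param connectome An [aggregate_connectome()] result.
#' @param measures [structural_measures()] of the same sheet.
#' @param areas [sheet_areas()] of the same sheet (per-area densities).
#' @param config An [analysis_config()].
#' @return One-row data frame with columns `fraction_connected`,
#'   `n_connections`, `rho_distance`, `p_distance`, `rho_density`,
#'   `p_density`, `n_bins_density`, `r2_distance`, `r2_density`, `r2_both`,
#'   `rho_degree`, `p_degree`.
#' @export
analyze_instance <- function(connectome, measures, areas,
                             config = analysis_config()) {
  pt <- pair_table(connectome, measures)
  bf_dist <- bin_relative_frequency(pt$distance, pt$exists,
                                    n_bins = config$n_bins_max)
  bf_dens <- bin_relative_frequency(pt$abs_density_diff, pt$exists,
                                    n_bins = config$n_bins_max)
  ct_dist <- spearman_correlation(bf_dist$bin_mid,
                                  bf_dist$relative_frequency)
  ct_dens <- spearman_correlation(bf_dens$bin_mid,
                                  bf_dens$relative_frequency)
  null_fit <- fit_logistic(pt$exists, NULL, "null")
  fit_d <- fit_logistic(pt$exists, pt["distance"], "distance")
  fit_a <- fit_logistic(pt$exists, pt["abs_density_diff"],
                        "abs_density_diff")
  fit_b <- fit_logistic(pt$exists, pt[c("distance", "abs_density_diff")],
                        "both")
  deg <- area_degree(connectome)
  ct_deg <- spearman_correlation(areas$density, deg)
  data.frame(
    fraction_connected = fraction_connected(connectome),
    n_connections = sum(connectome$exists),
    rho_distance = ct_dist$rho, p_distance = ct_dist$p_value,
    rho_density = ct_dens$rho, p_density = ct_dens$p_value,
    n_bins_density = nrow(bf_dens),
    r2_distance = mcfadden_r2(fit_d, null_fit),
    r2_density = mcfadden_r2(fit_a, null_fit),
    r2_both = mcfadden_r2(fit_b, null_fit),
    rho_degree = ct_deg$rho, p_degree = ct_deg$p_value)
}

#' Aggregate per-instance analyses for one layout
#'
#' Medians of the per-instance statistics plus left-tailed sign tests on the
#' per-instance Spearman p-values (against `alpha_spearman`).
#'
#' @param reports Data frame of rows from [analyze_instance()].
#' @param config An [analysis_config()].
#' @return One-row data frame with median statistics and sign-test `z` and
#'   `p` for the distance, density and degree correlations.
#' @export
aggregate_instances <- function(reports, config = analysis_config()) {
  med <- function(v) stats::median(v, na.rm = TRUE)
  st <- function(p) {
    p <- p[is.finite(p)]
    if (!length(p)) return(list(z = NA_real_, p_value = NA_real_))
    sign_test_left(p, config$alpha_spearman)
  }
  st_dist <- st(reports$p_distance)
  st_dens <- st(reports$p_density)
  st_deg <- st(reports$p_degree)
  data.frame(
    n_instances = nrow(reports),
    median_fraction_connected = med(reports$fraction_connected),
    median_n_connections = med(reports$n_connections),
    median_rho_distance = med(reports$rho_distance),
    median_p_distance = med(reports$p_distance),
    sign_z_distance = st_dist$z, sign_p_distance = st_dist$p_value,
    median_rho_density = med(reports$rho_density),
    median_p_density = med(reports$p_density),
    sign_z_density = st_dens$z, sign_p_density = st_dens$p_value,
    median_r2_distance = med(reports$r2_distance),
    median_r2_density = med(reports$r2_density),
    median_r2_both = med(reports$r2_both),
    median_rho_degree = med(reports$rho_degree),
    median_p_degree = med(reports$p_degree),
    sign_z_degree = st_deg$z, sign_p_degree = st_deg$p_value)
}
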