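#' Specification for a synthetic tract-tracing-style dataset
#'
#' Describes a generator for connectivity tables in the empirical format
#' (directed area pairs with binary existence, an architectonic
#' differentiation measure and a distance measure). The generative model
#' plants the architectonic-type-principle signature: the log-odds of a
#' connection existing decrease with the absolute differentiation
#' difference (`atp_strength`) and with distance (`distance_decay`).
#'
#' @param n_rows Number of directed pairs, e.g. 1128 (macaque-like) or 954
#'   (cat-like).
#' @param measure_kind `"continuous"` (density-like differentiation) or
#'   `"ordinal"` (cortical-type-like, discretized into `n_levels` levels).
#' @param atp_strength Log-odds decrease of existence per standardized unit
#'   of absolute differentiation difference (>= 0).
#' @param distance_decay Log-odds decrease per standardized unit of
#'   distance (>= 0).
#' @param base_rate Target overall connectivity (default 0.6, within the
#'   empirically reported 0.50--0.77 band).
#' @param n_levels Number of ordinal differentiation levels (<= 8).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_rows = 1128L,
                         measure_kind = c("continuous", "ordinal"),
                         atp_strength = 1.5, distance_decay = 1.0,
                         base_rate = 0.6, n_levels = 8L) {
  measure_kind <- match.arg(measure_kind)
  stopifnot(n_rows >= 2, atp_strength >= 0, distance_decay >= 0,
            base_rate > 0, base_rate < 1, n_levels >= 2, n_levels <= 8)
  structure(list(n_rows = as.integer(n_rows), measure_kind = measure_kind,
                 atp_strength = atp_strength,
                 distance_decay = distance_decay, base_rate = base_rate,
                 n_levels = as.integer(n_levels)),
            class = "fixture_spec")
}

#' Generate a synthetic empirical-format connectivity dataset
#'
#' Samples synthetic cortical areas with a differentiation level and a
#' planar position, derives pairwise measures for directed area pairs, and
#' draws connection existence from a logistic model whose intercept is
#' solved so that the expected existence rate equals the spec's base rate.
#' The result emulates the column structure and the statistical signature
#' of tract-tracing connectivity tables; it is synthetic data, not a
#' representation of any real connectome.
#'
#' @param spec A [fixture_spec()].
#' @param seed Optional seed applied before generation.
#' @param species_label Label stored with the dataset.
#' @return Data frame of class `empirical_dataset` with columns `source`,
#'   `target`, `exists`, `differentiation`, `distance` and attribute
#'   `species_label`.
#' @export
generate_fixture <- function(spec, seed = NULL,
                             species_label = "synthetic") {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(seed)) set.seed(seed)
  n_areas <- ceiling((1 + sqrt(1 + 4 * spec$n_rows)) / 2)
  diff_level <- stats::runif(n_areas)
  if (spec$measure_kind == "ordinal")
    diff_level <- ceiling(diff_level * spec$n_levels)
  pos <- cbind(stats::runif(n_areas), stats::runif(n_areas))
  pairs <- expand.grid(target = seq_len(n_areas), source = seq_len(n_areas))
  pairs <- pairs[pairs$source != pairs$target, c("source", "target")]
  pairs <- pairs[sample.int(nrow(pairs), spec$n_rows), ]
  dd <- abs(diff_level[pairs$source] - diff_level[pairs$target])
  dist <- sqrt(rowSums((pos[pairs$source, ] - pos[pairs$target, ])^2))
  eta <- -spec$atp_strength * zscore(dd) - spec$distance_decay * zscore(dist)
  b0 <- stats::uniroot(
    function(b) mean(stats::plogis(b + eta)) - spec$base_rate,
    interval = c(-20, 20))$root
  exists <- as.integer(stats::runif(spec$n_rows) < stats::plogis(b0 + eta))
  out <- data.frame(source = pairs$source, target = pairs$target,
                    exists = exists, differentiation = dd,
                    distance = dist, row.names = NULL)
  attr(out, "species_label") <- species_label
  attr(out, "spec") <- spec
  class(out) <- c("empirical_dataset", "data.frame")
  out
}

#' Read an empirical-format connectivity table from CSV
#'
#' Expects a header with at least the columns `source`, `target`, `exists`,
#' `differentiation`, `distance`. A sidecar JSON (`<file>.json`) with a
#' `species_label` entry is honoured when present.
#'
#' @param path CSV path.
#' @return An `empirical_dataset` data frame.
#' @export
read_empirical_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("source", "target", "exists", "differentiation", "distance")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("empirical CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$exists %in% c(0L, 1L)))
    stop("'exists' column must be binary (0/1)")
  label <- "unknown"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$species_label)) label <- meta$species_label
  }
  attr(df, "species_label") <- label
  class(df) <- c("empirical_dataset", "data.frame")
  df
}

#' Write an empirical-format connectivity table to CSV
#'
#' @param dataset An `empirical_dataset`.
#' @param path CSV path; the species label is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_empirical_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset)[, c("source", "target", "exists",
                                              "differentiation", "distance")],
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(species_label = attr(dataset, "species_label") %||% "unknown"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
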