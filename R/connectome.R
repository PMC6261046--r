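#' Collapse neuron-level synapses into a directed area-level connectome
#'
#' Counts, for every ordered pair of distinct areas, the number of axons
#' (synapses) projecting from neurons of the source area onto neurons of the
#' target area, and binarizes existence at a minimum axon count.
#' Within-area synapses are ignored; the diagonal is excluded from all
#' derived statistics.
#'
#' @param synapses Data frame with `source_neuron_id`, `target_neuron_id`
#'   (and optionally `time_step`).
#' @param neuron_area Integer vector mapping neuron id to area id.
#' @param n_areas Number of areas; defaults to `max(neuron_area)`.
#' @param min_axons Minimum number of constituent axons for a connection to
#'   count as present (default 1; 10 is the robustness variant used to
#'   discard very weak connections).
#' @return An object of class `area_connectome` with components
#'   `axon_counts` (integer matrix), `exists` (binary matrix), `n_areas`,
#'   `min_axons`.
#' @export
aggregate_connectome <- function(synapses, neuron_area, n_areas = NULL,
                                 min_axons = 1L) {
  if (is.null(n_areas)) n_areas <- max(neuron_area)
  src <- neuron_area[synapses$source_neuron_id]
  tgt <- neuron_area[synapses$target_neuron_id]
  if (anyNA(src) || anyNA(tgt)) stop("synapse references an unmapped neuron")
  counts <- matrix(0L, n_areas, n_areas)
  keep <- src != tgt
  if (any(keep)) {
    tab <- table(factor(src[keep], levels = seq_len(n_areas)),
                 factor(tgt[keep], levels = seq_len(n_areas)))
    counts <- matrix(as.integer(tab), n_areas, n_areas)
  }
  diag(counts) <- 0L
  exists <- (counts >= min_axons) * 1L
  diag(exists) <- 0L
  structure(list(n_areas = n_areas, axon_counts = counts, exists = exists,
                 min_axons = as.integer(min_axons)),
            class = "area_connectome")
}

#' @export
print.area_connectome <- function(x, ...) {
  cat(sprintf(
    "<area_connectome> %d areas, %d connections (min_axons=%d), density %.3f\n",
    x$n_areas, sum(x$exists), x$min_axons, fraction_connected(x)))
  invisible(x)
}

#' Pairwise structural measures of a cortical sheet
#'
#' For every ordered pair of distinct areas: the signed neuron-density
#' difference (source minus target), its absolute value, and the Euclidean
#' distance between area centres of mass, all computed from the final
#' coordinates and densities.
#'
#' @param sheet A `cortical_sheet` (finalized).
#' @return Data frame with columns `source`, `target`, `density_diff`,
#'   `abs_density_diff`, `distance`.
#' @export
structural_measures <- function(sheet) {
  a <- sheet_areas(sheet)
  n <- nrow(a)
  pairs <- expand.grid(target = seq_len(n), source = seq_len(n))
  pairs <- pairs[pairs$source != pairs$target, c("source", "target")]
  dd <- a$density[pairs$source] - a$density[pairs$target]
  dist <- sqrt((a$centroid_x[pairs$source] - a$centroid_x[pairs$target])^2 +
               (a$centroid_y[pairs$source] - a$centroid_y[pairs$target])^2)
  data.frame(source = a$area_id[pairs$source],
             target = a$area_id[pairs$target],
             density_diff = dd, abs_density_diff = abs(dd),
             distance = dist, row.names = NULL)
}

#' Fraction of possible interareal connections present
#'
#' @param connectome An `area_connectome`.
#' @return Number of present ordered off-diagonal connections divided by
#'   `n_areas * (n_areas - 1)`.
#' @export
fraction_connected <- function(connectome) {
  n <- connectome$n_areas
  stopifnot(n >= 2)
  sum(connectome$exists) / (n * (n - 1))
}

#' Area degree (afferent plus efferent connections)
#'
#' @param connectome An `area_connectome`.
#' @return Integer vector: for each area, the sum of its efferent and
#'   afferent binary connections.
#' @export
area_degree <- function(connectome) {
  as.integer(rowSums(connectome$exists) + colSums(connectome$exists))
}

#' Align measures with connection existence over ordered pairs
#'
#' Utility joining [structural_measures()] with the existence entries of an
#' [aggregate_connectome()] for the same sheet.
#'
#' @param connectome An `area_connectome`.
#' @param measures Output of [structural_measures()].
#' @return `measures` with an added binary `exists` column.
#' @export
pair_table <- function(connectome, measures) {
  measures$exists <- connectome$exists[cbind(measures$source,
                                             measures$target)]
  measures
}
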