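#' Export the layout registry as JSON
#'
#' @param registry Output of [make_layout_registry()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_registry_json <- function(registry, path) {
  jsonlite::write_json(lapply(registry, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write sheet snapshots to CSV
#'
#' One row per area (`area_id`, `origin_id`, `creation_event`, `density`,
#' `centroid_x`, `centroid_y`, `n_somata`) and, optionally, one row per
#' soma (`neuron_id`, `area_id`, `x`, `y`).
#'
#' @param sheet A `cortical_sheet`.
#' @param areas_path CSV path for the area table.
#' @param somata_path Optional CSV path for the soma table.
#' @return `areas_path`, invisibly.
#' @export
write_sheet_csv <- function(sheet, areas_path, somata_path = NULL) {
  a <- sheet_areas(sheet)
  utils::write.csv(a[, c("area_id", "origin_id", "creation_event",
                         "density", "centroid_x", "centroid_y",
                         "n_somata")], areas_path, row.names = FALSE)
  if (!is.null(somata_path))
    utils::write.csv(soma_positions(sheet), somata_path, row.names = FALSE)
  invisible(areas_path)
}

#' Write and read a synapse table
#'
#' @param synapses Data frame with `source_neuron_id`, `target_neuron_id`,
#'   `time_step`.
#' @param path CSV path.
#' @return `path` (write) / the synapse data frame (read).
#' @export
write_synapses_csv <- function(synapses, path) {
  utils::write.csv(synapses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_synapses_csv
#' @export
read_synapses_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("source_neuron_id", "target_neuron_id", "time_step")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("synapse CSV is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write and read an area connectome
#'
#' The connectome is written both as a dense axon-count matrix CSV and as an
#' edge list CSV (`source_area`, `target_area`, `axon_count`, `exists`).
#' Reading reconstructs the `area_connectome` from the edge list.
#'
#' @param connectome An `area_connectome`.
#' @param matrix_path CSV path for the dense axon-count matrix.
#' @param edges_path CSV path for the edge list.
#' @param min_axons Binarization threshold used when reading back.
#' @return Paths invisibly (write); an `area_connectome` (read).
#' @export
write_connectome_csv <- function(connectome, matrix_path, edges_path) {
  utils::write.csv(connectome$axon_counts, matrix_path, row.names = FALSE)
  n <- connectome$n_areas
  idx <- which(row(connectome$axon_counts) != col(connectome$axon_counts))
  edges <- data.frame(source_area = row(connectome$axon_counts)[idx],
                      target_area = col(connectome$axon_counts)[idx],
                      axon_count = connectome$axon_counts[idx],
                      exists = connectome$exists[idx])
  utils::write.csv(edges[order(edges$source_area, edges$target_area), ],
                   edges_path, row.names = FALSE)
  invisible(c(matrix_path, edges_path))
}

#' @rdname write_connectome_csv
#' @export
read_connectome_csv <- function(edges_path, min_axons = 1L) {
  edges <- utils::read.csv(edges_path)
  need <- c("source_area", "target_area", "axon_count")
  miss <- setdiff(need, names(edges))
  if (length(miss))
    stop("edge CSV is missing column(s): ", paste(miss, collapse = ", "))
  n <- max(edges$source_area, edges$target_area)
  counts <- matrix(0L, n, n)
  counts[cbind(edges$source_area, edges$target_area)] <-
    as.integer(edges$axon_count)
  diag(counts) <- 0L
  structure(list(n_areas = n, axon_counts = counts,
                 exists = (counts >= min_axons) * 1L,
                 min_axons = as.integer(min_axons)),
            class = "area_connectome")
}

#' Write pairwise structural measures to CSV
#'
#' @param measures Output of [structural_measures()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_measures_csv <- function(measures, path) {
  utils::write.csv(measures, path, row.names = FALSE)
  invisible(path)
}

#' Run a simulation campaign over growth layouts
#'
#' Simulates `n_instances` seeded instances per layout (instance `i`
#' receives seed `base_seed + i - 1`), analyses each instance, and
#' aggregates per layout. Optionally writes per-layout CSV tables and a
#' JSON run manifest with file checksums.
#'
#' @param layouts List of [growth_layout()] objects (or a single one).
#' @param n_instances Instances per layout.
#' @param base_seed First instance seed.
#' @param out_dir Optional output directory (created if needed; one
#'   subdirectory per layout).
#' @param params Optional [sim_params()] override applied to every layout
#'   (defaults to the per-mode calibrated parameters).
#' @param config An [analysis_config()].
#' @return List of class `campaign_result`: `per_instance` (data frame with
#'   layout and instance columns), `aggregate` (one row per layout),
#'   `manifest` (when `out_dir` given).
#' @export
run_campaign <- function(layouts, n_instances = 100L, base_seed = 1L,
                         out_dir = NULL, params = NULL,
                         config = analysis_config()) {
  if (inherits(layouts, "growth_layout")) layouts <- list(layouts)
  per_instance <- list()
  aggregate <- list()
  files <- character(0)
  for (layout in layouts) {
    p <- if (is.null(params)) default_sim_params(layout$growth_mode)
         else params
    reports <- vector("list", n_instances)
    for (i in seq_len(n_instances)) {
      r <- run_instance(layout, p, seed = base_seed + i - 1L)
      conn <- aggregate_connectome(r$synapses, r$neuron_area,
                                   n_areas = nrow(r$sheet$areas))
      rep_i <- analyze_instance(conn, structural_measures(r$sheet),
                                sheet_areas(r$sheet), config)
      rep_i <- cbind(data.frame(layout = layout$abbreviation, instance = i,
                                seed = r$seed, occupancy = r$occupancy),
                     rep_i)
      reports[[i]] <- rep_i
    }
    inst <- do.call(rbind, reports)
    agg <- cbind(data.frame(layout = layout$abbreviation),
                 aggregate_instances(inst, config))
    per_instance[[layout$abbreviation]] <- inst
    aggregate[[layout$abbreviation]] <- agg
    if (!is.null(out_dir)) {
      dir <- file.path(out_dir, layout$abbreviation)
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      f1 <- file.path(dir, "instances.csv")
      f2 <- file.path(dir, "aggregate.csv")
      utils::write.csv(inst, f1, row.names = FALSE)
      utils::write.csv(agg, f2, row.names = FALSE)
      files <- c(files, f1, f2)
    }
  }
  out <- list(per_instance = do.call(rbind, per_instance),
              aggregate = do.call(rbind, aggregate), manifest = NULL)
  rownames(out$per_instance) <- rownames(out$aggregate) <- NULL
  if (!is.null(out_dir)) {
    manifest <- list(
      layouts = vapply(layouts, `[[`, character(1), "abbreviation"),
      n_instances = n_instances, base_seed = base_seed,
      version = as.character(utils::packageVersion("cortisim")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      files = lapply(files, function(f)
        list(path = f, md5 = unname(tools::md5sum(f)))))
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE)
    out$manifest <- manifest
  }
  class(out) <- "campaign_result"
  out
}

#' Verify a campaign manifest against the files on disk
#'
#' @param out_dir Campaign output directory containing `manifest.json`.
#' @return `TRUE` invisibly; stops with an integrity error on checksum
#'   mismatch or missing files.
#' @export
verify_manifest <- function(out_dir) {
  mpath <- file.path(out_dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", out_dir)
  manifest <- jsonlite::read_json(mpath)
  for (f in manifest$files) {
    if (!file.exists(f$path)) stop("manifest integrity error: missing ",
                                   f$path)
    if (!identical(unname(tools::md5sum(f$path)), f$md5))
      stop("manifest integrity error: checksum mismatch for ", f$path)
  }
  invisible(TRUE)
}
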