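# shared simulation cache: several test files analyse the same seeded
# instances; run each (layout, seed) once per session
.sim_cache <- new.env(parent = emptyenv())

cached_instance <- function(abbr, seed) {
  key <- paste(abbr, seed, sep = "#")
  if (is.null(.sim_cache[[key]])) {
    r <- run_instance(get_layout(abbr), seed = seed)
    conn <- aggregate_connectome(r$synapses, r$neuron_area,
                                 n_areas = nrow(r$sheet$areas))
    meas <- structural_measures(r$sheet)
    .sim_cache[[key]] <- list(
      result = r, conn = conn, measures = meas,
      areas = sheet_areas(r$sheet),
      pairs = pair_table(conn, meas))
  }
  .sim_cache[[key]]
}

cached_reports <- function(abbr, seeds) {
  do.call(rbind, lapply(seeds, function(s) {
    ci <- cached_instance(abbr, s)
    analyze_instance(ci$conn, ci$measures, ci$areas)
  }))
}

# tiny layouts for fast unit runs
toy_static_layout <- function(density_min = 6, total_steps = 30,
                              density_fold = 5) {
  growth_layout("static", "1D_1row", 2, 1, total_steps = total_steps,
                density_min = density_min, density_fold = density_fold,
                n_ref_events = 2)
}

# hand-assembled terminal state on a sheet: positions/eligibility set
# directly so single update rules can be exercised in isolation
make_toy_state <- function(sheet, px, py, eligible = NULL, occupied = NULL) {
  st <- new_sim_state(sheet)
  st$px <- px
  st$py <- py
  if (!is.null(eligible)) st$eligible <- eligible
  if (!is.null(occupied)) st$occupied <- occupied
  st
}
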