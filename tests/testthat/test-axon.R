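test_that("terminal extension follows the step geometry", {
  sheet <- grow_sheet(toy_static_layout(density_min = 4), seed = 1)
  st <- new_sim_state(sheet)
  p <- sim_params(0.1, 0.001)
  n <- length(st$px)
  x0 <- st$px
  y0 <- st$py
  st2 <- extend_unoccupied_terminals(st, p, angles = rep(0, n))
  expect_equal(st2$px, x0 + 0.1)
  expect_equal(st2$py, y0)
  # mirror reflection at the sheet boundary
  st$px[1] <- 0.01
  st$py[1] <- 0.5
  st3 <- extend_unoccupied_terminals(st, p, angles = rep(pi, n))
  expect_equal(st3$px[1], 0.09)
  expect_equal(st3$py[1], 0.5)
  # occupied terminals do not move
  st$occupied[2] <- TRUE
  pos2 <- c(st$px[2], st$py[2])
  st4 <- extend_unoccupied_terminals(st, p, angles = rep(0, n))
  expect_equal(c(st4$px[2], st4$py[2]), pos2)
})

test_that("eligibility requires leaving the parent area and is permanent", {
  sheet <- grow_sheet(toy_static_layout(density_min = 4), seed = 1)
  st <- new_sim_state(sheet)
  p <- sim_params(0.05, 0.3, accept_prob = 1)
  # somata of area 2 are within reach, but the terminal never left area 1
  st$px[1] <- 0.95
  st$py[1] <- 0.5
  expect_false(st$eligible[1])
  st2 <- attempt_synapses(st, p)
  expect_equal(nrow(st2$synapses), 0)
  # one step to the right crosses the area border: eligible, then synapse
  n <- length(st$px)
  st3 <- extend_unoccupied_terminals(st, p, angles = rep(0, n))
  expect_true(st3$eligible[1])
  st3$time <- 1L
  st4 <- attempt_synapses(st3, p)
  expect_true(st4$occupied[1])
  expect_true(1 %in% st4$synapses$source_neuron_id)
})

test_that("the nearest in-range soma is contacted, ties split at random", {
  # origin area holds a 2x2 soma grid at 0.25 / 0.75
  sheet <- grow_sheet(toy_static_layout(density_min = 4), seed = 1)
  pos <- soma_positions(sheet)
  p <- sim_params(0.05, 0.4, accept_prob = 1)
  st <- new_sim_state(sheet)
  st$eligible[] <- TRUE
  st$occupied[] <- TRUE
  # terminal 1 placed just off soma 3: soma 3 is the unique nearest
  st$occupied[1] <- FALSE
  st$px[1] <- pos$x[3] + 0.01
  st$py[1] <- pos$y[3]
  set.seed(1)
  st1 <- attempt_synapses(st, p)
  expect_equal(st1$target[1], 3)
  expect_equal(c(st1$px[1], st1$py[1]), c(pos$x[3], pos$y[3]))
  # terminal 3 equidistant between somata 1 and 2 (exact midpoint of the
  # bottom grid row): the tie is split at random
  st$occupied[1] <- TRUE
  st$occupied[3] <- FALSE
  st$px[3] <- (pos$x[1] + pos$x[2]) / 2
  st$py[3] <- pos$y[1]
  picks <- vapply(1:40, function(s) {
    set.seed(s)
    attempt_synapses(st, p)$target[3]
  }, integer(1))
  expect_setequal(unique(picks), c(1L, 2L))
})

test_that("potential contacts are realised at the configured probability", {
  # large sheet of eligible terminals, each with its nearest soma in range
  sheet <- grow_sheet(growth_layout("static", "1D_1row", 2, 1,
                                    total_steps = 30, density_min = 300,
                                    n_ref_events = 1), seed = 1)
  st <- new_sim_state(sheet)
  st$eligible[] <- TRUE
  st$time <- 1L
  p <- sim_params(0.01, 0.1, accept_prob = 0.9)
  set.seed(42)
  st2 <- attempt_synapses(st, p)
  n <- length(st$px)
  frac <- nrow(st2$synapses) / n
  expect_gt(n, 5000)
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / n))
})

test_that("growth events carry terminals and preserve contacts", {
  l <- growth_layout("realistic", "1D_1row", 2, 2, total_steps = 30,
                     density_min = 5)
  set.seed(1)
  sheet <- init_sheet(l)
  st <- new_sim_state(sheet)
  st$px[1] <- 0.2  # inside area 1
  new_sheet <- apply_growth_event(sheet, 1)
  shift <- new_sheet$displacement_log[[1]]
  st2 <- shift_terminals_on_growth(st, new_sheet, shift)
  d1 <- shift[shift$area_id == 1, ]
  expect_equal(st2$px[1], 0.2 + d1$dx)
  # occupied terminal remains coincident with its target soma
  set.seed(1)
  sheet <- init_sheet(l)
  st <- new_sim_state(sheet)
  st$occupied[1] <- TRUE
  st$target[1] <- 5L
  st3 <- shift_terminals_on_growth(st, new_sheet, shift)
  pos <- soma_positions(new_sheet)
  expect_equal(c(st3$px[1], st3$py[1]), c(pos$x[5], pos$y[5]))
  # synapse table untouched, new terminals appended at their somata
  expect_equal(st3$synapses, st$synapses)
  expect_equal(length(st3$px), nrow(pos))
  # static layouts record zero displacement
  sst <- grow_sheet(toy_static_layout(), seed = 2)
  expect_true(all(sst$displacement_log[[1]]$dx == 0))
  expect_true(all(sst$displacement_log[[1]]$dy == 0))
})

test_that("instances are reproducible and axons are one-shot", {
  l <- toy_static_layout(density_min = 8)
  p <- sim_params(0.3, 0.08, total_steps = 30)
  a <- run_instance(l, p, seed = 5)
  b <- run_instance(l, p, seed = 5)
  expect_identical(a$synapses, b$synapses)
  n <- length(a$neuron_area)
  expect_lte(nrow(a$synapses), n)
  expect_false(anyDuplicated(a$synapses$source_neuron_id) > 0)
  expect_true(all(a$synapses$source_neuron_id !=
                  a$synapses$target_neuron_id))
  expect_true(all(diff(sort(a$synapses$time_step)) >= 0))
})

test_that("compiled kernel and reference implementation agree bitwise", {
  cases <- list(
    list(l = toy_static_layout(density_min = 6),
         p = sim_params(0.3, 0.08, total_steps = 30)),
    list(l = growth_layout("realistic", "1D_1row", 2, 3, total_steps = 60,
                           density_min = 5),
         p = sim_params(0.3, 0.08, total_steps = 60)),
    list(l = growth_layout("radial", "1D_1row", 2, 3, total_steps = 60,
                           density_min = 5, n_ref_events = 3),
         p = sim_params(0.3, 0.08, total_steps = 60)))
  for (cs in cases) {
    a <- run_instance(cs$l, cs$p, seed = 7, use_compiled = TRUE)
    b <- run_instance(cs$l, cs$p, seed = 7, use_compiled = FALSE)
    expect_identical(a$synapses, b$synapses,
                     label = cs$l$abbreviation)
    expect_equal(a$occupancy, b$occupancy)
  }
})

test_that("with certain acceptance and global reach every axon connects", {
  l <- growth_layout("static", "1D_1row", 2, 1, total_steps = 30,
                     density_min = 4, n_ref_events = 1)
  p <- sim_params(0.8, 10, accept_prob = 1, total_steps = 30)
  r <- run_instance(l, p, seed = 3)
  expect_equal(r$occupancy, 1)
  expect_equal(nrow(r$synapses), length(r$neuron_area))
  # occupancy monotone: synapse times only accumulate
  expect_true(all(table(r$synapses$time_step) >= 0))
  expect_lte(max(r$synapses$time_step), 30)
})

test_that("neuron-level connection probability declines with distance", {
  # near-uniform density static strip
  l <- growth_layout("static", "1D_1row", 2, 1, total_steps = 300,
                     density_min = 100, density_fold = 1.0001,
                     n_ref_events = 6)
  r <- run_instance(l, default_sim_params("1D_1row"), seed = 9)
  pos <- soma_positions(r$sheet)
  d <- sqrt((pos$x[r$synapses$source_neuron_id] -
             pos$x[r$synapses$target_neuron_id])^2 +
            (pos$y[r$synapses$source_neuron_id] -
             pos$y[r$synapses$target_neuron_id])^2)
  # per-source connection distances, binned against availability
  set.seed(9)
  src <- sample(nrow(pos), 4000, replace = TRUE)
  tgt <- sample(nrow(pos), 4000, replace = TRUE)
  avail <- sqrt((pos$x[src] - pos$x[tgt])^2 + (pos$y[src] - pos$y[tgt])^2)
  edges <- seq(0, max(avail) + 1e-9, length.out = 11)
  hits <- tabulate(findInterval(d, edges, all.inside = TRUE), 10)
  base <- tabulate(findInterval(avail, edges, all.inside = TRUE), 10)
  ratio <- ifelse(base > 0, hits / base, NA)
  ct <- spearman_correlation(seq_len(10), ratio)
  expect_lt(ct$rho, -0.8)
})

test_that("the calibration search respects its targets and reports back", {
  l <- toy_static_layout(density_min = 30, total_steps = 60)
  cal <- calibrate("1D_1row", target_occupancy = 0,
                   target_range = c(0, 1), step_grid = 0.3,
                   radius_grid = 0.05, steps_grid = 60L, n_pilot = 2,
                   layout = l)
  expect_true(cal$satisfied)  # vacuous targets are always met
  expect_s3_class(cal$params, "sim_params")
  expect_equal(nrow(cal$trace), 1)
  # unattainable occupancy: best candidate returned, flagged unsatisfied
  cal2 <- calibrate("1D_1row", target_occupancy = 1.0,
                    target_range = c(0.999, 1), step_grid = 0.05,
                    radius_grid = 1e-5, steps_grid = 60L, n_pilot = 1,
                    layout = l)
  expect_false(cal2$satisfied)
  # vanishing contact radius yields vanishing occupancy
  expect_lt(cal2$trace$occupancy[1], 0.1)
})
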