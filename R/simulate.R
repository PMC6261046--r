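#' Simulation parameters for axon outgrowth
#'
#' @param step_length Fixed axon extension per time step (length units).
#' @param contact_radius Maximal terminal-to-soma distance for synapse
#'   formation (length units).
#' @param accept_prob Probability that a potential synaptic contact is
#'   realised at a given time step (default 0.9; in the remaining cases the
#'   axon keeps growing).
#' @param total_steps Simulated duration; defaults to the layout's
#'   `total_steps` when `NULL`.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(step_length, contact_radius, accept_prob = 0.9,
                       total_steps = NULL) {
  stopifnot(step_length > 0, contact_radius > 0,
            accept_prob >= 0, accept_prob <= 1)
  structure(list(step_length = step_length, contact_radius = contact_radius,
                 accept_prob = accept_prob,
                 total_steps = if (is.null(total_steps)) NULL
                               else as.integer(total_steps)),
            class = "sim_params")
}

#' Calibrated default simulation parameters
#'
#' Parameter sets per growth mode, products of the shipped calibration
#' procedure (see [calibrate()]): at the default densities they leave more
#' than 99.9\% of axon terminals occupied at simulation end and interareal
#' connectivity of 1D layouts within the empirically reported 39--66\% range.
#' 1D and 2D growth modes use slightly different values.
#'
#' @param growth_mode `"1D_1row"`, `"1D_2rows"` or `"2D"`.
#' @return A [sim_params()] object.
#' @export
default_sim_params <- function(growth_mode = c("1D_1row", "1D_2rows", "2D")) {
  growth_mode <- match.arg(growth_mode)
  if (growth_mode == "2D") {
    sim_params(step_length = 1.0, contact_radius = 0.006, total_steps = 450L)
  } else {
    sim_params(step_length = 1.0, contact_radius = 0.013)
  }
}

#' Create the axon-terminal state for a sheet
#'
#' Each neuron carries exactly one axon terminal, initially located at its
#' soma. Terminals become eligible to form synapses only after first leaving
#' their parent area.
#'
#' @param sheet A `cortical_sheet`.
#' @return An object of class `sim_state`.
#' @export
new_sim_state <- function(sheet) {
  pos <- soma_positions(sheet)
  n <- nrow(pos)
  structure(
    list(sheet = sheet,
         px = pos$x, py = pos$y,
         occupied = logical(n), eligible = logical(n),
         parent_area = pos$area_id, target = rep(NA_integer_, n),
         soma_x = pos$x, soma_y = pos$y, soma_area = pos$area_id,
         time = 0L,
         synapses = data.frame(source_neuron_id = integer(0),
                               target_neuron_id = integer(0),
                               time_step = integer(0))),
    class = "sim_state")
}

#' Extend all unoccupied axon terminals by one step
#'
#' Reference (pure R) implementation of the first pass of a time step: every
#' unoccupied terminal, in neuron-id order, moves by `step_length` at an
#' angle drawn uniformly on `[0, 2*pi)`; moves beyond the sheet rectangle
#' are mirror-reflected at the boundary; a terminal becomes (permanently)
#' eligible the first time its position lies outside its parent area.
#' Occupied terminals do not move. The compiled kernel used by
#' [run_instance()] performs the identical update with the identical RNG
#' draw order.
#'
#' @param state A `sim_state`.
#' @param params A [sim_params()].
#' @param angles Optional vector of fixed angles (radians) per terminal,
#'   bypassing the RNG; used for controlled geometry checks.
#' @return The updated state.
#' @export
extend_unoccupied_terminals <- function(state, params, angles = NULL) {
  b <- state$sheet$bounds
  ab <- .area_bounds(state$sheet)
  aid <- state$sheet$areas$area_id
  for (i in seq_along(state$px)) {
    if (state$occupied[i]) next
    ang <- if (is.null(angles)) 2 * pi * stats::runif(1) else angles[i]
    x <- .reflect(state$px[i] + params$step_length * cos(ang), b[1], b[2])
    y <- .reflect(state$py[i] + params$step_length * sin(ang), b[3], b[4])
    state$px[i] <- x
    state$py[i] <- y
    if (!state$eligible[i]) {
      a <- match(state$parent_area[i], aid)
      if (x < ab[a, "x0"] || x > ab[a, "x1"] ||
          y < ab[a, "y0"] || y > ab[a, "y1"])
        state$eligible[i] <- TRUE
    }
  }
  state
}

#' Attempt synapse formation for eligible terminals
#'
#' Reference (pure R) implementation of the second pass of a time step: for
#' every unoccupied, eligible terminal (in neuron-id order) with at least one
#' soma other than its own closer than `contact_radius`, the nearest
#' candidate soma is selected (exact distance ties broken uniformly at
#' random) and, with probability `accept_prob`, a synapse forms: the terminal
#' occupies the soma position and the contact is recorded. Otherwise the
#' axon continues to grow in later steps.
#'
#' @inheritParams extend_unoccupied_terminals
#' @return The updated state with any new rows appended to `state$synapses`.
#' @export
attempt_synapses <- function(state, params) {
  r2 <- params$contact_radius^2
  new_syn <- list()
  for (i in seq_along(state$px)) {
    if (state$occupied[i] || !state$eligible[i]) next
    d2 <- (state$soma_x - state$px[i])^2 + (state$soma_y - state$py[i])^2
    d2[i] <- Inf
    hit <- which(d2 < r2)
    if (!length(hit)) next
    best <- min(d2[hit])
    tied <- hit[d2[hit] == best]          # ascending soma id
    j <- if (length(tied) == 1L) tied else
      tied[floor(stats::runif(1) * length(tied)) + 1L]
    if (stats::runif(1) < params$accept_prob) {
      state$occupied[i] <- TRUE
      state$target[i] <- j
      state$px[i] <- state$soma_x[j]
      state$py[i] <- state$soma_y[j]
      new_syn[[length(new_syn) + 1L]] <- data.frame(
        source_neuron_id = i, target_neuron_id = j,
        time_step = state$time)
    }
  }
  if (length(new_syn))
    state$synapses <- rbind(state$synapses, do.call(rbind, new_syn))
  state
}

#' Advance the reference simulation by one time step
#'
#' @inheritParams extend_unoccupied_terminals
#' @return The updated state (time incremented, terminals extended, synapse
#'   attempts made).
#' @export
sim_step <- function(state, params) {
  state$time <- state$time + 1L
  state <- extend_unoccupied_terminals(state, params)
  attempt_synapses(state, params)
}

#' Shift axon terminals with a growth event
#'
#' When a growth event re-lays-out the sheet, every terminal is translated by
#' the displacement vector of the area containing its current position
#' (looked up on the pre-event layout); terminals outside all areas are
#' assigned the nearest area. Occupied terminals end up coincident with their
#' (shifted) target soma; the synapse table is unchanged.
#'
#' @param state A `sim_state` whose `state$sheet` is still the pre-event
#'   sheet.
#' @param new_sheet The sheet after the growth event.
#' @param displacement The displacement entry recorded for the event
#'   (`data.frame` with `area_id`, `dx`, `dy`).
#' @return The updated state, with `state$sheet` replaced by `new_sheet` and
#'   cached soma positions refreshed (terminals for newly grown somata are
#'   appended at their soma positions).
#' @export
shift_terminals_on_growth <- function(state, new_sheet, displacement) {
  old_sheet <- state$sheet
  if (nrow(displacement) && nrow(old_sheet$areas)) {
    idx <- .containing_area(old_sheet, state$px, state$py)
    d <- displacement[match(old_sheet$areas$area_id[idx],
                            displacement$area_id), ]
    state$px <- state$px + ifelse(is.na(d$dx), 0, d$dx)
    state$py <- state$py + ifelse(is.na(d$dy), 0, d$dy)
  }
  state$sheet <- new_sheet
  pos <- soma_positions(new_sheet)
  state$soma_x <- pos$x
  state$soma_y <- pos$y
  state$soma_area <- pos$area_id
  # occupied terminals remain coincident with their target soma
  occ <- which(state$occupied)
  state$px[occ] <- state$soma_x[state$target[occ]]
  state$py[occ] <- state$soma_y[state$target[occ]]
  # new somata receive terminals at their soma position
  n_old <- length(state$px)
  n_new <- nrow(pos) - n_old
  if (n_new > 0L) {
    new_idx <- n_old + seq_len(n_new)
    state$px <- c(state$px, pos$x[new_idx])
    state$py <- c(state$py, pos$y[new_idx])
    state$occupied <- c(state$occupied, logical(n_new))
    state$eligible <- c(state$eligible, logical(n_new))
    state$parent_area <- c(state$parent_area, pos$area_id[new_idx])
    state$target <- c(state$target, rep(NA_integer_, n_new))
  }
  state
}

#' Run one simulation instance
#'
#' Executes the full spatiotemporal schedule for a growth layout: at each
#' scheduled growth event the sheet grows, terminals are shifted with their
#' areas and new somata receive terminals; at every time step all unoccupied
#' terminals extend and eligible ones attempt synapse formation. The rules of
#' axon growth and synapse formation are identical across all layouts.
#'
#' @param layout A [growth_layout()].
#' @param params A [sim_params()]; defaults to the calibrated parameters for
#'   the layout's growth mode.
#' @param seed Integer seed; all stochastic draws of the instance derive
#'   from it.
#' @param use_compiled Use the compiled step kernel (default). The pure R
#'   path ([sim_step()]) produces bit-identical results and is intended for
#'   small verification runs.
#' @return An object of class `sim_result`: final `sheet`, `synapses` table
#'   (`source_neuron_id`, `target_neuron_id`, `time_step`), `neuron_area`
#'   map, `occupancy` (fraction of terminals occupied at the final step),
#'   `params`, `seed`.
#' @export
run_instance <- function(layout, params = default_sim_params(layout$growth_mode),
                         seed = 1L, use_compiled = TRUE) {
  stopifnot(inherits(layout, "growth_layout"))
  total_steps <- if (is.null(params$total_steps)) layout$total_steps
                 else params$total_steps
  set.seed(seed)
  sheet <- init_sheet(layout)
  state <- new_sim_state(sheet)
  events <- schedule_growth_events(layout)
  t_cur <- 1L
  for (e in seq_along(events)) {
    state <- .advance(state, params, t_cur, events[e] - 1L, use_compiled)
    new_sheet <- apply_growth_event(state$sheet, e)
    state <- shift_terminals_on_growth(
      state, new_sheet, new_sheet$displacement_log[[e]])
    t_cur <- events[e]
  }
  state <- .advance(state, params, t_cur, total_steps, use_compiled)
  structure(
    list(sheet = state$sheet, synapses = state$synapses,
         neuron_area = state$soma_area,
         occupancy = if (length(state$occupied)) mean(state$occupied) else NA,
         params = params, layout = layout, seed = seed),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %s seed=%d: %d neurons, %d synapses, occupancy %.4f\n",
    x$layout$abbreviation, x$seed, length(x$neuron_area),
    nrow(x$synapses), x$occupancy))
  invisible(x)
}

#' Calibrate simulation parameters for a growth mode
#'
#' Grid search over step length, contact radius and simulated duration on
#' pilot instances of a representative layout, until the median terminal
#' occupancy reaches `target_occupancy` and the median fraction of connected
#' area pairs falls inside `target_range`. The shipped defaults
#' ([default_sim_params()]) are products of this procedure.
#'
#' @param growth_mode `"1D_1row"`, `"1D_2rows"` or `"2D"`.
#' @param target_occupancy Minimum acceptable median occupancy (default
#'   0.999).
#' @param target_range Acceptable range for the median fraction of connected
#'   area pairs (default `c(0.39, 0.66)`).
#' @param step_grid,radius_grid,steps_grid Candidate values searched.
#' @param n_pilot Pilot instances per candidate.
#' @param layout Pilot layout; defaults to the realistic two-origin layout of
#'   the growth mode.
#' @param seed Base seed for pilot instances.
#' @return A list with `params` (a [sim_params()]), `satisfied` (logical),
#'   and `trace` (a data.frame of all candidates with their pilot medians).
#'   If no candidate satisfies both criteria, the best found is returned
#'   with `satisfied = FALSE`.
#' @export
calibrate <- function(growth_mode = c("1D_1row", "1D_2rows", "2D"),
                      target_occupancy = 0.999,
                      target_range = c(0.39, 0.66),
                      step_grid = c(0.5, 1.0),
                      radius_grid = c(0.006, 0.013, 0.02),
                      steps_grid = c(300L, 450L), n_pilot = 3L,
                      layout = NULL, seed = 1L) {
  growth_mode <- match.arg(growth_mode)
  stopifnot(target_occupancy >= 0, target_occupancy <= 1,
            target_range[1] < target_range[2])
  if (is.null(layout)) {
    abbr <- c("1D_1row" = "1D-1row-2or", "1D_2rows" = "1D-2row-2or",
              "2D" = "2D-2or")[[growth_mode]]
    layout <- get_layout(abbr)
  }
  grid <- expand.grid(step_length = step_grid, contact_radius = radius_grid,
                      total_steps = steps_grid)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    p <- sim_params(grid$step_length[g], grid$contact_radius[g],
                    total_steps = grid$total_steps[g])
    occ <- frac <- numeric(n_pilot)
    for (i in seq_len(n_pilot)) {
      r <- run_instance(layout, p, seed = seed + i - 1L)
      occ[i] <- r$occupancy
      conn <- aggregate_connectome(r$synapses, r$neuron_area,
                                   n_areas = nrow(r$sheet$areas))
      frac[i] <- fraction_connected(conn)
    }
    c(occupancy = stats::median(occ), fraction = stats::median(frac))
  })
  trace <- cbind(grid, do.call(rbind, res))
  ok <- trace$occupancy >= target_occupancy &
    trace$fraction >= target_range[1] & trace$fraction <= target_range[2]
  pick <- if (any(ok)) which(ok)[1] else {
    # best found: prioritise occupancy, then distance to the target band
    miss <- pmax(target_range[1] - trace$fraction,
                 trace$fraction - target_range[2], 0)
    order(trace$occupancy < target_occupancy, miss)[1]
  }
  list(params = sim_params(trace$step_length[pick],
                           trace$contact_radius[pick],
                           total_steps = trace$total_steps[pick]),
       satisfied = any(ok), trace = trace)
}

## ---- internal ---------------------------------------------------------

.reflect <- function(v, lo, hi) {
  for (guard in 1:64) {
    if (v < lo) v <- 2 * lo - v
    else if (v > hi) v <- 2 * hi - v
    else return(v)
  }
  min(max(v, lo), hi)
}

# index (row in sheet$areas) of the area containing each point; points on
# shared boundaries resolve to the higher cell, points outside clamp to the
# nearest area (boundary float tolerance)
.containing_area <- function(sheet, x, y) {
  side <- sheet$layout$area_side
  ax <- round(sheet$areas$x0 / side)
  ay <- round(sheet$areas$y0 / side)
  key <- paste(ax, ay)
  cx <- pmin(pmax(floor(x / side), min(ax)), max(ax))
  cy <- pmin(pmax(floor(y / side), min(ay)), max(ay))
  idx <- match(paste(cx, cy), key)
  if (anyNA(idx)) {
    # grid cell without an area (multi-row sheets during growth): nearest
    # area centroid
    for (i in which(is.na(idx))) {
      d2 <- (sheet$areas$x0 + side / 2 - x[i])^2 +
        (sheet$areas$y0 + side / 2 - y[i])^2
      idx[i] <- which.min(d2)
    }
  }
  idx
}

.advance <- function(state, params, t_from, t_to, use_compiled) {
  n_steps <- t_to - t_from + 1L
  if (n_steps <= 0L || !length(state$px)) {
    state$time <- max(state$time, t_to)
    return(state)
  }
  if (use_compiled) {
    ab <- .area_bounds(state$sheet)
    pa <- match(state$parent_area, state$sheet$areas$area_id)
    out <- run_steps_cpp(state$px, state$py, state$occupied, state$eligible,
                         pa, state$target, state$soma_x, state$soma_y,
                         ab, state$sheet$bounds,
                         params$step_length, params$contact_radius,
                         params$accept_prob, t_from, n_steps)
    state$px <- out$px
    state$py <- out$py
    state$occupied <- out$occupied
    state$eligible <- out$eligible
    state$target <- out$target
    if (length(out$syn_source))
      state$synapses <- rbind(state$synapses, data.frame(
        source_neuron_id = out$syn_source,
        target_neuron_id = out$syn_target,
        time_step = out$syn_time))
    state$time <- t_to
  } else {
    state$time <- t_from - 1L
    for (t in t_from:t_to) state <- sim_step(state, params)
  }
  state
}
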