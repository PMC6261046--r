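#' Initialise a cortical sheet
#'
#' Creates the state of the cortical sheet at time 0 for a growth layout.
#' Planar 1D layouts start with one area per origin per row; planar 2D
#' layouts start empty (the first growth event places the origin areas);
#' radial layouts start with the full final arrangement of areas but no
#' somata; static layouts start fully formed, somata included.
#'
#' Stochastic choices made at initialisation (the density permutation of the
#' random set, the per-area soma fill order of the radial set) are drawn from
#' the R random number generator; pass `seed` or call [set.seed()] first for
#' reproducibility.
#'
#' @param config A [growth_layout()].
#' @param seed Optional integer seed applied before initialisation.
#' @return An object of class `cortical_sheet`.
#' @export
init_sheet <- function(config, seed = NULL) {
  stopifnot(inherits(config, "growth_layout"))
  if (!is.null(seed)) set.seed(seed)
  sheet <- structure(
    list(layout = config, current_event = 0L,
         areas = .empty_areas(), somata = .empty_somata(),
         displacement_log = list(),
         bounds = .sheet_bounds(config, 0L),
         density_pool = NULL, fill_order = NULL, n_filled = integer(0)),
    class = "cortical_sheet")
  n_tiers <- n_density_tiers(config)

  if (config$set_name == "random") {
    # permute the realistic density multiset over the creation order
    tiers <- .final_slots(config)$creation_tier
    pool <- config$density_min *
      (1 + (config$density_fold - 1) *
         (if (n_tiers == 1L) 0 else tiers / (n_tiers - 1)))
    sheet$density_pool <- sample(pool)
  }

  if (config$set_name %in% c("radial", "static")) {
    slots <- .final_slots(config)
    dens <- density_for_tier(slots$creation_tier, n_tiers, config)
    sheet <- .add_areas(sheet, slots, creation_event = 0L, density = dens,
                        events_applied = config$n_ref_events,
                        with_somata = (config$set_name == "static"))
    if (config$set_name == "radial") {
      sheet$fill_order <- lapply(seq_len(nrow(sheet$areas)), function(i) {
        a <- sheet$areas[i, ]
        g <- place_somata(a$n_target, 0, 0, config$area_side)
        g[sample.int(nrow(g)), , drop = FALSE]
      })
      sheet$n_filled <- integer(nrow(sheet$areas))
    }
    sheet$bounds <- .sheet_bounds(config, config$n_ref_events)
  } else if (config$growth_mode != "2D") {
    slots <- .event_slots(config, 0L)
    dens <- .planar_density(sheet, slots$creation_tier, n_existing = 0L)
    sheet <- .add_areas(sheet, slots, creation_event = 0L, density = dens,
                        events_applied = 0L, with_somata = TRUE)
  }
  sheet
}

#' @export
print.cortical_sheet <- function(x, ...) {
  cat(sprintf("<cortical_sheet> %s: event %d/%d, %d areas, %d somata\n",
              x$layout$abbreviation, x$current_event,
              x$layout$n_growth_events, nrow(x$areas), nrow(x$somata)))
  invisible(x)
}

#' Apply the next growth event to a sheet
#'
#' Planar layouts append new areas on the fringes of each origin block (1D:
#' one area per side per origin per row; 2D: the first event places the
#' origin areas, later events add a complete square ring per origin),
#' re-position all areas so the sheet stays contiguous, and record the
#' displacement applied to every pre-existing area. Radial layouts add a
#' fixed number of somata to every unfinished area. Static layouts are
#' complete after initialisation; their single event is a no-op.
#'
#' @param sheet A `cortical_sheet`.
#' @param event_index Must equal `sheet$current_event + 1`.
#' @return The updated sheet; `sheet$displacement_log[[event_index]]` holds
#'   the per-area shift vectors applied at this event.
#' @export
apply_growth_event <- function(sheet, event_index) {
  config <- sheet$layout
  if (event_index != sheet$current_event + 1L)
    stop("events must be applied in order")
  if (event_index > config$n_growth_events)
    stop("event beyond growth schedule")
  no_shift <- data.frame(area_id = sheet$areas$area_id,
                         dx = numeric(nrow(sheet$areas)),
                         dy = numeric(nrow(sheet$areas)))

  if (config$set_name == "static") {
    sheet$displacement_log[[event_index]] <- no_shift
  } else if (config$set_name == "radial") {
    k_add <- ceiling(max(sheet$areas$n_target) / config$n_growth_events)
    added <- list()
    next_id <- nrow(sheet$somata)
    for (i in seq_len(nrow(sheet$areas))) {
      done <- sheet$n_filled[i]
      take <- min(k_add, sheet$areas$n_target[i] - done)
      if (take > 0L) {
        pos <- sheet$fill_order[[i]][done + seq_len(take), , drop = FALSE]
        added[[length(added) + 1L]] <- data.frame(
          neuron_id = next_id + seq_len(take),
          area_id = sheet$areas$area_id[i], rx = pos$rx, ry = pos$ry)
        next_id <- next_id + take
        sheet$n_filled[i] <- done + take
      }
    }
    if (length(added))
      sheet$somata <- rbind(sheet$somata, do.call(rbind, added))
    sheet$displacement_log[[event_index]] <- no_shift
  } else {
    slots <- .event_slots(config, event_index)
    dens <- .planar_density(sheet, slots$creation_tier,
                            n_existing = nrow(sheet$areas))
    old_pos <- sheet$areas[, c("area_id", "x0", "y0")]
    sheet <- .add_areas(sheet, slots, creation_event = event_index,
                        density = dens, events_applied = event_index,
                        with_somata = TRUE)
    # recompute positions of all areas under the enlarged sheet
    pos <- .area_positions(config, sheet$areas, event_index)
    sheet$areas$x0 <- pos$x0
    sheet$areas$y0 <- pos$y0
    sheet$bounds <- .sheet_bounds(config, event_index)
    shift <- data.frame(
      area_id = old_pos$area_id,
      dx = sheet$areas$x0[match(old_pos$area_id, sheet$areas$area_id)] -
        old_pos$x0,
      dy = sheet$areas$y0[match(old_pos$area_id, sheet$areas$area_id)] -
        old_pos$y0)
    sheet$displacement_log[[event_index]] <- shift
  }
  sheet$current_event <- event_index
  sheet
}

#' Grow a sheet through all its growth events
#'
#' Convenience wrapper applying every growth event in order (geometry only;
#' no axon simulation).
#'
#' @inheritParams init_sheet
#' @return The final `cortical_sheet`.
#' @export
grow_sheet <- function(config, seed = NULL) {
  sheet <- init_sheet(config, seed)
  for (e in seq_len(config$n_growth_events))
    sheet <- apply_growth_event(sheet, e)
  sheet
}

#' Area table of a sheet
#'
#' @param sheet A `cortical_sheet`.
#' @return Data frame with one row per area: `area_id`, `origin_id`,
#'   `creation_event`, `creation_tier`, `density`, `centroid_x`,
#'   `centroid_y`, `n_somata` (currently placed somata).
#' @export
sheet_areas <- function(sheet) {
  a <- sheet$areas
  half <- sheet$layout$area_side / 2
  n_somata <- as.integer(table(factor(sheet$somata$area_id,
                                      levels = a$area_id)))
  data.frame(area_id = a$area_id, origin_id = a$origin_id,
             creation_event = a$creation_event,
             creation_tier = a$creation_tier, density = a$density,
             centroid_x = a$x0 + half, centroid_y = a$y0 + half,
             n_somata = n_somata)
}

#' Absolute soma coordinates of a sheet
#'
#' @param sheet A `cortical_sheet`.
#' @return Data frame with `neuron_id`, `area_id`, `x`, `y`.
#' @export
soma_positions <- function(sheet) {
  s <- sheet$somata
  i <- match(s$area_id, sheet$areas$area_id)
  data.frame(neuron_id = s$neuron_id, area_id = s$area_id,
             x = sheet$areas$x0[i] + s$rx, y = sheet$areas$y0[i] + s$ry)
}

# per-area axis-aligned bounds, rows aligned with sheet$areas
.area_bounds <- function(sheet) {
  side <- sheet$layout$area_side
  cbind(x0 = sheet$areas$x0, x1 = sheet$areas$x0 + side,
        y0 = sheet$areas$y0, y1 = sheet$areas$y0 + side)
}

## ---- internal helpers -------------------------------------------------

.empty_areas <- function() {
  data.frame(area_id = integer(0), origin_id = integer(0), ux = integer(0),
             uy = integer(0), creation_event = integer(0),
             creation_tier = integer(0), density = numeric(0),
             n_target = integer(0), x0 = numeric(0), y0 = numeric(0))
}

.empty_somata <- function() {
  data.frame(neuron_id = integer(0), area_id = integer(0),
             rx = numeric(0), ry = numeric(0))
}

# density values for newly created planar areas (consumes the permuted pool
# for the random set, otherwise evaluates the oriented gradient)
.planar_density <- function(sheet, creation_tier, n_existing) {
  config <- sheet$layout
  if (config$set_name == "random") {
    sheet$density_pool[n_existing + seq_along(creation_tier)]
  } else {
    density_for_tier(creation_tier, n_density_tiers(config), config)
  }
}

.add_areas <- function(sheet, slots, creation_event, density, events_applied,
                       with_somata) {
  config <- sheet$layout
  n0 <- nrow(sheet$areas)
  ids <- n0 + seq_len(nrow(slots))
  n_target <- as.integer(round(density * config$area_side^2))
  new_areas <- data.frame(
    area_id = ids, origin_id = slots$origin_id, ux = slots$ux, uy = slots$uy,
    creation_event = creation_event, creation_tier = slots$creation_tier,
    density = density, n_target = n_target, x0 = 0, y0 = 0)
  sheet$areas <- rbind(sheet$areas, new_areas)
  pos <- .area_positions(config, sheet$areas, events_applied)
  sheet$areas$x0 <- pos$x0
  sheet$areas$y0 <- pos$y0
  if (with_somata) {
    added <- vector("list", nrow(new_areas))
    next_id <- nrow(sheet$somata)
    for (j in seq_len(nrow(new_areas))) {
      grid <- place_somata(new_areas$n_target[j], 0, 0, config$area_side)
      added[[j]] <- data.frame(
        neuron_id = next_id + seq_len(nrow(grid)),
        area_id = new_areas$area_id[j], rx = grid$rx, ry = grid$ry)
      next_id <- next_id + nrow(grid)
    }
    sheet$somata <- rbind(sheet$somata, do.call(rbind, added))
  }
  sheet
}
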