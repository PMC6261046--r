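#' Growth layout configuration
#'
#' Defines one spatiotemporal growth layout of the developing cortical sheet.
#' A layout combines a layout set (the relation between time of neurogenesis
#' and neuron density), a growth mode (one or two rows of areas growing along
#' one dimension, or fully two-dimensional growth), and a number of
#' neurogenetic origins. Areas are unit squares (side `area_side`) whose
#' neuron density follows a linear gradient from `density_min` up to
#' `density_fold * density_min` across the layout's density tiers, emulating
#' the roughly five-fold variation of neuron density across the cortex.
#'
#' @param set_name One of `"realistic"`, `"inverse"`, `"radial"`, `"static"`,
#'   `"random"`. `"realistic"` grows planarly with later areas denser;
#'   `"inverse"` grows planarly with later areas sparser; `"radial"` keeps the
#'   final sheet geometry fixed and fills all areas with neurons at a constant
#'   rate; `"static"` starts fully formed; `"random"` grows planarly but
#'   permutes the realistic density multiset over areas.
#' @param growth_mode One of `"1D_1row"`, `"1D_2rows"`, `"2D"`.
#' @param n_origins Number of neurogenetic origins: 1, 2 or 3 for 1D modes,
#'   1, 2 or 4 for the 2D mode.
#' @param n_growth_events Number of growth events (see Details).
#' @param total_steps Simulated duration in time steps; all growth events are
#'   scheduled within the first third.
#' @param density_min Neuron density (somata per unit area) of the lowest
#'   density tier.
#' @param density_fold Ratio of highest to lowest tier density.
#' @param area_side Side length of each (square) cortical area.
#' @param n_ref_events For `"static"` and `"radial"` sets, the number of
#'   growth events of the corresponding planar layout, which defines the
#'   final geometry and density gradient. Defaults to `n_growth_events`.
#' @param abbreviation Short label for the layout; autogenerated if `NULL`.
#'
#' @details Growth-event counting differs between modes. In 1D modes the
#' origin areas pre-exist at time 0 and each growth event adds one new area
#' per side per origin per row. In the 2D mode the sheet starts empty, the
#' first growth event places the origin area(s) and every later event adds a
#' complete square ring around each origin block.
#'
#' @return An object of class `growth_layout`.
#' @export
growth_layout <- function(set_name, growth_mode, n_origins, n_growth_events,
                          total_steps = 300L, density_min = 100,
                          density_fold = 5, area_side = 1,
                          n_ref_events = NULL, abbreviation = NULL) {
  set_name <- match.arg(set_name,
                        c("realistic", "inverse", "radial", "static", "random"))
  growth_mode <- match.arg(growth_mode, c("1D_1row", "1D_2rows", "2D"))
  n_origins <- as.integer(n_origins)
  n_growth_events <- as.integer(n_growth_events)
  total_steps <- as.integer(total_steps)
  if (growth_mode == "2D") {
    if (!n_origins %in% c(1L, 2L, 4L))
      stop("2D growth supports 1, 2 or 4 origins")
  } else {
    if (!n_origins %in% c(1L, 2L, 3L))
      stop("1D growth supports 1, 2 or 3 origins")
  }
  if (n_growth_events < 1L) stop("n_growth_events must be positive")
  if (is.null(n_ref_events)) n_ref_events <- n_growth_events
  n_ref_events <- as.integer(n_ref_events)
  if (set_name %in% c("realistic", "inverse", "random") &&
      n_ref_events != n_growth_events)
    stop("n_ref_events only applies to static and radial layouts")
  if (density_fold <= 1) stop("density_fold must exceed 1")
  if (density_min <= 0 || area_side <= 0)
    stop("density_min and area_side must be positive")
  if (total_steps < 3L * n_growth_events)
    stop("total_steps too short: all growth events must fit in total_steps/3")
  if (is.null(abbreviation)) {
    mode_tag <- c("1D_1row" = "1D-1row", "1D_2rows" = "1D-2row", "2D" = "2D")
    abbreviation <- paste0(
      if (set_name == "realistic") "" else paste0(set_name, "-"),
      mode_tag[[growth_mode]], "-", n_origins, "or")
  }
  structure(
    list(set_name = set_name, growth_mode = growth_mode,
         n_origins = n_origins, n_growth_events = n_growth_events,
         n_ref_events = n_ref_events, total_steps = total_steps,
         density_min = density_min, density_fold = density_fold,
         area_side = area_side, abbreviation = abbreviation),
    class = "growth_layout")
}

#' @export
print.growth_layout <- function(x, ...) {
  cat(sprintf("<growth_layout> %s: set=%s mode=%s origins=%d events=%d (T=%d)\n",
              x$abbreviation, x$set_name, x$growth_mode, x$n_origins,
              x$n_growth_events, x$total_steps))
  invisible(x)
}

#' Number of density tiers of a layout
#'
#' 1D layouts have one tier per growth event plus the origin tier; 2D layouts
#' have one tier per growth event (the first event places the origin areas).
#' Static and radial layouts inherit the tier structure of the planar layout
#' that defines their final geometry.
#'
#' @param config A [growth_layout()].
#' @return Integer number of distinct density tiers.
#' @export
n_density_tiers <- function(config) {
  k <- config$n_ref_events
  if (config$growth_mode == "2D") k else k + 1L
}

#' Neuron density for a creation tier
#'
#' Linear density ramp from `density_min` to `density_fold * density_min`
#' across `n_tiers` tiers. For realistic, radial and static layouts the
#' creation tier maps ascending onto the gradient (later areas denser); for
#' the inverse set it maps descending. The random set draws from the same
#' multiset of values as the realistic gradient; the permutation over areas
#' is applied when the sheet is built.
#'
#' @param tier Creation tier, `0 <= tier < n_tiers` (0 = formed first).
#' @param n_tiers Total number of tiers.
#' @param config A [growth_layout()].
#' @return Density in somata per unit area.
#' @export
density_for_tier <- function(tier, n_tiers, config) {
  if (any(tier < 0L | tier >= n_tiers)) stop("tier out of range")
  g <- if (config$set_name == "inverse") n_tiers - 1L - tier else tier
  frac <- if (n_tiers == 1L) 0 else g / (n_tiers - 1)
  config$density_min * (1 + (config$density_fold - 1) * frac)
}

#' Registry of the 21 growth layouts
#'
#' Enumerates all 21 spatiotemporal growth layouts: the realistic set in
#' three growth modes with 1, 2 and 3 (1D) or 4 (2D) origins, and the
#' inverse, radial, static and random sets in three growth modes with two
#' origins each.
#'
#' @param total_steps Simulated duration (time steps) for every layout.
#' @param density_min Lowest tier density for every layout.
#' @param ... Further arguments passed to [growth_layout()].
#' @return Named list of 21 `growth_layout` objects, keyed by abbreviation.
#' @export
make_layout_registry <- function(total_steps = 300L, density_min = 100, ...) {
  ev1d <- c(`1` = 12L, `2` = 6L, `3` = 4L)
  ev2d <- c(`1` = 5L, `2` = 5L, `4` = 4L)
  specs <- list()
  add <- function(set, mode, orig, ev, ref = ev) {
    specs[[length(specs) + 1L]] <<- list(set = set, mode = mode, orig = orig,
                                         ev = ev, ref = ref)
  }
  for (orig in c(1L, 2L, 3L)) {
    add("realistic", "1D_1row", orig, ev1d[[as.character(orig)]])
    add("realistic", "1D_2rows", orig, ev1d[[as.character(orig)]])
    add("realistic", "2D", if (orig == 3L) 4L else orig,
        ev2d[[as.character(if (orig == 3L) 4L else orig)]])
  }
  for (set in c("inverse", "radial", "static", "random")) {
    for (mode in c("1D_1row", "1D_2rows", "2D")) {
      ref <- if (mode == "2D") 5L else 6L
      add(set, mode, 2L, if (set == "static") 1L else ref, ref)
    }
  }
  configs <- lapply(specs, function(s)
    growth_layout(s$set, s$mode, s$orig, s$ev, total_steps = total_steps,
                  density_min = density_min, n_ref_events = s$ref, ...))
  names(configs) <- vapply(configs, `[[`, character(1), "abbreviation")
  stopifnot(length(configs) == 21L, !anyDuplicated(names(configs)))
  configs
}

#' Retrieve one layout from the registry by abbreviation
#' @param abbreviation Layout abbreviation, e.g. `"1D-1row-2or"`.
#' @inheritParams make_layout_registry
#' @return A `growth_layout`.
#' @export
get_layout <- function(abbreviation, total_steps = 300L, density_min = 100,
                       ...) {
  reg <- make_layout_registry(total_steps = total_steps,
                              density_min = density_min, ...)
  if (!abbreviation %in% names(reg))
    stop("unknown layout abbreviation: ", abbreviation)
  reg[[abbreviation]]
}

#' Schedule of growth events
#'
#' Growth events are evenly spaced within the first third of the simulated
#' duration, with the last event exactly at `floor(total_steps / 3)`, so that
#' the full complement of neurons is present for the remaining two thirds.
#'
#' @param config A [growth_layout()].
#' @return Integer vector of event time steps, strictly increasing.
#' @export
schedule_growth_events <- function(config) {
  k <- config$n_growth_events
  horizon <- config$total_steps %/% 3L
  if (horizon < k) stop("growth events do not fit in total_steps / 3")
  times <- as.integer(round(seq_len(k) * horizon / k))
  if (k == 1L) times <- 1L
  if (any(diff(times) < 1L)) stop("growth events do not fit in total_steps / 3")
  times
}

#' Place somata on a regular grid inside an area
#'
#' Somata are spaced equidistantly: `n` somata are arranged on an `r x c`
#' grid (`r <= c`, `r * c = n`, factor pair closest to square), cell-centred
#' within the area bounds.
#'
#' @param n Number of somata.
#' @param x0,y0 Lower-left corner of the area.
#' @param side Side length of the area.
#' @return Data frame with columns `rx`, `ry`: offsets from the lower-left
#'   corner, strictly inside the area.
#' @export
place_somata <- function(n, x0 = 0, y0 = 0, side = 1) {
  stopifnot(n >= 1)
  divs <- which(n %% seq_len(floor(sqrt(n))) == 0)
  r <- max(divs)          # largest divisor <= sqrt(n): closest-to-square pair
  cc <- n %/% r
  xs <- (seq_len(cc) - 0.5) / cc * side
  ys <- (seq_len(r) - 0.5) / r * side
  g <- expand.grid(rx = xs, ry = ys)
  data.frame(rx = x0 + g$rx, ry = y0 + g$ry)
}

## ---- internal geometry ------------------------------------------------

# block grid positions for 2D origin blocks: on a line (<=2) or 2x2 (4)
.block_grid <- function(n_origins) {
  if (n_origins <= 2L) {
    cbind(bi = seq_len(n_origins) - 1L, bj = rep(0L, n_origins))
  } else {
    cbind(bi = c(0L, 1L, 0L, 1L), bj = c(0L, 0L, 1L, 1L))
  }
}

# absolute lower-left corners for all areas, given slots and events applied
.area_positions <- function(config, areas, events_applied) {
  side <- config$area_side
  if (config$growth_mode == "2D") {
    e <- max(events_applied, 1L)
    W <- 2L * (e - 1L) + 1L
    bg <- .block_grid(config$n_origins)
    bi <- bg[areas$origin_id, "bi"]
    bj <- bg[areas$origin_id, "bj"]
    x0 <- (bi * W + areas$ux + (e - 1L)) * side
    y0 <- (bj * W + areas$uy + (e - 1L)) * side
  } else {
    e <- events_applied
    w <- 2L * e + 1L                      # width of each origin block
    x0 <- ((areas$origin_id - 1L) * w + areas$ux + e) * side
    y0 <- areas$uy * side
  }
  list(x0 = x0, y0 = y0)
}

.sheet_bounds <- function(config, events_applied) {
  side <- config$area_side
  if (config$growth_mode == "2D") {
    e <- max(events_applied, 1L)
    W <- 2L * (e - 1L) + 1L
    bg <- .block_grid(config$n_origins)
    c(0, (max(bg[, "bi"]) + 1L) * W * side,
      0, (max(bg[, "bj"]) + 1L) * W * side)
  } else {
    e <- events_applied
    nrows <- if (config$growth_mode == "1D_2rows") 2L else 1L
    c(0, config$n_origins * (2L * e + 1L) * side, 0, nrows * side)
  }
}

# slots of areas added at a given creation event (planar sets), with
# creation tier; event 0 = origin areas (1D only)
.event_slots <- function(config, event) {
  nrows <- if (config$growth_mode == "1D_2rows") 2L else 1L
  if (config$growth_mode == "2D") {
    stopifnot(event >= 1L)
    r <- event - 1L
    if (r == 0L) {
      cells <- cbind(ux = 0L, uy = 0L)
    } else {
      u <- seq.int(-r, r)
      ring <- rbind(cbind(ux = u, uy = -r), cbind(ux = u, uy = r),
                    cbind(ux = -r, uy = u[-c(1L, length(u))]),
                    cbind(ux = r, uy = u[-c(1L, length(u))]))
      cells <- ring[order(ring[, "uy"], ring[, "ux"]), , drop = FALSE]
    }
    do.call(rbind, lapply(seq_len(config$n_origins), function(b)
      data.frame(origin_id = b, ux = cells[, "ux"], uy = cells[, "uy"],
                 creation_tier = r)))
  } else {
    if (event == 0L) {
      do.call(rbind, lapply(seq_len(config$n_origins), function(b)
        data.frame(origin_id = b, ux = 0L, uy = seq_len(nrows) - 1L,
                   creation_tier = 0L)))
    } else {
      do.call(rbind, lapply(seq_len(config$n_origins), function(b)
        do.call(rbind, lapply(c(-event, event), function(s)
          data.frame(origin_id = b, ux = s, uy = seq_len(nrows) - 1L,
                     creation_tier = event)))))
    }
  }
}

# full final complement of area slots in creation order (used by radial,
# static and for the realistic density multiset)
.final_slots <- function(config) {
  k <- config$n_ref_events
  first <- if (config$growth_mode == "2D") 1L else 0L
  do.call(rbind, lapply(seq.int(first, k),
                        function(e) .event_slots(config, e)))
}
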