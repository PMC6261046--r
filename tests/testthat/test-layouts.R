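table1_area_counts <- c(
  "1D-1row-1or" = 25, "1D-2row-1or" = 50, "2D-1or" = 81,
  "1D-1row-2or" = 26, "1D-2row-2or" = 52, "2D-2or" = 162,
  "1D-1row-3or" = 27, "1D-2row-3or" = 54, "2D-4or" = 196,
  "inverse-1D-1row-2or" = 26, "inverse-1D-2row-2or" = 52,
  "inverse-2D-2or" = 162,
  "radial-1D-1row-2or" = 26, "radial-1D-2row-2or" = 52,
  "radial-2D-2or" = 162,
  "static-1D-1row-2or" = 26, "static-1D-2row-2or" = 52,
  "static-2D-2or" = 162,
  "random-1D-1row-2or" = 26, "random-1D-2row-2or" = 52,
  "random-2D-2or" = 162)

test_that("the registry enumerates the 21 growth layouts", {
  reg <- make_layout_registry()
  expect_length(reg, 21)
  expect_false(anyDuplicated(names(reg)) > 0)
  sets <- vapply(reg, `[[`, character(1), "set_name")
  expect_equal(sum(sets == "realistic"), 9)
  expect_equal(unname(table(sets)[c("inverse", "radial", "static",
                                    "random")]),
               rep(3L, 4), ignore_attr = TRUE)
  expect_error(make_layout_registry(total_steps = 10), "total_steps")
  expect_error(growth_layout("realistic", "2D", 3, 4), "origins")
})

test_that("every layout reaches its published final area count", {
  reg <- make_layout_registry()
  counts <- vapply(reg, function(l) nrow(grow_sheet(l, seed = 1)$areas),
                   integer(1))
  expect_equal(counts[names(table1_area_counts)], table1_area_counts,
               ignore_attr = TRUE)
})

test_that("density tiers interpolate linearly and respect orientation", {
  cfg <- growth_layout("realistic", "1D_1row", 2, 6, density_min = 100)
  expect_equal(density_for_tier(0, 7, cfg), 100)
  expect_equal(density_for_tier(6, 7, cfg), 500)
  expect_equal(density_for_tier(3, 7, cfg), 300)
  expect_error(density_for_tier(7, 7, cfg), "range")
  inv <- growth_layout("inverse", "1D_1row", 2, 6, density_min = 100)
  expect_equal(density_for_tier(0, 7, inv), 500)
  expect_equal(density_for_tier(6, 7, inv), 100)
})

test_that("sheet initialisation matches each layout family", {
  s <- init_sheet(growth_layout("realistic", "1D_1row", 2, 6), seed = 1)
  expect_equal(nrow(s$areas), 2)
  s2d <- init_sheet(growth_layout("realistic", "2D", 2, 5), seed = 1)
  expect_equal(nrow(s2d$areas), 0)
  st <- init_sheet(get_layout("static-1D-1row-2or"), seed = 1)
  expect_equal(nrow(st$areas), 26)
  expect_equal(nrow(st$somata), sum(st$areas$n_target))
  rad <- init_sheet(get_layout("radial-1D-2row-2or"), seed = 1)
  expect_equal(nrow(rad$areas), 52)
  expect_equal(nrow(rad$somata), 0)
})

test_that("somata sit on a centred near-square grid", {
  g9 <- place_somata(9)
  expect_equal(sort(unique(g9$rx)), c(1 / 6, 1 / 2, 5 / 6))
  expect_equal(sort(unique(g9$ry)), c(1 / 6, 1 / 2, 5 / 6))
  expect_equal(place_somata(1), data.frame(rx = 0.5, ry = 0.5))
  # oracle: enumerate factor pairs, keep the one closest to square
  for (n in c(12, 10, 7, 30, 17)) {
    pairs <- cbind(r = which(n %% seq_len(n) == 0))
    pairs <- cbind(pairs, c = n / pairs[, "r"])
    pairs <- pairs[pairs[, "r"] <= pairs[, "c"], , drop = FALSE]
    best <- pairs[which.min(pairs[, "c"] - pairs[, "r"]), ]
    g <- place_somata(n)
    expect_equal(length(unique(g$ry)), unname(best["r"]), label = n)
    expect_equal(length(unique(g$rx)), unname(best["c"]), label = n)
    expect_true(all(g$rx > 0 & g$rx < 1 & g$ry > 0 & g$ry < 1))
  }
})

test_that("growth events are evenly spaced within the first third", {
  expect_equal(schedule_growth_events(
    growth_layout("realistic", "1D_1row", 2, 6, total_steps = 300)),
    c(17, 33, 50, 67, 83, 100))
  expect_equal(schedule_growth_events(get_layout("static-1D-1row-2or")), 1)
  expect_error(growth_layout("realistic", "1D_1row", 2, 6,
                             total_steps = 12), "total_steps")
  sched <- schedule_growth_events(get_layout("1D-1row-1or"))
  expect_length(sched, 12)
  expect_true(all(diff(sched) >= 1))
  expect_equal(max(sched), 100)
})

test_that("planar growth only moves existing areas apart", {
  for (abbr in c("1D-1row-2or", "2D-2or", "1D-2row-3or")) {
    l <- get_layout(abbr)
    sh <- init_sheet(l, seed = 1)
    for (e in seq_len(l$n_growth_events)) {
      ids <- sh$areas$area_id
      d_before <- dist(cbind(sh$areas$x0, sh$areas$y0))
      sh <- apply_growth_event(sh, e)
      m <- match(ids, sh$areas$area_id)
      d_after <- dist(cbind(sh$areas$x0[m], sh$areas$y0[m]))
      expect_true(all(d_after - d_before > -1e-9), label = abbr)
    }
    expect_error(apply_growth_event(sh, l$n_growth_events + 1), "schedule")
  }
})

test_that("final density gradients have the prescribed orientation", {
  s <- grow_sheet(get_layout("1D-1row-2or"), seed = 1)
  expect_equal(cor(s$areas$creation_event, s$areas$density,
                   method = "spearman"), 1)
  si <- grow_sheet(get_layout("inverse-1D-1row-2or"), seed = 1)
  expect_equal(cor(si$areas$creation_event, si$areas$density,
                   method = "spearman"), -1)
  for (abbr in c("radial-1D-1row-2or", "static-1D-1row-2or")) {
    sr <- grow_sheet(get_layout(abbr), seed = 1)
    expect_equal(cor(sr$areas$creation_tier, sr$areas$density,
                     method = "spearman"), 1, label = abbr)
    expect_equal(sort(sr$areas$density), sort(s$areas$density),
                 label = abbr)
  }
  srand <- grow_sheet(get_layout("random-1D-1row-2or"), seed = 5)
  expect_equal(sort(srand$areas$density), sort(s$areas$density))
})

test_that("neuron numbers are conserved and radial growth is uniform", {
  l <- get_layout("radial-1D-1row-2or")
  sh <- init_sheet(l, seed = 3)
  prev <- 0L
  for (e in seq_len(l$n_growth_events)) {
    before <- table(factor(sh$somata$area_id, levels = sh$areas$area_id))
    sh <- apply_growth_event(sh, e)
    after <- table(factor(sh$somata$area_id, levels = sh$areas$area_id))
    added <- after - before
    unfinished <- before < sh$areas$n_target
    # every unfinished area receives the same increment (up to its target)
    full_add <- added[unfinished & after < sh$areas$n_target]
    if (length(full_add) > 1) expect_length(unique(full_add), 1)
    expect_true(all(added[!unfinished] == 0))
  }
  expect_equal(nrow(sh$somata), sum(sh$areas$n_target))
  # planar layouts: total somata equals the sum of per-area targets
  sp <- grow_sheet(get_layout("1D-2row-2or"), seed = 1)
  expect_equal(nrow(sp$somata), sum(sp$areas$n_target))
  expect_equal(unique(table(sp$somata$area_id)[
    as.character(sp$areas$area_id[sp$areas$creation_tier == 0])]),
    sp$areas$n_target[sp$areas$creation_tier == 0][1])
})

test_that("sheet trajectories are reproducible from the seed", {
  for (abbr in c("random-1D-1row-2or", "radial-1D-2row-2or")) {
    a <- grow_sheet(get_layout(abbr), seed = 11)
    b <- grow_sheet(get_layout(abbr), seed = 11)
    expect_identical(a$areas, b$areas, label = abbr)
    expect_identical(a$somata, b$somata, label = abbr)
  }
})

test_that("sheets tile without overlap and somata stay inside bounds", {
  s <- grow_sheet(get_layout("2D-4or"), seed = 1)
  key <- paste(round(s$areas$x0, 6), round(s$areas$y0, 6))
  expect_false(anyDuplicated(key) > 0)
  pos <- soma_positions(s)
  expect_true(all(pos$x > s$bounds[1] & pos$x < s$bounds[2] &
                  pos$y > s$bounds[3] & pos$y < s$bounds[4]))
})
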