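test_that("cladogenetic events classify by daughter configuration", {
  expect_identical(classify_cladogenetic_event(3L, 1L, 2L), "vicariance")
  expect_identical(classify_cladogenetic_event(3L, 3L, 1L), "subset_sympatry")
  expect_identical(classify_cladogenetic_event(1L, 1L, 1L), "sympatry")
  expect_identical(classify_cladogenetic_event(7L, 3L, 4L), "vicariance")
  # daughter outside the parent: flagged, not an error
  expect_identical(classify_cladogenetic_event(1L, 1L, 2L), "anagenetic_adjusted")
  expect_error(classify_cladogenetic_event(3L, 0L, 1L), "null")
})

test_that("anagenetic extraction dates events at midpoints and counts sources", {
  geo <- geo_complete(3, horizon = 358.9)
  # start {A}, end {A,B}, branch 100-80 Ma: one dispersal into B at 90
  ev <- extract_anagenetic_events(1L, 3L, 80, 100, geo)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$event_type, "dispersal")
  expect_identical(ev$gained_area, "B")
  expect_equal(ev$time, 90)
  expect_identical(ev$n_sources, 1L)
  # start {A,C}, end {A,B,C}: dispersal into B with two source areas
  ev2 <- extract_anagenetic_events(5L, 7L, 80, 100, geo)
  expect_identical(ev2$n_sources, 2L)
  expect_identical(ev2$source_areas, "A+C")
  # start {A,B}, end {A}: one extirpation of B at the midpoint
  ev3 <- extract_anagenetic_events(3L, 1L, 80, 100, geo)
  expect_identical(ev3$event_type, "extirpation")
  expect_identical(ev3$lost_area, "B")
  expect_equal(ev3$time, 90)
})

test_that("impossible midpoint events snap to the nearest allowed sub-interval", {
  # two areas: connected only in the older half of the branch's span
  geo <- geo_sliced(list(matrix(1, 2, 2), diag(1, 2)), horizon = 100)
  # branch 20-80 Ma, midpoint 50 in the disconnected slice; gain of B possible
  # only in (50, 80], so the event snaps to the midpoint of that sub-interval
  ev <- extract_anagenetic_events(1L, 3L, 20, 80, geo)
  expect_equal(ev$time, 65)
  expect_false(ev$unconstrained)
  expect_identical(ev$slice, 1L)
  # branch entirely inside the disconnected slice: unconstrained flag
  ev2 <- extract_anagenetic_events(1L, 3L, 10, 40, geo)
  expect_true(ev2$unconstrained)
  expect_equal(ev2$time, 25)
})

test_that("event summaries tally per area, class and bin, and are additive", {
  geo <- geo_complete(3, horizon = 358.9, high = "A")
  ev <- dplyr::bind_rows(
    extract_anagenetic_events(1L, 3L, 80, 100, geo),   # dispersal into B out of A
    extract_anagenetic_events(3L, 1L, 10, 30, geo),    # extirpation of B
    tibble::tibble(event_type = "vicariance", branch = NA_integer_,
                   gained_area = NA_character_, lost_area = NA_character_,
                   source_areas = "A+B", n_sources = NA_integer_,
                   time = 120, slice = 1L, unconstrained = FALSE))
  s <- summarize_events(ev, geo)
  expect_identical(s$totals$vicariance, 1L)
  pa <- s$per_area
  expect_equal(pa$into[pa$area == "B"], 1)
  expect_equal(pa$out_of[pa$area == "A"], 1)
  expect_equal(pa$extirpations[pa$area == "B"], 1)
  pc <- s$per_class
  expect_equal(sum(pc$into), sum(pa$into))
  expect_equal(pc$out_of[pc$latitude_class == "high"], 1)
  expect_equal(s$per_bin$extirpations[1], 1)    # 20 Ma -> Cenozoic bin

  # permutation invariance and additivity against a one-line counting oracle
  set.seed(51)
  ev_big <- ev[sample(rep(1:3, 7)), ]
  s2 <- summarize_events(ev_big, geo)
  expect_equal(s2$per_area$into, 7 * pa$into)
  expect_equal(s2$totals$dispersal, sum(ev_big$event_type == "dispersal"))
  sA <- summarize_events(ev_big[1:10, ], geo)
  sB <- summarize_events(ev_big[11:21, ], geo)
  expect_equal(sA$per_area$out_of + sB$per_area$out_of, s2$per_area$out_of)
})

test_that("multi-source dispersal adds one out-of count per source area", {
  geo <- geo_complete(3, horizon = 358.9)
  ev <- extract_anagenetic_events(5L, 7L, 80, 100, geo)    # sources {A,C}
  s <- summarize_events(ev, geo)
  expect_equal(s$per_area$out_of[s$per_area$area == "A"], 1)
  expect_equal(s$per_area$out_of[s$per_area$area == "C"], 1)
  expect_equal(sum(s$per_area$out_of), 2)
  expect_equal(sum(s$per_area$into), 1)
})

test_that("tree walk recovers forced event sets from best ranges", {
  geo <- geo_complete(2, horizon = 100)
  # vicariance at the root, no anagenetic events
  tr <- tree2()
  obs <- obs_tbl(c("t1", "t2"), c(1L, 2L))
  anc <- tibble::tibble(node = 3L, rank = 1L, mask = 3L)
  ev <- events_from_ancestral(tr, anc, obs, geo)
  expect_identical(ev$event_type, "vicariance")

  # chain: root {A}, child {A}, grandchild tip {B}: one dispersal into B and
  # one extirpation of A on the terminal branch
  tr3 <- ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")
  obs3 <- obs_tbl(c("t1", "t2", "t3"), c(1L, 2L, 1L))
  anc3 <- tibble::tibble(node = c(4L, 5L), rank = 1L, mask = c(1L, 1L))
  ev3 <- events_from_ancestral(tr3, anc3, obs3, geo)
  anag <- ev3[ev3$event_type %in% c("dispersal", "extirpation"), ]
  expect_identical(sort(anag$event_type), c("dispersal", "extirpation"))
  expect_identical(anag$branch, c(2L, 2L))      # both on the t2 terminal branch
  expect_identical(anag$gained_area[anag$event_type == "dispersal"], "B")
  expect_identical(anag$lost_area[anag$event_type == "extirpation"], "A")
})

test_that("event times stay inside their branch interval on simulated histories", {
  set.seed(61)
  geo <- geo_complete(3, horizon = 100)
  tr <- simulate_fbd_tree(lambda = 0.12, mu = 0.02, psi = 0.02, rho = 1,
                          origin = 60, min_tips = 10)
  h <- simulate_dec_history(tr, geo, d = 0.01, e = 0.01)
  obs <- as_range_observations(h)
  keep <- h$tip_ranges$mask != 0L
  tr2 <- if (all(keep)) tr else ape::drop.tip(tr, h$tip_ranges$label[!keep])
  anc <- ancestral_ranges(tr2, obs, geo, 0.01, 0.01)
  ev <- events_from_ancestral(tr2, anc, obs, geo)
  ta <- tree_ages(tr2)
  anag <- ev[!is.na(ev$branch), ]
  for (r in seq_len(nrow(anag))) {
    ch <- anag$branch[r]
    p <- tr2$edge[tr2$edge[, 2] == ch, 1]
    expect_gte(anag$time[r], ta$ages[ch] - 1e-9)
    expect_lte(anag$time[r], ta$ages[p] + 1e-9)
  }
  # into-count equals (branch, gained area) pairs; out-of >= into
  s <- summarize_events(ev, geo)
  disp <- ev[ev$event_type == "dispersal", ]
  expect_equal(sum(s$per_area$into), nrow(disp))
  expect_gte(sum(s$per_area$out_of), sum(s$per_area$into))
})
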