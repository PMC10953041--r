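# Biogeographic events are extracted from point estimates of ancestral ranges:
# cladogenetic events at nodes (vicariance, subset sympatry, sympatry) and
# anagenetic events along branches (dispersal = area gain, extirpation = area
# loss), dated at branch midpoints and constrained by the time-stratified
# geographic model.

#' Classify a cladogenetic range-inheritance event
#'
#' @param parent,left,right range bitmasks (non-null).
#' @return one of `"vicariance"`, `"subset_sympatry"`, `"sympatry"`, or
#'   `"anagenetic_adjusted"` for configurations not matching any scenario
#'   (these are logged, not errors).
#' @export
classify_cladogenetic_event <- function(parent, left, right) {
  if (parent == 0L || left == 0L || right == 0L) abort("null range in event")
  psz <- range_size(parent)
  if (bitwAnd(left, right) == 0L &&
      bitwAnd(bitwOr(left, right), bitwNot(parent)) == 0L && psz > 1L)
    return("vicariance")
  if (psz == 1L && left == parent && right == parent) return("sympatry")
  if (psz > 1L) {
    if (left == parent && right != parent &&
        bitwAnd(right, bitwNot(parent)) == 0L) return("subset_sympatry")
    if (right == parent && left != parent &&
        bitwAnd(left, bitwNot(parent)) == 0L) return("subset_sympatry")
  }
  "anagenetic_adjusted"
}

# is a dispersal into `area` from any source in `srcmask` possible in slice k?
.dispersal_possible <- function(srcmask, area, geo, k) {
  adj <- geo$slices[[k]]$adjacency
  src <- mask_areas(srcmask, nrow(adj))
  src <- setdiff(src, area)
  length(src) > 0 && any(adj[src, area] != 0)
}

# nominal time = branch midpoint; if the event is impossible in the midpoint's
# slice, snap to the midpoint of the nearest branch sub-interval where it is
# possible; if possible nowhere on the branch, keep the midpoint and flag.
.event_time <- function(possible_fun, age_child, age_parent, geo) {
  mid <- (age_child + age_parent) / 2
  if (possible_fun(slice_at(mid, geo)))
    return(list(time = mid, slice = slice_at(mid, geo), unconstrained = FALSE))
  segs <- .branch_segments(age_child, age_parent, geo)
  lo <- age_child
  cand <- list()
  for (seg in segs) {
    hi <- lo + seg$dt
    if (possible_fun(seg$slice))
      cand[[length(cand) + 1L]] <- list(mid = (lo + hi) / 2, slice = seg$slice)
    lo <- hi
  }
  if (length(cand) == 0)
    return(list(time = mid, slice = slice_at(mid, geo), unconstrained = TRUE))
  dd <- vapply(cand, function(cc) abs(cc$mid - mid), numeric(1))
  best <- cand[[which.min(dd)]]
  list(time = best$mid, slice = best$slice, unconstrained = FALSE)
}

#' Anagenetic events implied by a range change along a branch
#'
#' Each area gained yields one dispersal event (with the full starting range
#' as source areas: one "out of" count per source area); each area lost yields
#' one extirpation. Events are dated at the branch midpoint, snapped to the
#' nearest sub-interval of the branch where the slice connectivity permits the
#' event.
#'
#' @param start range bitmask at the parent-side corner of the branch.
#' @param end range bitmask at the child node or tip.
#' @param age_child,age_parent branch interval (Ma), `age_parent > age_child`.
#' @param geo a `geo_model`.
#' @param branch branch identifier carried into the records.
#' @return tibble of event records.
#' @export
extract_anagenetic_events <- function(start, end, age_child, age_parent, geo,
                                      branch = NA_integer_) {
  if (start == 0L || end == 0L) abort("null range on branch")
  A <- nrow(geo$areas)
  gains <- mask_areas(bitwAnd(end, bitwNot(start)), A)
  losses <- mask_areas(bitwAnd(start, bitwNot(end)), A)
  recs <- list()
  for (a in gains) {
    et <- .event_time(function(k) .dispersal_possible(start, a, geo, k),
                      age_child, age_parent, geo)
    recs[[length(recs) + 1L]] <- tibble(
      event_type = "dispersal", branch = branch,
      gained_area = geo$areas$code[a], lost_area = NA_character_,
      source_areas = format_range(start, geo), n_sources = range_size(start),
      time = et$time, slice = et$slice, unconstrained = et$unconstrained)
  }
  for (a in losses) {
    mid <- (age_child + age_parent) / 2
    recs[[length(recs) + 1L]] <- tibble(
      event_type = "extirpation", branch = branch,
      gained_area = NA_character_, lost_area = geo$areas$code[a],
      source_areas = NA_character_, n_sources = NA_integer_,
      time = mid, slice = slice_at(mid, geo), unconstrained = FALSE)
  }
  bind_rows(recs)
}

# anagenetic cost of turning range a into range b (gains + losses)
.anag_cost <- function(a, b) {
  range_size(bitwAnd(b, bitwNot(a))) + range_size(bitwAnd(a, bitwNot(b)))
}

#' Extract biogeographic events from an ancestral-range table
#'
#' Walks the tree once. At each internal node the best-supported cladogenetic
#' scenario consistent with the best parent range is chosen as the inheritance
#' outcome minimizing the anagenetic changes implied on the two daughter
#' branches (ties: fewer dispersals, then deterministic outcome order); the
#' scenario is classified and the implied anagenetic events on each daughter
#' branch are extracted and dated.
#'
#' @param tree dated `phylo`.
#' @param anc an `ancestral_ranges` table (best range per node is used).
#' @param observations tip range observations (best tip range = observed areas).
#' @param geo a `geo_model`.
#' @return tibble of event records (cladogenetic and anagenetic).
#' @export
events_from_ancestral <- function(tree, anc, observations, geo) {
  ta <- tree_ages(tree)
  ntip <- ape::Ntip(tree)
  best <- anc[anc$rank == 1, c("node", "mask")]
  node_mask <- integer(ntip + tree$Nnode)
  node_mask[best$node] <- best$mask
  tipm <- setNames(observations$mask, observations$label)
  node_mask[seq_len(ntip)] <- as.integer(tipm[tree$tip.label])

  A <- nrow(geo$areas)
  recs <- list()
  for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
    pm <- node_mask[nd]
    if (pm == 0L) next
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    cl <- cladogenesis_events(pm, A)
    costs <- .anag_cost(cl$left, node_mask[kids[1]]) +
             .anag_cost(cl$right, node_mask[kids[2]])
    disp <- range_size(bitwAnd(node_mask[kids[1]], bitwNot(cl$left))) +
            range_size(bitwAnd(node_mask[kids[2]], bitwNot(cl$right)))
    pick <- order(costs, disp, cl$left, cl$right)[1]
    lcorner <- cl$left[pick]; rcorner <- cl$right[pick]
    recs[[length(recs) + 1L]] <- tibble(
      event_type = classify_cladogenetic_event(pm, lcorner, rcorner),
      branch = NA_integer_, gained_area = NA_character_,
      lost_area = NA_character_, source_areas = format_range(pm, geo),
      n_sources = NA_integer_, time = ta$ages[nd],
      slice = slice_at(ta$ages[nd], geo), unconstrained = FALSE)
    corners <- c(lcorner, rcorner)
    for (j in 1:2) {
      ch <- kids[j]
      if (node_mask[ch] == 0L) next
      ev <- extract_anagenetic_events(corners[j], node_mask[ch],
                                      ta$ages[ch], ta$ages[nd], geo,
                                      branch = ch)
      if (nrow(ev) > 0) recs[[length(recs) + 1L]] <- ev
    }
  }
  out <- bind_rows(recs)
  attr(out, "geo") <- geo
  out
}

#' Summarize biogeographic events
#'
#' Per-area counts of dispersals into, dispersals out of (one count per source
#' area per dispersal event) and extirpations from each area; aggregates over
#' high- and low-latitude area classes; total vicariance count; and per-time-
#' bin extirpation tallies.
#'
#' @param events event table from [events_from_ancestral()] or
#'   [extract_anagenetic_events()].
#' @param geo a `geo_model` (for the latitude classes).
#' @param time_bins boundaries (Ma) of the extirpation time bins; default 66
#'   (Cenozoic vs earlier).
#' @return an object of class `event_summary`: list with `per_area`,
#'   `per_class`, `totals` and `per_bin` tibbles.
#' @export
summarize_events <- function(events, geo, time_bins = 66) {
  codes <- geo$areas$code
  per_area <- tibble(area = codes,
                     latitude_class = geo$areas$latitude_class,
                     into = 0, out_of = 0, extirpations = 0)
  if (nrow(events) > 0) {
    disp <- events[events$event_type == "dispersal", ]
    if (nrow(disp) > 0) {
      ti <- table(disp$gained_area)
      per_area$into <- as.numeric(ti[codes]); per_area$into[is.na(per_area$into)] <- 0
      src <- unlist(strsplit(disp$source_areas, "+", fixed = TRUE))
      to <- table(src)
      per_area$out_of <- as.numeric(to[codes]); per_area$out_of[is.na(per_area$out_of)] <- 0
    }
    ext <- events[events$event_type == "extirpation", ]
    if (nrow(ext) > 0) {
      te <- table(ext$lost_area)
      per_area$extirpations <- as.numeric(te[codes])
      per_area$extirpations[is.na(per_area$extirpations)] <- 0
    }
  }
  per_class <- per_area |>
    group_by(.data$latitude_class) |>
    summarise(into = sum(.data$into), out_of = sum(.data$out_of),
              extirpations = sum(.data$extirpations), .groups = "drop")
  totals <- tibble(
    vicariance = sum(events$event_type == "vicariance"),
    subset_sympatry = sum(events$event_type == "subset_sympatry"),
    sympatry = sum(events$event_type == "sympatry"),
    dispersal = sum(events$event_type == "dispersal"),
    extirpation = sum(events$event_type == "extirpation"))
  brks <- sort(unique(c(0, time_bins, Inf)))
  ext <- events[events$event_type == "extirpation", ]
  bin_id <- cut(ext$time, breaks = brks, include.lowest = TRUE, right = TRUE)
  per_bin <- tibble(bin = levels(bin_id),
                    extirpations = as.numeric(table(bin_id)))
  structure(list(per_area = per_area, per_class = per_class,
                 totals = totals, per_bin = per_bin),
            class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat("Biogeographic event summary\n")
  cat(sprintf("  vicariance %d | subset sympatry %d | sympatry %d | dispersal %d | extirpation %d\n",
              x$totals$vicariance, x$totals$subset_sympatry, x$totals$sympatry,
              x$totals$dispersal, x$totals$extirpation))
  print(x$per_class)
  invisible(x)
}

#' @export
autoplot.event_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_area,
                              c("into", "out_of", "extirpations"),
                              names_to = "measure", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$area, y = .data$count,
                                     fill = .data$latitude_class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "events",
                  title = "Dispersals into / out of areas and extirpations") +
    ggplot2::theme_minimal()
}
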