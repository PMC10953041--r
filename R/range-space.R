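# Geographic ranges are encoded as bitmasks over the area list: bit a (0-based)
# set <=> area a+1 occupied. The null range (mask 0) is the absorbing extinct
# state and is never an observable tip state.

.bit <- function(area_index) bitwShiftL(1L, area_index - 1L)

#' Number of areas in a range bitmask
#' @param mask integer bitmask(s).
#' @return integer vector of range sizes.
#' @export
range_size <- function(mask) {
  vapply(mask, function(m) {
    n <- 0L
    while (m > 0L) {
      n <- n + bitwAnd(m, 1L)
      m <- bitwShiftR(m, 1L)
    }
    n
  }, integer(1))
}

#' Area indices occupied by a range
#' @param mask a single integer bitmask.
#' @param n_areas number of areas.
#' @return integer vector of 1-based area indices.
#' @export
mask_areas <- function(mask, n_areas) {
  which(bitwAnd(mask, .bit(seq_len(n_areas))) != 0L)
}

#' Build a range bitmask from area codes or indices
#' @param areas character vector of area codes (or integer indices).
#' @param geo a `geo_model` (needed when `areas` is character).
#' @return integer bitmask.
#' @export
range_mask <- function(areas, geo = NULL) {
  if (is.character(areas)) {
    stopifnot(!is.null(geo))
    idx <- match(areas, geo$areas$code)
    if (anyNA(idx)) abort(paste0("unknown area code(s): ",
                                 paste(areas[is.na(idx)], collapse = ", ")))
  } else {
    idx <- as.integer(areas)
  }
  out <- 0L
  for (i in idx) out <- bitwOr(out, .bit(i))
  out
}

#' Format a range bitmask as "WP+EP" style label
#' @param mask integer bitmask(s).
#' @param geo a `geo_model`.
#' @return character vector.
#' @export
format_range <- function(mask, geo) {
  vapply(mask, function(m) {
    if (m == 0L) return("(extinct)")
    paste(geo$areas$code[mask_areas(m, nrow(geo$areas))], collapse = "+")
  }, character(1))
}

#' Is a set of areas connected under an adjacency matrix?
#'
#' A range is biologically plausible in a time slice only if its areas form a
#' single connected component of that slice's connectivity graph.
#'
#' @param mask integer bitmask of occupied areas (non-null).
#' @param adjacency symmetric 0/1 matrix, 1s on the diagonal.
#' @return `TRUE` iff the occupied areas form one connected component.
#' @export
is_connected_range <- function(mask, adjacency) {
  if (mask == 0L) abort("empty range")
  occ <- mask_areas(mask, nrow(adjacency))
  if (length(occ) == 1L) return(TRUE)
  # breadth-first search restricted to occupied areas
  seen <- occ[1]
  frontier <- occ[1]
  while (length(frontier) > 0L) {
    nb <- occ[occ %in% unlist(lapply(frontier, function(a) which(adjacency[a, ] != 0)))]
    new <- setdiff(nb, seen)
    seen <- c(seen, new)
    frontier <- new
  }
  length(seen) == length(occ)
}

#' Enumerate allowed (connected) ranges under an adjacency matrix
#'
#' @param adjacency symmetric 0/1 connectivity matrix over areas.
#' @param max_range_size largest allowed number of areas in a range.
#' @return integer vector of bitmasks, sorted by range size then bitmask value.
#' @export
enumerate_allowed_ranges <- function(adjacency, max_range_size) {
  if (max_range_size < 1) abort("max_range_size must be >= 1")
  A <- nrow(adjacency)
  # grow connected sets by adding adjacent areas; avoids scanning all 2^A masks
  found <- new.env(hash = TRUE)
  singles <- .bit(seq_len(A))
  for (m in singles) assign(as.character(m), TRUE, envir = found)
  frontier <- as.list(singles)
  size <- 1L
  while (size < max_range_size && length(frontier) > 0L) {
    nxt <- list()
    for (m in frontier) {
      occ <- mask_areas(m, A)
      nb <- setdiff(which(colSums(adjacency[occ, , drop = FALSE] != 0) > 0), occ)
      for (a in nb) {
        m2 <- bitwOr(m, .bit(a))
        key <- as.character(m2)
        if (!exists(key, envir = found, inherits = FALSE)) {
          assign(key, TRUE, envir = found)
          nxt[[length(nxt) + 1L]] <- m2
        }
      }
    }
    frontier <- nxt
    size <- size + 1L
  }
  masks <- as.integer(ls(envir = found))
  masks[order(range_size(masks), masks)]
}

#' Construct a time-stratified geographic model
#'
#' Defines the areas, the geological time slices with their connectivity
#' matrices, and the per-slice and global range state spaces used by the DEC
#' model. The global state space is the union of the per-slice allowed ranges
#' plus the null (extinct) range, ordered by range size then bitmask value
#' (null first).
#'
#' @param areas data frame with columns `code`, `name` (optional) and
#'   `latitude_class` (`"high"` or `"low"`; used only by event summaries).
#' @param slices list of slices, each a list with `older_bound` and
#'   `younger_bound` (Ma) and `adjacency` (A x A symmetric 0/1 matrix with 1s
#'   on the diagonal). Oldest slice first; slices must tile down to 0 Ma.
#' @param max_range_size largest allowed range size (default 5).
#' @return an object of class `geo_model`.
#' @export
geo_model <- function(areas, slices, max_range_size = 5L) {
  areas <- as_tibble(areas)
  if (!"name" %in% names(areas)) areas$name <- areas$code
  stopifnot(all(c("code", "latitude_class") %in% names(areas)))
  if (anyDuplicated(areas$code)) abort("area codes must be unique")
  if (!all(areas$latitude_class %in% c("high", "low")))
    abort("latitude_class must be 'high' or 'low' for every area")
  A <- nrow(areas)
  if (A > 24) abort("at most 24 areas supported (bitmask encoding)")

  ob <- vapply(slices, function(s) s$older_bound, numeric(1))
  yb <- vapply(slices, function(s) s$younger_bound, numeric(1))
  if (any(ob <= yb)) abort("each slice needs older_bound > younger_bound")
  if (yb[length(yb)] != 0) abort("youngest slice must end at 0 Ma")
  if (length(slices) > 1 && any(abs(yb[-length(yb)] - ob[-1]) > 1e-9))
    abort("slices must tile time with no gaps or overlaps (oldest first)")
  for (s in slices) {
    adj <- s$adjacency
    if (!is.matrix(adj) || nrow(adj) != A || ncol(adj) != A)
      abort("each adjacency matrix must be A x A")
    if (!isTRUE(all(adj == Matrix::t(adj)))) abort("adjacency must be symmetric")
    if (!all(diag(adj) == 1)) abort("adjacency diagonal must be 1")
  }

  allowed <- lapply(slices, function(s)
    enumerate_allowed_ranges(s$adjacency, max_range_size))
  states <- sort(unique(unlist(allowed)))
  states <- states[order(range_size(states), states)]
  state_space <- c(0L, states)                 # null range first
  lookup <- integer(bitwShiftL(1L, A))         # mask + 1 -> state index
  lookup[state_space + 1L] <- seq_along(state_space)

  allowed_idx <- lapply(allowed, function(m) sort(lookup[m + 1L]))

  geo <- structure(list(
    areas = areas,
    slices = slices,
    max_range_size = as.integer(max_range_size),
    state_space = state_space,
    state_lookup = lookup,
    allowed_per_slice = allowed_idx,
    older_bounds = ob,
    younger_bounds = yb
  ), class = "geo_model")
  geo$clado <- .clado_table(geo)
  geo$rate_template <- lapply(seq_along(slices), function(k) .rate_template(geo, k))
  geo
}

#' @export
print.geo_model <- function(x, ...) {
  cat("Time-stratified geographic model\n")
  cat(sprintf("  %d areas: %s\n", nrow(x$areas), paste(x$areas$code, collapse = " ")))
  cat(sprintf("  %d time slices spanning %.1f-0 Ma\n",
              length(x$slices), x$older_bounds[1]))
  cat(sprintf("  max range size %d; %d range states (+ null)\n",
              x$max_range_size, length(x$state_space) - 1L))
  invisible(x)
}

#' Time slice containing a given time
#'
#' Slices are half-open `(older_bound, younger_bound]`: a time exactly on a
#' boundary belongs to the younger slice.
#'
#' @param time time in Ma (0 = present).
#' @param geo a `geo_model`.
#' @return 1-based slice index (oldest slice is 1).
#' @export
slice_at <- function(time, geo) {
  if (time < 0 || time > geo$older_bounds[1] + 1e-9)
    abort(sprintf("time %.3f Ma outside the slice tiling [0, %.1f]",
                  time, geo$older_bounds[1]))
  for (k in seq_along(geo$slices)) {
    if (time > geo$younger_bounds[k]) return(k)
  }
  length(geo$slices)
}

# segments of [age_young, age_old] intersected with the slice tiling,
# returned youngest-first as (slice, dt) pairs
.branch_segments <- function(age_young, age_old, geo) {
  if (age_old - age_young <= 0) return(list())
  cuts <- geo$younger_bounds[geo$younger_bounds > age_young + 1e-12 &
                             geo$younger_bounds < age_old - 1e-12]
  pts <- sort(unique(c(age_young, cuts, age_old)))
  lapply(seq_len(length(pts) - 1L), function(i) {
    mid <- (pts[i] + pts[i + 1L]) / 2
    list(slice = slice_at(mid, geo), dt = pts[i + 1L] - pts[i])
  })
}
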