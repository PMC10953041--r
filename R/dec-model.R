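# The DEC model: anagenetic dispersal (rate d per source-destination pair,
# gated by slice connectivity) and extirpation (rate e per occupied area), plus
# a cladogenetic range-inheritance distribution at nodes. The null range is an
# absorbing extinct state; the likelihood is not conditioned on survival
# (classic Lagrange/DECX behaviour).

#' Cladogenetic range-inheritance distribution
#'
#' For a single-area parent range the daughters both inherit it. For a wider
#' range the outcome is uniform over: subset sympatry (one daughter a single
#' occupied area, the other the full parent range; both orders) and vicariance
#' (an ordered split into two disjoint covering subsets, at least one a single
#' area).
#'
#' @param mask parent range bitmask (non-null).
#' @param n_areas number of areas (only needed for masks, any upper bound ok).
#' @return tibble with columns `left`, `right` (bitmasks) and `prob`.
#' @export
cladogenesis_events <- function(mask, n_areas = 24L) {
  if (mask == 0L) abort("null range has no cladogenetic outcomes")
  occ <- mask_areas(mask, n_areas)
  if (length(occ) == 1L) return(tibble(left = mask, right = mask, prob = 1))
  singles <- .bit(occ)
  left <- c(singles, rep(mask, length(occ)),      # subset sympatry
            singles, mask - singles)              # vicariance (ordered)
  right <- c(rep(mask, length(occ)), singles,
             mask - singles, singles)
  out <- unique(data.frame(left = left, right = right))
  tibble(left = out$left, right = out$right, prob = 1 / nrow(out))
}

# per-state cladogenesis triplets over the global state space, as two sparse
# matrices used by the pruning and ancestral passes:
#   Cmat %*% (uL[l] * uR[r])  combines daughter partials into a node partial
#   Lmat %*% (above[p] * prob * uSib[r]) accumulates corner weights by left state
.clado_table <- function(geo) {
  S1 <- length(geo$state_space)
  A <- nrow(geo$areas)
  ps <- ls <- rs <- integer(0)
  pr <- numeric(0)
  for (s in 2:S1) {
    cl <- cladogenesis_events(geo$state_space[s], A)
    li <- geo$state_lookup[cl$left + 1L]
    ri <- geo$state_lookup[cl$right + 1L]
    keep <- li > 0L & ri > 0L    # daughters outside the state space contribute 0
    ps <- c(ps, rep(s, sum(keep)))
    ls <- c(ls, li[keep]); rs <- c(rs, ri[keep]); pr <- c(pr, cl$prob[keep])
  }
  nt <- length(pr)
  list(
    pidx = ps, lidx = ls, ridx = rs, prob = pr,
    Cmat = sparseMatrix(i = ps, j = seq_len(nt), x = pr, dims = c(S1, nt)),
    Lmat = sparseMatrix(i = ls, j = seq_len(nt), x = 1, dims = c(S1, nt)))
}

# transition skeleton for one slice: triplets (i, j) with multipliers for d
# (number of adjacent source areas) and e (1 per loss). Built once per model.
.rate_template <- function(geo, slice_index) {
  S1 <- length(geo$state_space)
  masks <- geo$state_space
  adj <- geo$slices[[slice_index]]$adjacency
  A <- nrow(adj)
  allowed <- logical(S1)
  allowed[geo$allowed_per_slice[[slice_index]]] <- TRUE
  ti <- tj <- integer(0)
  dmult <- emult <- numeric(0)
  for (a in seq_len(A)) {
    b_adj <- setdiff(which(adj[, a] != 0), a)
    srcmask <- if (length(b_adj)) range_mask(b_adj) else 0L
    has_a <- bitwAnd(masks, .bit(a)) != 0L
    # dispersal gains into a
    src <- which(allowed & !has_a & masks > 0L)
    if (length(src) > 0 && srcmask > 0L) {
      tgt_mask <- bitwOr(masks[src], .bit(a))
      tgt <- geo$state_lookup[tgt_mask + 1L]
      nsrc <- range_size(bitwAnd(masks[src], srcmask))
      keep <- tgt > 0L & allowed[pmax(tgt, 1L)] & nsrc > 0L
      ti <- c(ti, src[keep]); tj <- c(tj, tgt[keep])
      dmult <- c(dmult, nsrc[keep]); emult <- c(emult, numeric(sum(keep)))
    }
    # extirpation losses of a
    src <- which(allowed & has_a)
    if (length(src) > 0) {
      tgt_mask <- bitwAnd(masks[src], bitwNot(.bit(a)))
      tgt <- geo$state_lookup[tgt_mask + 1L]
      tgt[tgt_mask == 0L] <- 1L               # null range slot
      keep <- tgt > 0L
      ti <- c(ti, src[keep]); tj <- c(tj, tgt[keep])
      dmult <- c(dmult, numeric(sum(keep))); emult <- c(emult, rep(1, sum(keep)))
    }
  }
  list(i = ti, j = tj, dmult = dmult, emult = emult, n = S1)
}

#' DEC anagenetic rate matrix for one time slice
#'
#' Sparse rate matrix over the global range state space (null range first).
#' Dispersal into area a proceeds at rate `d` times the number of occupied
#' areas adjacent to a in the slice's connectivity graph, and only into ranges
#' allowed in the slice; each occupied area is lost at rate `e`. Rows of
#' ranges not allowed in the slice are zero, as is the absorbing null row.
#'
#' @param geo a `geo_model`.
#' @param slice_index 1-based slice index.
#' @param d dispersal rate (per lineage per Myr per source-destination pair).
#' @param e extirpation rate (per occupied area per lineage per Myr).
#' @return a `dgCMatrix` with zero row sums.
#' @export
dec_rate_matrix <- function(geo, slice_index, d, e) {
  if (slice_index < 1 || slice_index > length(geo$slices))
    abort("slice_index out of bounds")
  if (d < 0 || e < 0) abort("rates must be non-negative")
  tpl <- geo$rate_template[[slice_index]]
  x <- d * tpl$dmult + e * tpl$emult
  rs <- numeric(tpl$n)
  if (length(x) > 0) {
    agg <- rowsum(x, tpl$i)
    rs[as.integer(rownames(agg))] <- agg[, 1]
  }
  sparseMatrix(i = c(tpl$i, seq_len(tpl$n)), j = c(tpl$j, seq_len(tpl$n)),
               x = c(x, -rs), dims = c(tpl$n, tpl$n))
}

#' Tip likelihood vector for a range observation
#'
#' Exact coding puts likelihood 1 on the observed range only. Ambiguous coding
#' (fossils: presence known, absence unknown) puts likelihood 1 on every range
#' containing the observed areas. The null state always has likelihood 0.
#'
#' @param mask observed range bitmask (non-null).
#' @param ambiguous logical; `TRUE` for presence-only (fossil) coding.
#' @param geo a `geo_model`.
#' @return numeric vector over the global state space.
#' @export
tip_likelihood <- function(mask, ambiguous, geo) {
  if (mask == 0L) abort("tip observation cannot be the null range")
  A <- nrow(geo$areas)
  if (bitwAnd(mask, bitwNot(bitwShiftL(1L, A) - 1L)) != 0L)
    abort("observed area outside the area list")
  v <- numeric(length(geo$state_space))
  if (ambiguous) {
    v[bitwAnd(geo$state_space, mask) == mask] <- 1
    v[1] <- 0
  } else {
    idx <- geo$state_lookup[mask + 1L]
    if (idx == 0L)
      abort(sprintf("observed range %d is not in the model state space", mask))
    v[idx] <- 1
  }
  v
}
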