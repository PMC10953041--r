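# Independent oracles: dense matrix exponentials (ape::matexpo), explicit
# subset loops, and exhaustive joint enumeration. These deliberately share no
# code path with the package internals (sparse uniformization, precomputed
# templates, vectorized cladogenesis tables).

# all nonempty subsets of 1..A occupied areas for a mask, via plain division
o_mask_areas <- function(mask, A) which(bitwAnd(mask, 2L^(0:(A - 1))) != 0L)

o_popcount <- function(mask) sum(as.integer(intToBits(mask)))

# connectivity check via igraph components (independent of the package BFS)
o_is_connected <- function(mask, adj) {
  occ <- o_mask_areas(mask, nrow(adj))
  if (length(occ) == 1) return(TRUE)
  g <- igraph::graph_from_adjacency_matrix(
    adj[occ, occ, drop = FALSE] - diag(1, length(occ)), mode = "undirected")
  igraph::components(g)$no == 1
}

# brute-force allowed-range enumeration: scan every mask
o_enumerate_ranges <- function(adj, max_size) {
  A <- nrow(adj)
  masks <- 1:(2^A - 1)
  keep <- vapply(masks, function(m)
    o_popcount(m) <= max_size && o_is_connected(m, adj), logical(1))
  sort(masks[keep])
}

# exhaustive cladogenetic outcome enumeration by scanning ordered mask pairs
o_clado_outcomes <- function(parent, A) {
  if (o_popcount(parent) == 1)
    return(data.frame(left = parent, right = parent))
  out <- list()
  for (l in 1:(2^A - 1)) for (r in 1:(2^A - 1)) {
    ss <- (l == parent && bitwAnd(r, parent) == r && r != parent &&
             o_popcount(r) == 1) ||
          (r == parent && bitwAnd(l, parent) == l && l != parent &&
             o_popcount(l) == 1)
    vic <- bitwAnd(l, r) == 0 && bitwOr(l, r) == parent &&
           (o_popcount(l) == 1 || o_popcount(r) == 1)
    if (ss || vic) out[[length(out) + 1]] <- c(l, r)
  }
  m <- do.call(rbind, out)
  data.frame(left = m[, 1], right = m[, 2])
}

# dense DEC rate matrix over a given state list (null first), plain loops
o_rate_matrix <- function(states, adj, allowed, d, e) {
  A <- nrow(adj)
  S <- length(states)
  Q <- matrix(0, S, S)
  for (i in seq_len(S)) {
    mi <- states[i]
    if (mi == 0 || !allowed[i]) next
    occ <- o_mask_areas(mi, A)
    for (j in seq_len(S)) {
      mj <- states[j]
      if (mj == 0) { if (o_popcount(mi) == 1) Q[i, j] <- e; next }
      gain <- bitwAnd(mj, bitwNot(mi)); loss <- bitwAnd(mi, bitwNot(mj))
      if (o_popcount(gain) == 1 && loss == 0 && allowed[j]) {
        a <- o_mask_areas(gain, A)
        Q[i, j] <- d * sum(adj[setdiff(occ, a), a])
      } else if (o_popcount(loss) == 1 && gain == 0) {
        Q[i, j] <- e
      }
    }
    Q[i, i] <- -sum(Q[i, ])
  }
  Q
}

# dense stratified DEC log-likelihood: recursion with ape::matexpo and
# explicit outcome loops. geo supplies areas/slices; obs is label->list.
o_dec_loglik <- function(tree, obs, geo, d, e, condition = "none") {
  A <- nrow(geo$areas)
  states <- geo$state_space
  S <- length(states)
  allowed <- lapply(seq_along(geo$slices), function(k) {
    al <- logical(S); al[geo$allowed_per_slice[[k]]] <- TRUE; al
  })
  Qs <- lapply(seq_along(geo$slices), function(k)
    o_rate_matrix(states, geo$slices[[k]]$adjacency, allowed[[k]], d, e))
  ta <- tree_ages(tree)
  ntip <- ape::Ntip(tree)

  o_segments <- function(young, old) {
    bounds <- sort(unique(c(young, old,
      geo$younger_bounds[geo$younger_bounds > young & geo$younger_bounds < old])))
    segs <- list()
    if (old - young <= 0) return(segs)
    for (i in seq_len(length(bounds) - 1)) {
      mid <- (bounds[i] + bounds[i + 1]) / 2
      k <- max(which(geo$older_bounds >= mid - 1e-12))
      for (kk in seq_along(geo$slices))
        if (mid > geo$younger_bounds[kk] && mid <= geo$older_bounds[kk] + 1e-9) k <- kk
      segs[[length(segs) + 1]] <- list(k = k, dt = bounds[i + 1] - bounds[i])
    }
    segs
  }

  below <- function(node) {
    if (node <= ntip) {
      row <- obs[obs$label == tree$tip.label[node], ]
      v <- numeric(S)
      for (s in 2:S) {
        if (isTRUE(row$ambiguous[1])) {
          if (bitwAnd(states[s], row$mask[1]) == row$mask[1]) v[s] <- 1
        } else if (states[s] == row$mask[1]) v[s] <- 1
      }
      return(v)
    }
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    u <- lapply(kids, function(ch) {
      v <- below(ch)
      Pbr <- diag(S)
      for (seg in o_segments(ta$ages[ch], ta$ages[node]))
        Pbr <- ape::matexpo(Qs[[seg$k]] * seg$dt) %*% Pbr
      v <- Pbr %*% v
      if (condition == "branch_survival") {
        surv <- 1 - Pbr[, 1]
        surv[1] <- 1
        v <- v / pmax(surv, 1e-300)
        v[1] <- 0
      }
      as.numeric(v)
    })
    v <- numeric(S)
    for (s in 2:S) {
      oc <- o_clado_outcomes(states[s], A)
      tot <- 0
      for (rr in seq_len(nrow(oc))) {
        li <- match(oc$left[rr], states); ri <- match(oc$right[rr], states)
        if (is.na(li) || is.na(ri)) next
        tot <- tot + u[[1]][li] * u[[2]][ri] / nrow(oc)
      }
      v[s] <- tot
    }
    v
  }
  vroot <- below(ntip + 1L)
  rk <- 1
  for (kk in seq_along(geo$slices))
    if (ta$root_age > geo$younger_bounds[kk] &&
        ta$root_age <= geo$older_bounds[kk] + 1e-9) rk <- kk
  log(sum(vroot[allowed[[rk]]]))
}

# exhaustive joint enumeration of marginal ancestral probabilities for a
# 3-tip tree ((t1,t2),t3); returns matrix [node x state] of marginals
o_marginals_3tip <- function(tree, obs, geo, d, e) {
  A <- nrow(geo$areas)
  states <- geo$state_space
  S <- length(states)
  ta <- tree_ages(tree)
  ntip <- 3
  root <- ntip + 1L
  inner <- setdiff(unique(tree$edge[, 1]), root)
  allowed <- lapply(seq_along(geo$slices), function(k) {
    al <- logical(S); al[geo$allowed_per_slice[[k]]] <- TRUE; al
  })
  Qs <- lapply(seq_along(geo$slices), function(k)
    o_rate_matrix(states, geo$slices[[k]]$adjacency, allowed[[k]], d, e))
  Pmat <- function(young, old) {
    P <- diag(S)
    bounds <- sort(unique(c(young, old,
      geo$younger_bounds[geo$younger_bounds > young & geo$younger_bounds < old])))
    if (old - young <= 0) return(P)
    for (i in seq_len(length(bounds) - 1)) {
      mid <- (bounds[i] + bounds[i + 1]) / 2
      k <- 1
      for (kk in seq_along(geo$slices))
        if (mid > geo$younger_bounds[kk] && mid <= geo$older_bounds[kk] + 1e-9) k <- kk
      P <- ape::matexpo(Qs[[k]] * (bounds[i + 1] - bounds[i])) %*% P
    }
    P
  }
  tipv <- lapply(1:3, function(i) {
    row <- obs[obs$label == tree$tip.label[i], ]
    v <- numeric(S)
    for (s in 2:S) {
      if (isTRUE(row$ambiguous[1])) {
        if (bitwAnd(states[s], row$mask[1]) == row$mask[1]) v[s] <- 1
      } else if (states[s] == row$mask[1]) v[s] <- 1
    }
    v
  })
  kids_root <- tree$edge[tree$edge[, 1] == root, 2]
  kids_in <- tree$edge[tree$edge[, 1] == inner, 2]
  stopifnot(inner %in% kids_root)
  tip_solo <- setdiff(kids_root, inner)
  P_r_in <- Pmat(ta$ages[inner], ta$ages[root])
  P_r_tip <- Pmat(ta$ages[tip_solo], ta$ages[root])
  P_in_k1 <- Pmat(ta$ages[kids_in[1]], ta$ages[inner])
  P_in_k2 <- Pmat(ta$ages[kids_in[2]], ta$ages[inner])

  slice_of <- function(t) {
    k <- 1
    for (kk in seq_along(geo$slices))
      if (t > geo$younger_bounds[kk] && t <= geo$older_bounds[kk] + 1e-9) k <- kk
    k
  }
  marg <- matrix(0, nrow = 5, ncol = S)
  for (sr in which(allowed[[slice_of(ta$ages[root])]])) {
    ocr <- o_clado_outcomes(states[sr], A)
    for (rr in seq_len(nrow(ocr))) {
      c_in <- match(ocr$left[rr], states); c_tip <- match(ocr$right[rr], states)
      if (is.na(c_in) || is.na(c_tip)) next
      w_tip <- sum(P_r_tip[c_tip, ] * tipv[[tip_solo]])
      for (si in 2:S) {
        w_in_path <- P_r_in[c_in, si]
        if (w_in_path == 0 && w_tip == 0) next
        oci <- o_clado_outcomes(states[si], A)
        for (ri in seq_len(nrow(oci))) {
          c1 <- match(oci$left[ri], states); c2 <- match(oci$right[ri], states)
          if (is.na(c1) || is.na(c2)) next
          w1 <- sum(P_in_k1[c1, ] * tipv[[kids_in[1]]])
          w2 <- sum(P_in_k2[c2, ] * tipv[[kids_in[2]]])
          w <- (1 / nrow(ocr)) * (1 / nrow(oci)) * w_tip * w_in_path * w1 * w2
          if (w == 0) next
          marg[root, sr] <- marg[root, sr] + w
          marg[inner, si] <- marg[inner, si] + w
        }
      }
    }
  }
  sweep(marg, 1, pmax(rowSums(marg), .Machine$double.xmin), "/")
}
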