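# Forward simulators providing ground truth for every inference stage:
# fossilized birth-death trees with fossil tips, DEC range histories along a
# dated tree (Gillespie with slice-dependent rates), and Brownian latitudes
# with a piecewise directional trend.

#' Simulate a fossilized birth-death tree
#'
#' Forward birth-death simulation from a single lineage at `origin` Ma, with
#' Poisson fossil sampling along lineages (rate `psi`); fossil samples become
#' zero-length terminal branches (sampled ancestors), keeping the tree binary.
#' Extant tips are retained with probability `rho`; the tree is pruned to the
#' sampled tips and re-simulated until at least `min_tips` survive.
#'
#' @param lambda,mu birth and death rates (/lineage/Myr).
#' @param psi fossil-sampling rate (/lineage/Myr).
#' @param rho extant sampling probability.
#' @param origin origin age (Ma).
#' @param min_tips minimum sampled tips (default 2).
#' @param max_lineages abort a replicate beyond this many lineages.
#' @param max_tries rejection budget.
#' @return a `phylo`; fossil tips are labelled `f*`, extant tips `t*`.
#' @export
simulate_fbd_tree <- function(lambda, mu = 0, psi = 0, rho = 1, origin,
                              min_tips = 2, max_lineages = 20000,
                              max_tries = 1000) {
  stopifnot(lambda > 0, mu >= 0, psi >= 0, rho > 0, rho <= 1, origin > 0)
  for (try in seq_len(max_tries)) {
    total <- lambda + mu + psi
    # lineage records built iteratively
    start <- origin; status <- NA_character_; endt <- NA_real_
    kid1 <- kid2 <- NA_integer_
    fossils <- list(numeric(0))
    stack <- 1L; nl <- 1L
    ok <- TRUE
    while (length(stack) > 0) {
      ln <- stack[1]; stack <- stack[-1]
      tcur <- start[ln]
      fs <- numeric(0)
      repeat {
        tcur <- tcur - rexp(1, total)
        if (tcur <= 0) { status[ln] <- "extant"; endt[ln] <- 0; break }
        u <- runif(1)
        if (u < lambda / total) {
          status[ln] <- "split"; endt[ln] <- tcur
          nl <- nl + 2L
          if (nl > max_lineages) { ok <- FALSE; break }
          start[nl - 1L] <- tcur; start[nl] <- tcur
          status[c(nl - 1L, nl)] <- NA; endt[c(nl - 1L, nl)] <- NA
          fossils[[nl - 1L]] <- numeric(0); fossils[[nl]] <- numeric(0)
          kid1[ln] <- nl - 1L; kid2[ln] <- nl
          stack <- c(stack, nl - 1L, nl)
          break
        } else if (u < (lambda + mu) / total) {
          status[ln] <- "extinct"; endt[ln] <- tcur; break
        } else {
          fs <- c(fs, tcur)
        }
      }
      fossils[[ln]] <- fs
      if (!ok) break
    }
    if (!ok) next

    sampled_extant <- which(status == "extant" & runif(length(status)) <= rho &
                            seq_along(status) <= nl)
    n_fos <- sum(lengths(fossils[seq_len(nl)]))
    if (length(sampled_extant) + n_fos < min_tips) next

    fi <- 0L; xi <- 0L; ei <- 0L
    build <- function(ln) {
      # core subtree below the lineage's end
      if (is.na(status[ln])) stop("incomplete lineage")
      if (status[ln] == "split") {
        core <- paste0("(", build(kid1[ln]), ",", build(kid2[ln]), ")")
      } else if (status[ln] == "extant") {
        if (ln %in% sampled_extant) { xi <<- xi + 1L; core <- paste0("t", xi) }
        else { ei <<- ei + 1L; core <- paste0("xx", ei) }
      } else {
        ei <<- ei + 1L; core <- paste0("xx", ei)
      }
      prev <- endt[ln]
      for (f in sort(fossils[[ln]])) {      # ascending age: innermost first
        fi <<- fi + 1L
        core <- paste0("(", core, ":", f - prev, ",f", fi, ":0)")
        prev <- f
      }
      paste0(core, ":", start[ln] - prev)
    }
    if (nl < 2 && n_fos == 0) next      # single unbranched lineage
    nwk <- paste0("(", build(1L), ");")
    tr <- ape::read.tree(text = nwk)
    tr <- ape::collapse.singles(tr)
    drop <- grep("^xx", tr$tip.label, value = TRUE)
    if (length(drop) >= ape::Ntip(tr) - 1) next
    if (length(drop) > 0) tr <- ape::drop.tip(tr, drop)
    if (is.null(tr) || ape::Ntip(tr) < min_tips) next
    return(tr)
  }
  abort("all replicates went extinct or undersampled within the retry budget")
}

#' Simulate a DEC range history along a dated tree
#'
#' Gillespie simulation with slice-dependent transition rates taken from the
#' same templates as the likelihood: the root range is drawn uniformly from
#' the ranges allowed in the root's slice, cladogenetic outcomes are drawn
#' from [cladogenesis_events()] at each node, and dispersal/extirpation events
#' occur along branches with rate changes applied at slice boundaries.
#' Lineages reaching the null range are extinct-in-place (topology unchanged;
#' their tips carry mask 0 and are excluded from observations).
#'
#' @param tree dated `phylo`.
#' @param geo a `geo_model`.
#' @param d,e dispersal and extirpation rates.
#' @param root_mask optional fixed root range (bitmask); default random.
#' @param condition_survival when `TRUE`, each branch trajectory is rejection-
#'   sampled against absorption into the null range (sampled lineages are, by
#'   construction, lineages whose ranges survived); default `FALSE` gives the
#'   unconditioned process.
#' @return list with `tip_ranges` (tibble label/mask), `node_masks` (range at
#'   each node), `corner_masks` (range at the parent-side corner of each
#'   branch, by child node), `events` (true event log) — class `dec_history`.
#' @export
simulate_dec_history <- function(tree, geo, d, e, root_mask = NULL,
                                 condition_survival = FALSE) {
  ta <- tree_ages(tree)
  ntip <- ape::Ntip(tree)
  S1 <- length(geo$state_space)
  # per-slice transition rows: list[slice][[state]] -> (targets, rates)
  rows <- lapply(seq_along(geo$slices), function(k) {
    tpl <- geo$rate_template[[k]]
    x <- d * tpl$dmult + e * tpl$emult
    split(data.frame(j = tpl$j, x = x), factor(tpl$i, levels = seq_len(S1)))
  })
  root_slice <- slice_at(ta$root_age, geo)
  if (is.null(root_mask)) {
    cand <- geo$allowed_per_slice[[root_slice]]
    root_idx <- cand[sample.int(length(cand), 1)]
  } else {
    root_idx <- geo$state_lookup[root_mask + 1L]
    if (root_idx == 0L) abort("root_mask not in the state space")
  }

  node_masks <- integer(ntip + tree$Nnode)
  corner_masks <- integer(ntip + tree$Nnode)   # by child node
  node_masks[ntip + 1L] <- geo$state_space[root_idx]
  events <- list()

  pre <- tree$edge[order(ta$ages[tree$edge[, 1]], decreasing = TRUE), , drop = FALSE]
  # cladogenetic draws done per node when first child edge encountered
  drawn <- logical(ntip + tree$Nnode)
  corner_for <- list()
  for (r in seq_len(nrow(pre))) {
    p <- pre[r, 1]; ch <- pre[r, 2]
    pm <- node_masks[p]
    if (!drawn[p]) {
      drawn[p] <- TRUE
      kids <- tree$edge[tree$edge[, 1] == p, 2]
      if (pm == 0L) {
        corner_for[[as.character(p)]] <- c(0L, 0L)
      } else {
        # draw among outcomes whose daughters are both inside the state space
        # (mirrors the likelihood, where out-of-space corners contribute zero)
        tab <- geo$clado
        sel <- which(tab$pidx == geo$state_lookup[pm + 1L])
        pick <- sel[sample.int(length(sel), 1, prob = tab$prob[sel])]
        lm <- geo$state_space[tab$lidx[pick]]
        rm <- geo$state_space[tab$ridx[pick]]
        corner_for[[as.character(p)]] <- c(lm, rm)
        events[[length(events) + 1L]] <- tibble(
          event_type = classify_cladogenetic_event(pm, lm, rm),
          branch = NA_integer_, node = p, area = NA_character_,
          time = ta$ages[p])
      }
      names(corner_for[[as.character(p)]]) <- as.character(kids)
    }
    start_mask <- corner_for[[as.character(p)]][[as.character(ch)]]
    corner_masks[ch] <- start_mask
    evolve_branch <- function() {
      cur <- start_mask
      tcur <- ta$ages[p]; tend <- ta$ages[ch]
      ev <- list()
      while (cur != 0L && tcur > tend + 1e-12) {
        k <- slice_at(tcur - 1e-9, geo)   # slice containing (tcur - eps)
        floor_t <- max(tend, geo$younger_bounds[k])
        idx <- geo$state_lookup[cur + 1L]
        rr <- rows[[k]][[idx]]
        tot <- sum(rr$x)
        if (tot <= 0) { tcur <- floor_t; if (tcur <= tend + 1e-12) break else next }
        wait <- rexp(1, tot)
        if (tcur - wait < floor_t) { tcur <- floor_t; if (tcur <= tend + 1e-12) break else next }
        tcur <- tcur - wait
        tgt <- rr$j[sample.int(nrow(rr), 1, prob = rr$x)]
        newm <- geo$state_space[tgt]
        gained <- bitwAnd(newm, bitwNot(cur))
        lost <- bitwAnd(cur, bitwNot(newm))
        ev[[length(ev) + 1L]] <- tibble(
          event_type = if (gained != 0L) "dispersal" else "extirpation",
          branch = ch, node = NA_integer_,
          area = geo$areas$code[mask_areas(if (gained != 0L) gained else lost,
                                           nrow(geo$areas))][1],
          time = tcur)
        cur <- newm
      }
      list(end = cur, events = ev)
    }
    res <- evolve_branch()
    if (condition_survival && start_mask != 0L) {
      tries <- 1L
      while (res$end == 0L && tries < 100L) {
        res <- evolve_branch()
        tries <- tries + 1L
      }
    }
    events <- c(events, res$events)
    node_masks[ch] <- res$end
  }
  tips <- tibble(label = tree$tip.label,
                 mask = node_masks[seq_len(ntip)],
                 age = ta$ages[seq_len(ntip)])
  structure(list(tip_ranges = tips, node_masks = node_masks,
                 corner_masks = corner_masks,
                 events = bind_rows(events), tree = tree, geo = geo),
            class = "dec_history")
}

#' Tip range observations from a simulated history
#'
#' Extinct-in-place tips (null range) are dropped; fossil tips are coded
#' ambiguously (presence-only) when `ambiguous_fossils = TRUE`.
#'
#' @param history a `dec_history`.
#' @param ambiguous_fossils logical.
#' @return tibble with `label`, `mask`, `ambiguous`.
#' @export
as_range_observations <- function(history, ambiguous_fossils = TRUE) {
  tr <- history$tip_ranges
  tr <- tr[tr$mask != 0L, ]
  tibble(label = tr$label, mask = tr$mask,
         ambiguous = ambiguous_fossils & tr$age > 0)
}

#' Simulate latitudes under Brownian motion with a piecewise trend
#'
#' @param tree dated `phylo`.
#' @param sigma2 BM rate (degrees^2/Myr).
#' @param mu drift per bin (degrees/Myr), youngest bin first.
#' @param bin_bounds interior bin boundaries (Ma).
#' @param root_value latitude at the root (degrees).
#' @return tibble with `node`, `label` (tips), `age`, `latitude`.
#' @export
simulate_latitudes <- function(tree, sigma2, mu, bin_bounds,
                               root_value = 0) {
  ta <- tree_ages(tree)
  bt <- .branch_table(tree, ta$ages)
  Texp <- .branch_bin_exposure(bt$age_child, bt$age_parent, bin_bounds)
  if (is.null(dim(Texp))) Texp <- matrix(Texp, nrow = 1)
  drift <- as.numeric(Texp %*% mu)
  t_br <- bt$age_parent - bt$age_child
  ntip <- ape::Ntip(tree)
  x <- numeric(ntip + tree$Nnode)
  x[ntip + 1L] <- root_value
  ord <- order(ta$ages[bt$parent], decreasing = TRUE)
  for (r in ord)
    x[bt$child[r]] <- x[bt$parent[r]] + drift[r] +
      rnorm(1, 0, sqrt(sigma2 * max(t_br[r], 0)))
  tibble(node = seq_along(x),
         label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
         age = ta$ages[seq_along(x)], latitude = x)
}

#' Generate a study-sized synthetic fixture
#'
#' Emulates the shape of the empirical cycad dataset: a tree of roughly 320
#' extant plus 60 fossil tips with a Carboniferous root, the 14-area/4-slice
#' geographic model, a Lagrange-style range file with presence-only ('?')
#' fossil coding and mostly single-area ranges, and a latitude table with a
#' poleward-then-equatorward trend. Files are written under `dir` when given.
#'
#' @param seed integer seed.
#' @param dir optional output directory for the files.
#' @param n_extant,n_fossil target tip counts (accepted within a band).
#' @param d,e DEC rates used for the simulated range history.
#' @return list with `tree`, `geo`, `observations`, `latitudes`, `history`,
#'   and (when `dir` given) `paths`.
#' @export
make_paper_like_fixture <- function(seed = 1, dir = NULL,
                                    n_extant = 321, n_fossil = 60,
                                    d = 0.0004, e = 0.0035) {
  set.seed(seed)
  geo <- default_cycad_geo()
  origin <- 330
  r <- log(n_extant) / origin
  lambda <- r + 0.02; mu <- 0.02
  psi <- 0.0026
  tr <- NULL
  for (try in 1:400) {
    cand <- try(simulate_fbd_tree(lambda, mu, psi, rho = 0.87, origin = origin,
                                  min_tips = 10, max_lineages = 60000),
                silent = TRUE)
    if (inherits(cand, "try-error")) next
    ages <- tree_ages(cand)
    nf <- sum(ages$is_fossil); nx <- ape::Ntip(cand) - nf
    if (nx >= n_extant * 0.75 && nx <= n_extant * 1.3 &&
        nf >= n_fossil * 0.75 && nf <= n_fossil * 1.3 &&
        ages$root_age >= 296 && ages$root_age <= 358.9) { tr <- cand; break }
  }
  if (is.null(tr)) abort("could not assemble a study-sized tree; adjust rates")

  hist <- simulate_dec_history(tr, geo, d = d, e = e,
                               condition_survival = TRUE)
  obs <- as_range_observations(hist, ambiguous_fossils = TRUE)
  keep <- hist$tip_ranges$mask != 0L
  tip_ranges <- hist$tip_ranges[keep, ]
  if (any(!keep)) {
    # node-indexed history fields go stale once tips are pruned; keep only the
    # label-keyed tip ranges and the event log
    tr <- ape::drop.tip(tr, hist$tip_ranges$label[!keep])
    hist <- list(tip_ranges = tip_ranges, events = hist$events)
  }

  bb <- c(23, 66, 201.3)
  lat <- simulate_latitudes(tr, sigma2 = 2,
                            mu = c(-0.25, 0, 0.12, 0.05),
                            bin_bounds = bb, root_value = 25)
  ages <- tree_ages(tr)
  lat_tips <- lat[!is.na(lat$label), c("label", "age", "latitude")]
  lat_tips$latitude <- pmax(pmin(lat_tips$latitude, 89), -89)

  out <- list(tree = tr, geo = geo, observations = obs,
              latitudes = lat_tips, history = hist)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(tree = file.path(dir, "tree.nwk"),
                  ranges = file.path(dir, "ranges.data"),
                  geo = file.path(dir, "geo.yaml"),
                  latitudes = file.path(dir, "latitudes.tsv"))
    ape::write.tree(tr, paths$tree)
    write_ranges(obs, geo, paths$ranges)
    write_geo_model(geo, paths$geo)
    write_latitudes(lat_tips, paths$latitudes)
    out$paths <- paths
  }
  out
}
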