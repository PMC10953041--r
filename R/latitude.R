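# Latitudinal evolution: Brownian motion with a piecewise-constant directional
# trend (drift mu_k per time bin, rate sigma2), latent internal-node states
# sampled by MCMC. Fossil paleolatitudes at non-zero tip ages are what makes
# the trend identifiable; extant-only data cannot separate trend from root
# state. Traits are rescaled (default /10) internally to help mixing; outputs
# are back on the degree scale.

# time spent by each branch in each trend bin; bins given as boundaries in Ma
.branch_bin_exposure <- function(age_child, age_parent, bin_bounds) {
  brks <- sort(unique(c(0, bin_bounds, Inf)))
  nb <- length(brks) - 1L
  vapply(seq_len(nb), function(k) {
    lo <- brks[k]; hi <- brks[k + 1L]
    pmax(pmin(age_parent, hi) - pmax(age_child, lo), 0)
  }, numeric(length(age_child)))
}

#' Log posterior density of the trended Brownian-motion model
#'
#' Sum over branches of Normal increment densities, child minus parent ~
#' N(sum_k mu_k t_k, sigma2 t), plus priors: half-Cauchy(1) on sigma2,
#' Normal(0, 10) on each mu_k, Normal(0, 50) on the root state (all on the
#' rescaled trait scale).
#'
#' @param tree dated `phylo`.
#' @param node_values numeric vector of trait values for every node (tips and
#'   internal), indexed like ape nodes, on the rescaled scale.
#' @param sigma2 BM rate (rescaled-trait units squared per Myr), > 0.
#' @param mu drift per bin (rescaled-trait units per Myr), one per bin.
#' @param bin_bounds interior bin boundaries in Ma (bins are
#'   `[0, b1], (b1, b2], ...` up to the root).
#' @param min_branch floor (Myr) applied to branch lengths so that zero-length
#'   sampled-ancestor attachments stay proper.
#' @return log posterior density (scalar).
#' @export
bm_trend_log_posterior <- function(tree, node_values, sigma2, mu, bin_bounds,
                                   min_branch = 1e-4) {
  if (sigma2 <= 0) abort("sigma2 must be positive")
  ta <- tree_ages(tree)
  bt <- .branch_table(tree, ta$ages)
  t_br <- pmax(bt$age_parent - bt$age_child, min_branch)
  if (any(bt$age_parent - bt$age_child < 0)) abort("non-positive branch length")
  Texp <- .branch_bin_exposure(bt$age_child, bt$age_parent, bin_bounds)
  if (is.null(dim(Texp))) Texp <- matrix(Texp, nrow = 1)
  if (length(mu) != ncol(Texp)) abort("length(mu) must equal number of bins")
  drift <- as.numeric(Texp %*% mu)
  incr <- node_values[bt$child] - node_values[bt$parent]
  root <- ape::Ntip(tree) + 1L
  sum(stats::dnorm(incr, drift, sqrt(sigma2 * t_br), log = TRUE)) +
    stats::dnorm(node_values[root], 0, 50, log = TRUE) +
    sum(stats::dnorm(mu, 0, 10, log = TRUE)) +
    (-log(1 + sigma2^2))
}

#' MCMC reconstruction of latitudinal evolution with a directional trend
#'
#' Metropolis-Hastings sampling of internal-node latitudes (sliding-window
#' updates), the BM rate (multiplicative proposals) and the per-bin trend
#' (additive proposals), run as one chain per supplied tree and pooled.
#'
#' @param trees a `phylo` or list of `phylo` (e.g. a posterior tree sample).
#' @param latitudes tibble with columns `label` and `latitude` (degrees); tips
#'   without data are pruned from each tree before sampling.
#' @param bin_bounds interior trend-bin boundaries in Ma; default the slice
#'   boundaries of [default_cycad_geo()] (23, 66, 201.3).
#' @param n_generations MCMC generations per tree (default 100000).
#' @param burnin_frac fraction discarded as burn-in (default 0.1).
#' @param thin keep every `thin`-th generation (default 100).
#' @param rescale trait rescaling factor (default 10: degrees are divided by
#'   10 internally; reported samples are back-transformed to degrees).
#' @param seed integer seed.
#' @return object of class `latitude_trend`: `samples` (tibble: tree, draw,
#'   sigma2 in degrees^2/Myr, mu_k in degrees/Myr), `node_states` (list of
#'   matrices, degrees), `trees` (pruned), `bin_bounds`, `acceptance`.
#' @export
run_latitude_mcmc <- function(trees, latitudes, bin_bounds = c(23, 66, 201.3),
                              n_generations = 100000, burnin_frac = 0.1,
                              thin = 100, rescale = 10, seed = 1) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 1) abort("need at least one tree")
  set.seed(seed)
  lat <- setNames(latitudes$latitude, latitudes$label)
  nbin <- length(sort(unique(c(0, bin_bounds, Inf)))) - 1L
  burnin <- max(1L, floor(n_generations * burnin_frac))

  samples <- list()
  node_states <- list()
  acc <- list()
  pruned <- list()
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]
    drop <- setdiff(tr$tip.label, names(lat))
    if (length(drop) > 0) tr <- ape::drop.tip(tr, drop)
    if (is.null(tr) || ape::Ntip(tr) < 2)
      abort("fewer than 2 tips with latitude data")
    ta <- tree_ages(tr)
    bt <- .branch_table(tr, ta$ages)
    t_br <- pmax(bt$age_parent - bt$age_child, 1e-4)
    Texp <- .branch_bin_exposure(bt$age_child, bt$age_parent, bin_bounds)
    if (is.null(dim(Texp))) Texp <- matrix(Texp, nrow = 1)
    ntip <- ape::Ntip(tr)
    nn <- ntip + tr$Nnode
    x0 <- numeric(nn)
    x0[seq_len(ntip)] <- lat[tr$tip.label] / rescale
    # initialize latents at the mean of descendant tips
    po <- ape::reorder.phylo(tr, "postorder")$edge
    cnt <- numeric(nn); sm <- numeric(nn)
    for (r in seq_len(nrow(po))) {
      p <- po[r, 1]; ch <- po[r, 2]
      v <- if (ch <= ntip) x0[ch] else sm[ch] / max(cnt[ch], 1)
      sm[p] <- sm[p] + v; cnt[p] <- cnt[p] + 1
    }
    x0[(ntip + 1):nn] <- sm[(ntip + 1):nn] / pmax(cnt[(ntip + 1):nn], 1)
    is_latent <- c(rep(0L, ntip), rep(1L, tr$Nnode))

    res <- bm_trend_mcmc(x0, is_latent, bt$child - 1L, bt$parent - 1L,
                         t_br, Texp, ntip, 0.5, rep(0, nbin),
                         as.integer(n_generations), as.integer(burnin),
                         as.integer(thin), 1.0, 0.02, 0.6)
    if (all(is.finite(res$accept)) && all(res$accept == 0))
      warn(sprintf("tree %d: zero acceptance across the chain", ti))
    n_keep <- length(res$sigma2)
    sm_tbl <- tibble(tree = ti, draw = seq_len(n_keep),
                     sigma2 = res$sigma2 * rescale^2)
    for (k in seq_len(nbin))
      sm_tbl[[paste0("mu_", k)]] <- res$mu[, k] * rescale
    samples[[ti]] <- sm_tbl
    node_states[[ti]] <- res$states * rescale
    acc[[ti]] <- res$accept
    pruned[[ti]] <- tr
  }
  structure(list(samples = bind_rows(samples), node_states = node_states,
                 trees = pruned, bin_bounds = bin_bounds, rescale = rescale,
                 acceptance = acc),
            class = "latitude_trend")
}

#' @export
print.latitude_trend <- function(x, ...) {
  cat(sprintf("Latitude trend MCMC: %d tree(s), %d pooled draws\n",
              length(x$trees), nrow(x$samples)))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.latitude_trend <- function(x, ...) {
  pars <- setdiff(names(x$samples), c("tree", "draw"))
  bind_rows(lapply(pars, function(pp) {
    v <- x$samples[[pp]]
    tibble(term = pp, estimate = mean(v),
           conf.low = unname(quantile(v, 0.025)),
           conf.high = unname(quantile(v, 0.975)))
  }))
}

#' @export
glance.latitude_trend <- function(x, ...) {
  tibble(n_trees = length(x$trees), n_draws = nrow(x$samples),
         accept_states = mean(vapply(x$acceptance, `[[`, numeric(1), "x")),
         accept_sigma2 = mean(vapply(x$acceptance, `[[`, numeric(1), "sigma2")),
         accept_mu = mean(vapply(x$acceptance, `[[`, numeric(1), "mu")))
}

#' Latitudinal span of the clade through time
#'
#' For each posterior draw and tree, lineage latitudes at a grid time are
#' linear interpolations between the sampled node states bracketing that time;
#' the envelope pools all lineages and draws and takes either quantiles
#' (default 2.5-97.5%) or the absolute min/max.
#'
#' @param fit a `latitude_trend`.
#' @param grid times (Ma) at which to evaluate; default 100 points from the
#'   oldest root to the present.
#' @param type `"quantile"` (default) or `"minmax"`.
#' @param probs quantiles used when `type = "quantile"`.
#' @return tibble with `time`, `lat_min`, `lat_max`; class `span_envelope`.
#' @export
span_through_time <- function(fit, grid = NULL, type = c("quantile", "minmax"),
                              probs = c(0.025, 0.975)) {
  type <- match.arg(type)
  roots <- vapply(fit$trees, function(tr) tree_ages(tr)$root_age, numeric(1))
  if (is.null(grid)) grid <- seq(max(roots), 0, length.out = 100)
  grid <- grid[grid <= max(roots) + 1e-9]
  vals_at <- vector("list", length(grid))
  for (ti in seq_along(fit$trees)) {
    tr <- fit$trees[[ti]]
    ta <- tree_ages(tr)
    bt <- .branch_table(tr, ta$ages)
    st <- fit$node_states[[ti]]           # draws x nodes, degrees
    for (gi in seq_along(grid)) {
      tt <- grid[gi]
      on_br <- which(bt$age_child <= tt + 1e-12 & bt$age_parent >= tt - 1e-12)
      if (length(on_br) == 0) next
      w <- ifelse(bt$age_parent[on_br] - bt$age_child[on_br] > 0,
                  (bt$age_parent[on_br] - tt) /
                    (bt$age_parent[on_br] - bt$age_child[on_br]), 1)
      # interpolate per branch: value = parent*(1-w) + child*w
      vp <- st[, bt$parent[on_br], drop = FALSE]
      vc <- st[, bt$child[on_br], drop = FALSE]
      v <- sweep(vp, 2, 1 - w, `*`) + sweep(vc, 2, w, `*`)
      vals_at[[gi]] <- c(vals_at[[gi]], as.numeric(v))
    }
  }
  lo <- hi <- rep(NA_real_, length(grid))
  for (gi in seq_along(grid)) {
    v <- vals_at[[gi]]
    if (is.null(v)) next
    if (type == "minmax") { lo[gi] <- min(v); hi[gi] <- max(v) }
    else { qs <- quantile(v, probs); lo[gi] <- qs[1]; hi[gi] <- qs[2] }
  }
  out <- tibble(time = grid, lat_min = lo, lat_max = hi)
  out <- out[!is.na(out$lat_min), ]
  class(out) <- c("span_envelope", class(out))
  out
}

#' @export
autoplot.span_envelope <- function(object, latitudes = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lat_min,
                                      ymax = .data$lat_max),
                         fill = "grey70") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Time (Ma)", y = "Latitude (degrees)",
                  title = "Reconstructed latitudinal span through time") +
    ggplot2::theme_minimal()
  if (!is.null(latitudes) && all(c("age", "latitude") %in% names(latitudes)))
    p <- p + ggplot2::geom_point(data = latitudes,
                                 ggplot2::aes(x = .data$age, y = .data$latitude))
  p
}
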