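# Felsenstein pruning over the time-stratified DEC process. Branches are cut
# into segments at slice boundaries; each segment's propagation exp(Q_s dt) v
# is computed by Poisson-truncated uniformization on the sparse rate matrix.
# Partial likelihoods are rescaled per node to avoid underflow.

.unif_prep <- function(Q) {
  n <- nrow(Q)
  lambda <- max(-Matrix::diag(Q), 0)
  if (lambda <= 0) return(list(lambda = 0, n = n))
  P <- Q / lambda + Matrix::Diagonal(n)
  P <- methods::as(P, "CsparseMatrix")
  list(lambda = lambda, n = n, p = P@p, i = P@i, x = P@x)
}

.propagate <- function(prep, v, dt) {
  if (prep$lambda <= 0 || dt <= 0) return(v)
  unif_expmv(prep$p, prep$i, prep$x, prep$n, prep$lambda, v, dt)
}

# one full pruning pass; returns node partials, per-edge propagated partials
# (at the parent-side corner), the log scaling constant, and bookkeeping.
# condition = "branch_survival" divides each branch kernel by the probability
# of not being absorbed into the null range along that branch (given the
# older-end state), the counterpart of rejection-sampled survivor lineages.
.dec_pruning <- function(tree, observations, geo, d, e, condition = "none") {
  ta <- tree_ages(tree)
  ages <- ta$ages
  if (ta$root_age > geo$older_bounds[1] + 1e-9)
    abort(sprintf("root age %.1f Ma exceeds the geographic model horizon %.1f Ma",
                  ta$root_age, geo$older_bounds[1]))
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  S1 <- length(geo$state_space)

  obs <- observations
  miss <- setdiff(tree$tip.label, obs$label)
  if (length(miss) > 0)
    abort(paste0("no range observation for tip(s): ",
                 paste(head(miss, 5), collapse = ", ")))
  tipvec <- lapply(tree$tip.label, function(lb) {
    row <- obs[obs$label == lb, ]
    tip_likelihood(row$mask[1], isTRUE(row$ambiguous[1]), geo)
  })

  preps <- lapply(seq_along(geo$slices), function(k)
    .unif_prep(dec_rate_matrix(geo, k, d, e)))

  edge <- tree$edge
  po <- ape::reorder.phylo(tree, "postorder")$edge
  # match rows of postorder edges back to original edge indices
  eid <- match(paste(po[, 1], po[, 2]), paste(edge[, 1], edge[, 2]))

  partial <- matrix(0, nrow = ntip + nnode, ncol = S1)
  u_edge <- matrix(0, nrow = nrow(edge), ncol = S1)
  seen_children <- vector("list", ntip + nnode)
  logscale <- 0

  surv_edge <- if (condition == "branch_survival")
    matrix(1, nrow = nrow(edge), ncol = S1) else NULL

  for (r in seq_len(nrow(po))) {
    p <- po[r, 1]; ch <- po[r, 2]
    v <- if (ch <= ntip) tipvec[[ch]] else partial[ch, ]
    segs <- .branch_segments(ages[ch], ages[p], geo)
    for (seg in segs) v <- .propagate(preps[[seg$slice]], v, seg$dt)
    if (!is.null(surv_edge)) {
      nullv <- c(1, numeric(S1 - 1L))          # indicator of the null range
      for (seg in segs) nullv <- .propagate(preps[[seg$slice]], nullv, seg$dt)
      surv <- pmax(1 - nullv, 1e-300)
      surv[1] <- 1
      v <- v / surv
      v[1] <- 0
      surv_edge[eid[r], ] <- surv
    }
    u_edge[eid[r], ] <- v
    seen_children[[p]] <- c(seen_children[[p]], eid[r])
    if (length(seen_children[[p]]) == 2L) {
      es <- seen_children[[p]]
      uL <- u_edge[es[1], ]; uR <- u_edge[es[2], ]
      cl <- geo$clado
      vn <- as.numeric(cl$Cmat %*% (uL[cl$lidx] * uR[cl$ridx]))
      s <- max(vn)
      if (!is.finite(s) || s <= 0)
        abort(sprintf("non-finite or zero partial likelihood at node %d", p))
      partial[p, ] <- vn / s
      logscale <- logscale + log(s)
    }
  }
  root <- ntip + 1L
  list(partial = partial, u_edge = u_edge, logscale = logscale,
       ages = ages, root = root, ntip = ntip, preps = preps,
       tipvec = tipvec, surv_edge = surv_edge,
       root_slice = slice_at(ta$root_age, geo))
}

#' Time-stratified DEC log-likelihood
#'
#' Felsenstein pruning from the tips to the root, with branch segments
#' propagated under each slice's rate matrix and daughter partial likelihoods
#' combined through the cladogenetic inheritance distribution at nodes. The
#' root sums the partial likelihood over all ranges allowed in the root's
#' slice with equal (unit) weight, the Lagrange convention.
#'
#' @param tree binary dated `phylo`; fossil tips may end above 0 Ma.
#' @param observations tibble with columns `label`, `mask`, `ambiguous`
#'   (see [read_ranges()] / [range_mask()]).
#' @param geo a `geo_model`.
#' @param d,e dispersal and extirpation rates.
#' @param condition `"none"` (classic DEC: the null range is absorbing and
#'   the likelihood includes the probability that observed lineages escaped
#'   it) or `"branch_survival"` (each branch kernel is conditioned on not
#'   being absorbed, matching data that consist of surviving lineages only).
#' @return the log-likelihood (scalar).
#' @export
dec_loglik <- function(tree, observations, geo, d, e,
                       condition = c("none", "branch_survival")) {
  condition <- match.arg(condition)
  pr <- .dec_pruning(tree, observations, geo, d, e, condition)
  rootv <- pr$partial[pr$root, ]
  L <- sum(rootv[geo$allowed_per_slice[[pr$root_slice]]])
  if (!is.finite(L) || L <= 0)
    abort("non-finite likelihood at the root (all root states excluded?)")
  log(L) + pr$logscale
}

#' Maximum-likelihood fit of the DEC dispersal and extirpation rates
#'
#' Bounded derivative-free optimization (Nelder-Mead on the log rates, with
#' the box enforced by a penalty wall) of [dec_loglik()] from several
#' starting points. The log parameterization keeps the search well scaled
#' across orders of magnitude.
#'
#' @inheritParams dec_loglik
#' @param starts list of named numeric vectors `c(d = , e = )` used as starts
#'   (defaults span two orders of magnitude).
#' @param lower,upper box bounds on the rates (per Myr).
#' @param control passed to [stats::optim()].
#' @return an object of class `dec_fit` with elements `d`, `e`, `lnL`,
#'   `convergence` (per-start report) and the inputs needed downstream.
#' @export
fit_dec <- function(tree, observations, geo,
                    starts = list(c(d = 0.01, e = 0.01),
                                  c(d = 0.001, e = 0.005)),
                    lower = 1e-8, upper = 10,
                    control = list(maxit = 200, reltol = 1e-8),
                    condition = c("none", "branch_survival")) {
  condition <- match.arg(condition)
  lb <- log(lower); ub <- log(upper)
  nll <- function(logpar) {
    if (any(logpar < lb) || any(logpar > ub))
      return(1e10 + sum(pmax(lb - logpar, 0) + pmax(logpar - ub, 0)))
    val <- tryCatch(
      -dec_loglik(tree, observations, geo, exp(logpar[1]), exp(logpar[2]),
                  condition = condition),
      error = function(err) Inf)
    if (!is.finite(val)) 1e10 else val
  }
  reports <- lapply(starts, function(st) {
    opt <- tryCatch(
      optim(log(st), nll, method = "Nelder-Mead", control = control),
      error = function(err) NULL)
    if (is.null(opt)) return(NULL)
    par <- pmin(pmax(opt$par, lb), ub)
    tibble(d_start = st[["d"]], e_start = st[["e"]],
           d = exp(par[1]), e = exp(par[2]),
           lnL = -opt$value, convergence = opt$convergence)
  })
  reports <- bind_rows(reports)
  if (nrow(reports) == 0) abort("optimizer failed from every start")
  best <- reports[which.max(reports$lnL), ]
  structure(list(
    d = best$d, e = best$e, lnL = best$lnL,
    convergence = reports,
    n_tips = ape::Ntip(tree), n_states = length(geo$state_space) - 1L,
    geo = geo), class = "dec_fit")
}

#' @export
print.dec_fit <- function(x, ...) {
  cat("DEC fit (time-stratified)\n")
  cat(sprintf("  d = %.5g per Myr, e = %.5g per Myr, lnL = %.4f\n",
              x$d, x$e, x$lnL))
  cat(sprintf("  %d tips, %d range states, %d optimizer starts\n",
              x$n_tips, x$n_states, nrow(x$convergence)))
  invisible(x)
}

#' @export
tidy.dec_fit <- function(x, ...) {
  tibble(term = c("d", "e"), estimate = c(x$d, x$e),
         description = c("dispersal rate (per source-destination pair per Myr)",
                         "extirpation rate (per occupied area per Myr)"))
}

#' @export
glance.dec_fit <- function(x, ...) {
  tibble(logLik = x$lnL, n_tips = x$n_tips, n_states = x$n_states,
         converged = any(x$convergence$convergence == 0))
}

#' Marginal ancestral-range estimates
#'
#' Combines below-node partial likelihoods with above-node likelihoods (a
#' re-rooting pass through the cladogenetic distribution) to obtain, for each
#' internal node, the relative probability of every range, ranked. Ranges not
#' allowed in the node's slice get probability 0. The "equally likely" flag
#' marks ranges whose log marginal likelihood is within 2 units of the best.
#'
#' @inheritParams dec_loglik
#' @param d,e rates, typically the MLE from [fit_dec()].
#' @param top_k ranges reported per node (the equally-likely set is always
#'   kept in full).
#' @return tibble with columns `node`, `age`, `rank`, `range`, `mask`,
#'   `rel_prob`, `equally_likely`; class `ancestral_ranges`.
#' @export
ancestral_ranges <- function(tree, observations, geo, d, e, top_k = 10,
                             condition = c("none", "branch_survival")) {
  condition <- match.arg(condition)
  pr <- .dec_pruning(tree, observations, geo, d, e, condition)
  ntip <- pr$ntip
  S1 <- length(geo$state_space)
  edge <- tree$edge
  cl <- geo$clado

  tpreps <- lapply(seq_along(geo$slices), function(k)
    .unif_prep(Matrix::t(dec_rate_matrix(geo, k, d, e))))

  above <- matrix(0, nrow = ntip + tree$Nnode, ncol = S1)
  rootw <- numeric(S1)
  rootw[geo$allowed_per_slice[[pr$root_slice]]] <- 1
  above[pr$root, ] <- rootw

  pre <- edge[order(pr$ages[edge[, 1]], decreasing = TRUE), , drop = FALSE]
  for (r in seq_len(nrow(pre))) {
    p <- pre[r, 1]; ch <- pre[r, 2]
    sib_edges <- which(edge[, 1] == p & edge[, 2] != ch)
    u_sib <- pr$u_edge[sib_edges[1], ]
    ab <- above[p, ]
    a_corner <- as.numeric(cl$Lmat %*% (ab[cl$pidx] * cl$prob * u_sib[cl$ridx]))
    if (!is.null(pr$surv_edge)) {
      # conditioned kernel: divide by the branch survival of the older-end state
      a_corner <- a_corner / pr$surv_edge[which(edge[, 1] == p & edge[, 2] == ch), ]
      a_corner[1] <- 0
    }
    segs <- rev(.branch_segments(pr$ages[ch], pr$ages[p], geo))  # oldest first
    for (seg in segs) a_corner <- .propagate(tpreps[[seg$slice]], a_corner, seg$dt)
    s <- max(a_corner)
    above[ch, ] <- if (s > 0) a_corner / s else a_corner
  }

  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  out <- lapply(nodes, function(nd) {
    marg <- above[nd, ] * pr$partial[nd, ]
    k <- slice_at(pr$ages[nd], geo)
    keep <- logical(S1)
    keep[geo$allowed_per_slice[[k]]] <- TRUE
    marg[!keep] <- 0
    tot <- sum(marg)
    if (tot <= 0) return(NULL)
    rel <- marg / tot
    ord <- order(rel, -range_size(geo$state_space), -geo$state_space,
                 decreasing = TRUE)
    ord <- ord[rel[ord] > 0]
    lbest <- log(rel[ord[1]])
    eq <- (lbest - log(rel[ord])) < 2
    take <- max(min(top_k, length(ord)), sum(eq))
    idx <- ord[seq_len(take)]
    tibble(node = nd, age = pr$ages[nd], slice = k,
           rank = seq_len(take), mask = geo$state_space[idx],
           range = format_range(geo$state_space[idx], geo),
           rel_prob = rel[idx], equally_likely = eq[seq_len(take)])
  })
  res <- bind_rows(out)
  attr(res, "geo") <- geo
  attr(res, "params") <- c(d = d, e = e)
  class(res) <- c("ancestral_ranges", class(res))
  res
}
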