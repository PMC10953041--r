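# Small in-code fixtures shared across tests.

geo_complete <- function(A = 2, horizon = 100, max_range_size = A,
                         high = character(0)) {
  codes <- LETTERS[seq_len(A)]
  geo_model(
    areas = data.frame(code = codes,
                       latitude_class = ifelse(codes %in% high, "high", "low")),
    slices = list(list(older_bound = horizon, younger_bound = 0,
                       adjacency = matrix(1, A, A))),
    max_range_size = max_range_size)
}

geo_chain3 <- function(horizon = 100, max_range_size = 3) {
  adj <- diag(1, 3); adj[1, 2] <- adj[2, 1] <- 1; adj[2, 3] <- adj[3, 2] <- 1
  geo_model(
    areas = data.frame(code = c("A", "B", "C"),
                       latitude_class = c("low", "low", "low")),
    slices = list(list(older_bound = horizon, younger_bound = 0,
                       adjacency = adj)),
    max_range_size = max_range_size)
}

# multi-slice 2/3-area models; `adjs` is a list of adjacency matrices,
# oldest first, slicing the horizon evenly
geo_sliced <- function(adjs, horizon = 100, max_range_size = NULL) {
  A <- nrow(adjs[[1]])
  n <- length(adjs)
  bounds <- seq(horizon, 0, length.out = n + 1)
  geo_model(
    areas = data.frame(code = LETTERS[seq_len(A)],
                       latitude_class = rep("low", A)),
    slices = lapply(seq_len(n), function(k)
      list(older_bound = bounds[k], younger_bound = bounds[k + 1],
           adjacency = adjs[[k]])),
    max_range_size = max_range_size %||% A)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

obs_tbl <- function(labels, masks, ambiguous = FALSE) {
  tibble::tibble(label = labels, mask = as.integer(masks),
                 ambiguous = rep_len(ambiguous, length(labels)))
}

tree2 <- function(b1 = 1, b2 = 1) {
  ape::read.tree(text = sprintf("(t1:%g,t2:%g);", b1, b2))
}
tree3 <- function() ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")
tree4 <- function() ape::read.tree(text = "((t1:1,t2:1):1,(t3:1.5,t4:1.5):0.5);")
# fossil tip f1 ends above the present
tree3_fossil <- function() ape::read.tree(text = "((t1:2,f1:1.2):1,t3:3);")
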