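# Shared fixtures built in code: small phantoms and independent oracles.

# Small circumpapillary phantom stack with truth attached.
small_cp_stack <- function(ascans = 256L, bscans = 1L, seed = 1L,
                           speckle = TRUE, noise_sd = 0.05,
                           offsets = c(0L, 0L, 0L),
                           layers = default_retina_layers(), ...) {
  pat <- scan_pattern("circumpapillary", ascans_per_bscan = ascans,
                      bscans = bscans)
  truth <- phantom_truth(pat, channel_depth_offsets = offsets, ...)
  list(pattern = pat, truth = truth,
       stack = render_multichannel(truth, pattern = pat, layers = layers,
                                   seed = seed, speckle = speckle,
                                   noise_sd = noise_sd))
}

# Exhaustive enumeration oracle for the boundary shortest path
# (feasible for small grids only).
enumerate_min_path_cost <- function(cost, jump_limit) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- Inf
  recurse <- function(col, row, acc) {
    acc <- acc + cost[row, col]
    if (acc >= best) return()
    if (col == nc) { best <<- acc; return() }
    for (r in max(1L, row - jump_limit):min(nr, row + jump_limit))
      recurse(col + 1L, r, acc)
  }
  for (r0 in seq_len(nr)) recurse(1L, r0, 0)
  best
}

# Exact independent shortest-path oracle on the boundary DAG (igraph).
igraph_min_path_cost <- function(cost, jump_limit) {
  nr <- nrow(cost); nc <- ncol(cost)
  id <- function(r, c) (c - 1L) * nr + r
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (j in seq_len(nc)[-1]) for (o in -jump_limit:jump_limit) {
    r <- seq_len(nr); pr <- r - o
    ok <- pr >= 1L & pr <= nr
    from <- c(from, id(pr[ok], j - 1L)); to <- c(to, id(r[ok], j))
    w <- c(w, cost[cbind(r[ok], j)])
  }
  S <- nr * nc + 1L; E2 <- nr * nc + 2L
  from <- c(from, rep(S, nr), id(seq_len(nr), nc))
  to <- c(to, id(seq_len(nr), 1L), rep(E2, nr))
  w <- c(w, cost[, 1], rep(0, nr))
  g <- igraph::graph_from_edgelist(cbind(from, to))
  igraph::E(g)$weight <- w
  igraph::distances(g, v = S, to = E2, mode = "out")[1, 1]
}
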