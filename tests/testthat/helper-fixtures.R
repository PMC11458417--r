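# Shared fixture builders and independent oracles for the test suite.

# a timeseries4d from a voxels-x-T matrix laid over a small grid
h_vol <- function(values, shape, voxel_size = 1) {
  geom <- grid_geometry(shape, voxel_size)
  nt <- ncol(values)
  stopifnot(nrow(values) == prod(shape))
  timeseries4d(array(values, c(shape, nt)), geom)
}

# mask from 0-based ijk rows
h_mask <- function(ijk, shape, role = "roi", name = "m", voxel_size = 1) {
  volume_mask(matrix(as.integer(ijk), ncol = 3), grid_geometry(shape, voxel_size),
              role = role, name = name)
}

# all set partitions of n elements as membership vectors (restricted growth)
h_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (g in seq_len(maxid + 1)) rec(c(prefix, g), max(maxid, g))
  }
  rec(integer(0), 0L)
  out
}

# independent two-level map-equation codelength: explicit entropy form,
# degree-proportional visit rates, no teleportation, log base 2
h_codelength <- function(adj, memb) {
  adj <- (adj != 0) * 1
  m2 <- sum(adj)
  if (m2 == 0) return(0)
  H <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  p <- rowSums(adj) / m2
  mods <- sort(unique(memb))
  q <- vapply(mods, function(c) sum(adj[memb == c, memb != c, drop = FALSE]) / m2,
              numeric(1))
  pm <- vapply(mods, function(c) sum(p[memb == c]), numeric(1))
  index_term <- if (sum(q) > 0) sum(q) * H(q / sum(q)) else 0
  module_terms <- vapply(seq_along(mods), function(mi) {
    tot <- pm[mi] + q[mi]
    if (tot == 0) return(0)
    tot * H(c(q[mi], p[memb == mods[mi]]) / tot)
  }, numeric(1))
  index_term + sum(module_terms)
}

# adjacency matrix of k disjoint cliques of size s (optionally bridged in a ring)
h_cliques <- function(k, s, ring = FALSE) {
  n <- k * s
  adj <- matrix(FALSE, n, n)
  for (c in seq_len(k)) {
    idx <- ((c - 1) * s + 1):(c * s)
    adj[idx, idx] <- TRUE
  }
  if (ring && k > 1) {
    for (c in seq_len(k)) {
      a <- (c - 1) * s + 1
      b <- (c %% k) * s + s      # last node of next clique
      adj[a, b] <- adj[b, a] <- TRUE
    }
  }
  diag(adj) <- FALSE
  adj
}

h_graph <- function(adj, p = 0.9) {
  structure(list(adjacency = adj | t(adj), p = p, n_nodes = nrow(adj),
                 roi_voxel_order = NULL), class = "binary_graph")
}

# small planted-network config for fast pipeline tests:
# grid 14x14x12, ROI 9x5x2 = 90 voxels, 3 networks of 30
h_small_config <- function(n_participants = 8, n_timepoints = 60,
                           n_vessel = 0, ...) {
  synth_config(n_participants = n_participants, n_timepoints = n_timepoints,
               k_networks = 3, grid_shape = c(14, 14, 12),
               roi_slab = list(i = c(2, 10), j = c(2, 6), k = c(4, 5)),
               n_vessel = n_vessel, ...)
}

# binarize threshold placed in the quantile gap below the within-network tie
# block: for a similarity matrix whose top f-fraction of pairs are exact ties
# at 1 (the noiseless limit), a p in ((B-1)/(N-1), B/(N-1)) with B the number
# of between-network pairs interpolates the cutoff strictly between the two
# blocks, so exactly the within-network pairs become edges
h_gap_threshold <- function(n_nodes, within_pairs) {
  N <- n_nodes * (n_nodes - 1) / 2
  B <- N - within_pairs
  (B - 0.5) / (N - 1)
}

# deterministic "stable threshold" reading of an agreement curve: the modal
# prototype count over the grid, then the threshold attaining it with the
# highest coverage (ties: lowest threshold) -- the documented user procedure
# of picking a threshold where count and coverage are stable
h_stable_threshold <- function(curve) {
  counts <- curve$n_prototypes
  modal <- as.integer(names(sort(table(counts), decreasing = TRUE))[1])
  cand <- curve[counts == modal, , drop = FALSE]
  cand$threshold[order(-cand$coverage, cand$threshold)][1]
}

# shared cache for expensive fixtures (filled lazily by acceptance tests)
h_cache <- new.env(parent = emptyenv())
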