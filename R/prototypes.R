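#' Two-level map-equation community detection
#'
#' Clusters a binary graph with the InfoMap algorithm (map equation), taking
#' the best two-level partition over \code{n_trials} seeded restarts. The
#' engine is \code{igraph::cluster_infomap}, which performs the best-of-trials
#' search internally; the reported codelength is recomputed with this
#' package's own evaluator (\code{\link{map_equation_codelength}}). Isolated
#' nodes become singleton communities.
#'
#' @param graph a non-empty \code{binary_graph}.
#' @param n_trials number of InfoMap search restarts (default 100).
#' @param seed optional integer seed; given the seed the result is
#'   deterministic and the caller's RNG stream is left untouched.
#' @return An object of class \code{prototype_partition}: list with
#'   \code{membership} (integer vector, community ids contiguous from 1,
#'   numbered by decreasing community size), \code{codelength} (bits),
#'   \code{n_communities}, \code{n_trials}.
#' @export
detect_communities <- function(graph, n_trials = 100, seed = NULL) {
  adj <- graph$adjacency
  if (is.null(adj) || nrow(adj) == 0) stop("empty graph")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- with_seed(seed, {
    if (igraph::ecount(g) == 0) {
      seq_len(nrow(adj))           # all isolated: singletons
    } else {
      as.integer(igraph::membership(
        igraph::cluster_infomap(g, nb.trials = n_trials)))
    }
  })
  # contiguous ids 1..K, ordered by decreasing size (ties: smallest member)
  sizes <- tabulate(memb)
  first <- vapply(seq_along(sizes), function(c) match(c, memb), integer(1))
  relab <- integer(length(sizes))
  relab[order(-sizes, first)] <- seq_along(sizes)
  memb <- relab[memb]
  structure(list(membership = memb,
                 codelength = map_equation_codelength(adj, memb),
                 n_communities = max(memb),
                 n_trials = as.integer(n_trials)),
            class = "prototype_partition")
}

#' @export
print.prototype_partition <- function(x, ...) {
  cat(sprintf("prototype_partition: %d nodes in %d communities (codelength %.4f bits)\n",
              length(x$membership), x$n_communities, x$codelength))
  invisible(x)
}

#' Two-level map-equation codelength
#'
#' Evaluates the map equation for a hard partition of an undirected,
#' unweighted graph: the expected per-step description length (in bits) of a
#' random walk encoded with one index codebook over modules and one codebook
#' per module. Node visit rates are degree-proportional
#' (\eqn{p_i = k_i / 2m}) and module exit rates are cut-proportional
#' (\eqn{q_m = cut_m / 2m}); no teleportation. Lower is better; InfoMap
#' minimises this quantity.
#'
#' @param adjacency symmetric logical/0-1 matrix, empty diagonal.
#' @param membership integer community id per node.
#' @return Codelength in bits (0 for an edgeless graph).
#' @export
map_equation_codelength <- function(adjacency, membership) {
  adj <- (unclass(adjacency) != 0) * 1
  stopifnot(nrow(adj) == length(membership))
  m2 <- sum(adj)                    # 2m
  if (m2 == 0) return(0)
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  p <- rowSums(adj) / m2            # node visit rates
  mods <- sort(unique(membership))
  p_mod <- vapply(mods, function(c) sum(p[membership == c]), numeric(1))
  # exit rate: edges with exactly one endpoint in the module
  q_mod <- vapply(mods, function(c) {
    inside <- membership == c
    sum(adj[inside, !inside, drop = FALSE]) / m2
  }, numeric(1))
  q <- sum(q_mod)
  # canonical four-term expansion; the exit term appears in both the index
  # codebook and its module's codebook, hence the factor 2
  plogp(q) - 2 * sum(plogp(q_mod)) - sum(plogp(p)) + sum(plogp(q_mod + p_mod))
}

#' Dice coefficient of two voxel sets
#'
#' \eqn{2|X \cap Y| / (|X| + |Y|)}: the overlap score used to decide whether
#' a network prototype found in one split-half replicates in the other.
#'
#' @param x,y vectors of voxel identifiers (duplicates ignored); not both
#'   empty.
#' @return Scalar in [0, 1].
#' @export
dice <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (length(x) == 0 && length(y) == 0) stop("Dice undefined for two empty sets")
  2 * sum(x %in% y) / (length(x) + length(y))
}

#' Replication criteria for prototypes
#'
#' The three thresholds governing which community distinctions survive:
#' a cross-half pair must overlap with Dice > \code{dice_min} and intersect in
#' at least \code{min_intersection_frac} of the ROI size, and a voxel pair
#' must co-occur in replicated prototypes in at least \code{consensus_min} of
#' the split iterations.
#'
#' @param dice_min minimum Dice overlap (strict; default 0.5).
#' @param min_intersection_frac minimum intersection volume as a fraction of
#'   ROI size (default 0.02).
#' @param consensus_min minimum proportion of iterations for the consensus
#'   rule (default 0.5).
#' @return An object of class \code{match_criteria}.
#' @export
match_criteria <- function(dice_min = 0.5, min_intersection_frac = 0.02,
                           consensus_min = 0.5) {
  stopifnot(dice_min > 0, dice_min <= 1,
            min_intersection_frac > 0, min_intersection_frac <= 1,
            consensus_min > 0, consensus_min <= 1)
  structure(list(dice_min = dice_min,
                 min_intersection_frac = min_intersection_frac,
                 consensus_min = consensus_min),
            class = "match_criteria")
}

partition_sets <- function(part) {
  split(seq_along(part$membership), part$membership)
}

#' Match prototypes across the two split-halves
#'
#' Pairs up communities from the two halves greedily in descending Dice order
#' (one-to-one; ties broken by community ids). A pair is retained iff its
#' Dice exceeds \code{crit$dice_min} and its intersection covers at least
#' \code{crit$min_intersection_frac} of the ROI. The replicated voxel set of
#' a retained pair is the intersection \eqn{X \cap Y} (the conservative
#' choice; set \code{use_union = TRUE} for the union).
#'
#' @param part_a,part_b \code{prototype_partition}s over the same node set.
#' @param roi_size voxel count of the ROI mask (the 2\% floor references the
#'   full mask, not the graph's node count).
#' @param crit a \code{\link{match_criteria}}.
#' @param use_union take the union instead of the intersection as the
#'   replicated set (default \code{FALSE}).
#' @return List of retained matches, each a list \code{a}, \code{b}
#'   (community ids), \code{dice}, \code{voxels} (node indices).
#' @export
match_prototypes <- function(part_a, part_b, roi_size, crit = match_criteria(),
                             use_union = FALSE) {
  stopifnot(length(part_a$membership) == length(part_b$membership))
  sa <- partition_sets(part_a)
  sb <- partition_sets(part_b)
  pairs <- expand.grid(a = seq_along(sa), b = seq_along(sb))
  pairs$inter <- mapply(function(a, b) sum(sa[[a]] %in% sb[[b]]),
                        pairs$a, pairs$b)
  pairs$dice <- 2 * pairs$inter /
    (lengths(sa)[pairs$a] + lengths(sb)[pairs$b])
  pairs <- pairs[order(-pairs$dice, pairs$a, pairs$b), , drop = FALSE]
  floor_n <- crit$min_intersection_frac * roi_size
  used_a <- logical(length(sa)); used_b <- logical(length(sb))
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$a[r]; b <- pairs$b[r]
    if (used_a[a] || used_b[b]) next
    if (pairs$dice[r] <= crit$dice_min) break   # sorted: nothing below qualifies
    if (pairs$inter[r] < floor_n) next
    used_a[a] <- TRUE; used_b[b] <- TRUE
    vox <- if (use_union) sort(union(sa[[a]], sb[[b]])) else
      sort(intersect(sa[[a]], sb[[b]]))
    out[[length(out) + 1]] <- list(a = a, b = b, dice = pairs$dice[r],
                                   voxels = vox)
  }
  out
}

#' Accumulate the agreement matrix
#'
#' Counts, for every voxel pair, the proportion of split iterations in which
#' the two voxels sat in the same replicated prototype: a pair replicated in
#' 8 of 10 iterations gets 0.8. The diagonal holds each voxel's own
#' replication proportion (how often it appeared in any replicated set); it
#' is excluded from component extraction and serves per-voxel stability
#' reporting.
#'
#' @param replicated_sets_by_iteration list over iterations; each element a
#'   list of pairwise-disjoint integer vectors (node indices) -- the
#'   replicated voxel sets of that iteration (as produced by
#'   \code{\link{match_prototypes}}).
#' @param n_iterations total number of iterations (the denominator).
#' @param n_voxels number of ROI voxels (matrix dimension).
#' @return An object of class \code{agreement_matrix}: symmetric numeric
#'   matrix in [0, 1] whose entries are exact multiples of
#'   \code{1/n_iterations}, with attribute \code{n_iterations}.
#' @export
accumulate_agreement <- function(replicated_sets_by_iteration, n_iterations,
                                 n_voxels) {
  acc <- matrix(0L, n_voxels, n_voxels)
  for (sets in replicated_sets_by_iteration) {
    if (length(sets) == 0) next
    all_v <- unlist(sets)
    if (anyDuplicated(all_v)) stop("replicated sets within an iteration must be disjoint")
    z <- matrix(0L, n_voxels, length(sets))
    for (s in seq_along(sets)) z[sets[[s]], s] <- 1L
    acc <- acc + tcrossprod(z)     # 0/1 co-membership; diag = own membership
  }
  structure(acc / n_iterations, n_iterations = as.integer(n_iterations),
            class = c("agreement_matrix", "matrix", "array"))
}

#' Consensus prototypes from an agreement matrix
#'
#' Binarizes the agreement matrix at the consensus threshold (>=
#' \code{crit$consensus_min} of iterations, diagonal excluded), extracts the
#' connected components of the resulting co-membership graph, and discards
#' components below the minimum-volume floor
#' (\code{crit$min_intersection_frac} of the ROI). At this point prototype
#' identity across iterations is gone -- the components are generic network
#' prototypes, labeled 1..K by decreasing size (ties by smallest member
#' index).
#'
#' @param agree an \code{agreement_matrix}.
#' @param crit a \code{\link{match_criteria}}.
#' @param roi_size voxel count of the ROI mask.
#' @return An object of class \code{prototype_set}: list with
#'   \code{prototypes} (list of sorted integer vectors), \code{coverage}
#'   (fraction of \code{roi_size} covered), \code{roi_size}.
#' @export
consensus_prototypes <- function(agree, crit = match_criteria(), roi_size) {
  b <- unclass(agree) >= crit$consensus_min
  diag(b) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(b, mode = "undirected")
  comp <- igraph::components(g)
  floor_n <- crit$min_intersection_frac * roi_size
  keep <- which(comp$csize >= floor_n & comp$csize >= 2)
  protos <- lapply(keep, function(c) sort(which(comp$membership == c)))
  ord <- order(-lengths(protos), vapply(protos, function(p) p[1] %||% 0L, numeric(1)))
  protos <- protos[ord]
  prototype_set(protos, roi_size)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

prototype_set <- function(prototypes, roi_size) {
  structure(list(prototypes = prototypes,
                 coverage = sum(lengths(prototypes)) / roi_size,
                 roi_size = as.integer(roi_size)),
            class = "prototype_set")
}

#' @export
print.prototype_set <- function(x, ...) {
  cat(sprintf("prototype_set: %d prototypes covering %.1f%% of %d ROI voxels\n",
              length(x$prototypes), 100 * x$coverage, x$roi_size))
  if (length(x$prototypes)) {
    cat("  sizes:", paste(lengths(x$prototypes), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build an agreement curve across thresholds
#'
#' Summarises, per graph threshold, the consensus coverage (fraction of ROI
#' voxels assigned to any retained prototype) and the number of prototypes,
#' together with +-1 SD of the per-iteration replicated-set coverage and
#' count across the split iterations. Users read these curves to pick the
#' threshold where both coverage and prototype count are stable.
#'
#' @param per_threshold named list (names = threshold proportions); each
#'   element a list with \code{consensus} (a \code{prototype_set}) and
#'   \code{replicated_sets} (list over iterations of lists of voxel sets).
#' @param roi_size voxel count of the ROI mask.
#' @return A data frame of class \code{agreement_curve} with columns
#'   \code{threshold}, \code{coverage}, \code{coverage_sd},
#'   \code{n_prototypes}, \code{n_prototypes_sd}.
#' @export
agreement_curve <- function(per_threshold, roi_size) {
  stopifnot(length(per_threshold) >= 1)
  rows <- lapply(names(per_threshold), function(th) {
    x <- per_threshold[[th]]
    cov_it <- vapply(x$replicated_sets,
                     function(sets) length(unique(unlist(sets))) / roi_size,
                     numeric(1))
    cnt_it <- vapply(x$replicated_sets, length, numeric(1))
    data.frame(threshold = as.numeric(th),
               coverage = x$consensus$coverage,
               coverage_sd = stats::sd(cov_it),
               n_prototypes = length(x$consensus$prototypes),
               n_prototypes_sd = stats::sd(cnt_it))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$threshold), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("agreement_curve", "data.frame")
  out
}

#' @export
plot.agreement_curve <- function(x, main = "Split-half agreement", ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$threshold, x$coverage, type = "b", pch = 16,
                 ylim = c(0, 1), xlab = "threshold (proportion)",
                 ylab = "coverage", main = main, ...)
  graphics::arrows(x$threshold, pmax(0, x$coverage - x$coverage_sd),
                   x$threshold, pmin(1, x$coverage + x$coverage_sd),
                   angle = 90, code = 3, length = 0.03)
  graphics::plot(x$threshold, x$n_prototypes, type = "b", pch = 16,
                 xlab = "threshold (proportion)", ylab = "prototypes retained",
                 main = "", ...)
  graphics::arrows(x$threshold, x$n_prototypes - x$n_prototypes_sd,
                   x$threshold, x$n_prototypes + x$n_prototypes_sd,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Render a prototype set onto the brain volume
#'
#' Writes an integer-labeled NIfTI volume in the (downsampled) analysis grid
#' (0 = unlabeled) plus a paired 1D text file with voxel coordinates and
#' labels, so the user can inspect prototypes before committing to a
#' threshold.
#'
#' @param protos a \code{prototype_set} whose indices refer to the canonical
#'   order of \code{mask}'s members.
#' @param mask the ROI \code{volume_mask} the prototypes live in.
#' @param path output NIfTI path (.nii or .nii.gz); the 1D sidecar replaces
#'   the extension with \code{.1D}.
#' @return The label volume as a 3D integer array, invisibly.
#' @export
prototypes_to_volume <- function(protos, mask, path) {
  n <- mask_size(mask)
  lab <- integer(n)
  for (s in seq_along(protos$prototypes)) {
    vox <- protos$prototypes[[s]]
    if (any(vox < 1 | vox > n)) stop("prototype voxel outside the mask")
    lab[vox] <- s
  }
  arr <- array(0L, mask$geometry$shape)
  arr[mask_linear_index(mask)] <- lab
  write_nifti_array(arr, mask$geometry, path, datatype = "int16")
  ijk <- mask_members(mask)
  side <- sub("\\.nii(\\.gz)?$", ".1D", path)
  writeLines(c("# splitparc prototype labels (i j k label, 0-based)",
               paste(ijk[, 1], ijk[, 2], ijk[, 3], lab)), side)
  invisible(arr)
}
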