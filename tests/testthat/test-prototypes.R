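test_that("detect_communities recovers planted graph structure", {
  two <- detect_communities(h_graph(h_cliques(2, 5)), n_trials = 10, seed = 1)
  expect_equal(two$n_communities, 2)
  expect_equal(two$membership[1:5], rep(two$membership[1], 5))
  expect_equal(two$membership[6:10], rep(two$membership[6], 5))

  one <- detect_communities(h_graph(h_cliques(1, 6)), n_trials = 5, seed = 1)
  expect_equal(one$n_communities, 1)

  ring <- detect_communities(h_graph(h_cliques(4, 5, ring = TRUE)),
                             n_trials = 20, seed = 2)
  expect_equal(ring$n_communities, 4)
  for (c in 1:4) {
    idx <- ((c - 1) * 5 + 1):(c * 5)
    expect_length(unique(ring$membership[idx]), 1)
  }

  # determinism given seed; caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  a <- detect_communities(h_graph(h_cliques(3, 4)), n_trials = 7, seed = 5)
  set.seed(99)
  b <- detect_communities(h_graph(h_cliques(3, 4)), n_trials = 7, seed = 5)
  expect_identical(a, b)
  expect_equal({ set.seed(99); runif(1) }, before)

  # isolated nodes become singleton communities
  adj <- h_cliques(2, 3)
  adj <- rbind(cbind(adj, FALSE), FALSE)
  iso <- detect_communities(h_graph(adj), n_trials = 5, seed = 1)
  expect_equal(sum(iso$membership == iso$membership[7]), 1)

  expect_error(detect_communities(h_graph(matrix(FALSE, 0, 0))), "empty")
})

test_that("map-equation codelength matches the closed form for disjoint cliques", {
  # two disjoint 5-cliques: q = 0, each module carries half the visit rate,
  # within-module entropy log2(5)
  adj <- h_cliques(2, 5)
  memb <- rep(1:2, each = 5)
  expect_equal(map_equation_codelength(adj, memb), log2(5))
  # the all-in-one partition costs the full node entropy
  expect_equal(map_equation_codelength(adj, rep(1, 10)), log2(10))
  # evaluator agrees with the independent entropy-form oracle
  expect_equal(map_equation_codelength(adj, memb), h_codelength(adj, memb))
  expect_equal(map_equation_codelength(adj, c(1, 1, 1, 2, 2, 3, 3, 3, 4, 4)),
               h_codelength(adj, c(1, 1, 1, 2, 2, 3, 3, 3, 4, 4)))
})

test_that("winning partition is map-equation optimal on small graphs", {
  graphs <- list(
    h_cliques(2, 4),
    h_cliques(2, 3, ring = TRUE),
    h_cliques(2, 4, ring = TRUE),
    { set.seed(17); a <- matrix(runif(64) < 0.45, 8, 8); a & upper.tri(a) }
  )
  for (adj in graphs) {
    adj <- adj | t(adj); diag(adj) <- FALSE
    if (sum(adj) == 0) next
    parts <- h_partitions(nrow(adj))
    det <- detect_communities(h_graph(adj), n_trials = 50, seed = 3)
    best <- min(vapply(parts, function(p) h_codelength(adj, p), numeric(1)))
    won <- h_codelength(adj, det$membership)
    expect_lte(won, best + 1e-9)
    expect_equal(det$codelength, won)   # package evaluator == oracle evaluator
  }
})

test_that("dice measures set overlap", {
  expect_equal(dice(1:5, 1:5), 1)
  expect_equal(dice(1:3, 4:6), 0)
  expect_equal(dice(c("a", "b", "c"), c("b", "c", "d")), 2 * 2 / 6)
  expect_equal(dice(integer(0), 1:3), 0)
  expect_error(dice(integer(0), integer(0)), "empty")
})

test_that("match_prototypes applies Dice and volume criteria greedily", {
  part <- function(m) structure(list(membership = m), class = "prototype_partition")

  # identical partitions: every community self-matched at Dice 1
  pa <- part(rep(1:3, times = c(10, 6, 4)))
  m <- match_prototypes(pa, pa, roi_size = 20, crit = match_criteria())
  expect_length(m, 3)
  expect_true(all(vapply(m, `[[`, numeric(1), "dice") == 1))
  expect_setequal(unlist(lapply(m, `[[`, "voxels")), 1:20)

  # no pair above Dice 0.5
  pb <- part(rep(c(1, 2), times = 10))   # interleaved vs blocked
  m2 <- match_prototypes(part(rep(1:2, each = 10)), pb, roi_size = 20)
  expect_true(all(vapply(m2, `[[`, numeric(1), "dice") > 0.5))

  disjointish <- part(c(rep(1, 10), rep(2, 10)))
  quarters <- part(rep(1:4, each = 5))
  m3 <- match_prototypes(disjointish, quarters, roi_size = 20,
                         crit = match_criteria(dice_min = 0.99))
  expect_length(m3, 0)

  # worked pairing: A = {1..10},{11..20}; B = {1..8,11,12},{9,10,13..20}
  a <- part(rep(1:2, each = 10))
  b <- part(c(rep(1, 8), rep(2, 2), rep(1, 2), rep(2, 8)))
  m4 <- match_prototypes(a, b, roi_size = 20)
  expect_length(m4, 2)
  expect_equal(vapply(m4, `[[`, numeric(1), "dice"), c(0.8, 0.8))
  expect_identical(m4[[1]]$voxels, 1:8)
  expect_identical(m4[[2]]$voxels, 13:20)

  # the 2% volume floor removes small intersections
  m5 <- match_prototypes(a, b, roi_size = 20,
                         crit = match_criteria(min_intersection_frac = 0.45))
  expect_length(m5, 0)
})

test_that("accumulate_agreement counts co-replication proportions", {
  # a pair together in exactly 8 of 10 iterations -> cell 0.8
  sets <- c(replicate(8, list(list(c(1L, 2L), c(3L, 4L)))),
            replicate(2, list(list(c(1L, 3L)))))
  ag <- accumulate_agreement(sets, 10, 4)
  expect_identical(ag[1, 2], 0.8)
  expect_identical(ag[2, 1], 0.8)
  expect_identical(ag[3, 4], 0.8)
  expect_identical(ag[1, 3], 0.2)
  expect_identical(ag[2, 3], 0)
  expect_identical(ag[1, 1], 1)      # voxel 1 replicated in all 10
  expect_identical(ag[4, 4], 0.8)
  expect_true(all(abs(ag * 10 - round(ag * 10)) < 1e-12))
  expect_identical(unclass(ag), t(unclass(ag)))

  expect_error(accumulate_agreement(list(list(c(1L, 2L), c(2L, 3L))), 1, 3),
               "disjoint")
})

test_that("consensus_prototypes extracts floor-filtered components", {
  crit <- match_criteria()
  # identity-like agreement: nothing reaches consensus
  ag <- structure(diag(10), n_iterations = 10L,
                  class = c("agreement_matrix", "matrix", "array"))
  empty <- consensus_prototypes(ag, crit, roi_size = 10)
  expect_length(empty$prototypes, 0)
  expect_equal(empty$coverage, 0)

  # two full-agreement blocks
  b <- matrix(0, 10, 10)
  b[1:6, 1:6] <- 1; b[7:10, 7:10] <- 1
  agb <- structure(b, n_iterations = 10L,
                   class = c("agreement_matrix", "matrix", "array"))
  two <- consensus_prototypes(agb, crit, roi_size = 10)
  expect_length(two$prototypes, 2)
  expect_identical(two$prototypes[[1]], 1:6)   # labeled by decreasing size
  expect_identical(two$prototypes[[2]], 7:10)
  expect_equal(two$coverage, 1)

  # third block below the volume floor is discarded, its voxels uncovered
  b3 <- matrix(0, 20, 20)
  b3[1:9, 1:9] <- 1; b3[10:17, 10:17] <- 1; b3[18:20, 18:20] <- 0.6
  ag3 <- structure(b3, n_iterations = 10L,
                   class = c("agreement_matrix", "matrix", "array"))
  got <- consensus_prototypes(ag3, match_criteria(min_intersection_frac = 0.2),
                              roi_size = 20)
  expect_length(got$prototypes, 2)
  expect_false(any(18:20 %in% unlist(got$prototypes)))

  # sub-consensus agreement does not join components
  weak <- matrix(0.4, 6, 6); weak[1:3, 1:3] <- 1; weak[4:6, 4:6] <- 1
  agw <- structure(weak, n_iterations = 10L,
                   class = c("agreement_matrix", "matrix", "array"))
  gw <- consensus_prototypes(agw, match_criteria(min_intersection_frac = 0.1),
                             roi_size = 6)
  expect_length(gw$prototypes, 2)
})

test_that("consensus prototypes are invariant to voxel permutation", {
  set.seed(6)
  b <- matrix(0, 12, 12)
  b[1:5, 1:5] <- 1; b[6:12, 6:12] <- 1
  perm <- sample(12)
  agp <- structure(b[perm, perm], n_iterations = 10L,
                   class = c("agreement_matrix", "matrix", "array"))
  got <- consensus_prototypes(agp, match_criteria(), roi_size = 12)
  sets <- lapply(got$prototypes, function(v) sort(perm[v]))
  expect_setequal(lapply(sets, paste, collapse = ","),
                  list("1,2,3,4,5", "6,7,8,9,10,11,12"))
})

test_that("agreement_curve summarises coverage and counts per threshold", {
  protos2 <- splitparc:::prototype_set(list(1:6, 7:10), 10)
  reps <- replicate(4, list(list(1:6, 7:10)))
  curve <- agreement_curve(list(`0.9` = list(consensus = protos2,
                                             replicated_sets = reps)),
                           roi_size = 10)
  expect_equal(curve$coverage, 1)
  expect_equal(curve$n_prototypes, 2)
  expect_equal(curve$coverage_sd, 0)
  expect_true(all(curve$coverage <= 1))
})

test_that("prototype volumes round-trip through NIfTI", {
  shape <- c(6, 5, 4)
  arr <- array(FALSE, shape); arr[2:5, 2:4, 2:3] <- TRUE
  mask <- volume_mask(arr, grid_geometry(shape, 3), role = "roi", name = "roi")
  n <- mask_size(mask)
  protos <- splitparc:::prototype_set(list(1:8, 15:24), n)
  path <- tempfile(fileext = ".nii.gz")
  vol <- prototypes_to_volume(protos, mask, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("\\.nii\\.gz$", ".1D", path)))

  back <- read_volume(path)
  lab <- as.vector(back$data[, , , 1])[splitparc:::mask_linear_index(mask)]
  expect_identical(which(lab == 1L), 1:8)
  expect_identical(which(lab == 2L), 15:24)
  expect_equal(sum(back$data != 0), 18)

  empty <- splitparc:::prototype_set(list(), n)
  p2 <- tempfile(fileext = ".nii.gz")
  expect_true(all(prototypes_to_volume(empty, mask, p2) == 0))

  bad <- splitparc:::prototype_set(list(c(1L, n + 5L)), n)
  expect_error(prototypes_to_volume(bad, mask, tempfile(fileext = ".nii")),
               "outside")
})
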