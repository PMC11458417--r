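test_that("make_split_plan produces valid, reproducible equal bipartitions", {
  ids <- sprintf("s%d", 1:4)
  plan <- make_split_plan(ids, n_iterations = 1, seed = 3)
  h <- plan$halves[[1]]
  expect_length(h[[1]], 2)
  expect_length(h[[2]], 2)
  expect_setequal(c(h[[1]], h[[2]]), ids)
  expect_length(intersect(h[[1]], h[[2]]), 0)

  expect_identical(make_split_plan(ids, 5, seed = 42),
                   make_split_plan(ids, 5, seed = 42))

  plan6 <- make_split_plan(sprintf("s%d", 1:6), 10, seed = 8)
  for (it in 1:10) {
    h <- plan6$halves[[it]]
    expect_setequal(c(h[[1]], h[[2]]), sprintf("s%d", 1:6))
    expect_length(h[[1]], 3)
  }
  keys <- vapply(plan6$halves, function(h)
    paste(sort(vapply(list(h[[1]], h[[2]]), function(g)
      paste(sort(g), collapse = ","), character(1))), collapse = "|"),
    character(1))
  expect_gt(length(unique(keys)), 1)   # not all identical, w.h.p.

  expect_error(make_split_plan(sprintf("s%d", 1:5), 1), "even")
  expect_error(make_split_plan(c("a", "a", "b", "c"), 1), "unique")
})

h_tsm <- function(m, pid = "p1", mask = "m") {
  splitparc:::ts_matrix(m, matrix(0L, nrow(m), 3), mask, pid,
                        grid_geometry(c(1, 1, 1)))
}

test_that("roi_context_correlation computes voxelwise Pearson r", {
  x <- c(1, 2, 3, 4)
  roi <- h_tsm(rbind(x, -x, c(1, 2, 3, 4)))
  ctx <- h_tsm(rbind(x, c(1, 2, 4, 3)))
  r <- roi_context_correlation(roi, ctx)
  expect_equal(r[1, 1], 1)
  expect_equal(r[2, 1], -1)
  expect_equal(r[3, 2], cor(c(1, 2, 3, 4), c(1, 2, 4, 3)))
  expect_equal(r[3, 2], 0.8)

  const <- h_tsm(rbind(c(2, 2, 2, 2)))
  rc <- roi_context_correlation(const, ctx)
  expect_true(all(is.na(rc)))

  expect_error(roi_context_correlation(roi, h_tsm(matrix(1:6, 2, 3))),
               "timepoint")
  expect_error(
    roi_context_correlation(h_tsm(rbind(x), pid = "a"), h_tsm(rbind(x), pid = "b")),
    "participants")
})

h_conn <- function(m) splitparc:::connectivity_matrix(m, NULL, NULL)

test_that("group_average combines correlations by Fisher-z or raw mean", {
  m <- h_conn(matrix(c(0.3, -0.6, 0.1, 0.9), 2, 2))
  expect_equal(unclass(group_average(list(m), "fisher_z")), unclass(m),
               ignore_attr = TRUE)
  expect_equal(unclass(group_average(list(m), "raw")), unclass(m),
               ignore_attr = TRUE)

  mneg <- h_conn(-unclass(m))
  expect_equal(unclass(group_average(list(m, mneg), "fisher_z")),
               matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(unclass(group_average(list(m, mneg), "raw")), matrix(0, 2, 2),
               ignore_attr = TRUE)

  a <- h_conn(matrix(0.5)); b <- h_conn(matrix(0.9))
  expect_equal(group_average(list(a, b), "fisher_z")[1, 1],
               tanh((atanh(0.5) + atanh(0.9)) / 2))
  expect_equal(group_average(list(a, b), "raw")[1, 1], 0.7)

  # undefined entries excluded pairwise
  withna <- h_conn(matrix(c(NA, 0.2), 1, 2))
  other <- h_conn(matrix(c(0.4, 0.4), 1, 2))
  avg <- group_average(list(withna, other), "raw")
  expect_equal(unclass(avg), matrix(c(0.4, 0.3), 1, 2), ignore_attr = TRUE)

  expect_error(group_average(list()), "empty")
})

test_that("raw group average of identical matrices is exact", {
  set.seed(21)
  m <- h_conn(matrix(runif(12, -1, 1), 3, 4))
  avg <- group_average(list(m, m, m), "raw")
  expect_identical(as.vector(avg), as.vector(unclass(m)))
})

test_that("similarity_matrix matches brute-force pairwise Pearson", {
  set.seed(5)
  v <- matrix(rnorm(12), 3, 4)
  v[2, ] <- v[1, ] + 2              # identical pattern up to offset -> r = 1
  s <- similarity_matrix(h_conn(v))
  expect_equal(s[1, 2], 1)
  expect_equal(unname(diag(s)), rep(1, 3))
  expect_equal(s, t(s), ignore_attr = TRUE)
  for (a in 1:3) for (b in 1:3) {
    if (a != b) expect_equal(s[a, b], cor(v[a, ], v[b, ]))
  }

  vc <- rbind(v, 5)                 # constant pattern row
  sc <- similarity_matrix(h_conn(vc))
  expect_true(all(is.na(sc[4, ])))
  expect_identical(attr(sc, "undefined"), 4L)
  dropped <- drop_undefined(sc)
  expect_equal(dim(dropped), c(3, 3))
  expect_identical(attr(dropped, "dropped"), 4L)

  expect_error(similarity_matrix(h_conn(matrix(1, 2, 1))), "context")
})

test_that("binarize_top keeps the top fraction of pairs", {
  # 4 nodes, 6 distinct upper-triangle values, p = 0.5 -> exactly top 3 edges
  s <- matrix(0, 4, 4)
  vals <- c(0.1, 0.9, 0.3, 0.8, 0.2, 0.7)
  s[upper.tri(s)] <- vals
  s <- s + t(s); diag(s) <- 1
  g <- binarize_top(structure(s, class = c("similarity_matrix", "matrix", "array")), 0.5)
  expect_equal(sum(g$adjacency) / 2, 3)
  ut <- which(upper.tri(s), arr.ind = TRUE)
  top3 <- ut[order(-vals)[1:3], ]
  expect_true(all(g$adjacency[top3]))

  expect_true(isSymmetric(g$adjacency))
  expect_true(all(!diag(g$adjacency)))

  flat <- matrix(0.5, 3, 3); diag(flat) <- 1
  expect_warning(
    ge <- binarize_top(structure(flat, class = c("similarity_matrix", "matrix", "array")), 0.5),
    "empty")
  expect_equal(sum(ge$adjacency), 0)
})

test_that("edge count is monotone non-increasing in the threshold", {
  set.seed(31)
  n <- 20
  s <- matrix(rnorm(n * n), n, n); s <- (s + t(s)) / 2; diag(s) <- 1
  s <- structure(s, class = c("similarity_matrix", "matrix", "array"))
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 0.95),
                   function(p) sum(binarize_top(s, p)$adjacency) / 2, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pajek export round-trips edge sets", {
  tri <- h_graph(h_cliques(1, 3))
  p1 <- tempfile(fileext = ".net")
  export_pajek(tri, p1)
  lines <- readLines(p1)
  expect_equal(lines[1], "*Vertices 3")
  expect_length(grep("^\\d+ \\d+$", lines[grep("\\*Edges", lines):length(lines)]), 3)
  expect_identical(read_pajek(p1)$adjacency, tri$adjacency)

  empty <- h_graph(matrix(FALSE, 4, 4))
  p2 <- tempfile(fileext = ".net")
  export_pajek(empty, p2)
  expect_identical(read_pajek(p2)$adjacency, empty$adjacency)

  set.seed(8)
  adj <- matrix(runif(400) < 0.2, 20, 20)
  g <- h_graph(adj & upper.tri(adj))
  p3 <- tempfile(fileext = ".net")
  export_pajek(g, p3)
  expect_identical(read_pajek(p3)$adjacency, g$adjacency)
})

test_that("group averaging is invariant to participant order", {
  set.seed(19)
  mats <- lapply(1:4, function(i) h_conn(matrix(runif(20, -0.9, 0.9), 4, 5)))
  for (method in c("fisher_z", "raw")) {
    s1 <- similarity_matrix(group_average(mats, method))
    s2 <- similarity_matrix(group_average(mats[c(3, 1, 4, 2)], method))
    expect_equal(unclass(s1), unclass(s2), ignore_attr = TRUE)
  }
})

test_that("identical participants give identical half similarity matrices", {
  set.seed(14)
  base <- matrix(rnorm(5 * 30), 5, 30)
  pairsame <- lapply(1:4, function(p) list(
    roi = h_tsm(base[1:2, , drop = FALSE], pid = sprintf("p%d", p)),
    context = h_tsm(base, pid = sprintf("p%d", p))))
  fit <- splitparc(pairsame, thresholds = 0.5, n_iterations = 2, n_trials = 5,
                   seed = 2)
  # all halves identical -> every pair replicates every iteration
  ag <- fit$agreement[[1]]
  expect_true(all(ag == 1 | ag == 0))
})
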