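#' Random equal split-half plan
#'
#' Each iteration splits the cohort uniformly at random into two disjoint
#' groups of equal size. Repeated random splits (10 by default, a good
#' trade-off between detecting stability and computation time) drive the
#' replication test: only network distinctions found independently in both
#' halves count.
#'
#' @param participant_ids vector of unique participant identifiers; must have
#'   even length >= 4 (with an odd cohort, drop one participant).
#' @param n_iterations number of random splits (default 10).
#' @param seed integer seed making the plan reproducible.
#' @return An object of class \code{split_plan}: list with \code{halves}
#'   (list per iteration of two id vectors), \code{n_iterations}, \code{seed}.
#' @export
make_split_plan <- function(participant_ids, n_iterations = 10, seed = 1L) {
  ids <- participant_ids
  if (anyDuplicated(ids)) stop("participant ids must be unique")
  n <- length(ids)
  if (n < 4) stop("need at least 4 participants")
  if (n %% 2 != 0) {
    stop("cohort size must be even for equal split-halves; drop one participant")
  }
  halves <- with_seed(seed, lapply(seq_len(n_iterations), function(i) {
    perm <- sample(ids)
    list(perm[seq_len(n / 2)], perm[(n / 2 + 1):n])
  }))
  structure(list(halves = halves, n_iterations = as.integer(n_iterations),
                 seed = seed, participant_ids = ids),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d iterations over %d participants (seed %s)\n",
              x$n_iterations, length(x$participant_ids), format(x$seed)))
  invisible(x)
}

# run code with a temporary RNG state; restores the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Pearson correlation between rows of a and rows of b (variables are rows,
# observations are columns). Zero-variance rows give NA without warnings.
row_cor <- function(a, b = NULL) {
  az <- t(scale(t(a)))              # rows standardized
  bz <- if (is.null(b)) az else t(scale(t(b)))
  r <- tcrossprod(az, bz) / (ncol(a) - 1)
  r[!is.finite(r)] <- NA_real_      # zero-variance rows propagate NaN
  r[r > 1] <- 1; r[r < -1] <- -1
  r
}

#' ROI-to-context connectivity matrix
#'
#' Pearson correlation over timepoints between every ROI voxel's series and
#' every context voxel's series for one participant. Zero-variance voxels
#' yield \code{NA} entries; they are flagged and excluded downstream rather
#' than silently zeroed.
#'
#' @param ts_roi,ts_context \code{ts_matrix} objects from the same participant
#'   with equal timepoint counts.
#' @return An object of class \code{connectivity_matrix}: |ROI| x |context|
#'   matrix with attributes \code{roi_voxel_order}, \code{context_voxel_order},
#'   \code{provenance}.
#' @export
roi_context_correlation <- function(ts_roi, ts_context) {
  if (ncol(ts_roi) != ncol(ts_context)) stop("timepoint counts differ")
  pa <- attr(ts_roi, "participant_id"); pb <- attr(ts_context, "participant_id")
  if (!is.null(pa) && !is.null(pb) && !identical(pa, pb)) {
    stop("ROI and context matrices come from different participants")
  }
  r <- row_cor(unclass(ts_roi), unclass(ts_context))
  connectivity_matrix(r, attr(ts_roi, "voxel_order"),
                      attr(ts_context, "voxel_order"),
                      provenance = list(participant = pa))
}

connectivity_matrix <- function(values, roi_voxel_order, context_voxel_order,
                                provenance = list()) {
  structure(values,
            roi_voxel_order = roi_voxel_order,
            context_voxel_order = context_voxel_order,
            provenance = provenance,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: %d ROI voxels x %d context voxels\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Group-average connectivity matrices
#'
#' Averages per-participant connectivity matrices entrywise. The default
#' Fisher-z method transforms r with atanh (|r| clipped at 1 - 1e-7), averages
#' in z space and transforms back -- the statistically conventional way to
#' average correlations. \code{raw} is the plain arithmetic mean. Undefined
#' (\code{NA}) entries are excluded pairwise.
#'
#' @param mats non-empty list of \code{connectivity_matrix} objects with
#'   identical voxel orders.
#' @param method \code{"fisher_z"} (default) or \code{"raw"}.
#' @return A \code{connectivity_matrix} of the group average.
#' @export
group_average <- function(mats, method = c("fisher_z", "raw")) {
  method <- match.arg(method)
  if (length(mats) == 0) stop("empty list of matrices")
  acc <- matrix(0, nrow(mats[[1]]), ncol(mats[[1]]))
  cnt <- matrix(0L, nrow(acc), ncol(acc))
  for (m in mats) {
    stopifnot(identical(dim(m), dim(acc)))
    v <- unclass(m)
    if (method == "fisher_z") v <- atanh(pmin(pmax(v, -1 + 1e-7), 1 - 1e-7))
    ok <- !is.na(v)
    v[!ok] <- 0
    acc <- acc + v
    cnt <- cnt + ok
  }
  avg <- acc / cnt                 # 0/0 -> NaN where never defined
  avg[cnt == 0] <- NA_real_
  if (method == "fisher_z") avg <- tanh(avg)
  connectivity_matrix(avg, attr(mats[[1]], "roi_voxel_order"),
                      attr(mats[[1]], "context_voxel_order"),
                      provenance = list(group_of = length(mats), method = method))
}

#' ROI-voxel similarity matrix
#'
#' Squares an ROI x context connectivity matrix by correlating every pair of
#' ROI voxels' connectivity-pattern vectors (their rows), yielding the
#' |ROI| x |ROI| similarity matrix that is the clustering substrate: two ROI
#' voxels are similar when they connect to the context in the same way.
#'
#' @param conn a \code{connectivity_matrix} with >= 2 context voxels. Context
#'   columns that are \code{NA} for any ROI voxel are dropped before
#'   correlating (pairwise-complete patterns are not comparable across pairs).
#' @return An object of class \code{similarity_matrix}: symmetric with unit
#'   diagonal; ROI voxels with constant or undefined patterns get \code{NA}
#'   rows/columns, listed in attribute \code{undefined}.
#' @export
similarity_matrix <- function(conn) {
  v <- unclass(conn)
  if (ncol(v) < 2) stop("need at least 2 context voxels")
  badcol <- colSums(is.na(v)) > 0
  if (all(badcol)) stop("all context columns contain undefined entries")
  v <- v[, !badcol, drop = FALSE]
  s <- row_cor(v)
  undef <- which(is.na(diag(s)))   # constant pattern rows: whole row/col is NA
  diag(s) <- 1
  if (length(undef)) diag(s)[undef] <- NA
  structure(s, roi_voxel_order = attr(conn, "roi_voxel_order"),
            undefined = undef,
            class = c("similarity_matrix", "matrix", "array"))
}

#' Threshold a similarity matrix into a binary graph
#'
#' Keeps approximately the top \code{(1 - p)} fraction of voxel pairs: the
#' cutoff is the \code{p}-quantile (linear interpolation) of the off-diagonal
#' upper-triangle similarities, and an undirected edge joins a pair iff its
#' similarity strictly exceeds the cutoff. So \code{p = 0.90} retains roughly
#' the top 10% of connections (exactly, modulo ties at the cutoff, which drop
#' together). Negative and positive similarities compete on the raw scale.
#'
#' @param sim a \code{similarity_matrix}. Voxels flagged undefined must be
#'   removed beforehand (see \code{\link{drop_undefined}}).
#' @param p proportion in (0, 1), e.g. 0.90 for the "top 10%" graph.
#' @return An object of class \code{binary_graph}: list with \code{adjacency}
#'   (symmetric logical, empty diagonal), \code{p}, \code{n_nodes}.
#' @export
binarize_top <- function(sim, p) {
  stopifnot(p > 0, p < 1)
  s <- unclass(sim)
  if (anyNA(s)) stop("similarity matrix contains undefined voxels; drop them first")
  ut <- s[upper.tri(s)]
  cutoff <- stats::quantile(ut, p, names = FALSE)  # type 7, linear interpolation
  adj <- s > cutoff
  adj <- adj & t(adj)
  diag(adj) <- FALSE
  if (!any(adj)) warning("no pair exceeds the cutoff; graph is empty")
  structure(list(adjacency = adj, p = p, n_nodes = nrow(s),
                 roi_voxel_order = attr(sim, "roi_voxel_order")),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("binary_graph: %d nodes, %d edges (top %.1f%% of pairs)\n",
              x$n_nodes, sum(x$adjacency) / 2, 100 * (1 - x$p)))
  invisible(x)
}

#' Drop undefined voxels from a similarity matrix
#'
#' Removes the rows/columns flagged undefined (zero-variance patterns) so the
#' remaining matrix is a valid graph substrate. The removed voxels are
#' reported via the \code{dropped} attribute of the result.
#'
#' @param sim a \code{similarity_matrix}.
#' @return A \code{similarity_matrix} without undefined voxels; attribute
#'   \code{dropped} holds the removed positions (indices into the original
#'   ROI voxel order).
#' @export
drop_undefined <- function(sim) {
  undef <- attr(sim, "undefined")
  if (length(undef) == 0) {
    attr(sim, "dropped") <- integer(0)
    return(sim)
  }
  keep <- setdiff(seq_len(nrow(sim)), undef)
  out <- unclass(sim)[keep, keep, drop = FALSE]
  structure(out,
            roi_voxel_order = attr(sim, "roi_voxel_order")[keep, , drop = FALSE],
            undefined = integer(0), dropped = undef,
            class = c("similarity_matrix", "matrix", "array"))
}

#' Export / read a binary graph in Pajek .net format
#'
#' Vertices are written 1-based in the graph's node order; each undirected
#' edge appears once under \code{*Edges}.
#'
#' @param graph a \code{binary_graph}.
#' @param path output path (.net).
#' @return \code{export_pajek}: the path invisibly; \code{read_pajek}: a
#'   \code{binary_graph} (with \code{p = NA}).
#' @export
export_pajek <- function(graph, path) {
  n <- graph$n_nodes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("*Vertices %d", n), con)
  writeLines(sprintf('%d "v%d"', seq_len(n), seq_len(n)), con)
  writeLines("*Edges", con)
  e <- which(graph$adjacency & upper.tri(graph$adjacency), arr.ind = TRUE)
  if (nrow(e) > 0) {
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
    writeLines(sprintf("%d %d", e[, 1], e[, 2]), con)
  }
  invisible(path)
}

#' @rdname export_pajek
#' @export
read_pajek <- function(path) {
  lines <- trimws(readLines(path))
  nv <- as.integer(sub("(?i)^\\*vertices\\s+", "", lines[1], perl = TRUE))
  eidx <- grep("(?i)^\\*(edges|arcs)", lines, perl = TRUE)[1]
  adj <- matrix(FALSE, nv, nv)
  if (!is.na(eidx) && eidx < length(lines)) {
    el <- lines[(eidx + 1):length(lines)]
    el <- el[nzchar(el) & !grepl("^\\*", el)]
    if (length(el) > 0) {
      e <- do.call(rbind, lapply(strsplit(el, "[ \t]+"), function(x) as.integer(x[1:2])))
      adj[e] <- TRUE
      adj[e[, 2:1, drop = FALSE]] <- TRUE
    }
  }
  diag(adj) <- FALSE
  structure(list(adjacency = adj, p = NA_real_, n_nodes = nv,
                 roi_voxel_order = NULL),
            class = "binary_graph")
}
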