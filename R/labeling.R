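#' Group-average connectivity fingerprints for full-resolution voxels
#'
#' For every brain voxel at the original spatial resolution, computes its
#' Pearson connectivity pattern to the (downsampled) context voxels in each
#' participant and averages the patterns across participants. These
#' fingerprints live over the same context set as the prototype patterns, so
#' the two are directly comparable in the winner-take-all step.
#'
#' @param brain_ts list over participants of \code{ts_matrix} (full-resolution
#'   brain voxels x T).
#' @param context_ts list over participants of \code{ts_matrix} (downsampled
#'   context voxels x T), same participant order and timepoint count.
#' @param method averaging method, as in \code{\link{group_average}}.
#' @return A \code{connectivity_matrix} (|brain voxels| x |context|); voxels
#'   with zero temporal variance get \code{NA} patterns and stay unlabeled.
#' @export
fullres_patterns <- function(brain_ts, context_ts,
                             method = c("fisher_z", "raw")) {
  method <- match.arg(method)
  stopifnot(length(brain_ts) == length(context_ts), length(brain_ts) >= 1)
  acc <- NULL; cnt <- NULL
  for (p in seq_along(brain_ts)) {
    r <- unclass(roi_context_correlation(brain_ts[[p]], context_ts[[p]]))
    if (method == "fisher_z") r <- atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
    ok <- !is.na(r)
    r[!ok] <- 0
    if (is.null(acc)) {
      acc <- r; cnt <- ok + 0L
    } else {
      acc <- acc + r; cnt <- cnt + ok
    }
  }
  avg <- acc / cnt
  avg[cnt == 0] <- NA_real_
  if (method == "fisher_z") avg <- tanh(avg)
  connectivity_matrix(avg, attr(brain_ts[[1]], "voxel_order"),
                      attr(context_ts[[1]], "voxel_order"),
                      provenance = list(group_of = length(brain_ts),
                                        method = method, space = "fullres"))
}

#' Average connectivity pattern of each prototype
#'
#' Averages the group-level connectivity rows of a prototype's member voxels
#' into one pattern per prototype -- the template each brain voxel is
#' correlated against in the winner-take-all step. Prototypes from several
#' ROI masks are pooled into one candidate list by calling this per mask and
#' concatenating (see \code{\link{label_networks}}).
#'
#' @param group_conn group-averaged \code{connectivity_matrix} (ROI x
#'   context, downsampled space).
#' @param protos a \code{prototype_set} whose indices refer to
#'   \code{group_conn}'s rows.
#' @return Numeric matrix, one row per prototype (K x |context|).
#' @export
prototype_patterns <- function(group_conn, protos) {
  v <- unclass(group_conn)
  pats <- lapply(protos$prototypes, function(vox) {
    if (length(vox) == 0) stop("empty prototype")
    colMeans(v[vox, , drop = FALSE])
  })
  do.call(rbind, pats)
}

#' Winner-take-all network labeling
#'
#' Correlates every voxel's connectivity fingerprint with every prototype's
#' average pattern and assigns the label of the prototype explaining the most
#' variance (largest squared Pearson correlation). A voxel is labeled only if
#' the winner's \eqn{R^2} strictly exceeds \code{r2_min} (default 0.5, i.e.
#' the winning prototype must explain at least half the variance); otherwise
#' it stays unlabeled (label 0) -- a quality gate that keeps noise voxels out
#' of the map. By default strong negative correlations may win (literal
#' most-variance-explained); \code{sign_restricted = TRUE} additionally
#' requires r > 0.
#'
#' @param voxel_patterns \code{connectivity_matrix} or plain matrix (n voxels
#'   x |context|).
#' @param proto_patterns matrix (K x |context|) from
#'   \code{\link{prototype_patterns}}.
#' @param r2_min variance-explained floor in [0, 1) (default 0.5).
#' @param sign_restricted require positive correlation to win.
#' @return An object of class \code{network_labels}: list with \code{labels}
#'   (integer, 0 = unlabeled), \code{r2} (winning R-squared, \code{NA} where
#'   undefined), \code{voxel_order}, \code{geometry} (when available),
#'   \code{r2_min}.
#' @export
assign_labels <- function(voxel_patterns, proto_patterns, r2_min = 0.5,
                          sign_restricted = FALSE) {
  if (is.null(dim(proto_patterns)) || nrow(proto_patterns) < 1) {
    stop("no prototype patterns")
  }
  v <- unclass(voxel_patterns)
  stopifnot(ncol(v) == ncol(proto_patterns))
  r <- row_cor(v, proto_patterns)          # n x K; NA rows for undefined voxels
  r2 <- r * r
  if (sign_restricted) r2[r <= 0] <- 0
  win <- max.col(replace(r2, is.na(r2), -Inf), ties.method = "first")
  win_r2 <- r2[cbind(seq_len(nrow(r2)), win)]
  labels <- ifelse(!is.na(win_r2) & win_r2 > r2_min, win, 0L)
  structure(list(labels = as.integer(labels), r2 = win_r2,
                 voxel_order = attr(voxel_patterns, "roi_voxel_order"),
                 geometry = attr(voxel_patterns, "geometry"),
                 r2_min = r2_min, sign_restricted = sign_restricted),
            class = "network_labels")
}

#' @export
print.network_labels <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("network_labels: %d voxels, %d labeled (%.1f%%), %d networks\n",
              n, sum(x$labels > 0), 100 * mean(x$labels > 0),
              length(setdiff(unique(x$labels), 0L))))
  invisible(x)
}

#' Write network labels as a 1D text table
#'
#' One voxel per row: 0-based \code{i j k} coordinates in the original
#' resolution, the final label (0 = unlabeled) and the winning R-squared.
#'
#' @param labels a \code{network_labels} with a \code{voxel_order}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_labels_1d <- function(labels, path) {
  vo <- labels$voxel_order
  stopifnot(!is.null(vo))
  writeLines(c("# splitparc network labels (i j k label r2, 0-based)",
               sprintf("%d %d %d %d %.6f", vo[, 1], vo[, 2], vo[, 3],
                       labels$labels,
                       ifelse(is.na(labels$r2), 0, labels$r2))),
             path)
  invisible(path)
}
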