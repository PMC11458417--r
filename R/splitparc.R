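#' Fit a split-half consensus parcellation for one ROI mask
#'
#' The core estimator. For each of \code{n_iterations} random equal
#' split-halves of the cohort it (1) group-averages the per-participant
#' ROI-to-context correlation matrices within each half, (2) squares them
#' into ROI-voxel similarity matrices, (3) thresholds each into binary graphs
#' over the \code{thresholds} grid and clusters each graph with two-level
#' InfoMap (\code{n_trials} restarts), and (4) keeps only prototypes that
#' replicate across the two halves (Dice and minimum-volume criteria). The
#' replicated co-memberships are accumulated into one agreement matrix per
#' threshold; the consensus rule (co-membership in at least half the
#' iterations) and connected-component extraction yield the consensus
#' prototypes, and coverage/count agreement curves summarise every threshold
#' for the user's threshold choice.
#'
#' ROI voxels (or context voxels) with zero temporal variance in any
#' participant have undefined correlations; they are removed before graph
#' construction and reported in the result rather than silently zeroed. The
#' 2\% minimum-volume floor always references the full ROI mask size.
#'
#' @param x either a list of per-participant \code{timeseries4d} volumes
#'   (requires \code{roi} and \code{context} masks), or a list of
#'   per-participant lists with elements \code{roi} and \code{context}, each
#'   a \code{ts_matrix}.
#' @param roi,context \code{volume_mask}s at the analysis resolution (only
#'   when \code{x} is a list of volumes).
#' @param thresholds graph thresholds as proportions in (0, 1); the default
#'   covers 0.80 to 0.95 in steps of 0.03.
#' @param n_iterations number of random split-halves (default 10).
#' @param n_trials InfoMap restarts per graph (default 100).
#' @param criteria a \code{\link{match_criteria}}.
#' @param average correlation averaging method (see
#'   \code{\link{group_average}}).
#' @param seed integer seed; every source of randomness (split plan, InfoMap
#'   searches) derives from it.
#' @param keep_agreement keep the per-threshold agreement matrices in the
#'   returned object (default TRUE).
#' @param verbose print progress messages.
#' @return An object of class \code{splitparc}. Key components:
#'   \code{curve} (an \code{\link{agreement_curve}}), \code{prototypes}
#'   (named list per threshold of \code{prototype_set}s, voxel indices in the
#'   canonical order of the ROI mask), \code{agreement} (named list per
#'   threshold of \code{agreement_matrix}), \code{group_conn} (all-cohort
#'   average connectivity of the kept ROI voxels), \code{roi_keep} (indices
#'   of kept ROI voxels), \code{dropped} (removed zero-variance voxels),
#'   \code{plan} (the \code{split_plan}), \code{settings}.
#' @seealso \code{\link{label_networks}}, \code{\link{fill_unlabeled}},
#'   \code{\link{run_pipeline}}, \code{\link{synth_generate}}
#' @export
splitparc <- function(x, roi = NULL, context = NULL,
                      thresholds = seq(0.80, 0.95, by = 0.03),
                      n_iterations = 10, n_trials = 100,
                      criteria = match_criteria(),
                      average = c("fisher_z", "raw"), seed = 1L,
                      keep_agreement = TRUE, verbose = FALSE) {
  average <- match.arg(average)
  stopifnot(all(thresholds > 0), all(thresholds < 1), length(thresholds) >= 1)
  thresholds <- sort(unique(thresholds))
  cl <- match.call()

  if (length(x) < 4) stop("need at least 4 participants")
  if (inherits(x[[1]], "timeseries4d")) {
    stopifnot(inherits(roi, "volume_mask"), inherits(context, "volume_mask"))
    pid <- names(x) %||% sprintf("p%02d", seq_along(x))
    pairs <- lapply(seq_along(x), function(p) list(
      roi = extract_timeseries(x[[p]], roi, pid[p]),
      context = extract_timeseries(x[[p]], context, pid[p])))
    roi_n <- mask_size(roi)
    roi_order <- mask_members(roi)
    roi_name <- roi$name
  } else {
    pairs <- x
    pid <- names(x) %||% vapply(pairs, function(p)
      as.character(attr(p$roi, "participant_id")), character(1))
    if (anyDuplicated(pid)) pid <- sprintf("p%02d", seq_along(pairs))
    roi_n <- nrow(pairs[[1]]$roi)
    roi_order <- attr(pairs[[1]]$roi, "voxel_order")
    roi_name <- attr(pairs[[1]]$roi, "mask_name") %||% "roi"
  }
  nt <- unique(vapply(pairs, function(p) ncol(p$roi), integer(1)))
  if (length(nt) != 1) stop("all participants must share one timeseries length")

  # master seed stream: one draw for the split plan, one per InfoMap call
  n_im <- n_iterations * 2 * length(thresholds)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 1 + n_im))
  plan <- make_split_plan(pid, n_iterations, seed = seeds[1])

  if (verbose) message("computing per-participant connectivity (",
                       length(pairs), " participants)")
  zconn <- lapply(pairs, function(p) {
    r <- unclass(roi_context_correlation(p$roi, p$context))
    if (average == "fisher_z") atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)) else r
  })

  # drop voxels whose correlations are undefined for any participant
  # an all-NA row/column marks a zero-variance voxel in that participant
  bad_roi <- Reduce(`|`, lapply(zconn, function(z) rowSums(is.na(z)) == ncol(z)))
  bad_ctx <- Reduce(`|`, lapply(zconn, function(z) colSums(is.na(z)) == nrow(z)))
  roi_keep <- which(!bad_roi)
  ctx_keep <- which(!bad_ctx)
  if (length(roi_keep) < 2) stop("fewer than 2 ROI voxels with defined connectivity")
  zconn <- lapply(zconn, function(z) z[roi_keep, ctx_keep, drop = FALSE])
  if (verbose && (any(bad_roi) || any(bad_ctx))) {
    message("dropped ", sum(bad_roi), " ROI and ", sum(bad_ctx),
            " context voxels with undefined connectivity")
  }

  half_avg <- function(ids) {
    z <- Reduce(`+`, zconn[match(ids, pid)]) / length(ids)
    if (average == "fisher_z") tanh(z) else z
  }

  replicated <- stats::setNames(
    lapply(thresholds, function(t) vector("list", n_iterations)),
    sprintf("%g", thresholds))
  si <- 2L  # next unused seed
  for (it in seq_len(n_iterations)) {
    if (verbose) message("split iteration ", it, "/", n_iterations)
    parts <- lapply(1:2, function(h) {
      conn <- connectivity_matrix(half_avg(plan$halves[[it]][[h]]),
                                  roi_order[roi_keep, , drop = FALSE], NULL)
      sim <- similarity_matrix(conn)
      if (length(attr(sim, "undefined")) > 0) sim <- drop_undefined(sim)
      lapply(thresholds, function(th) {
        g <- suppressWarnings(binarize_top(sim, th))
        s <- seeds[si]; si <<- si + 1L
        detect_communities(g, n_trials = n_trials, seed = s)
      })
    })
    for (ti in seq_along(thresholds)) {
      m <- match_prototypes(parts[[1]][[ti]], parts[[2]][[ti]],
                            roi_size = roi_n, crit = criteria)
      replicated[[ti]][[it]] <- lapply(m, `[[`, "voxels")
    }
  }

  per_threshold <- lapply(seq_along(thresholds), function(ti) {
    agree <- accumulate_agreement(replicated[[ti]], n_iterations,
                                  length(roi_keep))
    cons <- consensus_prototypes(agree, criteria, roi_size = roi_n)
    cons$prototypes <- lapply(cons$prototypes, function(v) roi_keep[v])
    list(agreement = agree, consensus = cons,
         replicated_sets = replicated[[ti]])
  })
  names(per_threshold) <- sprintf("%g", thresholds)
  curve <- agreement_curve(per_threshold, roi_size = roi_n)

  group_conn <- connectivity_matrix(
    if (average == "fisher_z") tanh(Reduce(`+`, zconn) / length(zconn))
    else Reduce(`+`, zconn) / length(zconn),
    roi_order[roi_keep, , drop = FALSE], NULL,
    provenance = list(group_of = length(zconn), method = average))

  structure(list(
    curve = curve,
    prototypes = lapply(per_threshold, `[[`, "consensus"),
    agreement = if (keep_agreement) lapply(per_threshold, `[[`, "agreement"),
    replicated = lapply(per_threshold, `[[`, "replicated_sets"),
    group_conn = group_conn,
    roi_keep = roi_keep, ctx_keep = ctx_keep,
    dropped = list(roi = which(bad_roi), context = which(bad_ctx)),
    roi_name = roi_name, roi_size = roi_n, roi_voxel_order = roi_order,
    plan = plan,
    settings = list(thresholds = thresholds, n_iterations = n_iterations,
                    n_trials = n_trials, criteria = criteria,
                    average = average, seed = seed),
    call = cl), class = "splitparc")
}

#' @export
print.splitparc <- function(x, ...) {
  cat("Split-half consensus parcellation fit\n")
  cat(sprintf("  ROI '%s': %d voxels (%d kept), %d participants, %d split iterations\n",
              x$roi_name, x$roi_size, length(x$roi_keep),
              length(x$plan$participant_ids), x$settings$n_iterations))
  cat(sprintf("  thresholds: %s\n",
              paste(sprintf("%g", x$settings$thresholds), collapse = ", ")))
  cat("  agreement curve:\n")
  print(as.data.frame(x$curve), digits = 3)
  invisible(x)
}

#' @export
summary.splitparc <- function(object, ...) {
  out <- list(curve = object$curve,
              dropped = object$dropped,
              sizes = lapply(object$prototypes,
                             function(p) lengths(p$prototypes)),
              settings = object$settings, roi_name = object$roi_name)
  class(out) <- "summary.splitparc"
  out
}

#' @export
print.summary.splitparc <- function(x, ...) {
  cat(sprintf("splitparc fit for ROI '%s'\n\nAgreement curve:\n", x$roi_name))
  print(as.data.frame(x$curve), digits = 3)
  cat("\nPrototype sizes by threshold:\n")
  for (th in names(x$sizes)) {
    cat(sprintf("  %s: %s\n", th,
                if (length(x$sizes[[th]])) paste(x$sizes[[th]], collapse = ", ")
                else "(none)"))
  }
  if (length(x$dropped$roi) || length(x$dropped$context)) {
    cat(sprintf("\nDropped zero-variance voxels: %d ROI, %d context\n",
                length(x$dropped$roi), length(x$dropped$context)))
  }
  invisible(x)
}

#' @export
plot.splitparc <- function(x, ...) {
  plot(x$curve, main = sprintf("Split-half agreement ('%s')", x$roi_name), ...)
}

# prototypes of a fit at one threshold, with exact name matching
fit_prototypes <- function(fit, threshold) {
  key <- sprintf("%g", threshold)
  if (!key %in% names(fit$prototypes)) {
    stop(sprintf("threshold %s was not evaluated (available: %s)", key,
                 paste(names(fit$prototypes), collapse = ", ")))
  }
  fit$prototypes[[key]]
}

#' Assign final network labels from one or more fits
#'
#' Pools the consensus prototypes of each fit at its chosen threshold,
#' averages each prototype's group connectivity pattern, computes every brain
#' voxel's group-average connectivity fingerprint at the original resolution
#' against the downsampled context, and labels each voxel winner-take-all
#' (see \code{\link{assign_labels}}). Prototypes from different ROI masks
#' compete on equal footing, so a prototype that originated in one mask may
#' claim voxels anywhere in the brain.
#'
#' @param fits a \code{splitparc} fit or (possibly named) list of fits.
#' @param thresholds chosen threshold per fit (scalar recycled).
#' @param brain_ts list over participants of full-resolution brain
#'   \code{ts_matrix}.
#' @param context_ts list over participants of downsampled context
#'   \code{ts_matrix} (same order).
#' @param r2_min winner variance-explained floor (default 0.5).
#' @param sign_restricted see \code{\link{assign_labels}}.
#' @return A \code{network_labels} with a \code{legend} data frame mapping
#'   each global label to its source ROI mask, threshold and local prototype
#'   id.
#' @export
label_networks <- function(fits, thresholds, brain_ts, context_ts,
                           r2_min = 0.5, sign_restricted = FALSE) {
  if (inherits(fits, "splitparc")) fits <- list(fits)
  thresholds <- rep_len(thresholds, length(fits))
  pats <- list(); legend <- list()
  for (f in seq_along(fits)) {
    fit <- fits[[f]]
    protos <- fit_prototypes(fit, thresholds[f])
    if (length(protos$prototypes) == 0) next
    kept_sets <- lapply(protos$prototypes, function(v) match(v, fit$roi_keep))
    pp <- prototype_patterns(fit$group_conn,
                             prototype_set(kept_sets, protos$roi_size))
    pats[[length(pats) + 1]] <- pp
    legend[[length(legend) + 1]] <- data.frame(
      mask = fit$roi_name, threshold = thresholds[f],
      local_label = seq_along(protos$prototypes),
      size = lengths(protos$prototypes))
  }
  if (length(pats) == 0) stop("no prototypes at the chosen thresholds")
  proto_mat <- do.call(rbind, pats)
  legend <- do.call(rbind, legend)
  legend <- cbind(label = seq_len(nrow(legend)), legend)
  vox_pat <- fullres_patterns(brain_ts, context_ts,
                              method = fits[[1]]$settings$average)
  lab <- assign_labels(vox_pat, proto_mat, r2_min = r2_min,
                       sign_restricted = sign_restricted)
  lab$legend <- legend
  lab$geometry <- attr(brain_ts[[1]], "geometry")
  lab
}

#' Run the full parcellation pipeline
#'
#' Orchestrates the five stages end to end for one or more ROI masks:
#' downsampling and timeseries extraction, split-half connectivity and
#' similarity, InfoMap prototypes with replication and consensus, agreement
#' curves with (interactive or configured) threshold selection,
#' winner-take-all labeling at the original resolution, and nearest-neighbour
#' filling. When \code{out_dir} is given, intermediates are persisted:
#' per-mask agreement curves (CSV), prototype volumes at the chosen
#' thresholds, the label table (1D text), the final volume with legend and
#' JSON run metadata.
#'
#' @param participants list of per-participant \code{timeseries4d} volumes at
#'   the original resolution (equal length, one per participant).
#' @param roi_masks a \code{volume_mask} or named list of them (role roi).
#' @param context_mask the context \code{volume_mask} (typically whole
#'   brain).
#' @param brain_mask mask of voxels to receive final labels (defaults to the
#'   context mask).
#' @param roi_factors downsampling factor per ROI mask (list or scalar;
#'   default 1 = no downsampling).
#' @param context_factor downsampling factor for the context (default 1).
#' @param chosen_thresholds named numeric vector (names = ROI mask names)
#'   selecting the threshold per mask; required unless \code{interactive}.
#' @param interactive pause and ask for a threshold on the command line after
#'   showing each mask's agreement curve.
#' @param exclude_roi_from_context remove each ROI's voxels from its context
#'   (used in focused parcellations of small regions).
#' @param out_dir optional output directory for persisted artifacts.
#' @param persist_timeseries also write the extracted per-mask voxelwise
#'   timeseries as 1D text files under \code{out_dir/timeseries/} (default
#'   FALSE; these files are large).
#' @param r2_min,sign_restricted see \code{\link{label_networks}}.
#' @param seed master seed; per-mask fit seeds derive from it.
#' @inheritParams splitparc
#' @return An object of class \code{splitparc_run}: list with \code{fits},
#'   \code{chosen_thresholds}, \code{labels} (a \code{network_labels}),
#'   \code{parcellation} (a \code{parcellation}), \code{seed}.
#' @export
run_pipeline <- function(participants, roi_masks, context_mask,
                         brain_mask = context_mask,
                         roi_factors = 1, context_factor = 1,
                         thresholds = seq(0.80, 0.95, by = 0.03),
                         chosen_thresholds = NULL, interactive = FALSE,
                         exclude_roi_from_context = FALSE,
                         n_iterations = 10, n_trials = 100,
                         criteria = match_criteria(),
                         average = c("fisher_z", "raw"),
                         r2_min = 0.5, sign_restricted = FALSE,
                         out_dir = NULL, persist_timeseries = FALSE,
                         seed = 1L, verbose = FALSE) {
  average <- match.arg(average)
  if (inherits(roi_masks, "volume_mask")) {
    roi_masks <- stats::setNames(list(roi_masks), roi_masks$name)
  }
  if (is.null(names(roi_masks))) {
    names(roi_masks) <- vapply(roi_masks, `[[`, character(1), "name")
  }
  if (!interactive && is.null(chosen_thresholds)) {
    stop("supply chosen_thresholds (named per ROI mask) or set interactive = TRUE; ",
         "no automatic threshold selection is performed")
  }
  if (!is.list(roi_factors)) {
    roi_factors <- stats::setNames(rep(list(roi_factors), length(roi_masks)),
                                   names(roi_masks))
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pid <- names(participants) %||% sprintf("p%02d", seq_along(participants))
  names(participants) <- pid

  mask_seeds <- with_seed(seed,
                          sample.int(.Machine$integer.max - 1L,
                                     length(roi_masks)))

  ds_cache <- list()
  ds_vols <- function(factor) {
    key <- paste(rep_len(factor, 3), collapse = "x")
    if (is.null(ds_cache[[key]])) {
      ds_cache[[key]] <<- if (all(rep_len(factor, 3) == 1)) participants
      else lapply(participants, downsample_timeseries, factor = factor)
    }
    ds_cache[[key]]
  }

  if (exclude_roi_from_context && length(roi_masks) > 1) {
    stop("exclude_roi_from_context is only supported with a single ROI mask: ",
         "each mask would otherwise see a different context and the pooled ",
         "winner-take-all patterns would not be comparable")
  }
  ctx_ds_mask <- downsample_mask(context_mask, context_factor)
  ctx_vols <- ds_vols(context_factor)

  label_ctx_mask <- ctx_ds_mask   # context the labeling fingerprints live over
  fits <- list(); chosen <- numeric(0)
  for (mi in seq_along(roi_masks)) {
    mname <- names(roi_masks)[mi]
    if (verbose) message("== ROI mask '", mname, "' ==")
    roi_ds <- downsample_mask(roi_masks[[mi]], roi_factors[[mname]])
    ctx_mask_m <- ctx_ds_mask
    if (exclude_roi_from_context) {
      roi_in_ctx <- downsample_mask(roi_masks[[mi]], context_factor,
                                    min_occupancy = 1e-9)
      ctx_mask_m <- mask_difference(ctx_ds_mask, roi_in_ctx)
      label_ctx_mask <- ctx_mask_m   # keep fingerprints in the same space
    }
    roi_vols <- ds_vols(roi_factors[[mname]])
    x <- lapply(pid, function(p) list(
      roi = extract_timeseries(roi_vols[[p]], roi_ds, p),
      context = extract_timeseries(ctx_vols[[p]], ctx_mask_m, p)))
    names(x) <- pid
    if (!is.null(out_dir) && persist_timeseries) {
      tsd <- file.path(out_dir, "timeseries")
      dir.create(tsd, showWarnings = FALSE)
      for (p in pid) {
        write_ts1d(x[[p]]$roi, file.path(tsd, sprintf("%s_%s.1D", p, mname)))
      }
    }
    fit <- splitparc(x, thresholds = thresholds, n_iterations = n_iterations,
                     n_trials = n_trials, criteria = criteria,
                     average = average, seed = mask_seeds[mi],
                     verbose = verbose)
    fit$roi_name <- mname
    fit$roi_mask_ds <- roi_ds
    fits[[mname]] <- fit
    if (!is.null(out_dir)) {
      utils::write.csv(as.data.frame(fit$curve),
                       file.path(out_dir, sprintf("curve_%s.csv", mname)),
                       row.names = FALSE)
    }
    th <- if (interactive) {
      print(fit$curve)
      as.numeric(readline(sprintf("threshold for mask '%s': ", mname)))
    } else {
      if (!mname %in% names(chosen_thresholds)) {
        stop("no chosen threshold for mask '", mname, "'")
      }
      chosen_thresholds[[mname]]
    }
    chosen[mname] <- th
    if (!is.null(out_dir)) {
      prototypes_to_volume(fit_prototypes(fit, th), roi_ds,
                           file.path(out_dir, sprintf("prototypes_%s_%g.nii.gz",
                                                      mname, th)))
    }
    if (verbose) print(fit_prototypes(fit, th))
  }

  if (verbose) message("== winner-take-all labeling ==")
  brain_ts <- lapply(pid, function(p)
    extract_timeseries(participants[[p]], brain_mask, p))
  ctx_ts <- lapply(pid, function(p)
    extract_timeseries(ctx_vols[[p]], label_ctx_mask, p))
  if (!is.null(out_dir) && persist_timeseries) {
    tsd <- file.path(out_dir, "timeseries")
    dir.create(tsd, showWarnings = FALSE)
    for (p in seq_along(pid)) {
      write_ts1d(ctx_ts[[p]], file.path(tsd, sprintf("%s_context.1D", pid[p])))
    }
  }
  labels <- label_networks(fits, chosen[names(fits)], brain_ts, ctx_ts,
                           r2_min = r2_min, sign_restricted = sign_restricted)
  parc <- fill_unlabeled(labels, brain_mask)
  meta <- list(thresholds = thresholds, chosen_thresholds = as.list(chosen),
               n_iterations = n_iterations, n_trials = n_trials,
               criteria = unclass(criteria), average = average,
               r2_min = r2_min, sign_restricted = sign_restricted,
               seed = seed, pattern_space = "fullres-vs-downsampled-context")
  if (!is.null(out_dir)) {
    write_labels_1d(labels, file.path(out_dir, "labels.1D"))
    write_parcellation(parc, file.path(out_dir, "parcellation.nii.gz"),
                       metadata = meta)
  }
  structure(list(fits = fits, chosen_thresholds = chosen, labels = labels,
                 parcellation = parc, metadata = meta, seed = seed),
            class = "splitparc_run")
}

#' @export
print.splitparc_run <- function(x, ...) {
  cat(sprintf("splitparc_run: %d ROI mask(s), thresholds %s\n",
              length(x$fits),
              paste(sprintf("%s=%g", names(x$chosen_thresholds),
                            x$chosen_thresholds), collapse = ", ")))
  print(x$parcellation)
  invisible(x)
}

#' Focused (recursive) parcellation of one parcel
#'
#' Re-runs the whole pipeline with a previously found parcel as the ROI mask,
#' yielding a finer-grained parcellation within it. The context is the whole
#' brain by default, or excludes the parcel's own voxels when
#' \code{exclude_roi_from_context = TRUE} (useful for small regions whose
#' internal correlations would dominate).
#'
#' @param participants list of per-participant \code{timeseries4d} volumes.
#' @param parent a \code{parcellation} or \code{network_labels} from a
#'   previous run (must carry \code{voxel_order} and \code{geometry}).
#' @param parcel_label the label within \code{parent} to refine.
#' @param context_mask the context \code{volume_mask}.
#' @param min_parcel_size smallest refinable parcel (default 10 voxels).
#' @param ... further arguments passed to \code{\link{run_pipeline}}
#'   (\code{chosen_thresholds} should name the new ROI, which is called
#'   \code{"parcel<label>"}).
#' @inheritParams run_pipeline
#' @return A \code{splitparc_run} for the focused ROI.
#' @export
run_focused <- function(participants, parent, parcel_label, context_mask,
                        exclude_roi_from_context = FALSE,
                        min_parcel_size = 10, ...) {
  vo <- parent$voxel_order
  if (is.null(vo) || is.null(parent$geometry)) {
    stop("parent parcellation lacks voxel coordinates")
  }
  sel <- parent$labels == parcel_label
  if (!any(sel)) stop("parcel_label not present in the parent parcellation")
  if (sum(sel) < min_parcel_size) {
    stop(sprintf("parcel %s has %d voxels, below the minimum feasible size %d",
                 format(parcel_label), sum(sel), min_parcel_size))
  }
  roi <- volume_mask(vo[sel, , drop = FALSE], parent$geometry, role = "roi",
                     name = sprintf("parcel%s", format(parcel_label)))
  run_pipeline(participants, roi_masks = roi, context_mask = context_mask,
               exclude_roi_from_context = exclude_roi_from_context, ...)
}
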