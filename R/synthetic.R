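#' Configuration for the planted-network generator
#'
#' Describes a multi-participant synthetic resting-state dataset with K
#' planted networks. Each network owns a contiguous strip of the ROI slab and
#' a matching context-only block; every voxel in a network mixes that
#' network's latent unit-variance Gaussian series with voxel-specific
#' Gaussian noise (\code{series = mixing * signal + noise_sd * eps}), so two
#' voxels of the same network correlate at
#' \eqn{r = mixing^2 / (mixing^2 + noise\_sd^2)} in expectation while voxels
#' of different networks are uncorrelated. The defaults emulate the desk
#' scale of a small-cohort study: a 24 x 24 x 12 grid of nominal 6 mm voxels,
#' a 600-voxel ROI slab inside a ~5,300-voxel in-brain context, K = 5
#' networks, 20 participants, 140 timepoints per run, and
#' \code{mixing = noise_sd = 1} for a within-network r of about 0.5.
#'
#' Optional "vessel" voxels -- high-variance pure-noise voxels emulating
#' prominent blood-vessel signal -- can be planted in the background to
#' exercise the high-SD exclusion and the R-squared labeling gate.
#'
#' @param n_participants cohort size (even for split-halves; default 20).
#' @param n_timepoints timepoints per run (default 140).
#' @param k_networks number of planted networks (default 5, >= 2).
#' @param mixing network-signal weight per voxel (default 1).
#' @param noise_sd voxel noise SD within network voxels (default 1).
#' @param background_sd noise SD of non-network brain voxels (default 1).
#' @param n_vessel number of vessel voxels (default 25; 0 disables).
#' @param vessel_sd vessel noise SD (default 10).
#' @param baseline additive signal offset, so tSNR is meaningful (default 1000).
#' @param grid_shape 3-vector of voxel counts (default \code{c(24, 24, 12)}).
#' @param voxel_size mm per voxel edge (default 6).
#' @param roi_slab list with 0-based inclusive ranges \code{i}, \code{j},
#'   \code{k} of the ROI slab; the slab's i-range is split into K equal
#'   strips, so its width must be divisible by K.
#' @param context_block_k 0-based inclusive k-range of the per-network
#'   context-only blocks (must not intersect the ROI slab's k-range).
#' @param seed integer seed; the whole dataset is a deterministic function of
#'   the config.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n_participants = 20, n_timepoints = 140,
                         k_networks = 5, mixing = 1, noise_sd = 1,
                         background_sd = 1, n_vessel = 25, vessel_sd = 10,
                         baseline = 1000, grid_shape = c(24, 24, 12),
                         voxel_size = 6,
                         roi_slab = list(i = c(2, 21), j = c(2, 16), k = c(4, 5)),
                         context_block_k = c(7, 9), seed = 1L) {
  stopifnot(k_networks >= 2, n_timepoints >= 2, n_participants >= 1,
            mixing > 0, noise_sd >= 0, background_sd >= 0)
  grid_shape <- as.integer(grid_shape)
  wi <- roi_slab$i[2] - roi_slab$i[1] + 1
  if (wi %% k_networks != 0) {
    stop("ROI slab i-width must divide evenly into k_networks strips")
  }
  if (roi_slab$i[1] < 1 || roi_slab$j[1] < 1 || roi_slab$k[1] < 1 ||
      roi_slab$i[2] >= grid_shape[1] - 1 || roi_slab$j[2] >= grid_shape[2] - 1 ||
      roi_slab$k[2] >= grid_shape[3] - 1 || context_block_k[2] >= grid_shape[3] - 1) {
    stop("planted blocks exceed the grid (or its in-brain interior)")
  }
  if (context_block_k[1] <= roi_slab$k[2] && context_block_k[2] >= roi_slab$k[1]) {
    stop("context blocks must not intersect the ROI slab")
  }
  roi_n <- wi * (roi_slab$j[2] - roi_slab$j[1] + 1) * (roi_slab$k[2] - roi_slab$k[1] + 1)
  if ((roi_n / k_networks) / roi_n < 0.02) {
    stop("each planted network must cover at least 2% of the ROI")
  }
  structure(list(n_participants = n_participants, n_timepoints = n_timepoints,
                 k_networks = k_networks, mixing = mixing, noise_sd = noise_sd,
                 background_sd = background_sd, n_vessel = n_vessel,
                 vessel_sd = vessel_sd, baseline = baseline,
                 grid_shape = grid_shape, voxel_size = voxel_size,
                 roi_slab = roi_slab, context_block_k = context_block_k,
                 seed = as.integer(seed), levels = 1L),
            class = "synth_config")
}

#' Two-level (nested network) generator configuration
#'
#' Variant of \code{\link{synth_config}} in which each of
#' \code{n_super} parent networks contains \code{subs_per_super}
#' sub-networks: a sub-network voxel mixes its parent's latent series, its
#' own sub-network series and voxel noise
#' (\code{parent_mixing * P + sub_mixing * L + noise_sd * eps}). A first-pass
#' parcellation groups whole parents (within-parent voxels share the parent
#' signal); a focused re-parcellation of one parent parcel separates its
#' sub-networks.
#'
#' The default scale is deliberately compact (an 18 x 18 x 12 grid, 240-voxel
#' ROI of 2 parents x 3 sub-networks of 40 voxels): focused parcellation
#' re-runs the full pipeline once per parent parcel, so the fixture is sized
#' for repeated fits.
#'
#' @param n_super number of parent networks (default 2).
#' @param subs_per_super sub-networks per parent (default 3).
#' @param parent_mixing weight of the shared parent series (default 1).
#' @param sub_mixing weight of the sub-network series (default 1).
#' @param noise_sd voxel noise SD (default 0.5).
#' @inheritParams synth_config
#' @param ... further arguments passed to \code{\link{synth_config}}.
#' @return A \code{synth_config} with \code{levels = 2}.
#' @export
synth_config_twolevel <- function(n_super = 2, subs_per_super = 3,
                                  parent_mixing = 1, sub_mixing = 1,
                                  noise_sd = 0.5,
                                  grid_shape = c(18, 18, 12),
                                  roi_slab = list(
                                    i = c(2, 2 + n_super * subs_per_super * 2 - 1),
                                    j = c(2, 11), k = c(4, 5)), ...) {
  cfg <- synth_config(k_networks = n_super * subs_per_super,
                      mixing = sub_mixing, noise_sd = noise_sd,
                      grid_shape = grid_shape, roi_slab = roi_slab, ...)
  cfg$levels <- 2L
  cfg$n_super <- as.integer(n_super)
  cfg$subs_per_super <- as.integer(subs_per_super)
  cfg$parent_mixing <- parent_mixing
  cfg
}

# masks and per-voxel planted labels implied by a config
synth_layout <- function(config) {
  gs <- config$grid_shape
  geom <- grid_geometry(gs, rep(config$voxel_size, 3))
  brain_arr <- array(FALSE, gs)
  brain_arr[2:(gs[1] - 1), 2:(gs[2] - 1), 1:(gs[3] - 1)] <- TRUE
  rs <- config$roi_slab
  roi_arr <- array(FALSE, gs)
  roi_arr[(rs$i[1]:rs$i[2]) + 1, (rs$j[1]:rs$j[2]) + 1, (rs$k[1]:rs$k[2]) + 1] <- TRUE
  stopifnot(!any(roi_arr & !brain_arr))   # ROI must sit inside the brain
  k <- config$k_networks
  w <- (rs$i[2] - rs$i[1] + 1) / k
  net_arr <- array(0L, gs)
  for (c in seq_len(k)) {
    irange <- (rs$i[1] + (c - 1) * w):(rs$i[1] + c * w - 1) + 1
    net_arr[irange, (rs$j[1]:rs$j[2]) + 1, (rs$k[1]:rs$k[2]) + 1] <- c
    cb <- config$context_block_k
    net_arr[irange, (rs$j[1]:rs$j[2]) + 1, (cb[1]:cb[2]) + 1] <- c
  }
  net_arr[!brain_arr] <- 0L
  list(geometry = geom,
       brain = volume_mask(brain_arr, geom, role = "context", name = "brain"),
       roi = volume_mask(roi_arr, geom, role = "roi", name = "roi"),
       net_arr = net_arr)
}

#' Generate a planted-network synthetic dataset
#'
#' @param config a \code{\link{synth_config}}.
#' @return A list with \code{participants} (list of \code{timeseries4d}),
#'   \code{roi_mask}, \code{context_mask} (the in-brain mask),
#'   \code{truth} (a \code{synth_truth}: per-voxel planted network ids over
#'   the ROI and brain masks in canonical order, super-network ids for
#'   two-level configs, vessel voxel indices, per-participant seeds) and
#'   \code{config}.
#' @export
synth_generate <- function(config) {
  lay <- synth_layout(config)
  gs <- config$grid_shape
  nt <- config$n_timepoints
  brain_lin <- mask_linear_index(lay$brain)
  net_of_brain <- as.vector(lay$net_arr)[brain_lin]
  with_seed(config$seed, {
    vessel_idx <- integer(0)
    if (config$n_vessel > 0) {
      bg <- which(net_of_brain == 0)
      vessel_idx <- sort(sample(bg, min(config$n_vessel, length(bg))))
    }
    p_seeds <- sample.int(.Machine$integer.max - 1L, config$n_participants)
    participants <- lapply(seq_len(config$n_participants), function(p) {
      with_seed(p_seeds[p], {
        lat <- matrix(stats::rnorm(config$k_networks * nt), config$k_networks, nt)
        if (identical(config$levels, 2L)) {
          par_lat <- matrix(stats::rnorm(config$n_super * nt), config$n_super, nt)
          super_of <- rep(seq_len(config$n_super), each = config$subs_per_super)
          lat <- config$mixing * lat +
            config$parent_mixing * par_lat[super_of, , drop = FALSE]
        } else {
          lat <- config$mixing * lat
        }
        nb <- length(brain_lin)
        sdv <- rep(config$background_sd, nb)
        sdv[net_of_brain > 0] <- config$noise_sd
        sdv[vessel_idx] <- config$vessel_sd
        mat <- matrix(stats::rnorm(nb * nt), nb, nt) * sdv + config$baseline
        innet <- net_of_brain > 0
        mat[innet, ] <- mat[innet, , drop = FALSE] + lat[net_of_brain[innet], , drop = FALSE]
        arr <- array(0, c(gs, nt))
        flat <- matrix(arr, ncol = nt)
        flat[brain_lin, ] <- mat
        timeseries4d(array(flat, c(gs, nt)), lay$geometry)
      })
    })
    roi_lin <- mask_linear_index(lay$roi)
    truth <- structure(list(
      roi_labels = as.vector(lay$net_arr)[roi_lin],
      brain_labels = net_of_brain,
      super_of = if (identical(config$levels, 2L))
        rep(seq_len(config$n_super), each = config$subs_per_super) else NULL,
      vessel_brain_index = vessel_idx,
      participant_seeds = p_seeds), class = "synth_truth")
    list(participants = participants, roi_mask = lay$roi,
         context_mask = lay$brain, truth = truth, config = config)
  })
}

#' Score recovery of planted networks
#'
#' Matches recovered networks to planted networks greedily by descending Dice
#' (one-to-one, label-free) and reports the per-planted-network Dice, their
#' mean, and an adjusted Rand index computed over the voxels with a planted
#' label.
#'
#' @param recovered a \code{prototype_set}, a list of voxel-index sets, or an
#'   integer label vector (0 = unassigned) over the same voxel domain as
#'   \code{truth_labels}.
#' @param truth_labels integer vector of planted network ids (0 = none).
#' @return A list with \code{per_network_dice} (named by planted id),
#'   \code{mean_dice}, \code{ari}, \code{n_recovered}.
#' @export
score_recovery <- function(recovered, truth_labels) {
  if (inherits(recovered, "prototype_set")) recovered <- recovered$prototypes
  if (!is.list(recovered)) {
    lab <- as.integer(recovered)
    stopifnot(length(lab) == length(truth_labels))
    recovered <- split(which(lab > 0), lab[lab > 0])
  }
  planted <- split(which(truth_labels > 0), truth_labels[truth_labels > 0])
  kd <- rep(0, length(planted))
  names(kd) <- names(planted)
  if (length(recovered) > 0) {
    dmat <- vapply(recovered, function(r)
      vapply(planted, function(p) dice(p, r), numeric(1)),
      numeric(length(planted)))
    dmat <- matrix(dmat, nrow = length(planted))
    for (step in seq_len(min(dim(dmat)))) {
      best <- which(dmat == max(dmat), arr.ind = TRUE)[1, , drop = TRUE]
      if (dmat[best[1], best[2]] <= 0) break
      kd[best[1]] <- dmat[best[1], best[2]]
      dmat[best[1], ] <- -1
      dmat[, best[2]] <- -1
    }
  }
  rec_lab <- integer(length(truth_labels))
  for (s in seq_along(recovered)) rec_lab[recovered[[s]]] <- s
  sel <- truth_labels > 0
  ari <- mclust::adjustedRandIndex(truth_labels[sel], rec_lab[sel])
  list(per_network_dice = kd, mean_dice = mean(kd), ari = ari,
       n_recovered = length(recovered))
}
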