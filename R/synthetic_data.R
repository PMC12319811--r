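# Synthetic dyadic BOLD generator.
#
# Generative model per ROI: K_true event mean patterns (V-vectors, separation
# set by event_contrast); a couple-shared zero-mean fluctuation series and one
# idiosyncratic series per spouse, each a unit-variance Gaussian process
# smoothed with a 3-TR moving average to mimic BOLD autocorrelation. The
# spouse signal at TR t is
#   event_mean[event(t)] + sqrt(c) * shared_t + sqrt(1 - c) * idio_t + noise
# so c in [0, 1] is the fraction of fluctuation variance shared within the
# couple and the per-voxel fluctuation variance decomposes as
# c + (1 - c) + noise_sd^2.

#' Synthetic-cohort configuration
#'
#' Defaults are a desk-scale stand-in for the full study geometry
#' (200 ROIs / ~400 TRs): 20 ROIs of 50 voxels, 100 TRs, 5 latent events.
#'
#' @param n_couples Number of married couples (2 subjects each).
#' @param n_rois Number of regions of interest.
#' @param voxels_per_roi Voxels per ROI.
#' @param n_trs Number of TRs.
#' @param n_events True number of latent events K_true.
#' @param coupling Shared-trajectory strength c in `[0, 1]`; scalar (all
#'   couples) or one value per couple.
#' @param event_contrast SD of event mean patterns (separation between the
#'   stable patterns that define events).
#' @param noise_sd SD of additive measurement noise.
#' @param satisfaction_slope Score units per SD of coupling (see
#'   [generate_satisfaction()]).
#' @param satisfaction_noise_sd SD of score noise.
#' @param seed Integer RNG seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_couples = 30, n_rois = 20, voxels_per_roi = 50,
                             n_trs = 100, n_events = 5, coupling = 0.5,
                             event_contrast = 1, noise_sd = 0.5,
                             satisfaction_slope = 10,
                             satisfaction_noise_sd = 5, seed = 1L) {
  stopifnot(n_couples >= 1, n_rois >= 1, voxels_per_roi >= 3, n_trs >= 3,
            n_events >= 1, n_events <= n_trs,
            all(coupling >= 0), all(coupling <= 1),
            event_contrast >= 0, noise_sd > 0, satisfaction_noise_sd >= 0)
  coupling <- rep_len(coupling, n_couples)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Draw a feasible latent event sequence
#'
#' Partitions `[0, T)` into `K_true` contiguous events whose lengths are all
#' at least `max(3, floor(T / (3 * K_true)))`, so within-event trajectory
#' matrices are well defined.
#'
#' @param K_true Number of events.
#' @param T Number of TRs.
#' @param seed Integer seed; the same seed always yields the same boundaries.
#' @return Integer vector of the K_true - 1 interior boundaries (0-based TR
#'   index of the first TR of each event after the first), strictly
#'   increasing in `(0, T)`.
#' @export
generate_event_sequence <- function(K_true, T, seed = 1L) {
  stopifnot(K_true >= 1, T >= 1)
  if (K_true == 1L) return(integer(0))
  min_len <- max(3L, T %/% (3L * K_true))
  if (K_true * min_len > T) {
    stop(sprintf("cannot place %d events of length >= %d in %d TRs", K_true, min_len, T))
  }
  set.seed(seed)
  # lengths = min_len each + a random composition of the remainder
  extra <- T - K_true * min_len
  add <- if (extra > 0) tabulate(sample.int(K_true, extra, replace = TRUE), K_true) else integer(K_true)
  lens <- min_len + add
  cumsum(lens)[-K_true]
}

# boundaries -> per-TR event index (1-based events)
event_assignment <- function(boundaries, T) {
  findInterval(seq_len(T) - 1L, c(0L, boundaries)) # 0-based TRs
}

# moving-average(3) smoothing along rows' time axis, rescaled to keep unit
# variance for an iid N(0,1) input (interior kernel variance 1/3)
smooth_ma3 <- function(mat) {
  T <- ncol(mat)
  padded <- cbind(mat[, 1L], mat, mat[, T])
  sm <- (padded[, 1:T] + padded[, 2:(T + 1L)] + padded[, 3:(T + 2L)]) / 3
  sm * sqrt(3)
}

#' Generate CMQI-like satisfaction scores from coupling strengths
#'
#' score = 60 + slope * standardised(c) + N(0, noise_sd); classes follow the
#' CMQI threshold of 60 (`> 60` highly satisfied, otherwise low).
#'
#' @param c_values Per-couple coupling strengths.
#' @param slope Score units per SD of coupling; 0 decouples scores from c.
#' @param noise_sd Score noise SD; 0 makes score rank order equal c rank order.
#' @param seed Integer seed.
#' @return List with `scores` and `classes` (couple_high / couple_low).
#' @export
generate_satisfaction <- function(c_values, slope = 10, noise_sd = 5, seed = 1L) {
  set.seed(seed)
  n <- length(c_values)
  s <- stats::sd(c_values)
  std <- if (is.na(s) || s == 0) c_values - mean(c_values) else (c_values - mean(c_values)) / s
  scores <- 60 + slope * std + stats::rnorm(n, 0, noise_sd)
  # avoid ambiguous scores sitting exactly on the threshold
  scores[scores == 60] <- 60 + 1e-9
  list(scores = scores, classes = ifelse(scores > 60, "couple_high", "couple_low"))
}

#' Generate a synthetic dyadic dataset with known ground truth
#'
#' @param config A [synthetic_config()].
#' @return List with `dataset` (a `dyad_dataset`) and `ground_truth`
#'   (boundaries, per-couple coupling, satisfaction scores, seed).
#' @export
generate_dyad_timeseries <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  V <- config$voxels_per_roi; T <- config$n_trs
  boundaries <- generate_event_sequence(config$n_events, T, seed = config$seed)
  assign <- event_assignment(boundaries, T)

  set.seed(config$seed)
  male_ids <- sprintf("M%03d", seq_len(config$n_couples))
  female_ids <- sprintf("F%03d", seq_len(config$n_couples))

  ts_list <- vector("list", config$n_couples * 2L * config$n_rois)
  idx <- 0L
  for (roi in seq_len(config$n_rois)) {
    means <- matrix(stats::rnorm(V * config$n_events, 0, config$event_contrast),
                    V, config$n_events)
    base <- means[, assign, drop = FALSE] # V x T event scaffold, same for all
    for (cp in seq_len(config$n_couples)) {
      c_cp <- config$coupling[cp]
      shared <- smooth_ma3(matrix(stats::rnorm(V * T), V, T))
      for (spouse in 1:2) {
        idio <- smooth_ma3(matrix(stats::rnorm(V * T), V, T))
        sig <- base + sqrt(c_cp) * shared + sqrt(1 - c_cp) * idio +
          matrix(stats::rnorm(V * T, 0, config$noise_sd), V, T)
        sid <- if (spouse == 1) male_ids[cp] else female_ids[cp]
        idx <- idx + 1L
        ts_list[[idx]] <- roi_timeseries(sid, roi, sig)
      }
    }
  }

  sat <- generate_satisfaction(config$coupling, config$satisfaction_slope,
                               config$satisfaction_noise_sd,
                               seed = config$seed + 1L)
  dyads <- data.frame(
    dyad_id = sprintf("D%03d", seq_len(config$n_couples)),
    male_id = male_ids, female_id = female_ids,
    dyad_class = sat$classes, cmqi_score = sat$scores,
    marriage_duration = round(pmax(1, stats::rnorm(config$n_couples, 6.19, 5.25)), 1),
    stringsAsFactors = FALSE
  )
  parc <- data.frame(
    roi_id = seq_len(config$n_rois),
    roi_name = sprintf("ROI_%03d", seq_len(config$n_rois)),
    network = rep_len(NETWORKS, config$n_rois),
    stringsAsFactors = FALSE
  )
  ds <- dyad_dataset(ts_list, parc, dyads)
  list(dataset = ds,
       ground_truth = list(boundaries = boundaries,
                           event_assignment = assign,
                           coupling = config$coupling,
                           satisfaction = sat$scores,
                           seed = config$seed))
}

#' Write a synthetic dataset plus its ground truth to disk
#'
#' Produces the standard dataset layout plus `ground_truth.json`.
#'
#' @param sim Output of [generate_dyad_timeseries()].
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  mpath <- write_dataset(sim$dataset, dir)
  jsonlite::write_json(sim$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
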