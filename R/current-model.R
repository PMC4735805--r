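# Analytic bridge from cluster geometry to an ensemble sodium-current
# prediction: channels per cluster from cluster area and pore spacing,
# clusters sampled by a patch pipette on an amplified (folded) surface, and
# the aggregate peak current I = n_clusters * channels * g * V.

site_area_nm2 <- function(pore_spacing_nm, packing) {
  switch(packing,
         square = pore_spacing_nm^2,
         hexagonal = sqrt(3) / 2 * pore_spacing_nm^2,
         abort(sprintf("unknown packing '%s'", packing)))
}

#' Channels per cluster from cluster area
#'
#' `round(area / site_area)` with the per-channel site area set by the
#' pore-to-pore spacing and packing (`spacing^2` for square,
#' `sqrt(3)/2 * spacing^2` for hexagonal). At 33 nm spacing and square
#' packing, a 47,916 nm^2 cluster holds 44 channels.
#'
#' @param area_nm2 Cluster area (nm^2).
#' @param pore_spacing_nm Pore-to-pore channel spacing (nm; default 33).
#' @param packing `"square"` (default) or `"hexagonal"`.
#' @return Channel count (rounded).
#' @export
channels_from_cluster_area <- function(area_nm2, pore_spacing_nm = 33,
                                       packing = c("square", "hexagonal")) {
  packing <- match.arg(packing)
  if (any(area_nm2 <= 0) || pore_spacing_nm <= 0) {
    abort("area and pore spacing must be positive")
  }
  round(area_nm2 / site_area_nm2(pore_spacing_nm, packing))
}

#' Expected clusters under a patch pipette
#'
#' The membrane area sampled by a pipette of diameter `patch_diameter_um`
#' is the flat patch area times the surface amplification factor; dividing
#' by the per-cluster tile area (cluster spacing squared for square
#' packing, `sqrt(3)/2 *` spacing squared for hexagonal) gives the expected
#' cluster count. With a 2 um pipette, 6.5x amplification and 1 um square
#' spacing: `pi * 6.5 / 1 = 20.4`.
#'
#' @param patch_diameter_um Pipette diameter (um; default 2).
#' @param amplification Surface-area amplification factor (default 6.5).
#' @param cluster_spacing_um Inter-cluster distance (um; default 1).
#' @param packing Cluster tiling convention.
#' @return List with `expected` (unrounded) and `rounded`.
#' @export
clusters_under_patch <- function(patch_diameter_um = 2, amplification = 6.5,
                                 cluster_spacing_um = 1,
                                 packing = c("square", "hexagonal")) {
  packing <- match.arg(packing)
  stopifnot(patch_diameter_um > 0, amplification > 0, cluster_spacing_um > 0)
  tile <- switch(packing, square = cluster_spacing_um^2,
                 hexagonal = sqrt(3) / 2 * cluster_spacing_um^2)
  expected <- pi * (patch_diameter_um / 2)^2 * amplification / tile
  list(expected = expected, rounded = round(expected))
}

#' Predicted ensemble peak current under a patch
#'
#' `I = n_clusters * channels_per_cluster * g * V` with pS * mV -> pA unit
#' handling (10 pS x 60 mV = 0.6 pA per channel). The reference worked
#' example — 19 clusters of 44 channels at 10 pS and 60 mV — gives
#' 501.6 pA.
#'
#' @param n_clusters Clusters under the patch.
#' @param channels_per_cluster Channels per cluster (default 44).
#' @param g_pS Unitary conductance (pS; default 10).
#' @param v_mV Driving force (mV; default 60).
#' @return Current in pA.
#' @export
predicted_patch_current <- function(n_clusters, channels_per_cluster = 44,
                                    g_pS = 10, v_mV = 60) {
  stopifnot(n_clusters >= 0, channels_per_cluster >= 0, g_pS >= 0, v_mV >= 0)
  n_clusters * channels_per_cluster * g_pS * v_mV * 1e-3
}

#' Full current-model breakdown
#'
#' Composes [clusters_under_patch()] and [predicted_patch_current()] into a
#' per-channel / per-cluster / total current table.
#'
#' @inheritParams clusters_under_patch
#' @inheritParams predicted_patch_current
#' @param round_clusters Round the cluster count before computing the
#'   current (default `TRUE`, matching a count of discrete clusters).
#' @return Tibble with the parameter set and `per_channel_pA`,
#'   `per_cluster_pA`, `n_clusters`, `total_pA`.
#' @export
patch_current_breakdown <- function(patch_diameter_um = 2,
                                    amplification = 6.5,
                                    cluster_spacing_um = 1,
                                    packing = c("square", "hexagonal"),
                                    channels_per_cluster = 44, g_pS = 10,
                                    v_mV = 60, round_clusters = TRUE) {
  packing <- match.arg(packing)
  cl <- clusters_under_patch(patch_diameter_um, amplification,
                             cluster_spacing_um, packing)
  n <- if (round_clusters) cl$rounded else cl$expected
  per_channel <- g_pS * v_mV * 1e-3
  tibble(patch_diameter_um = patch_diameter_um,
         amplification = amplification,
         cluster_spacing_um = cluster_spacing_um, packing = packing,
         n_clusters = n, channels_per_cluster = channels_per_cluster,
         per_channel_pA = per_channel,
         per_cluster_pA = per_channel * channels_per_cluster,
         total_pA = predicted_patch_current(n, channels_per_cluster,
                                            g_pS, v_mV))
}
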