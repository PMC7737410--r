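# Electrode montage on a cylindrical forearm surface and the lead field
# mapping muscle sources to electrode gains.

#' Build a cylindrical forearm electrode montage
#'
#' Lays `n_rings * per_ring` electrodes on a regular cylindrical grid along
#' the forearm: rings of `per_ring` equally spaced circumferential positions
#' at constant axial spacing. The last grid channel is designated as the
#' ground-reference electrode and its position is moved to the hand dorsum
#' (beyond the distal end of the forearm), so a default 12 x 8 grid yields 96
#' recorded channels of which 95 sit on the forearm proper.
#'
#' @param n_rings Number of rings along the forearm axis (default 12).
#' @param per_ring Electrodes per ring (default 8).
#' @param forearm_length_mm Axial extent covered by the rings (default 240).
#' @param radius_mm Forearm radius used to convert angle to arc length
#'   (default 40).
#' @return An object of class `emg_montage`: list with `n_channels`,
#'   `positions` (data.frame: `channel`, `axial_mm`, `circ_deg`, `is_ground`),
#'   `ground_index`, `radius_mm`, and grid descriptors `n_rings`, `per_ring`.
#' @examples
#' m <- build_montage()
#' m$n_channels      # 96
#' m$ground_index    # 96
#' @export
build_montage <- function(n_rings = 12, per_ring = 8,
                          forearm_length_mm = 240, radius_mm = 40) {
  if (n_rings < 1 || per_ring < 1) {
    stop("n_rings and per_ring must be positive counts")
  }
  n <- n_rings * per_ring
  if (n < 2) {
    stop("montage must have at least 2 channels for pipeline use")
  }
  axial_spacing <- forearm_length_mm / n_rings
  axial <- rep(seq_len(n_rings) * axial_spacing - axial_spacing / 2,
               each = per_ring)
  circ <- rep(seq(0, 360 - 360 / per_ring, by = 360 / per_ring),
              times = n_rings)
  pos <- data.frame(
    channel = seq_len(n),
    axial_mm = axial,
    circ_deg = circ,
    is_ground = FALSE
  )
  # ground electrode: re-designate the last grid channel, placed on the hand
  # dorsum distal to the forearm, off the muscle volume
  ground_index <- n
  pos$axial_mm[ground_index] <- forearm_length_mm + 80
  pos$circ_deg[ground_index] <- 0
  pos$is_ground[ground_index] <- TRUE
  structure(
    list(
      n_channels = n,
      positions = pos,
      ground_index = ground_index,
      radius_mm = radius_mm,
      n_rings = n_rings,
      per_ring = per_ring,
      axial_spacing_mm = axial_spacing,
      forearm_length_mm = forearm_length_mm
    ),
    class = "emg_montage"
  )
}

#' Specify a simulated muscle or noise source
#'
#' @param kind `"superficial"`, `"deep"` or `"noise"`. Superficial sources
#'   project locally onto nearby electrodes; deep sources project diffusely
#'   across the forearm cross-section at their axial position; noise sources
#'   are untuned.
#' @param axial_mm,circ_deg,depth_mm Source position (depth 0 for
#'   superficial, > 0 for deep).
#' @param a0 Baseline activation level.
#' @param w Tuning weight (modulation depth); must be 0 for noise sources.
#' @param pd_deg Preferred direction in degrees.
#' @param frame `"intrinsic"` (tuning rotates with the forearm across elbow
#'   postures) or `"extrinsic"` (screen-fixed).
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(kind = c("superficial", "deep", "noise"),
                        axial_mm, circ_deg, depth_mm = 0,
                        a0 = 0.5, w = 0.4, pd_deg = 0,
                        frame = c("intrinsic", "extrinsic")) {
  kind <- match.arg(kind)
  frame <- match.arg(frame)
  if (w < 0) stop("tuning weight w must be >= 0")
  if (kind == "deep" && depth_mm <= 0) stop("deep sources need depth_mm > 0")
  if (kind == "noise" && w != 0) stop("noise sources must have w = 0")
  structure(
    list(kind = kind, axial_mm = axial_mm, circ_deg = circ_deg,
         depth_mm = depth_mm, a0 = a0, w = w, pd_deg = wrap_deg(pd_deg),
         frame = frame),
    class = "source_spec"
  )
}

#' Build the lead-field (gain) matrix from sources to electrodes
#'
#' Gains decay exponentially with distance on the cylindrical surface.
#' Superficial sources use one isotropic short length constant (about one
#' inter-electrode spacing) so their footprint is local. Deep sources use
#' the same short constant axially but a long circumferential constant
#' (about half the circumference), so their footprint spreads around the
#' ring at their axial position. Columns are scaled to unit maximum; the
#' ground electrode row is zero (it sits off the muscle volume).
#'
#' @param montage An `emg_montage`.
#' @param sources List of `source_spec` objects.
#' @param lambda_superficial_mm Length constant for superficial decay;
#'   default = inter-electrode axial spacing.
#' @param lambda_deep_circ_mm Circumferential length constant for deep
#'   sources; default = half circumference.
#' @return Non-negative matrix, channels x sources, entries in `[0, 1]`.
#' @export
make_leadfield <- function(montage, sources,
                           lambda_superficial_mm = NULL,
                           lambda_deep_circ_mm = NULL) {
  stopifnot(inherits(montage, "emg_montage"))
  if (length(sources) == 0) stop("empty source list")
  lam_s <- lambda_superficial_mm %||% montage$axial_spacing_mm
  circumference <- 2 * pi * montage$radius_mm
  lam_d <- lambda_deep_circ_mm %||% (circumference / 2)
  pos <- montage$positions
  A <- vapply(sources, function(src) {
    d_ax <- abs(pos$axial_mm - src$axial_mm)
    d_circ <- abs(ang_diff_deg(pos$circ_deg, src$circ_deg)) *
      pi / 180 * montage$radius_mm
    if (src$kind == "deep") {
      g <- exp(-d_ax / lam_s - d_circ / lam_d)
    } else {
      g <- exp(-sqrt(d_ax^2 + d_circ^2) / lam_s)
    }
    g[montage$ground_index] <- 0
    g / max(g)
  }, numeric(nrow(pos)))
  dimnames(A) <- list(NULL, NULL)
  A
}
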