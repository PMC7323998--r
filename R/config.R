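#' Simulation configuration for the two-wave ocular neural crest model
#'
#' Collects every tunable of the ground-truth generator: the frame grid, the
#' sizes and schedules of the two neural crest (NC) populations, motility and
#' division parameters, reporter kinetics and the genotype mode. Defaults are
#' the study conditions the simulator is calibrated to: the first (1NC) wave
#' delaminates laterally at 12-14 hpf and settles on the proximal eye
#' hemisphere; the second (2NC) wave arises mediodorsally at 16-17 hpf,
#' clusters near the dorsal eye rim during 18-22 hpf and migrates over the rim
#' into the distal hemisphere during 22-28 hpf, so that 20-30 cells occupy the
#' distal eye at the end of the entry window.
#'
#' @param dt_s seconds per frame. The default 20.4 s makes a 10-frame stride
#'   equal 3 min 24 s, the stride used for migration-angle sampling.
#' @param t_start_hpf,t_end_hpf simulated window, hours post fertilisation.
#' @param n_1nc,n_2nc founder counts for the two populations.
#' @param delamination_window_1nc,delamination_window_2nc birth windows (hpf).
#' @param cluster_window 2NC cluster phase (hpf).
#' @param entry_window 2NC dispersal/entry phase (hpf).
#' @param n_entering_2nc cap on the number of 2NC founder lineages programmed
#'   to enter the distal eye; must not exceed `n_2nc`.
#' @param division_rate_per_h per-cell Poisson division rate. The paper-scale
#'   biology gives no rate; 0.05/h is a free parameter.
#' @param division_window_hpf window in which divisions occur; divisions cease
#'   at cluster dissolution when cells enter the differentiation programme.
#' @param speed_um_per_min named per-population directed migration speed.
#' @param drift_um_per_min residual distal-ward drift speed of settled 1NC
#'   cells after 22 hpf.
#' @param drift_angle_deg direction of that drift in the horizontal plane,
#'   measured from anterior toward the distal side.
#' @param noise_sigma_um positional jitter, micrometres per sqrt(minute).
#' @param cluster_sd_um stationary spread of the 2NC cluster.
#' @param cluster_kappa_per_h mean-reversion rate of the cluster attraction.
#' @param genotype one of `"wildtype"`, `"pax6b_null"`, `"pax6_double_null"`.
#'   In both mutant modes the 2NC cluster persists periocularly; the double
#'   null additionally lets 1NC cells cross the equator into the distal
#'   hemisphere.
#' @param mixing_fraction probability that a founder lineage is programmed
#'   mixed-destination (its first division assigns divergent daughter
#'   programmes). Default 0.09 echoes the observed 9 percent.
#' @param wnt_wave2_fraction fraction of 2NC lineages carrying the second
#'   Wnt-reporter wave (default 0.5).
#' @param k_syn_per_h reporter (green EosFP) synthesis rate while the sox10
#'   promoter is active, arbitrary units per hour.
#' @param halflife_h fluorophore half-life in hours (both forms); 12 h keeps
#'   converted red fluorescence visible to about 48 hpf.
#' @param silencing_hpf named per-population promoter silencing times; the
#'   1NC promoter is off from 16 hpf, the 2NC promoter from 20 hpf.
#' @param wnt_peaks_hpf,wnt_amplitudes_au,wnt_sigmas_h the two Wnt-reporter
#'   activity waves (gaussian bumps in time).
#' @param division_sep_um displacement of each daughter from the division
#'   point; the default puts sister nuclei one nuclear diameter (7 um)
#'   apart, the minimum physically resolvable arrangement.
#' @param eye_radius_um eye sphere radius.
#' @param shell_um half-thickness of the ocular shell used when clamping
#'   settled cells to the eye surface.
#' @param mirrored logical; mirrors the embryo so the proximodistal unit
#'   vector flips sign along the mediolateral axis.
#' @param seed integer seed; all randomness of a simulation flows from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(dt_s = 20.4,
                              t_start_hpf = 11,
                              t_end_hpf = 31,
                              n_1nc = 90,
                              n_2nc = 22,
                              delamination_window_1nc = c(12, 14),
                              delamination_window_2nc = c(16, 17),
                              cluster_window = c(18, 22),
                              entry_window = c(22, 28),
                              n_entering_2nc = min(22L, n_2nc),
                              division_rate_per_h = 0.05,
                              division_window_hpf = c(12, 22),
                              speed_um_per_min = c("1NC" = 0.8, "2NC" = 1.5),
                              drift_um_per_min = 0.25,
                              drift_angle_deg = 55,
                              noise_sigma_um = 0.3,
                              cluster_sd_um = 9,
                              cluster_kappa_per_h = 1,
                              genotype = c("wildtype", "pax6b_null",
                                           "pax6_double_null"),
                              mixing_fraction = 0.09,
                              wnt_wave2_fraction = 0.5,
                              k_syn_per_h = 1,
                              halflife_h = 12,
                              silencing_hpf = c("1NC" = 16, "2NC" = 20),
                              wnt_peaks_hpf = c(14, 21),
                              wnt_amplitudes_au = c(30, 150),
                              wnt_sigmas_h = c(1, 2.5),
                              division_sep_um = 3.5,
                              eye_radius_um = 50,
                              shell_um = 6,
                              mirrored = FALSE,
                              seed = 1L) {
  genotype <- match.arg(genotype)
  cfg <- list(dt_s = dt_s, t_start_hpf = t_start_hpf, t_end_hpf = t_end_hpf,
              n_1nc = as.integer(n_1nc), n_2nc = as.integer(n_2nc),
              delamination_window_1nc = delamination_window_1nc,
              delamination_window_2nc = delamination_window_2nc,
              cluster_window = cluster_window,
              entry_window = entry_window,
              n_entering_2nc = as.integer(n_entering_2nc),
              division_rate_per_h = division_rate_per_h,
              division_window_hpf = division_window_hpf,
              speed_um_per_min = speed_um_per_min,
              drift_um_per_min = drift_um_per_min,
              drift_angle_deg = drift_angle_deg,
              noise_sigma_um = noise_sigma_um,
              cluster_sd_um = cluster_sd_um,
              cluster_kappa_per_h = cluster_kappa_per_h,
              genotype = genotype,
              mixing_fraction = mixing_fraction,
              wnt_wave2_fraction = wnt_wave2_fraction,
              k_syn_per_h = k_syn_per_h,
              halflife_h = halflife_h,
              silencing_hpf = silencing_hpf,
              wnt_peaks_hpf = wnt_peaks_hpf,
              wnt_amplitudes_au = wnt_amplitudes_au,
              wnt_sigmas_h = wnt_sigmas_h,
              division_sep_um = division_sep_um,
              eye_radius_um = eye_radius_um,
              shell_um = shell_um,
              mirrored = isTRUE(mirrored),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname simulation_config
#' @param config object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    chk_win <- function(w, nm) {
      if (length(w) != 2 || w[1] > w[2] ||
          w[1] < t_start_hpf - 1e-9 || w[2] > t_end_hpf + 1e-9)
        .stopf("window %s = [%s] must be ordered and within [%s, %s] hpf",
               nm, paste(w, collapse = ", "), t_start_hpf, t_end_hpf)
    }
    if (dt_s <= 0) .stopf("dt_s must be positive")
    if (t_end_hpf <= t_start_hpf) .stopf("t_end_hpf must exceed t_start_hpf")
    chk_win(delamination_window_1nc, "delamination_window_1nc")
    chk_win(delamination_window_2nc, "delamination_window_2nc")
    chk_win(cluster_window, "cluster_window")
    chk_win(entry_window, "entry_window")
    if (delamination_window_2nc[1] < delamination_window_1nc[1])
      .stopf("2NC delamination must not precede 1NC delamination")
    for (f in c(mixing_fraction, wnt_wave2_fraction))
      if (f < 0 || f > 1) .stopf("fractions must lie in [0, 1]")
    if (n_1nc < 0 || n_2nc < 0) .stopf("population sizes must be >= 0")
    if (n_entering_2nc > n_2nc)
      .stopf("n_entering_2nc (%d) must not exceed n_2nc (%d)",
             n_entering_2nc, n_2nc)
    if (division_rate_per_h < 0) .stopf("division_rate_per_h must be >= 0")
    if (eye_radius_um <= 0) .stopf("eye_radius_um must be positive")
    if (!all(c("1NC", "2NC") %in% names(speed_um_per_min)))
      .stopf("speed_um_per_min must be named for populations 1NC and 2NC")
  })
  invisible(config)
}

#' Frame time grid of a configuration
#'
#' @param config a `sim_config`.
#' @return numeric vector of frame times in hpf (frame index 0 maps to
#'   element 1).
#' @export
frame_times <- function(config) {
  seq(config$t_start_hpf, config$t_end_hpf, by = config$dt_s / 3600)
}
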