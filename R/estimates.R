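#' Microwell geometry
#'
#' The experimental compartment is a sealed cylinder (radius 50 um, height
#' 20 um). Order-of-magnitude estimates use pi ~ 3 (`pi_mode = "approx3"`).
#'
#' @param radius_um cylinder radius, um. Default 50.
#' @param height_um cylinder height, um. Default 20.
#' @param pi_mode `"exact"` or `"approx3"`.
#' @return list of class `microwell_geometry`.
#' @export
microwell_geometry <- function(radius_um = 50, height_um = 20,
                               pi_mode = c("approx3", "exact")) {
  stopifnot(radius_um > 0, height_um > 0)
  structure(list(radius_um = radius_um, height_um = height_um,
                 pi_mode = match.arg(pi_mode)),
            class = "microwell_geometry")
}

.pi_value <- function(pi_mode) if (pi_mode == "approx3") 3 else pi

#' Physical constants used by the molecular estimates
#'
#' @param omega molecules per (uM um^3); ~600 (1 uM is about 600 molecules
#'   per cubic micron). Default 600.
#' @param subunit_rise_um filament length per subunit, um. Default 0.0027.
#' @param mean_filament_length_um mean filament length in branched networks,
#'   um. Default 0.3.
#' @return list of class `estimate_constants`.
#' @export
estimate_constants <- function(omega = 600, subunit_rise_um = 0.0027,
                               mean_filament_length_um = 0.3) {
  stopifnot(omega > 0, subunit_rise_um > 0, mean_filament_length_um > 0)
  structure(list(omega = omega, subunit_rise_um = subunit_rise_um,
                 mean_filament_length_um = mean_filament_length_um),
            class = "estimate_constants")
}

#' Microwell volume
#'
#' `W = pi R^2 H`; with pi ~ 3, R = 50 um and H = 20 um this is
#' 1.5e5 um^3 (= 150 pl).
#'
#' @param geom a [microwell_geometry()].
#' @return volume, um^3.
#' @export
well_volume <- function(geom) {
  stopifnot(inherits(geom, "microwell_geometry"))
  .pi_value(geom$pi_mode) * geom$radius_um^2 * geom$height_um
}

#' Molecule count from concentration and volume
#'
#' `omega * volume * concentration`; 3 uM actin in 1.5e5 um^3 is ~3e8
#' subunits.
#'
#' @param conc_uM concentration, uM.
#' @param volume_um3 compartment volume, um^3.
#' @param omega molecules per (uM um^3). Default 600.
#' @param sig_figs optional significant-figure rounding of the returned
#'   count.
#' @return molecule count.
#' @export
molecule_count <- function(conc_uM, volume_um3, omega = 600,
                           sig_figs = NULL) {
  stopifnot(conc_uM >= 0, volume_um3 >= 0, omega > 0)
  n <- omega * volume_um3 * conc_uM
  if (!is.null(sig_figs)) signif(n, sig_figs) else n
}

#' Total filament length from a subunit count
#'
#' `n_subunits * subunit_rise`; 1.5e8 subunits at 2.7 nm each is ~4e5 um.
#'
#' @param n_subunits number of polymerized subunits.
#' @param subunit_rise length per subunit, um. Default 0.0027.
#' @param sig_figs optional significant-figure rounding.
#' @return total length, um.
#' @export
subunits_to_length <- function(n_subunits, subunit_rise = 0.0027,
                               sig_figs = NULL) {
  stopifnot(n_subunits >= 0, subunit_rise > 0)
  l <- n_subunits * subunit_rise
  if (!is.null(sig_figs)) signif(l, sig_figs) else l
}

#' Filaments per tail cross-section
#'
#' Total filament length over tail length: ~4e5/60 ~ 6,700 filaments cross
#' any section of the tail.
#'
#' @param total_length_um total filament length, um.
#' @param tail_length_um comet tail length, um.
#' @param sig_figs significant figures for the reported count. Default 2.
#' @return filament count per cross-section.
#' @export
filaments_per_cross_section <- function(total_length_um, tail_length_um,
                                        sig_figs = 2) {
  if (tail_length_um <= 0) stop("tail length must be positive")
  signif(total_length_um / tail_length_um, sig_figs)
}

#' Network mesh size
#'
#' `zeta = sqrt(cross_section_area / N_fil)` in nm: average spacing between
#' neighboring filaments; ~40 nm for ~6,700 filaments in ~12 um^2.
#'
#' @param cross_section_um2 tail cross-section area, um^2.
#' @param n_fil filaments per cross-section.
#' @return mesh size, nm.
#' @export
mesh_size <- function(cross_section_um2, n_fil) {
  stopifnot(cross_section_um2 > 0, n_fil > 0)
  sqrt(cross_section_um2 / n_fil) * 1000
}

#' Number of filaments in the tail
#'
#' Total filament length over the mean filament length (~300 nm in branched
#' networks): ~1.3e6 filaments.
#'
#' @param total_length_um total filament length, um.
#' @param mean_filament_length_um mean filament length, um. Default 0.3.
#' @param sig_figs significant figures. Default 2.
#' @return filament count.
#' @export
filament_count <- function(total_length_um, mean_filament_length_um = 0.3,
                           sig_figs = 2) {
  if (mean_filament_length_um <= 0) stop("mean filament length must be positive")
  signif(total_length_um / mean_filament_length_um, sig_figs)
}

#' Fraction of the Arp2/3 pool engaged in the tail
#'
#' Assuming one branch junction (one Arp2/3 complex) per filament:
#' `100 * n_filaments / n_arp_total`, in percent. With 1.3e6 filaments and
#' 1e7 complexes this is 13%.
#'
#' @param n_filaments filaments in the tail.
#' @param n_arp_total total Arp2/3 complexes in the well.
#' @return percent.
#' @export
arp_fraction <- function(n_filaments, n_arp_total) {
  if (n_arp_total <= 0) stop("n_arp_total must be positive")
  stopifnot(n_filaments >= 0)
  100 * n_filaments / n_arp_total
}

#' Pool length-equivalent from the mean comet length and tail fraction
#'
#' If a fraction `f` of the pool builds a tail of mean length `L`, the full
#' pool corresponds to `L / f`: 63 um / 0.57 ~ 110 um, the canonical
#' conversion between polymerized length and pool consumption.
#'
#' @param mean_comet_length_um mean comet length, um.
#' @param tail_fraction fraction of the pool in the tail, in (0, 1].
#' @param sig_figs significant figures. Default 2.
#' @return pool length-equivalent, um.
#' @export
pool_length_equivalent <- function(mean_comet_length_um, tail_fraction,
                                   sig_figs = 2) {
  if (tail_fraction <= 0 || tail_fraction > 1)
    stop("tail_fraction must lie in (0, 1]")
  signif(mean_comet_length_um / tail_fraction, sig_figs)
}

#' Bead density ratio between two compartments
#'
#' `(n1/vol1) / (n2/vol2)` (any consistent volume unit). One bead per
#' 140-pl microwell vs ~20 beads per 120,000-pl field of view gives ~43,
#' i.e. the order-of-magnitude "50 times more diluted".
#'
#' @param n1,vol1 bead count and volume of compartment 1.
#' @param n2,vol2 bead count and volume of compartment 2.
#' @return dimensionless density ratio.
#' @export
bead_density_ratio <- function(n1, vol1, n2, vol2) {
  stopifnot(n1 > 0, vol1 > 0, n2 > 0, vol2 > 0)
  (n1 / vol1) / (n2 / vol2)
}

#' Full back-of-envelope report for the microwell system
#'
#' Chains the geometric and molecular estimates: well volume, subunit and
#' regulator counts, tail subunits and total filament length, filaments per
#' cross-section, mesh size, filament number, Arp2/3 engagement, pool
#' length-equivalent and bead-density comparison. Every entry carries the
#' exact value plus a rounded value and the rounding mode, since the
#' source arithmetic mixes pi ~ 3 with one- and two-significant-figure
#' rounding.
#'
#' @param geom a [microwell_geometry()].
#' @param constants an [estimate_constants()].
#' @param actin_uM total actin, uM. Default 3.
#' @param arp_uM Arp2/3 complex, uM. Default 0.09.
#' @param cp_uM capping protein, uM. Default 0.015.
#' @param tail_subunit_fraction fraction of subunits in the longest tail.
#'   Default 0.5.
#' @param max_tail_length_um maximal tail length in assembly conditions,
#'   um. Default 60.
#' @param tail_cross_section_um2 tail cross-section area, um^2. Default 12.
#' @param mean_comet_length_um mean comet length, um. Default 63.
#' @param measured_tail_fraction measured fraction of pool in the tail.
#'   Default 0.57.
#' @return list of class `estimate_report`; each element a list with
#'   `value` (exact chain), `rounded` (chain in which every intermediate is
#'   rounded the way the source arithmetic rounds it before being reused),
#'   `rounding`, `units`.
#' @export
estimate_report <- function(geom = microwell_geometry(),
                            constants = estimate_constants(),
                            actin_uM = 3, arp_uM = 0.09, cp_uM = 0.015,
                            tail_subunit_fraction = 0.5,
                            max_tail_length_um = 60,
                            tail_cross_section_um2 = 12,
                            mean_comet_length_um = 63,
                            measured_tail_fraction = 0.57) {
  entry <- function(value, rounded, rounding, units)
    list(value = value, rounded = rounded, rounding = rounding,
         units = units)
  # exact chain
  W <- well_volume(geom)
  n_actin <- molecule_count(actin_uM, W, constants$omega)
  n_arp <- molecule_count(arp_uM, W, constants$omega)
  n_cp <- molecule_count(cp_uM, W, constants$omega)
  n_tail <- tail_subunit_fraction * n_actin
  L_tot <- subunits_to_length(n_tail, constants$subunit_rise_um)
  # rounded chain: each intermediate rounded before reuse, matching the
  # order-of-magnitude arithmetic this reproduces
  W_r <- signif(W, 2)
  n_actin_r <- signif(molecule_count(actin_uM, W_r, constants$omega), 1)
  n_arp_oom <- 10^round(log10(molecule_count(arp_uM, W_r, constants$omega)))
  n_tail_r <- tail_subunit_fraction * n_actin_r
  L_tot_r <- signif(subunits_to_length(n_tail_r, constants$subunit_rise_um), 1)
  n_fil_cs_r <- filaments_per_cross_section(L_tot_r, max_tail_length_um)
  zeta_r <- signif(mesh_size(tail_cross_section_um2, n_fil_cs_r), 1)
  n_fil_r <- filament_count(L_tot_r, constants$mean_filament_length_um)
  arp_pct_r <- signif(arp_fraction(n_fil_r, n_arp_oom), 2)
  pool_len_r <- pool_length_equivalent(mean_comet_length_um,
                                       measured_tail_fraction)
  dens <- bead_density_ratio(1, 140, 20, 120000)
  structure(list(
    volume_um3 = entry(W, W_r,
                       sprintf("pi %s, 2 sig figs", geom$pi_mode), "um^3"),
    n_actin_subunits = entry(n_actin, n_actin_r, "1 sig fig", ""),
    n_arp_complexes = entry(n_arp, n_arp_oom,
                            "order of magnitude (exact 8.1e6 ~ 1e7)", ""),
    n_capping_protein = entry(
      n_cp, signif(n_cp, 2),
      "2 sig figs (exact 1.35e6; commonly quoted as 1.5e6)", ""),
    n_tail_subunits = entry(n_tail, n_tail_r, "half of the 1-sig-fig count",
                            ""),
    total_filament_length_um = entry(L_tot, L_tot_r, "1 sig fig", "um"),
    n_fil_cross_section = entry(L_tot / max_tail_length_um, n_fil_cs_r,
                                "2 sig figs of rounded chain", ""),
    mesh_size_nm = entry(mesh_size(tail_cross_section_um2,
                                   L_tot / max_tail_length_um),
                         zeta_r, "1 sig fig of rounded chain", "nm"),
    filament_count = entry(L_tot / constants$mean_filament_length_um, n_fil_r,
                           "2 sig figs of rounded chain", ""),
    arp_fraction_percent = entry(
      arp_fraction(L_tot / constants$mean_filament_length_um, n_arp),
      arp_pct_r, "2 sig figs of rounded chain", "%"),
    pool_length_um = entry(mean_comet_length_um / measured_tail_fraction,
                           pool_len_r, "2 sig figs", "um"),
    bead_density_ratio = entry(dens, signif(dens, 1),
                               "1 sig fig (order of magnitude ~50)", "")
  ), class = "estimate_report")
}

#' @export
print.estimate_report <- function(x, ...) {
  cat("microwell back-of-envelope estimates:\n")
  for (nm in names(x)) {
    e <- x[[nm]]
    cat(sprintf("  %-26s %-12.5g (rounded %.5g %s; %s)\n", nm, e$value,
                e$rounded, e$units, e$rounding))
  }
  invisible(x)
}
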