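#' Specify an unmyelinated axon
#'
#' Geometry, passive membrane and channel populations of a cylindrical,
#' unbranched axon. The compartment length must not exceed one tenth of the
#' passive length constant lambda = sqrt(R_m d / (4 R_a)).
#'
#' @param diameter_um axon diameter (um).
#' @param length_um axon length (um).
#' @param dx_um compartment length (um).
#' @param cm_uF_cm2 specific membrane capacitance (uF/cm^2).
#' @param ra_ohm_cm axial resistivity (Ohm cm).
#' @param g_leak_mS_cm2 leak conductance density (mS/cm^2).
#' @param e_leak_mV leak reversal potential (mV).
#' @param v_rest_mV resting potential (mV).
#' @param channels list of channel populations, each
#'   `list(scheme = <kinetic_scheme>, density_um2 = <channels per um^2>)`.
#'   Channel counts per compartment are `round(density * pi * d * dx)`.
#' @param temperature_C nominal temperature of the kinetics (degC); recorded
#'   in metadata only -- rate functions are used at the temperature of their
#'   source recordings, with no additional Q10 scaling.
#' @return an object of class `axon_spec`.
#' @export
axon_spec <- function(diameter_um, length_um, dx_um = 10,
                      cm_uF_cm2 = 1, ra_ohm_cm = 35.4,
                      g_leak_mS_cm2 = 0.3, e_leak_mV = -54.4,
                      v_rest_mV = -65, channels = list(),
                      temperature_C = NA_real_) {
  stopifnot(diameter_um > 0, length_um > 0, dx_um > 0, g_leak_mS_cm2 > 0)
  lam <- lambda_um(diameter_um, ra_ohm_cm, g_leak_mS_cm2)
  if (dx_um > 0.1 * lam)
    stop("compartment length ", dx_um, " um violates the lambda/10 rule ",
         "(lambda = ", round(lam, 1), " um; need dx <= ", round(0.1 * lam, 2),
         " um)")
  for (ch in channels) {
    stopifnot(inherits(ch$scheme, "kinetic_scheme"), ch$density_um2 >= 0)
  }
  structure(list(diameter_um = diameter_um, length_um = length_um,
                 dx_um = dx_um, cm_uF_cm2 = cm_uF_cm2,
                 ra_ohm_cm = ra_ohm_cm, g_leak_mS_cm2 = g_leak_mS_cm2,
                 e_leak_mV = e_leak_mV, v_rest_mV = v_rest_mV,
                 channels = channels, temperature_C = temperature_C,
                 lambda_um = lam),
            class = "axon_spec")
}

#' Passive length constant of a cylindrical cable
#'
#' lambda = sqrt(R_m d / (4 R_a)) with R_m = 1000 / g_leak (Ohm cm^2).
#'
#' @inheritParams axon_spec
#' @return length constant in um.
#' @export
lambda_um <- function(diameter_um, ra_ohm_cm, g_leak_mS_cm2) {
  rm_ohm_cm2 <- 1000 / g_leak_mS_cm2
  d_cm <- diameter_um * 1e-4
  1e4 * sqrt(rm_ohm_cm2 * d_cm / (4 * ra_ohm_cm))
}

#' @export
print.axon_spec <- function(x, ...) {
  cat("Axon: d =", x$diameter_um, "um, L =", x$length_um, "um, dx =",
      x$dx_um, "um (", round(x$length_um / x$dx_um), "compartments)\n")
  cat("  Cm =", x$cm_uF_cm2, "uF/cm2, Ra =", x$ra_ohm_cm, "Ohm cm, gL =",
      x$g_leak_mS_cm2, "mS/cm2 (lambda =", round(x$lambda_um), "um)\n")
  cat("  EL =", x$e_leak_mV, "mV, Vrest =", x$v_rest_mV, "mV, T =",
      x$temperature_C, "C\n")
  for (ch in x$channels)
    cat("  channels:", ch$scheme$name, "-", ch$density_um2, "/um2\n")
  invisible(x)
}

#' Table of standard axon parameter sets
#'
#' Returns one of the four standard axon models as an [axon_spec()]:
#' `squid_hh` (squid giant axon, canonical gate kinetics, 6.3 degC),
#' `squid_patlak` (squid giant axon, delayed-opening Na+ kinetics),
#' `rat_interneuron` (fast-spiking hippocampal interneuron kinetics, 35 degC)
#' and `c_fibre` (unmyelinated C-fibre, 24 degC). The `squid_patlak` and
#' `c_fibre` kinetic schemes are not built in and must be supplied via
#' `na_scheme` / `k_scheme`; densities, conductances, reversals and passive
#' parameters are preset for all four.
#'
#' @param name preset name.
#' @param diameter_um axon diameter (um).
#' @param length_um axon length (um).
#' @param dx_um compartment length (um).
#' @param na_scheme,k_scheme user-supplied [kinetic_scheme()]s for presets
#'   whose kinetics are configuration-supplied.
#' @param ... overrides passed on to [axon_spec()] (e.g. `g_leak_mS_cm2`).
#' @return an [axon_spec()].
#' @examples
#' preset <- axon_preset("rat_interneuron", diameter_um = 0.2)
#' preset$channels[[1]]$density_um2  # 23 Na+ channels per um^2
#' @export
axon_preset <- function(name = c("squid_hh", "squid_patlak",
                                 "rat_interneuron", "c_fibre"),
                        diameter_um = 0.2, length_um = 2000, dx_um = 10,
                        na_scheme = NULL, k_scheme = NULL, ...) {
  name <- match.arg(name)
  pars <- switch(name,
    squid_hh = list(cm = 1, ra = 35.4, gl = 0.3, el = -54.4,
                    dna = 60, gna = 20, ena = 50,
                    dk = 18, gk = 20, ek = -77, temp = 6.3),
    squid_patlak = list(cm = 1, ra = 35.4, gl = 0.3, el = -54.4,
                        dna = 60, gna = 20, ena = 50,
                        dk = 18, gk = 20, ek = -77, temp = 6.3),
    rat_interneuron = list(cm = 1, ra = 70, gl = 0.1, el = -65,
                           dna = 23, gna = 15, ena = 55,
                           dk = 6, gk = 14, ek = -90, temp = 35),
    c_fibre = list(cm = 0.81, ra = 70, gl = 0.14, el = -61.14,
                   dna = 62.5, gna = 20, ena = 79.6,
                   dk = 10, gk = 17, ek = -85, temp = 24))
  if (name == "squid_hh") {
    sch <- hh_squid_schemes(pars$gna, pars$gk, pars$ena, pars$ek)
  } else if (name == "rat_interneuron") {
    sch <- interneuron_schemes(pars$gna, pars$gk, pars$ena, pars$ek)
  } else {
    if (is.null(na_scheme) || is.null(k_scheme))
      stop("preset '", name, "' requires user-supplied kinetic schemes ",
           "(na_scheme, k_scheme): its published kinetics are not built in")
    sch <- list(na = na_scheme, k = k_scheme)
  }
  args <- list(diameter_um = diameter_um, length_um = length_um,
               dx_um = dx_um, cm_uF_cm2 = pars$cm, ra_ohm_cm = pars$ra,
               g_leak_mS_cm2 = pars$gl, e_leak_mV = pars$el,
               v_rest_mV = -65,
               channels = list(list(scheme = sch$na, density_um2 = pars$dna),
                               list(scheme = sch$k, density_um2 = pars$dk)),
               temperature_C = pars$temp)
  over <- list(...)
  args[names(over)] <- over
  do.call(axon_spec, args)
}

#' Discretize an axon specification into a compartmental cable
#'
#' Builds the per-compartment capacitances, axial coupling conductances,
#' leak conductances and channel counts, with channel states initialized at
#' the resting-potential stationary distribution and sealed (zero axial
#' flux) boundary conditions at both ends.
#'
#' @param spec an [axon_spec()].
#' @return an object of class `cable`: compartment arrays plus, per channel
#'   population, the integer channel count and the equilibrium distribution
#'   used for initialization.
#' @export
build_cable <- function(spec) {
  stopifnot(inherits(spec, "axon_spec"))
  n_comp <- round(spec$length_um / spec$dx_um)
  if (n_comp < 1) stop("axon shorter than one compartment")
  area_cm2 <- pi * spec$diameter_um * spec$dx_um * 1e-8
  cap_nF <- spec$cm_uF_cm2 * area_cm2 * 1e3
  g_leak_uS <- spec$g_leak_mS_cm2 * area_cm2 * 1e3
  d_cm <- spec$diameter_um * 1e-4
  dx_cm <- spec$dx_um * 1e-4
  g_ax_uS <- 1e6 * pi * d_cm^2 / (4 * spec$ra_ohm_cm * dx_cm)
  pops <- lapply(spec$channels, function(ch) {
    n_per_comp <- round(ch$density_um2 * pi * spec$diameter_um * spec$dx_um)
    list(scheme = ch$scheme, n_per_comp = n_per_comp,
         eq = equilibrium_distribution(ch$scheme, spec$v_rest_mV))
  })
  structure(list(spec = spec, n_comp = n_comp,
                 cap_nF = rep(cap_nF, n_comp),
                 g_leak_uS = rep(g_leak_uS, n_comp),
                 g_ax_uS = rep(g_ax_uS, max(n_comp - 1, 1))[seq_len(max(n_comp - 1, 0))],
                 pops = pops),
            class = "cable")
}

#' @export
print.cable <- function(x, ...) {
  cat("Cable:", x$n_comp, "compartments of", x$spec$dx_um, "um\n")
  for (p in x$pops)
    cat("  ", p$scheme$name, ":", p$n_per_comp, "channels/compartment\n")
  invisible(x)
}
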