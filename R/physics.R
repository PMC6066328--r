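# Closed-form single-bond kinetics (Bell-Evans) and the two-state extended
# freely jointed chain (FJC) description of PEG tethers. These are the pure
# physical primitives shared by the simulator and every fitting stage.

EULER_GAMMA <- 0.577215664901532861

#' Bell-Evans kinetic parameters of a slip bond
#'
#' Bundles the intrinsic off-rate at zero force \eqn{k^0_{off}}, the distance
#' from the bound state to the transition barrier along the pulling coordinate
#' \eqn{x_\beta}, and the thermal energy \eqn{k_BT}. Under the Bell-Evans
#' picture a tensile force F tilts the energy landscape so the off-rate grows
#' as \eqn{k(F) = k^0_{off} \exp(F x_\beta / k_BT)}.
#'
#' @param k0_off Intrinsic off-rate at zero force (1/s). `1/k0_off` is the
#'   intrinsic bond lifetime.
#' @param x_beta Width of the transition energy barrier (nm).
#' @param kBT Thermal energy (pN nm). Default 4.114 corresponds to 25 C.
#' @return An object of class `kinetic_params`.
#' @examples
#' kin <- kinetic_params(k0_off = 0.2, x_beta = 0.3)
#' bell_off_rate(50, kin)
#' @export
kinetic_params <- function(k0_off, x_beta, kBT = 4.114) {
  check_scalar(k0_off, "k0_off")
  check_scalar(x_beta, "x_beta")
  check_scalar(kBT, "kBT")
  structure(list(k0_off = k0_off, x_beta = x_beta, kBT = kBT),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Bell-Evans bond: k0_off = %.4g 1/s (lifetime %.3g s), x_beta = %.3g nm, kBT = %.4g pN nm\n",
              x$k0_off, 1 / x$k0_off, x$x_beta, x$kBT))
  invisible(x)
}

#' Two-state extended freely jointed chain tether
#'
#' Describes a PEG tether whose monomers interconvert between a short helical
#' conformer and a long planar conformer under force, with Langevin alignment
#' of Kuhn segments and a per-monomer backbone elasticity in series. The
#' defaults describe two MW-5000 PEG spacers in series (one on the tip, one on
#' the substrate), the geometry in which a specific single-bond rupture
#' stretches both tethers; the monomer lengths, conformer free-energy gap and
#' Kuhn length are literature-typical values for PEG in aqueous buffer, not
#' quantities measured here, and every one is overridable.
#'
#' @param n_monomers Total monomer count of the (series) tether. Default 226
#'   = 2 x ~113 monomers per MW-5000 PEG.
#' @param l_planar Planar-conformer monomer length (nm).
#' @param l_helical Helical-conformer monomer length (nm).
#' @param delta_g0 Conformer free-energy gap at zero force (units of kBT).
#' @param kuhn_length Kuhn segment length (nm).
#' @param monomer_stiffness Per-monomer backbone elasticity (pN/nm per
#'   monomer); the chain stiffness is `monomer_stiffness / n_monomers`.
#'   Default gives 150 pN/nm for a single 113-mer.
#' @param kBT Thermal energy (pN nm).
#' @return An object of class `tether_model`. The contour length
#'   `Lc = n_monomers * l_planar` is available via [contour_length()].
#' @export
tether_model <- function(n_monomers = 226, l_planar = 0.358, l_helical = 0.28,
                         delta_g0 = 3, kuhn_length = 0.7,
                         monomer_stiffness = 150 * 113, kBT = 4.114) {
  check_scalar(n_monomers, "n_monomers")
  if (n_monomers < 1) abort_domain("'n_monomers' must be >= 1")
  check_scalar(l_planar, "l_planar")
  check_scalar(l_helical, "l_helical")
  if (l_planar <= l_helical)
    abort_domain("'l_planar' must exceed 'l_helical' (planar is the long conformer)")
  check_scalar(delta_g0, "delta_g0", positive = FALSE)
  check_scalar(kuhn_length, "kuhn_length")
  check_scalar(monomer_stiffness, "monomer_stiffness")
  check_scalar(kBT, "kBT")
  structure(list(n_monomers = n_monomers, l_planar = l_planar,
                 l_helical = l_helical, delta_g0 = delta_g0,
                 kuhn_length = kuhn_length,
                 monomer_stiffness = monomer_stiffness, kBT = kBT),
            class = "tether_model")
}

#' @export
print.tether_model <- function(x, ...) {
  cat(sprintf("Extended FJC tether: n = %.4g monomers, Lc = %.4g nm, Kuhn length %.3g nm\n",
              x$n_monomers, contour_length(x), x$kuhn_length))
  invisible(x)
}

#' Contour length of a tether
#'
#' @param tether A [tether_model()].
#' @return `n_monomers * l_planar` in nm.
#' @export
contour_length <- function(tether) tether$n_monomers * tether$l_planar

# Same tether with a different monomer count (attachment-point / MW variation).
tether_with_n <- function(tether, n) {
  tether$n_monomers <- n
  tether
}

#' Force-dependent off-rate of a Bell-Evans bond
#'
#' \eqn{k(F) = k^0_{off} \exp(F x_\beta / k_BT)}.
#'
#' @param force Tensile force (pN), non-negative; vectorised.
#' @param kin A [kinetic_params()].
#' @return Off-rate(s) in 1/s, strictly increasing in force.
#' @export
bell_off_rate <- function(force, kin) {
  if (any(!is.finite(force)) || any(force < 0))
    abort_domain("'force' must be finite and >= 0 (tensile forces are positive)")
  kin$k0_off * exp(force * kin$x_beta / kin$kBT)
}

#' Most probable rupture force at a given loading rate
#'
#' The mode of the Bell-Evans rupture-force distribution under a constant
#' loading rate r: \eqn{F^* = (k_BT/x_\beta)\,\ln(r x_\beta / (k^0_{off} k_BT))},
#' clamped at zero for loading rates below \eqn{k^0_{off} k_BT / x_\beta}
#' (a negative most-probable force is unphysical; such slow ramps rupture
#' thermally near zero force).
#'
#' @param rate Loading rate (pN/s), positive; vectorised.
#' @param kin A [kinetic_params()].
#' @return Force(s) in pN.
#' @export
most_probable_force <- function(rate, kin) {
  if (any(!is.finite(rate)) || any(rate <= 0))
    abort_domain("'rate' (loading rate) must be finite and > 0")
  b <- kin$kBT / kin$x_beta
  pmax(0, b * log(rate / (kin$k0_off * b)))
}

#' Bell-Evans rupture-force probability density
#'
#' First-passage density of rupture at force F under a constant loading rate:
#' \deqn{p(F) = \frac{k(F)}{r} \exp\!\left[\frac{k^0_{off} k_BT}{x_\beta r}
#'   \left(1 - e^{F x_\beta / k_BT}\right)\right].}
#' Normalised over \eqn{[0, \infty)}; unimodal with mode at the unclamped
#' [most_probable_force()].
#'
#' @param force Force grid (pN), non-negative; vectorised.
#' @param rate Loading rate (pN/s), positive scalar.
#' @param kin A [kinetic_params()].
#' @return Density values (1/pN).
#' @export
rupture_force_pdf <- function(force, rate, kin) {
  if (any(!is.finite(force)) || any(force < 0))
    abort_domain("'force' must be finite and >= 0")
  check_scalar(rate, "rate")
  b <- kin$kBT / kin$x_beta
  cc <- kin$k0_off * b / rate
  # log-space guards against overflow of exp(F/b) at large F
  lp <- log(kin$k0_off) + force / b - log(rate) + cc * (1 - exp(force / b))
  exp(lp)
}

# exp(c) * E1(c), the scaled exponential integral, stable for small and
# large c. Appears in the exact mean of the Bell-Evans density.
e1_scaled <- function(cc) {
  out <- numeric(length(cc))
  big <- cc > 40
  if (any(!big)) {
    v <- cc[!big]
    out[!big] <- exp(v) * pracma::expint(v)
  }
  if (any(big)) {
    v <- cc[big]  # asymptotic series of e^c E1(c)
    out[big] <- (1 - 1 / v + 2 / v^2 - 6 / v^3) / v
  }
  out
}

#' Mean rupture force of the Bell-Evans distribution
#'
#' Exact mean of [rupture_force_pdf()]:
#' \eqn{\langle F\rangle = b\, e^{c} E_1(c)} with \eqn{b = k_BT/x_\beta} and
#' \eqn{c = k^0_{off} b / r}. For fast loading (\eqn{c \ll 1}) this approaches
#' the familiar \eqn{F^* - \gamma b}, i.e. the mean sits about
#' \eqn{0.577\,k_BT/x_\beta} below the most probable force. This is the
#' response curve against which per-cluster mean forces are fitted.
#'
#' @inheritParams most_probable_force
#' @return Mean force(s) in pN.
#' @export
mean_rupture_force <- function(rate, kin) {
  if (any(!is.finite(rate)) || any(rate <= 0))
    abort_domain("'rate' (loading rate) must be finite and > 0")
  b <- kin$kBT / kin$x_beta
  cc <- kin$k0_off * b / rate
  b * e1_scaled(cc)
}

#' Sample a rupture force by inverse-CDF
#'
#' Maps a uniform variate u in (0, 1] through the inverse survival function of
#' the Bell-Evans density:
#' \eqn{F = (k_BT/x_\beta)\,\ln[1 - (x_\beta r/(k^0_{off} k_BT))\ln u]}.
#'
#' @param rate Loading rate (pN/s), positive scalar.
#' @param kin A [kinetic_params()].
#' @param u Uniform variate(s) in (0, 1]; vectorised.
#' @return Rupture force(s) in pN, >= 0.
#' @export
sample_rupture_force <- function(rate, kin, u) {
  check_scalar(rate, "rate")
  if (any(!is.finite(u)) || any(u <= 0) || any(u > 1))
    abort_domain("'u' must lie in (0, 1]")
  b <- kin$kBT / kin$x_beta
  A <- rate / (kin$k0_off * b)
  b * log1p(-A * log(u))
}

# Langevin alignment factor coth(a) - 1/a with a stable small-a series.
langevin_factor <- function(a) {
  out <- numeric(length(a))
  small <- abs(a) < 1e-4
  out[small] <- a[small] / 3 - a[small]^3 / 45
  if (any(!small)) {
    v <- a[!small]
    out[!small] <- 1 / tanh(v) - 1 / v
  }
  out
}

#' Extension of the two-state extended FJC tether at a given force
#'
#' Force-extension relation of the tether:
#' \deqn{x(F) = n\left[\frac{l_p}{e^{\Delta G(F)/k_BT}+1} +
#'   \frac{l_h}{e^{-\Delta G(F)/k_BT}+1}\right]
#'   \left(\coth\alpha - \frac{1}{\alpha}\right) + \frac{n F}{K_s},}
#' with \eqn{\Delta G(F) = \Delta G_0 k_BT - F(l_p - l_h)} the force-tilted
#' conformer free-energy gap and \eqn{\alpha = F L_K / k_BT}. At rest the
#' short helical conformer dominates; under load the population shifts to
#' the long planar conformer, so the conformational term saturates at the
#' contour length \eqn{n l_p}. The second term is the backbone elasticity.
#'
#' @param force Tensile force (pN), non-negative; vectorised.
#' @param tether A [tether_model()].
#' @return Extension(s) in nm; 0 at zero force, strictly increasing.
#' @export
fjc_extension <- function(force, tether) {
  if (any(!is.finite(force)) || any(force < 0))
    abort_domain("'force' must be finite and >= 0")
  kBT <- tether$kBT
  # Force-tilted conformer gap: at rest (dg = delta_g0 * kBT > 0) the short
  # helical conformer dominates; pulling lowers dg and converts monomers to
  # the long planar conformer, which saturates the chain at Lc = n * l_planar.
  dg <- tether$delta_g0 * kBT - force * (tether$l_planar - tether$l_helical)
  w_p <- 1 / (exp(dg / kBT) + 1)
  w_h <- 1 / (exp(-dg / kBT) + 1)
  l_eff <- tether$l_helical * w_h + tether$l_planar * w_p
  a <- force * tether$kuhn_length / kBT
  tether$n_monomers * (l_eff * langevin_factor(a) + force / tether$monomer_stiffness)
}

# d(extension)/d(force), central difference; smooth enough that numeric
# differentiation at h ~ 1e-4 pN is accurate to ~1e-8 nm/pN.
fjc_dxdf <- function(force, tether) {
  h <- pmax(1e-4, 1e-6 * force)
  (fjc_extension(force + h, tether) - fjc_extension(pmax(0, force - h), tether)) /
    (force + h - pmax(0, force - h))
}

#' Tether force at a given extension (numeric inversion)
#'
#' Monotone bracketed root-find of [fjc_extension()]; round-trips
#' `fjc_force(fjc_extension(F))` to better than 1e-9 relative over the
#' working force range.
#'
#' @param extension Extension(s) in nm, `0 <= extension < fjc_extension(f_max)`.
#' @param tether A [tether_model()].
#' @param f_max Upper force bracket (pN); default 500.
#' @return Force(s) in pN.
#' @export
fjc_force <- function(extension, tether, f_max = 500) {
  if (any(!is.finite(extension)) || any(extension < 0))
    abort_domain("'extension' must be finite and >= 0")
  xmax <- fjc_extension(f_max, tether)
  if (any(extension >= xmax))
    abort_range(sprintf(
      "extension %.6g nm is at or beyond the tether extension %.6g nm reachable at f_max = %g pN",
      max(extension), xmax, f_max))
  vapply(extension, function(x1) {
    if (x1 == 0) return(0)
    f <- stats::uniroot(function(f) fjc_extension(f, tether) - x1,
                        lower = 0, upper = f_max, tol = 1e-12)$root
    # two Newton polish steps to push the round-trip error to machine level
    for (i in 1:2) {
      g <- fjc_extension(f, tether) - x1
      f <- max(0, f - g / fjc_dxdf(f, tether))
    }
    f
  }, numeric(1))
}
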