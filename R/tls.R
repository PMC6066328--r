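# Total-least-squares fit of the extended-FJC tether to the stretch region of
# a force curve. Both coordinates of an AFM trace are noisy, so the fit
# minimises orthogonal distances to the model curve rather than vertical
# force residuals; free parameters are the monomer count (equivalently the
# contour length Lc) and a distance offset, with all other tether parameters
# held at template values.

#' Fit the tether stretch region by total least squares
#'
#' Extracts the stretch segment preceding the detected rupture (from the last
#' upward crossing of 5% of the peak force to the rupture index), then
#' minimises the sum of squared orthogonal distances from the (distance,
#' force) samples to the series tether-plus-cantilever model curve
#' `z(F) = n * phi(F) + F/k_c + offset`, where `phi` is the per-monomer
#' extended-FJC extension of the `template` tether. Optimisation is
#' Nelder-Mead over `(n, offset)` with the orthogonal-distance objective
#' evaluated against a dense model polyline in compiled code.
#'
#' @param curve A [force_curve()].
#' @param event A candidate from [detect_rupture()].
#' @param template A [tether_model()] supplying every fixed tether parameter.
#' @param min_points Minimum samples in the stretch segment (default 5);
#'   fewer is a fit error.
#' @param grid_size Nodes in the model polyline (default 220).
#' @param max_points Data points used in the objective; longer segments are
#'   thinned evenly (default 80).
#' @param sigma_z Distance-axis noise SD (nm), default 0.3.
#' @param sigma_f Force-axis noise SD (pN); `NULL` (default) estimates it
#'   robustly from the final 10% of the trace, floored at 0.5 pN.
#' @return A list of class `tls_fit`: `lc` (nm), `n_monomers`, `offset` (nm),
#'   `residual` (root-mean orthogonal distance), `converged`.
#' @export
fit_tether_tls <- function(curve, event, template, min_points = 5L,
                           grid_size = 220L, max_points = 80L,
                           sigma_z = 0.3, sigma_f = NULL) {
  i_r <- event$rupture_index
  fb <- baseline_correct(curve$force)
  if (is.null(sigma_f)) {
    nn <- length(fb)
    tail_idx <- (nn - min(nn, max(5L, floor(0.1 * nn))) + 1L):nn
    sigma_f <- max(stats::mad(fb[tail_idx]), 0.5)
  }
  sm <- moving_average(fb, 5L)
  thr <- max(0.05 * sm[i_r], 1)
  below <- which(sm[seq_len(i_r)] < thr)
  j0 <- if (length(below)) min(max(below) + 1L, i_r) else 1L
  idx <- j0:i_r
  if (length(idx) < min_points)
    abort_fit(sprintf("stretch segment has %d samples (< %d); cannot fit tether",
                      length(idx), min_points))
  if (length(idx) > max_points)
    idx <- idx[unique(round(seq(1L, length(idx), length.out = max_points)))]

  zd <- curve$tip_sample_distance[idx]
  fd <- fb[idx]
  kc <- curve$spring_constant

  f_hi <- 1.3 * max(fd) + 20
  fgrid <- seq(0, f_hi, length.out = grid_size)
  phigrid <- fjc_extension(fgrid, template) / template$n_monomers

  f_last <- max(fd[length(fd)], 5)
  phi_last <- fjc_extension(f_last, template) / template$n_monomers
  n0 <- max(2, (zd[length(zd)] - f_last / kc) / phi_last)

  # noise-standardised coordinates: Z = z/sigma_z, Y = F/sigma_f; the model
  # polyline transforms with n -> n/sigma_z, offset -> offset/sigma_z,
  # k_c -> k_c * sigma_z / sigma_f
  obj <- function(par) {
    if (par[1L] <= 1) return(1e12)
    tls_rss(par[1L] / sigma_z, par[2L] / sigma_z, zd / sigma_z,
            fd / sigma_f, fgrid / sigma_f, phigrid,
            kc * sigma_z / sigma_f)
  }
  opt <- stats::optim(c(n0, 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 600L))
  if (!is.finite(opt$value))
    abort_fit("tether TLS optimisation failed to produce a finite objective")

  structure(list(lc = opt$par[1L] * template$l_planar,
                 n_monomers = opt$par[1L], offset = opt$par[2L],
                 residual = sqrt(opt$value / length(zd)),
                 sigma_f = sigma_f, sigma_z = sigma_z,
                 converged = opt$convergence == 0L),
            class = "tls_fit")
}

#' @export
print.tls_fit <- function(x, ...) {
  cat(sprintf("TLS tether fit: Lc = %.3f nm (n = %.1f monomers), offset = %.3f nm, residual = %.3g, %s\n",
              x$lc, x$n_monomers, x$offset, x$residual,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
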