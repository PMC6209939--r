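#' Analytic line-source + circular-cylinder scattering oracle
#'
#' Classical eigenfunction (Bessel/Hankel) series for the field of an
#' electric line current near an infinite circular cylinder, both embedded
#' in a homogeneous (possibly lossy) background. Serves as the independent
#' oracle for the FDTD forward solver. Uses the \eqn{e^{+j\omega t}}
#' convention, so outgoing waves are Hankel functions of the second kind
#' and the complex wave number has a negative imaginary part in lossy media.
#'
#' The line source carries current spectrum `current` (A·s at the given
#' frequency, i.e. the Fourier transform of the current waveform), making
#' the returned fields directly comparable to DFT fields from [run_fdtd()].
#'
#' @param eps_bg Complex relative permittivity of the background
#'   (\eqn{\epsilon' - j\epsilon''}).
#' @param eps_cyl Complex relative permittivity of the cylinder, or `"PEC"`.
#' @param radius Cylinder radius in meters.
#' @param freq Frequency in Hz.
#' @param source_pos Length-2 (x, y) of the line source, meters.
#' @param probe_pos Matrix (n x 2) of probe positions, meters; all probes
#'   must lie outside the cylinder.
#' @param cylinder_center Length-2 center of the cylinder (default origin).
#' @param n_terms Series truncation order; `NULL` (default) auto-estimates
#'   and is converged to < 1e-8 relative (adding 5 terms changes nothing).
#' @param current Complex current spectrum of the source (default 1).
#' @return List with complex vectors `incident`, `scattered`, `total` (one
#'   entry per probe) and the truncation order `n_terms`.
#' @export
analytic_cylinder_fields <- function(eps_bg, eps_cyl, radius, freq,
                                     source_pos, probe_pos,
                                     cylinder_center = c(0, 0),
                                     n_terms = NULL, current = 1) {
  if (freq <= 0) mwt_stop("freq must be > 0")
  if (is.null(dim(probe_pos))) probe_pos <- matrix(probe_pos, ncol = 2)
  w <- 2 * pi * freq
  kb <- w / C0 * sqrt(as.complex(eps_bg))

  sp <- source_pos - cylinder_center
  pp <- sweep(probe_pos, 2, cylinder_center)
  rho_s <- sqrt(sum(sp^2)); phi_s <- atan2(sp[2], sp[1])
  rho_p <- sqrt(rowSums(pp^2)); phi_p <- atan2(pp[, 2], pp[, 1])
  if (any(rho_p <= radius))
    mwt_stop("probes must lie outside the cylinder")
  if (rho_s <= radius) mwt_stop("source must lie outside the cylinder")

  N <- if (is.null(n_terms)) max(10L, ceiling(Mod(kb) * radius) + 20L) else as.integer(n_terms)
  amp <- -w * MU0 * as.complex(current) / 4

  # exact incident field
  dist <- sqrt((probe_pos[, 1] - source_pos[1])^2 +
               (probe_pos[, 2] - source_pos[2])^2)
  h0_inc <- vapply(dist, function(d)
    if (d > 0) hankel2_seq(kb * d, 0)[1] else NA_complex_, complex(1))
  incident <- amp * h0_inc

  # scattering coefficients c_n, orders 0..N
  jb <- bessel_j_seq(kb * radius, N + 1)
  hb <- hankel2_seq(kb * radius, N + 1)
  jbp <- bessel_deriv(jb, kb * radius)
  hbp <- bessel_deriv(hb, kb * radius)
  if (is_pec(eps_cyl)) {
    cn <- -jb[1:(N + 1)] / hb[1:(N + 1)]
  } else {
    kc <- w / C0 * sqrt(as.complex(eps_cyl))
    jc <- bessel_j_seq(kc * radius, N + 1)
    jcp <- bessel_deriv(jc, kc * radius)
    n_idx <- 1:(N + 1)
    num <- kc * jcp * jb[n_idx] - kb * jc[n_idx] * jbp
    den <- kc * jcp * hb[n_idx] - kb * jc[n_idx] * hbp
    cn <- -num / den
  }

  hs <- hankel2_seq(kb * rho_s, N)
  scattered <- complex(nrow(probe_pos))
  for (p in seq_len(nrow(probe_pos))) {
    hp <- hankel2_seq(kb * rho_p[p], N)
    terms <- cn[1:(N + 1)] * hs * hp
    fac <- c(1, 2 * cos((1:N) * (phi_p[p] - phi_s)))
    scattered[p] <- amp * sum(terms * fac)
  }
  list(incident = incident, scattered = scattered,
       total = incident + scattered, n_terms = N)
}

#' Field of a line source in a homogeneous background
#'
#' @inheritParams analytic_cylinder_fields
#' @return Complex field values at the probes.
#' @export
analytic_line_source_field <- function(eps_bg, freq, source_pos, probe_pos,
                                       current = 1) {
  if (is.null(dim(probe_pos))) probe_pos <- matrix(probe_pos, ncol = 2)
  w <- 2 * pi * freq
  kb <- w / C0 * sqrt(as.complex(eps_bg))
  dist <- sqrt((probe_pos[, 1] - source_pos[1])^2 +
               (probe_pos[, 2] - source_pos[2])^2)
  if (any(dist <= 0)) mwt_stop("probe coincides with the source")
  amp <- -w * MU0 * as.complex(current) / 4
  amp * vapply(dist, function(d) hankel2_seq(kb * d, 0)[1], complex(1))
}
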