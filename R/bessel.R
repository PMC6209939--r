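# Integer-order Bessel functions of complex argument, needed by the
# analytic line-source / cylinder scattering series in lossy media (base R
# Bessel functions are real-argument only).
#
# J_n: Miller's downward recurrence with rescaling, normalized by the
#      identity J_0(z) + 2 sum_k J_{2k}(z) = 1 (valid for complex z).
# Y_n: power series for Y_0, Y_1 (A&S 9.1.11 log form), then the upward
#      recurrence, which is stable for the dominant solution.
# H^(2)_n = J_n - i Y_n, the outgoing wave for e^{+j omega t}.

EULER_GAMMA <- 0.57721566490153286

#' Bessel J of integer orders 0..nmax at complex z
#' @param z Complex scalar, z != 0.
#' @param nmax Highest order.
#' @return Complex vector of length nmax + 1 (orders 0..nmax).
#' @keywords internal
bessel_j_seq <- function(z, nmax) {
  stopifnot(length(z) == 1, abs(z) > 0)
  z <- as.complex(z)
  mstart <- nmax + ceiling(abs(z)) + 28
  if (mstart %% 2L == 1L) mstart <- mstart + 1L
  out <- complex(nmax + 1)
  jp1 <- 0 + 0i
  jc <- 1e-30 + 0i
  norm <- 0 + 0i
  for (m in seq(mstart, 1)) {
    jm1 <- (2 * m / z) * jc - jp1
    jp1 <- jc
    jc <- jm1
    if (m - 1 <= nmax) out[m] <- jc  # order m-1 stored at index m
    if ((m - 1) %% 2L == 0L) norm <- norm + (if (m - 1 == 0) 1 else 2) * jc
    if (Mod(jc) > 1e250) {
      sc <- 1e-250
      jc <- jc * sc; jp1 <- jp1 * sc; norm <- norm * sc
      out <- out * sc
    }
  }
  out / norm
}

#' Bessel Y of integer orders 0..nmax at complex z
#' @inheritParams bessel_j_seq
#' @keywords internal
bessel_y_seq <- function(z, nmax) {
  z <- as.complex(z)
  j <- bessel_j_seq(z, max(1, nmax))
  u <- z * z / 4
  lg <- log(z / 2)
  # Y_0
  s <- 0 + 0i; term <- 1 + 0i; hk <- 0
  for (k in 1:60) {
    term <- term * (-u) / (k * k)
    hk <- hk + 1 / k
    s <- s + term * hk
    if (Mod(term * hk) < 1e-18 * (Mod(s) + 1e-300)) break
  }
  y0 <- (2 / pi) * ((lg + EULER_GAMMA) * j[1] - s)
  # Y_1 (A&S 9.1.11, n = 1)
  s1 <- 0 + 0i; term <- z / 2
  psi_a <- -EULER_GAMMA          # psi(1)
  psi_b <- 1 - EULER_GAMMA       # psi(2)
  for (k in 0:60) {
    s1 <- s1 + (if (k %% 2 == 0) 1 else -1) * (psi_a + psi_b) * term
    tnew <- term * u / ((k + 1) * (k + 2))
    psi_a <- psi_a + 1 / (k + 1)
    psi_b <- psi_b + 1 / (k + 2)
    if (Mod(tnew) * abs(psi_a + psi_b) < 1e-18 * (Mod(s1) + 1e-300)) { term <- tnew; break }
    term <- tnew
  }
  y1 <- (2 / pi) * lg * j[2] - (2 / (pi * z)) - s1 / pi
  out <- complex(nmax + 1)
  out[1] <- y0
  if (nmax >= 1) out[2] <- y1
  if (nmax >= 2) {
    for (n in 1:(nmax - 1)) out[n + 2] <- (2 * n / z) * out[n + 1] - out[n]
  }
  out
}

#' Hankel function of the second kind, orders 0..nmax
#' @inheritParams bessel_j_seq
#' @keywords internal
hankel2_seq <- function(z, nmax) {
  bessel_j_seq(z, nmax) - 1i * bessel_y_seq(z, nmax)
}

# derivative from the standard recurrence, given the order sequence f_0..f_N
bessel_deriv <- function(fseq, z) {
  n <- length(fseq) - 1
  d <- complex(n)  # derivatives for orders 0..n-1
  d[1] <- -fseq[2]
  if (n >= 2)
    for (k in 1:(n - 1)) d[k + 1] <- fseq[k] - (k / z) * fseq[k + 1]
  d
}
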