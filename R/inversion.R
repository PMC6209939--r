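#' TwIST solver configuration
#'
#' Two-step iterative shrinkage-thresholding parameters. With the system
#' matrix scaled to unit spectral norm, the two-step relaxation parameters
#' default to the standard choice driven by `lam1`, an estimate of the
#' smallest relevant eigenvalue of \eqn{A^T A} relative to the largest:
#' \eqn{\rho_0 = (1 - \xi_1)/(1 + \xi_1)}, \eqn{\alpha = 2/(1 +
#' \sqrt{1 - \rho_0^2})}, \eqn{\beta = 2\alpha/(1 + \xi_1)}.
#'
#' @param lambda_reg Regularization weight \eqn{\lambda} for the
#'   \eqn{\ell_1} term; `NULL` selects `lambda_frac * max|A^T y|` on the
#'   normalized problem.
#' @param lambda_frac Fraction used by the automatic \eqn{\lambda} rule.
#' @param alpha,beta Two-step relaxation parameters; `NULL` = from `lam1`.
#' @param lam1 Relative smallest eigenvalue estimate in (0, 1].
#' @param max_inner_iters Iteration cap.
#' @param tolerance Relative step-size stopping tolerance.
#' @return An object of class `twist_config`.
#' @export
twist_config <- function(lambda_reg = NULL, lambda_frac = 0.001,
                         alpha = NULL, beta = NULL, lam1 = 1e-4,
                         max_inner_iters = 400, tolerance = 1e-6) {
  if (!is.null(lambda_reg) && lambda_reg < 0) mwt_stop("lambda_reg must be >= 0")
  if (lam1 <= 0 || lam1 > 1) mwt_stop("lam1 must be in (0, 1]")
  structure(list(lambda_reg = lambda_reg, lambda_frac = lambda_frac,
                 alpha = alpha, beta = beta, lam1 = lam1,
                 max_inner_iters = max_inner_iters, tolerance = tolerance),
            class = "twist_config")
}

spectral_norm <- function(A, iters = 60) {
  v <- rep(1, ncol(A)); v <- v / sqrt(sum(v^2))
  s <- 0
  for (k in seq_len(iters)) {
    w <- drop(crossprod(A, A %*% v))
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- w / nw
    s <- sqrt(nw)
  }
  s
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Solve a linear system with TwIST (l1-regularized least squares)
#'
#' Minimizes \eqn{\frac12 \|y - Ax\|^2 + \lambda \|x\|_1} with the two-step
#' iterative shrinkage-thresholding recursion
#' \eqn{x_{t+1} = (1-\alpha) x_{t-1} + (\alpha-\beta) x_t +
#' \beta\,\Gamma_\lambda(x_t + A^T (y - A x_t))}.
#' The matrix is internally scaled to unit spectral norm (the scheme's
#' stability requirement); a monotone safeguard falls back to a plain IST
#' step whenever the two-step update would increase the objective, and
#' persistent growth raises an error pointing at the normalization.
#'
#' @param A Real matrix (m x n).
#' @param y Real data vector (length m).
#' @param cfg A [twist_config()].
#' @return Solution vector with attributes `objective` (history),
#'   `lambda`, `iters`.
#' @export
twist_solve <- function(A, y, cfg = twist_config()) {
  stopifnot(inherits(cfg, "twist_config"))
  if (all(y == 0)) {
    out <- rep(0, ncol(A))
    attr(out, "objective") <- 0; attr(out, "lambda") <- cfg$lambda_reg %||% 0
    attr(out, "iters") <- 0L
    return(out)
  }
  s <- spectral_norm(A)
  if (s == 0) return(rep(0, ncol(A)))
  An <- A / s
  yn <- y / s
  g0 <- drop(crossprod(An, yn))
  lambda <- cfg$lambda_reg %||% (cfg$lambda_frac * max(abs(g0)))

  xi1 <- cfg$lam1
  rho0 <- (1 - xi1) / (1 + xi1)
  alpha <- cfg$alpha %||% (2 / (1 + sqrt(1 - rho0^2)))
  beta <- cfg$beta %||% (alpha * 2 / (1 + xi1))

  obj <- function(x, Ax) 0.5 * sum((yn - Ax)^2) + lambda * sum(abs(x))
  xm1 <- rep(0, ncol(A))
  Axm1 <- rep(0, nrow(A))
  x <- soft_threshold(g0, lambda)           # first step: plain IST from zero
  Ax <- drop(An %*% x)
  objs <- c(obj(xm1, Axm1), obj(x, Ax))
  bad <- 0L
  iters <- 1L
  for (t in seq_len(cfg$max_inner_iters)) {
    grad_step <- x + drop(crossprod(An, yn - Ax))
    xd <- soft_threshold(grad_step, lambda)
    xn <- (1 - alpha) * xm1 + (alpha - beta) * x + beta * xd
    Axn <- drop(An %*% xn)
    if (obj(xn, Axn) > objs[length(objs)]) {
      xn <- xd                               # monotone fallback: IST step
      Axn <- drop(An %*% xn)
      if (obj(xn, Axn) > objs[length(objs)] * (1 + 1e-9)) {
        bad <- bad + 1L
        if (bad >= 5L)
          mwt_stop("TwIST objective keeps growing; spectral normalization violated",
                   class = "mwtomo_divergence")
      } else bad <- 0L
    } else bad <- 0L
    step <- sqrt(sum((xn - x)^2))
    xm1 <- x; Axm1 <- Ax
    x <- xn; Ax <- Axn
    objs <- c(objs, obj(x, Ax))
    iters <- t + 1L
    if (step <= cfg$tolerance * max(sqrt(sum(x^2)), 1e-300)) break
  }
  attr(x, "objective") <- objs
  attr(x, "lambda") <- lambda
  attr(x, "iters") <- iters
  x
}

#' Solve a least-squares system with CGLS
#'
#' Conjugate gradient on the normal equations \eqn{A^T A x = A^T y},
#' started from zero. Early stopping (the iteration cap) is the
#' regularization knob.
#'
#' @param A Real matrix.
#' @param y Real data vector.
#' @param max_iters Iteration cap (default `min(dim(A))`).
#' @param tolerance Stop when \eqn{\|A^T(y - Ax)\|} falls below
#'   `tolerance` times its initial value.
#' @return Solution vector with attribute `iters`.
#' @export
cgls_solve <- function(A, y, max_iters = min(dim(A)), tolerance = 1e-8) {
  x <- rep(0, ncol(A))
  r <- y
  s <- drop(crossprod(A, r))
  p <- s
  gamma <- sum(s^2)
  g0 <- sqrt(gamma)
  if (g0 == 0) { attr(x, "iters") <- 0L; return(x) }
  iters <- 0L
  for (k in seq_len(max_iters)) {
    q <- drop(A %*% p)
    denom <- sum(q^2)
    if (denom == 0) break
    a <- gamma / denom
    x <- x + a * p
    r <- r - a * q
    s <- drop(crossprod(A, r))
    gnew <- sum(s^2)
    iters <- k
    if (sqrt(gnew) <= tolerance * g0) break
    p <- s + (gnew / gamma) * p
    gamma <- gnew
  }
  attr(x, "iters") <- iters
  x
}

#' Assemble the distorted-Born sensitivity matrix
#'
#' Row (m, n) and column k hold the Born kernel
#' \deqn{J_{(m,n),k} = \frac{j\omega\epsilon_0\,\Delta A}{\hat I(\omega)}\,
#'       E^{(m)}(r_k)\, E^{(n)}(r_k)}
#' which maps a complex relative-permittivity contrast
#' \eqn{\delta\chi = \delta\epsilon' - j\,\delta\sigma/(\omega\epsilon_0)}
#' at voxel k to the perturbation of the (tx = m, rx = n) probe field.
#' \eqn{E^{(n)}} is the receiver-sourced background run, standing in for
#' the background Green's function by reciprocity; \eqn{\hat I(\omega)} is
#' the source current spectrum carried by every run, which removes the
#' double-counted excitation spectrum.
#'
#' @param background_fields List of [run_fdtd()] fieldsets, one per
#'   antenna, computed on the current background with fields at the voxel
#'   cells.
#' @param pairs Integer matrix with columns `tx`, `rx` defining the rows.
#' @param adjoint_fields Receiver-sourced fieldsets; defaults to
#'   `background_fields` (transceivers).
#' @param freq_index Which stored DFT frequency to use.
#' @return Complex matrix (nrow(pairs) x n_voxels).
#' @export
assemble_jacobian <- function(background_fields, pairs,
                              adjoint_fields = background_fields,
                              freq_index = 1) {
  f1 <- background_fields[[1]]
  nv <- nrow(f1$cell_idx)
  if (nv == 0) mwt_stop("fieldsets carry no voxel cells",
                        class = "mwtomo_alignment_error")
  for (fs in c(background_fields, adjoint_fields))
    if (!identical(dim(fs$cells), dim(f1$cells)) ||
        !identical(fs$grid$dx, f1$grid$dx))
      mwt_stop("fieldsets disagree on grid or voxel set",
               class = "mwtomo_alignment_error")
  w <- 2 * pi * f1$freqs[freq_index]
  dA <- f1$grid$dx^2
  Ihat <- f1$src_spectrum[freq_index]
  coef <- 1i * w * EPS0 * dA / Ihat
  E <- vapply(background_fields, function(fs) fs$cells[, freq_index], complex(nv))
  Ea <- vapply(adjoint_fields, function(fs) fs$cells[, freq_index], complex(nv))
  J <- matrix(0i, nrow(pairs), nv)
  for (r in seq_len(nrow(pairs)))
    J[r, ] <- coef * E[, pairs[r, 1]] * Ea[, pairs[r, 2]]
  J
}

# real block system for delta_chi = u1 - j u2 split into two real unknowns
born_real_system <- function(J, y) {
  Jr <- Re(J); Ji <- Im(J)
  list(A = rbind(cbind(Jr, Ji), cbind(Ji, -Jr)),
       b = c(Re(y), Im(y)))
}

#' DBIM reconstruction configuration
#'
#' Defaults mirror the validated acquisition protocol: frequency hopping
#' over 1.2, 1.5, 1.8, 2.1 and 2.4 GHz with 20 DBIM iterations per hop,
#' 2.0 mm voxels, and a 120 mm reconstruction ring.
#'
#' @param freq_schedule Increasing frequencies in Hz.
#' @param iters_per_freq DBIM iterations per hop (>= 1).
#' @param voxel_size Inversion voxel edge, meters.
#' @param recon_ring_diam Reconstruction ring diameter, meters (`NULL`:
#'   take it from the scenario).
#' @param solver `"twist"` or `"cgls"`.
#' @param twist A [twist_config()].
#' @param cgls_max_iters,cgls_tol CGLS controls (iteration count is the
#'   regularization knob).
#' @param sim A [sim_config()] for the per-iteration forward runs (its
#'   `dx` is forced to `voxel_size`).
#' @param pulse A [pulse_spec()].
#' @param eps1_bounds Physical clamp for the reconstructed \eqn{\epsilon'}.
#' @param report_freq Frequency at which final complex-permittivity maps
#'   are evaluated (`NULL`: first schedule frequency).
#' @param early_exit_tol Optional early exit when the relative residual
#'   change within a hop falls below this (0 disables, the default, which
#'   keeps the fixed-iteration protocol).
#' @param col_normalize Equalize Jacobian column norms before the linear
#'   solve. Off by default: equalization counteracts the concentration of
#'   strong-contrast solutions in the high-sensitivity voxels next to the
#'   antennas, but amplifies artifacts in the low-sensitivity ring center
#'   on moderate-contrast scenes.
#' @param max_backtracks Monotone outer-loop guard: number of times a
#'   Born update is halved while it would increase the data residual.
#' @return An object of class `dbim_config`.
#' @export
dbim_config <- function(freq_schedule = c(1.2e9, 1.5e9, 1.8e9, 2.1e9, 2.4e9),
                        iters_per_freq = 20, voxel_size = 2e-3,
                        recon_ring_diam = NULL, solver = c("twist", "cgls"),
                        twist = twist_config(), cgls_max_iters = 15,
                        cgls_tol = 1e-6, sim = sim_config(dx = 2e-3),
                        pulse = pulse_spec(), eps1_bounds = c(1, 90),
                        report_freq = NULL, early_exit_tol = 0,
                        col_normalize = FALSE, max_backtracks = 3) {
  if (any(diff(freq_schedule) <= 0)) mwt_stop("freq_schedule must be increasing")
  if (iters_per_freq < 1) mwt_stop("iters_per_freq must be >= 1")
  solver <- match.arg(solver)
  structure(list(freq_schedule = freq_schedule, iters_per_freq = iters_per_freq,
                 voxel_size = voxel_size, recon_ring_diam = recon_ring_diam,
                 solver = solver, twist = twist,
                 cgls_max_iters = cgls_max_iters, cgls_tol = cgls_tol,
                 sim = sim, pulse = pulse, eps1_bounds = eps1_bounds,
                 report_freq = report_freq, early_exit_tol = early_exit_tol,
                 col_normalize = col_normalize,
                 max_backtracks = max_backtracks),
            class = "dbim_config")
}

# effective (eps1, sigma) of the Debye rasters at angular frequency w,
# restricted to the voxel linear indices
debye_maps_at <- function(maps, lin, w) {
  D <- 1 + (w * maps$tau[lin])^2
  eps1 <- maps$eps_inf[lin] + maps$delta_eps[lin] / D
  sigma <- maps$sigma_s[lin] + EPS0 * maps$delta_eps[lin] * w^2 * maps$tau[lin] / D
  list(eps1 = eps1, sigma = sigma)
}

# write updated (eps1, sigma) back into the Debye rasters, holding
# eps_inf and tau at their background values
debye_maps_update <- function(maps, lin, w, eps1, sigma) {
  D <- 1 + (w * maps$tau[lin])^2
  de <- pmax(0, (eps1 - maps$eps_inf[lin]) * D)
  ss <- pmax(0, sigma - EPS0 * de * w^2 * maps$tau[lin] / D)
  maps$delta_eps[lin] <- de
  maps$sigma_s[lin] <- ss
  maps
}

#' Reconstruct permittivity maps with the distorted Born iterative method
#'
#' Outer DBIM loop with frequency hopping: at each scheduled frequency the
#' nonlinear scattering problem is linearized about the current background
#' (Born approximation with numerical background Green's functions from
#' receiver-sourced FDTD runs via reciprocity), the linear system is
#' solved with TwIST or CGLS, and the background Debye maps are updated.
#' The reconstruction at each hop warm-starts the next; the first hop
#' starts from the homogeneous immersion medium of known properties.
#'
#' Two real unknowns per voxel are solved for — the contrast of
#' \eqn{\epsilon'} and of \eqn{\sigma} at the working frequency — and
#' mapped back to per-voxel Debye parameters holding \eqn{\epsilon_\infty}
#' and \eqn{\tau} at background values.
#'
#' @param data A [calibrate()]d dataset covering the frequency schedule.
#' @param scn Target-free [scenario()] (the known prior: geometry plus
#'   homogeneous immersion background).
#' @param cfg A [dbim_config()].
#' @return An object of class `recon_result`: final Debye rasters `maps`,
#'   complex-permittivity maps `eps1`/`eps2` at `report_freq`, per-hop
#'   snapshots, `residuals` (data frame freq/iter/residual), `grid`,
#'   `voxels`, `config`.
#' @export
dbim_reconstruct <- function(data, scn, cfg = dbim_config()) {
  stopifnot(inherits(data, "calibrated_data"), inherits(scn, "mwt_scenario"))
  cfg$sim$dx <- cfg$voxel_size
  ring <- cfg$recon_ring_diam %||% scn$recon_ring_diam
  scn_prior <- scn
  scn_prior$targets <- list()
  scn_prior$recon_ring_diam <- ring
  grid <- scenario_grid(scn_prior, cfg$voxel_size,
                        margin_cells = cfg$sim$pml_cells + 4)
  vox <- recon_voxels(scn_prior, grid)
  lin <- vox[, 1] + (vox[, 2] - 1L) * grid$nx
  maps <- rasterize(scn_prior, grid)
  n_ant <- scn$n_antennas

  have <- unique(data$entries$freq_hz)
  for (f in cfg$freq_schedule)
    if (!any(abs(have - f) < 0.5))
      mwt_stop(sprintf("calibrated data lacks frequency %.3g Hz", f),
               class = "mwtomo_config_error")

  residuals <- data.frame(freq_hz = numeric(0), iter = integer(0),
                          residual = numeric(0))
  snapshots <- list()
  partial <- FALSE

  nv <- nrow(vox)

  for (f in cfg$freq_schedule) {
    w <- 2 * pi * f
    rows <- data$entries[abs(data$entries$freq_hz - f) < 0.5 &
                           !data$entries$excluded, ]
    pairs <- cbind(tx = rows$tx, rx = rows$rx)
    d_tot <- rows$total

    sweep_state <- function(maps) {
      fields <- lapply(seq_len(n_ant), function(tx)
        run_fdtd(maps, scn_prior, tx, cfg$pulse, f, cfg$sim, cells = vox))
      p_model <- vapply(seq_len(nrow(pairs)), function(r)
        fields[[pairs[r, 1]]]$probe[pairs[r, 2], 1], complex(1))
      y <- d_tot - p_model
      list(fields = fields, y = y, res = sqrt(sum(Mod(y)^2)))
    }
    st <- sweep_state(maps)
    prev_res <- NA_real_
    for (it in seq_len(cfg$iters_per_freq)) {
      residuals <- rbind(residuals,
                         data.frame(freq_hz = f, iter = it, residual = st$res))
      if (cfg$early_exit_tol > 0 && is.finite(prev_res) &&
          abs(prev_res - st$res) <= cfg$early_exit_tol * prev_res) break
      prev_res <- st$res

      J <- assemble_jacobian(st$fields, pairs)
      sys <- born_real_system(J, st$y)
      # sensitivity equalization: without it the solution concentrates in
      # the high-|E|^2 voxels next to the antennas
      if (cfg$col_normalize) {
        cn <- sqrt(colSums(sys$A^2))
        cn[cn < max(cn) * 1e-12] <- Inf
        sys$A <- sweep(sys$A, 2, cn, "/")
      }
      u <- tryCatch(
        if (cfg$solver == "twist") twist_solve(sys$A, sys$b, cfg$twist)
        else cgls_solve(sys$A, sys$b, cfg$cgls_max_iters, cfg$cgls_tol),
        error = function(e) {
          warning("linear solver failed (", conditionMessage(e),
                  "); returning partial result")
          NULL
        })
      if (is.null(u)) { partial <- TRUE; break }
      if (cfg$col_normalize) u <- u / cn
      d_eps1 <- u[seq_len(nv)]
      d_sig <- u[nv + seq_len(nv)] * w * EPS0

      # monotone outer step: backtrack (halve) the Born update while the
      # data residual would grow -- guards the linearization at strong
      # contrast, where the plain distorted-Born step overshoots
      cur <- debye_maps_at(maps, lin, w)
      scale <- 1
      for (bt in seq_len(cfg$max_backtracks + 1L)) {
        eps1 <- pmin(pmax(cur$eps1 + scale * d_eps1, cfg$eps1_bounds[1]),
                     cfg$eps1_bounds[2])
        sigma <- pmax(cur$sigma + scale * d_sig, 0)
        maps_try <- debye_maps_update(maps, lin, w, eps1, sigma)
        st_try <- sweep_state(maps_try)
        if (st_try$res <= st$res * (1 + 1e-3) || bt > cfg$max_backtracks) break
        scale <- scale / 2
      }
      maps <- maps_try
      st <- st_try
    }
    snapshots[[sprintf("%.3fGHz", f / 1e9)]] <- maps
    if (partial) break
  }

  f_rep <- cfg$report_freq %||% cfg$freq_schedule[1]
  wr <- 2 * pi * f_rep
  D <- 1 + (wr * maps$tau)^2
  eps1_map <- maps$eps_inf + maps$delta_eps / D
  eps2_map <- maps$delta_eps * wr * maps$tau / D +
    maps$sigma_s / (wr * EPS0)
  structure(list(maps = maps, eps1 = eps1_map, eps2 = eps2_map,
                 report_freq = f_rep, snapshots = snapshots,
                 residuals = residuals, grid = grid, voxels = vox,
                 partial = partial, config = cfg),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %d voxels, %d hops, final residual %.3g%s\n",
              nrow(x$voxels), length(x$snapshots),
              utils::tail(x$residuals$residual, 1),
              if (x$partial) " (partial)" else ""))
  invisible(x)
}

#' Local maxima of a reconstructed map inside the ring
#'
#' Finds voxels whose \eqn{\epsilon'} exceeds all 8 neighbors, restricted
#' to the reconstruction support, sorted by value.
#'
#' @param result A [dbim_reconstruct()] result.
#' @param n Maximum number of maxima to return.
#' @param min_separation Minimum distance between reported maxima, meters.
#' @return Data frame with `x`, `y` (meters), `eps1`.
#' @export
recon_local_maxima <- function(result, n = 2, min_separation = 0.02) {
  m <- result$eps1
  grid <- result$grid
  inside <- matrix(FALSE, grid$nx, grid$ny)
  inside[result$voxels] <- TRUE
  cand <- list()
  for (r in seq_len(nrow(result$voxels))) {
    i <- result$voxels[r, 1]; j <- result$voxels[r, 2]
    v <- m[i, j]
    nb <- m[cbind(i + c(-1, -1, -1, 0, 0, 1, 1, 1),
                  j + c(-1, 0, 1, -1, 1, -1, 0, 1))]
    if (all(v > nb)) cand[[length(cand) + 1L]] <- c(i, j, v)
  }
  if (!length(cand)) return(data.frame(x = numeric(0), y = numeric(0),
                                       eps1 = numeric(0)))
  cm <- do.call(rbind, cand)
  cm <- cm[order(-cm[, 3]), , drop = FALSE]
  ax <- grid_axes(grid)
  picked <- matrix(numeric(0), 0, 3)
  for (r in seq_len(nrow(cm))) {
    px <- ax$x[cm[r, 1]]; py <- ax$y[cm[r, 2]]
    if (nrow(picked) > 0 &&
        any(sqrt((picked[, 1] - px)^2 + (picked[, 2] - py)^2) < min_separation))
      next
    picked <- rbind(picked, c(px, py, cm[r, 3]))
    if (nrow(picked) >= n) break
  }
  data.frame(x = picked[, 1], y = picked[, 2], eps1 = picked[, 3])
}
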