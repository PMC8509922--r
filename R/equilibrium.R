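#' Solve a network to equilibrium (algebraic path)
#'
#' Computes the unique steady state of the closed mass-action system for
#' each parameter set (row) by solving the conservation equations for the
#' free ligand and receptor concentrations. Because the network satisfies
#' detailed balance, every complex concentration is an explicit product of
#' free concentrations, `gamma`, and the species statistical weight; the
#' solver runs a damped Newton iteration in log-free-concentration space
#' (which enforces positivity and makes the Jacobian symmetric positive
#' definite), vectorized across all parameter sets at once.
#'
#' This is the production path for large screens; [integrate_to_steady_state()]
#' provides an independent ODE route used for cross-validation.
#'
#' @param params A data frame with one column per free species (ligand
#'   dimers and receptors, named as in the network) giving total
#'   concentrations in nM, plus an optional `gamma` column. Totals must be
#'   >= 0; a zero total simply removes that species.
#' @param network A `"bmp_network"` from [build_network()].
#' @param gamma Surface enhancement factor used for rows without a
#'   `gamma` column; defaults to the network's kinetic configuration.
#' @param tol Convergence tolerance on the relative conservation residual.
#' @param maxit Maximum Newton iterations.
#' @return A tibble of class `"bmp_steady_state"`, one row per parameter
#'   set: the input totals (`total_*` columns), `gamma`, free
#'   concentrations (`free_*` columns), one column per oligomer species
#'   (nM), and `.converged` / `.residual` diagnostics. The network is
#'   attached as attribute `"network"`.
#' @export
#' @examples
#' net <- build_network()
#' ps <- tibble::tibble("Bmp2/2" = 0.1, "Bmp7/7" = 0.1, "Bmp2/7" = 0.1,
#'                      BmpR1 = 10, Acvr1 = 10, TypeII = 10, gamma = 100)
#' st <- solve_equilibrium(ps, net)
#' st$.residual
solve_equilibrium <- function(params, network, gamma = NULL,
                              tol = 1e-12, maxit = 300) {
  stopifnot(inherits(network, "bmp_network"))
  params <- tibble::as_tibble(params)
  fn <- network$free_names
  missing <- setdiff(fn, names(params))
  if (length(missing) > 0) {
    stop("params is missing total concentration column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  totals <- as.matrix(params[, fn, drop = FALSE])
  if (any(!is.finite(totals)) || any(totals < 0)) {
    stop("total concentrations must be finite and >= 0", call. = FALSE)
  }
  g <- if ("gamma" %in% names(params)) params$gamma else
    rep(gamma %||% network$kinetics$gamma, nrow(params))
  if (any(g < 1)) stop("gamma must be >= 1", call. = FALSE)

  sol <- eq_solve_batch(network, totals, g, tol = tol, maxit = maxit)
  if (any(!sol$converged)) {
    warning(sum(!sol$converged), " parameter set(s) did not converge; ",
            "max residual ", format(max(sol$residual)), call. = FALSE)
  }
  assemble_steady_state(network, totals, g, sol)
}

assemble_steady_state <- function(network, totals, g, sol) {
  fn <- network$free_names
  out <- tibble::as_tibble(as.data.frame(totals, check.names = FALSE))
  names(out) <- paste0("total_", fn)
  out$gamma <- g
  free <- tibble::as_tibble(as.data.frame(sol$free, check.names = FALSE))
  names(free) <- paste0("free_", fn)
  out <- dplyr::bind_cols(out, free)
  if (ncol(sol$conc) > 0) {
    conc <- tibble::as_tibble(as.data.frame(sol$conc, check.names = FALSE))
    names(conc) <- network$species$id
    out <- dplyr::bind_cols(out, conc)
  }
  out$.converged <- sol$converged
  out$.residual <- sol$residual
  attr(out, "network") <- network
  class(out) <- c("bmp_steady_state", class(out))
  out
}

# Vectorized damped Newton solver for the equilibrium free concentrations.
#
# Minimizes, per parameter set, the strictly convex dual
#   Phi(u) = sum_s c_s(u) + sum_f exp(u_f) - sum_f t_f u_f
# whose gradient is (recovered totals - target totals) and whose Hessian
# J_fg = sum_s n_sf n_sg c_s + delta_fg x_f is symmetric positive
# definite. All parameter sets advance together; the per-point 6x6 (in
# general FxF) Newton systems are solved by a batched unrolled Cholesky.
eq_solve_batch <- function(network, totals, gamma, tol = 1e-11, maxit = 100,
                           clamped = NULL, retry = TRUE, init_logx = NULL) {
  N <- network$stoich
  S <- nrow(N)
  nf <- ncol(N)
  P <- nrow(totals)
  logW <- network$species$log_weight
  bexp <- pmax(network$species$bonds - 1L, 0L)
  lg <- log(gamma)

  # clamped species hold their FREE concentration at the supplied value
  # (an open reservoir, e.g. ambient morphogen); they are excluded from
  # the conservation system
  is_clamped <- rep(FALSE, nf)
  if (!is.null(clamped)) {
    stopifnot(all(clamped %in% colnames(N)))
    is_clamped[match(clamped, colnames(N))] <- TRUE
  }
  active <- totals > 0
  active[, is_clamped] <- FALSE
  logx <- matrix(-745, P, nf)
  pos <- totals > 0
  logx[pos] <- log(totals[pos])
  if (!is.null(init_logx)) logx[active] <- init_logx[active]

  conc_of <- function(logx_m, lg_v) {
    if (S == 0) return(matrix(0, nrow(logx_m), 0))
    lc <- logx_m %*% t(N) + outer(lg_v, bexp)
    lc <- sweep(lc, 2, logW, "+")
    exp(lc)
  }
  phi_of <- function(logx_m, C_m, t_m) {
    # totals of 0 pair with frozen logx entries and contribute nothing
    rowSums(C_m) + rowSums(exp(logx_m)) - rowSums(t_m * logx_m * (t_m > 0))
  }

  # damped ratio-update warm start: cheap global progress toward the basin
  # of quadratic Newton convergence, valuable at large gamma where free
  # receptors are depleted by many orders of magnitude
  for (ws in 1:12) {
    C <- conc_of(logx, lg)
    recov <- if (S > 0) C %*% N + exp(logx) else exp(logx)
    step <- log(pmax(recov, .Machine$double.xmin) / pmax(totals, .Machine$double.xmin))
    step[!active] <- 0
    logx <- logx - 0.6 * pmax(pmin(step, 12), -12)
  }

  idx <- seq_len(P)        # unconverged working set
  converged <- rep(FALSE, P)
  residual <- rep(NA_real_, P)
  iters <- 0L

  while (length(idx) > 0 && iters < maxit) {
    iters <- iters + 1L
    lx <- logx[idx, , drop = FALSE]
    tt <- totals[idx, , drop = FALSE]
    ac <- active[idx, , drop = FALSE]
    C <- conc_of(lx, lg[idx])
    X <- exp(lx)
    recov <- if (S > 0) C %*% N + X else X
    grad <- recov - tt
    grad[!ac] <- 0
    rel <- abs(grad) / pmax(tt, .Machine$double.xmin)
    rel[!ac] <- 0
    point_rel <- apply(rel, 1, max)
    residual[idx] <- apply(abs(grad), 1, max)

    done <- point_rel <= tol
    if (any(done)) {
      converged[idx[done]] <- TRUE
      keep <- !done
      idx <- idx[keep]
      if (length(idx) == 0) break
      lx <- lx[keep, , drop = FALSE]; tt <- tt[keep, , drop = FALSE]
      ac <- ac[keep, , drop = FALSE]; C <- C[keep, , drop = FALSE]
      X <- X[keep, , drop = FALSE]; grad <- grad[keep, , drop = FALSE]
    }
    p <- length(idx)

    J <- array(0, c(p, nf, nf))
    for (f in seq_len(nf)) {
      for (h in f:nf) {
        v <- if (S > 0) as.vector(C %*% (N[, f] * N[, h])) else 0
        J[, f, h] <- v
        if (h > f) J[, h, f] <- v
      }
      J[, f, f] <- J[, f, f] + X[, f]
    }
    # frozen (zero-total) coordinates: identity row/col
    for (f in seq_len(nf)) {
      fro <- !ac[, f]
      if (any(fro)) {
        J[fro, f, ] <- 0
        J[fro, , f] <- 0
        J[fro, f, f] <- 1
      }
    }

    delta <- -chol_solve_batch(J, grad)
    # trust cap keeps exp() in range far from the solution
    mx <- apply(abs(delta), 1, max)
    fac <- pmin(1, 8 / pmax(mx, .Machine$double.xmin))
    delta <- delta * fac

    phi0 <- phi_of(lx, C, tt)
    gtd <- rowSums(grad * delta)
    alpha <- rep(1, p)
    # near the solution the objective decrease drops below floating-point
    # noise; a full (undamped) Newton step is then always safe and
    # converges quadratically to the numerical floor
    todo <- point_rel[!done] > 1e-6
    for (ls in 1:40) {
      if (!any(todo)) break
      trial <- lx + alpha * delta
      Ct <- conc_of(trial, lg[idx])
      phit <- phi_of(trial, Ct, tt)
      ok <- is.finite(phit) & (phit <= phi0 + 1e-4 * alpha * gtd)
      todo <- todo & !ok
      alpha[todo] <- alpha[todo] / 2
    }
    logx[idx, ] <- lx + alpha * delta
  }

  # stubborn points (rare, deep-depletion corners) get one fresh attempt
  # with a larger iteration budget, then an ODE-seeded polish
  if (retry && any(!converged)) {
    bad <- which(!converged)
    again <- eq_solve_batch(network, totals[bad, , drop = FALSE], gamma[bad],
                            tol = tol, maxit = 4 * maxit, clamped = clamped,
                            retry = FALSE)
    fixed <- again$converged
    logx[bad[fixed], ] <- log(pmax(again$free[fixed, , drop = FALSE],
                                   .Machine$double.xmin))
    converged[bad] <- again$converged
    still <- which(!converged)
    if (length(still) > 0 && is.null(clamped)) {
      for (i in still) {
        o <- ode_steady_state_one(network, stats::setNames(totals[i, ], colnames(N)),
                                  gamma[i], tol_rate = 1e-10, window = 100,
                                  tmax = 1e7, floor = 1e-12,
                                  rtol = 1e-12, atol = 1e-18)
        if (!o$converged) next
        seed <- matrix(log(pmax(o$free[1, colnames(N)], .Machine$double.xmin)),
                       1, nf)
        pol <- eq_solve_batch(network, totals[i, , drop = FALSE],
                              gamma[i], tol = tol, maxit = maxit,
                              retry = FALSE, init_logx = seed)
        if (pol$converged) {
          logx[i, ] <- log(pmax(pol$free[1, ], .Machine$double.xmin))
          converged[i] <- TRUE
        } else if (o$residual <= tol * max(totals[i, ])) {
          # accept the ODE answer: conservation meets the requested standard
          logx[i, ] <- seed
          converged[i] <- TRUE
        }
      }
    }
  }

  C <- conc_of(logx, lg)
  free <- exp(logx)
  free[totals == 0] <- 0
  if (S > 0) {
    # species containing an absent (zero-total) constituent are exactly zero
    absent <- (totals == 0) %*% t(N > 0) > 0
    C[absent] <- 0
  }
  recov <- if (S > 0) C %*% N + free else free
  residual <- apply(abs(recov - totals) * active, 1, max)
  list(free = free, conc = C, converged = converged, residual = residual,
       iterations = iters)
}

# Batched Cholesky solve of p small SPD systems J[i,,] x = b[i,].
chol_solve_batch <- function(J, b) {
  p <- dim(J)[1]
  nf <- dim(J)[2]
  L <- array(0, dim(J))
  for (i in seq_len(nf)) {
    s <- J[, i, i]
    if (i > 1) for (k in 1:(i - 1)) s <- s - L[, i, k]^2
    L[, i, i] <- sqrt(pmax(s, .Machine$double.xmin))
    if (i < nf) for (j in (i + 1):nf) {
      s <- J[, j, i]
      if (i > 1) for (k in 1:(i - 1)) s <- s - L[, j, k] * L[, i, k]
      L[, j, i] <- s / L[, i, i]
    }
  }
  y <- matrix(0, p, nf)
  for (i in seq_len(nf)) {
    s <- b[, i]
    if (i > 1) for (k in 1:(i - 1)) s <- s - L[, i, k] * y[, k]
    y[, i] <- s / L[, i, i]
  }
  x <- matrix(0, p, nf)
  for (i in rev(seq_len(nf))) {
    s <- y[, i]
    if (i < nf) for (k in (i + 1):nf) s <- s - L[, k, i] * x[, k]
    x[, i] <- s / L[, i, i]
  }
  x
}

#' Integrate the mass-action ODEs to steady state
#'
#' The fidelity route: builds one ordinary differential equation per
#' species (free ligands, free receptors, and every oligomer) from the
#' network's reversible reactions and integrates from the all-free initial
#' condition with `deSolve::lsoda` until the relative rate of change of
#' every species stays below `tol_rate` across a `window`-second interval,
#' or `tmax` is reached (in which case `.converged` is `FALSE`).
#'
#' @inheritParams solve_equilibrium
#' @param tol_rate Steady-state criterion: max over species of
#'   `|dC/dt| / max(C, floor)` must fall below this (per second).
#' @param window Sustain interval (seconds) over which the criterion must
#'   hold at both endpoints.
#' @param tmax Maximum simulated time in seconds.
#' @param floor Concentration floor (nM) in the relative-rate denominator.
#' @param rtol,atol Integrator tolerances.
#' @return A `"bmp_steady_state"` tibble, one row per parameter set (same
#'   layout as [solve_equilibrium()]).
#' @export
#' @examples
#' net <- build_network(bmp_ligands("Bmp2/2"))
#' ps <- tibble::tibble("Bmp2/2" = 0.1, BmpR1 = 5, Acvr1 = 5, TypeII = 5)
#' integrate_to_steady_state(ps, net, gamma = 10)$.converged
integrate_to_steady_state <- function(params, network, gamma = NULL,
                                      tol_rate = 1e-9, window = 100,
                                      tmax = 1e7, floor = 1e-12,
                                      rtol = 1e-10, atol = 1e-16) {
  stopifnot(inherits(network, "bmp_network"))
  params <- tibble::as_tibble(params)
  fn <- network$free_names
  missing <- setdiff(fn, names(params))
  if (length(missing) > 0) {
    stop("params is missing total concentration column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  g_default <- gamma %||% network$kinetics$gamma
  rows <- purrr::map(seq_len(nrow(params)), function(i) {
    g <- if ("gamma" %in% names(params)) params$gamma[i] else g_default
    ode_steady_state_one(network, unlist(params[i, fn]), g,
                         tol_rate, window, tmax, floor, rtol, atol)
  })
  totals <- as.matrix(params[, fn, drop = FALSE])
  g <- if ("gamma" %in% names(params)) params$gamma else rep(g_default, nrow(params))
  sol <- list(
    free = do.call(rbind, purrr::map(rows, "free")),
    conc = do.call(rbind, purrr::map(rows, "conc")),
    converged = purrr::map_lgl(rows, "converged"),
    residual = purrr::map_dbl(rows, "residual")
  )
  assemble_steady_state(network, totals, g, sol)
}

ode_steady_state_one <- function(network, totals, gamma, tol_rate, window,
                                 tmax, floor, rtol, atol) {
  fn <- network$free_names
  sp <- network$species$id
  state_names <- c(fn, sp)
  nF <- length(fn)
  nS <- length(sp)
  rx <- network$reactions
  nR <- if (is.null(rx)) 0L else nrow(rx)
  kon_ref <- network$kinetics$kon_ref

  x0 <- c(unname(totals[fn]), rep(0, nS))

  if (nR == 0) {
    # nothing can react
    return(list(free = matrix(x0[seq_len(nF)], 1, dimnames = list(NULL, fn)),
                conc = matrix(numeric(0), 1, nS, dimnames = list(NULL, sp)),
                converged = TRUE, residual = 0))
  }

  ia <- match(rx$reactant, state_names)
  ib <- match(rx$receptor, state_names)
  ip <- match(rx$product, state_names)
  kon <- rx$m_assoc * kon_ref * ifelse(rx$surface, gamma, 1)
  koff <- rx$m_diss * kon_ref * rx$kd_eff

  Smat <- matrix(0, nF + nS, nR)
  for (r in seq_len(nR)) {
    Smat[ia[r], r] <- Smat[ia[r], r] - 1
    Smat[ib[r], r] <- Smat[ib[r], r] - 1
    Smat[ip[r], r] <- Smat[ip[r], r] + 1
  }

  deriv <- function(t, x, p) {
    v <- kon * x[ia] * x[ib] - koff * x[ip]
    list(as.vector(Smat %*% v))
  }
  rate_ok <- function(x) {
    d <- deriv(0, x, NULL)[[1]]
    max(abs(d) / pmax(x, floor)) <= tol_rate
  }

  t_now <- 0
  x <- x0
  converged <- FALSE
  t_next <- 1000
  while (t_now < tmax) {
    t_seg <- min(t_next, tmax - t_now)
    out <- deSolve::lsoda(x, c(0, t_seg), deriv, parms = NULL,
                          rtol = rtol, atol = atol, maxsteps = 50000)
    x <- pmax(out[nrow(out), -1], 0)
    t_now <- t_now + t_seg
    if (rate_ok(x)) {
      out2 <- deSolve::lsoda(x, c(0, window), deriv, parms = NULL,
                             rtol = rtol, atol = atol, maxsteps = 50000)
      x2 <- pmax(out2[nrow(out2), -1], 0)
      if (rate_ok(x2)) {
        x <- x2
        converged <- TRUE
        break
      }
      x <- x2
      t_now <- t_now + window
    }
    t_next <- t_next * 4
  }

  free <- matrix(x[seq_len(nF)], 1, dimnames = list(NULL, fn))
  conc <- matrix(x[nF + seq_len(nS)], 1, dimnames = list(NULL, sp))
  recov <- as.vector(conc %*% network$stoich) + as.vector(free)
  list(free = free, conc = conc, converged = converged,
       residual = max(abs(recov - unname(totals[fn]))))
}

#' Conservation (mass-balance) report for a steady state
#'
#' Recomputes, for every conserved total (each ligand dimer and each
#' receptor), the amount recovered as free plus bound species and reports
#' the violation against the input totals.
#'
#' @param state A `"bmp_steady_state"` tibble.
#' @param network The network that produced it; defaults to the one
#'   attached to `state`.
#' @return A tibble with one row per parameter set and conserved species:
#'   `.row`, `species`, `total`, `recovered`, `violation` (nM).
#' @export
#' @examples
#' net <- build_network()
#' ps <- tibble::tibble("Bmp2/2" = 0.1, "Bmp7/7" = 0.1, "Bmp2/7" = 0.1,
#'                      BmpR1 = 10, Acvr1 = 10, TypeII = 10, gamma = 100)
#' mass_balance(solve_equilibrium(ps, net))
mass_balance <- function(state, network = attr(state, "network")) {
  stopifnot(inherits(network, "bmp_network"))
  fn <- network$free_names
  sp <- network$species$id
  conc <- as.matrix(state[, intersect(sp, names(state)), drop = FALSE])
  N <- network$stoich[intersect(sp, names(state)), , drop = FALSE]
  free <- as.matrix(state[, paste0("free_", fn), drop = FALSE])
  totals <- as.matrix(state[, paste0("total_", fn), drop = FALSE])
  recov <- free + if (ncol(conc) > 0) conc %*% N else 0
  tibble::tibble(
    .row = rep(seq_len(nrow(state)), times = length(fn)),
    species = rep(fn, each = nrow(state)),
    total = as.vector(totals),
    recovered = as.vector(recov),
    violation = abs(as.vector(recov) - as.vector(totals))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
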