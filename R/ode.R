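#' Default initial condition
#'
#' All PLC-gamma1 starts in the cytosolic autoinhibited unphosphorylated
#' state (nSH2 free, Tyr783 unphosphorylated, cSH2 on the core, core
#' inactive); all receptor is free.  Steady-state results do not depend on
#' how PLC is initially distributed among its 16 states (same totals).
#'
#' @param network a \code{plcg_network}.
#' @param phosphomimetic start instead from the constitutively
#'   phosphorylated autoinhibited state (Tyr783 phosphorylated, cSH2 on
#'   the core).
#' @return named numeric vector of concentrations (uM) over the 17 species.
#' @export
initial_state <- function(network, phosphomimetic = FALSE) {
  p <- network$params
  y0 <- stats::setNames(numeric(nrow(network$species)),
                        network$species$label)
  start <- plc_state_label(data.frame(
    nsh2 = "free", y783 = if (phosphomimetic) "phos" else "unphos",
    csh2 = "core_bound", core = "inactive", stringsAsFactors = FALSE))
  y0[start] <- p$plc_total
  y0["RTK"] <- p$rtk_total
  y0
}

#' Build the mass-action derivative evaluator
#'
#' Returns a pure function computing dc/dt = S v(c), with per-reaction
#' mass-action fluxes v_j = k_j * prod of reactant concentrations.
#'
#' @param network a \code{plcg_network} with rate values bound.
#' @return function(c) -> named derivative vector (uM/s).
#' @export
build_rate_function <- function(network) {
  if (any(network$reactions$rate_value < 0))
    stop("negative rate constant in network")
  S <- network$stoich
  k <- network$reactions$rate_value
  r1 <- vapply(network$reactions$reactants,
               function(s) reaction_side(s)[1], integer(1))
  r2 <- vapply(network$reactions$reactants, function(s) {
    v <- reaction_side(s); if (length(v) > 1) v[2] else NA_integer_
  }, integer(1))
  has2 <- !is.na(r2)
  labels <- network$species$label
  function(conc) {
    v <- k * conc[r1]
    v[has2] <- v[has2] * conc[r2[has2]]
    stats::setNames(as.numeric(S %*% v), labels)
  }
}

#' Active fraction of a concentration vector or matrix
#'
#' Sum of the six active species divided by total PLC.
#' @param network a \code{plcg_network}.
#' @param conc vector (length = n species) or matrix (rows = times).
#' @return numeric scalar or vector.
#' @export
active_fraction <- function(network, conc) {
  idx <- which(network$species$active)
  tot <- network$params$plc_total
  if (is.matrix(conc)) rowSums(conc[, idx, drop = FALSE]) / tot
  else sum(conc[idx]) / tot
}

#' Integrate the compartmental model
#'
#' Stiff integration (deSolve::lsoda) with relative tolerance 1e-8,
#' absolute tolerance 1e-12 uM, and a maximum internal step of 1 s over a
#' 5000 s horizon by default.
#'
#' @param network a \code{plcg_network}.
#' @param y0 initial concentrations (default \code{\link{initial_state}}).
#' @param t_end final time, s.
#' @param max_step maximum solver step, s.
#' @param dt output interval, s.
#' @param times explicit output times (overrides \code{t_end}/\code{dt}).
#' @return object of class \code{plcg_trajectory}: list with \code{times},
#'   \code{conc} (times x species matrix, uM), \code{active_fraction},
#'   \code{network}.
#' @export
simulate_network <- function(network, y0 = initial_state(network),
                             t_end = 5000, max_step = 1, dt = NULL,
                             times = NULL) {
  if (any(y0 < 0)) stop("initial state must be nonnegative")
  if (is.null(times)) {
    if (is.null(dt)) dt <- max(t_end / 5000, 1e-3)
    times <- seq(0, t_end, by = dt)
  }
  S <- network$stoich
  k <- network$reactions$rate_value
  if (any(k < 0)) stop("negative rate constant in network")
  r1 <- vapply(network$reactions$reactants,
               function(s) reaction_side(s)[1], integer(1))
  r2 <- vapply(network$reactions$reactants, function(s) {
    v <- reaction_side(s); if (length(v) > 1) v[2] else NA_integer_
  }, integer(1))
  has2 <- !is.na(r2)
  deriv <- function(t, y, parms) {
    v <- k * y[r1]
    v[has2] <- v[has2] * y[r2[has2]]
    list(as.numeric(S %*% v))
  }
  sol <- deSolve::lsoda(y = y0, times = times, func = deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-12, hmax = max_step)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed (istate = ", attr(sol, "istate")[1], ")")
  conc <- sol[, -1, drop = FALSE]
  if (min(conc) < -1e-9)
    stop("negative concentration excursion beyond tolerance: ", min(conc))
  conc[conc < 0] <- 0
  colnames(conc) <- network$species$label
  structure(list(times = sol[, 1], conc = conc,
                 active_fraction = active_fraction(network, conc),
                 network = network),
            class = "plcg_trajectory")
}

#' @export
print.plcg_trajectory <- function(x, ...) {
  cat(sprintf("PLC-gamma1 trajectory: %d time points over [0, %g] s\n",
              length(x$times), max(x$times)))
  cat(sprintf("  final active fraction: %.6g\n",
              utils::tail(x$active_fraction, 1)))
  invisible(x)
}

#' Conserved totals along a trajectory
#'
#' @param traj a \code{plcg_trajectory}.
#' @return data.frame with per-time PLC and RTK totals (uM).
#' @export
conserved_totals <- function(traj) {
  sp <- traj$network$species
  data.frame(time = traj$times,
             plc = as.numeric(traj$conc %*% sp$plc_content),
             rtk = as.numeric(traj$conc %*% sp$rtk_content))
}

#' Run to steady state
#'
#' Steady state is declared when the horizon (default 5000 s) is reached
#' and the largest derivative, relative to total PLC, is below
#' \code{deriv_tol}; if not, integration is extended (up to
#' \code{max_extend} doublings) so that slow variants still converge.
#'
#' @param network a \code{plcg_network}.
#' @param y0 initial state.
#' @param t_end nominal horizon, s.
#' @param deriv_tol convergence criterion on max|dc/dt|/plc_total (1/s).
#' @param max_extend maximum number of horizon doublings.
#' @inheritParams simulate_network
#' @return list with \code{trajectory}, \code{final_state},
#'   \code{active_fraction_ss}, \code{t_half_activation}, \code{converged}.
#' @export
steady_state <- function(network, y0 = initial_state(network),
                         t_end = 5000, max_step = 1, dt = NULL,
                         deriv_tol = 1e-8, max_extend = 3) {
  f <- build_rate_function(network)
  traj <- simulate_network(network, y0, t_end = t_end,
                           max_step = max_step, dt = dt)
  extend <- 0
  while (extend < max_extend) {
    final <- traj$conc[nrow(traj$conc), ]
    rate <- max(abs(f(final))) / network$params$plc_total
    if (rate < deriv_tol) break
    t_end <- t_end * 2
    extend <- extend + 1
    traj <- simulate_network(network, y0, t_end = t_end,
                             max_step = max_step, dt = dt)
  }
  final <- traj$conc[nrow(traj$conc), ]
  converged <- max(abs(f(final))) / network$params$plc_total < deriv_tol
  a_ss <- utils::tail(traj$active_fraction, 1)
  t_half <- tryCatch(activation_halftime(traj, a_ss), error = function(e) NA_real_)
  list(trajectory = traj, final_state = final, active_fraction_ss = a_ss,
       t_half_activation = t_half, converged = converged)
}

#' Half-time of approach to steady state
#'
#' First time the active fraction crosses half its steady-state value,
#' located by linear interpolation between output points.
#'
#' @param traj a \code{plcg_trajectory} (from rest toward steady state).
#' @param a_ss the steady-state active fraction.
#' @return time, s.
#' @export
activation_halftime <- function(traj, a_ss) {
  first_crossing(traj$times, traj$active_fraction, a_ss / 2,
                 direction = "up")
}

# linear-interpolated first crossing of y(t) = level
first_crossing <- function(times, y, level, direction = c("up", "down")) {
  direction <- match.arg(direction)
  hit <- if (direction == "up") y >= level else y <= level
  if (hit[1]) return(times[1])
  i <- which(hit)[1]
  if (is.na(i)) stop("crossing of level ", level, " not bracketed")
  t0 <- times[i - 1]; t1 <- times[i]
  y0 <- y[i - 1]; y1 <- y[i]
  if (y1 == y0) return(t1)
  t0 + (level - y0) / (y1 - y0) * (t1 - t0)
}
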