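#' Spatial grid for the 1D polarization model
#'
#' Cell-centered uniform grid on a 1D domain with no-flux boundaries.
#' The default 30 um length is a typical fibroblast dimension; geometry
#' is configurable and recorded in run manifests.
#'
#' @param length domain length, um.
#' @param n_points number of grid cells (>= 50 recommended for
#'   production runs; coarser grids are fine for quick scans given the
#'   smooth fields).
#' @return list with \code{length}, \code{n_points}, \code{dx},
#'   \code{x} (cell-center coordinates, um).
#' @export
spatial_grid <- function(length = 30, n_points = 60) {
  if (n_points < 1) stop("n_points must be >= 1")
  dx <- length / n_points
  list(length = length, n_points = n_points, dx = dx,
       x = (seq_len(n_points) - 0.5) * dx)
}

#' Fractional receptor-occupancy profile
#'
#' Linear gradient r(x) = rfrac (1 + steepness (x/L - 1/2)): the spatial
#' mean equals \code{rfrac} and the front-minus-back difference relative
#' to the mean equals \code{steepness}.  The front (up-gradient end) is
#' at x = L.
#'
#' @param rfrac mean fractional receptor occupancy, in [0, 1].
#' @param steepness relative gradient (default 0.10, i.e. 10\%); a
#'   negative value mirrors the gradient (front at x = 0).
#' @param grid a \code{\link{spatial_grid}}.
#' @return numeric field over grid cells.
#' @export
receptor_profile <- function(rfrac, steepness = 0.10, grid = spatial_grid()) {
  if (rfrac < 0 || rfrac > 1) stop("rfrac must be in [0, 1]")
  if (abs(steepness) >= 2) stop("|steepness| must be < 2")
  r <- rfrac * (1 + steepness * (grid$x / grid$length - 0.5))
  if (any(r < 0 | r > 1))
    stop("receptor profile leaves [0, 1]; reduce rfrac or steepness")
  r
}

#' Phosphatidic-acid feedback multiplier (PFL 1*)
#'
#' PA at the membrane enhances the frequency of catalytic-core membrane
#' insertion; both \code{k_act} and \code{k_act_2} are multiplied locally
#' by 1 + K_PA d_p.
#'
#' @param d_p local PA density, um^-2 (>= 0).
#' @param K_PA feedback constant, um^2 (default 10).
#' @return dimensionless multiplier >= 1.
#' @export
pfl1star_factor <- function(d_p, K_PA = 10) {
  if (any(d_p < 0)) stop("d_p must be >= 0")
  1 + K_PA * d_p
}

#' PKC-driven PA production (PFL 2)
#'
#' Active PKC stimulates phospholipase D and hence PA synthesis, modeled
#' as a Hill function gamma_V_synth_dp * pkc^n / (K_PLD^n + pkc^n).
#'
#' @param pkc_active local active-PKC level (>= 0).
#' @param n Hill coefficient (default 2).
#' @param K_PLD half-saturation PKC activity (default 0.1).
#' @param gamma_V_synth_dp maximal production rate (default 10).
#' @return production rate added to the PA balance.
#' @export
pfl2_rate <- function(pkc_active, n = 2, K_PLD = 0.1,
                      gamma_V_synth_dp = 10) {
  pk <- pkc_active^n
  gamma_V_synth_dp * pk / (K_PLD^n + pk)
}

#' Downstream lipid-circuit parameters
#'
#' Parameters coupling the 16-state PLC-gamma1 network to a stand-in
#' PIP2/DAG/PA/MARCKS/PKC circuit.  The coupling mechanics (receptor
#' availability correction, hydrolysis driven by the six active PLC
#' species, PA enhancement of membrane insertion) are fixed; every
#' stand-in rate of the downstream circuit is a named parameter here so
#' alternative circuit formulations can be substituted without code
#' changes.
#'
#' @param ... named overrides.  Defaults: \code{K_PA = 10} um^2;
#'   \code{k_DAGK = 0.2} s^-1; PFL 2 disabled with \code{pfl2_n = 2},
#'   \code{K_PLD = 0.1}, \code{gamma_V_synth_dp = 10}; MARCKS enabled;
#'   diffusivities \code{D_cyt = 19}, \code{D_mem = 0.01} um^2/s;
#'   spatial receptor-binding constants \code{k_on_nSH2_sp = 0.1}
#'   uM^-1 s^-1, \code{k_off_nSH2_sp = 0.1} s^-1; receptor scale
#'   \code{r_total = 0.05} uM; \code{rfrac = 0.077};
#'   \code{steepness = 0.10}.  Stand-in circuit rates: PIP2 resynthesis
#'   \code{k_Psynth = 5} s^-1 toward the resting level \code{P0 = 1}
#'   (relative units); hydrolysis throughput \code{k_hyd = 20000}
#'   uM^-1 s^-1 per unit available PIP2; basal DAG consumption
#'   \code{k_Dcons = 2} s^-1; PA turnover \code{k_PAturn = 1} s^-1;
#'   cooperative PKC activation by DAG with \code{K_DAG = 1},
#'   \code{n_PKC = 2}, \code{k_PKCact = 0.03}, deactivation
#'   \code{k_PKCdeact = 1} s^-1, total 1; MARCKS membrane association
#'   \code{k_Mon = 0.1} s^-1, basal release \code{k_Moff0 = 0.01}
#'   s^-1, PKC-driven release \code{k_MoffC = 6} s^-1, PIP2
#'   sequestration strength \code{marcks_seq = 0.9}.  These scales put
#'   the PA feedback in an engaged regime (K_PA d_p of order 1-10 at the
#'   front of a responding cell) while keeping back-of-cell PKC below
#'   the PLD threshold \code{K_PLD}.
#' @return list of class \code{plcg_circuit}.
#' @export
circuit_params <- function(...) {
  cp <- list(
    K_PA = 10, k_DAGK = 0.2,
    pfl2_enabled = FALSE, pfl2_n = 2, K_PLD = 0.1, gamma_V_synth_dp = 10,
    marcks_enabled = TRUE,
    D_cyt = 19, D_mem = 0.01,
    k_on_nSH2_sp = 0.1, k_off_nSH2_sp = 0.1,
    r_total = 0.05, rfrac = 0.077, steepness = 0.10,
    P0 = 1, k_Psynth = 5, k_hyd = 20000, k_Dcons = 2, k_PAturn = 1,
    K_DAG = 1, n_PKC = 2, k_PKCact = 0.03, k_PKCdeact = 1, pkc_total = 1,
    k_Mon = 0.1, k_Moff0 = 0.01, k_MoffC = 6, marcks_seq = 0.9
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cp))
  if (length(bad)) stop("unknown circuit parameter(s): ",
                        paste(bad, collapse = ", "))
  cp[names(dots)] <- dots
  structure(cp, class = "plcg_circuit")
}

.circuit_vars <- c("PIP2", "DAG", "PA", "MARCKS", "PKC")

#' Build the 1D reaction-diffusion model
#'
#' Method-of-lines system over the grid.  All 16 PLC-gamma1 states react
#' locally and diffuse (cytosolic states at \code{D_cyt}, receptor- or
#' membrane-bound states at \code{D_mem}).  Three couplings embed the
#' activation network in the lipid circuit: (1) receptor availability in
#' the nSH2-binding rate laws is the local active-receptor density minus
#' the sum of the eight receptor-bound PLC species; (2) the PIP2
#' hydrolysis flux is proportional to the sum of the six active PLC
#' species times available PIP2; (3) PA multiplies the membrane-insertion
#' rate constants via \code{\link{pfl1star_factor}} (PFL 1*).  The
#' receptor binding constants are overridden to their spatial values
#' (\code{k_on_nSH2_sp}, \code{k_off_nSH2_sp}); all other rule constants
#' keep their base values unless edited in \code{params}.
#'
#' @param circuit a \code{\link{circuit_params}} object.
#' @param grid a \code{\link{spatial_grid}}.
#' @param params compartmental parameter set supplying the PLC rule
#'   constants (variant edits enter here).
#' @param diffusion logical; disable to drop all transport terms.
#' @return list of class \code{plcg_spatial_model} with the derivative
#'   function, indices, grid, circuit, network.
#' @export
build_spatial_model <- function(circuit = circuit_params(),
                                grid = spatial_grid(),
                                params = plcg_parameters(),
                                diffusion = TRUE) {
  p <- params
  p$k_on_nSH2 <- circuit$k_on_nSH2_sp
  p$k_off_nSH2 <- circuit$k_off_nSH2_sp
  net <- generate_network(params = p)

  sp <- net$species
  plc_rows <- which(sp$kind != "rtk_free")          # 16 PLC species
  S_plc <- t(net$stoich[plc_rows, , drop = FALSE])  # reactions x 16
  k <- net$reactions$rate_value
  # reactant PLC species (position within plc_rows) per reaction
  r1 <- vapply(net$reactions$reactants,
               function(s) reaction_side(s)[1], integer(1))
  r1 <- match(r1, plc_rows)
  bimol <- net$reactions$rule %in%
    c("nSH2_bind_RTK_core_inactive", "nSH2_bind_RTK_core_active")
  act_rule <- net$reactions$rate_name %in% c("k_act", "k_act_2")

  active_cols <- which(sp$active[plc_rows])
  bound_cols <- which(sp$rtk_bound[plc_rows])
  cyt_cols <- which(sp$cytosolic[plc_rows])
  n_plc <- length(plc_rows)
  nvar <- n_plc + length(.circuit_vars)
  N <- grid$n_points

  D_spec <- c(ifelse(sp$cytosolic[plc_rows], circuit$D_cyt, circuit$D_mem),
              rep(circuit$D_mem, length(.circuit_vars)))
  r_field <- receptor_profile(circuit$rfrac, circuit$steepness, grid) *
    circuit$r_total
  dx2 <- grid$dx^2

  iP <- n_plc + 1L; iD <- n_plc + 2L; iA <- n_plc + 3L
  iM <- n_plc + 4L; iC <- n_plc + 5L

  lap <- function(u) {
    if (N == 1) return(0)
    (c(u[1], u[-N]) - 2 * u + c(u[-1], u[N])) / dx2  # reflecting ends
  }

  deriv <- function(t, y, parms) {
    Y <- matrix(y, nrow = N, ncol = nvar)
    C_plc <- Y[, seq_len(n_plc), drop = FALSE]
    P <- Y[, iP]; Dg <- Y[, iD]; A <- Y[, iA]; M <- Y[, iM]; Ck <- Y[, iC]

    avail <- r_field - rowSums(C_plc[, bound_cols, drop = FALSE])
    avail <- pmax(avail, 0)
    fb <- pfl1star_factor(pmax(A, 0), circuit$K_PA)

    # mass-action fluxes, vectorized over grid cells: N x 53
    V <- C_plc[, r1, drop = FALSE] * rep(k, each = N)
    if (any(bimol)) V[, bimol] <- V[, bimol, drop = FALSE] * avail
    if (any(act_rule)) V[, act_rule] <- V[, act_rule, drop = FALSE] * fb
    dPLC <- V %*% S_plc

    plc_act <- rowSums(C_plc[, active_cols, drop = FALSE])
    P_avail <- pmax(P * (1 - circuit$marcks_seq * M), 0)
    V_hyd <- circuit$k_hyd * plc_act * P_avail

    dP <- circuit$k_Psynth * (circuit$P0 - P) - V_hyd
    dDg <- V_hyd - (circuit$k_DAGK + circuit$k_Dcons) * Dg
    dA <- circuit$k_DAGK * Dg - circuit$k_PAturn * A
    if (circuit$pfl2_enabled)
      dA <- dA + pfl2_rate(pmax(Ck, 0), circuit$pfl2_n, circuit$K_PLD,
                           circuit$gamma_V_synth_dp)
    hD <- pmax(Dg, 0)^circuit$n_PKC
    hD <- hD / (circuit$K_DAG^circuit$n_PKC + hD)
    dCk <- circuit$k_PKCact * hD * (circuit$pkc_total - Ck) -
      circuit$k_PKCdeact * Ck
    dM <- if (circuit$marcks_enabled) {
      circuit$k_Mon * (1 - M) - (circuit$k_Moff0 + circuit$k_MoffC * Ck) * M
    } else 0 * M

    dY <- cbind(dPLC, dP, dDg, dA, dM, dCk)
    if (diffusion && N > 1)
      for (j in seq_len(nvar)) dY[, j] <- dY[, j] + D_spec[j] * lap(Y[, j])
    list(as.numeric(dY))
  }

  structure(list(deriv = deriv, grid = grid, circuit = circuit,
                 network = net, n_plc = n_plc, nvar = nvar,
                 plc_rows = plc_rows, r_field = r_field,
                 idx = list(P = iP, DAG = iD, PA = iA, MARCKS = iM,
                            PKC = iC),
                 D_spec = D_spec),
            class = "plcg_spatial_model")
}

#' Initial fields for the spatial model
#'
#' PLC uniformly distributed in the cytosolic autoinhibited state; PIP2
#' at its resting level; DAG, PA, and active PKC at zero; membrane
#' MARCKS at its PKC-free equilibrium.
#'
#' @param model a \code{plcg_spatial_model}.
#' @return numeric vector (n_points x n variables, column-major by
#'   variable).
#' @export
spatial_initial_state <- function(model) {
  cp <- model$circuit
  N <- model$grid$n_points
  Y <- matrix(0, N, model$nvar)
  start_label <- plc_state_label(data.frame(
    nsh2 = "free", y783 = "unphos", csh2 = "core_bound",
    core = "inactive", stringsAsFactors = FALSE))
  j <- match(start_label, model$network$species$label[model$plc_rows])
  Y[, j] <- model$network$params$plc_total
  Y[, model$idx$P] <- cp$P0
  if (cp$marcks_enabled)
    Y[, model$idx$MARCKS] <- cp$k_Mon / (cp$k_Mon + cp$k_Moff0)
  as.numeric(Y)
}

#' Simulate the polarization model
#'
#' Integrates the method-of-lines system and classifies the outcome:
#' steady if the envelope of active PKC at each domain end varies by less
#' than \code{envelope_tol} (relative) over the last
#' \code{window_frac} of the run, otherwise oscillating (with min/max
#' envelopes reported).  The polarization readout is the front/back
#' ratio of active PKC (front = up-gradient end).
#'
#' @param model a \code{plcg_spatial_model}.
#' @param t_end integration horizon, s.
#' @param n_out number of stored time points.
#' @param envelope_tol relative envelope width below which the run is
#'   called steady (default 1\%).
#' @param window_frac trailing fraction of the run inspected.
#' @return list of class \code{plcg_polarization}: \code{times},
#'   \code{fields} (array time x cell x variable), \code{front_value},
#'   \code{back_value}, \code{front_back_ratio}, \code{oscillating},
#'   \code{envelope}, \code{model}.
#' @export
simulate_polarization <- function(model, t_end = 2000, n_out = 200,
                                  envelope_tol = 0.01,
                                  window_frac = 0.1) {
  y0 <- spatial_initial_state(model)
  times <- seq(0, t_end, length.out = n_out + 1)
  N <- model$grid$n_points
  sol <- deSolve::ode.1D(y = y0, times = times, func = model$deriv,
                         parms = NULL, nspec = model$nvar, dimens = N,
                         method = "lsodes", rtol = 1e-6, atol = 1e-10,
                         lrw = 500000L + 200L * length(y0))
  if (attr(sol, "istate")[1] < 0) stop("spatial solver failed")
  fields <- array(sol[, -1], dim = c(nrow(sol), N, model$nvar))
  pkc <- fields[, , model$idx$PKC]
  if (N == 1) pkc <- matrix(pkc, ncol = 1)
  win <- times >= (1 - window_frac) * t_end
  front_win <- pkc[win, N]; back_win <- pkc[win, 1]
  env <- function(v) c(min = min(v), max = max(v))
  rel_width <- function(v) {
    m <- mean(v); if (m <= 0) 0 else (max(v) - min(v)) / m
  }
  oscillating <- rel_width(front_win) > envelope_tol ||
    rel_width(back_win) > envelope_tol
  front_value <- if (oscillating) mean(front_win) else front_win[length(front_win)]
  back_value <- if (oscillating) mean(back_win) else back_win[length(back_win)]
  structure(list(
    times = times, fields = fields,
    front_value = front_value, back_value = back_value,
    front_back_ratio = if (back_value > 0) front_value / back_value else NA_real_,
    oscillating = oscillating,
    envelope = list(front = env(front_win), back = env(back_win)),
    model = model), class = "plcg_polarization")
}

#' @export
print.plcg_polarization <- function(x, ...) {
  cat(sprintf("polarization run: front/back active PKC = %.4g / %.4g (ratio %.3g)%s\n",
              x$front_value, x$back_value, x$front_back_ratio,
              if (x$oscillating) " [oscillating]" else ""))
  invisible(x)
}

#' Sweep the mean receptor occupancy
#'
#' Runs the polarization model over a grid of mean fractional receptor
#' occupancies and reports the front/back readouts, flagging the
#' occupancy with the highest steady front/back ratio.
#'
#' @param rfrac_values occupancy grid.
#' @param circuit base circuit parameters (rfrac overridden per point).
#' @param grid,params,t_end passed through.
#' @param ... further arguments to \code{\link{simulate_polarization}}.
#' @return data.frame (rfrac, front, back, ratio, oscillating, error)
#'   with attribute \code{best_rfrac} (highest steady ratio).
#' @export
dose_sweep <- function(rfrac_values, circuit = circuit_params(),
                       grid = spatial_grid(), params = plcg_parameters(),
                       t_end = 2000, ...) {
  rows <- lapply(rfrac_values, function(rf) {
    out <- data.frame(rfrac = rf, front = NA_real_, back = NA_real_,
                      ratio = NA_real_, oscillating = NA,
                      error = NA_character_, stringsAsFactors = FALSE)
    tryCatch({
      cp <- circuit; cp$rfrac <- rf
      m <- build_spatial_model(cp, grid, params)
      res <- simulate_polarization(m, t_end = t_end, ...)
      out$front <- res$front_value; out$back <- res$back_value
      out$ratio <- res$front_back_ratio
      out$oscillating <- res$oscillating
    }, error = function(e) out$error <<- conditionMessage(e))
    out
  })
  res <- do.call(rbind, rows)
  steady <- !is.na(res$ratio) & !res$oscillating
  attr(res, "best_rfrac") <-
    if (any(steady)) res$rfrac[steady][which.max(res$ratio[steady])] else NA_real_
  res
}
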