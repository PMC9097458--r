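#' Receptor dose-response of steady-state activation
#'
#' One steady-state run per receptor concentration.  The steady-state
#' active fraction is monotone nondecreasing in the receptor input.
#'
#' @param params a \code{plcg_parameters} object (its \code{rtk_total} is
#'   overridden per dose).
#' @param rtk_values receptor concentrations to sweep, uM; default spans
#'   the standard input range 0.005--0.05 uM.
#' @param phosphomimetic simulate the constitutively phosphorylated
#'   limiting case (initial Tyr783 phosphorylated, dephosphorylation off).
#' @param ... passed to \code{\link{steady_state}}.
#' @return data.frame (rtk_total, active_fraction_ss, t_half, converged).
#' @export
dose_response <- function(params = plcg_parameters(),
                          rtk_values = seq(0.005, 0.05, length.out = 10),
                          phosphomimetic = FALSE, ...) {
  if (any(rtk_values < 0)) stop("receptor concentrations must be >= 0")
  rows <- lapply(rtk_values, function(r) {
    p <- params
    p$rtk_total <- r
    if (phosphomimetic) p$k_dephos <- 0
    net <- generate_network(params = p)
    ss <- tryCatch(
      steady_state(net, y0 = initial_state(net, phosphomimetic), ...),
      error = function(e) stop("dose rtk_total = ", r, ": ",
                               conditionMessage(e), call. = FALSE))
    data.frame(rtk_total = r, active_fraction_ss = ss$active_fraction_ss,
               t_half = ss$t_half_activation, converged = ss$converged)
  })
  do.call(rbind, rows)
}

#' Lifetime (decay) protocol
#'
#' Runs to steady state, then shuts off recruitment of PLC-gamma1 from
#' the cytosol: the two rules whose reactants are cytosolic species
#' (nSH2 capture of the inactive enzyme, \code{k_on_nSH2}, and direct
#' membrane insertion from the cytosol, \code{k_act}) are zeroed at the
#' switch time, while the receptor-proximal rebinding rules keep their
#' pre-switch absolute values (\code{k_on_nSH2_2}, \code{k_act_2}); the
#' decay of the active species is then followed and its half-life
#' measured as the time after the switch for the active fraction to reach
#' half its value at the switch.
#'
#' @param params a \code{plcg_parameters} object.
#' @param switch_time time at which recruitment is shut off, s.
#' @param t_follow how long to follow the decay after the switch, s.
#' @param phosphomimetic as in \code{\link{dose_response}}.
#' @param deriv_tol steady-state criterion at the switch.
#' @return list with \code{pre} and \code{post} trajectories,
#'   \code{half_life} (s), \code{active_at_switch}.
#' @export
decay_protocol <- function(params = plcg_parameters(), switch_time = 5000,
                           t_follow = 20000, phosphomimetic = FALSE,
                           deriv_tol = 1e-8) {
  p0 <- params
  if (phosphomimetic) p0$k_dephos <- 0
  net <- generate_network(params = p0)
  ss <- steady_state(net, y0 = initial_state(net, phosphomimetic),
                     t_end = switch_time, deriv_tol = deriv_tol,
                     max_extend = 0)
  if (!ss$converged)
    stop("steady state not converged at switch_time = ", switch_time, " s")
  d <- derived_constants(p0)
  p1 <- p0
  p1$k_on_nSH2 <- 0
  p1$k_act <- 0
  p1$k_on_nSH2_2 <- d$k_on_nSH2_2  # freeze rebinding at pre-switch values
  p1$k_act_2 <- d$k_act_2
  net1 <- generate_network(params = p1)
  a0 <- ss$active_fraction_ss
  half_life <- NA_real_
  for (try in 1:4) {  # extend the follow-up window for slow variants
    times <- sort(unique(c(seq(0, min(100, t_follow), by = 0.2),
                           seq(0, t_follow, length.out = 4000))))
    post <- simulate_network(net1, y0 = ss$final_state, times = times)
    half_life <- tryCatch(
      first_crossing(post$times, post$active_fraction, a0 / 2,
                     direction = "down"),
      error = function(e) NA_real_)
    if (!is.na(half_life)) break
    t_follow <- t_follow * 4
  }
  if (is.na(half_life))
    stop("active fraction did not reach half its switch value within ",
         t_follow, " s")
  list(pre = ss$trajectory, post = post, half_life = half_life,
       active_at_switch = a0)
}
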