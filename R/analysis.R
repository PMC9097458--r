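#' Hypothetical activating variants
#'
#' Activating mutations of PLC-gamma1 are mimicked by parameter edits of
#' two mechanistic classes: disruption of the cSH2--core autoinhibition
#' (K_c variants) and enhanced membrane affinity of the uninhibited core
#' (K_a variants).  Edits to \code{k_act} propagate automatically to the
#' chi-coupled \code{k_act_2}, preserving detailed balance.
#'
#' @param fold fold-change applied by each edit (default 10, applied
#'   down for on-rates of autoinhibition / inactivation and up for the
#'   activating direction).
#' @param include_phospho also return the nonphosphorylatable (Y783F,
#'   \code{k_phos = 0}) and phosphomimetic limiting cases.
#' @return list of variant specs; each has \code{name}, \code{class}
#'   (\code{"Kc"}, \code{"Ka"}, \code{"phospho"}), \code{edits} (named
#'   multiplicative factors), \code{set} (named absolute assignments),
#'   and \code{phosphomimetic} flag.
#' @export
standard_variants <- function(fold = 10, include_phospho = FALSE) {
  v <- list(
    list(name = "Kc_i_bind_c_down", class = "Kc",
         edits = c(k_bind_c = 1 / fold)),
    list(name = "Kc_ii_unbind_c_up", class = "Kc",
         edits = c(k_unbind_c = fold)),
    list(name = "Kc_iii_both", class = "Kc",
         edits = c(k_bind_c = 1 / fold, k_unbind_c = fold)),
    list(name = "Ka_iv_act_up", class = "Ka",
         edits = c(k_act = fold)),
    list(name = "Ka_v_inact_down", class = "Ka",
         edits = c(k_inact = 1 / fold)),
    list(name = "Ka_vi_both", class = "Ka",
         edits = c(k_act = fold, k_inact = 1 / fold))
  )
  if (include_phospho) {
    v <- c(v, list(
      list(name = "Y783F", class = "phospho", set = c(k_phos = 0)),
      list(name = "phosphomimetic", class = "phospho",
           set = c(k_dephos = 0), phosphomimetic = TRUE)
    ))
  }
  for (i in seq_along(v)) {
    v[[i]]$edits <- if (is.null(v[[i]]$edits)) numeric(0) else v[[i]]$edits
    v[[i]]$set <- if (is.null(v[[i]]$set)) numeric(0) else v[[i]]$set
    if (is.null(v[[i]]$phosphomimetic)) v[[i]]$phosphomimetic <- FALSE
  }
  v
}

#' Apply a variant to a parameter set
#'
#' @param params base \code{plcg_parameters}.
#' @param variant one element of \code{\link{standard_variants}} (or a
#'   list with \code{edits} and/or \code{set} entries).
#' @return edited \code{plcg_parameters}; chi-derived constants stay
#'   coupled, so a 10x edit of \code{k_act} also scales \code{k_act_2}.
#' @export
apply_variant <- function(params, variant) {
  p <- params
  for (nm in names(variant$edits)) {
    if (!nm %in% .param_names) stop("unknown parameter in variant: ", nm)
    p[[nm]] <- p[[nm]] * variant$edits[[nm]]
  }
  for (nm in names(variant$set)) {
    if (!nm %in% .param_names) stop("unknown parameter in variant: ", nm)
    p[[nm]] <- variant$set[[nm]]
  }
  validate_parameters(p)
}

#' Two-state reduction of an activation time course
#'
#' The full 16-state activation kinetics are summarized by a reduced
#' model dA/dt = kf (1 - A) - kr A, whose relaxation rate is kf + kr and
#' steady state is kf / (kf + kr).  Identifying the relaxation half-time
#' with the measured activation half-time gives
#' kf_app = a_ss ln2 / t_half and kr_app = (1 - a_ss) ln2 / t_half.
#'
#' @param a_ss steady-state active fraction, in (0, 1).
#' @param t_half activation half-time, s (> 0).
#' @return list with \code{kf_app}, \code{kr_app} (s^-1), \code{a_ss},
#'   \code{t_half}.
#' @examples
#' fit_two_state(0.5, log(2))  # kf = kr = 0.5 /s
#' @export
fit_two_state <- function(a_ss, t_half) {
  if (!is.finite(a_ss) || a_ss <= 0 || a_ss >= 1)
    stop("a_ss must be in (0, 1)")
  if (!is.finite(t_half) || t_half <= 0)
    stop("t_half must be > 0")
  lambda <- log(2) / t_half
  list(kf_app = a_ss * lambda, kr_app = (1 - a_ss) * lambda,
       a_ss = a_ss, t_half = t_half)
}

#' Closed-form two-state activation trajectory
#'
#' A(t) = a_ss (1 - exp(-(kf + kr) t)) with a_ss = kf / (kf + kr); used
#' as an independent oracle for the reduction.
#'
#' @param kf,kr forward / reverse rate constants, s^-1.
#' @param times output times, s.
#' @return data.frame (time, active_fraction).
#' @export
two_state_trajectory <- function(kf, kr, times) {
  a_ss <- kf / (kf + kr)
  data.frame(time = times,
             active_fraction = a_ss * (1 - exp(-(kf + kr) * times)))
}

#' Scan activation and decay kinetics over variants
#'
#' For the base parameter set and each variant, runs one activation time
#' course to steady state and one decay (lifetime) protocol at a fixed
#' receptor dose, then reduces each activation course to apparent
#' two-state rate constants.
#'
#' @param params base \code{plcg_parameters} (with the scan dose set in
#'   \code{rtk_total}; default 0.05 uM, the top of the receptor input
#'   range, so every variant is well activated).
#' @param variants list of variant specs; default the six 10-fold
#'   K_c / K_a variants.
#' @param include_base prepend the unedited base case.
#' @param decay also run the lifetime protocol per variant.
#' @return data.frame with one row per case: \code{variant},
#'   \code{class}, \code{a_ss}, \code{t_half}, \code{kf_app},
#'   \code{kr_app}, \code{decay_half_life}, \code{predicted_half_life}
#'   (= ln2 / kr_app), \code{error}.  Attribute
#'   \code{t_half_fold_range} gives max/min t_half across the scanned
#'   cases.
#' @export
variant_scan <- function(params = plcg_parameters(),
                         variants = standard_variants(),
                         include_base = TRUE, decay = TRUE) {
  cases <- list()
  if (include_base)
    cases <- list(list(name = "base", class = "base",
                       edits = numeric(0), set = numeric(0),
                       phosphomimetic = FALSE))
  cases <- c(cases, variants)
  rows <- lapply(cases, function(v) {
    out <- data.frame(variant = v$name, class = v$class, a_ss = NA_real_,
                      t_half = NA_real_, kf_app = NA_real_,
                      kr_app = NA_real_, decay_half_life = NA_real_,
                      predicted_half_life = NA_real_,
                      error = NA_character_, stringsAsFactors = FALSE)
    tryCatch({
      p <- apply_variant(params, v)
      net <- generate_network(params = p)
      ss <- steady_state(net, y0 = initial_state(net, v$phosphomimetic))
      fit <- fit_two_state(ss$active_fraction_ss, ss$t_half_activation)
      out$a_ss <- ss$active_fraction_ss
      out$t_half <- ss$t_half_activation
      out$kf_app <- fit$kf_app
      out$kr_app <- fit$kr_app
      out$predicted_half_life <- log(2) / fit$kr_app
      if (decay) {
        dp <- decay_protocol(p, phosphomimetic = v$phosphomimetic)
        out$decay_half_life <- dp$half_life
      }
    }, error = function(e) out$error <<- conditionMessage(e))
    out
  })
  res <- do.call(rbind, rows)
  ok <- !is.na(res$t_half)
  attr(res, "t_half_fold_range") <-
    if (any(ok)) max(res$t_half[ok]) / min(res$t_half[ok]) else NA_real_
  res
}
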