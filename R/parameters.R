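#' Model parameters
#'
#' The base parameter set of the PLC-gamma1 model.  Rate constants are in
#' s^-1 except the bimolecular nSH2--receptor association rate
#' (uM^-1 s^-1).  The enhancement factor \code{chi} couples two rules:
#' receptor binding of the membrane-inserted (active) enzyme
#' (\code{k_on_nSH2_2 = chi * k_on_nSH2}) and membrane insertion of the
#' receptor-anchored enzyme (\code{k_act_2 = chi * k_act}).  Using one
#' shared factor satisfies detailed balance for assembly of the
#' canonically active state.
#'
#' @name plc-parameters
NULL

.param_names <- c("k_on_nSH2", "k_off_nSH2", "k_phos", "k_dephos",
                  "k_bind_c", "k_unbind_c", "k_bind_p", "k_unbind_p",
                  "k_act", "k_inact", "chi", "plc_total", "rtk_total")

# optional absolute overrides of the chi-derived constants (used by the
# decay protocol, which freezes rebinding rates while zeroing recruitment)
.override_names <- c("k_on_nSH2_2", "k_act_2")

#' Construct a parameter set
#'
#' Defaults are the base values of the model: k_on_nSH2 = 1 uM^-1 s^-1,
#' k_off_nSH2 = 1, k_phos = 1, k_dephos = 1, k_bind_c = 100,
#' k_unbind_c = 1, k_bind_p = 100, k_unbind_p = 1, k_act = 0.01,
#' k_inact = 0.1 (all s^-1), chi = 1000, with total PLC-gamma1 at 0.02 uM
#' and receptor input 0.005--0.05 uM (default 0.05).
#'
#' @param ... named overrides of any base parameter, or of the derived
#'   constants \code{k_on_nSH2_2} / \code{k_act_2} (normally left
#'   chi-coupled; an absolute override decouples that rule).
#' @return object of class \code{plcg_parameters} (a named list).
#' @examples
#' p <- plcg_parameters()
#' derived_constants(p)$K_c   # 100
#' @export
plcg_parameters <- function(...) {
  p <- list(k_on_nSH2 = 1, k_off_nSH2 = 1, k_phos = 1, k_dephos = 1,
            k_bind_c = 100, k_unbind_c = 1, k_bind_p = 100, k_unbind_p = 1,
            k_act = 0.01, k_inact = 0.1, chi = 1000,
            plc_total = 0.02, rtk_total = 0.05,
            k_on_nSH2_2 = NULL, k_act_2 = NULL)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), c(.param_names, .override_names))
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_parameters(structure(p, class = "plcg_parameters"))
}

validate_parameters <- function(p) {
  rates <- unlist(p[c("k_on_nSH2", "k_off_nSH2", "k_phos", "k_dephos",
                      "k_bind_c", "k_unbind_c", "k_bind_p", "k_unbind_p",
                      "k_act", "k_inact")])
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0")
  if (!is.finite(p$chi) || p$chi <= 0) stop("chi must be > 0")
  if (p$plc_total < 0 || p$rtk_total < 0)
    stop("totals must be nonnegative")
  p
}

#' Derived equilibrium and coupled rate constants
#'
#' @param p a \code{plcg_parameters} object.
#' @return list with \code{k_on_nSH2_2}, \code{k_act_2} (chi-coupled
#'   unless explicitly overridden), and the equilibrium constants
#'   \code{K_p} (cSH2--pTyr783), \code{K_c} (autoinhibition),
#'   \code{K_a} (membrane association), \code{K_D} (nSH2--RTK
#'   dissociation, uM).
#' @export
derived_constants <- function(p) {
  list(
    k_on_nSH2_2 = if (is.null(p$k_on_nSH2_2)) p$chi * p$k_on_nSH2 else p$k_on_nSH2_2,
    k_act_2     = if (is.null(p$k_act_2)) p$chi * p$k_act else p$k_act_2,
    K_p = p$k_bind_p / p$k_unbind_p,
    K_c = p$k_bind_c / p$k_unbind_c,
    K_a = p$k_act / p$k_inact,
    K_D = p$k_off_nSH2 / p$k_on_nSH2
  )
}

#' Resolve every rule rate constant to a numeric value
#'
#' @param p a \code{plcg_parameters} object.
#' @return named numeric vector over the 12 rule rate-constant names.
#' @keywords internal
rate_values <- function(p) {
  d <- derived_constants(p)
  c(k_on_nSH2 = p$k_on_nSH2, k_on_nSH2_2 = d$k_on_nSH2_2,
    k_off_nSH2 = p$k_off_nSH2, k_phos = p$k_phos, k_dephos = p$k_dephos,
    k_bind_c = p$k_bind_c, k_unbind_c = p$k_unbind_c,
    k_bind_p = p$k_bind_p, k_unbind_p = p$k_unbind_p,
    k_act = p$k_act, k_act_2 = d$k_act_2, k_inact = p$k_inact)
}

#' @export
print.plcg_parameters <- function(x, ...) {
  d <- derived_constants(x)
  cat("PLC-gamma1 parameter set\n")
  for (nm in .param_names)
    cat(sprintf("  %-11s %g\n", nm, x[[nm]]))
  cat(sprintf("  derived: k_on_nSH2_2 = %g, k_act_2 = %g\n",
              d$k_on_nSH2_2, d$k_act_2))
  cat(sprintf("  K_p = %g, K_c = %g, K_a = %g, K_D = %g uM\n",
              d$K_p, d$K_c, d$K_a, d$K_D))
  invisible(x)
}

#' Check detailed balance of the binding/insertion cycle
#'
#' The four-state thermodynamic cycle {nSH2 free/receptor-bound} x
#' {core inactive/active} must have a product of equilibrium constants of
#' one around the loop.  With both enhanced rate constants sharing the
#' factor chi this holds identically; an independent override of either
#' derived constant breaks it.  Phosphorylation/dephosphorylation cycles
#' are excluded: they are chemically driven (ATP hydrolysis) and not
#' required to balance.
#'
#' @param p a \code{plcg_parameters} object; all rate constants in the
#'   cycle must be positive.
#' @param tol relative tolerance on the cycle product.
#' @return list with \code{balanced} (logical), \code{residual}
#'   (log of the cycle product; 0 when balanced), and \code{cycle}
#'   (the edge equilibrium constants).
#' @examples
#' check_detailed_balance(plcg_parameters())$balanced          # TRUE
#' @export
check_detailed_balance <- function(p, tol = 1e-9) {
  d <- derived_constants(p)
  ks <- c(p$k_on_nSH2, p$k_off_nSH2, p$k_act, p$k_inact,
          d$k_on_nSH2_2, d$k_act_2)
  if (any(ks <= 0))
    stop("detailed-balance check requires positive rate constants in the cycle")
  # traverse: bind receptor (active enzyme), leave membrane, unbind
  # receptor, re-insert from cytosol -- back to start
  edges <- c(bind_active   = d$k_on_nSH2_2 / p$k_off_nSH2,
             inactivate    = p$k_inact / d$k_act_2,
             unbind_inact  = p$k_off_nSH2 / p$k_on_nSH2,
             activate_cyt  = p$k_act / p$k_inact)
  residual <- sum(log(edges))
  list(balanced = abs(residual) < tol, residual = residual, cycle = edges)
}

#' Read / write parameter sets as plain-text config
#'
#' Parameters serialize to YAML or JSON with the canonical constant names
#' (\code{k_on_nSH2}, ..., \code{chi}, \code{plc_total},
#' \code{rtk_total}).  Unknown names in a config are rejected.
#'
#' @param p a \code{plcg_parameters} object.
#' @param path file path; format chosen by extension
#'   (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return \code{write_parameters} returns \code{path} invisibly;
#'   \code{read_parameters} returns a \code{plcg_parameters} object.
#' @export
write_parameters <- function(p, path) {
  keep <- p[.param_names]
  over <- p[.override_names]
  keep <- c(keep, over[!vapply(over, is.null, logical(1))])
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(keep, path)
  }
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(plcg_parameters, vals)
}
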