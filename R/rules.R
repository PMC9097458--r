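#' Reaction rules of the PLC-gamma1 model
#'
#' Each rule constrains only the sites it reads (a pattern maps a site name
#' to the set of admissible values) and changes exactly one site.  Two rules
#' are bimolecular: binding of the nSH2 domain to a free receptor
#' phosphotyrosine, with distinct rate constants depending on whether the
#' catalytic core is membrane-inserted (induced proximity).  All other
#' transitions are unimolecular.
#'
#' @name plc-rules
NULL

new_rule <- function(name, pattern, site, to, rate, molecularity = "unimolecular",
                     rtk_change = 0L, derived_from = NULL) {
  structure(list(name = name, pattern = pattern, site = site, to = to,
                 rate = rate, molecularity = molecularity,
                 rtk_change = rtk_change, derived_from = derived_from),
            class = "plc_rule")
}

#' Build the PLC-gamma1 rule set
#'
#' Returns the 12 reaction rules governing PLC-gamma1 regulation:
#' nSH2--RTK binding with the core inactive (\code{k_on_nSH2}) or active
#' (\code{k_on_nSH2_2 = chi * k_on_nSH2}), nSH2 unbinding
#' (\code{k_off_nSH2}), Tyr783 phosphorylation by the receptor
#' (\code{k_phos}; only while receptor-bound), dephosphorylation
#' (\code{k_dephos}; only while the cSH2 domain does not protect pTyr783),
#' the intramolecular cSH2--core (autoinhibition) and cSH2--pTyr783 binding
#' equilibria, membrane insertion of the unoccluded core from the cytosol
#' (\code{k_act}) or while receptor-anchored
#' (\code{k_act_2 = chi * k_act}), and core inactivation (\code{k_inact}).
#'
#' The two chi-coupled rules are marked \code{derived_from} so that the
#' shared enhancement factor (which enforces detailed balance around the
#' binding/insertion cycle) is encoded structurally, not repeated.
#'
#' @return An object of class \code{plc_ruleset}: a list of 12 rules in the
#'   fixed canonical order above.
#' @examples
#' rs <- plcg_ruleset()
#' length(rs)  # 12
#' @export
plcg_ruleset <- function() {
  r <- list(
    new_rule("nSH2_bind_RTK_core_inactive",
             list(nsh2 = "free", core = "inactive"),
             "nsh2", "rtk_bound", "k_on_nSH2",
             molecularity = "bimolecular", rtk_change = -1L),
    new_rule("nSH2_bind_RTK_core_active",
             list(nsh2 = "free", core = "active"),
             "nsh2", "rtk_bound", "k_on_nSH2_2",
             molecularity = "bimolecular", rtk_change = -1L,
             derived_from = list(base = "k_on_nSH2", factor = "chi")),
    new_rule("nSH2_unbind_RTK",
             list(nsh2 = "rtk_bound"),
             "nsh2", "free", "k_off_nSH2", rtk_change = 1L),
    new_rule("Y783_phosphorylation",
             list(nsh2 = "rtk_bound", y783 = "unphos"),
             "y783", "phos", "k_phos"),
    new_rule("Y783_dephosphorylation",
             list(y783 = "phos", csh2 = c("free", "core_bound")),
             "y783", "unphos", "k_dephos"),
    new_rule("cSH2_bind_core",
             list(csh2 = "free", core = "inactive"),
             "csh2", "core_bound", "k_bind_c"),
    new_rule("cSH2_unbind_core",
             list(csh2 = "core_bound"),
             "csh2", "free", "k_unbind_c"),
    new_rule("cSH2_bind_pY783",
             list(csh2 = "free", y783 = "phos"),
             "csh2", "py_bound", "k_bind_p"),
    new_rule("cSH2_unbind_pY783",
             list(csh2 = "py_bound"),
             "csh2", "free", "k_unbind_p"),
    new_rule("core_activation_nSH2_free",
             list(core = "inactive", csh2 = c("free", "py_bound"),
                  nsh2 = "free"),
             "core", "active", "k_act"),
    new_rule("core_activation_nSH2_bound",
             list(core = "inactive", csh2 = c("free", "py_bound"),
                  nsh2 = "rtk_bound"),
             "core", "active", "k_act_2",
             derived_from = list(base = "k_act", factor = "chi")),
    new_rule("core_inactivation",
             list(core = "active"),
             "core", "inactive", "k_inact")
  )
  structure(r, class = "plc_ruleset")
}

#' @export
print.plc_ruleset <- function(x, ...) {
  cat(sprintf("PLC-gamma1 rule set: %d rules\n", length(x)))
  for (r in x) {
    pat <- paste(vapply(names(r$pattern), function(s)
      sprintf("%s in {%s}", s, paste(r$pattern[[s]], collapse = ",")),
      character(1)), collapse = "; ")
    cat(sprintf("  %-28s %-12s [%s] %s -> %s\n",
                r$name, r$rate, pat, r$site, r$to))
  }
  invisible(x)
}

#' Does a rule's reactant pattern match a state?
#'
#' @param rule a \code{plc_rule}.
#' @param state one-row data.frame (or list) with the four site values.
#' @return logical.
#' @export
rule_matches <- function(rule, state) {
  for (site in names(rule$pattern)) {
    if (!site %in% c("nsh2", "y783", "csh2", "core"))
      stop("rule '", rule$name, "' references unknown site '", site, "'")
    if (!(state[[site]] %in% rule$pattern[[site]])) return(FALSE)
  }
  TRUE
}

#' Apply a rule to a matching state
#'
#' @param rule a \code{plc_rule}.
#' @param state one-row data.frame with the four site columns.
#' @return the product state (same shape, one site changed).
#' @export
rule_apply <- function(rule, state) {
  state[[rule$site]] <- rule$to
  state
}

#' Count the independent rate constants of a rule set
#'
#' Each rule carries one rate constant, but constants marked as derived
#' share a base constant and a named coupling factor (here \code{chi},
#' applied to both receptor binding of the active enzyme and
#' receptor-anchored membrane insertion; a single shared factor is what
#' closes the thermodynamic cycle).  The count is the number of distinct
#' underived rate constants plus the number of distinct coupling factors.
#'
#' @param ruleset a \code{plc_ruleset}.
#' @return integer count of free rate parameters (11 for the base model).
#' @examples
#' count_independent_rate_constants(plcg_ruleset())  # 11
#' @export
count_independent_rate_constants <- function(ruleset) {
  base <- character(0)
  factors <- character(0)
  for (r in ruleset) {
    if (is.null(r$derived_from)) {
      base <- c(base, r$rate)
    } else {
      base <- c(base, r$derived_from$base)
      factors <- c(factors, r$derived_from$factor)
    }
  }
  length(unique(base)) + length(unique(factors))
}
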