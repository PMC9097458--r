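#' Expand the rule set into a concrete reaction network
#'
#' Every rule is applied to every PLC state whose sites match its reactant
#' pattern.  Species are the 8 free-PLC states, the 8 PLC.RTK complexes
#' (a complex is a single species, not separate receptor bookkeeping),
#' and free receptor, in a deterministic order: free PLC in canonical
#' state order, then complexes in the same order, then RTK last.
#' Reactions are kept unidirectional (forward and reverse are separate
#' entries), mirroring rule granularity.
#'
#' @param ruleset rules from \code{\link{plcg_ruleset}}.
#' @param params parameter set from \code{\link{plcg_parameters}} used to
#'   bind numeric rate values.
#' @return object of class \code{plcg_network}: list with
#'   \itemize{
#'     \item \code{species}: data.frame (id, kind, label, the four site
#'       columns or NA for free RTK, flags, plc/rtk content),
#'     \item \code{reactions}: data.frame (id, rule, rate_name,
#'       rate_value, reactants, products as ";"-joined id strings),
#'     \item \code{stoich}: species x reaction coefficient matrix,
#'     \item \code{states}, \code{params}.
#'   }
#' @examples
#' net <- generate_network()
#' nrow(net$species)    # 17
#' nrow(net$reactions)  # 53
#' @export
generate_network <- function(ruleset = plcg_ruleset(),
                             params = plcg_parameters()) {
  states <- plc_states()
  kv <- rate_values(params)

  free_idx <- which(states$nsh2 == "free")
  cplx_idx <- which(states$nsh2 == "rtk_bound")

  sp <- data.frame(
    id = seq_len(nrow(states) + 1L),
    kind = c(ifelse(states$nsh2 == "rtk_bound", "plc_rtk_complex",
                    "plc_free")[c(free_idx, cplx_idx)], "rtk_free"),
    stringsAsFactors = FALSE
  )
  ordered_states <- states[c(free_idx, cplx_idx), , drop = FALSE]
  for (col in c("nsh2", "y783", "csh2", "core"))
    sp[[col]] <- c(ordered_states[[col]], NA)
  sp$rtk_bound <- c(ordered_states$rtk_bound, FALSE)
  sp$active    <- c(ordered_states$active, FALSE)
  sp$cytosolic <- c(ordered_states$cytosolic, FALSE)
  sp$plc_content <- c(rep(1L, nrow(ordered_states)), 0L)
  sp$rtk_content <- c(as.integer(ordered_states$rtk_bound), 1L)
  sp$label <- c(ifelse(ordered_states$rtk_bound,
                       paste0(ordered_states$label, ".RTK"),
                       ordered_states$label), "RTK")
  rtk_id <- nrow(sp)

  # map a full site assignment to its species id
  state_key <- function(nsh2, y783, csh2, core)
    paste(nsh2, y783, csh2, core, sep = "|")
  key2id <- structure(sp$id[seq_len(nrow(ordered_states))],
                      names = state_key(ordered_states$nsh2, ordered_states$y783,
                                        ordered_states$csh2, ordered_states$core))

  rx <- list()
  for (r in ruleset) {
    if (!all(names(r$pattern) %in% c("nsh2", "y783", "csh2", "core")))
      stop("rule '", r$name, "' references an unknown site")
    for (i in seq_len(nrow(states))) {
      st <- states[i, , drop = FALSE]
      if (!rule_matches(r, st)) next
      prod_st <- rule_apply(r, st)
      rid <- key2id[[state_key(st$nsh2, st$y783, st$csh2, st$core)]]
      pid <- key2id[[state_key(prod_st$nsh2, prod_st$y783,
                               prod_st$csh2, prod_st$core)]]
      reactants <- rid
      products <- pid
      if (r$rtk_change == -1L) reactants <- c(reactants, rtk_id)
      if (r$rtk_change == 1L)  products  <- c(products, rtk_id)
      rx[[length(rx) + 1L]] <- list(rule = r$name, rate_name = r$rate,
                                    rate_value = unname(kv[[r$rate]]),
                                    reactants = reactants,
                                    products = products)
    }
  }

  reactions <- data.frame(
    id = seq_along(rx),
    rule = vapply(rx, `[[`, character(1), "rule"),
    rate_name = vapply(rx, `[[`, character(1), "rate_name"),
    rate_value = vapply(rx, `[[`, numeric(1), "rate_value"),
    reactants = vapply(rx, function(x) paste(x$reactants, collapse = ";"),
                       character(1)),
    products = vapply(rx, function(x) paste(x$products, collapse = ";"),
                      character(1)),
    stringsAsFactors = FALSE
  )

  net <- structure(list(species = sp, reactions = reactions,
                        states = ordered_states, params = params),
                   class = "plcg_network")
  net$stoich <- stoichiometry_matrix(net)
  net
}

#' Stoichiometry matrix of a generated network
#'
#' @param network a \code{plcg_network}.
#' @return numeric matrix, species (rows, labeled) x reactions (columns);
#'   entries are net coefficients.
#' @export
stoichiometry_matrix <- function(network) {
  ns <- nrow(network$species)
  nr <- nrow(network$reactions)
  S <- matrix(0, ns, nr,
              dimnames = list(network$species$label, network$reactions$id))
  for (j in seq_len(nr)) {
    for (i in reaction_side(network$reactions$reactants[j]))
      S[i, j] <- S[i, j] - 1
    for (i in reaction_side(network$reactions$products[j]))
      S[i, j] <- S[i, j] + 1
  }
  S
}

reaction_side <- function(s) as.integer(strsplit(s, ";", fixed = TRUE)[[1]])

#' @export
print.plcg_network <- function(x, ...) {
  cat(sprintf("PLC-gamma1 reaction network: %d species, %d reactions\n",
              nrow(x$species), nrow(x$reactions)))
  cnt <- table(factor(x$reactions$rule,
                      levels = unique(x$reactions$rule)))
  for (nm in names(cnt))
    cat(sprintf("  %-28s %2d reactions\n", nm, cnt[[nm]]))
  invisible(x)
}

#' Per-rule reaction instance counts
#'
#' @param network a \code{plcg_network}.
#' @param ruleset the rule set used to generate it (fixes the order).
#' @return named integer vector, one entry per rule in rule-set order.
#' @export
rule_instance_counts <- function(network, ruleset = plcg_ruleset()) {
  nm <- vapply(ruleset, `[[`, character(1), "name")
  cnt <- table(factor(network$reactions$rule, levels = nm))
  structure(as.integer(cnt), names = nm)
}
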