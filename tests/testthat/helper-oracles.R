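# Independent brute-force oracles, deliberately written without the
# package's pattern machinery so they can disagree with it.

# every raw combination of the four sites (24 rows)
oracle_raw_states <- function() {
  out <- NULL
  for (nsh2 in c("free", "rtk_bound"))
    for (y783 in c("unphos", "phos"))
      for (csh2 in c("free", "core_bound", "py_bound"))
        for (core in c("inactive", "active"))
          out <- rbind(out, data.frame(nsh2 = nsh2, y783 = y783,
                                       csh2 = csh2, core = core,
                                       stringsAsFactors = FALSE))
  out
}

# filter by the two structural constraints, written out longhand
oracle_valid_states <- function() {
  raw <- oracle_raw_states()
  keep <- logical(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    ok <- TRUE
    if (raw$csh2[i] == "core_bound" && raw$core[i] == "active") ok <- FALSE
    if (raw$csh2[i] == "py_bound" && raw$y783[i] == "unphos") ok <- FALSE
    keep[i] <- ok
  }
  raw[keep, , drop = FALSE]
}

# brute-force reaction list: nested loops over states, hand-coded rule
# conditions and products; returns a character multiset of
# "rate|reactant-state|product-state" (R = free-receptor involvement)
oracle_reactions <- function() {
  st <- oracle_valid_states()
  key <- function(s) paste(s$nsh2, s$y783, s$csh2, s$core, sep = ",")
  out <- character(0)
  add <- function(rate, from, to, rtk = "")
    out <<- c(out, paste(rate, key(from), key(to), rtk, sep = "|"))
  for (i in seq_len(nrow(st))) {
    s <- st[i, , drop = FALSE]
    if (s$nsh2 == "free" && s$core == "inactive") {
      t <- s; t$nsh2 <- "rtk_bound"; add("k_on_nSH2", s, t, "R-")
    }
    if (s$nsh2 == "free" && s$core == "active") {
      t <- s; t$nsh2 <- "rtk_bound"; add("k_on_nSH2_2", s, t, "R-")
    }
    if (s$nsh2 == "rtk_bound") {
      t <- s; t$nsh2 <- "free"; add("k_off_nSH2", s, t, "R+")
    }
    if (s$nsh2 == "rtk_bound" && s$y783 == "unphos") {
      t <- s; t$y783 <- "phos"; add("k_phos", s, t)
    }
    if (s$y783 == "phos" && s$csh2 != "py_bound") {
      t <- s; t$y783 <- "unphos"; add("k_dephos", s, t)
    }
    if (s$csh2 == "free" && s$core == "inactive") {
      t <- s; t$csh2 <- "core_bound"; add("k_bind_c", s, t)
    }
    if (s$csh2 == "core_bound") {
      t <- s; t$csh2 <- "free"; add("k_unbind_c", s, t)
    }
    if (s$csh2 == "free" && s$y783 == "phos") {
      t <- s; t$csh2 <- "py_bound"; add("k_bind_p", s, t)
    }
    if (s$csh2 == "py_bound") {
      t <- s; t$csh2 <- "free"; add("k_unbind_p", s, t)
    }
    if (s$core == "inactive" && s$csh2 != "core_bound" && s$nsh2 == "free") {
      t <- s; t$core <- "active"; add("k_act", s, t)
    }
    if (s$core == "inactive" && s$csh2 != "core_bound" && s$nsh2 == "rtk_bound") {
      t <- s; t$core <- "active"; add("k_act_2", s, t)
    }
    if (s$core == "active") {
      t <- s; t$core <- "inactive"; add("k_inact", s, t)
    }
  }
  out
}

# the same multiset encoding for a generated plcg_network
network_reaction_multiset <- function(net) {
  sp <- net$species
  skey <- function(id) {
    i <- match(id, sp$id)
    paste(sp$nsh2[i], sp$y783[i], sp$csh2[i], sp$core[i], sep = ",")
  }
  rtk_id <- sp$id[sp$kind == "rtk_free"]
  vapply(seq_len(nrow(net$reactions)), function(j) {
    re <- as.integer(strsplit(net$reactions$reactants[j], ";")[[1]])
    pr <- as.integer(strsplit(net$reactions$products[j], ";")[[1]])
    rtk <- if (rtk_id %in% re) "R-" else if (rtk_id %in% pr) "R+" else ""
    paste(net$reactions$rate_name[j],
          skey(setdiff(re, rtk_id)), skey(setdiff(pr, rtk_id)), rtk,
          sep = "|")
  }, character(1))
}

# per-reaction mass-action fluxes at a state vector
reaction_fluxes <- function(net, conc) {
  vapply(seq_len(nrow(net$reactions)), function(j) {
    re <- as.integer(strsplit(net$reactions$reactants[j], ";")[[1]])
    net$reactions$rate_value[j] * prod(conc[re])
  }, numeric(1))
}
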