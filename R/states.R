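#' @title Molecular state space of PLC-gamma1
#'
#' @description
#' PLC-gamma1 is tracked at four internal sites: occupancy of the nSH2
#' domain by the receptor (RTK), phosphorylation of Tyr783, the binding
#' partner of the cSH2 domain, and the activity of the catalytic core
#' (membrane-inserted or not).  Two structural constraints prune the raw
#' combinations: the cSH2 domain can occupy the catalytic core only while
#' the core is inactive (autoinhibition), and it can engage Tyr783 only
#' when that residue is phosphorylated.
#' @name plc-states
NULL

# canonical site value orders; these fix species indexing everywhere
.plc_site_levels <- list(
  nsh2 = c("free", "rtk_bound"),
  y783 = c("unphos", "phos"),
  csh2 = c("free", "core_bound", "py_bound"),
  core = c("inactive", "active")
)

#' Is a site combination structurally valid?
#'
#' @param nsh2,y783,csh2,core site values (vectorized).
#' @return logical vector.
#' @keywords internal
plc_state_valid <- function(nsh2, y783, csh2, core) {
  ok_auto <- !(csh2 == "core_bound" & core == "active")
  ok_py   <- !(csh2 == "py_bound" & y783 == "unphos")
  ok_auto & ok_py
}

#' Enumerate the valid internal states of PLC-gamma1
#'
#' Builds all raw combinations of the four sites (2 x 2 x 3 x 2 = 24),
#' removes those violating the structural constraints, and returns the
#' survivors in a deterministic canonical order (lexicographic on
#' nsh2, y783, csh2, core with the site-level orders fixed internally).
#'
#' @return A data.frame with one row per valid state and columns
#'   \code{nsh2}, \code{y783}, \code{csh2}, \code{core} (character),
#'   derived flags \code{rtk_bound}, \code{active}, \code{cytosolic}
#'   (logical), and a canonical \code{label}.  A state is cytosolic when
#'   its nSH2 domain is free and its core is inactive (i.e. it is attached
#'   neither to the receptor nor to the membrane); it is active when the
#'   core is membrane-inserted.
#' @examples
#' s <- plc_states()
#' nrow(s)            # 16
#' sum(s$rtk_bound)   # 8
#' sum(s$active)      # 6
#' @export
plc_states <- function() {
  lv <- .plc_site_levels
  raw <- expand.grid(core = lv$core, csh2 = lv$csh2, y783 = lv$y783,
                     nsh2 = lv$nsh2, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  raw <- raw[, c("nsh2", "y783", "csh2", "core")]
  keep <- plc_state_valid(raw$nsh2, raw$y783, raw$csh2, raw$core)
  st <- raw[keep, , drop = FALSE]
  ord <- order(match(st$nsh2, lv$nsh2), match(st$y783, lv$y783),
               match(st$csh2, lv$csh2), match(st$core, lv$core))
  st <- st[ord, , drop = FALSE]
  rownames(st) <- NULL
  st$rtk_bound <- st$nsh2 == "rtk_bound"
  st$active    <- st$core == "active"
  st$cytosolic <- st$nsh2 == "free" & st$core == "inactive"
  st$label <- plc_state_label(st)
  st
}

# site-value abbreviations used in species labels
.abbrev <- list(
  nsh2 = c(free = "free", rtk_bound = "RTK"),
  y783 = c(unphos = "u", phos = "p"),
  csh2 = c(free = "free", core_bound = "core", py_bound = "pY"),
  core = c(inactive = "inact", active = "act")
)

#' Canonical text label for a PLC state
#'
#' Follows a fixed site grammar, e.g.
#' \code{PLC(nSH2~free,Y783~p,cSH2~core,core~inact)}.
#' @param states data.frame with nsh2/y783/csh2/core columns.
#' @return character vector of labels.
#' @keywords internal
plc_state_label <- function(states) {
  sprintf("PLC(nSH2~%s,Y783~%s,cSH2~%s,core~%s)",
          .abbrev$nsh2[states$nsh2], .abbrev$y783[states$y783],
          .abbrev$csh2[states$csh2], .abbrev$core[states$core])
}

#' Partition the state space into receptor-bound, active, and cytosolic sets
#'
#' The partitions are not disjoint: a state can be both receptor-bound and
#' active (the canonically active species are).
#'
#' @param states state table from \code{\link{plc_states}}.
#' @return list with elements \code{counts} (named integer vector with
#'   \code{n_states}, \code{rtk_bound}, \code{active}, \code{cytosolic})
#'   and \code{members} (list of integer row indices per class).
#' @export
classify_states <- function(states = plc_states()) {
  members <- list(
    rtk_bound = which(states$rtk_bound),
    active    = which(states$active),
    cytosolic = which(states$cytosolic)
  )
  counts <- c(n_states = nrow(states),
              vapply(members, length, integer(1)))
  list(counts = counts, members = members)
}
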