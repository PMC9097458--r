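test_that("state enumeration matches the brute-force filter of all 24 combinations", {
  states <- plc_states()
  oracle <- oracle_valid_states()

  expect_equal(nrow(oracle_raw_states()), 24)
  expect_equal(nrow(states), nrow(oracle))

  key <- function(d) paste(d$nsh2, d$y783, d$csh2, d$core)
  expect_setequal(key(states), key(oracle))

  # 8 raw combinations rejected: 4 cSH2-core with active core,
  # 4 cSH2-pY with unphosphorylated Tyr783
  raw <- oracle_raw_states()
  rej <- raw[!(key(raw) %in% key(oracle)), ]
  expect_equal(sum(rej$csh2 == "core_bound" & rej$core == "active"), 4)
  expect_equal(sum(rej$csh2 == "py_bound" & rej$y783 == "unphos"), 4)
})

test_that("state partition counts are correct and order-stable", {
  states <- plc_states()
  cl <- classify_states(states)
  expect_equal(unname(cl$counts["n_states"]), 16)
  expect_equal(unname(cl$counts["rtk_bound"]), 8)
  expect_equal(unname(cl$counts["active"]), 6)
  # cytosolic = free nSH2 AND inactive core, by brute force
  oracle <- oracle_valid_states()
  n_cyt <- sum(oracle$nsh2 == "free" & oracle$core == "inactive")
  expect_equal(unname(cl$counts["cytosolic"]), n_cyt)

  # counts invariant under permutation of the state table
  set.seed(1)
  perm <- states[sample(nrow(states)), ]
  expect_equal(classify_states(perm)$counts, cl$counts)

  # enumeration order is deterministic
  expect_identical(plc_states(), states)
})

test_that("the rule set has 12 rules with the stated applicability constraints", {
  rs <- plcg_ruleset()
  states <- plc_states()
  expect_length(rs, 12)

  by_name <- stats::setNames(rs, vapply(rs, `[[`, character(1), "name"))

  # phosphorylation inapplicable to any state with free nSH2
  phos <- by_name[["Y783_phosphorylation"]]
  free_states <- states[states$nsh2 == "free", ]
  for (i in seq_len(nrow(free_states)))
    expect_false(rule_matches(phos, free_states[i, ]))

  # dephosphorylation inapplicable while cSH2 protects pTyr783
  dephos <- by_name[["Y783_dephosphorylation"]]
  protected <- states[states$csh2 == "py_bound", ]
  for (i in seq_len(nrow(protected)))
    expect_false(rule_matches(dephos, protected[i, ]))

  # every rule matches at least one valid state and never produces an
  # invalid one
  for (r in rs) {
    hits <- 0
    for (i in seq_len(nrow(states))) {
      if (rule_matches(r, states[i, ])) {
        hits <- hits + 1
        prod <- rule_apply(r, states[i, ])
        expect_true(plc_state_valid(prod$nsh2, prod$y783, prod$csh2,
                                    prod$core),
                    info = paste(r$name, "produced an invalid state"))
      }
    }
    expect_gt(hits, 0)
  }
})

test_that("independent rate-constant counting respects the shared coupling factor", {
  expect_equal(count_independent_rate_constants(plcg_ruleset()), 11)

  # declaring the two enhancement factors independent gives 12
  rs2 <- plcg_ruleset()
  rs2[[2]]$derived_from$factor <- "chi_on"
  rs2[[11]]$derived_from$factor <- "chi_act"
  expect_equal(count_independent_rate_constants(rs2), 12)

  # a single uncoupled rule counts once
  rs1 <- structure(plcg_ruleset()[12], class = "plc_ruleset")
  expect_equal(count_independent_rate_constants(rs1), 1)
})

test_that("detailed balance holds iff both enhanced constants share one factor", {
  expect_true(check_detailed_balance(plcg_parameters())$balanced)
  expect_equal(check_detailed_balance(plcg_parameters())$residual, 0,
               tolerance = 1e-12)

  # doubling one derived constant breaks the cycle
  p_bad <- plcg_parameters()
  p_bad$k_act_2 <- 2 * p_bad$chi * p_bad$k_act
  res <- check_detailed_balance(p_bad)
  expect_false(res$balanced)
  expect_equal(res$residual, log(1 / 2), tolerance = 1e-12)

  # balanced for any positive random draw with the shared factor
  set.seed(42)
  for (i in 1:25) {
    draw <- 10^stats::runif(5, -2, 2)
    p <- plcg_parameters(k_on_nSH2 = draw[1], k_off_nSH2 = draw[2],
                         k_act = draw[3], k_inact = draw[4],
                         chi = draw[5])
    expect_true(check_detailed_balance(p)$balanced)
  }

  expect_error(check_detailed_balance(plcg_parameters(k_act = 0)),
               "positive")
})

test_that("parameter sets expose the Table-style base values and derived constants", {
  p <- plcg_parameters()
  d <- derived_constants(p)
  expect_equal(d$k_on_nSH2_2, 1000)
  expect_equal(d$k_act_2, 10)
  expect_equal(d$K_p, 100)
  expect_equal(d$K_c, 100)
  expect_equal(d$K_a, 0.1)
  expect_equal(d$K_D, 1)

  expect_error(plcg_parameters(k_phos = -1), "rate constants")
  expect_error(plcg_parameters(nonsense = 2), "unknown parameter")
})

test_that("parameter serialization round-trips through YAML and JSON", {
  p <- plcg_parameters(k_phos = 0.3, rtk_total = 0.01)
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_parameters(p, f)
    q <- read_parameters(f)
    expect_equal(unclass(q)[names(unclass(p))], unclass(p))
    unlink(f)
  }
})
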