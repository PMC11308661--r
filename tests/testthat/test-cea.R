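# Decision-tree rollback, costs, responder accounting, ICER and NMB.

params <- cea_parameters()

test_that("AE disutility is 10% of the mapped baseline utility", {
  expect_equal(disutility_from_baseline(30.37), -0.0881805)
  expect_equal(disutility_from_baseline(0), -0.09881)
  expect_equal(disutility_from_baseline(50, mapping_intercept = 1,
                                        mapping_slope = 0), -0.1)
})

test_that("expected cost reproduces the published per-patient totals", {
  low <- expected_cost(params$arms$low_dose, params$econ)
  high <- expected_cost(params$arms$high_dose, params$econ)
  expect_equal(round(low$total, 2), 1894.98)
  expect_equal(round(high$total, 2), 2092.97)
  # drug-cost component oracle: 0.72 * 364 * (0.977 + 0.023 * 8/52)
  expect_equal(low$drug, 0.72 * 364 * (0.977 + 0.023 * 8 / 52))
  expect_equal(low$direct_medical, 31.50 * 52)

  # zero prices -> zero cost
  free <- economic_parameters(weekly_direct_medical_cost = 0,
                              drug_price_per_5mg = 0)
  expect_equal(expected_cost(params$arms$high_dose, free)$total, 0)

  # placebo accrues direct medical cost only
  plc <- expected_cost(params$arms$placebo, params$econ)
  expect_equal(plc$total, 1638)
})

test_that("cost is linear in each unit cost", {
  econ2 <- economic_parameters(drug_price_per_5mg = 2 * 0.72)
  expect_equal(expected_cost(params$arms$low_dose, econ2)$drug,
               2 * expected_cost(params$arms$low_dose, params$econ)$drug)
  econ3 <- economic_parameters(weekly_direct_medical_cost = 3 * 31.50)
  expect_equal(expected_cost(params$arms$low_dose, econ3)$direct_medical,
               3 * expected_cost(params$arms$low_dose, params$econ)$direct_medical)
})

test_that("expected QALYs follow the tree rollback", {
  # degenerate utilities: QALY = u * horizon regardless of probabilities
  flat <- utility_parameters(u_posthoc = 0.9, u_partial = 0.9,
                             u_nonresponse = 0.9, disutility_ae = 0,
                             ae_utility_convention = "nonresponse_minus_disutility")
  for (arm in params$arms) {
    expect_equal(expected_qaly(arm, flat, params$econ), 0.9)
  }

  # hand rollback oracle for the default convention, low dose:
  # 0.977 * 0.920621 + 0.023 * (0.881805 - 0.090)
  mix <- 0.405 * 0.934 + 0.333 * 0.919 + (1 - 0.405 - 0.333) * 0.902
  hand <- 0.977 * mix + 0.023 * (0.881805 - 0.090)
  expect_equal(expected_qaly(params$arms$low_dose, params$util, params$econ),
               hand)
  expect_equal(round(hand, 5), 0.91766)

  # single-branch tree: everyone discontinues
  all_ae <- arm_parameters("ae", 1, 0.5, 0.3, 5)
  nr_conv <- utility_parameters(ae_utility_convention = "nonresponse_minus_disutility")
  expect_equal(expected_qaly(all_ae, nr_conv, params$econ), 0.902 - 0.090)

  # half-year horizon halves the QALYs
  half <- economic_parameters(horizon_weeks = 26)
  expect_equal(expected_qaly(params$arms$low_dose, params$util, half),
               expected_qaly(params$arms$low_dose, params$util, params$econ) / 2)
})

test_that("closed-form rollback equals brute-force leaf enumeration", {
  for (conv in all_ae_conventions) {
    util <- utility_parameters(ae_utility_convention = conv)
    for (arm in params$arms) {
      res <- evaluate_arm(arm, params$econ, util)
      leaves <- enumerate_arm(arm, params$econ, util)
      expect_equal(res$expected_cost, leaves$expected_cost, tolerance = 1e-12)
      expect_equal(res$expected_qaly, leaves$expected_qaly, tolerance = 1e-12)
      expect_equal(leaves$total_probability, 1, tolerance = 1e-12)
    }
  }
})

test_that("responder accounting matches the published per-1000 counts", {
  low <- cases_per_1000(params$arms$low_dose)
  high <- cases_per_1000(params$arms$high_dose)
  expect_identical(c(low$posthoc, low$partial), c(396, 325))
  expect_identical(c(high$posthoc, high$partial), c(482, 265))
  expect_identical(high$responders, 747)
  expect_identical(high$responders - low$responders, 26)

  none <- arm_parameters("none", 1, 0.5, 0.3, 5)
  expect_identical(unlist(cases_per_1000(none)),
                   c(posthoc = 0, partial = 0, responders = 0))
})

test_that("arm invariants: chance-node probabilities sum to one", {
  for (arm in params$arms) {
    expect_equal(arm$p_posthoc + arm$p_partial + arm$p_nonresponse, 1)
  }
  expect_error(arm_parameters("bad", 0.1, 0.7, 0.4, 5), "exceeds 1")
  expect_error(arm_parameters("bad", 1.2, 0.1, 0.1, 5), "\\[0, 1\\]")
})

test_that("ICER classifies dominance and degenerate increments", {
  mk <- function(cost, qaly) {
    structure(list(name = "x", expected_cost = cost, expected_qaly = qaly),
              class = "arm_result")
  }
  plain <- icer(mk(1000, 0.5), mk(1100, 0.51))
  expect_equal(plain$icer, 100 / 0.01)
  expect_equal(plain$dominance, "none")

  dominated <- icer(mk(1000, 0.5), mk(1100, 0.49))
  expect_true(is.na(dominated$icer))
  expect_equal(dominated$dominance, "comparator_dominated")

  dominant <- icer(mk(1000, 0.5), mk(900, 0.51))
  expect_equal(dominant$dominance, "comparator_dominant")

  flat <- icer(mk(1000, 0.5), mk(1100, 0.5))
  expect_true(is.na(flat$icer))
  expect_equal(flat$dominance, "undefined_dqaly_zero")

  # cheaper and worse is a defined (south-west) ICER, not dominance
  sw <- icer(mk(1000, 0.5), mk(900, 0.4))
  expect_equal(sw$icer, 1000)
  expect_equal(sw$dominance, "none")
})

test_that("net monetary benefit and its indifference point", {
  inc <- list(delta_cost = 197.99, delta_qaly = 0.001)
  expect_equal(net_monetary_benefit(inc, 36832.95),
               36832.95 * 0.001 - 197.99)
  expect_lt(net_monetary_benefit(inc, 36832.95), 0) # low dose preferred
  expect_equal(net_monetary_benefit(inc, 197.99 / 0.001), 0)
  free <- list(delta_cost = 0, delta_qaly = 0.002)
  expect_gt(net_monetary_benefit(free, 1), 0)
  expect_error(net_monetary_benefit(inc, -1), "wtp")
})

test_that("the qualitative conclusion is AE-convention invariant", {
  for (conv in all_ae_conventions) {
    util <- utility_parameters(ae_utility_convention = conv)
    low <- evaluate_arm(params$arms$low_dose, params$econ, util)
    high <- evaluate_arm(params$arms$high_dose, params$econ, util)
    inc <- icer(low, high)
    not_ce <- inc$dominance == "comparator_dominated" ||
      (!is.na(inc$icer) && inc$icer > 36832.95)
    expect_true(not_ce, label = paste("high dose not cost-effective under", conv))
    expect_gte(low$expected_qaly, 0.89)
    expect_lte(low$expected_qaly, 0.93)
  }
  expect_error(utility_parameters(ae_utility_convention = "nonsense"),
               "unknown ae_utility_convention")
})

test_that("results table mirrors the published layout", {
  tab <- cea_results_table(params)
  expect_setequal(tab$strategy, c("low_dose", "high_dose", "placebo"))
  hi <- tab[tab$strategy == "high_dose", ]
  expect_equal(round(hi$incremental_cost, 2), 197.99)
  expect_true(is.na(tab$incremental_cost[tab$strategy == "low_dose"]))
  expect_equal(tab$responders_per_1000[tab$strategy == "high_dose"], 747)
})
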