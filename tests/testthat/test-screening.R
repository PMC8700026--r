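# brute-force oracle: enumerate every leaf path of the decision tree
# explicitly and sum probability * cost / detection mass
enumerate_cascade <- function(setting, true_state, pset, societal) {
  p <- function(test) if (true_state == "diseased") pset$sens[[test]]
                      else 1 - pset$spec[[test]]
  ct <- pset$cost_test
  adh <- pset$adherence_referral
  leaves <- list()
  if (setting == "CHS") {
    visit0 <- if (societal) pset$cost_visit[["chs"]] else 0
    ref <- if (societal) pset$cost_visit[["dhc"]] else 0
    leaves <- list(
      list(pr = 1 - p("findrisc"), cost = ct[["findrisc"]] + visit0,
           pos = FALSE),
      list(pr = p("findrisc") * (1 - p("fcg")),
           cost = ct[["findrisc"]] + ct[["fcg"]] + visit0, pos = FALSE),
      list(pr = p("findrisc") * p("fcg") * (1 - adh),
           cost = ct[["findrisc"]] + ct[["fcg"]] + visit0, pos = FALSE),
      list(pr = p("findrisc") * p("fcg") * adh * (1 - p("fpg")),
           cost = ct[["findrisc"]] + ct[["fcg"]] + ct[["fpg"]] +
             visit0 + ref, pos = FALSE),
      list(pr = p("findrisc") * p("fcg") * adh * p("fpg"),
           cost = ct[["findrisc"]] + ct[["fcg"]] + ct[["fpg"]] +
             visit0 + ref, pos = TRUE))
  } else {
    visit0 <- if (societal) pset$cost_visit[["dhc"]] else 0
    leaves <- list(
      list(pr = 1 - p("findrisc"), cost = ct[["findrisc"]] + visit0,
           pos = FALSE),
      list(pr = p("findrisc") * (1 - p("fpg")),
           cost = ct[["findrisc"]] + ct[["fpg"]] + visit0, pos = FALSE),
      list(pr = p("findrisc") * p("fpg") * (1 - p("fpg")),
           cost = ct[["findrisc"]] + 2 * ct[["fpg"]] + visit0,
           pos = FALSE),
      list(pr = p("findrisc") * p("fpg") * p("fpg"),
           cost = ct[["findrisc"]] + 2 * ct[["fpg"]] + visit0,
           pos = TRUE))
  }
  pr <- vapply(leaves, `[[`, numeric(1), "pr")
  list(total_pr = sum(pr),
       exp_cost = sum(pr * vapply(leaves, `[[`, numeric(1), "cost")),
       p_pos = sum(pr[vapply(leaves, `[[`, logical(1), "pos")]))
}

test_that("detection probabilities chain the printed sensitivities", {
  chs <- screening_strategy("CHS", "annual", 40)
  dhc <- screening_strategy("DHC", "annual", 40)
  expect_equal(detection_probability(chs, fix$pset),
               0.864 * 0.842 * 0.544)
  expect_equal(detection_probability(chs, fix$pset), 0.3958,
               tolerance = 1e-3)
  expect_equal(detection_probability(dhc, fix$pset), 0.864 * 0.544^2)
  expect_equal(detection_probability(dhc, fix$pset), 0.2557,
               tolerance = 1e-3)
  noadh <- pset_with(adherence_referral = 0)
  expect_equal(detection_probability(chs, noadh), 0)
  expect_gt(detection_probability(dhc, noadh), 0) # DHC has no referral leg
})

test_that("expected screening costs match hand-enumerated branches", {
  chs <- screening_strategy("CHS", "annual", 40)
  dhc <- screening_strategy("DHC", "annual", 40)
  expect_equal(
    expected_screening_cost(chs, "healthy", "societal", fix$pset),
    0.3 + 0.6 + 0.417 * 0.7 + 0.417 * 0.234 * (0.9 + 1.96),
    tolerance = 1e-12)
  expect_equal(
    expected_screening_cost(chs, "healthy", "societal", fix$pset),
    1.4710, tolerance = 1e-4)
  expect_equal(
    expected_screening_cost(dhc, "healthy", "provider", fix$pset),
    0.3 + 0.417 * 0.9 + 0.417 * 0.011 * 0.9, tolerance = 1e-12)
  expect_equal(
    expected_screening_cost(dhc, "healthy", "provider", fix$pset),
    0.6794, tolerance = 1e-4)
  # perfect pre-screen specificity stops healthy subjects at the first node
  perfect <- pset_with(spec_findrisc = 1 - 1e-12)
  expect_equal(
    expected_screening_cost(chs, "healthy", "societal", perfect),
    0.3 + 0.6, tolerance = 1e-9)
  expect_equal(
    expected_screening_cost(chs, "healthy", "provider", perfect),
    0.3, tolerance = 1e-9)
})

test_that("cascade agrees with the leaf-path enumeration oracle", {
  set.seed(42)
  for (k in 1:20) {
    ps <- pset_with(
      sens_findrisc = runif(1, 0.3, 0.99), spec_findrisc = runif(1, 0.3, 0.99),
      sens_fcg = runif(1, 0.3, 0.99), spec_fcg = runif(1, 0.3, 0.99),
      sens_fpg = runif(1, 0.3, 0.99), spec_fpg = runif(1, 0.3, 0.99),
      adherence_referral = runif(1))
    for (setting in c("CHS", "DHC")) {
      strat <- screening_strategy(setting, "annual", 40)
      for (st in c("healthy", "diseased")) {
        for (societal in c(TRUE, FALSE)) {
          oracle <- enumerate_cascade(setting, st, ps, societal)
          expect_equal(oracle$total_pr, 1, tolerance = 1e-12)
          expect_equal(
            expected_screening_cost(strat, st,
                                    if (societal) "societal" else "provider",
                                    ps),
            oracle$exp_cost, tolerance = 1e-12)
          if (st == "diseased")
            expect_equal(detection_probability(strat, ps), oracle$p_pos,
                         tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("misclassification outcomes: false cascades and complementarity", {
  dhc <- screening_strategy("DHC", "annual", 40)
  mo <- misclassification_outcomes(dhc, fix$pset)
  expect_equal(mo$p_full_false_cascade_given_healthy, 0.417 * 0.011^2,
               tolerance = 1e-12)
  perfect <- pset_with(spec_findrisc = 1 - 1e-15, spec_fcg = 1 - 1e-15,
                       spec_fpg = 1 - 1e-15)
  for (setting in c("CHS", "DHC")) {
    s <- screening_strategy(setting, "annual", 40)
    expect_lt(
      misclassification_outcomes(s, perfect)$p_full_false_cascade_given_healthy,
      1e-14)
  }
  # detected + missed partition the diseased
  p <- mo$p_detect_given_diseased
  expect_equal(p + (1 - p), 1)
  # provider cost never exceeds societal cost
  expect_true(all(mo$expected_cost[, "provider"] <=
                  mo$expected_cost[, "societal"]))
})

test_that("detection probability is monotone in sensitivities and adherence", {
  base <- c(sens_findrisc = 0.8, sens_fcg = 0.8, sens_fpg = 0.5,
            adherence_referral = 0.9)
  for (setting in c("CHS", "DHC")) {
    strat <- screening_strategy(setting, "annual", 40)
    p0 <- detection_probability(strat, pset_with(base))
    for (nm in names(base)) {
      up <- base; up[nm] <- up[nm] + 0.05
      expect_gte(detection_probability(strat, pset_with(up)), p0)
    }
  }
})
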