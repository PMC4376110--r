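# Back-substitution oracle for the contribution transform: with baseline
# p0 = c0 and one-exposure fall probability p1 = 1 - (1 - c0)(1 - C), the
# odds ratio odds(p1)/odds(p0) must reproduce the input.
odds <- function(p) p / (1 - p)

test_that("contribution transform matches the odds-ratio back-substitution oracle", {
  expect_identical(contribution_from_or(1, 0.2), 0)
  for (case in list(c(3, 0.2, 2/7), c(2, 0.1, 1/11))) {
    C <- contribution_from_or(case[1], case[2])
    expect_equal(C, case[3], tolerance = 1e-14)
    p1 <- 1 - (1 - case[2]) * (1 - C)
    expect_equal(odds(p1) / odds(case[2]), case[1], tolerance = 1e-12)
  }
  expect_true(all(diff(contribution_from_or(c(1, 1.5, 2, 5, 50), 0.3)) > 0))
  expect_error(contribution_from_or(0.9, 0.2), "protective")
  expect_error(contribution_from_or(2, 1), "c0")
})

test_that("odds-ratio recovery is the exact inverse of the contribution", {
  expect_equal(or_from_contribution(0, 0.3), 1)
  expect_equal(or_from_contribution(2/7, 0.2), 3, tolerance = 1e-12)
  expect_equal(or_from_contribution(0.5, 0.5), 3, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:50) {
    or <- runif(1, 1, 100); c0 <- runif(1, 0.01, 0.99)
    expect_equal(or_from_contribution(contribution_from_or(or, c0), c0), or,
                 tolerance = 1e-12)
  }
  expect_error(or_from_contribution(1, 0.3), "\\[0, 1\\)")
})

test_that("compile_model converts every odds ratio at the final baseline", {
  m0 <- compile_model(knowledge_base(list(), baseline_c0 = 0.25))
  expect_equal(m0$c0, 0.25)
  expect_length(m0$contributions, 0L)

  m1 <- compile_model(kb_one_dich(or = 3, c0 = 0.2))
  expect_equal(m1$contributions[["factor a"]], 2/7, tolerance = 1e-14)

  kb <- knowledge_base(list(risk_factor("s", "scalar", c(2, 2), max_level = 2,
                                        level_prevalence = c(0.5, 0.3, 0.2))),
                       baseline_c0 = 0.1)
  expect_equal(compile_model(kb)$contributions[["s"]], c(1/11, 1/11),
               tolerance = 1e-14)
})

test_that("fall_risk composes multipliers per the noisy-OR closed form", {
  m <- compile_model(kb_one_dich(or = 3, p = 0.5, c0 = 0.2))
  # baseline-only
  expect_equal(fall_risk(m, subject_profile("factor a" = "absent"))$probability, 0.2)
  # present: back-check the odds ratio of the resulting risk
  rp <- fall_risk(m, subject_profile("factor a" = "present"))$probability
  expect_equal(rp, 1 - 0.8 * (1 - 2/7), tolerance = 1e-14)
  expect_equal(odds(rp) / odds(0.2), 3, tolerance = 1e-12)
  # unknown: prevalence marginalization, checked both ways
  ru <- fall_risk(m, subject_profile("factor a" = "unknown"))$probability
  expect_equal(ru, 1 - 0.8 * (1 - 0.5 * 2/7), tolerance = 1e-14)
  expect_equal(ru, 0.5 * rp + 0.5 * 0.2, tolerance = 1e-14)
  # assessment invariant: probability reproduces c0 times the multipliers
  a <- fall_risk(m, subject_profile("factor a" = "unknown"))
  expect_equal(a$probability,
               1 - (1 - a$c0) * prod(a$per_factor_multipliers), tolerance = 1e-12)
})

test_that("a synergy needs at least two present members to add risk", {
  kb <- knowledge_base(list(
    risk_factor("a", "dichotomous", 2, prevalence = 0.3),
    risk_factor("b", "dichotomous", 2, prevalence = 0.3),
    risk_factor("c", "dichotomous", 2, prevalence = 0.3),
    risk_factor("syn", "synergy", 1.8, members = c("a", "b", "c"))),
    baseline_c0 = 0.2)
  m <- compile_model(kb)
  one <- fall_risk(m, subject_profile(a = 1, b = 0, c = 0))
  expect_equal(unname(one$per_factor_multipliers["syn"]), 1)
  two <- fall_risk(m, subject_profile(a = 1, b = 1, c = 0))
  expect_lt(unname(two$per_factor_multipliers["syn"]), 1)
  three <- fall_risk(m, subject_profile(a = 1, b = 1, c = 1))
  expect_lt(three$per_factor_multipliers["syn"], two$per_factor_multipliers["syn"])
})

test_that("synergy groups marginalize unknown members jointly and exactly", {
  kb <- knowledge_base(list(
    risk_factor("a", "dichotomous", 2, prevalence = 0.5),
    risk_factor("b", "dichotomous", 3, prevalence = 0.4),
    risk_factor("syn", "synergy", 1.5, members = c("a", "b"))),
    baseline_c0 = 0.2)
  m <- compile_model(kb)
  Ca <- m$contributions[["a"]]; Cb <- m$contributions[["b"]]
  Cs <- m$contributions[["syn"]]
  # 4-pattern enumeration oracle for the all-unknown group value
  g <- 0.5 * 0.6 * 1 +                       # a only absent/present combos
       0.5 * 0.4 * (1 - Cb) +
       0.5 * 0.6 * (1 - Ca) +
       0.5 * 0.4 * (1 - Ca) * (1 - Cb) * (1 - Cs)
  expect_equal(expected_incidence(m), 1 - 0.8 * g, tolerance = 1e-12)
  # marginalization identity holds for a synergy member despite the coupling
  r1 <- fall_risk(m, subject_profile(a = 1, b = NA))$probability
  r0 <- fall_risk(m, subject_profile(a = 0, b = NA))$probability
  ru <- fall_risk(m, subject_profile(a = NA, b = NA))$probability
  expect_equal(ru, 0.5 * r1 + 0.5 * r0, tolerance = 1e-14)
})

test_that("switching any exposure on never decreases the risk", {
  for (seed in 1:8) {
    kb <- random_kb(seed)
    m <- compile_model(kb)
    pat <- all_exposure_patterns(kb, include_unknown = FALSE)
    if (nrow(pat) > 64L) pat <- pat[sample.int(nrow(pat), 64L), , drop = FALSE]
    risks <- predict_risk(m, pat)
    for (nm in observable_factors(kb)) {
      f <- fallrisk:::get_factor(kb, nm)
      top <- if (f$kind == "dichotomous") 1L else f$max_level
      bumped <- pat
      bumped[[nm]] <- pmin(bumped[[nm]] + 1L, top)
      expect_true(all(predict_risk(m, bumped) >= risks - 1e-14))
    }
  }
})

test_that("unknown exposures with OR > 1 and prevalence > 0 raise the risk", {
  m <- compile_model(kb_two_factor_fixture())
  base <- fall_risk(m, subject_profile("history of falls" = 0, "gait problems" = 0))
  with_unknown <- fall_risk(m, subject_profile("history of falls" = NA,
                                               "gait problems" = 0))
  expect_gt(with_unknown$probability, base$probability)
})

test_that("expected incidence agrees with pattern enumeration and Monte Carlo", {
  expect_equal(expected_incidence(compile_model(knowledge_base(list(), baseline_c0 = 0.31))),
               0.31)
  m <- compile_model(kb_one_dich(or = 3, p = 0.5, c0 = 0.2))
  expect_equal(expected_incidence(m), 1 - 0.8 * (1 - 0.5 * 2/7), tolerance = 1e-12)
  # Monte-Carlo cross-check on a mixed random model
  kb <- random_kb(42)
  m <- compile_model(kb)
  n <- 2e5
  cohort <- simulate_cohort(m, n, seed = 99L)
  ei <- expected_incidence(m)
  se <- sqrt(ei * (1 - ei) / n)
  expect_lt(abs(mean(cohort$outcomes) - ei), 3 * se)
})

test_that("bisection calibration hits the target incidence", {
  expect_lt(abs(calibrate_c0(knowledge_base(list(), target_incidence = 0.31)) - 0.31),
            1e-9)
  # factors with OR = 1 contribute nothing
  kb_null <- knowledge_base(list(
    risk_factor("a", "dichotomous", 1, prevalence = 0.5),
    risk_factor("b", "dichotomous", 1, prevalence = 0.2)),
    target_incidence = 0.31)
  expect_lt(abs(calibrate_c0(kb_null) - 0.31), 1e-9)
  # informative factor: c0 below the target, fixed point verified
  kb <- knowledge_base(list(risk_factor("a", "dichotomous", 3, prevalence = 0.5)),
                       target_incidence = 0.31)
  c0 <- calibrate_c0(kb)
  expect_lt(c0, 0.31)
  expect_lt(abs(expected_incidence(fallrisk:::build_model(kb, c0)) - 0.31), 1e-9)
})

test_that("profiles are validated against the knowledge base", {
  m <- compile_model(kb_two_factor_fixture())
  expect_error(fall_risk(m, subject_profile(ghost = 1)), "unknown factor")
  kb <- knowledge_base(list(risk_factor("s", "scalar", c(2, 2), max_level = 2,
                                        level_prevalence = c(0.5, 0.3, 0.2))),
                       baseline_c0 = 0.2)
  ms <- compile_model(kb)
  expect_error(fall_risk(ms, subject_profile(s = 3)), "outside")
  kb_syn <- knowledge_base(list(
    risk_factor("a", "dichotomous", 2, prevalence = 0.5),
    risk_factor("b", "dichotomous", 2, prevalence = 0.5),
    risk_factor("syn", "synergy", 1.5, members = c("a", "b"))),
    baseline_c0 = 0.2)
  expect_error(fall_risk(compile_model(kb_syn), subject_profile(syn = 1)),
               "no direct state")
})
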