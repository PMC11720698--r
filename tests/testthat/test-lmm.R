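# The reference outputs for these models come from the worked analyses the
# package re-implements; agreement is asserted to the precision those
# outputs are printed at (the optimizer is not bit-identical across
# implementations).

test_that("random-intercept model on the two-group data reduces to the
           classical t-test", {
  wm <- load_fixture("wm_between")
  fit <- fit_lmm(wm, fixed = "group", random = random_spec("participant"),
                 scheme = coding_scheme("dummy", reference = "65yr"))
  fe <- fixed_effects(fit)
  expect_equal(fe$estimate[fe$term == "(Intercept)"], 39.5, tolerance = 1e-4)
  expect_equal(fe$estimate[fe$term == "group"], -5, tolerance = 1e-4)
  expect_equal(fe$t[fe$term == "group"], -1.016, tolerance = 0.001)
  expect_equal(as.numeric(satterthwaite_df(fit, "group")), 18,
               tolerance = 0.01)
  vc <- variance_components(fit)
  expect_equal(vc$components$sd[vc$components$term == "(Intercept)"],
               10.957, tolerance = 0.001)
  expect_equal(marginal_r2(fit), 0.0498, tolerance = 5e-4)
  # ICC reported for the intercept only
  expect_true(is.na(vc$components$icc[vc$components$term != "(Intercept)"]) ||
              all(!is.na(vc$components$icc[vc$components$term ==
                                           "(Intercept)"])))
})

test_that("random slopes on the longitudinal data reproduce the paired
           t-test and its marginal R2", {
  wl <- load_fixture("wm_longitudinal")
  fit <- fit_lmm(wl, fixed = "age",
                 random = random_spec("participant", slopes = "age"))
  fe <- fixed_effects(fit)
  expect_equal(fe$estimate[fe$term == "age"], -3.3, tolerance = 1e-3)
  expect_equal(fe$t[fe$term == "age"], -3.23, tolerance = 0.005)
  expect_equal(as.numeric(satterthwaite_df(fit, "age")), 9,
               tolerance = 0.01)
  expect_equal(marginal_r2(fit), 0.0230, tolerance = 2e-4)
})

test_that("the 2x2 model under deviation coding estimates marginal effects
           and the difference of simple effects", {
  tb <- load_fixture("twobytwo")
  fit <- fit_lmm(tb, fixed = c("day", "stimtype", "day:stimtype"),
                 random = random_spec("participant",
                                      slopes = c("day", "stimtype",
                                                 "day:stimtype")))
  fe <- fixed_effects(fit)
  expect_equal(fe$estimate,
               c(5.275, 0.400, 0.150, -2.000), tolerance = 1e-4)
  expect_equal(fe$SE, c(0.493, 0.357, 0.291, 0.687), tolerance = 0.002)
  expect_equal(as.numeric(satterthwaite_df(fit, "stimtype")), 14.07,
               tolerance = 0.005)
  expect_equal(marginal_r2(fit), 0.0725, tolerance = 5e-4)
  vc <- variance_components(fit)$components
  expect_equal(vc$variance[vc$term == "(Intercept)"], 2.283,
               tolerance = 0.005)
  expect_equal(variance_components(fit)$residual_sd^2, 1.152,
               tolerance = 0.005)
})

test_that("with all random variances at zero the estimates equal ordinary
           least squares", {
  spec <- sim_spec(n_participants = 12, fixed = c(a = 2),
                   participant_sd = c("(Intercept)" = 0),
                   residual_sd = 0.7, replicates = 2, seed = 31)
  lt <- simulate_crossed(spec)
  fit <- fit_lmm(lt, fixed = "a", random = random_spec("participant"))
  X <- build_design_matrix(lt, "a")$X
  ols <- stats::lm.fit(X, lt$response)$coefficients
  fe <- fixed_effects(fit)
  expect_equal(fe$estimate, unname(ols), tolerance = 1e-6)
})

test_that("marginal and semi-partial R2 are invariant to contrast coding", {
  tb <- load_fixture("twobytwo")
  fits <- lapply(c("deviation", "sum", "dummy"), function(k) {
    fit_lmm(tb, fixed = c("day", "stimtype", "day:stimtype"),
            random = random_spec("participant",
                                 slopes = c("day", "stimtype",
                                            "day:stimtype")),
            scheme = coding_scheme(k))
  })
  r2 <- vapply(fits, marginal_r2, 0)
  expect_lt(abs(r2[2] - r2[1]), 1e-4)
  expect_lt(abs(r2[3] - r2[1]), 1e-4)
  # fitted values identical across codings
  f1 <- stats::fitted(fits[[1]]$model)
  expect_equal(stats::fitted(fits[[2]]$model), f1, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(stats::fitted(fits[[3]]$model), f1, tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("the dummy-coding pitfall is reproduced on the 2x2 data", {
  tb <- load_fixture("twobytwo")
  random <- random_spec("participant",
                        slopes = c("day", "stimtype", "day:stimtype"))
  dev <- fixed_effects(fit_lmm(tb, c("day", "stimtype", "day:stimtype"),
                               random, coding_scheme("deviation")))
  dum <- fixed_effects(fit_lmm(tb, c("day", "stimtype", "day:stimtype"),
                               random, coding_scheme("dummy")))
  mains <- c("day", "stimtype")
  # marginal main effects are null; simple effects at the reference level
  # look "significant"
  expect_true(all(dev$p[dev$term %in% mains] > 0.05))
  expect_true(all(dum$p[dum$term %in% mains] < 0.05))
  # the interaction is unaffected by the coding
  expect_lt(abs(dum$p[dum$term == "day:stimtype"] -
                dev$p[dev$term == "day:stimtype"]), 1e-3)
})

test_that("participant-centered refits yield eta squared within for the
           2x2 design", {
  tb <- load_fixture("twobytwo")
  random <- random_spec("participant",
                        slopes = c("day", "stimtype", "day:stimtype"))
  e2w <- eta2w_lmm(tb, c("day", "stimtype", "day:stimtype"), random,
                   center_unit = "participant")
  expect_equal(unname(e2w["day:stimtype"]), 0.152, tolerance = 0.002)
  expect_equal(length(attr(e2w, "undefined")), 0)
  # within shares exceed the total shares when intercept variance is
  # removed
  fit <- fit_lmm(tb, c("day", "stimtype", "day:stimtype"), random)
  semi <- semipartial_r2(fit)
  expect_true(all(e2w > semi))
})

test_that("eta squared within does not depend on whether the retained
           random intercept is modelled", {
  tb <- load_fixture("twobytwo")
  slopes <- c("day", "stimtype", "day:stimtype")
  with_int <- eta2w_lmm(tb, slopes, random_spec("participant",
                                                slopes = slopes),
                        center_unit = "participant")
  without_int <- eta2w_lmm(tb, slopes,
                           random_spec("participant", slopes = slopes,
                                       intercept = FALSE),
                           center_unit = "participant")
  expect_lt(max(abs(as.numeric(without_int) - as.numeric(with_int))),
            0.02)
})

test_that("crossed participant/stimulus models reproduce the face-rating
           analysis", {
  f <- load_fixture("faces")
  random <- list(random_spec("participant"),
                 random_spec("stimulus", slopes = "age"))
  rep <- effect_report(f, fixed = "age", random = random,
                       center_unit = "stimulus")
  age <- rep[rep$term == "age", ]
  expect_equal(abs(age$t), 1.549, tolerance = 0.005)
  expect_equal(age$p, 0.144, tolerance = 0.005)
  expect_equal(age$df, 14, tolerance = 0.1)
  expect_equal(age$eta2, 0.032, tolerance = 0.01)
  expect_equal(age$eta2_w, 0.053, tolerance = 0.01)
  # age is between participants: centering by participant flags it
  expect_warning(
    e2w_p <- eta2w_lmm(f, "age", random, center_unit = "participant"),
    "between-unit")
  expect_true(is.na(e2w_p["age"]))
  expect_equal(attr(e2w_p, "undefined"), "age")
})

test_that("the text-reading model reproduces the combined analysis and its
           variance shares", {
  r <- load_fixture("reading")
  random <- list(random_spec("participant",
                             slopes = c("language", "background",
                                        "language:background")),
                 random_spec("text"))
  rep <- effect_report(r, fixed = c("language", "background",
                                    "language:background"),
                       random = random, center_unit = "participant")
  int <- rep[rep$term == "language:background", ]
  expect_equal(int$t, -1.607, tolerance = 0.015)
  expect_equal(int$p, 0.125, tolerance = 0.03)
  expect_equal(int$df, 18.9, tolerance = 0.25)
  expect_equal(rep$eta2[match(c("language", "background",
                                "language:background"), rep$term)],
               c(0.047, 0.128, 0.018), tolerance = 0.04)
  expect_equal(rep$eta2_w[match(c("language", "background",
                                  "language:background"), rep$term)],
               c(0.087, 0.221, 0.034), tolerance = 0.025)
  expect_equal(attr(rep, "R2_marginal"), 0.175, tolerance = 0.002)
})

test_that("effect_report handles intercept-only models and optional
           partial eta squared", {
  wm <- load_fixture("wm_between")
  rep0 <- effect_report(wm, fixed = character(),
                        random = random_spec("participant"))
  expect_equal(nrow(rep0), 1)
  expect_equal(rep0$term, "(Intercept)")

  tb <- load_fixture("twobytwo")
  expect_warning(
    repp <- effect_report(tb, fixed = c("day", "stimtype", "day:stimtype"),
                          random = random_spec("participant",
                                               slopes = c("day", "stimtype",
                                                          "day:stimtype")),
                          eta2p = TRUE),
    "not recommended")
  expect_true(all(repp$eta2_p[repp$term != "(Intercept)"] >= 0))
})

test_that("fit_lmm validates its inputs", {
  wm <- load_fixture("wm_between")
  expect_error(fit_lmm(wm, "group", random_spec("nope")), "not found")
  expect_error(fit_lmm(wm, "group",
                       random_spec("participant", slopes = "zz")),
               "not among the fixed terms")
  expect_error(satterthwaite_df(
    fit_lmm(wm, "group", random_spec("participant")), "zz"),
    "unknown term")
})
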