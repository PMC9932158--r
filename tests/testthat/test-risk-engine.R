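mk_call <- function(call, tissues = character(0)) {
  structure(list(call = call, mosaic_tissues = tissues, floor = 0.003,
                 evidence = list()), class = "mosaic_call")
}
mk_est <- function(p_hat, lo, hi, status = "ok") {
  structure(list(p_hat = p_hat, ci_low = lo, ci_high = hi, k = 1, n = 1,
                 control_k = 0, control_n = 1, level = 0.95,
                 status = status), class = "vaf_estimate")
}
mk_origin <- function(origin) phasing_result_for_test(origin)
phasing_result_for_test <- function(origin) {
  structure(list(origin = origin, method = "phase_set",
                 supporting_snp = NA, p_value = NULL, table = NULL,
                 note = NULL), class = "phasing_result")
}
clean <- mk_call("none")
const <- mk_call("constitutional")

test_that("the category decision tree is total over all evidence combinations", {
  father_states <- list(none = clean,
                        somatic = mk_call("mosaic", c("3", "6")),
                        sperm_only = mk_call("mosaic", "6"))
  mother_states <- list(none = clean, somatic = mk_call("mosaic", "3"))
  child_states <- list(const = const, pz = mk_call("post_zygotic_mosaic", "1"))
  origins <- list(paternal = mk_origin("paternal"),
                  maternal = mk_origin("maternal"),
                  unresolved = mk_origin("unresolved"),
                  skipped = NULL)
  for (fa in names(father_states)) for (mo in names(mother_states))
    for (ch in names(child_states)) for (org in names(origins)) {
      res <- tryCatch(
        assign_category(father_states[[fa]], mother_states[[mo]],
                        child_states[[ch]], origins[[org]]),
        error = function(e) e)
      conflict <- (fa != "none" && org == "maternal") ||
        (mo != "none" && org == "paternal") ||
        (ch == "pz" && (fa != "none" || mo != "none"))
      if (conflict) {
        expect_s3_class(res, "error")
        expect_match(conditionMessage(res), "conflicting evidence")
      } else {
        expect_s3_class(res, "category_assignment")
        expected <-
          if (ch == "pz") "G"
          else if (fa == "somatic") "C"
          else if (fa == "sperm_only") "B"
          else if (mo == "somatic") "F"
          else if (org == "paternal") "A"
          else if (org == "maternal") "D_or_E"
          else "A_or_D_or_E"
        expect_identical(res$category, expected,
                         label = paste(fa, mo, ch, org))
      }
    }
})

test_that("published-style evidence patterns land in the expected categories", {
  # tissue-variable proband, clean parents -> post-zygotic (G)
  g <- assign_category(clean, clean, mk_call("post_zygotic_mosaic", "7"),
                       NULL)
  expect_equal(g$category, "G")
  # father sperm-only mosaic at low VAF -> confined gonadal (B)
  b <- assign_category(mk_call("mosaic", "6"), clean, const, NULL)
  expect_equal(b$category, "B")
  # no mosaicism anywhere, paternal haplotype -> one-off paternal (A)
  a <- assign_category(clean, clean, const, mk_origin("paternal"))
  expect_equal(a$category, "A")
})

test_that("sperm-based risk uses the conservative upper bound by default", {
  est <- mk_est(0.0023, 0.0019, 0.0026)
  cons <- risk_from_sperm(est)
  expect_equal(cons$risk, 0.0026)
  expect_equal(cons$basis, "sperm_vaf_upper_ci")
  point <- risk_from_sperm(est, conservative = FALSE)
  expect_equal(point$risk, 0.0023)
  expect_equal(point$ci_low, 0.0019)
  expect_equal(point$ci_high, 0.0026)
  expect_equal(risk_from_sperm(mk_est(0, 0, 0))$risk, 0)
  expect_error(risk_from_sperm(mk_est(NA, NA, NA, status = "sample_failure")),
               "failed")
})

test_that("model-based composite risks reproduce the calibrated cohort values", {
  de <- model_based_risk("D_or_E", seed = 1)
  expect_equal(round(100 * de$risk, 2), 0.49)
  expect_equal(round(100 * de$ci_low, 2), 0.43)
  expect_equal(round(100 * de$ci_high, 2), 0.57)
  ade <- model_based_risk("A_or_D_or_E", seed = 1)
  expect_equal(round(100 * ade$risk, 2), 0.09)
  expect_equal(round(100 * ade$ci_low, 2), 0.08)
  expect_equal(round(100 * ade$ci_high, 2), 0.11)
  # prior ratios behind the two composites
  pri <- default_priors()
  expect_equal(de$risk / mean(germline_vaf_model()$vafs), 2 / 17)
  expect_equal(ade$risk / mean(germline_vaf_model()$vafs), 2 / 88)
})

test_that("model-based risk vanishes without gonadal-mosaic prior mass and scales linearly", {
  pri0 <- default_priors()
  pri0["A"] <- pri0["A"] + pri0["E"]; pri0["E"] <- 0
  expect_equal(model_based_risk("D_or_E", priors = pri0, seed = 1)$risk, 0)

  base <- model_based_risk("D_or_E", seed = 1)$risk
  # doubling the germline VAF panel doubles the risk
  vm2 <- germline_vaf_model(vafs = 2 * germline_vaf_model()$vafs)
  expect_equal(model_based_risk("D_or_E", vaf_model = vm2, seed = 1)$risk,
               2 * base, tolerance = 1e-12)
  # doubling the E prior mass (at fixed D) scales the conditional ratio
  pri2 <- default_priors()
  pri2["E"] <- 0.04; pri2["A"] <- pri2["A"] - 0.02
  r2 <- model_based_risk("D_or_E", priors = pri2, seed = 1)$risk
  expect_equal(r2 / base, (0.04 / 0.19) / (2 / 17), tolerance = 1e-12)
})

test_that("family risk dispatch covers all categories", {
  sperm <- mk_est(0.081, 0.078, 0.084)
  c_assign <- assign_category(mk_call("mosaic", c("3", "6")), clean, const,
                              mk_origin("paternal"))
  rc <- compute_family_risk(c_assign, sperm_estimate = sperm,
                            conservative = FALSE)
  expect_equal(rc$risk, 0.081)

  f_assign <- assign_category(clean, mk_call("mosaic", "3"), const,
                              mk_origin("maternal"))
  rf <- compute_family_risk(f_assign)
  expect_equal(rf$qualitative, "unquantifiable_increased")
  expect_equal(rf$basis, "maternal_mixed_unquantified")

  g_assign <- assign_category(clean, clean,
                              mk_call("post_zygotic_mosaic", "1"), NULL)
  rg <- compute_family_risk(g_assign)
  expect_equal(rg$risk, 0)
  expect_equal(rg$basis, "post_zygotic_zero")

  de_assign <- assign_category(clean, clean, const, mk_origin("maternal"))
  rde <- compute_family_risk(de_assign, seed = 1)
  expect_equal(rde$basis, "model_maternal_DE")

  # paternal family with a failed sperm sample falls back with a warning
  a_assign <- assign_category(clean, clean, const, mk_origin("paternal"))
  expect_warning(
    ra <- compute_family_risk(a_assign,
                              sperm_estimate = mk_est(NA, NA, NA,
                                                      "sample_failure"),
                              seed = 1),
    "falling back")
  expect_equal(ra$basis, "model_unresolved_ADE")
})

test_that("risk is monotone in the measured sperm VAF", {
  risks <- vapply(seq(0.001, 0.1, length.out = 8), function(v)
    risk_from_sperm(mk_est(v, v * 0.9, v * 1.1))$risk, numeric(1))
  expect_true(all(diff(risks) > 0))
})

test_that("cohort summaries report counts, exact CIs, and the risk floor", {
  fams <- c(
    replicate(7, list(category = "C",
                      risk = risk_from_sperm(mk_est(0.08, 0.07, 0.09))),
              simplify = FALSE),
    replicate(52, list(category = "A",
                       risk = risk_from_sperm(mk_est(1e-4, 0, 3e-4))),
               simplify = FALSE))
  s <- cohort_summary(fams)
  expect_equal(s$n_families, 59)
  byc <- s$by_category
  c_row <- byc[byc$category == "C", ]
  expect_equal(c_row$count, 7)
  expect_equal(round(100 * c_row$proportion, 1), 11.9)
  expect_equal(s$n_below_floor, 52)
  empty <- byc[byc$category == "G", ]
  expect_equal(empty$count, 0)
  expect_equal(empty$ci_low, 0)
  expect_gt(empty$ci_high, 0)
  expect_error(cohort_summary(list()), "empty")
})

test_that("cohort proportions reproduce the published worked arithmetic", {
  expect_equal(cohort_proportion(7, 59)[["pct"]], 11.9)
  expect_equal(cohort_proportion(43, 52)[["pct"]], 82.7)
  expect_equal(cohort_proportion(34, 43, digits = 0)[["pct"]], 79)
  six <- cohort_proportion(6, 59)
  expect_equal(six[["ci_low_pct"]], 3.8)
  expect_equal(six[["ci_high_pct"]], 20.8)
})

test_that("priors and VAF model configurations are validated", {
  bad <- default_priors(); bad["A"] <- 0.5
  expect_error(model_based_risk("D_or_E", priors = bad), "sum to 1")
  expect_error(germline_vaf_model(vafs = c(0.02)), "vafs")
  expect_error(germline_vaf_model(vafs = c(0.02, 1.5)), "vafs")
})
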