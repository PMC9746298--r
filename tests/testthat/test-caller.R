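# Minimal hand-built panel results let the calling logic be exercised
# without running PCR.
fake_panel <- function(panel, amplified, control_ok = TRUE,
                       scheme = rgp_scheme()) {
  pairs <- rgptyper:::.panel_pairs(scheme, panel)
  control <- rgptyper:::.panel_control(scheme, panel)
  s <- data.frame(pair = pairs$name, expected = pairs$amplicon,
                  n_hits = 0L, n_concordant = 0L, amplified = FALSE,
                  ambiguous = FALSE, best_length = NA_integer_)
  s$amplified[s$pair %in% amplified] <- TRUE
  s$best_length[s$pair %in% amplified] <-
    s$expected[s$pair %in% amplified]
  s$amplified[s$pair == control] <- control_ok
  structure(list(panel = panel, per_pair = list(), summary = s,
                 control_pair = control, control_ok = control_ok),
            class = "rgp_panel_result")
}

test_that("variable-type calls follow the single-amplified-pair rule", {
  sch <- rgp_scheme()
  vc <- call_variable_type(fake_panel("multiplex1", "Var3"), sch)
  expect_identical(vc$type, "Vt3")
  expect_identical(vc$evidence$pair, "Var3")
  expect_identical(vc$evidence$size, 271L)

  expect_identical(
    call_variable_type(fake_panel("multiplex1", character(0)), sch)$type,
    "untypeable")
  expect_identical(
    call_variable_type(fake_panel("multiplex1", c("Var1", "Var4")),
                       sch)$type,
    "ambiguous")
  expect_error(
    call_variable_type(fake_panel("multiplex1", "Var1",
                                  control_ok = FALSE), sch),
    class = "rgp_assay_invalid")
  expect_error(call_variable_type(fake_panel("multiplex2", "Fg1"), sch),
               "multiplex1")
})

test_that("backbone-type calls mirror the variable-type logic over Fg pairs", {
  sch <- rgp_scheme()
  expect_identical(
    call_backbone_type(fake_panel("multiplex2", "Fg2"), sch)$type, "Bt2")
  expect_identical(
    call_backbone_type(fake_panel("multiplex2", "Fg3"), sch)$type, "Bt3")
  expect_identical(
    call_backbone_type(fake_panel("multiplex2", character(0)), sch)$type,
    "untypeable")
  expect_error(
    call_backbone_type(fake_panel("multiplex2", "Fg1",
                                  control_ok = FALSE), sch),
    class = "rgp_assay_invalid")
})

test_that("binomial assignment maps observed, novel and tentative combinations", {
  sch <- rgp_scheme()
  vc <- function(vt) structure(list(type = vt),
                               class = c("rgp_variable_call",
                                         "rgp_type_call"))
  bc <- function(bt) structure(list(type = bt),
                               class = c("rgp_backbone_call",
                                         "rgp_type_call"))
  call <- assign_binomial(vc("Vt3"), bc("Bt2"), sch)
  expect_identical(call$binomial, "V3B2")
  expect_identical(call$group, "3")
  expect_false(call$tentative)

  expect_identical(assign_binomial(vc("Vt1"), bc("Bt1"), sch)$group, "1")
  expect_identical(assign_binomial(vc("Vt4"), bc("Bt1"), sch)$group, "6")
  expect_identical(assign_binomial(vc("Vt5"), bc("Bt1"), sch)$group, "7")

  novel <- assign_binomial(vc("Vt1"), bc("Bt3"), sch)
  expect_identical(novel$binomial, "V1B3")
  expect_identical(novel$group, "novel")

  r5 <- assign_binomial(vc("untypeable"), bc("Bt3"), sch)
  expect_identical(r5$group, "5")
  expect_true(r5$tentative)
  expect_true(is.na(r5$binomial))

  un <- assign_binomial(vc("untypeable"), bc("Bt1"), sch)
  expect_identical(un$group, "unassigned")
  expect_identical(assign_binomial(vc("ambiguous"), bc("Bt2"),
                                   sch)$group, "unassigned")
})

test_that("legacy calls map the amplified classification pair to its group", {
  sch <- rgp_scheme()
  expect_identical(legacy_call(fake_panel("classification", "RGPgroup2"),
                               sch), "2")
  expect_identical(legacy_call(fake_panel("classification", "RGPgroup4"),
                               sch), "4")
  expect_identical(legacy_call(fake_panel("classification", character(0)),
                               sch), "unassigned")
  expect_warning(
    out <- legacy_call(fake_panel("classification",
                                  c("RGPgroup1", "RGPgroup3")), sch),
    "multiple")
  expect_identical(out, "unassigned")
  expect_error(legacy_call(fake_panel("classification", "RGPgroup1",
                                      control_ok = FALSE), sch),
               class = "rgp_assay_invalid")
})

test_that("collection summaries reproduce known percentage tables", {
  # legacy distribution of a 70-strain collection, 2-decimal reporting
  legacy <- rep(c("1", "2", "3", "4"), c(28, 27, 1, 14))
  out <- summarize_collection(legacy)
  expect_identical(out$count, c(28L, 27L, 1L, 14L))
  expect_identical(out$percent, c(40, 38.57, 1.43, 20))

  # variable-type distribution of a 21-strain panel, 1-decimal reporting
  vt <- rep(paste0("Vt", 1:5), c(10, 3, 6, 1, 1))
  out1 <- summarize_collection(vt, digits = 1)
  expect_identical(out1$percent, c(47.6, 14.3, 28.6, 4.8, 4.8))

  expect_identical(summarize_collection("3")$percent, 100)
  expect_error(summarize_collection(character(0)), "no calls")
})

test_that("summary percentages always total 100 within rounding error", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    labels <- rep(letters[seq_len(n)], sample(1:40, n, replace = TRUE))
    out <- summarize_collection(labels)
    expect_lt(abs(sum(out$percent) - 100), 0.05)
  }
})
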