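test_that("the knowledge base is total with the documented confidence classes", {
  kb <- rgp_structure_kb()
  expect_setequal(names(kb), c("1", "2", "2A", "3", "4", "5", "6", "7"))
  conf <- vapply(kb, `[[`, character(1), "confidence")
  expect_true(all(conf[c("1", "2", "3", "4", "6")] == "elucidated"))
  expect_identical(conf[["7"]], "predicted")
  expect_true(all(conf[c("2A", "5")] == "unknown"))
  expect_error(predict_structure("9"), "unknown Rgp group")
})

test_that("backbone repeats and side chains match the elucidated chemistry", {
  m2 <- predict_structure("2")
  expect_identical(render_backbone(m2$backbone_repeat),
                   "-2-\u03b1-Rha-3-\u03b1-Rha-")
  expect_identical(m2$branch_residue, "GlcNAc")
  expect_identical(m2$side_chain_size, 4L)
  expect_true(m2$side_chain_branched)
  expect_match(m2$attachment, "position 4 of residue A")

  m3 <- predict_structure("3")
  expect_identical(render_backbone(m3$backbone_repeat),
                   render_backbone(m2$backbone_repeat))
  expect_identical(render_side_chain(m3$side_chain),
                   "\u03b2-Gal-3-\u03b2-GalNAc")
  expect_identical(m3$branch_residue, "GalNAc")

  m4 <- predict_structure("4")
  expect_identical(render_backbone(m4$backbone_repeat),
                   "-3-\u03b1-Rha-2-\u03b1-Rha-2-\u03b1-Rha-")
  expect_identical(nrow(m4$backbone_repeat), 3L)
  expect_identical(render_side_chain(m4$side_chain),
                   "\u03b2-Gal-3-\u03b2-GalNAc")
  expect_match(m4$attachment, "variable")

  # glucose-containing backbones and the predicted Galf side chain
  expect_true(predict_structure("1")$backbone_contains_glc)
  expect_true(predict_structure("6")$backbone_contains_glc)
  expect_false(m2$backbone_contains_glc)
  expect_true(predict_structure("7")$side_chain_contains_galf)
})

test_that("elucidated backbone strings round-trip through the renderer", {
  for (g in c("2", "3", "4")) {
    rep <- predict_structure(g)$backbone_repeat
    expect_identical(parse_backbone(render_backbone(rep)), rep)
  }
  expect_error(parse_backbone("-2-Rha-"), "malformed")
})

test_that("locus/structure consistency flags missing side-chain transferases", {
  fix1 <- generate_locus("1", seed = 501)
  loc1 <- extract_locus(fix1$genome, fix1$genes, rgp_anchor_queries())
  rep1 <- check_consistency(loc1, predict_structure("1"))
  expect_identical(rep1$status, "consistent")
  expect_gte(rep1$n_variable_gt, rep1$side_chain_size - 1L)

  fix3 <- generate_locus("3", seed = 502)
  loc3 <- extract_locus(fix3$genome, fix3$genes, rgp_anchor_queries())
  expect_identical(check_consistency(loc3,
                                     predict_structure("3"))$status,
                   "consistent")
  # strip the side-chain transferases from the variable region
  gutted <- loc3
  gutted$genes <- gutted$genes[
    !(gutted$genes$region == "variable" &
        grepl("side-chain.*transferase", gutted$genes$product)), ]
  expect_identical(check_consistency(gutted,
                                     predict_structure("3"))$status,
                   "inconsistent")

  # a group-5-style locus (no variable-region transferases) is
  # inconsistent with any side-chain-bearing model
  fix5 <- generate_locus("5", seed = 503)
  loc5 <- extract_locus(fix5$genome, fix5$genes, rgp_anchor_queries())
  expect_identical(check_consistency(loc5,
                                     predict_structure("3"))$status,
                   "inconsistent")

  # unannotated input is skipped with a warning
  bare <- loc3
  bare$genes <- bare$genes[, setdiff(names(bare$genes),
                                     c("product", "region"))]
  expect_warning(out <- check_consistency(bare, predict_structure("3")),
                 "skipped")
  expect_identical(out$status, "skipped")

  # structure unknown -> indeterminate
  expect_identical(check_consistency(loc3,
                                     predict_structure("2A"))$status,
                   "indeterminate")
})

test_that("the knowledge base exports to JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_structure_kb(path)
  kb <- jsonlite::read_json(path)
  expect_setequal(names(kb), c("1", "2", "2A", "3", "4", "5", "6", "7"))
  expect_identical(kb[["4"]]$confidence, "elucidated")
})
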