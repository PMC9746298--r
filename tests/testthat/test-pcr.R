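test_that("a primer finds itself and its reverse complement", {
  p <- "CAGGTGCAAATGGCCAACTCG"
  hits <- find_binding_sites(p, p, max_mismatch = 0)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 1L)
  expect_identical(hits$strand, "+")
  expect_identical(hits$mismatches, 0L)

  rc <- oracle_revcomp(p)
  hits <- find_binding_sites(rc, p, max_mismatch = 0)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$strand, "-")
})

test_that("binding sites match the exhaustive sliding-window oracle", {
  set.seed(42)
  seqs <- replicate(4, random_dna(10000))
  primers <- c("CAGGTGCAAATGGCCAACTCG",  # exact scheme primer
               "GCTTCCAGATGCAAAAACG",
               "GTANNTAATGCACRAGAGGG")   # degenerate primer
  for (s in seqs) {
    # plant a perfect site and a 1-mismatch site on each strand
    p0 <- primers[1]
    s2 <- paste0(s, p0, random_dna(50),
                 mutate_dna(oracle_revcomp(p0), 1), random_dna(50))
    for (p in primers) {
      for (mm in 0:2) {
        got <- find_binding_sites(s2, p, max_mismatch = mm)
        want <- oracle_sites(s2, p, max_mismatch = mm)
        rownames(got) <- rownames(want) <- NULL
        expect_identical(got, want)
      }
    }
  }
})

test_that("degenerate genome bases match when expansion sets intersect", {
  p <- "GCTTCCAGATGCAAAAACG"
  site <- paste0(substr(p, 1, 12), "N", substr(p, 14, nchar(p)))
  s <- paste0("TTTTT", site, "TTTTT")  # N in the assembly
  hits <- find_binding_sites(s, p, max_mismatch = 0)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$mismatches, 0L)
  expect_identical(hits$strand, "+")
  expect_error(find_binding_sites("ACGT-ACGT", p), "non-IUPAC")
})

test_that("the 3' clamp rejects otherwise tolerated terminal mismatches", {
  p <- "GCTTCCAGATGCAAAAACG"
  site <- paste0(substr(p, 1, nchar(p) - 1), "T")  # 3'-terminal mismatch
  set.seed(5)
  s <- paste0(random_dna(100), site, random_dna(100))
  expect_identical(nrow(find_binding_sites(s, p, max_mismatch = 1,
                                           exact_3prime = 3)), 0L)
  found <- find_binding_sites(s, p, max_mismatch = 1, exact_3prime = 0)
  expect_identical(found$start, 101L)
  expect_identical(found$mismatches, 1L)
})

test_that("site reporting is monotone in the mismatch allowance", {
  set.seed(7)
  s <- random_dna(8000)
  p <- "GTCATGTGCTCTACCAATTG"
  s <- paste0(s, mutate_dna(p, 2), random_dna(100))
  prev <- 0L
  for (mm in 0:3) {
    hits <- find_binding_sites(s, p, max_mismatch = mm)
    expect_gte(nrow(hits), prev)
    prev <- nrow(hits)
  }
  expect_gte(prev, 1L)
})

test_that("predict_amplicons reproduces the scheme's inclusive span convention", {
  sch <- rgp_scheme()
  pair <- as.list(sch$pairs[sch$pairs$name == "RGPpos", ])
  set.seed(11)
  s <- plant_pair(pair$forward, pair$reverse, 801L)
  hits <- predict_amplicons(s, pair)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$length, 801L)
  expect_identical(hits$end - hits$start + 1L, 801L)

  # forward primer alone yields nothing
  lonely <- paste0(random_dna(200), pair$forward, random_dna(400))
  expect_identical(nrow(predict_amplicons(lonely, pair)), 0L)
})

test_that("multi-site pairing equals the brute-force pairing oracle", {
  sch <- rgp_scheme()
  pair <- as.list(sch$pairs[sch$pairs$name == "Var3", ])
  set.seed(23)
  # two forward and two reverse sites -> four candidate convergent products
  s <- paste0(random_dna(150), pair$forward, random_dna(100),
              pair$forward, random_dna(120),
              oracle_revcomp(pair$reverse), random_dna(90),
              oracle_revcomp(pair$reverse), random_dna(150))
  got <- predict_amplicons(s, pair, max_len = 10000L)
  want <- oracle_amplicons(s, pair$forward, pair$reverse,
                           max_len = 10000L)
  expect_identical(got[, names(want)], want)
  expect_identical(nrow(got), 4L)

  # size bounds filter the same set
  got2 <- predict_amplicons(s, pair, min_len = 250L, max_len = 400L)
  want2 <- oracle_amplicons(s, pair$forward, pair$reverse,
                            min_len = 250L, max_len = 400L)
  expect_identical(got2[, names(want2)], want2)
})

test_that("amplicon lengths are invariant under reverse complementing the genome", {
  sch <- rgp_scheme()
  set.seed(31)
  for (nm in c("Var1", "Fg2", "MSControl")) {
    pair <- as.list(sch$pairs[sch$pairs$name == nm, ])
    s <- plant_pair(pair$forward, pair$reverse, pair$amplicon)
    rc <- oracle_revcomp(s)
    fwd_hits <- predict_amplicons(s, pair)
    rc_hits <- predict_amplicons(rc, pair)
    expect_identical(sort(fwd_hits$length), sort(rc_hits$length))
    expect_identical(nrow(fwd_hits), 1L)
  }
})

test_that("run_panel scores pairs by size concordance with a working control", {
  sch <- rgp_scheme()
  fix <- generate_locus("3", seed = 301)
  res <- run_panel(fix$genome, sch, "multiplex1")
  s <- res$summary
  expect_true(res$control_ok)
  expect_true(s$amplified[s$pair == "Var3"])
  expect_identical(s$best_length[s$pair == "Var3"], 271L)
  expect_false(any(s$amplified[s$pair %in% c("Var1", "Var2", "Var4",
                                             "Var5")]))

  # a control-free genome: no amplicons anywhere, control fails
  blank <- stats::setNames(strrep("A", 5000), "blank")
  res0 <- run_panel(blank, sch, "multiplex1")
  expect_false(res0$control_ok)
  expect_identical(sum(res0$summary$n_hits), 0L)

  # deleting the control region fails the control while Var still amplifies
  fix_nc <- generate_locus("3", seed = 301, include_control = FALSE)
  res_nc <- run_panel(fix_nc$genome, sch, "multiplex1")
  expect_false(res_nc$control_ok)
  expect_true(res_nc$summary$amplified[res_nc$summary$pair == "Var3"])
})

test_that("amplicons never span contigs", {
  sch <- rgp_scheme()
  pair <- as.list(sch$pairs[sch$pairs$name == "RGPpos", ])
  set.seed(53)
  left <- paste0(random_dna(100), pair$forward, random_dna(100))
  right <- paste0(random_dna(100), oracle_revcomp(pair$reverse),
                  random_dna(100))
  res <- run_panel(c(c1 = left, c2 = right), sch, "classification")
  expect_identical(res$summary$n_hits[res$summary$pair == "RGPpos"], 0L)
})
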