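test_that("pairwise similarity reports identity and per-sequence coverage", {
  set.seed(61)
  a <- random_protein(200)
  self <- pairwise_similarity(a, a)
  expect_equal(self$identity, 100)
  expect_equal(self$coverage_a, 100)
  expect_equal(self$coverage_b, 100)
  expect_true(self$bidirectional_pass)

  half <- substr(a, 1, 100)
  sim <- pairwise_similarity(half, a)
  expect_equal(sim$identity, 100)
  expect_equal(sim$coverage_a, 100)
  expect_equal(sim$coverage_b, 50)
  # exactly 50% coverage meets the inclusive threshold; 60% does not,
  # unless the coverage requirement is relaxed to the query only
  expect_true(sim$bidirectional_pass)
  expect_false(pairwise_similarity(half, a,
                                   min_cov = 60)$bidirectional_pass)
  expect_true(pairwise_similarity(half, a, min_cov = 60,
                                  both_coverage = FALSE)$bidirectional_pass)

  b <- random_protein(200)
  expect_false(pairwise_similarity(a, b)$bidirectional_pass)

  expect_error(pairwise_similarity("MKT*", a), "non-amino-acid")
})

test_that("families form connected components over passing edges", {
  set.seed(71)
  p <- random_protein(180)
  trio <- c(x_p = p, y_p = p, z_p = p)
  fams <- build_families(trio)
  expect_identical(length(fams$families), 1L)
  expect_setequal(fams$families[[1]], names(trio))

  singletons <- stats::setNames(replicate(5, random_protein(150)),
                                paste0("s", 1:5))
  fams5 <- build_families(singletons)
  expect_identical(length(fams5$families), 5L)
})

test_that("planted families are recovered exactly at the 50/50 criterion", {
  set.seed(81)
  n_fam <- 10L
  seeds <- replicate(n_fam, random_protein(sample(150:350, 1)))
  prot <- list()
  for (f in seq_len(n_fam)) {
    for (m in 1:3) {
      # ~10% per-site divergence keeps intra-family identity near 80%
      chars <- strsplit(seeds[f], "", fixed = TRUE)[[1]]
      hit <- which(stats::runif(length(chars)) < 0.1)
      for (i in hit) chars[i] <- sample(
        setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], chars[i]), 1)
      prot[[sprintf("fam%02d_m%d", f, m)]] <- paste(chars, collapse = "")
    }
  }
  prot <- unlist(prot)
  fams <- build_families(prot)
  expect_identical(length(fams$families), n_fam)
  truth <- sub("_m[0-9]$", "", names(prot))
  for (members in fams$families) {
    expect_identical(length(unique(truth[match(members, names(prot))])), 1L)
  }

  # order invariance: shuffled input yields the same partition
  shuffled <- prot[sample(length(prot))]
  fams2 <- build_families(shuffled)
  expect_identical(fams2$membership[names(fams$membership)],
                   fams$membership)

  # prefilter off agrees with prefilter on
  fams3 <- build_families(prot, prefilter = FALSE)
  expect_identical(fams3$membership, fams$membership)
})

test_that("at 100/100 thresholds families are exact-duplicate classes", {
  set.seed(91)
  a <- random_protein(120)
  b <- random_protein(140)
  prot <- c(p1 = a, p2 = a, p3 = b, p4 = paste0(substr(b, 1, 139), "A"))
  fams <- build_families(prot, min_id = 100, min_cov = 100)
  # oracle: string equality classes
  canon <- function(groups) sort(vapply(groups, function(m)
    paste(sort(m), collapse = ","), character(1)))
  oracle <- split(names(prot), match(prot, unique(prot)))
  expect_identical(canon(unname(fams$families)), canon(unname(oracle)))
})

test_that("Markov clustering agrees with components on well-separated graphs", {
  set.seed(95)
  seeds <- replicate(4, random_protein(200))
  prot <- c(stats::setNames(rep(seeds, each = 2),
                            paste0("f", rep(1:4, each = 2),
                                   c("_a", "_b"))))
  cc <- build_families(prot, method = "components")
  mcl <- build_families(prot, method = "mcl")
  expect_identical(length(mcl$families), length(cc$families))
  canon <- function(f) sort(vapply(unname(f$families), function(m)
    paste(sort(m), collapse = ","), character(1)))
  expect_identical(canon(mcl), canon(cc))
})

test_that("presence/absence matrices are block structured for disjoint loci", {
  set.seed(105)
  a <- stats::setNames(replicate(3, random_protein(150)), paste0("a", 1:3))
  b <- stats::setNames(replicate(2, random_protein(150)), paste0("b", 1:2))
  fams <- build_families(c(a, b))
  mat <- presence_absence(fams, list(A = names(a), B = names(b)))
  expect_identical(dim(mat), c(2L, 5L))
  expect_identical(unname(rowSums(mat)), c(3, 2))
  # no family is shared between the two loci
  expect_true(all(colSums(mat) == 1))

  single <- presence_absence(build_families(a), list(A = names(a)))
  expect_true(all(single))
})

test_that("hierarchical clustering uses Jaccard distance with average linkage", {
  m <- rbind(
    l1 = c(TRUE, TRUE, FALSE, FALSE),
    l2 = c(TRUE, TRUE, FALSE, FALSE),
    l3 = c(FALSE, FALSE, TRUE, TRUE),
    l4 = c(TRUE, FALSE, TRUE, FALSE)
  )
  hcl <- hcl_cluster(m, k = 2)
  d <- as.matrix(hcl$dist)
  # identical rows at distance zero merge first
  expect_identical(d["l1", "l2"], 0)
  # disjoint profiles at distance one
  expect_identical(d["l1", "l3"], 1)
  # manual Jaccard for a mixed pair: shares 1 of 3 present-in-either
  expect_equal(d["l1", "l4"], 2 / 3)
  expect_identical(hcl$clusters[["l1"]], hcl$clusters[["l2"]])
  expect_false(hcl$clusters[["l1"]] == hcl$clusters[["l3"]])
  expect_error(hcl_cluster(m[1, , drop = FALSE]), "at least two")
})

test_that("dendrograms export as readable Newick", {
  set.seed(115)
  m <- matrix(stats::runif(60) > 0.5, nrow = 6,
              dimnames = list(paste0("locus", 1:6), NULL))
  m[, 1] <- TRUE  # avoid all-absent rows
  hcl <- hcl_cluster(m)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hcl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(m))
})
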