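# Deterministic synthetic rgp-locus fixtures.
#
# Each fixture genome carries, left to right: flanking filler, anchor gene A
# (30S ribosomal-protein placeholder), the variable side-chain region
# (genotype-specific gene families plus the genotype's Var primer cassette
# and the legacy classification cassette), the rhamnan backbone region
# (backbone families, the matching Fg cassette and the legacy RGPpos
# cassette), anchor gene B (transcriptional-regulator placeholder), and the
# adjacent DNA-primase gene wrapped in the shared MSControl cassette.
# A primer "cassette" is forward primer + filler + reverse complement of the
# reverse primer, sized so the inclusive span equals the scheme's expected
# amplicon; cassettes sit in intergenic DNA so the planted protein families
# are not disturbed.

.AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
           "T","V","W","Y")

.GENOTYPES <- c("1", "2", "2A", "3", "4", "5", "6", "7")

# Which primer cassettes each genotype carries.
.FIXTURE_TARGETS <- list(
  "1"  = list(var = "Var1", fg = "Fg1", legacy = "RGPgroup1"),
  "2"  = list(var = "Var1", fg = "Fg2", legacy = "RGPgroup2"),
  "2A" = list(var = "Var2", fg = "Fg2", legacy = "RGPgroup2"),
  "3"  = list(var = "Var3", fg = "Fg2", legacy = "RGPgroup3"),
  "4"  = list(var = "Var3", fg = "Fg3", legacy = "RGPgroup4"),
  "5"  = list(var = NA,     fg = "Fg3", legacy = NA),
  "6"  = list(var = "Var4", fg = "Fg1", legacy = "RGPgroup1"),
  "7"  = list(var = "Var5", fg = "Fg1", legacy = "RGPgroup1")
)

#' Planted gene families of the fixture generator
#'
#' The gene-family blueprint the synthetic loci are built from: one row per
#' family with its locus region, annotated product, protein length, the
#' genotypes that carry it, and whether it counts as a side-chain elongating
#' glycosyltransferase. Conserved core families (RgpA-D, RmlD, RgpI) are
#' shared by all or most genotypes; the three rgpF variants define the
#' backbone types; genotype-restricted families (scb glycosyltransferases,
#' the UDP-galactopyranose mutase of genotype 7, the membrane proteins of
#' genotype 5) define the variable regions.
#'
#' @return A data frame with columns \code{family}, \code{region},
#'   \code{product}, \code{length_aa}, \code{genotypes} (comma-separated),
#'   \code{is_gt}.
#' @export
rgp_fixture_families <- function() {
  f <- function(family, region, product, len, genotypes, is_gt = FALSE) {
    data.frame(family = family, region = region, product = product,
               length_aa = len, genotypes = genotypes, is_gt = is_gt,
               stringsAsFactors = FALSE)
  }
  all8 <- "1,2,2A,3,4,5,6,7"
  rbind(
    f("rgpI", "variable", "rhamnan branching regulator glycosyltransferase RgpI", 320L, "1,2,2A,3,4,6,7"),
    f("rmlD", "variable", "dTDP-L-rhamnose reductase RmlD", 280L, all8),
    f("wpsA_I", "variable", "side-chain priming glycosyltransferase ScbA (GlcNAc-type WpsA homolog)", 230L, "1,2,6,7"),
    f("wpsA_II", "variable", "side-chain priming glycosyltransferase ScbA (GalNAc-type WpsA homolog)", 230L, "2A,3,4"),
    f("scbB", "variable", "priming glycosyltransferase activator ScbB", 160L, "1,2,2A,3,4,6,7"),
    f("scbC", "variable", "side-chain glycosyltransferase ScbC", 300L, "1,2", TRUE),
    f("scbD", "variable", "side-chain glycosyltransferase ScbD", 290L, "1,2", TRUE),
    f("scbE", "variable", "side-chain glycosyltransferase ScbE", 310L, "1,2", TRUE),
    f("gt2var", "variable", "glycosyltransferase family 2 protein", 260L, "1,2"),
    f("duf2142v", "variable", "DUF2142 domain membrane protein", 240L, "1,2"),
    f("scbX2A", "variable", "side-chain glycosyltransferase", 270L, "2A", TRUE),
    f("scbG34", "variable", "side-chain galactosyltransferase", 250L, "3,4", TRUE),
    f("gt6a", "variable", "side-chain glycosyltransferase", 280L, "6", TRUE),
    f("gt6b", "variable", "side-chain glycosyltransferase", 260L, "6", TRUE),
    f("gt6c", "variable", "side-chain glycosyltransferase", 300L, "6", TRUE),
    f("glf7", "variable", "UDP-galactopyranose mutase", 380L, "7"),
    f("gt7a", "variable", "side-chain glycosyltransferase", 270L, "7", TRUE),
    f("gt7b", "variable", "side-chain glycosyltransferase", 290L, "7", TRUE),
    f("gt7c", "variable", "side-chain glycosyltransferase", 250L, "7", TRUE),
    f("scbF_I", "variable", "Wzx-like flippase ScbF", 460L, "1,2,6,7"),
    f("scbF_II", "variable", "Wzx-like flippase ScbF", 460L, "2A,3,4"),
    f("gtBig167", "backbone", "multidomain glycosyltransferase", 620L, "1,6,7"),
    f("duf2142b", "backbone", "DUF2142 domain membrane protein", 240L, "1,6,7"),
    f("rgpE_like", "backbone", "putative rhamnan capping glycosyltransferase", 330L, "1,6,7"),
    f("rgpE", "backbone", "rhamnan chain-length determinant RgpE", 330L, "2,2A,3,4,5"),
    f("rgpA", "backbone", "rhamnosyltransferase RgpA", 300L, all8),
    f("rgpB", "backbone", "rhamnosyltransferase RgpB", 300L, all8),
    f("rgpC", "backbone", "polysaccharide ABC transporter permease RgpC", 270L, all8),
    f("rgpD", "backbone", "polysaccharide ABC transporter ATP-binding protein RgpD", 230L, all8),
    f("rgpF_1", "backbone", "rhamnosyltransferase RgpF (backbone genotype 1)", 390L, "1,6,7"),
    f("rgpF_2", "backbone", "rhamnosyltransferase RgpF (backbone genotype 2)", 390L, "2,2A,3"),
    f("rgpF_3", "backbone", "rhamnosyltransferase RgpF (backbone genotype 3)", 390L, "4,5"),
    f("ost5a", "backbone", "oligosaccharyltransferase-like polytopic membrane protein", 410L, "5"),
    f("ost5b", "backbone", "polytopic membrane protein", 360L, "5")
  )
}

# Deterministic seed protein per family, independent of the user seed.
.family_seed_protein <- local({
  cache <- list()
  function(family) {
    if (!is.null(cache[[family]])) return(cache[[family]])
    tab <- rgp_fixture_families()
    i <- match(family, tab$family)
    stopifnot(!is.na(i))
    p <- .with_seed(900100L + i, paste(
      sample(.AA20, tab$length_aa[i], replace = TRUE), collapse = ""))
    cache[[family]] <<- p
    p
  }
})

#' Anchor protein queries for the packaged fixtures
#'
#' The two synthetic anchor proteins flanking every fixture locus: a 30S
#' ribosomal-protein placeholder on the variable (5') side and a
#' transcriptional-regulator placeholder on the backbone (3') side. Real
#' genomes require user-supplied anchor sequences.
#'
#' @return A list with character elements \code{five_prime} and
#'   \code{three_prime}.
#' @export
rgp_anchor_queries <- function() {
  list(
    five_prime = .with_seed(900001L, paste(
      sample(.AA20, 240L, replace = TRUE), collapse = "")),
    three_prime = .with_seed(900002L, paste(
      sample(.AA20, 210L, replace = TRUE), collapse = ""))
  )
}

.PRIMASE_PROTEIN <- function() {
  .with_seed(900003L, paste(sample(.AA20, 300L, replace = TRUE),
                            collapse = ""))
}

# S. thermophilus-like filler: GC about 39%.
.filler <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.305, 0.195, 0.195, 0.305)), collapse = "")
}

.mutate_protein <- function(p, rate) {
  if (rate <= 0) return(p)
  chars <- strsplit(p, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(.AA20, chars[i]), 1L)
  paste(chars, collapse = "")
}

# Back-translate a protein with uniformly sampled synonymous codons and a
# TAA stop.
.backtranslate <- local({
  codon_table <- NULL
  function(p) {
    if (is.null(codon_table)) {
      gc <- Biostrings::GENETIC_CODE
      codon_table <<- split(names(gc), unname(gc))
    }
    chars <- strsplit(p, "", fixed = TRUE)[[1L]]
    codons <- vapply(chars, function(a) {
      opts <- codon_table[[a]]
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, character(1))
    paste0(paste(codons, collapse = ""), "TAA")
  }
})

#' Generate one synthetic rgp-locus fixture genome
#'
#' Emits a complete single-contig fixture for a genotype with planted anchor
#' genes, genotype-specific gene families (proteins mutated from fixed
#' family seeds at \code{mutation_rate} per site, then back-translated),
#' primer cassettes at scheme-consistent spacings for the genotype's Var and
#' Fg pairs, the legacy classification cassettes, and the DNA-primase gene
#' wrapped in the shared MSControl cassette. The same \code{(genotype,
#' seed)} always yields byte-identical output.
#'
#' @param genotype Rgp group label: one of \code{"1"}, \code{"2"},
#'   \code{"2A"}, \code{"3"}, \code{"4"}, \code{"5"}, \code{"6"},
#'   \code{"7"}.
#' @param seed Integer seed controlling all randomness of this fixture.
#' @param mutation_rate Per-site protein mutation probability used to
#'   diverge family members between strains (default 0.05, keeping
#'   intra-family identity around 90 percent).
#' @param include_control Plant the MSControl cassette? (\code{FALSE}
#'   simulates a failed assay control.)
#' @param strain Strain identifier (default derived from genotype and
#'   seed).
#' @param scheme Typing scheme supplying primer sequences and spacings.
#' @return An object of class \code{rgp_fixture}: list with \code{strain},
#'   \code{genotype}, \code{genome} (named character vector of one contig),
#'   \code{genes} (gene-record data frame with product/region/family),
#'   \code{cassettes} (planted primer-cassette coordinates) and
#'   \code{truth} (planted vt, bt, binomial, group, legacy group, family
#'   labels).
#' @export
generate_locus <- function(genotype, seed = 1L, mutation_rate = 0.05,
                           include_control = TRUE, strain = NULL,
                           scheme = rgp_scheme()) {
  genotype <- as.character(genotype)
  if (!genotype %in% .GENOTYPES) {
    stop("unknown genotype: ", sQuote(genotype), call. = FALSE)
  }
  if (is.null(strain)) strain <- sprintf("Rgp%s_s%d", genotype, seed)
  .with_seed(seed, .build_fixture(genotype, strain, mutation_rate,
                                  include_control, scheme))
}

.build_fixture <- function(genotype, strain, mutation_rate,
                           include_control, scheme) {
  tab <- rgp_fixture_families()
  carries <- vapply(strsplit(tab$genotypes, ","), function(g)
    genotype %in% g, logical(1))
  fam <- tab[carries, , drop = FALSE]
  targets <- .FIXTURE_TARGETS[[genotype]]
  anchors <- rgp_anchor_queries()

  seqs <- character(0)
  pos <- 0L
  genes <- list()
  cassettes <- list()
  emit <- function(s) {
    seqs[[length(seqs) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  emit_gene <- function(id, protein, product, region, family = NA) {
    cds <- .backtranslate(protein)
    genes[[length(genes) + 1L]] <<- data.frame(
      id = id, contig = strain, start = pos + 1L,
      end = pos + nchar(cds), strand = "+", product = product,
      region = region, family = family, protein = protein,
      stringsAsFactors = FALSE)
    emit(cds)
  }
  pair_row <- function(name) {
    as.list(scheme$pairs[scheme$pairs$name == name, ])
  }
  emit_cassette <- function(pair_name, region, inner = NULL) {
    p <- pair_row(pair_name)
    fill <- p$amplicon - nchar(p$forward) - nchar(p$reverse)
    start <- pos + 1L
    emit(p$forward)
    if (is.null(inner)) {
      emit(.filler(fill))
    } else {
      # inner gene sits inside the cassette filler; pad to the exact
      # expected amplicon length afterwards
      emit(.filler(200L))
      emit_gene(inner$id, inner$protein, inner$product, inner$region)
      trail <- (start - 1L + p$amplicon - nchar(p$reverse)) - pos
      stopifnot(trail >= 0L)
      emit(.filler(trail))
    }
    emit(.revcomp(p$reverse))
    cassettes[[length(cassettes) + 1L]] <<- data.frame(
      pair = pair_name, start = start, end = pos,
      length = pos - start + 1L, region = region,
      stringsAsFactors = FALSE)
  }
  spacer <- function() emit(.filler(sample(40:120, 1L)))

  emit(.filler(400L))
  emit_gene(paste0(strain, "_anchorA"), anchors$five_prime,
            "30S ribosomal protein (locus anchor)", "flank")

  # --- variable (5') region ---
  vr <- fam[fam$region == "variable", , drop = FALSE]
  for (i in seq_len(nrow(vr))) {
    spacer()
    f <- vr$family[i]
    emit_gene(paste(strain, f, sep = "_"),
              .mutate_protein(.family_seed_protein(f), mutation_rate),
              vr$product[i], "variable", f)
    if (i == min(2L, nrow(vr)) && !is.na(targets$var)) {
      spacer()
      emit_cassette(targets$var, "variable")
    }
    if (i == min(3L, nrow(vr)) && !is.na(targets$legacy)) {
      spacer()
      emit_cassette(targets$legacy, "variable")
    }
  }
  # genotype 5 has essentially no variable region and plants no Var site

  # --- backbone (3') region ---
  br <- fam[fam$region == "backbone", , drop = FALSE]
  for (i in seq_len(nrow(br))) {
    spacer()
    f <- br$family[i]
    emit_gene(paste(strain, f, sep = "_"),
              .mutate_protein(.family_seed_protein(f), mutation_rate),
              br$product[i], "backbone", f)
    if (i == 1L) {
      spacer()
      emit_cassette("RGPpos", "backbone")
    }
    if (i == nrow(br)) {
      spacer()
      emit_cassette(targets$fg, "backbone")
    }
  }

  spacer()
  emit_gene(paste0(strain, "_anchorB"), anchors$three_prime,
            "transcriptional regulator (locus anchor)", "flank")

  # --- adjacent DNA primase carrying the multiplex control sites ---
  emit(.filler(150L))
  if (include_control) {
    emit_cassette("MSControl", "flank", inner = list(
      id = paste0(strain, "_primase"),
      protein = .mutate_protein(.PRIMASE_PROTEIN(), mutation_rate),
      product = "DNA primase", region = "flank"))
  } else {
    emit_gene(paste0(strain, "_primase"),
              .mutate_protein(.PRIMASE_PROTEIN(), mutation_rate),
              "DNA primase", "flank")
  }
  emit(.filler(400L))

  genome <- paste(seqs, collapse = "")
  genes <- do.call(rbind, genes)
  cassettes <- do.call(rbind, cassettes)
  .check_site_uniqueness(genome, cassettes, scheme)

  vt <- if (is.na(targets$var)) "untypeable" else
    unname(scheme$vt_map[targets$var])
  bt <- unname(scheme$bt_map[targets$fg])
  binomial <- if (vt == "untypeable") NA_character_ else
    sprintf("V%sB%s", sub("^Vt", "", vt), sub("^Bt", "", bt))
  truth <- list(
    genotype = genotype, vt = vt, bt = bt, binomial = binomial,
    group = genotype, tentative = is.na(targets$var),
    legacy_group = if (is.na(targets$legacy)) NA_character_ else
      unname(scheme$legacy_map[targets$legacy]),
    families = fam$family,
    n_genes = sum(genes$region != "flank"))
  structure(
    list(strain = strain, genotype = genotype,
         genome = stats::setNames(genome, strain), genes = genes,
         cassettes = cassettes, truth = truth,
         mutation_rate = mutation_rate),
    class = "rgp_fixture")
}

# Every planted primer site must be unique in the fixture genome so the
# panels see single-copy targets.
.check_site_uniqueness <- function(genome, cassettes, scheme) {
  pairs <- scheme$pairs[scheme$pairs$name %in% cassettes$pair, ]
  for (i in seq_len(nrow(pairs))) {
    for (primer in c(pairs$forward[i], pairs$reverse[i])) {
      n <- .count_fixed(genome, primer) + .count_fixed(genome,
                                                       .revcomp(primer))
      if (n != 1L) {
        stop("fixture generation failed: primer site of pair ",
             pairs$name[i], " occurs ", n, " times", call. = FALSE)
      }
    }
  }
}

.count_fixed <- function(s, pat) {
  m <- gregexpr(pat, s, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

#' @export
print.rgp_fixture <- function(x, ...) {
  cat(sprintf(
    "Synthetic rgp fixture %s (genotype %s): %d bp, %d genes, planted %s/%s -> %s\n",
    x$strain, x$genotype, nchar(x$genome), nrow(x$genes), x$truth$vt,
    x$truth$bt, if (is.na(x$truth$binomial)) "tentative Rgp5" else
      x$truth$binomial))
  invisible(x)
}

#' Write a fixture to disk (FASTA + GFF3 + proteins + truth)
#'
#' @param fixture An \code{rgp_fixture}.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths (\code{fna},
#'   \code{gff}, \code{faa}, \code{truth}), invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "rgp_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, fixture$strain)
  fna <- paste0(base, ".fna")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(fixture$genome), fna)

  g <- fixture$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "rgptyper_fixture", type = "CDS", phase = 0L, ID = g$id,
    product = g$product, region = g$region, family = g$family)
  gff <- paste0(base, ".gff3")
  rtracklayer::export(gr, gff, format = "gff3")

  faa <- paste0(base, ".faa")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(g$protein, g$id)), faa)

  truth <- paste0(base, "_truth.tsv")
  tr <- fixture$truth
  utils::write.table(
    data.frame(strain = fixture$strain, genotype = tr$genotype,
               vt = tr$vt, bt = tr$bt, binomial = tr$binomial,
               group = tr$group, legacy_group = tr$legacy_group,
               n_genes = tr$n_genes),
    truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fna = fna, gff = gff, faa = faa, truth = truth))
}

#' Generate a collection of fixture genomes
#'
#' Draws independent per-strain seeds from the master seed and generates
#' \code{counts[g]} fixtures of each genotype \code{g}, each diverged from
#' the family seed proteins at \code{mutation_rate}.
#'
#' @param counts Named integer vector: genotype label -> number of strains.
#' @param seed Master seed.
#' @param mutation_rate Per-site protein mutation probability per strain.
#' @param ... Passed to [generate_locus()].
#' @return An object of class \code{rgp_collection}: list with
#'   \code{fixtures} (named list of \code{rgp_fixture}) and \code{truth}
#'   (data frame of planted calls, one row per strain).
#' @export
generate_collection <- function(counts, seed = 1L, mutation_rate = 0.05,
                                ...) {
  if (!length(counts)) stop("empty genotype counts", call. = FALSE)
  if (is.null(names(counts)) ||
      !all(names(counts) %in% .GENOTYPES)) {
    stop("counts must be named by genotype label (",
         paste(.GENOTYPES, collapse = ", "), ")", call. = FALSE)
  }
  counts <- counts[counts > 0]
  total <- sum(counts)
  seeds <- .with_seed(seed, sample.int(2147483646L, total))
  fixtures <- vector("list", total)
  k <- 0L
  for (g in names(counts)) {
    for (i in seq_len(counts[[g]])) {
      k <- k + 1L
      fixtures[[k]] <- generate_locus(
        g, seed = seeds[k], mutation_rate = mutation_rate,
        strain = sprintf("Rgp%s_%03d", g, i), ...)
    }
  }
  names(fixtures) <- vapply(fixtures, `[[`, character(1), "strain")
  truth <- do.call(rbind, lapply(fixtures, function(f) {
    tr <- f$truth
    data.frame(strain = f$strain, genotype = tr$genotype, vt = tr$vt,
               bt = tr$bt, binomial = tr$binomial, group = tr$group,
               legacy_group = tr$legacy_group, stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  structure(list(fixtures = fixtures, truth = truth, seed = seed),
            class = "rgp_collection")
}

#' @export
print.rgp_collection <- function(x, ...) {
  tb <- table(x$truth$genotype)
  cat(sprintf("Fixture collection: %d strains (%s)\n", nrow(x$truth),
              paste(sprintf("Rgp%s x %d", names(tb), tb), collapse = ", ")))
  invisible(x)
}
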