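#' Find primer binding sites on both strands
#'
#' Scans a DNA sequence for sites where a primer can anneal with at most
#' \code{max_mismatch} mismatches, requiring the 3'-terminal
#' \code{exact_3prime} bases of the primer to match without mismatch (the
#' polymerase-extension clamp). IUPAC ambiguity codes are honoured on both
#' sides: a primer base matches a sequence base iff their expansion sets
#' intersect, so an \code{N} in a draft assembly never counts as a mismatch.
#'
#' A site on the \code{+} strand is a window of the input sequence equal
#' (up to mismatches) to the primer read 5'->3'; a site on the \code{-}
#' strand is a window equal to the reverse complement of the primer, i.e. the
#' primer anneals to the forward strand and extends leftwards. Coordinates
#' are 1-based and inclusive.
#'
#' @param seq DNA sequence: a single character string or \code{DNAString}.
#' @param primer Primer sequence, 5'->3' (character string).
#' @param max_mismatch Maximum number of tolerated mismatches (default 0).
#' @param exact_3prime Number of 3'-terminal primer bases that must match
#'   exactly (default 3).
#' @return A data frame with columns \code{start}, \code{end}, \code{strand},
#'   \code{mismatches}, ordered by position then strand. A primer longer than
#'   the sequence yields zero rows.
#' @export
find_binding_sites <- function(seq, primer, max_mismatch = 0L,
                               exact_3prime = 3L) {
  stopifnot(max_mismatch >= 0L, exact_3prime >= 0L)
  seq <- as.character(seq)
  sbits <- .encode_dna(seq, what = "sequence")
  fwd <- .scan_primer(sbits, .encode_dna(primer, "primer"),
                      max_mismatch, exact_3prime, three_prime_left = FALSE)
  rev <- .scan_primer(sbits, .encode_dna(.revcomp(primer), "primer"),
                      max_mismatch, exact_3prime, three_prime_left = TRUE)
  out <- rbind(
    if (nrow(fwd)) cbind(fwd, strand = "+") else NULL,
    if (nrow(rev)) cbind(rev, strand = "-") else NULL
  )
  if (is.null(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  out <- out[order(out$start, out$strand), c("start", "end", "strand",
                                             "mismatches")]
  rownames(out) <- NULL
  out
}

# Hamming scan of an encoded primer against an encoded sequence. The primer
# bits are given in genome orientation; `three_prime_left` says which end of
# the window corresponds to the primer's 3' terminus.
.scan_primer <- function(sbits, pbits, max_mismatch, exact_3prime,
                         three_prime_left) {
  N <- length(sbits)
  L <- length(pbits)
  n <- N - L + 1L
  empty <- data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0))
  if (n < 1L) return(empty)
  k <- min(exact_3prime, L)
  idx3 <- if (k == 0L) integer(0)
          else if (three_prime_left) seq_len(k) else (L - k + 1L):L
  mm <- integer(n)
  mm3 <- integer(n)
  for (j in seq_len(L)) {
    miss <- bitwAnd(sbits[j:(j + n - 1L)], pbits[j]) == 0L
    mm <- mm + miss
    if (j %in% idx3) mm3 <- mm3 + miss
  }
  keep <- which(mm <= max_mismatch & mm3 == 0L)
  if (!length(keep)) return(empty)
  data.frame(start = keep, end = keep + L - 1L, mismatches = mm[keep])
}

#' Predict PCR products of a primer pair
#'
#' Enumerates all convergent forward/reverse binding-site pairings on a
#' single contig and reports every product whose inclusive span (first base
#' of the forward site through last base of the reverse site) falls within
#' \code{[min_len, max_len]}. Primer sites may not overlap, so every product
#' is at least as long as the two primers combined.
#'
#' @param seq DNA sequence of one contig (character or \code{DNAString}).
#' @param pair Primer pair: a list or one-row data frame with elements
#'   \code{name}, \code{forward}, \code{reverse} (primer sequences 5'->3').
#' @param max_mismatch,exact_3prime Passed to [find_binding_sites()].
#' @param min_len Minimum product length (default: summed primer lengths).
#' @param max_len Maximum product length (default 5000 bp).
#' @param contig Contig identifier carried into the output.
#' @return A data frame of amplicon hits: \code{pair_name}, \code{contig},
#'   \code{start}, \code{end}, \code{length}, \code{fwd_mismatches},
#'   \code{rev_mismatches}. Absence of product yields zero rows.
#' @export
predict_amplicons <- function(seq, pair, max_mismatch = 0L,
                              exact_3prime = 3L, min_len = NULL,
                              max_len = 5000L, contig = "contig1") {
  pair <- as.list(pair)
  stopifnot(!is.null(pair$forward), !is.null(pair$reverse))
  pname <- if (is.null(pair$name)) NA_character_ else pair$name
  if (is.null(min_len)) min_len <- nchar(pair$forward) + nchar(pair$reverse)
  stopifnot(min_len <= max_len)

  fs <- find_binding_sites(seq, pair$forward, max_mismatch, exact_3prime)
  rs <- find_binding_sites(seq, pair$reverse, max_mismatch, exact_3prime)
  hits <- rbind(
    .pair_sites(fs[fs$strand == "+", ], rs[rs$strand == "-", ]),
    .pair_sites(rs[rs$strand == "+", ], fs[fs$strand == "-", ], flip = TRUE)
  )
  hits <- hits[hits$length >= max(min_len, nchar(pair$forward) +
                                    nchar(pair$reverse)) &
               hits$length <= max_len, , drop = FALSE]
  if (nrow(hits)) {
    hits <- cbind(pair_name = pname, contig = contig, hits)
    hits <- hits[order(hits$start, hits$end), ]
    rownames(hits) <- NULL
  } else {
    hits <- data.frame(pair_name = character(0), contig = character(0),
                       start = integer(0), end = integer(0),
                       length = integer(0), fwd_mismatches = integer(0),
                       rev_mismatches = integer(0))
  }
  hits
}

# Convergent pairings of left (+ strand) and right (- strand) sites. With
# `flip`, the reverse primer provides the left site, so the mismatch columns
# swap roles.
.pair_sites <- function(left, right, flip = FALSE) {
  if (!nrow(left) || !nrow(right)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), fwd_mismatches = integer(0),
                      rev_mismatches = integer(0)))
  }
  grid <- expand.grid(i = seq_len(nrow(left)), j = seq_len(nrow(right)))
  ls <- left$start[grid$i]; le <- left$end[grid$i]
  rs <- right$start[grid$j]; re <- right$end[grid$j]
  ok <- rs > le  # convergent, non-overlapping
  data.frame(
    start = ls[ok], end = re[ok], length = re[ok] - ls[ok] + 1L,
    fwd_mismatches = if (flip) right$mismatches[grid$j][ok]
                     else left$mismatches[grid$i][ok],
    rev_mismatches = if (flip) left$mismatches[grid$i][ok]
                     else right$mismatches[grid$j][ok]
  )
}

#' Run a typing panel in silico
#'
#' Evaluates every primer pair of a panel (plus the panel's control pair) on
#' a genome, possibly split over several contigs; amplicons never span
#' contigs. A pair is scored as \emph{amplified} iff at least one product
#' lies within \code{expected_amplicon * (1 +/- size_tolerance)}. A pair with
#' size-concordant products at more than one location is flagged ambiguous
#' (the scheme assumes single-copy targets). \code{control_ok} is
#' \code{TRUE} iff the panel's control pair amplified.
#'
#' @param genome A FASTA path, named character vector of contig sequences,
#'   or \code{DNAStringSet}.
#' @param scheme An \code{rgp_scheme}.
#' @param panel \code{"classification"}, \code{"multiplex1"} or
#'   \code{"multiplex2"}.
#' @param size_tolerance Fractional size tolerance around the expected
#'   amplicon (default 0.10, a gel-resolution surrogate).
#' @param max_mismatch,exact_3prime Passed to [find_binding_sites()].
#' @param max_len Upper product-size bound passed to [predict_amplicons()].
#' @return An object of class \code{rgp_panel_result}: list with
#'   \code{panel}, \code{per_pair} (named list of amplicon-hit data frames),
#'   \code{summary} (data frame: pair, expected, n_hits, n_concordant,
#'   amplified, ambiguous, best_length), \code{control_pair} and
#'   \code{control_ok}.
#' @export
run_panel <- function(genome, scheme, panel, size_tolerance = 0.10,
                      max_mismatch = 0L, exact_3prime = 3L,
                      max_len = 5000L) {
  stopifnot(inherits(scheme, "rgp_scheme"))
  stopifnot(size_tolerance > 0, size_tolerance <= 0.5)
  panel <- match.arg(panel, c("classification", "multiplex1", "multiplex2"))
  contigs <- .as_contigs(genome)
  pairs <- .panel_pairs(scheme, panel)
  control <- .panel_control(scheme, panel)

  per_pair <- vector("list", nrow(pairs))
  names(per_pair) <- pairs$name
  summ <- data.frame(pair = pairs$name, expected = pairs$amplicon,
                     n_hits = 0L, n_concordant = 0L, amplified = FALSE,
                     ambiguous = FALSE, best_length = NA_integer_)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    hits <- do.call(rbind, lapply(names(contigs), function(ctg) {
      predict_amplicons(contigs[[ctg]], p, max_mismatch = max_mismatch,
                        exact_3prime = exact_3prime, max_len = max_len,
                        contig = ctg)
    }))
    dev <- abs(hits$length - p$amplicon)
    conc <- dev <= size_tolerance * p$amplicon
    per_pair[[i]] <- cbind(hits, size_concordant = conc)
    summ$n_hits[i] <- nrow(hits)
    summ$n_concordant[i] <- sum(conc)
    summ$amplified[i] <- any(conc)
    summ$ambiguous[i] <- sum(conc) > 1L
    if (any(conc)) summ$best_length[i] <- hits$length[conc][
      which.min(dev[conc])]
  }
  structure(
    list(panel = panel, per_pair = per_pair, summary = summ,
         control_pair = control,
         control_ok = summ$amplified[summ$pair == control]),
    class = "rgp_panel_result"
  )
}

#' @export
print.rgp_panel_result <- function(x, ...) {
  cat(sprintf("In-silico PCR panel %s (control %s: %s)\n", x$panel,
              x$control_pair, if (x$control_ok) "ok" else "FAILED"))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write amplicon hits to TSV or JSON
#'
#' @param result An \code{rgp_panel_result}.
#' @param path Output path; format chosen by extension (\code{.json} vs TSV).
#' @return \code{path}, invisibly.
#' @export
write_amplicons <- function(result, path) {
  stopifnot(inherits(result, "rgp_panel_result"))
  hits <- do.call(rbind, result$per_pair)
  rownames(hits) <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(panel = result$panel,
                              control_ok = isTRUE(result$control_ok),
                              hits = hits),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(hits, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
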