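# Independent brute-force oracles used to cross-check the scanning and
# pairing logic. These deliberately use a different mechanism from the
# implementation: per-character IUPAC expansion sets and explicit
# sliding-window loops.

IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"), V = c("A", "C", "G"),
  H = c("A", "C", "T"), D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

iupac_compatible <- function(x, y) {
  length(intersect(IUPAC_EXPAND[[x]], IUPAC_EXPAND[[y]])) > 0L
}

# Character-indexed compatibility table derived from the expansion sets.
IUPAC_COMPAT <- {
  codes <- names(IUPAC_EXPAND)
  m <- matrix(FALSE, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (x in codes) for (y in codes) m[x, y] <- iupac_compatible(x, y)
  m
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A",
            M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
            V = "B", H = "D", D = "H", B = "V", N = "N")
  paste(rev(comp[strsplit(toupper(s), "", fixed = TRUE)[[1L]]]),
        collapse = "")
}

# All binding sites of a primer on both strands by exhaustive window scan.
oracle_sites <- function(seq, primer, max_mismatch = 0L, exact_3prime = 3L) {
  schars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  out <- list()
  for (strand in c("+", "-")) {
    p <- if (strand == "+") primer else oracle_revcomp(primer)
    pchars <- strsplit(toupper(p), "", fixed = TRUE)[[1L]]
    L <- length(pchars)
    n <- length(schars) - L + 1L
    if (n < 1L) next
    k <- min(exact_3prime, L)
    clamp <- if (k == 0L) integer(0)
             else if (strand == "+") (L - k + 1L):L else seq_len(k)
    for (i in seq_len(n)) {
      miss <- !IUPAC_COMPAT[cbind(schars[i:(i + L - 1L)], pchars)]
      if (sum(miss) <= max_mismatch && !any(miss[clamp])) {
        out[[length(out) + 1L]] <- data.frame(
          start = i, end = i + L - 1L, strand = strand,
          mismatches = sum(miss))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  out <- do.call(rbind, out)
  out[order(out$start, out$strand), ]
}

# All convergent amplicons by exhaustive pairing of oracle sites.
oracle_amplicons <- function(seq, fwd, rev, max_mismatch = 0L,
                             exact_3prime = 3L, min_len = NULL,
                             max_len = 5000L) {
  if (is.null(min_len)) min_len <- nchar(fwd) + nchar(rev)
  fs <- oracle_sites(seq, fwd, max_mismatch, exact_3prime)
  rs <- oracle_sites(seq, rev, max_mismatch, exact_3prime)
  out <- list()
  for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs))) {
    f <- fs[i, ]; r <- rs[j, ]
    if (f$strand == r$strand) next
    left <- if (f$strand == "+") f else r
    right <- if (f$strand == "+") r else f
    if (right$start <= left$end) next
    len <- right$end - left$start + 1L
    if (len < max(min_len, nchar(fwd) + nchar(rev)) || len > max_len) next
    out[[length(out) + 1L]] <- data.frame(
      start = left$start, end = right$end, length = len,
      fwd_mismatches = f$mismatches, rev_mismatches = r$mismatches)
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), fwd_mismatches = integer(0),
                      rev_mismatches = integer(0)))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$start, out$end), ]
  rownames(out) <- NULL
  out
}

random_dna <- function(n, gc = 0.39) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n,
               replace = TRUE), collapse = "")
}

# Mutate a DNA string at `k` random positions (to plant imperfect sites).
mutate_dna <- function(s, k) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  pos <- sample(seq_along(chars), k)
  for (i in pos) chars[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                            chars[i]), 1L)
  paste(chars, collapse = "")
}

# Plant a convergent primer-site pair in filler so the inclusive span is
# `amplicon` bp; returns the assembled sequence.
plant_pair <- function(fwd, rev, amplicon, before = 300L, after = 300L) {
  fill <- amplicon - nchar(fwd) - nchar(rev)
  paste0(random_dna(before), fwd, random_dna(fill), oracle_revcomp(rev),
         random_dna(after))
}
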