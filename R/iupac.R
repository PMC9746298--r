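#' @importFrom methods is
NULL

# 4-bit encoding of the IUPAC DNA alphabet: A=1, C=2, G=4, T=8, ambiguity
# codes are unions. Two bases are compatible iff their bit sets intersect.
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

# Encode a DNA string as an integer vector of IUPAC bit codes.
# Errors on any character outside the IUPAC alphabet.
.encode_dna <- function(x, what = "sequence") {
  chars <- strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1L]]
  bits <- .IUPAC_BITS[chars]
  if (anyNA(bits)) {
    bad <- unique(chars[is.na(bits)])
    stop("non-IUPAC character(s) in ", what, ": ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  unname(bits)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Coerce genome input (file path, character vector, DNAString(Set)) to a
# named character vector of contig sequences.
.as_contigs <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    if (is.null(names(out))) names(out) <- paste0("contig", seq_along(out))
    return(out)
  }
  if (is(genome, "DNAString")) {
    return(c(contig1 = as.character(genome)))
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTUMRWSYKVHDBN]+$", toupper(genome))) {
    seqs <- Biostrings::readDNAStringSet(genome)
    out <- as.character(seqs)
    # FASTA headers may carry descriptions; keep the first word as the id
    names(out) <- sub("\\s.*$", "", names(seqs))
    return(out)
  }
  out <- as.character(genome)
  if (is.null(names(out))) {
    names(out) <- if (length(out) == 1L) "contig1" else
      paste0("contig", seq_along(out))
  }
  out
}

# Scoped RNG: run code under a fixed seed without disturbing the caller's
# random stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
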