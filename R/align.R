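# Local protein alignment shared by anchor location and family clustering.

.AA_OK <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"

.check_protein <- function(x, what = "protein") {
  x <- toupper(as.character(x))
  if (!nzchar(x)) stop(what, " is empty", call. = FALSE)
  if (!grepl(.AA_OK, x)) {
    stop("non-amino-acid character in ", what, call. = FALSE)
  }
  x
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Pairwise protein similarity under the bidirectional 50/50 criterion
#'
#' Aligns two protein sequences locally (BLOSUM62, affine gaps, open 11 /
#' extend 1) and reports percent identity over the alignment columns and the
#' fraction of each sequence covered by the aligned region. The
#' \code{bidirectional_pass} flag applies the gene-family acceptance
#' criterion: identity at least \code{min_id} percent and, by default,
#' coverage of \emph{both} sequences at least \code{min_cov} percent
#' (\code{both_coverage = FALSE} relaxes this to the query \code{a} only).
#'
#' @param a,b Protein sequences (character strings).
#' @param min_id,min_cov Acceptance thresholds in percent (default 50/50).
#' @param both_coverage Require the coverage threshold on both sequences?
#' @return A one-row data frame: \code{identity}, \code{coverage_a},
#'   \code{coverage_b}, \code{score}, \code{bidirectional_pass}.
#' @export
pairwise_similarity <- function(a, b, min_id = 50, min_cov = 50,
                                both_coverage = TRUE) {
  a <- .check_protein(a, "protein a")
  b <- .check_protein(b, "protein b")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = .blosum62(),
    gapOpening = 11, gapExtension = 1)
  cols <- Biostrings::nchar(aln)
  identity <- if (cols > 0L) 100 * Biostrings::nmatch(aln) / cols else 0
  cov_a <- 100 * (BiocGenerics::end(Biostrings::pattern(aln)) -
                  BiocGenerics::start(Biostrings::pattern(aln)) + 1L) /
           nchar(a)
  cov_b <- 100 * (BiocGenerics::end(Biostrings::subject(aln)) -
                  BiocGenerics::start(Biostrings::subject(aln)) + 1L) /
           nchar(b)
  if (cols == 0L) cov_a <- cov_b <- 0
  pass <- identity >= min_id && cov_a >= min_cov &&
    (!both_coverage || cov_b >= min_cov)
  data.frame(identity = identity, coverage_a = cov_a, coverage_b = cov_b,
             score = Biostrings::score(aln), bidirectional_pass = pass)
}
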