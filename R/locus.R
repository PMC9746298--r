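#' Read gene annotations for a genome
#'
#' Loads CDS features from a GFF3 file and attaches protein sequences,
#' either from a supplied protein FASTA (matched by feature ID) or by
#' translating the coding sequence from the genome. Optional GFF attributes
#' \code{product}, \code{region} and \code{family} are carried through when
#' present (the fixture generator writes all three).
#'
#' @param gff Path to a GFF3 annotation file.
#' @param genome FASTA path, named character vector, or \code{DNAStringSet};
#'   required when \code{proteins} is not supplied.
#' @param proteins Optional \code{AAStringSet} or protein FASTA path with
#'   names matching the GFF feature IDs.
#' @return A data frame of gene records: \code{id}, \code{contig},
#'   \code{start}, \code{end} (1-based inclusive), \code{strand},
#'   \code{protein}, plus \code{product}/\code{region}/\code{family} when
#'   annotated.
#' @export
read_annotation <- function(gff, genome = NULL, proteins = NULL) {
  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (!length(gr)) stop("no CDS features in ", gff, call. = FALSE)
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    stop("CDS features must carry an ID attribute", call. = FALSE)
  }
  out <- data.frame(
    id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  for (extra in c("product", "region", "family")) {
    v <- S4Vectors::mcols(gr)[[extra]]
    if (!is.null(v)) out[[extra]] <- as.character(v)
  }
  if (!is.null(proteins)) {
    if (is.character(proteins) && length(proteins) == 1L) {
      proteins <- Biostrings::readAAStringSet(proteins)
      names(proteins) <- sub("\\s.*$", "", names(proteins))
    }
    prot <- as.character(proteins)[out$id]
    if (anyNA(prot)) {
      stop("protein FASTA is missing sequence(s) for: ",
           paste(out$id[is.na(prot)], collapse = ", "), call. = FALSE)
    }
    out$protein <- unname(prot)
  } else {
    if (is.null(genome)) {
      stop("either `genome` or `proteins` must be supplied", call. = FALSE)
    }
    contigs <- .as_contigs(genome)
    out$protein <- vapply(seq_len(nrow(out)), function(i) {
      ctg <- contigs[[out$contig[i]]]
      if (is.null(ctg)) stop("contig not in genome: ", out$contig[i],
                             call. = FALSE)
      cds <- substr(ctg, out$start[i], out$end[i])
      if (out$strand[i] == "-") cds <- .revcomp(cds)
      p <- as.character(Biostrings::translate(
        Biostrings::DNAString(cds), if.fuzzy.codon = "X"))
      sub("\\*$", "", p)
    }, character(1))
  }
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Naive ORF finder for unannotated assemblies
#'
#' Fallback annotation when no GFF3 is available: ATG-initiated open reading
#' frames of at least \code{min_aa} codons under the standard genetic code,
#' on both strands, trimmed to the outermost start per stop-bounded frame.
#' Results are lower-confidence than a real annotation and flagged as such.
#'
#' @param genome FASTA path, named character vector, or \code{DNAStringSet}.
#' @param min_aa Minimum protein length in amino acids (default 100).
#' @return A gene-record data frame as in [read_annotation()], with
#'   \code{product = "predicted ORF (naive finder)"}.
#' @export
find_orfs <- function(genome, min_aa = 100L) {
  contigs <- .as_contigs(genome)
  recs <- list()
  for (ctg in names(contigs)) {
    s <- toupper(contigs[[ctg]])
    n <- nchar(s)
    for (str in c("+", "-")) {
      dna <- if (str == "+") s else .revcomp(s)
      for (frame in 0:2) {
        sub <- substr(dna, frame + 1L, n)
        len <- (nchar(sub) %/% 3L) * 3L
        if (len < 3L) next
        aa <- as.character(Biostrings::translate(
          Biostrings::DNAString(substr(sub, 1L, len)),
          if.fuzzy.codon = "X"))
        # M...* stretches of at least min_aa codons (incl. M, excl. stop)
        m <- gregexpr(sprintf("M[^*]{%d,}(?=\\*|$)", min_aa - 1L), aa,
                      perl = TRUE)[[1L]]
        if (m[1L] == -1L) next
        for (k in seq_along(m)) {
          aa_start <- m[k]
          aa_len <- attr(m, "match.length")[k]
          nt_start <- frame + (aa_start - 1L) * 3L + 1L  # on `dna`
          nt_end <- nt_start + aa_len * 3L - 1L
          if (str == "+") {
            gs <- nt_start; ge <- nt_end
          } else {
            gs <- n - nt_end + 1L; ge <- n - nt_start + 1L
          }
          recs[[length(recs) + 1L]] <- data.frame(
            id = sprintf("%s_orf%05d", ctg, length(recs) + 1L),
            contig = ctg, start = gs, end = ge, strand = str,
            product = "predicted ORF (naive finder)",
            protein = substr(aa, aa_start, aa_start + aa_len - 1L),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(recs)) {
    return(data.frame(id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), product = character(0),
                      protein = character(0)))
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  out$id <- sprintf("%s_orf%05d", out$contig, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Locate an anchor gene in a proteome
#'
#' Finds the gene whose protein best matches an anchor query under local
#' alignment, requiring identity and coverage (both sequences) at or above
#' the given thresholds -- the same 50/50 contract used for gene families.
#' Ties in alignment score break deterministically towards the smaller
#' genomic coordinate.
#'
#' @param genes Gene-record data frame (see [read_annotation()]).
#' @param anchor_query Anchor protein sequence (character string).
#' @param min_id,min_cov Acceptance thresholds in percent (default 50/50).
#' @return The single best-matching gene record (one-row data frame) with
#'   extra columns \code{anchor_identity}, \code{anchor_coverage}.
#' @export
locate_anchor <- function(genes, anchor_query, min_id = 50, min_cov = 50) {
  stopifnot(is.data.frame(genes), nrow(genes) > 0L)
  anchor_query <- .check_protein(anchor_query, "anchor query")
  hits <- lapply(seq_len(nrow(genes)), function(i) {
    pairwise_similarity(anchor_query, genes$protein[i],
                        min_id = min_id, min_cov = min_cov)
  })
  hits <- do.call(rbind, hits)
  ok <- which(hits$bidirectional_pass)
  if (!length(ok)) {
    stop(structure(
      class = c("rgp_anchor_not_found", "error", "condition"),
      list(message = "anchor not found: no gene meets the identity/coverage thresholds",
           call = NULL)))
  }
  best <- ok[order(-hits$score[ok], genes$start[ok])][1L]
  out <- genes[best, , drop = FALSE]
  out$anchor_identity <- hits$identity[best]
  out$anchor_coverage <- pmin(hits$coverage_a[best], hits$coverage_b[best])
  rownames(out) <- NULL
  out
}

#' Extract the rgp locus between its two anchor genes
#'
#' Locates the two flanking anchors (the 30S ribosomal-protein gene on the
#' variable 5' side and the predicted transcriptional regulator on the
#' backbone 3' side) and returns the genes strictly between them, ordered so
#' that the variable region precedes the backbone region. When the locus
#' lies on the reverse strand of the assembly the gene order and strands are
#' normalized to this left-to-right convention.
#'
#' @param genome FASTA path, named character vector, or \code{DNAStringSet}.
#' @param annotation Path to a GFF3 file, or a gene-record data frame from
#'   [read_annotation()] / [find_orfs()].
#' @param anchors List with protein queries \code{five_prime} (30S side) and
#'   \code{three_prime} (regulator side); see [rgp_anchor_queries()] for the
#'   queries matching the packaged fixtures.
#' @param proteins Optional protein FASTA/\code{AAStringSet} forwarded to
#'   [read_annotation()].
#' @param min_id,min_cov Anchor acceptance thresholds (default 50/50).
#' @param strain Optional strain identifier carried into the locus object.
#' @return An object of class \code{rgp_locus}: list with \code{strain},
#'   \code{contig}, \code{genes} (ordered gene records, anchors excluded),
#'   \code{span} (locus coordinates including anchors) and
#'   \code{orientation_normalized}.
#' @export
extract_locus <- function(genome, annotation, anchors, proteins = NULL,
                          min_id = 50, min_cov = 50,
                          strain = NA_character_) {
  genes <- if (is.data.frame(annotation)) annotation
           else read_annotation(annotation, genome = genome,
                                proteins = proteins)
  a5 <- locate_anchor(genes, anchors$five_prime, min_id, min_cov)
  a3 <- locate_anchor(genes, anchors$three_prime, min_id, min_cov)
  if (a5$contig != a3$contig) {
    stop(structure(
      class = c("rgp_split_locus", "error", "condition"),
      list(message = sprintf(
        "anchors found on different contigs (%s vs %s): locus split or misassembled",
        a5$contig, a3$contig), call = NULL)))
  }
  lo <- min(a5$end, a3$end)
  hi <- max(a5$start, a3$start)
  inside <- genes$contig == a5$contig & genes$start > lo & genes$end < hi
  body <- genes[inside, , drop = FALSE]
  flipped <- a5$start > a3$start
  if (flipped) {
    body <- body[order(-body$start), , drop = FALSE]
    body$strand <- chartr("+-", "-+", body$strand)
  } else {
    body <- body[order(body$start), , drop = FALSE]
  }
  rownames(body) <- NULL
  structure(
    list(strain = strain, contig = a5$contig, genes = body,
         span = c(start = min(a5$start, a3$start),
                  end = max(a5$end, a3$end)),
         orientation_normalized = flipped,
         anchors = rbind(a5, a3)),
    class = "rgp_locus"
  )
}

#' @export
print.rgp_locus <- function(x, ...) {
  cat(sprintf(
    "rgp locus%s on %s: %d genes between anchors [%d-%d]%s\n",
    if (is.na(x$strain)) "" else paste0(" [", x$strain, "]"),
    x$contig, nrow(x$genes), x$span["start"], x$span["end"],
    if (x$orientation_normalized) " (orientation normalized)" else ""))
  invisible(x)
}

#' Write locus products to disk
#'
#' Emits the locus gene table (TSV), the protein sequences (FASTA) and the
#' locus nucleotide span (FASTA) for downstream comparison.
#'
#' @param locus An \code{rgp_locus}.
#' @param genome The genome the locus was extracted from (for the
#'   nucleotide span); may be \code{NULL} to skip the locus FASTA.
#' @param prefix Output path prefix; files get suffixes
#'   \code{_genes.tsv}, \code{_proteins.faa}, \code{_locus.fna}.
#' @return Character vector of written paths, invisibly.
#' @export
write_locus <- function(locus, prefix, genome = NULL) {
  stopifnot(inherits(locus, "rgp_locus"))
  paths <- character(0)
  tsv <- paste0(prefix, "_genes.tsv")
  utils::write.table(locus$genes, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, tsv)
  aa <- Biostrings::AAStringSet(stats::setNames(locus$genes$protein,
                                                locus$genes$id))
  faa <- paste0(prefix, "_proteins.faa")
  Biostrings::writeXStringSet(aa, faa)
  paths <- c(paths, faa)
  if (!is.null(genome)) {
    contigs <- .as_contigs(genome)
    span <- substr(contigs[[locus$contig]], locus$span["start"],
                   locus$span["end"])
    fna <- paste0(prefix, "_locus.fna")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(span, "rgp_locus")), fna)
    paths <- c(paths, fna)
  }
  invisible(paths)
}
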