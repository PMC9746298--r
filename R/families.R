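#' Build gene families from per-locus protein sets
#'
#' All-vs-all local alignment of the input proteins, keeping edges that pass
#' the bidirectional 50/50 criterion (identity >= \code{min_id} percent over
#' at least \code{min_cov} percent of both sequences), then grouping the
#' similarity graph into families either as connected components (default)
#' or by Markov clustering (MCL). Proteins are sorted canonically by name
#' before clustering so the partition is invariant to input order.
#'
#' With \code{prefilter = TRUE} (default) a pair is aligned only when the
#' two sequences share at least one amino-acid 8-mer and their length ratio
#' does not already rule out the coverage threshold; both conditions are
#' implied by any edge that could pass 50/50 on realistic sequences, and the
#' filter can be disabled for exhaustive comparison.
#'
#' @param proteins Named character vector or \code{AAStringSet} of protein
#'   sequences; names are protein ids and must be unique. A list of such
#'   vectors (one per locus) is flattened.
#' @param min_id,min_cov Acceptance thresholds in percent (default 50/50).
#' @param method \code{"components"} (default) or \code{"mcl"}.
#' @param inflation MCL inflation parameter (default 2.0).
#' @param both_coverage Require coverage on both sequences (default) or the
#'   query only.
#' @param prefilter Skip alignment of pairs that cannot plausibly pass.
#' @return An object of class \code{rgp_family_set}: list with
#'   \code{families} (named list of protein-id vectors, labelled
#'   \code{F001}, \code{F002}, ... in order of first member),
#'   \code{membership} (named character vector protein id -> family label)
#'   and \code{edges} (data frame of passing similarity edges).
#' @export
build_families <- function(proteins, min_id = 50, min_cov = 50,
                           method = c("components", "mcl"),
                           inflation = 2.0, both_coverage = TRUE,
                           prefilter = TRUE) {
  method <- match.arg(method)
  prot <- .as_protein_vector(proteins)
  if (!length(prot)) stop("no proteins supplied", call. = FALSE)
  prot <- prot[order(names(prot))]
  ids <- names(prot)
  n <- length(prot)

  kmers <- if (prefilter && n > 1L) lapply(prot, .aa_kmers, k = 8L) else NULL
  lens <- nchar(prot)
  edges <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (prefilter) {
          # the shorter sequence bounds the longer one's coverage
          if (both_coverage &&
              100 * min(lens[i], lens[j]) / max(lens[i], lens[j]) <
                min_cov) next
          if (!any(kmers[[i]] %in% kmers[[j]])) next
        }
        sim <- pairwise_similarity(prot[[i]], prot[[j]], min_id = min_id,
                                   min_cov = min_cov,
                                   both_coverage = both_coverage)
        if (sim$bidirectional_pass) {
          edges[[length(edges) + 1L]] <-
            cbind(a = ids[i], b = ids[j], sim)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(0), b = character(0), identity = numeric(0),
               coverage_a = numeric(0), coverage_b = numeric(0),
               score = numeric(0), bidirectional_pass = logical(0))

  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = ids))
  member <- if (method == "components") {
    igraph::components(g)$membership
  } else {
    .mcl_membership(g, inflation = inflation)
  }
  member <- member[ids]

  first_seen <- !duplicated(member)
  relabel <- stats::setNames(seq_len(sum(first_seen)), member[first_seen])
  member <- relabel[as.character(member)]
  labels <- sprintf("F%03d", member)
  families <- split(ids, labels)
  structure(
    list(families = families,
         membership = stats::setNames(labels, ids),
         edges = edges,
         params = list(min_id = min_id, min_cov = min_cov, method = method,
                       inflation = inflation,
                       both_coverage = both_coverage)),
    class = "rgp_family_set"
  )
}

.as_protein_vector <- function(proteins) {
  if (is.list(proteins) && !is.data.frame(proteins)) {
    # unname the outer list so per-locus names are not prefixed
    proteins <- unlist(unname(lapply(proteins, function(x)
      if (is(x, "AAStringSet")) as.character(x) else x)))
  }
  if (is(proteins, "AAStringSet")) proteins <- as.character(proteins)
  nm <- names(proteins)
  proteins <- vapply(unname(proteins), .check_protein, character(1),
                     USE.NAMES = FALSE)
  names(proteins) <- nm
  if (is.null(names(proteins)) || anyDuplicated(names(proteins)) ||
      any(!nzchar(names(proteins)))) {
    stop("proteins must carry unique non-empty names", call. = FALSE)
  }
  proteins
}

.aa_kmers <- function(x, k = 8L) {
  n <- nchar(x)
  if (n < k) return(x)
  unique(substring(x, 1:(n - k + 1L), k:n))
}

# Native Markov clustering on the similarity graph: column-stochastic
# adjacency (with self loops), iterated expansion (power 2) and inflation
# until convergence; clusters are read off the rows of the limit matrix.
.mcl_membership <- function(g, inflation = 2.0, max_iter = 200L,
                            tol = 1e-8) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  ids <- rownames(A)
  diag(A) <- 1
  M <- sweep(A, 2L, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M              # expansion
    M2 <- M2^inflation         # inflation
    M2 <- sweep(M2, 2L, colSums(M2), "/")
    M2[M2 < 1e-12] <- 0
    M2 <- sweep(M2, 2L, colSums(M2), "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  attract <- which(rowSums(M > 1e-6) > 0)
  member <- integer(ncol(M))
  names(member) <- ids
  cluster_of <- rep(NA_integer_, length(ids))
  next_id <- 0L
  for (r in attract) {
    cols <- which(M[r, ] > 1e-6)
    existing <- unique(stats::na.omit(cluster_of[cols]))
    if (length(existing)) {
      cl <- existing[1L]
      if (length(existing) > 1L) {
        cluster_of[cluster_of %in% existing] <- cl
      }
    } else {
      next_id <- next_id + 1L
      cl <- next_id
    }
    cluster_of[cols] <- cl
  }
  # isolated / never-attracted nodes become singletons
  for (i in which(is.na(cluster_of))) {
    next_id <- next_id + 1L
    cluster_of[i] <- next_id
  }
  stats::setNames(cluster_of, ids)
}

#' @export
print.rgp_family_set <- function(x, ...) {
  sizes <- lengths(x$families)
  cat(sprintf(
    "Gene family set: %d proteins in %d families (%s; id>=%g%%, cov>=%g%%)\n",
    length(x$membership), length(x$families), x$params$method,
    x$params$min_id, x$params$min_cov))
  cat("  family sizes:", paste(sort(unique(sizes)), collapse = " "), "\n")
  invisible(x)
}

#' Gene-family presence/absence matrix across loci
#'
#' @param fams An \code{rgp_family_set} built from the proteins of all loci.
#' @param loci Named list mapping locus id to the protein ids it contains
#'   (or to \code{rgp_locus} objects, whose gene ids are used).
#' @return A logical matrix, rows = loci, columns = family labels; a cell is
#'   \code{TRUE} iff the locus contributes at least one member.
#' @export
presence_absence <- function(fams, loci) {
  stopifnot(inherits(fams, "rgp_family_set"))
  ids_of <- lapply(loci, function(x) {
    if (inherits(x, "rgp_locus")) x$genes$id else as.character(x)
  })
  if (is.null(names(ids_of)) || any(!nzchar(names(ids_of)))) {
    stop("loci must be named", call. = FALSE)
  }
  all_ids <- unlist(ids_of, use.names = FALSE)
  missing <- setdiff(all_ids, names(fams$membership))
  if (length(missing)) {
    stop("protein(s) not covered by the family set: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  fam_labels <- names(fams$families)
  mat <- matrix(FALSE, nrow = length(ids_of), ncol = length(fam_labels),
                dimnames = list(names(ids_of), fam_labels))
  for (l in names(ids_of)) {
    mat[l, unique(fams$membership[ids_of[[l]]])] <- TRUE
  }
  mat
}

#' Hierarchically cluster loci by family presence/absence
#'
#' Jaccard distances between the binary family profiles (asymmetric binary
#' distance: shared absences are uninformative) with average-linkage
#' agglomeration. The dendrogram is deterministic; equal distances are
#' resolved by \code{stats::hclust}'s fixed merge order over the row order
#' of the matrix.
#'
#' @param matrix Logical/0-1 matrix from [presence_absence()] (>= 2 rows).
#' @param k Target number of flat clusters (optional).
#' @param h Cut height for flat clusters (optional; ignored when \code{k}
#'   is given).
#' @return An object of class \code{rgp_hcl}: list with \code{hclust},
#'   \code{dist} and, when a cut was requested, \code{clusters} (named
#'   integer vector).
#' @export
hcl_cluster <- function(matrix, k = NULL, h = NULL) {
  if (nrow(matrix) < 2L) {
    stop("hierarchical clustering needs at least two loci", call. = FALSE)
  }
  d <- stats::dist(matrix * 1, method = "binary")
  hc <- stats::hclust(d, method = "average")
  clusters <- NULL
  if (!is.null(k)) clusters <- stats::cutree(hc, k = k)
  else if (!is.null(h)) clusters <- stats::cutree(hc, h = h)
  structure(list(hclust = hc, dist = d, clusters = clusters),
            class = "rgp_hcl")
}

#' @export
print.rgp_hcl <- function(x, ...) {
  cat(sprintf("Locus HCL: %d loci (Jaccard distance, average linkage)\n",
              length(x$hclust$labels)))
  if (!is.null(x$clusters)) {
    cat("  flat clusters:", max(x$clusters), "\n")
  }
  invisible(x)
}

#' Export an HCL dendrogram as Newick
#'
#' @param hcl An \code{rgp_hcl} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(hcl, path) {
  stopifnot(inherits(hcl, "rgp_hcl"))
  phy <- ape::as.phylo(hcl$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write family assignments and presence/absence matrix to TSV
#'
#' @param fams An \code{rgp_family_set}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_families <- function(fams, path) {
  stopifnot(inherits(fams, "rgp_family_set"))
  df <- data.frame(protein = names(fams$membership),
                   family = unname(fams$membership))
  utils::write.table(df[order(df$family, df$protein), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
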