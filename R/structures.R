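# Curated knowledge base linking each Rgp genotype to its known or
# predicted chemical architecture: rhamnan backbone repeat, decorative side
# chain, branch residue and attachment. Entries for groups 2, 3 and 4 come
# from NMR-elucidated structures of strains UCCSt95, UCCSt89 and UCCSt12;
# group 1 (UCCSt50) and group 6 (St64987) were elucidated previously; group
# 7 is a sequence-based prediction (a UDP-galactopyranose mutase gene in the
# variable region implies a Galf residue); groups 2A and 5 are unknown.

.residue <- function(linkage, anomer, mono) {
  data.frame(linkage = linkage, anomer = anomer, monosaccharide = mono,
             stringsAsFactors = FALSE)
}

.kb_entry <- function(group, backbone_repeat = NULL,
                      backbone_contains_glc = FALSE, side_chain = NULL,
                      side_chain_size = NA_integer_,
                      side_chain_branched = NA,
                      side_chain_contains_galf = FALSE,
                      branch_residue = NA_character_,
                      attachment = NA_character_,
                      confidence, source_strain = NA_character_,
                      notes = NA_character_) {
  structure(list(group = group, backbone_repeat = backbone_repeat,
                 backbone_contains_glc = backbone_contains_glc,
                 side_chain = side_chain,
                 side_chain_size = side_chain_size,
                 side_chain_branched = side_chain_branched,
                 side_chain_contains_galf = side_chain_contains_galf,
                 branch_residue = branch_residue, attachment = attachment,
                 confidence = confidence, source_strain = source_strain,
                 notes = notes),
            class = "rgp_structure")
}

.DISACCH_BACKBONE <- rbind(.residue(2L, "\u03b1", "Rha"),
                           .residue(3L, "\u03b1", "Rha"))
.TRISACCH_BACKBONE <- rbind(.residue(3L, "\u03b1", "Rha"),
                            .residue(2L, "\u03b1", "Rha"),
                            .residue(2L, "\u03b1", "Rha"))
.GAL_GALNAC_SIDE <- rbind(.residue(NA_integer_, "\u03b2", "Gal"),
                          .residue(3L, "\u03b2", "GalNAc"))

.rgp_kb <- list(
  "1" = .kb_entry("1",
    backbone_contains_glc = TRUE,
    side_chain_size = 4L, side_chain_branched = TRUE,
    branch_residue = "GlcNAc",
    attachment = "rhamnan backbone (glucosylated)",
    confidence = "elucidated", source_strain = "UCCSt50",
    notes = "branched tetrasaccharide side chain; full linkages reported with the UCCSt50 structure"),
  "2" = .kb_entry("2",
    backbone_repeat = .DISACCH_BACKBONE,
    side_chain_size = 4L, side_chain_branched = TRUE,
    branch_residue = "GlcNAc",
    attachment = "position 4 of residue A (-2-\u03b1-Rha-)",
    confidence = "elucidated", source_strain = "UCCSt95",
    notes = "side chain identical to the UCCSt50 (group 1) tetrasaccharide; exact linkages in the source supplement"),
  "2A" = .kb_entry("2A", confidence = "unknown",
    notes = "subgroup of group 2 lacking a GT family 2 gene and a DUF2142 gene; structure not yet determined"),
  "3" = .kb_entry("3",
    backbone_repeat = .DISACCH_BACKBONE,
    side_chain = .GAL_GALNAC_SIDE,
    side_chain_size = 2L, side_chain_branched = FALSE,
    branch_residue = "GalNAc",
    attachment = "position 2 of residue B (-3-\u03b1-Rha-)",
    confidence = "elucidated", source_strain = "UCCSt89",
    notes = "an additional neutral polysaccharide (EPS, heptasaccharide repeat) is present in this strain"),
  "4" = .kb_entry("4",
    backbone_repeat = .TRISACCH_BACKBONE,
    side_chain = .GAL_GALNAC_SIDE,
    side_chain_size = 2L, side_chain_branched = FALSE,
    branch_residue = "GalNAc",
    attachment = "variable: either of the two -2-\u03b1-Rha- residues",
    confidence = "elucidated", source_strain = "UCCSt12",
    notes = "a putative additional EPS was detected in this strain"),
  "5" = .kb_entry("5", confidence = "unknown",
    notes = "variable region minimal, no side-chain glycosyltransferases; two oligosaccharyltransferase-like membrane proteins downstream of rgpF"),
  "6" = .kb_entry("6",
    backbone_contains_glc = TRUE,
    branch_residue = "GlcNAc",
    attachment = "rhamnan backbone (glucosylated)",
    confidence = "elucidated", source_strain = "St64987",
    notes = "an additional EPS has been described for this strain"),
  "7" = .kb_entry("7",
    side_chain_size = 4L, side_chain_branched = TRUE,
    side_chain_contains_galf = TRUE,
    branch_residue = "GlcNAc",
    attachment = "rhamnan backbone",
    confidence = "predicted", source_strain = "CNRZ302",
    notes = "prediction from gene content: UDP-galactopyranose mutase implies a Galf residue in the side chain; backbone region highly similar to group 1")
)

#' The Rgp structure knowledge base
#'
#' @return Named list of \code{rgp_structure} models, one per Rgp group
#'   (\code{"1"}, \code{"2"}, \code{"2A"}, \code{"3"}, \code{"4"},
#'   \code{"5"}, \code{"6"}, \code{"7"}).
#' @export
rgp_structure_kb <- function() .rgp_kb

#' Predicted Rgp chemical architecture for a genotype
#'
#' Looks up the knowledge-base model for a concrete Rgp group:
#' backbone repeat unit (for groups 2 and 3 a
#' \code{-2-}\eqn{\alpha}\code{-Rha-3-}\eqn{\alpha}\code{-Rha-}
#' disaccharide, for group 4 a
#' \code{-3-}\eqn{\alpha}\code{-Rha-2-}\eqn{\alpha}\code{-Rha-2-}\eqn{\alpha}\code{-Rha-}
#' trisaccharide), side chain (branched tetrasaccharide with GlcNAc at the
#' branch for groups 1/2; \eqn{\beta}-Gal-3-\eqn{\beta}-GalNAc with GalNAc
#' at the branch for groups 3/4), attachment position, and confidence
#' provenance (\code{elucidated} for groups 1, 2, 3, 4, 6;
#' \code{predicted} for group 7; \code{unknown} for groups 2A and 5).
#'
#' @param group An Rgp group label (character, e.g. \code{"4"} or
#'   \code{"2A"}).
#' @return An \code{rgp_structure} model.
#' @export
predict_structure <- function(group) {
  group <- as.character(group)
  m <- .rgp_kb[[group]]
  if (is.null(m)) {
    stop("unknown Rgp group: ", sQuote(group), call. = FALSE)
  }
  m
}

#' Render a backbone repeat unit as a linear glycan string
#'
#' Compact linear notation with explicit anomers and linkage positions,
#' e.g. \code{"-2-\u03b1-Rha-3-\u03b1-Rha-"}.
#'
#' @param residues Residue data frame (\code{linkage}, \code{anomer},
#'   \code{monosaccharide}) as stored in the knowledge base.
#' @return A single character string.
#' @export
render_backbone <- function(residues) {
  stopifnot(is.data.frame(residues), nrow(residues) > 0L)
  paste0(paste0("-", residues$linkage, "-", residues$anomer, "-",
                residues$monosaccharide, collapse = ""), "-")
}

#' Parse a linear backbone glycan string
#'
#' Inverse of [render_backbone()]; round-trips the knowledge-base repeat
#' units.
#'
#' @param x A backbone string such as \code{"-2-\u03b1-Rha-3-\u03b1-Rha-"}.
#' @return A residue data frame.
#' @export
parse_backbone <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  body <- sub("^-", "", sub("-$", "", x))
  parts <- strsplit(body, "-", fixed = TRUE)[[1L]]
  if (length(parts) %% 3L != 0L || !length(parts)) {
    stop("malformed backbone string: ", sQuote(x), call. = FALSE)
  }
  idx <- seq(1L, length(parts), by = 3L)
  out <- data.frame(linkage = as.integer(parts[idx]),
                    anomer = parts[idx + 1L],
                    monosaccharide = parts[idx + 2L],
                    stringsAsFactors = FALSE)
  if (anyNA(out$linkage) ||
      !all(out$monosaccharide %in% c("Rha", "Glc", "Gal", "Galf",
                                     "GlcNAc", "GalNAc"))) {
    stop("malformed backbone string: ", sQuote(x), call. = FALSE)
  }
  out
}

#' Render a side chain as a linear glycan string
#'
#' @param residues Side-chain residue data frame; the first residue's
#'   linkage is the (unspecified) attachment to the next residue and is
#'   omitted.
#' @return A character string such as \code{"\u03b2-Gal-3-\u03b2-GalNAc"}.
#' @export
render_side_chain <- function(residues) {
  stopifnot(is.data.frame(residues), nrow(residues) > 0L)
  parts <- character(0)
  for (i in seq_len(nrow(residues))) {
    r <- residues[i, ]
    prefix <- if (i == 1L || is.na(r$linkage)) "" else paste0(r$linkage, "-")
    parts <- c(parts, paste0(prefix, r$anomer, "-", r$monosaccharide))
  }
  paste(parts, collapse = "-")
}

#' @export
print.rgp_structure <- function(x, ...) {
  cat(sprintf("Rgp group %s structure [%s%s]\n", x$group, x$confidence,
              if (is.na(x$source_strain)) "" else
                paste0(", ", x$source_strain)))
  if (!is.null(x$backbone_repeat)) {
    cat("  backbone repeat:", render_backbone(x$backbone_repeat), "\n")
  } else if (isTRUE(x$backbone_contains_glc)) {
    cat("  backbone: rhamnan with glucose\n")
  } else if (x$confidence != "unknown") {
    cat("  backbone: rhamnan\n")
  }
  if (!is.null(x$side_chain)) {
    cat("  side chain:", render_side_chain(x$side_chain), "\n")
  } else if (!is.na(x$side_chain_size)) {
    cat(sprintf("  side chain: %s %d-saccharide\n",
                if (isTRUE(x$side_chain_branched)) "branched" else "linear",
                x$side_chain_size))
  }
  if (!is.na(x$branch_residue)) {
    cat("  branch residue:", x$branch_residue, "\n")
  }
  if (!is.na(x$attachment)) cat("  attachment:", x$attachment, "\n")
  if (!is.na(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}

#' Export structure models as JSON
#'
#' @param path Output JSON path.
#' @param kb Knowledge base (default the packaged one).
#' @return \code{path}, invisibly.
#' @export
write_structure_kb <- function(path, kb = rgp_structure_kb()) {
  jsonlite::write_json(lapply(kb, unclass), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Check a locus against a structure model
#'
#' Informational consistency check of the genotype-to-structure link: the
#' number of side-chain elongating glycosyltransferases encoded in the
#' variable region should be at least the number of side-chain residues
#' minus one (the priming transferase contributes the branch residue
#' itself). Requires gene records annotated with \code{product} and
#' \code{region} columns; loci without functional annotation are skipped
#' with a warning.
#'
#' @param locus An \code{rgp_locus} (or gene-record data frame).
#' @param model An \code{rgp_structure} model.
#' @return A list report: \code{status} (\code{"consistent"},
#'   \code{"inconsistent"}, \code{"indeterminate"} or \code{"skipped"}),
#'   \code{n_variable_gt}, \code{side_chain_size} and \code{message}.
#' @export
check_consistency <- function(locus, model) {
  stopifnot(inherits(model, "rgp_structure"))
  genes <- if (inherits(locus, "rgp_locus")) locus$genes else locus
  if (!is.data.frame(genes) || !all(c("product", "region") %in%
                                    names(genes))) {
    warning("locus lacks functional annotation (product/region); ",
            "consistency check skipped")
    return(list(status = "skipped", n_variable_gt = NA_integer_,
                side_chain_size = model$side_chain_size,
                message = "no functional annotation"))
  }
  vr <- genes[genes$region == "variable", , drop = FALSE]
  n_gt <- sum(grepl("side-chain .*(glycosyl|galactosyl)transferase",
                    vr$product, ignore.case = TRUE) &
              !grepl("priming", vr$product, ignore.case = TRUE))
  size <- model$side_chain_size
  if (is.na(size)) {
    return(list(status = "indeterminate", n_variable_gt = n_gt,
                side_chain_size = size,
                message = "side-chain size unknown for this model"))
  }
  ok <- n_gt >= size - 1L
  list(status = if (ok) "consistent" else "inconsistent",
       n_variable_gt = n_gt, side_chain_size = size,
       message = sprintf(
         "%d side-chain elongating glycosyltransferase(s) in the variable region vs %d side-chain residue(s)",
         n_gt, size))
}
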