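#' Load an Rgp typing scheme
#'
#' Reads a scheme-definition file describing the primer pairs of the two-step
#' multiplex Rgp typing system of \emph{Streptococcus thermophilus} (plus the
#' legacy single-step classification panel) and the genotype maps derived from
#' them. The bundled scheme (see [rgp_scheme()]) carries 14 primer pairs: five
#' for the legacy classification panel (including its positive control
#' \code{RGPpos}), the shared multiplex control \code{MSControl}, five
#' variable-chain pairs (\code{Var1}--\code{Var5}) for multiplex panel 1 and
#' three rhamnan-backbone (\emph{rgpF}) pairs (\code{Fg1}--\code{Fg3}) for
#' multiplex panel 2.
#'
#' The file format is a flat, versioned TSV: a header line
#' \code{# rgp-scheme<TAB>version=N}, comment lines starting with \code{#},
#' a column header, and one row per record. \code{record = "pair"} rows define
#' primer pairs (name, panel, forward/reverse primer written 5'->3', expected
#' amplicon in bp, target Rgp groups, and a type label: \code{Vt*} for
#' multiplex-1 pairs, \code{Bt*} for multiplex-2 pairs, a legacy group for
#' classification pairs). \code{record = "binomial"} rows map an observed
#' variable x backbone combination (e.g. \code{V3B2}) to its Rgp group.
#'
#' @param path Path to a scheme-definition file.
#' @return An object of class \code{rgp_scheme}: a list with elements
#'   \code{pairs} (data frame of primer pairs), \code{vt_map}, \code{bt_map},
#'   \code{legacy_map} (named character vectors keyed by pair name),
#'   \code{binomial_map} (named character vector keyed by binomial name) and
#'   \code{version}.
#' @seealso [rgp_scheme()], [write_scheme()], [expected_amplicon()]
#' @export
load_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("scheme parse error: file is empty", call. = FALSE)
  header <- lines[1L]
  if (!grepl("^#\\s*rgp-scheme\\tversion=\\d+", header)) {
    stop("scheme parse error: missing '# rgp-scheme\\tversion=N' header",
         call. = FALSE)
  }
  version <- as.integer(sub("^.*version=(\\d+).*$", "\\1", header))
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 2L) {
    stop("scheme parse error: no records after header", call. = FALSE)
  }
  tab <- utils::read.delim(text = body, header = TRUE,
                           colClasses = "character", quote = "")
  needed <- c("record", "name", "panel", "forward", "reverse", "amplicon",
              "targets", "type_label")
  if (!all(needed %in% names(tab))) {
    stop("scheme parse error: missing column(s) ",
         paste(setdiff(needed, names(tab)), collapse = ", "), call. = FALSE)
  }

  pairs <- tab[tab$record == "pair", , drop = FALSE]
  binom <- tab[tab$record == "binomial", , drop = FALSE]
  unknown <- setdiff(tab$record, c("pair", "binomial"))
  if (length(unknown)) {
    stop("scheme parse error: unknown record type(s) ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }
  if (!nrow(pairs)) stop("scheme parse error: no primer pairs", call. = FALSE)
  if (anyDuplicated(pairs$name)) {
    stop("scheme validation error: duplicate pair name(s): ",
         paste(unique(pairs$name[duplicated(pairs$name)]), collapse = ", "),
         call. = FALSE)
  }

  pairs$amplicon <- as.integer(pairs$amplicon)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    for (role in c("forward", "reverse")) {
      seqc <- p[[role]]
      .encode_dna(seqc, what = sprintf("%s primer of pair %s", role, p$name))
      if (nchar(seqc) < 15L || nchar(seqc) > 30L) {
        stop("scheme validation error: ", role, " primer of pair ", p$name,
             " has length ", nchar(seqc), " (expected 15-30 nt)",
             call. = FALSE)
      }
    }
    if (is.na(p$amplicon) ||
        p$amplicon <= nchar(p$forward) + nchar(p$reverse)) {
      stop("scheme validation error: pair ", p$name,
           ": expected amplicon must exceed the summed primer lengths",
           call. = FALSE)
    }
    if (!p$panel %in% c("classification", "control", "multiplex1",
                        "multiplex2")) {
      stop("scheme validation error: pair ", p$name, ": unknown panel ",
           sQuote(p$panel), call. = FALSE)
    }
  }

  vt_map <- .type_map(pairs, "multiplex1", "^Vt[0-9]+$", "variable type")
  bt_map <- .type_map(pairs, "multiplex2", "^Bt[0-9]+$", "backbone type")
  cls <- pairs[pairs$panel == "classification" & pairs$type_label != ".", ]
  legacy_map <- stats::setNames(cls$type_label, cls$name)

  binomial_map <- character(0)
  if (nrow(binom)) {
    if (anyDuplicated(binom$name)) {
      stop("scheme validation error: duplicate binomial record(s)",
           call. = FALSE)
    }
    if (!all(grepl("^V[0-9]+B[0-9]+$", binom$name))) {
      stop("scheme parse error: malformed binomial name(s): ",
           paste(binom$name[!grepl("^V[0-9]+B[0-9]+$", binom$name)],
                 collapse = ", "), call. = FALSE)
    }
    binomial_map <- stats::setNames(binom$targets, binom$name)
  }

  scheme <- structure(
    list(pairs = pairs[, needed[-1L]], vt_map = vt_map, bt_map = bt_map,
         legacy_map = legacy_map, binomial_map = binomial_map,
         version = version),
    class = "rgp_scheme"
  )
  .validate_controls(scheme)
  scheme
}

.type_map <- function(pairs, panel, pattern, what) {
  sub <- pairs[pairs$panel == panel, , drop = FALSE]
  bad <- sub$name[!grepl(pattern, sub$type_label)]
  if (length(bad)) {
    stop("scheme validation error: ", panel, " pair(s) without a valid ",
         what, " label: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::setNames(sub$type_label, sub$name)
}

.validate_controls <- function(scheme) {
  p <- scheme$pairs
  if (sum(p$panel == "control") != 1L) {
    stop("scheme validation error: expected exactly one shared multiplex ",
         "control pair", call. = FALSE)
  }
  cls <- p[p$panel == "classification", ]
  if (sum(cls$type_label == ".") != 1L) {
    stop("scheme validation error: expected exactly one classification ",
         "control pair (no legacy group label)", call. = FALSE)
  }
  invisible(scheme)
}

#' The bundled Rgp typing scheme
#'
#' Convenience loader for the scheme definition shipped with the package,
#' covering both multiplex panels and the legacy classification panel.
#'
#' @return An \code{rgp_scheme} object (see [load_scheme()]).
#' @examples
#' sch <- rgp_scheme()
#' expected_amplicon(sch, "Var1")
#' @export
rgp_scheme <- function() {
  load_scheme(system.file("extdata", "rgp_scheme_v1.tsv",
                          package = "rgptyper", mustWork = TRUE))
}

#' Serialize a typing scheme
#'
#' Writes an \code{rgp_scheme} back to the flat scheme-definition format so
#' that [load_scheme()] reproduces an identical object.
#'
#' @param scheme An \code{rgp_scheme}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "rgp_scheme"))
  p <- scheme$pairs
  rows <- cbind(record = "pair", p)
  if (length(scheme$binomial_map)) {
    rows <- rbind(rows, data.frame(
      record = "binomial", name = names(scheme$binomial_map), panel = ".",
      forward = ".", reverse = ".", amplicon = ".",
      targets = unname(scheme$binomial_map), type_label = ".",
      stringsAsFactors = FALSE))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rgp-scheme\tversion=%d", scheme$version), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expected amplicon size of a primer pair
#'
#' @param scheme An \code{rgp_scheme}.
#' @param pair_name Name of a primer pair in the scheme (e.g. \code{"Var1"}).
#' @return Integer expected product size in bp.
#' @export
expected_amplicon <- function(scheme, pair_name) {
  stopifnot(inherits(scheme, "rgp_scheme"))
  i <- match(pair_name, scheme$pairs$name)
  if (is.na(i)) {
    stop("unknown primer pair: ", sQuote(pair_name), call. = FALSE)
  }
  scheme$pairs$amplicon[i]
}

# Pair rows evaluated for a panel: the panel's own pairs plus its control.
.panel_pairs <- function(scheme, panel) {
  panel <- match.arg(panel, c("classification", "multiplex1", "multiplex2"))
  p <- scheme$pairs
  if (panel == "classification") {
    p[p$panel == "classification", , drop = FALSE]
  } else {
    rbind(p[p$panel == panel, , drop = FALSE],
          p[p$panel == "control", , drop = FALSE])
  }
}

# Name of the control pair of a panel.
.panel_control <- function(scheme, panel) {
  p <- scheme$pairs
  if (panel == "classification") {
    p$name[p$panel == "classification" & p$type_label == "."]
  } else {
    p$name[p$panel == "control"]
  }
}

#' Rgp group of a binomial name
#'
#' Maps a binomial variable x backbone name to its Rgp group via the scheme's
#' binomial map; combinations that have not been observed (e.g. \code{V1B3})
#' resolve to \code{"novel"}.
#'
#' @param scheme An \code{rgp_scheme}.
#' @param binomial A binomial name such as \code{"V3B2"}.
#' @return A group label (\code{"1"}, \code{"2"}, \code{"2A"}, ...,
#'   or \code{"novel"}).
#' @export
binomial_group <- function(scheme, binomial) {
  stopifnot(inherits(scheme, "rgp_scheme"))
  if (!grepl("^V[0-9]+B[0-9]+$", binomial)) {
    stop("malformed binomial name: ", sQuote(binomial), call. = FALSE)
  }
  g <- scheme$binomial_map[binomial]
  if (is.na(g)) "novel" else unname(g)
}

#' @export
print.rgp_scheme <- function(x, ...) {
  cat(sprintf("Rgp typing scheme (version %d): %d primer pairs\n",
              x$version, nrow(x$pairs)))
  tb <- table(x$pairs$panel)
  cat("  panels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
      "\n")
  cat("  binomial map:", paste(names(x$binomial_map), collapse = " "), "\n")
  invisible(x)
}
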