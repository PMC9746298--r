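# Condition helper: a panel whose control did not amplify is assay-invalid
# (no call can be made, as opposed to a valid assay with no product).
.assay_invalid <- function(panel) {
  stop(structure(
    class = c("rgp_assay_invalid", "error", "condition"),
    list(message = sprintf(
      "assay invalid: control pair of panel %s did not amplify", panel),
      call = NULL)))
}

# Shared logic of the two multiplex calls: zero amplified target pairs with
# a valid control -> untypeable; more than one -> ambiguous.
.call_type <- function(result, scheme, panel, map, labels) {
  stopifnot(inherits(result, "rgp_panel_result"))
  if (result$panel != panel) {
    stop("expected a ", panel, " panel result, got ", result$panel,
         call. = FALSE)
  }
  if (!isTRUE(result$control_ok)) .assay_invalid(panel)
  s <- result$summary
  amp <- s[s$pair %in% names(map) & s$amplified, , drop = FALSE]
  type <- if (nrow(amp) == 0L) "untypeable"
          else if (nrow(amp) > 1L) "ambiguous"
          else unname(map[amp$pair])
  evidence <- data.frame(pair = amp$pair, size = amp$best_length)
  structure(list(type = type, evidence = evidence), class = labels)
}

#' Call the variable side-chain type from a multiplex-1 panel
#'
#' Maps the single amplified \code{Var} pair to its variable type (Vt1-Vt5).
#' No amplified pair with a valid control yields \code{"untypeable"}; more
#' than one yields \code{"ambiguous"}. A failed control raises an
#' \code{rgp_assay_invalid} error (no call).
#'
#' @param result An \code{rgp_panel_result} from the \code{multiplex1} panel.
#' @param scheme The \code{rgp_scheme} used to run the panel.
#' @return An object of class \code{rgp_variable_call}: list with
#'   \code{type} and \code{evidence} (amplified pairs and product sizes).
#' @export
call_variable_type <- function(result, scheme = rgp_scheme()) {
  .call_type(result, scheme, "multiplex1", scheme$vt_map,
             c("rgp_variable_call", "rgp_type_call"))
}

#' Call the rhamnan-backbone (rgpF) type from a multiplex-2 panel
#'
#' Maps the single amplified \code{Fg} pair to its backbone type (Bt1-Bt3),
#' with the same untypeable/ambiguous/control semantics as
#' [call_variable_type()].
#'
#' @inheritParams call_variable_type
#' @return An object of class \code{rgp_backbone_call}.
#' @export
call_backbone_type <- function(result, scheme = rgp_scheme()) {
  .call_type(result, scheme, "multiplex2", scheme$bt_map,
             c("rgp_backbone_call", "rgp_type_call"))
}

#' @export
print.rgp_type_call <- function(x, ...) {
  kind <- if (inherits(x, "rgp_variable_call")) "Variable" else "Backbone"
  cat(sprintf("%s type: %s\n", kind, x$type))
  if (nrow(x$evidence)) {
    cat("  evidence:", paste(sprintf("%s (%d bp)", x$evidence$pair,
                                     x$evidence$size), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Combine variable and backbone calls into a binomial Rgp call
#'
#' Definite variable and backbone types combine into a binomial name
#' \code{V<i>B<j>} whose Rgp group is looked up in the scheme's binomial
#' map; combinations never observed in the reference collection resolve to
#' group \code{"novel"}. A strain that is untypeable by multiplex 1 but
#' carries backbone type Bt3 is reported as a \emph{tentative} group-5
#' candidate: the \code{Fg3} pair targets groups 4 and 5, and group-5 loci
#' have no variable-region target to amplify. Any other untypeable or
#' ambiguous component yields group \code{"unassigned"} without a binomial.
#'
#' @param vc An \code{rgp_variable_call}.
#' @param bc An \code{rgp_backbone_call}.
#' @param scheme An \code{rgp_scheme}.
#' @param strain Optional strain identifier carried into the call.
#' @return An object of class \code{rgp_call}: list with \code{strain},
#'   \code{vt}, \code{bt}, \code{binomial} (or \code{NA}), \code{group} and
#'   \code{tentative}.
#' @export
assign_binomial <- function(vc, bc, scheme = rgp_scheme(),
                            strain = NA_character_) {
  stopifnot(inherits(vc, "rgp_variable_call"),
            inherits(bc, "rgp_backbone_call"))
  vt <- vc$type
  bt <- bc$type
  definite_v <- grepl("^Vt[0-9]+$", vt)
  definite_b <- grepl("^Bt[0-9]+$", bt)
  binomial <- NA_character_
  tentative <- FALSE
  if (definite_v && definite_b) {
    binomial <- sprintf("V%sB%s", sub("^Vt", "", vt), sub("^Bt", "", bt))
    group <- binomial_group(scheme, binomial)
  } else if (vt == "untypeable" && bt == "Bt3") {
    group <- "5"
    tentative <- TRUE
  } else {
    group <- "unassigned"
  }
  structure(list(strain = strain, vt = vt, bt = bt, binomial = binomial,
                 group = group, tentative = tentative),
            class = "rgp_call")
}

#' @export
print.rgp_call <- function(x, ...) {
  cat(sprintf("Rgp call%s: Vt=%s Bt=%s binomial=%s group=%s%s\n",
              if (is.na(x$strain)) "" else paste0(" [", x$strain, "]"),
              x$vt, x$bt,
              ifelse(is.na(x$binomial), "-", x$binomial), x$group,
              if (isTRUE(x$tentative)) " (tentative)" else ""))
  invisible(x)
}

#' Legacy single-step Rgp classification call
#'
#' Interprets the classification panel of the earlier single-step multiplex
#' system: one amplified \code{RGPgroup} pair maps to its legacy Rgp group
#' (631 bp -> Rgp1, 464 bp -> Rgp2, 303 bp -> Rgp3, 162 bp -> Rgp4). The
#' legacy system has no pair for group 5 and cannot separate groups 1/6/7 or
#' 2/2A. Requires the \code{RGPpos} control (801 bp) to have amplified.
#'
#' @param result An \code{rgp_panel_result} from the \code{classification}
#'   panel.
#' @param scheme An \code{rgp_scheme}.
#' @return A legacy group label (\code{"1"}-\code{"4"}) or
#'   \code{"unassigned"}.
#' @export
legacy_call <- function(result, scheme = rgp_scheme()) {
  stopifnot(inherits(result, "rgp_panel_result"))
  if (result$panel != "classification") {
    stop("expected a classification panel result", call. = FALSE)
  }
  if (!isTRUE(result$control_ok)) .assay_invalid("classification")
  s <- result$summary
  amp <- s[s$pair %in% names(scheme$legacy_map) & s$amplified, ,
           drop = FALSE]
  if (nrow(amp) == 0L) return("unassigned")
  if (nrow(amp) > 1L) {
    warning("multiple legacy classification pairs amplified (",
            paste(amp$pair, collapse = ", "), "); no legacy group assigned")
    return("unassigned")
  }
  unname(scheme$legacy_map[amp$pair])
}

#' Summarize calls over a strain collection
#'
#' Tabulates calls by a chosen field and reports counts and percentages.
#'
#' @param calls A list of \code{rgp_call} objects, a character vector of
#'   labels, or a data frame containing column \code{by}.
#' @param by Field to tabulate when \code{calls} are \code{rgp_call}s or a
#'   data frame (default \code{"group"}).
#' @param digits Decimal places for percentages: 2 by default; use 1 to
#'   match one-decimal reporting conventions.
#' @return A data frame with columns \code{label}, \code{count},
#'   \code{percent}, ordered by label.
#' @export
summarize_collection <- function(calls, by = "group", digits = 2L) {
  labels <- if (is.character(calls)) {
    calls
  } else if (is.data.frame(calls)) {
    if (!by %in% names(calls)) stop("no column ", sQuote(by), call. = FALSE)
    as.character(calls[[by]])
  } else if (is.list(calls)) {
    vapply(calls, function(x) as.character(x[[by]]), character(1))
  } else {
    stop("unsupported input for `calls`", call. = FALSE)
  }
  if (!length(labels)) stop("no calls to summarize", call. = FALSE)
  tb <- table(labels)
  out <- data.frame(label = names(tb), count = as.integer(tb))
  out$percent <- round(100 * out$count / sum(out$count), digits)
  out[order(out$label), , drop = FALSE]
}

#' Type one genome through the two-step system
#'
#' Convenience wrapper running multiplex panels 1 and 2 (and optionally the
#' legacy classification panel) on one genome and combining the calls.
#'
#' @param genome FASTA path, named character vector, or \code{DNAStringSet}.
#' @param scheme An \code{rgp_scheme}.
#' @param strain Strain identifier for the report.
#' @param legacy Also run the legacy classification panel?
#' @param ... Passed to [run_panel()] (\code{max_mismatch},
#'   \code{size_tolerance}, ...).
#' @return An \code{rgp_call} with additional elements \code{panels} (the
#'   two/three panel results), \code{legacy_group} (if requested) and
#'   \code{structure} (the knowledge-base model for the called group, when
#'   concrete).
#' @export
type_genome <- function(genome, scheme = rgp_scheme(),
                        strain = NA_character_, legacy = FALSE, ...) {
  m1 <- run_panel(genome, scheme, "multiplex1", ...)
  m2 <- run_panel(genome, scheme, "multiplex2", ...)
  call <- assign_binomial(call_variable_type(m1, scheme),
                          call_backbone_type(m2, scheme),
                          scheme, strain = strain)
  call$panels <- list(multiplex1 = m1, multiplex2 = m2)
  if (legacy) {
    cl <- run_panel(genome, scheme, "classification", ...)
    call$panels$classification <- cl
    call$legacy_group <- tryCatch(legacy_call(cl, scheme),
                                  rgp_assay_invalid = function(e) NA_character_)
  }
  if (call$group %in% names(rgp_structure_kb())) {
    call$structure <- predict_structure(call$group)
  }
  call
}
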