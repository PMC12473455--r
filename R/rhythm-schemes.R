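# Rhythm taxonomy: 11 annotated rhythm codes, their 4 major rhythm groups,
# and the class schemes used throughout (11-class, 8-class, 4-class).

#' Rhythm taxonomy table
#'
#' The 11 rhythm codes annotated in the source database together with the
#' major rhythm group each belongs to (AFIB, SB, SR, GSVT).
#'
#' @return A data.frame with columns `code`, `group`, `name`.
#' @export
rhythm_taxonomy <- function() {
  data.frame(
    code = c("AFIB", "AF", "SB", "SA", "SR",
             "ST", "SVT", "AT", "AVNRT", "SAAWR", "AVRT"),
    group = c("AFIB", "AFIB", "SB", "SR", "SR",
              "GSVT", "GSVT", "GSVT", "GSVT", "GSVT", "GSVT"),
    name = c("Atrial Fibrillation", "Atrial Flutter", "Sinus Bradycardia",
             "Sinus Arrhythmia", "Sinus Rhythm", "Sinus Tachycardia",
             "Supraventricular Tachycardia", "Atrial Tachycardia",
             "Atrioventricular Node Reentrant Tachycardia",
             "Sinus Atrium to Atrial Wandering Rhythm",
             "Atrioventricular Reentrant Tachycardia"),
    stringsAsFactors = FALSE
  )
}

# codes excluded from the 8-class analyses: fewer than 20 examples each
.rare_codes <- c("AVNRT", "SAAWR", "AVRT")

#' Class scheme for rhythm labels
#'
#' Builds one of the three labelling schemes: `"eleven"` (identity on the 11
#' rhythm codes), `"eight"` (the 11 codes minus the three rare ones — AVNRT,
#' SAAWR, AVRT — each with fewer than 20 examples in the source database),
#' or `"four"` (every code mapped to its major rhythm group AFIB / SB / SR /
#' GSVT).
#'
#' @param name One of `"eleven"`, `"eight"`, `"four"`.
#' @return An object of class `rhythm_scheme` with elements `name`,
#'   `mapping` (named character vector code -> class label) and `excluded`
#'   (character vector of dropped codes).
#' @export
rhythm_scheme <- function(name = c("eleven", "eight", "four")) {
  name <- match.arg(name)
  tax <- rhythm_taxonomy()
  scheme <- switch(name,
    eleven = list(mapping = stats::setNames(tax$code, tax$code),
                  excluded = character(0)),
    eight = {
      keep <- setdiff(tax$code, .rare_codes)
      list(mapping = stats::setNames(keep, keep), excluded = .rare_codes)
    },
    four = list(mapping = stats::setNames(tax$group, tax$code),
                excluded = character(0))
  )
  structure(c(list(name = name), scheme), class = "rhythm_scheme")
}

#' @export
print.rhythm_scheme <- function(x, ...) {
  cat("Rhythm scheme:", x$name, "\n")
  cat("  classes: ", paste(unique(unname(x$mapping)), collapse = ", "), "\n")
  if (length(x$excluded))
    cat("  excluded codes:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Apply a class scheme to diagnostics rows
#'
#' Drops rows whose rhythm code is excluded by the scheme and maps the
#' remaining codes to class labels, preserving row order.
#'
#' @param diagnostics A data.frame of diagnostics rows (must have a `Rhythm`
#'   column), as returned by [load_diagnostics()] or [generate_cohort()].
#' @param scheme A [rhythm_scheme()] object.
#' @return A list with `rows` (the kept diagnostics rows) and `labels`
#'   (factor of class labels, one per kept row).
#' @export
apply_rhythm_scheme <- function(diagnostics, scheme) {
  stopifnot(inherits(scheme, "rhythm_scheme"))
  if (!"Rhythm" %in% names(diagnostics))
    stopf("diagnostics table lacks a 'Rhythm' column")
  rhythm <- as.character(diagnostics$Rhythm)
  unknown <- setdiff(unique(rhythm), c(names(scheme$mapping), scheme$excluded))
  if (length(unknown))
    stopf("unmapped rhythm code(s) not excluded by scheme '%s': %s",
          scheme$name, paste(unknown, collapse = ", "))
  keep <- !(rhythm %in% scheme$excluded)
  labels <- unname(scheme$mapping[rhythm[keep]])
  list(rows = diagnostics[keep, , drop = FALSE],
       labels = factor(labels, levels = unique(unname(scheme$mapping))))
}

#' Count examples per class
#'
#' @param labels Vector/factor of class labels.
#' @return Named integer vector of counts; classes with zero members are
#'   absent.
#' @export
class_counts <- function(labels) {
  if (length(labels) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(as.character(labels))
  stats::setNames(as.integer(tab), names(tab))
}
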