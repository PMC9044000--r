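# The mathematical core: unweighted and area-weighted means of the tumor-bed
# components, the 10%-increment rounding convention, and MPR/pCR labels.

.components <- c(viable = "pct_viable", necrosis = "pct_necrosis",
                 stroma = "pct_stroma")

#' Unweighted mean of a tumor-bed component across slides
#'
#' Plain arithmetic mean over slides that carry tumor bed; slides with zero
#' bed area are recorded but contribute nothing (averaging a percentage over
#' a slide without bed is undefined).
#'
#' @param slides Slide table ([slide_measurements()]).
#' @param component `"viable"`, `"necrosis"` or `"stroma"`.
#' @return The mean percentage.
#' @export
unweighted_mean <- function(slides, component = c("viable", "necrosis", "stroma")) {
  component <- match.arg(component)
  keep <- slide_bed_area(slides) > 0
  if (!any(keep, na.rm = TRUE)) {
    stop("no slide with tumor bed present; mean undefined", call. = FALSE)
  }
  mean(slides[[.components[[component]]]][which(keep)])
}

#' Area-weighted mean of a tumor-bed component across slides
#'
#' Each slide is weighted by its tumor-bed area `l_i * w_i` (less any
#' excluded cavity/lumen area), so slides carrying a lot of bed dominate:
#' `sum(a_i * V_i) / sum(a_i)` with `a_i = l_i * w_i - excluded_i`. This is
#' the estimator of the overall bed composition when the whole bed has been
#' sectioned.
#'
#' @inheritParams unweighted_mean
#' @return The weighted mean percentage.
#' @export
weighted_mean <- function(slides, component = c("viable", "necrosis", "stroma")) {
  component <- match.arg(component)
  a <- slide_bed_area(slides)
  total <- sum(a, na.rm = TRUE)
  if (!isTRUE(total > 0)) {
    stop("total tumor-bed area is zero; weighted mean undefined", call. = FALSE)
  }
  keep <- which(!is.na(a) & a > 0)
  sum(a[keep] * slides[[.components[[component]]]][keep]) / total
}

#' Round a percentage by the 10%-increment reporting convention
#'
#' Percentages are reported in 10% increments unless the amount is below 5%,
#' in which case single percents are kept: values below 5 round to the
#' nearest whole percent, values of 5 or more to the nearest multiple of 10.
#' Ties round up (half-up), so 15 reports as 20 — deterministic and matching
#' clinical rounding custom.
#'
#' @param pct Percentage(s) in \[0, 100\].
#' @return Rounded percentage(s).
#' @examples
#' round_iaslc(c(3.2, 17.14, 15, 0))  # 3 20 20 0
#' @export
round_iaslc <- function(pct) {
  pct <- as.numeric(pct)
  if (any(is.na(pct)) || any(pct < 0 | pct > 100)) {
    stop("percentage out of [0, 100]", call. = FALSE)
  }
  half_up <- function(x) floor(x + 0.5)
  ifelse(pct < 5, half_up(pct), pmin(100, 10 * half_up(pct / 10)))
}

#' Classify pathologic response
#'
#' pCR requires 0% viable tumor on every slide; with `nodes_negative = TRUE`
#' (all sampled regional lymph nodes clear) the label is `"pcr"`, with node
#' status unrecorded it is qualified as pCR of the primary tumor only and a
#' warning attribute is set, and with positive nodes pCR is withheld. MPR is
#' mean viable tumor at or below the threshold (boundary inclusive; default
#' 10, configurable for histology-specific cutoffs). pCR implies MPR and is
#' reported as `"pcr"`.
#'
#' @param mean_viable Mean percent viable tumor on the chosen basis.
#' @param slide_viable Per-slide percent viable tumor.
#' @param nodes_negative `TRUE`/`FALSE`/`NA` regional node status.
#' @param mpr_threshold MPR cutoff in percent (default 10).
#' @return One of `"pcr"`, `"mpr"`, `"no_mpr"`; attribute `"qualifier"`
#'   carries `"primary_tumor_only"` for pCR without recorded node status.
#' @export
classify_response <- function(mean_viable, slide_viable, nodes_negative = NA,
                              mpr_threshold = 10) {
  stopifnot(length(slide_viable) >= 1L)
  qualifier <- NULL
  pcr <- all(slide_viable == 0)
  if (pcr) {
    if (isFALSE(nodes_negative)) {
      pcr <- FALSE
    } else if (is.na(nodes_negative)) {
      qualifier <- "primary_tumor_only"
    }
  }
  label <- if (pcr) {
    "pcr"
  } else if (mean_viable <= mpr_threshold) {
    "mpr"
  } else {
    "no_mpr"
  }
  structure(label, qualifier = qualifier)
}

#' Compute pathologic response for a case
#'
#' The central entry point: takes the slide table of a resection case (or a
#' [case_record()]), validates it, computes the unweighted and area-weighted
#' means of viable tumor, necrosis and stroma, and classifies the response.
#' Returns a fitted-model-style object with `print`, `summary`, `coef`,
#' `residuals` and `plot` methods.
#'
#' The classification basis defaults to the unweighted mean — the historical
#' definition of MPR averaged plain slide percentages — while the weighted
#' mean is always computed and reported alongside.
#'
#' @param slides Slide table ([slide_measurements()]) or a [case_record()].
#' @param basis `"unweighted"` (default) or `"weighted"`: which mean viable
#'   tumor drives the MPR label.
#' @param mpr_threshold MPR cutoff in percent (default 10).
#' @param nodes_negative Regional lymph-node status; ignored when `slides`
#'   is a `case_record` (taken from the record).
#' @param strict Whole-number percentages enforced during validation.
#' @param tolerance_factor Gross-versus-microscopic area tolerance for
#'   [validate_case()].
#' @return An object of class `mprct` with elements `means` (2 x 3 matrix,
#'   rows unweighted/weighted, columns viable/necrosis/stroma),
#'   `total_bed_area_cm2`, `classification`, `mpr`, `pcr`, `basis`,
#'   `mpr_threshold`, `findings`, `slides`, `n_slides`, `n_slides_with_bed`.
#' @examples
#' s <- slide_measurements(c("A1", "A2"), bed_length_cm = c(2, 4),
#'                         bed_width_cm = c(1, 3), pct_viable = c(90, 5),
#'                         pct_necrosis = c(0, 10))
#' fit <- mprct(s)
#' coef(fit)
#' @export
mprct <- function(slides, basis = c("unweighted", "weighted"),
                  mpr_threshold = 10, nodes_negative = NA, strict = TRUE,
                  tolerance_factor = 1.2) {
  basis <- match.arg(basis)
  if (inherits(slides, "case_record")) {
    case <- slides
  } else {
    case <- case_record("case", slides, nodes_negative = nodes_negative)
  }
  findings <- validate_case(case, tolerance_factor = tolerance_factor,
                            strict = strict)
  if (any(findings$severity == "error")) {
    stop("case fails validation: ",
         paste(unique(findings$rule_code[findings$severity == "error"]),
               collapse = ", "),
         call. = FALSE)
  }
  sl <- case$slides
  means <- matrix(NA_real_, nrow = 2, ncol = 3,
                  dimnames = list(c("unweighted", "weighted"),
                                  c("viable", "necrosis", "stroma")))
  for (comp in colnames(means)) {
    means["unweighted", comp] <- unweighted_mean(sl, comp)
    means["weighted", comp] <- weighted_mean(sl, comp)
  }
  label <- classify_response(means[basis, "viable"], sl$pct_viable,
                             nodes_negative = case$nodes_negative,
                             mpr_threshold = mpr_threshold)
  structure(
    list(case_id = case$case_id,
         means = means,
         total_bed_area_cm2 = total_bed_area(sl),
         classification = as.character(label),
         classification_qualifier = attr(label, "qualifier"),
         mpr = as.character(label) %in% c("mpr", "pcr"),
         pcr = as.character(label) == "pcr",
         basis = basis,
         mpr_threshold = mpr_threshold,
         nodes_negative = case$nodes_negative,
         findings = findings,
         slides = sl,
         n_slides = nrow(sl),
         n_slides_with_bed = sum(slide_bed_area(sl) > 0, na.rm = TRUE),
         call = match.call()),
    class = "mprct"
  )
}

#' @export
print.mprct <- function(x, digits = 2, ...) {
  cat("Pathologic response (case ", x$case_id, ", ", x$n_slides,
      " slide(s), bed area ", format(round(x$total_bed_area_cm2, digits)),
      " cm^2)\n", sep = "")
  cat("  mean viable tumor: ",
      format(round(x$means["unweighted", "viable"], digits)), "% unweighted, ",
      format(round(x$means["weighted", "viable"], digits)), "% weighted\n",
      sep = "")
  cat("  classification (", x$basis, " basis, threshold ",
      x$mpr_threshold, "%): ", toupper(x$classification), sep = "")
  if (!is.null(x$classification_qualifier)) {
    cat(" [", x$classification_qualifier, "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.mprct <- function(object, ...) {
  structure(object, class = c("summary.mprct", "mprct"))
}

#' @export
print.summary.mprct <- function(x, digits = 2, ...) {
  print.mprct(x, digits = digits, ...)
  cat("\nComponent means (%):\n")
  print(round(x$means, digits))
  cat("\nReported with 10%-increment rounding (viable):",
      format(round_iaslc(pmin(100, pmax(0, x$means[, "viable"])))), "\n")
  cat("\nPer-slide measurements:\n")
  print(x$slides, row.names = FALSE)
  if (nrow(x$findings)) {
    cat("\nValidation findings:\n")
    print(x$findings, row.names = FALSE)
  }
  invisible(x)
}

#' Extract the component means from a fitted response object
#'
#' @param object An `mprct` object.
#' @param ... Unused.
#' @return Named numeric vector of the six means, e.g.
#'   `viable.unweighted`, `viable.weighted`, ...
#' @export
coef.mprct <- function(object, ...) {
  m <- object$means
  out <- as.vector(m)
  names(out) <- paste(rep(colnames(m), each = 2),
                      rep(rownames(m), times = 3), sep = ".")
  out
}

#' Per-slide deviations from the case mean viable tumor
#'
#' @param object An `mprct` object.
#' @param ... Unused.
#' @return `V_i` minus the mean viable tumor on the classification basis,
#'   one value per slide with bed present.
#' @export
residuals.mprct <- function(object, ...) {
  keep <- slide_bed_area(object$slides) > 0
  r <- object$slides$pct_viable[keep] - object$means[object$basis, "viable"]
  names(r) <- object$slides$slide_id[keep]
  r
}

#' Plot the per-slide tumor-bed composition
#'
#' Stacked bars of viable/necrosis/stroma per slide, bar widths proportional
#' to slide bed area, so the weighted mean can be read off visually while the
#' unweighted mean treats every bar equally.
#'
#' @param x An `mprct` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.mprct <- function(x, ...) {
  sl <- x$slides
  keep <- slide_bed_area(sl) > 0
  sl <- sl[keep, , drop = FALSE]
  h <- t(as.matrix(sl[, c("pct_viable", "pct_necrosis", "pct_stroma")]))
  rownames(h) <- c("viable", "necrosis", "stroma")
  w <- slide_bed_area(sl)
  cols <- c("#7b3294", "#404040", "#f4a6c0")
  graphics::barplot(h, width = w, names.arg = sl$slide_id, col = cols,
                    border = NA, space = 0.05,
                    ylab = "% of tumor bed", xlab = "slide", ...)
  graphics::legend("topright", legend = rownames(h), fill = cols,
                   bg = "white", cex = 0.8)
  invisible(x)
}
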