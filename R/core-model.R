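#' Derive the stroma percentage from viable tumor and necrosis
#'
#' The tumor bed is partitioned into viable tumor, necrosis and stroma
#' (fibrosis plus inflammation), so the stroma percentage is never entered by
#' the observer: it is computed as `100 - pct_viable - pct_necrosis`. When
#' both inputs are missing the form default of 100% stroma is returned;
#' a missing single input propagates `NA` (the slide is incomplete).
#'
#' @param pct_viable Percent viable tumor on the slide, in \[0, 100\].
#' @param pct_necrosis Percent necrosis on the slide, in \[0, 100\].
#' @return Percent stroma, same length as the inputs.
#' @examples
#' derive_stroma(20, 30)  # 50
#' derive_stroma(NA, NA)  # 100, the blank-form default
#' @export
derive_stroma <- function(pct_viable, pct_necrosis) {
  n <- max(length(pct_viable), length(pct_necrosis))
  v <- rep_len(as.numeric(pct_viable), n)
  x <- rep_len(as.numeric(pct_necrosis), n)
  bad <- (!is.na(v) & (v < 0 | v > 100)) | (!is.na(x) & (x < 0 | x > 100))
  if (any(bad)) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  over <- !is.na(v) & !is.na(x) & v + x > 100
  if (any(over)) {
    stop("percent viable + percent necrosis exceeds 100 on ",
         sum(over), " slide(s)", call. = FALSE)
  }
  s <- 100 - v - x
  s[is.na(v) & is.na(x)] <- 100
  s
}

#' Assemble slide-level tumor-bed measurements
#'
#' Builds the per-slide measurement table used throughout the package,
#' mirroring the data-collection form: one row per slide with the tumor-bed
#' length and width (cm), percent viable tumor and percent necrosis. Percent
#' stroma is always derived via [derive_stroma()], never taken on trust.
#' `excluded_area_cm2` records slide area subtracted from the bed (empty
#' cystic cavities, bronchial lumina; see [adjust_bed_for_exclusions()]) and
#' defaults to 0.
#'
#' Incomplete or out-of-range rows are permitted here so that
#' [validate_slides()] can report findings; computation functions reject
#' invalid input.
#'
#' @param slide_id Character or integer slide identifiers.
#' @param bed_length_cm,bed_width_cm Tumor-bed dimensions on each slide (cm).
#'   Both zero is allowed and means no tumor bed present on the slide.
#' @param pct_viable,pct_necrosis Component percentages in \[0, 100\].
#' @param excluded_area_cm2 Area subtracted from the slide's bed (cm^2).
#' @param derive When `TRUE` (default) compute `pct_stroma`; with incomplete
#'   rows the derived value may be `NA`.
#' @return A `data.frame` with columns `slide_id`, `bed_length_cm`,
#'   `bed_width_cm`, `pct_viable`, `pct_necrosis`, `pct_stroma`,
#'   `excluded_area_cm2`.
#' @examples
#' slide_measurements(c("A1", "A2"), bed_length_cm = c(2, 4),
#'                    bed_width_cm = c(1, 3), pct_viable = c(90, 5),
#'                    pct_necrosis = c(0, 10))
#' @export
slide_measurements <- function(slide_id, bed_length_cm, bed_width_cm,
                               pct_viable, pct_necrosis,
                               excluded_area_cm2 = 0, derive = TRUE) {
  n <- length(slide_id)
  out <- data.frame(
    slide_id = as.character(slide_id),
    bed_length_cm = rep_len(as.numeric(bed_length_cm), n),
    bed_width_cm = rep_len(as.numeric(bed_width_cm), n),
    pct_viable = rep_len(as.numeric(pct_viable), n),
    pct_necrosis = rep_len(as.numeric(pct_necrosis), n),
    stringsAsFactors = FALSE
  )
  out$pct_stroma <- if (derive) {
    s <- 100 - out$pct_viable - out$pct_necrosis
    s[is.na(out$pct_viable) & is.na(out$pct_necrosis)] <- 100
    s
  } else {
    NA_real_
  }
  out$excluded_area_cm2 <- rep_len(as.numeric(excluded_area_cm2), n)
  out
}

#' Construct a resection-case record
#'
#' A case bundles the slide table with the gross tumor(-bed) dimensions, the
#' regional lymph-node status and the fraction of the bed submitted. The
#' total bed area `T = sum(l_i * w_i - excluded_i)` is the weighting
#' denominator of the area-weighted means.
#'
#' @param case_id Case identifier.
#' @param slides Slide table as returned by [slide_measurements()] (or a
#'   data.frame with the same columns).
#' @param gross_length_cm,gross_width_cm,gross_depth_cm Gross tumor(-bed)
#'   dimensions in cm (`NA` when not recorded).
#' @param nodes_negative `TRUE` when all sampled regional lymph nodes are
#'   free of viable tumor, `FALSE` when any is involved, `NA` when node
#'   status was not recorded. pCR requires negative nodes; with `NA` the
#'   classification is qualified as primary-tumor-only.
#' @param sampled_fraction Fraction of the tumor bed submitted, in \[0, 1\]
#'   (`NA` when unknown).
#' @return An object of class `case_record`.
#' @export
case_record <- function(case_id, slides,
                        gross_length_cm = NA_real_, gross_width_cm = NA_real_,
                        gross_depth_cm = NA_real_, nodes_negative = NA,
                        sampled_fraction = NA_real_) {
  stopifnot(is.data.frame(slides))
  needed <- c("slide_id", "bed_length_cm", "bed_width_cm",
              "pct_viable", "pct_necrosis")
  missing_cols <- setdiff(needed, names(slides))
  if (length(missing_cols)) {
    stop("slides is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(slides$pct_stroma)) {
    slides$pct_stroma <- 100 - slides$pct_viable - slides$pct_necrosis
  }
  if (is.null(slides$excluded_area_cm2)) slides$excluded_area_cm2 <- 0
  structure(
    list(case_id = as.character(case_id)[1],
         slides = slides,
         gross_length_cm = as.numeric(gross_length_cm)[1],
         gross_width_cm = as.numeric(gross_width_cm)[1],
         gross_depth_cm = as.numeric(gross_depth_cm)[1],
         nodes_negative = as.logical(nodes_negative)[1],
         sampled_fraction = as.numeric(sampled_fraction)[1]),
    class = "case_record"
  )
}

#' @export
print.case_record <- function(x, ...) {
  cat("Resection case", x$case_id, "\n")
  cat("  slides:", nrow(x$slides),
      " total bed area:", format(total_bed_area(x$slides)), "cm^2\n")
  if (!is.na(x$gross_length_cm) || !is.na(x$gross_width_cm)) {
    cat("  gross:", x$gross_length_cm, "x", x$gross_width_cm,
        if (!is.na(x$gross_depth_cm)) paste("x", x$gross_depth_cm), "cm\n")
  }
  cat("  nodes negative:", x$nodes_negative, "\n")
  invisible(x)
}

# Per-slide effective bed area (cm^2): l*w minus any excluded cavity/lumen area.
slide_bed_area <- function(slides) {
  excl <- slides$excluded_area_cm2
  if (is.null(excl)) excl <- 0
  a <- slides$bed_length_cm * slides$bed_width_cm - excl
  if (any(!is.na(a) & a < 0)) {
    stop("excluded area exceeds slide bed area", call. = FALSE)
  }
  a
}

#' Total tumor-bed area of a slide set
#'
#' @param slides Slide table ([slide_measurements()]).
#' @return Total effective bed area in cm^2.
#' @export
total_bed_area <- function(slides) {
  sum(slide_bed_area(slides), na.rm = TRUE)
}
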