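# Error-detection safeguards on entered slide data: findings are returned,
# never thrown, so a data manager sees every problem at once.

.rule_registry <- data.frame(
  rule_code = c("MISSING_FIELD", "SUM_GT_100", "RANGE", "NON_INTEGER",
                "DUPLICATE_SLIDE_ID", "AREA_RANGE", "EMPTY_CASE"),
  default_severity = c("error", "error", "error", "warning",
                       "error", "warning", "error"),
  description = c(
    "required cell is blank",
    "percent viable + percent necrosis exceeds 100",
    "value outside [0, 100] or negative dimension",
    "percentage is not a whole number",
    "slide identifier occurs more than once",
    "slide or total bed area implausible versus gross dimensions",
    "case has no slides"
  ),
  stringsAsFactors = FALSE
)

#' Registry of validation rules
#'
#' The closed set of rule codes that [validate_slides()] and
#' [validate_case()] can emit, with default severities.
#'
#' @return A data.frame with columns `rule_code`, `default_severity`,
#'   `description`.
#' @export
validation_rules <- function() .rule_registry

new_finding <- function(case_id, slide_id, rule_code, severity, message) {
  data.frame(case_id = case_id, slide_id = slide_id, rule_code = rule_code,
             severity = severity, message = message, stringsAsFactors = FALSE)
}

no_findings <- function() {
  data.frame(case_id = character(), slide_id = character(),
             rule_code = character(), severity = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Validate slide-level measurements
#'
#' Applies the form safeguards row by row: `MISSING_FIELD` for blank required
#' cells, `SUM_GT_100` when viable + necrosis exceeds 100 (only checked when
#' both values are individually in range, so a single out-of-range cell
#' reports `RANGE` alone), `RANGE` for percentages outside \[0, 100\] or
#' negative dimensions, and `NON_INTEGER` for fractional percentages (an
#' error in strict mode, a warning otherwise — the simulator's continuous
#' output is legitimate in lenient mode).
#'
#' @param slides Slide table ([slide_measurements()]); may be partially filled.
#' @param strict Enforce whole-number percentages (the form accepts any whole
#'   number between 0 and 100).
#' @param case_id Identifier copied into the findings.
#' @return A data.frame of findings (zero rows when the slides are clean)
#'   with columns `case_id`, `slide_id`, `rule_code`, `severity`, `message`.
#' @export
validate_slides <- function(slides, strict = TRUE, case_id = NA_character_) {
  out <- no_findings()
  if (is.null(slides) || nrow(slides) == 0L) return(out)
  for (i in seq_len(nrow(slides))) {
    s <- slides[i, ]
    sid <- if (is.na(s$slide_id) || !nzchar(s$slide_id)) {
      paste0("row ", i)
    } else {
      s$slide_id
    }
    vals <- c(bed_length_cm = s$bed_length_cm, bed_width_cm = s$bed_width_cm,
              pct_viable = s$pct_viable, pct_necrosis = s$pct_necrosis)
    blank <- names(vals)[is.na(vals)]
    if (length(blank)) {
      out <- rbind(out, new_finding(case_id, sid, "MISSING_FIELD", "error",
        paste0("missing value for ", paste(blank, collapse = ", "))))
    }
    pct_bad <- c(
      !is.na(s$pct_viable) && (s$pct_viable < 0 || s$pct_viable > 100),
      !is.na(s$pct_necrosis) && (s$pct_necrosis < 0 || s$pct_necrosis > 100)
    )
    dim_bad <- c(
      !is.na(s$bed_length_cm) && s$bed_length_cm < 0,
      !is.na(s$bed_width_cm) && s$bed_width_cm < 0
    )
    if (any(pct_bad) || any(dim_bad)) {
      out <- rbind(out, new_finding(case_id, sid, "RANGE", "error",
        "value outside [0, 100] or negative dimension"))
    }
    if (!any(pct_bad) && !is.na(s$pct_viable) && !is.na(s$pct_necrosis) &&
        s$pct_viable + s$pct_necrosis > 100) {
      out <- rbind(out, new_finding(case_id, sid, "SUM_GT_100", "error",
        sprintf("viable (%s) + necrosis (%s) exceeds 100",
                format(s$pct_viable), format(s$pct_necrosis))))
    }
    frac <- vapply(c(s$pct_viable, s$pct_necrosis), function(p) {
      !is.na(p) && p >= 0 && p <= 100 && abs(p - round(p)) > 1e-9
    }, logical(1))
    if (any(frac)) {
      out <- rbind(out, new_finding(case_id, sid, "NON_INTEGER",
        if (strict) "error" else "warning",
        "fractional percentage entered"))
    }
  }
  out
}

#' Validate a full case against its gross dimensions
#'
#' Aggregates all slide-level findings and adds case-level checks:
#' `EMPTY_CASE` when there are no slides, `DUPLICATE_SLIDE_ID` for repeated
#' identifiers, and `AREA_RANGE` (a warning, never blocking) when a single
#' slide's bed area exceeds `tolerance_factor` times the gross footprint
#' `gross_length_cm * gross_width_cm`, or the total bed area exceeds
#' `tolerance_factor * n_slides` times the footprint. Gross and microscopic
#' measurements legitimately differ, hence the configurable tolerance and
#' warning severity. Passing at tolerance `t` implies passing at any larger
#' tolerance.
#'
#' @param case A [case_record()].
#' @param tolerance_factor Multiplier on the gross footprint before an area
#'   is flagged (default 1.2).
#' @param strict Passed to [validate_slides()].
#' @return Findings data.frame, as for [validate_slides()].
#' @export
validate_case <- function(case, tolerance_factor = 1.2, strict = TRUE) {
  stopifnot(inherits(case, "case_record"))
  slides <- case$slides
  if (is.null(slides) || nrow(slides) == 0L) {
    return(new_finding(case$case_id, NA_character_, "EMPTY_CASE", "error",
                       "case contains no slides"))
  }
  out <- validate_slides(slides, strict = strict, case_id = case$case_id)
  dup <- unique(slides$slide_id[duplicated(slides$slide_id)])
  for (d in dup) {
    out <- rbind(out, new_finding(case$case_id, d, "DUPLICATE_SLIDE_ID",
      "error", paste0("slide id '", d, "' occurs more than once")))
  }
  gl <- case$gross_length_cm
  gw <- case$gross_width_cm
  if (!is.na(gl) && !is.na(gw) && gl > 0 && gw > 0) {
    footprint <- gl * gw
    areas <- slides$bed_length_cm * slides$bed_width_cm
    big <- which(!is.na(areas) & areas > tolerance_factor * footprint)
    for (i in big) {
      out <- rbind(out, new_finding(case$case_id, slides$slide_id[i],
        "AREA_RANGE", "warning",
        sprintf("slide bed area %.2f cm^2 exceeds %.2f x gross footprint %.2f cm^2",
                areas[i], tolerance_factor, footprint)))
    }
    total <- sum(areas, na.rm = TRUE)
    if (total > tolerance_factor * nrow(slides) * footprint) {
      out <- rbind(out, new_finding(case$case_id, NA_character_,
        "AREA_RANGE", "warning",
        sprintf("total bed area %.2f cm^2 exceeds %.2f x %d slides x gross footprint",
                total, tolerance_factor, nrow(slides))))
    }
  }
  rownames(out) <- NULL
  out
}
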