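# Tumor-bed sampling strategy: how much of the bed must be submitted, and
# how little the legacy one-section-per-centimeter approach actually examines.

#' Plan tumor-bed sampling for a resection
#'
#' The proposed strategy: submit the entire visible tumor bed for tumors at
#' most 3 cm in greatest diameter or whenever pCR is suspected, and at least
#' 50% from alternate sections for larger tumors without suspected pCR. In
#' the latter case, finding no viable tumor in the initial sections escalates
#' to complete examination of the remaining bed to confirm pCR.
#'
#' @param max_diameter_cm Greatest tumor(-bed) diameter in cm (> 0).
#' @param suspected_pcr Is complete response suspected grossly?
#' @param slab_thickness_cm Section thickness used to count the minimum
#'   number of sections (default 0.5 cm).
#' @return An object of class `sampling_plan` with `required_fraction`
#'   (0.5 or 1), `scheme` (`"all_sections"` or `"alternate_sections"`),
#'   `escalate_to_full_on_no_viable` and `min_sections`.
#' @examples
#' plan_sampling(3)        # whole bed
#' plan_sampling(5)        # >= 50%, alternate sections, escalation on no viable
#' plan_sampling(7, TRUE)  # suspected pCR: whole bed regardless of size
#' @export
plan_sampling <- function(max_diameter_cm, suspected_pcr = FALSE,
                          slab_thickness_cm = 0.5) {
  if (!is.numeric(max_diameter_cm) || is.na(max_diameter_cm) ||
      max_diameter_cm <= 0) {
    stop("max_diameter_cm must be a positive number", call. = FALSE)
  }
  n_slabs <- max(1L, as.integer(ceiling(max_diameter_cm / slab_thickness_cm)))
  full <- max_diameter_cm <= 3 || isTRUE(suspected_pcr)
  plan <- list(
    max_diameter_cm = max_diameter_cm,
    suspected_pcr = isTRUE(suspected_pcr),
    required_fraction = if (full) 1 else 0.5,
    scheme = if (full) "all_sections" else "alternate_sections",
    escalate_to_full_on_no_viable = !full,
    min_sections = if (full) n_slabs else as.integer(ceiling(n_slabs / 2))
  )
  class(plan) <- "sampling_plan"
  plan
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat("Sampling plan for", x$max_diameter_cm, "cm tumor bed",
      if (x$suspected_pcr) "(suspected pCR)", "\n")
  cat("  submit:", sprintf("%.0f%%", 100 * x$required_fraction),
      "of tumor bed,", gsub("_", " ", x$scheme),
      "(>=", x$min_sections, "sections)\n")
  if (x$escalate_to_full_on_no_viable) {
    cat("  if no viable tumor in initial sections: examine remaining bed",
        "completely to confirm pCR\n")
  }
  invisible(x)
}

#' Fraction of tumor examined under the legacy one-section-per-centimeter rule
#'
#' The standard approach submits tumors of at most 3 cm entirely, but for
#' larger tumors takes about one cassette per centimeter of greatest
#' diameter, so the examined proportion shrinks as the tumor grows. This
#' geometric model counts the cassettes full submission would need — the
#' tumor is treated as a solid (sphere by default) cut into slabs of
#' `slab_thickness_cm`, each slab needing `ceiling(area / cassette_area_cm2)`
#' cassettes at its mid-slab cross-sectional area — and divides the
#' `ceiling(diameter)` cassettes actually taken by that total.
#'
#' @param max_diameter_cm Greatest tumor diameter (cm).
#' @param slab_thickness_cm Gross slab thickness (default 0.5 cm).
#' @param cassette_area_cm2 Tissue footprint of one cassette (default 4 cm^2).
#' @param shape Solid model of the tumor; `"sphere"` only.
#' @return Estimated examined fraction in (0, 1]; exactly 1 at or below 3 cm.
#' @examples
#' standard_proportion(3)  # 1: submitted entirely
#' standard_proportion(7)  # far less than half
#' @export
standard_proportion <- function(max_diameter_cm, slab_thickness_cm = 0.5,
                                cassette_area_cm2 = 4, shape = "sphere") {
  shape <- match.arg(shape, "sphere")
  if (!is.numeric(max_diameter_cm) || is.na(max_diameter_cm) ||
      max_diameter_cm <= 0 || slab_thickness_cm <= 0 || cassette_area_cm2 <= 0) {
    stop("all dimensions must be positive", call. = FALSE)
  }
  if (max_diameter_cm <= 3) return(1)
  r <- max_diameter_cm / 2
  n_slabs <- ceiling(max_diameter_cm / slab_thickness_cm)
  # mid-slab positions along the cutting axis, centered on the sphere
  mid <- (seq_len(n_slabs) - 0.5) * slab_thickness_cm - max_diameter_cm / 2
  areas <- pi * pmax(0, r^2 - mid^2)
  total_cassettes <- sum(ceiling(areas / cassette_area_cm2))
  taken <- ceiling(max_diameter_cm)
  min(1, taken / total_cassettes)
}
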