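# Conventions for morphologically ambiguous tissue elements, kept as a
# versioned data table (not hard-coded branches) so a future revision of the
# assessment rules can be swapped in without touching code.

.rules_cache <- new.env(parent = emptyenv())

#' The tissue-element categorization table
#'
#' Each row maps one challenging tissue element to the tumor-bed category it
#' contributes to. The three in-bed categories (`viable_tumor`, `necrosis`,
#' `stroma`) are exactly those entering the viable + necrosis + stroma = 100
#' decomposition; `excluded_from_bed` elements are subtracted from the bed
#' denominator, and `not_primary_bed` elements (encapsulated nodal
#' metastases) are assessed outside the primary tumor bed.
#'
#' @return A data.frame with columns `kind`, `category`, `rules_version`,
#'   `note`.
#' @export
tissue_rules <- function() {
  if (is.null(.rules_cache$table)) {
    path <- system.file("extdata", "tissue_rules.csv", package = "mprct",
                        mustWork = TRUE)
    .rules_cache$table <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .rules_cache$table
}

#' Categorize a tissue element for response assessment
#'
#' Deterministic lookup in [tissue_rules()]. The only context-sensitive
#' element is a nodal deposit: `nodal_metastasis_encapsulated` with an intact
#' capsule stays outside the primary bed, but when `capsule_intact = FALSE`
#' the deposit is indistinguishable from direct extension and is treated as
#' `nodal_direct_extension` (viable tumor bed).
#'
#' @param kind Element kind; one of the values in `tissue_rules()$kind`.
#' @param capsule_intact For nodal deposits: is a well-defined capsule
#'   present and intact? Default `NA` (taken at face value of `kind`).
#' @return One of `"viable_tumor"`, `"necrosis"`, `"stroma"`,
#'   `"excluded_from_bed"`, `"not_primary_bed"`.
#' @examples
#' categorize("extracellular_mucin")    # "stroma"
#' categorize("empty_cystic_cavity")    # "excluded_from_bed"
#' categorize("nodal_direct_extension") # "viable_tumor"
#' @export
categorize <- function(kind, capsule_intact = NA) {
  rules <- tissue_rules()
  kind <- as.character(kind)
  stopifnot(length(kind) == 1L)
  if (!kind %in% rules$kind) {
    stop("unknown tissue element kind: '", kind, "'", call. = FALSE)
  }
  if (kind == "nodal_metastasis_encapsulated" && isFALSE(capsule_intact)) {
    kind <- "nodal_direct_extension"
  }
  rules$category[match(kind, rules$kind)]
}

#' Subtract excluded empty space from a slide's tumor-bed area
#'
#' Empty cystic cavities and other sizable empty spaces (e.g. bronchial
#' lumina) meet no component's criteria and are removed from the tumor-bed
#' denominator; the resulting effective area is the slide's weight in the
#' area-weighted means.
#'
#' @param bed_length_cm,bed_width_cm Measured bed rectangle (cm).
#' @param excluded_area_cm2 Total excluded empty-space area (cm^2).
#' @return Effective bed area in cm^2.
#' @examples
#' adjust_bed_for_exclusions(4, 3, 2)  # 10
#' @export
adjust_bed_for_exclusions <- function(bed_length_cm, bed_width_cm,
                                      excluded_area_cm2 = 0) {
  if (any(bed_length_cm < 0) || any(bed_width_cm < 0) ||
      any(excluded_area_cm2 < 0)) {
    stop("dimensions and excluded area must be non-negative", call. = FALSE)
  }
  area <- bed_length_cm * bed_width_cm - excluded_area_cm2
  if (any(area < 0)) {
    stop("excluded area exceeds the slide bed area", call. = FALSE)
  }
  area
}
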