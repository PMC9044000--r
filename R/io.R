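# The data-collection form on disk: a per-slide CSV (one row per slide),
# optionally preceded by "# key: value" comment lines carrying the case
# metadata (case_id, gross dimensions, node status). The JSON report is the
# tool's machine-readable output.

.case_header <- c("slide_id", "bed_length_cm", "bed_width_cm",
                  "pct_viable", "pct_necrosis")

#' Read a case from the data-collection CSV
#'
#' The normative layout: columns `slide_id`, `bed_length_cm`, `bed_width_cm`,
#' `pct_viable`, `pct_necrosis`, optionally `pct_stroma` and
#' `excluded_area_cm2`. The stroma column is never authoritative: the value
#' is re-derived as `100 - viable - necrosis` and a disagreeing column
#' triggers a warning (the derived value wins). Blank cells are kept as `NA`
#' so [validate_case()] can flag them. Lines starting with `#` before the
#' header may carry case metadata as `# key: value` pairs (`case_id`,
#' `gross_length_cm`, `gross_width_cm`, `gross_depth_cm`, `nodes_negative`,
#' `sampled_fraction`).
#'
#' @param path CSV file.
#' @param strict Reserved for the caller's validation pass; stored on the
#'   record is irrelevant — parsing itself is identical in both modes.
#' @return A [case_record()].
#' @export
read_case_csv <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    stop("format error: empty file '", path, "'", call. = FALSE)
  }
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(.case_header, names(df))
  if (length(missing_cols)) {
    stop("format error: header missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$slide_id <- as.character(df$slide_id)
  if (anyDuplicated(df$slide_id)) {
    stop("format error: duplicate slide_id: ",
         paste(unique(df$slide_id[duplicated(df$slide_id)]), collapse = ", "),
         call. = FALSE)
  }
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ml))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  num_meta <- function(key) {
    if (is.null(meta[[key]])) NA_real_ else as.numeric(meta[[key]])
  }
  derived <- derive_stroma(df$pct_viable, df$pct_necrosis)
  if (!is.null(df$pct_stroma)) {
    disagree <- !is.na(df$pct_stroma) & !is.na(derived) &
      abs(df$pct_stroma - derived) > 1e-6
    if (any(disagree)) {
      warning("pct_stroma column disagrees with 100 - viable - necrosis on ",
              sum(disagree), " slide(s); derived value used", call. = FALSE)
    }
  }
  slides <- slide_measurements(
    slide_id = df$slide_id,
    bed_length_cm = df$bed_length_cm,
    bed_width_cm = df$bed_width_cm,
    pct_viable = df$pct_viable,
    pct_necrosis = df$pct_necrosis,
    excluded_area_cm2 = if (is.null(df$excluded_area_cm2)) 0
                        else ifelse(is.na(df$excluded_area_cm2), 0,
                                    df$excluded_area_cm2)
  )
  nodes <- if (is.null(meta$nodes_negative)) {
    NA
  } else {
    as.logical(toupper(meta$nodes_negative))
  }
  case_record(
    case_id = if (is.null(meta$case_id)) {
      sub("\\.[^.]*$", "", basename(path))
    } else {
      meta$case_id
    },
    slides = slides,
    gross_length_cm = num_meta("gross_length_cm"),
    gross_width_cm = num_meta("gross_width_cm"),
    gross_depth_cm = num_meta("gross_depth_cm"),
    nodes_negative = nodes,
    sampled_fraction = num_meta("sampled_fraction")
  )
}

#' Write a case back to the data-collection CSV layout
#'
#' Inverse of [read_case_csv()]; metadata goes into `# key: value` comment
#' lines. Numbers are written with full precision and a period decimal
#' separator, so a valid case round-trips losslessly.
#'
#' @param case A [case_record()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_case_csv <- function(case, path) {
  stopifnot(inherits(case, "case_record"))
  meta <- c(
    paste0("# case_id: ", case$case_id),
    if (!is.na(case$gross_length_cm))
      paste0("# gross_length_cm: ", format(case$gross_length_cm, digits = 17)),
    if (!is.na(case$gross_width_cm))
      paste0("# gross_width_cm: ", format(case$gross_width_cm, digits = 17)),
    if (!is.na(case$gross_depth_cm))
      paste0("# gross_depth_cm: ", format(case$gross_depth_cm, digits = 17)),
    if (!is.na(case$nodes_negative))
      paste0("# nodes_negative: ", case$nodes_negative),
    if (!is.na(case$sampled_fraction))
      paste0("# sampled_fraction: ", format(case$sampled_fraction, digits = 17))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(case$slides, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the JSON report for a computed case
#'
#' A stable, machine-readable report: tool version and configuration, both
#' bases of every component mean (continuous and with 10%-increment
#' rounding), total bed area, classification with any node-status caveat,
#' validation findings and, when supplied, the sampling plan. Numbers are
#' serialized at full precision so a report round-trips bit-exactly.
#'
#' @param result An [mprct()] object.
#' @param findings Optional findings data.frame (defaults to the ones stored
#'   on `result`).
#' @param plan Optional [plan_sampling()] object.
#' @param path File to write; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_report <- function(result, findings = NULL, plan = NULL, path = NULL) {
  stopifnot(inherits(result, "mprct"))
  if (is.null(findings)) findings <- result$findings
  means <- result$means
  rounded <- round_iaslc(pmin(100, pmax(0, means)))
  dim(rounded) <- dim(means)
  dimnames(rounded) <- dimnames(means)
  doc <- list(
    tool = "mprct",
    version = as.character(utils::packageVersion("mprct")),
    case_id = result$case_id,
    config = list(basis = result$basis,
                  mpr_threshold = result$mpr_threshold),
    n_slides = result$n_slides,
    n_slides_with_bed = result$n_slides_with_bed,
    total_bed_area_cm2 = result$total_bed_area_cm2,
    means = list(
      continuous = list(
        unweighted = as.list(means["unweighted", ]),
        weighted = as.list(means["weighted", ])
      ),
      iaslc10 = list(
        unweighted = as.list(rounded["unweighted", ]),
        weighted = as.list(rounded["weighted", ])
      )
    ),
    classification = list(
      label = result$classification,
      mpr = result$mpr,
      pcr = result$pcr,
      nodes_negative = result$nodes_negative,
      qualifier = result$classification_qualifier
    ),
    findings = findings,
    plan = if (!is.null(plan)) unclass(plan)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           null = "null", na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}
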