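# Programmatic fixtures: random valid slide tables and a reference CSV body.

# n slides with integer percentages and positive bed dimensions
random_slides <- function(n, integer_pct = TRUE) {
  v <- sample(0:100, n, replace = TRUE)
  nx <- vapply(v, function(p) sample(0:(100 - p), 1L), integer(1))
  if (!integer_pct) {
    shrink <- stats::runif(n)
    v <- v * shrink
    nx <- nx * shrink
  }
  slide_measurements(
    slide_id = sprintf("S%03d", seq_len(n)),
    bed_length_cm = round(stats::runif(n, 0.1, 5), 2),
    bed_width_cm = round(stats::runif(n, 0.1, 4), 2),
    pct_viable = v,
    pct_necrosis = nx
  )
}

# the worked two-slide case: weighted 240/14, unweighted 47.5
worked_case_slides <- function() {
  slide_measurements(c("A1", "A2"), bed_length_cm = c(2, 4),
                     bed_width_cm = c(1, 3), pct_viable = c(90, 5),
                     pct_necrosis = c(0, 10))
}

write_fixture_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
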