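# independent pixel-grid oracle for the area-weighted mean: rasterize every
# slide's bed rectangle at a fine resolution and average cell values
rasterized_mean <- function(slides, component, res_cm = 0.01) {
  vals <- slides[[paste0("pct_", component)]]
  cells <- round(slides$bed_length_cm / res_cm) *
    round(slides$bed_width_cm / res_cm)
  sum(cells * vals) / sum(cells)
}

test_that("unweighted mean averages slides with bed present", {
  expect_equal(unweighted_mean(slide_measurements("A", 1, 1, 37, 0), "viable"), 37)
  s <- slide_measurements(c("A", "B", "C"), 2, 2, c(10, 20, 30), 0)
  expect_equal(unweighted_mean(s, "viable"), 20)
  expect_equal(unweighted_mean(worked_case_slides(), "viable"), 47.5)
  # a bed-free slide is retained but excluded from the average
  s0 <- rbind(s, slide_measurements("D", 0, 0, 0, 0))
  expect_equal(unweighted_mean(s0, "viable"), 20)
  expect_error(unweighted_mean(slide_measurements("Z", 0, 0, 0, 0), "viable"),
               "undefined")
})

test_that("weighted mean matches hand evaluation and a pixel-grid oracle", {
  s <- worked_case_slides()
  expect_equal(weighted_mean(s, "viable"), 240 / 14)
  expect_equal(weighted_mean(s, "viable"), rasterized_mean(s, "viable"))
  set.seed(99)
  for (i in 1:10) {
    r <- random_slides(sample(2:8, 1))
    for (comp in c("viable", "necrosis", "stroma")) {
      expect_equal(weighted_mean(r, comp), rasterized_mean(r, comp),
                   tolerance = 1e-12)
    }
  }
  expect_error(weighted_mean(slide_measurements("Z", 0, 0, 0, 0), "viable"),
               "undefined")
})

test_that("weighted mean is scale- and permutation-invariant and reduces to the unweighted mean", {
  set.seed(5)
  s <- random_slides(6)
  wm <- weighted_mean(s, "viable")
  s_scaled <- s
  s_scaled$bed_length_cm <- s$bed_length_cm * 3.7
  s_scaled$bed_width_cm <- s$bed_width_cm * 3.7
  s_scaled$excluded_area_cm2 <- s$excluded_area_cm2 * 3.7^2
  expect_equal(weighted_mean(s_scaled, "viable"), wm)
  perm <- sample(nrow(s))
  expect_equal(weighted_mean(s[perm, ], "viable"), wm)
  expect_equal(unweighted_mean(s[perm, ], "viable"), unweighted_mean(s, "viable"))
  # equal areas: weights cancel exactly
  eq <- s
  eq$bed_length_cm <- 2
  eq$bed_width_cm <- 1.5
  expect_equal(weighted_mean(eq, "viable"), unweighted_mean(eq, "viable"))
})

test_that("both means conserve the decomposition and respect per-slide bounds", {
  set.seed(12)
  for (i in 1:20) {
    s <- random_slides(sample(2:10, 1))
    uw <- vapply(c("viable", "necrosis", "stroma"),
                 function(cmp) unweighted_mean(s, cmp), numeric(1))
    wm <- vapply(c("viable", "necrosis", "stroma"),
                 function(cmp) weighted_mean(s, cmp), numeric(1))
    expect_equal(sum(uw), 100, tolerance = 1e-9)
    expect_equal(sum(wm), 100, tolerance = 1e-9)
    expect_gte(wm["viable"], min(s$pct_viable) - 1e-12)
    expect_lte(wm["viable"], max(s$pct_viable) + 1e-12)
    expect_gte(uw["viable"], min(s$pct_viable) - 1e-12)
    expect_lte(uw["viable"], max(s$pct_viable) + 1e-12)
  }
})

test_that("the 10%-increment rounding convention keeps single percents below 5", {
  expect_equal(round_iaslc(3.2), 3)
  expect_equal(round_iaslc(17.14), 20)
  expect_equal(round_iaslc(0), 0)
  expect_equal(round_iaslc(15), 20)   # half-up tie-break
  expect_equal(round_iaslc(4.6), 5)
  expect_equal(round_iaslc(100), 100)
  expect_error(round_iaslc(101), "out of")
  expect_error(round_iaslc(-0.1), "out of")
})

test_that("MPR boundary is inclusive and pCR requires zero viable plus nodes", {
  expect_equal(as.character(classify_response(10, c(5, 15))), "mpr")
  expect_equal(as.character(classify_response(10.5, c(5, 16))), "no_mpr")
  expect_equal(as.character(classify_response(0, c(0, 0), nodes_negative = TRUE)), "pcr")
  expect_equal(as.character(classify_response(0, c(0, 0), nodes_negative = FALSE)), "mpr")
  unk <- classify_response(0, c(0, 0), nodes_negative = NA)
  expect_equal(as.character(unk), "pcr")
  expect_equal(attr(unk, "qualifier"), "primary_tumor_only")
  # configurable histology-specific threshold
  expect_equal(as.character(classify_response(50, c(40, 60), mpr_threshold = 65)), "mpr")
})

test_that("mprct() composes means, classification and methods", {
  s <- worked_case_slides()
  fit <- mprct(s)
  expect_s3_class(fit, "mprct")
  expect_equal(fit$means["weighted", "viable"], 240 / 14)
  expect_equal(fit$means["unweighted", "viable"], 47.5)
  expect_equal(fit$classification, "no_mpr")
  expect_equal(fit$total_bed_area_cm2, 14)
  # basis switch changes the driving mean, not the report
  fitw <- mprct(s, basis = "weighted")
  expect_equal(fitw$classification, "no_mpr")
  expect_equal(coef(fit)[["viable.weighted"]], 240 / 14)
  expect_length(residuals(fit), 2)
  expect_equal(unname(residuals(fit)), c(90, 5) - 47.5)
  expect_output(print(fit), "no_mpr", ignore.case = TRUE)
  expect_output(print(summary(fit)), "Component means")
  # all-zero viable case classifies as pCR (primary tumor, nodes unknown)
  s0 <- slide_measurements(c("A", "B"), 2, 2, 0, c(10, 30))
  fit0 <- mprct(s0)
  expect_true(fit0$pcr)
  expect_equal(fit0$classification_qualifier, "primary_tumor_only")
  # threshold override
  s65 <- slide_measurements(c("A", "B"), 2, 2, c(40, 60), 0)
  expect_equal(mprct(s65, mpr_threshold = 65)$classification, "mpr")
  # validation errors block computation
  bad <- slide_measurements("A", 2, 1, 60, 50)
  expect_error(mprct(bad), "SUM_GT_100")
})

test_that("plot method draws without error", {
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  expect_silent(plot(mprct(worked_case_slides())))
  grDevices::dev.off()
  unlink(f)
})
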