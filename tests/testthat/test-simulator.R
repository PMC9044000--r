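test_that("simulated beds honor their quotas and patterns", {
  # pCR bed: no viable cells at all
  bed0 <- simulate_bed(4, "random", viable_pct = 0, necrosis_pct = 30,
                       seed = 2)
  expect_equal(bed0$truth_viable_pct, 0)
  expect_equal(sum(bed0$label_grid == 3L), 0)
  # quota construction: realized truth equals the request to quota resolution
  bed <- simulate_bed(4, "central", viable_pct = 20, necrosis_pct = 10,
                      seed = 2)
  expect_equal(bed$truth_viable_pct, 20, tolerance = 100 / bed$n_bed_cells)
  expect_equal(bed$truth_viable_pct,
               100 * sum(bed$label_grid == 3L) / bed$n_bed_cells)
  expect_equal(bed$truth_viable_pct + bed$truth_necrosis_pct +
                 bed$truth_stroma_pct, 100)
  expect_error(simulate_bed(4, "random", 70, 40, seed = 1), "infeasible")
})

test_that("peripheral viable cells sit farther from the centroid than stroma", {
  bed <- simulate_bed(6, "peripheral", viable_pct = 15, necrosis_pct = 25,
                      cavity_pct = 10, cell_size_cm = 0.05, seed = 4)
  n <- nrow(bed$label_grid)
  ctr <- (n / 2 + 0.5 - 0.5) * bed$cell_size_cm
  coords <- which(bed$label_grid > 0, arr.ind = TRUE)
  d <- sqrt(((coords[, 1] - 0.5) * bed$cell_size_cm - ctr)^2 +
              ((coords[, 2] - 0.5) * bed$cell_size_cm - ctr)^2)
  lab <- bed$label_grid[coords]
  expect_gt(mean(d[lab == 3L]), mean(d[lab == 1L]))
  # and the mirror property for a central bed
  bedc <- simulate_bed(6, "central", 15, 25, 0, 0.05, seed = 4)
  coords <- which(bedc$label_grid > 0, arr.ind = TRUE)
  d <- sqrt(((coords[, 1] - 0.5) * 0.05 - 3)^2 + ((coords[, 2] - 0.5) * 0.05 - 3)^2)
  lab <- bedc$label_grid[coords]
  expect_lt(mean(d[lab == 3L]), mean(d[lab == 1L]))
})

test_that("identical seeds reproduce grids, slides and reports exactly", {
  b1 <- simulate_bed(5, "random", 22, 18, 5, 0.05, seed = 77)
  b2 <- simulate_bed(5, "random", 22, 18, 5, 0.05, seed = 77)
  expect_identical(b1$label_grid, b2$label_grid)
  expect_identical(section_bed(b1), section_bed(b2))
  r1 <- evaluate_strategies(diameters_cm = 5, viable_levels = 12,
                            n_reps = 5, seed = 9)
  r2 <- evaluate_strategies(diameters_cm = 5, viable_levels = 12,
                            n_reps = 5, seed = 9)
  expect_identical(r1, r2)
})

test_that("sectioning schemes retain the expected slabs", {
  bed <- simulate_bed(6, "random", 20, 20, 0, 0.05, seed = 5)
  all_s <- section_bed(bed, 0.5, "all")
  expect_equal(nrow(all_s), 12)
  expect_equal(attr(all_s, "fraction_examined"), 1)
  alt <- section_bed(bed, 0.5, "alternate")
  expect_equal(nrow(alt), 6)  # 6 of 12 slabs
  alt1 <- section_bed(bed, 0.5, "alternate", offset = 1)
  expect_equal(nrow(alt1), 6)
  expect_false(identical(alt$slide_id, alt1$slide_id))
  one <- section_bed(bed, 0.5, "one_per_cm")
  expect_equal(nrow(one), 1)  # the single maximum-dimension cross-section
  expect_lt(attr(one, "fraction_examined"), 0.2)
  # small tumors are submitted entirely under every scheme
  small <- simulate_bed(2.5, "random", 20, 20, 0, 0.05, seed = 5)
  expect_equal(attr(section_bed(small, 0.5, "one_per_cm"), "fraction_examined"), 1)
})

test_that("homogeneous composition makes every slide match the truth", {
  bed <- simulate_bed(4, "random", 0, 0, 0, 0.05, seed = 8)  # all stroma
  sl <- section_bed(bed, 0.5, "all")
  expect_true(all(sl$pct_viable == 0))
  expect_true(all(sl$pct_stroma == 100))
})

test_that("full sectioning with the weighted mean is an exact oracle identity", {
  for (pat in c("random", "central", "peripheral")) {
    bed <- simulate_bed(5, pat, 17, 23, 8, 0.05, seed = 13)
    sl <- section_bed(bed, 0.5, "all")
    expect_equal(weighted_mean(sl, "viable"), bed$truth_viable_pct,
                 tolerance = 1e-9, info = pat)
    expect_equal(weighted_mean(sl, "necrosis"), bed$truth_necrosis_pct,
                 tolerance = 1e-9, info = pat)
  }
})

test_that("cavity area leaves the component percentages unchanged", {
  with_cav <- simulate_bed(4, "random", 30, 20, 50, 0.05, seed = 21)
  without <- simulate_bed(4, "random", 30, 20, 0, 0.05, seed = 21)
  v_cav <- weighted_mean(section_bed(with_cav), "viable")
  v_no <- weighted_mean(section_bed(without), "viable")
  expect_equal(v_cav, with_cav$truth_viable_pct, tolerance = 1e-9)
  expect_equal(v_no, without$truth_viable_pct, tolerance = 1e-9)
  expect_equal(v_cav, v_no, tolerance = 0.1)  # quota rounding only
})

test_that("the observer model conserves the decomposition", {
  bed <- simulate_bed(5, "random", 18, 30, 0, 0.05, seed = 6)
  sl <- section_bed(bed)
  expect_identical(apply_observer(sl, "continuous", noise_sd = 0), sl)
  rounded <- apply_observer(sl, "iaslc10", noise_sd = 0)
  expect_equal(rounded$pct_viable, round_iaslc(sl$pct_viable))
  one <- slide_measurements("A", 2, 1, 17.14, 10)
  expect_equal(apply_observer(one, "iaslc10")$pct_viable, 20)
  noisy <- apply_observer(sl, "continuous", noise_sd = 5, seed = 3)
  expect_true(all(abs(noisy$pct_viable + noisy$pct_necrosis +
                        noisy$pct_stroma - 100) < 1e-9))
  expect_true(all(noisy$pct_viable >= 0 & noisy$pct_viable <= 100))
  expect_true(all(noisy$pct_stroma >= 0))
  noisy10 <- apply_observer(sl, "iaslc10", noise_sd = 5, seed = 3)
  expect_true(all(noisy10$pct_viable + noisy10$pct_necrosis +
                    noisy10$pct_stroma == 100))
})

test_that("strategy reports satisfy their internal consistency invariants", {
  r <- evaluate_strategies(diameters_cm = 5, patterns = "central",
                           viable_levels = c(10.5, 40), n_reps = 20, seed = 15)
  expect_true(all(r$rmse >= abs(r$bias) - 1e-12))
  expect_true(all(r$mpr_misclassification_rate >= 0 &
                    r$mpr_misclassification_rate <= 1))
  expect_true(all(r$mean_fraction_examined > 0 &
                    r$mean_fraction_examined <= 1))
  full <- r[r$scheme == "all", ]
  expect_true(all(full$mpr_misclassification_rate == 0))
  expect_true(all(abs(full$bias) < 1e-9))
})

test_that("text export round-trips the label census", {
  bed <- simulate_bed(3, "random", 25, 25, 0, 0.1, seed = 30)
  lines <- export_bed_text(bed)
  chars <- unlist(strsplit(lines, ""))
  expect_equal(sum(chars == "v"),  sum(bed$label_grid == 3L))
  expect_equal(sum(chars == "."), sum(bed$label_grid == 0L))
})
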