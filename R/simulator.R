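# Synthetic tumor beds and virtual sectioning. The bed is a 2-D labeled grid
# (one gross cut face): labels are assigned by exact quota so the ground
# truth is known to the cell, and sectioning/observer models are the only
# sources of estimation error.

.lab_outside <- 0L
.lab_stroma <- 1L
.lab_necrosis <- 2L
.lab_viable <- 3L
.lab_cavity <- 4L

#' Simulate a labeled 2-D tumor bed
#'
#' Generates a circular tumor-bed footprint on a square grid and assigns
#' each in-bed cell one of viable tumor, necrosis, stroma or empty cavity.
#' Label counts are exact quotas of the in-bed cell count (cavity first, as
#' a fraction of the footprint; then viable and necrosis as fractions of the
#' remaining bed cells), so the realized ground-truth fractions are known
#' exactly and stored in the object. Spatial arrangement follows `pattern`:
#' `"central"` places viable cells nearest the centroid, `"peripheral"`
#' farthest (residual tumor along the lesion periphery), `"random"`
#' uniformly; necrosis occupies the positions adjacent to viable in the same
#' ordering, stroma the rest. The cavity, when present, is one contiguous
#' blob around a seeded random center.
#'
#' @param diameter_cm Bed diameter (cm).
#' @param pattern `"random"`, `"central"` or `"peripheral"` heterogeneity.
#' @param viable_pct,necrosis_pct Target percentages of the (non-cavity)
#'   tumor bed; `viable_pct + necrosis_pct <= 100`.
#' @param cavity_pct Target percentage of the footprint occupied by empty
#'   cavity (excluded from the bed denominator). Default 0.
#' @param cell_size_cm Grid resolution (cm per cell side). Default 0.05.
#' @param seed Integer seed; the grid is fully reproducible from it.
#' @return An object of class `tumor_bed_grid`: `label_grid` (integer
#'   matrix), `cell_size_cm`, `pattern`, `diameter_cm`,
#'   `truth_viable_pct`, `truth_necrosis_pct`, `truth_stroma_pct` (realized
#'   fractions of non-cavity bed cells, summing to 100), `n_bed_cells`,
#'   `n_cavity_cells`, `seed`.
#' @examples
#' bed <- simulate_bed(4, "central", viable_pct = 20, necrosis_pct = 10,
#'                     seed = 1)
#' bed$truth_viable_pct
#' @export
simulate_bed <- function(diameter_cm,
                         pattern = c("random", "central", "peripheral"),
                         viable_pct, necrosis_pct, cavity_pct = 0,
                         cell_size_cm = 0.05, seed = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(diameter_cm > 0, cell_size_cm > 0,
            viable_pct >= 0, necrosis_pct >= 0, cavity_pct >= 0,
            cavity_pct < 100)
  if (viable_pct + necrosis_pct > 100) {
    stop("viable_pct + necrosis_pct exceeds 100: infeasible quotas",
         call. = FALSE)
  }
  if (diameter_cm / cell_size_cm < 4) {
    stop("cell_size_cm too coarse for this diameter", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- as.integer(ceiling(diameter_cm / cell_size_cm))
  r <- diameter_cm / 2
  centers <- (seq_len(n) - 0.5) * cell_size_cm
  cx <- matrix(centers, n, n)
  cy <- matrix(centers, n, n, byrow = TRUE)
  d2 <- (cx - r)^2 + (cy - r)^2
  inside <- d2 <= r^2
  idx_in <- which(inside)
  n_in <- length(idx_in)
  if (n_in == 0L) stop("degenerate grid", call. = FALSE)

  grid <- matrix(.lab_outside, n, n)

  # cavity: contiguous blob of nearest cells to a random in-bed center
  n_cavity <- round(cavity_pct / 100 * n_in)
  if (n_cavity > 0) {
    center_cell <- idx_in[sample.int(n_in, 1L)]
    ccx <- cx[center_cell]
    ccy <- cy[center_cell]
    dist_to_c <- (cx[idx_in] - ccx)^2 + (cy[idx_in] - ccy)^2
    cavity_cells <- idx_in[order(dist_to_c)][seq_len(n_cavity)]
    grid[cavity_cells] <- .lab_cavity
    idx_bed <- setdiff(idx_in, cavity_cells)
  } else {
    idx_bed <- idx_in
  }
  n_bed <- length(idx_bed)
  n_viable <- round(viable_pct / 100 * n_bed)
  n_necrosis <- round(necrosis_pct / 100 * n_bed)
  if (n_viable + n_necrosis > n_bed) {
    stop("infeasible quotas after cavity placement", call. = FALSE)
  }

  ord <- switch(pattern,
    random = sample.int(n_bed),
    central = {
      # seeded jitter breaks distance ties among symmetric cells
      order(d2[idx_bed] + stats::runif(n_bed, 0, cell_size_cm^2 / 1e3))
    },
    peripheral = {
      order(-(d2[idx_bed] + stats::runif(n_bed, 0, cell_size_cm^2 / 1e3)))
    }
  )
  ranked <- idx_bed[ord]
  grid[ranked] <- .lab_stroma
  if (n_viable > 0) grid[ranked[seq_len(n_viable)]] <- .lab_viable
  if (n_necrosis > 0) {
    grid[ranked[n_viable + seq_len(n_necrosis)]] <- .lab_necrosis
  }

  structure(
    list(label_grid = grid,
         cell_size_cm = cell_size_cm,
         pattern = pattern,
         diameter_cm = diameter_cm,
         truth_viable_pct = 100 * n_viable / n_bed,
         truth_necrosis_pct = 100 * n_necrosis / n_bed,
         truth_stroma_pct = 100 * (n_bed - n_viable - n_necrosis) / n_bed,
         n_bed_cells = n_bed,
         n_cavity_cells = n_cavity,
         seed = seed),
    class = "tumor_bed_grid"
  )
}

#' @export
print.tumor_bed_grid <- function(x, ...) {
  cat("Simulated tumor bed:", x$diameter_cm, "cm diameter,",
      x$pattern, "pattern,", x$cell_size_cm, "cm cells\n")
  cat(sprintf("  truth: %.2f%% viable, %.2f%% necrosis, %.2f%% stroma",
              x$truth_viable_pct, x$truth_necrosis_pct, x$truth_stroma_pct))
  if (x$n_cavity_cells > 0) cat(" (+", x$n_cavity_cells, "cavity cells)")
  cat("\n")
  invisible(x)
}

#' Export a simulated bed as a plain-text label matrix
#'
#' One character per cell: `.` outside, `s` stroma, `n` necrosis, `v`
#' viable, `c` cavity.
#'
#' @param grid A `tumor_bed_grid`.
#' @param path File to write; when `NULL` the lines are returned invisibly.
#' @return Character vector of lines, invisibly.
#' @export
export_bed_text <- function(grid, path = NULL) {
  chars <- c(".", "s", "n", "v", "c")
  m <- matrix(chars[grid$label_grid + 1L], nrow(grid$label_grid))
  lines <- apply(m, 1, paste0, collapse = "")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Virtually section a simulated bed into slides
#'
#' Cuts the bed into parallel slabs of `slab_thickness_cm` and converts each
#' retained slab into a slide measurement the way a pathologist would record
#' it: `bed_length_cm` and `bed_width_cm` are the slab's best-fitted
#' rectangle around the bed footprint, the component percentages are the
#' slab's in-bed label fractions (cavity cells meet no component's criteria
#' and are excluded from the denominator), and `excluded_area_cm2` is the
#' part of the measured rectangle not occupied by bed tissue (cavity plus
#' the rectangle's overhang beyond the curved bed edge), so the slide's
#' effective weight is its true bed area.
#'
#' Schemes: `"all"` retains every slab (complete submission); `"alternate"`
#' every other slab starting at `offset + 1` (the >= 50% strategy);
#' `"one_per_cm"` models the legacy standard for tumors over 3 cm — the
#' single slab at the maximum dimension (the most representative
#' cross-section), which is why its examined fraction shrinks as the tumor
#' grows. At or below 3 cm `"one_per_cm"` retains all slabs (such tumors are
#' submitted entirely under every strategy).
#'
#' @param grid A `tumor_bed_grid`.
#' @param slab_thickness_cm Slab thickness (default 0.5 cm); should be a
#'   multiple of the grid cell size.
#' @param scheme `"all"`, `"alternate"` or `"one_per_cm"`.
#' @param offset Starting offset (0 or 1) for the alternate scheme.
#' @return Slide table as from [slide_measurements()], one row per retained
#'   slab containing bed tissue, with attributes `fraction_examined`
#'   (share of bed cells on retained slides) and `n_slabs_total`.
#' @export
section_bed <- function(grid, slab_thickness_cm = 0.5,
                        scheme = c("all", "alternate", "one_per_cm"),
                        offset = 0) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(grid, "tumor_bed_grid"))
  cell <- grid$cell_size_cm
  g <- grid$label_grid
  n <- nrow(g)
  cols_per_slab <- slab_thickness_cm / cell
  if (abs(cols_per_slab - round(cols_per_slab)) > 1e-8) {
    stop("slab_thickness_cm must be a multiple of the grid cell size",
         call. = FALSE)
  }
  cols_per_slab <- as.integer(round(cols_per_slab))
  slab_of_col <- ((seq_len(n) - 1L) %/% cols_per_slab) + 1L
  n_slabs <- max(slab_of_col)

  per_slab <- lapply(seq_len(n_slabs), function(k) {
    cols <- which(slab_of_col == k)
    sub <- g[, cols, drop = FALSE]
    in_bed <- sub != .lab_outside           # bed footprint incl. cavity
    if (!any(in_bed)) return(NULL)
    rows_used <- range(which(rowSums(in_bed) > 0))
    cols_used <- range(which(colSums(in_bed) > 0))
    # best-fitted rectangle around the bed footprint on this slide
    w <- (rows_used[2] - rows_used[1] + 1L) * cell
    l <- (cols_used[2] - cols_used[1] + 1L) * cell
    n_cavity <- sum(sub == .lab_cavity)
    n_tissue <- sum(in_bed) - n_cavity
    if (n_tissue == 0L) return(NULL)
    v <- 100 * sum(sub == .lab_viable) / n_tissue
    nx <- 100 * sum(sub == .lab_necrosis) / n_tissue
    list(slab = k, l = l, w = w,
         v = v, nx = nx,
         excl = l * w - n_tissue * cell^2,
         n_tissue = n_tissue)
  })
  per_slab <- per_slab[!vapply(per_slab, is.null, logical(1))]
  n_with_bed <- length(per_slab)
  if (n_with_bed == 0L) stop("no bed tissue in any slab", call. = FALSE)

  keep <- switch(scheme,
    all = seq_len(n_with_bed),
    alternate = seq(1L + (offset %% 2L), n_with_bed, by = 2L),
    one_per_cm = {
      if (grid$diameter_cm <= 3) {
        seq_len(n_with_bed)
      } else {
        # the single most representative cross-section: widest bed extent
        which.max(vapply(per_slab, function(s) s$n_tissue, numeric(1)))
      }
    }
  )
  kept <- per_slab[keep]
  slides <- slide_measurements(
    slide_id = sprintf("S%02d", vapply(kept, function(s) s$slab, numeric(1))),
    bed_length_cm = vapply(kept, function(s) s$l, numeric(1)),
    bed_width_cm = vapply(kept, function(s) s$w, numeric(1)),
    pct_viable = vapply(kept, function(s) s$v, numeric(1)),
    pct_necrosis = vapply(kept, function(s) s$nx, numeric(1)),
    excluded_area_cm2 = vapply(kept, function(s) s$excl, numeric(1))
  )
  tissue_total <- sum(vapply(per_slab, function(s) s$n_tissue, numeric(1)))
  attr(slides, "fraction_examined") <-
    sum(vapply(kept, function(s) s$n_tissue, numeric(1))) / tissue_total
  attr(slides, "n_slabs_total") <- n_with_bed
  slides
}

#' Apply an observer model to slide measurements
#'
#' Simulates how a pathologist records the slide: optional Gaussian reading
#' noise on the viable and necrosis percentages (truncated so each stays in
#' \[0, 100\] and their sum at most 100), then optional rounding by the
#' 10%-increment convention ([round_iaslc()]). Stroma is re-derived, so the
#' three components always sum to 100.
#'
#' @param slides Slide table.
#' @param rounding `"continuous"` (record as measured) or `"iaslc10"`.
#' @param noise_sd Standard deviation of reading noise in percentage points.
#' @param seed Optional integer seed.
#' @return Slide table with perturbed/rounded `pct_viable`, `pct_necrosis`
#'   and re-derived `pct_stroma`.
#' @export
apply_observer <- function(slides, rounding = c("continuous", "iaslc10"),
                           noise_sd = 0, seed = NULL) {
  rounding <- match.arg(rounding)
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- slides$pct_viable
  nx <- slides$pct_necrosis
  if (noise_sd > 0) {
    v <- pmin(100, pmax(0, v + stats::rnorm(length(v), 0, noise_sd)))
    nx <- pmin(100 - v, pmax(0, nx + stats::rnorm(length(nx), 0, noise_sd)))
  }
  if (rounding == "iaslc10") {
    v <- round_iaslc(v)
    nx <- pmin(100 - v, round_iaslc(nx))
  }
  slides$pct_viable <- v
  slides$pct_necrosis <- nx
  slides$pct_stroma <- 100 - v - nx
  slides
}

#' Benchmark sampling strategies by Monte-Carlo simulation
#'
#' For every combination of diameter, heterogeneity pattern, true viable
#' level and sectioning scheme, repeatedly simulates a bed, sections it,
#' optionally applies the observer model, estimates the mean viable tumor
#' with [weighted_mean()] (or the unweighted mean) and classifies MPR at the
#' configured threshold. Reports bias and RMSE of the estimate against the
#' bed's exact ground truth, the MPR misclassification rate versus the truth
#' label, and the mean fraction of bed examined.
#'
#' @param diameters_cm,patterns,viable_levels,schemes Vectors defining the
#'   simulation grid.
#' @param necrosis_pct True necrosis percentage (single value; default 30).
#' @param cavity_pct Cavity percentage of the footprint (default 0).
#' @param n_reps Monte-Carlo replicates per stratum (default 200).
#' @param cell_size_cm Grid resolution (default 0.05).
#' @param slab_thickness_cm Section thickness (default 0.5).
#' @param rounding,noise_sd Observer model; defaults record continuous
#'   values with no noise.
#' @param mpr_threshold MPR cutoff (default 10).
#' @param basis `"weighted"` (default) or `"unweighted"` estimator.
#' @param seed Integer seed; replicate seeds are derived from it, so the
#'   whole report is reproducible.
#' @return A data.frame of class `strategy_report`: one row per stratum with
#'   `bias`, `rmse`, `mpr_misclassification_rate`, `mean_fraction_examined`,
#'   `n_reps`.
#' @export
evaluate_strategies <- function(diameters_cm = 7,
                                patterns = "random",
                                viable_levels = c(10.5, 40),
                                schemes = c("all", "alternate", "one_per_cm"),
                                necrosis_pct = 30, cavity_pct = 0,
                                n_reps = 200, cell_size_cm = 0.05,
                                slab_thickness_cm = 0.5,
                                rounding = "continuous", noise_sd = 0,
                                mpr_threshold = 10,
                                basis = c("weighted", "unweighted"),
                                seed = 1L) {
  basis <- match.arg(basis)
  stopifnot(n_reps >= 1)
  est_fun <- if (basis == "weighted") weighted_mean else unweighted_mean
  grid_cfg <- expand.grid(diameter_cm = diameters_cm, pattern = patterns,
                          truth_target = viable_levels,
                          stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(grid_cfg))) {
    cfg <- grid_cfg[i, ]
    est <- matrix(NA_real_, n_reps, length(schemes),
                  dimnames = list(NULL, schemes))
    frac <- est
    truth <- numeric(n_reps)
    for (rep in seq_len(n_reps)) {
      rep_seed <- (as.integer(seed) + 7919L * i + rep) %% .Machine$integer.max
      bed <- simulate_bed(cfg$diameter_cm, cfg$pattern,
                          viable_pct = cfg$truth_target,
                          necrosis_pct = necrosis_pct,
                          cavity_pct = cavity_pct,
                          cell_size_cm = cell_size_cm, seed = rep_seed)
      truth[rep] <- bed$truth_viable_pct
      for (sc in schemes) {
        slides <- section_bed(bed, slab_thickness_cm, scheme = sc)
        if (noise_sd > 0 || rounding != "continuous") {
          slides <- apply_observer(slides, rounding = rounding,
                                   noise_sd = noise_sd,
                                   seed = rep_seed + 17L)
        }
        est[rep, sc] <- est_fun(slides, "viable")
        frac[rep, sc] <- attr(slides, "fraction_examined")
      }
    }
    for (sc in schemes) {
      err <- est[, sc] - truth
      mis <- mean((est[, sc] <= mpr_threshold) != (truth <= mpr_threshold))
      out[[length(out) + 1L]] <- data.frame(
        scheme = sc, diameter_cm = cfg$diameter_cm, pattern = cfg$pattern,
        truth_viable_pct = cfg$truth_target,
        bias = mean(err), rmse = sqrt(mean(err^2)),
        mpr_misclassification_rate = mis,
        mean_fraction_examined = mean(frac[, sc]),
        n_reps = n_reps, stringsAsFactors = FALSE
      )
    }
  }
  report <- do.call(rbind, out)
  class(report) <- c("strategy_report", "data.frame")
  report
}
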