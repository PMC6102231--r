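test_that("combined shift perturbation matches hand-evaluated values", {
  ref <- make_peaklist(1:2, cs_h = 8.0, cs_n = 120)
  cond <- peaklist(tibble::tibble(
    residue = 1:2, aa = "X",
    cs_h_ppm = c(8.02, 8.0),
    cs_n_ppm = c(120.10, 120.5),
    intensity = 1
  ), ligand_conc = 600)
  csp <- compute_csp(ref, cond)
  # sqrt((0.02^2 + 0.10^2/25)/2) = sqrt((4e-4 + 4e-4)/2) = 0.02
  expect_equal(csp$csp[1], 0.02, tolerance = 1e-12)
  # sqrt((0 + 0.5^2/25)/2) = sqrt(0.005)
  expect_equal(csp$csp[2], sqrt(0.005), tolerance = 1e-12)
  expect_equal(csp$delta_h, c(0.02, 0))
  expect_equal(csp$delta_n, c(0.10, 0.5))

  expect_equal(compute_csp(ref, ref)$csp, c(0, 0))
  expect_error(compute_csp(ref, cond, scale_n = 0), "positive")
  expect_error(
    compute_csp(ref, make_peaklist(10:12, 8, 120, ligand_conc = 1)),
    "no residues shared")
})

test_that("CSP is symmetric and monotone in the nitrogen difference", {
  set.seed(42)
  for (i in 1:25) {
    a <- random_peaklist(8)
    b <- random_peaklist(8, ligand_conc = 100)
    expect_equal(compute_csp(a, b)$csp, compute_csp(b, a)$csp,
                 tolerance = 1e-12)
  }
  # growing |delta_n| at fixed delta_h never decreases the CSP
  ref <- make_peaklist(1, 8, 120)
  csps <- vapply(seq(0, 2, by = 0.1), function(dn) {
    cond <- make_peaklist(1, 8.01, 120 + dn, ligand_conc = 1)
    compute_csp(ref, cond)$csp
  }, numeric(1))
  expect_true(all(diff(csps) >= 0))
})

test_that("intensity change is an absolute percentage of the reference", {
  ref <- make_peaklist(1:3, 8, 120, intensity = c(100, 100, 50))
  cond <- make_peaklist(1:3, 8, 120, intensity = c(25, 120, 50),
                        ligand_conc = 600)
  ic <- compute_intensity_change(ref, cond)
  expect_equal(ic$intensity_change_pct, c(75, 20, 0))

  # zero-reference residues are excluded, with a report
  ref0 <- make_peaklist(1:2, 8, 120, intensity = c(0, 100))
  cond0 <- make_peaklist(1:2, 8, 120, intensity = c(1, 50),
                         ligand_conc = 10)
  expect_message(ic0 <- compute_intensity_change(ref0, cond0),
                 "zero reference intensity")
  expect_identical(ic0$residue, 2L)
  expect_identical(attr(ic0, "excluded"), 1L)
})

test_that("significance requires exceeding both threshold lines", {
  expect_equal(compute_thresholds(rep(0, 140))$black_line, 0)

  vals <- c(rep(0.01, 139), 0.10)
  thr <- compute_thresholds(vals, orange_floor = 0.02)
  expect_equal(thr$orange_line, 0.02)
  sig <- which(vals > thr$black_line & vals > thr$orange_line)
  expect_identical(sig, 140L)

  expect_error(compute_thresholds(0.1), "at least 2")

  # identical replicate apo spectra imply zero spectral variability
  apo1 <- random_peaklist(5)
  rep_vals <- replicate_variability(list(apo1, apo1), "csp")
  expect_equal(max(rep_vals), 0)
  thr2 <- compute_thresholds(vals, rep_vals, orange_floor = 0.02)
  expect_equal(thr2$orange_line, 0)
})

test_that("thresholds ignore residues that are not observable", {
  set.seed(8)
  ref <- random_peaklist(20)
  cond_tbl <- tibble::as_tibble(random_peaklist(20, ligand_conc = 600))
  cond_tbl$intensity[5] <- 0.001   # below the floor: broadened
  cond <- peaklist(cond_tbl, ligand_conc = 600)
  prof <- perturbation_profile(ref, cond, map = region_map(
    data.frame(region = "all", first = 1, last = 20)),
    noise_floor = 0.01)
  ok_csp <- prof$csp[prof$status == "ok"]
  thr <- attr(prof, "thresholds")$csp
  expect_equal(thr$black_line, mean(ok_csp) + sd(ok_csp))
  expect_true(all(prof$status[prof$significant_csp] == "ok"))
  # dropping the non-ok residue leaves the thresholds unchanged
  expect_equal(compute_thresholds(ok_csp)$black_line, thr$black_line)
})

test_that("broadened-beyond-detection classification follows the rule", {
  set.seed(5)
  ref <- random_peaklist(140)
  map <- default_region_map()

  expect_true(all(classify_broadened(ref, ref)$status == "ok"))

  # deleting the C-terminal peaks broadens exactly that region
  cond_tbl <- dplyr::filter(tibble::as_tibble(ref), residue < 96)
  cond <- peaklist(cond_tbl, ligand_conc = 600)
  st <- classify_broadened(ref, cond, map = map)
  tally <- tally_broadened(st)
  expect_identical(tally$n_broadened, c(0L, 0L, 45L))

  # an intensity below the detection floor is broadened too
  cond_tbl2 <- tibble::as_tibble(ref)
  cond_tbl2$intensity[cond_tbl2$residue == 30] <- 0.0001
  cond2 <- peaklist(cond_tbl2, ligand_conc = 600)
  st2 <- classify_broadened(ref, cond2, noise_floor = 0.01, map = map)
  expect_identical(st2$status[st2$residue == 30], factor(
    "broadened", levels = c("ok", "broadened", "absent_in_reference")))
  expect_identical(tally_broadened(st2)$n_broadened, c(1L, 0L, 0L))

  # peaks only present with ligand are flagged, never called broadened
  extra <- peaklist(dplyr::bind_rows(
    cond_tbl2, tibble::tibble(residue = 141L, aa = "X", cs_h_ppm = 8,
                              cs_n_ppm = 120, intensity = 1,
                              lw_n_hz = NA_real_)), ligand_conc = 600)
  st3 <- classify_broadened(ref, extra)
  expect_identical(as.character(st3$status[st3$residue == 141]),
                   "absent_in_reference")
})

test_that("per-region broadening tallies always sum to the total", {
  set.seed(99)
  map <- default_region_map()
  for (i in 1:50) {
    ref <- random_peaklist(140)
    keep <- sort(sample(140, sample(60:140, 1)))
    cond_tbl <- dplyr::filter(tibble::as_tibble(ref), residue %in% keep)
    cond_tbl$intensity <- cond_tbl$intensity * runif(nrow(cond_tbl), 0, 2)
    cond <- peaklist(cond_tbl, ligand_conc = 100)
    st <- classify_broadened(ref, cond, noise_floor = 0.2, map = map)
    tally <- tally_broadened(st)
    expect_identical(sum(tally$n_broadened),
                     sum(st$status == "broadened"))
  }
})

test_that("line-width differences use the condition-minus-reference sign", {
  ref <- make_peaklist(1:3, 8, 120, lw = c(30, 20, 25))
  cond <- make_peaklist(1:3, 8, 120, lw = c(20, 28, 25), ligand_conc = 10)
  lw <- compute_linewidth_diff(ref, cond, dead_band = 5)
  expect_equal(lw$delta_lw, c(-10, 8, 0))
  expect_identical(as.character(lw$classification),
                   c("narrowing", "broadening", "unchanged"))

  lw0 <- compute_linewidth_diff(ref, ref)
  expect_true(all(lw0$delta_lw == 0))
  expect_true(all(lw0$classification == "unchanged"))

  bare <- make_peaklist(1:3, 8, 120)  # no line widths at all
  expect_error(compute_linewidth_diff(ref, bare), "line width")
})

test_that("waterlogsy ratios divide by the ligand-alone intensity", {
  free <- tibble::tibble(signal_label = c("H1", "H2", "H3", "H4"),
                         intensity = c(100, 100, 0, 50))
  bound <- tibble::tibble(signal_label = c("H1", "H2", "H3", "H5"),
                          intensity = c(100, 80, 10, 7))
  expect_message(r <- waterlogsy_ratio(free, bound), "excluding")
  expect_equal(r$ratio[r$signal_label == "H1"], 1.0)
  expect_equal(r$ratio[r$signal_label == "H2"], 0.8)
  expect_setequal(attr(r, "excluded"), c("H3", "H4", "H5"))
})

test_that("statistics agree with brute-force recomputation to 1e-9", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    ref <- random_peaklist(n)
    cond <- random_peaklist(n, ligand_conc = 200)
    oracle <- brute_force_stats(ref, cond)
    csp <- compute_csp(ref, cond)
    ic <- compute_intensity_change(ref, cond)
    expect_equal(csp$csp, oracle$csp, tolerance = 1e-9)
    expect_equal(ic$intensity_change_pct, oracle$pct, tolerance = 1e-9)
  }
})
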