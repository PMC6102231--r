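printed_concs <- c(10, 20, 40, 100, 200, 400, 600, 1000)

test_that("C-terminal intensity response measures mean attenuation", {
  set.seed(2)
  ref <- random_peaklist(140)
  map <- default_region_map()
  halve <- function(pl, f, L) {
    tbl <- tibble::as_tibble(pl)
    ct <- tbl$residue >= 96
    tbl$intensity[ct] <- tbl$intensity[ct] * f
    peaklist(tbl, ligand_conc = L)
  }
  ser <- titration_series(ref, list(
    halve(ref, 1, 10), halve(ref, 0.5, 100), halve(ref, 0.25, 600)))
  resp <- cterm_intensity_response(ser, map)
  ct_mean <- mean(ref$intensity[ref$residue >= 96])
  expect_equal(resp$response, c(0, 0.5 * ct_mean, 0.75 * ct_mean),
               tolerance = 1e-12)
  expect_identical(resp$n_residues, rep(45L, 3))
  expect_false(attr(resp, "lower_limit"))

  # identical conditions give a zero response everywhere
  same <- titration_series(ref, list(
    halve(ref, 1, 10), halve(ref, 1, 100), halve(ref, 1, 600)))
  expect_equal(cterm_intensity_response(same, map)$response, c(0, 0, 0))

  expect_error(cterm_intensity_response(
    titration_series(ref, list(halve(ref, 1, 10), halve(ref, 1, 20))),
    map), "at least 3")
})

test_that("broadened residues count as fully attenuated in the response", {
  set.seed(4)
  ref <- random_peaklist(140)
  map <- default_region_map()
  drop_ct <- function(pl, drop, L) {
    tbl <- dplyr::filter(tibble::as_tibble(pl), !residue %in% drop)
    peaklist(tbl, ligand_conc = L)
  }
  ser <- titration_series(ref, list(
    drop_ct(ref, integer(0), 10),
    drop_ct(ref, 130:140, 100),
    drop_ct(ref, 120:140, 600)))
  resp <- cterm_intensity_response(ser, map)
  expect_identical(resp$n_broadened, c(0L, 11L, 21L))
  expect_true(attr(resp, "lower_limit"))
  # zero-substitution: each broadened residue contributes its full
  # reference intensity to the mean difference
  expected <- mean(ref$intensity[ref$residue %in% 130:140] ) * 11 / 45
  expect_equal(resp$response[2],
               sum(ref$intensity[ref$residue %in% 130:140]) / 45,
               tolerance = 1e-12)
  # with exclusion instead, the response is zero (remaining peaks equal)
  resp2 <- cterm_intensity_response(ser, map, broadened_zero = FALSE)
  expect_equal(resp2$response, c(0, 0, 0))
  expect_false(attr(resp2, "lower_limit"))
})

test_that("the saturation fit recovers an exact single-site curve", {
  y <- 1 * printed_concs / (100 + printed_concs)
  fit <- fit_saturation(tibble::tibble(ligand_conc = printed_concs,
                                       response = y))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["kd"]), 100, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["bmax"]), 1, tolerance = 1e-6)
  # half-saturation at L = Kd, by the model's closed form
  expect_equal(
    unname(predict(fit, tibble::tibble(ligand_conc = coef(fit)["kd"]))),
    unname(coef(fit)["bmax"]) / 2, tolerance = 1e-9)
  # tidy/glance expose the parameters
  td <- tidy(fit)
  expect_setequal(td$term, c("bmax", "kd"))
  expect_true(glance(fit)$converged)
  expect_error(fit_saturation(tibble::tibble(
    ligand_conc = printed_concs, response = rep(1, 8))), "all equal")
})

test_that("the saturation fit is scale-equivariant", {
  set.seed(21)
  y <- 2 * printed_concs / (250 + printed_concs) +
    rnorm(8, 0, 0.02)
  f1 <- fit_saturation(tibble::tibble(ligand_conc = printed_concs,
                                      response = y))
  f2 <- fit_saturation(tibble::tibble(ligand_conc = printed_concs,
                                      response = 10 * y))
  expect_equal(unname(coef(f2)["kd"]), unname(coef(f1)["kd"]),
               tolerance = 1e-6)
  expect_equal(unname(coef(f2)["bmax"]), 10 * unname(coef(f1)["bmax"]),
               tolerance = 1e-6)
})

test_that("the Hill fit recovers exact curves and nests the hyperbola", {
  # noiseless n = 5 curves for two reporter residues
  set.seed(31)
  fits <- lapply(c(118.2, 124.7), function(d0) {
    y <- d0 + 0.5 * hill_occupancy(printed_concs, 292, 5)
    fit_hill(tibble::tibble(ligand_conc = printed_concs, shift = y))
  })
  avg <- average_hill(fits)
  expect_equal(avg$mean_hill_n, 5, tolerance = 1e-4)
  expect_equal(unname(coef(fits[[1]])["k"]), 292, tolerance = 1e-3)

  # half-amplitude at L = K for any exponent
  f <- fits[[1]]
  expect_equal(
    unname(predict(f, tibble::tibble(ligand_conc = coef(f)["k"]))),
    unname(coef(f)["delta0"] + coef(f)["ddmax"] / 2),
    tolerance = 1e-9)

  # with n = 1 the model reduces to saturation: same midpoint
  y1 <- 120 + 0.8 * printed_concs / (150 + printed_concs)
  fh <- fit_hill(tibble::tibble(ligand_conc = printed_concs, shift = y1))
  fs <- fit_saturation(tibble::tibble(ligand_conc = printed_concs,
                                      response = y1 - 120))
  expect_equal(unname(coef(fh)["hill_n"]), 1, tolerance = 1e-3)
  expect_equal(unname(coef(fh)["k"]), unname(coef(fs)["kd"]),
               tolerance = 1e-2)
  # and fixing n = 1 gives the same answer as the free fit here
  fx <- fit_hill(tibble::tibble(ligand_conc = printed_concs, shift = y1),
                 fix_n = 1)
  expect_equal(unname(coef(fx)["k"]), unname(coef(fs)["kd"]),
               tolerance = 1e-4)
})

test_that("averaging Hill exponents is a plain arithmetic mean", {
  mk <- function(n) {
    y <- 120 + 0.5 * hill_occupancy(printed_concs, 292, n)
    fit_hill(tibble::tibble(ligand_conc = printed_concs, shift = y))
  }
  f4 <- mk(4); f6 <- mk(6)
  avg <- average_hill(list(f4, f6))
  expect_equal(avg$mean_hill_n, 5, tolerance = 1e-3)
  expect_equal(nrow(avg$per_fit), 2)
  expect_equal(average_hill(f4)$mean_hill_n,
               unname(coef(f4)["hill_n"]))

  broken <- f4
  broken$converged <- FALSE
  expect_error(average_hill(list(broken, f6)), "non-converged")
  expect_error(average_hill(list(fit_saturation(tibble::tibble(
    ligand_conc = printed_concs,
    response = printed_concs / (100 + printed_concs))))), "not a Hill")
})

test_that("parameter recovery holds under 5% noise at the printed design", {
  set.seed(104729)
  kd_hat <- replicate(100, {
    y <- printed_concs / (292 + printed_concs) + rnorm(8, 0, 0.05)
    f <- fit_saturation(tibble::tibble(ligand_conc = printed_concs,
                                       response = y))
    if (f$converged) unname(coef(f)["kd"]) else NA_real_
  })
  expect_lt(abs(median(kd_hat, na.rm = TRUE) - 292) / 292, 0.15)

  n_hat <- replicate(100, {
    y <- 120 + 0.5 * hill_occupancy(printed_concs, 292, 5) +
      rnorm(8, 0, 0.025)
    f <- fit_hill(tibble::tibble(ligand_conc = printed_concs, shift = y))
    if (f$converged) unname(coef(f)["hill_n"]) else NA_real_
  })
  expect_lt(abs(median(n_hat, na.rm = TRUE) - 5) / 5, 0.20)
})
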