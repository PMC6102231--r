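#' C-terminal mean intensity-difference response
#'
#' Builds the concentration response used for dissociation-constant
#' estimation: at each ligand concentration, the mean peak intensity
#' over C-terminal residues is subtracted from the corresponding apo
#' mean, giving the attenuation of the C-terminal signal envelope as a
#' saturating, non-negative response. Residues broadened beyond
#' detection contribute zero intensity in the condition (maximal
#' attenuation) rather than being dropped, so the response is not biased
#' downward at high ligand; set `broadened_zero = FALSE` to drop them
#' instead. When any broadened residue contributed, the resulting Kd is
#' best read as a lower limit (see [fit_saturation()]).
#'
#' @param series A [titration_series].
#' @param map A [region_map] whose last segment need not be named
#'   "C-terminal"; the segment used is selected by `region`.
#' @param region Name of the segment to average over (default
#'   `"C-terminal"`).
#' @param noise_floor Detection floor passed to [classify_broadened()].
#' @param broadened_zero Substitute zero intensity for broadened
#'   residues (default) instead of excluding them.
#' @return A tibble with one row per condition: `ligand_conc` (µM),
#'   `response` (mean reference minus mean condition intensity), `sem`
#'   (standard error over residues of the per-residue differences),
#'   `n_residues`, `n_broadened`. Attribute `lower_limit` is `TRUE` when
#'   any broadened residue contributed anywhere in the series.
#' @export
cterm_intensity_response <- function(series, map = default_region_map(),
                                     region = "C-terminal",
                                     noise_floor = 0,
                                     broadened_zero = TRUE) {
  stopifnot(inherits(series, "titration_series"),
            inherits(map, "region_map"))
  if (!region %in% map$region) {
    stop("region '", region, "' is not in the map", call. = FALSE)
  }
  if (length(series$conditions) < 3) {
    stop("need at least 3 titration conditions for a binding response",
         call. = FALSE)
  }
  ref <- tibble::as_tibble(series$reference)
  ref$region <- classify_region(ref$residue, map)
  ref_ct <- dplyr::filter(ref, .data$region == !!region)
  if (nrow(ref_ct) == 0) {
    stop("reference has no peaks in region '", region, "'", call. = FALSE)
  }

  rows <- purrr::map(series$conditions, function(cond) {
    conc <- attr(cond, "ligand_conc")
    status <- classify_broadened(series$reference, cond,
                                 noise_floor = noise_floor, map = map)
    st_ct <- dplyr::filter(status, .data$region == !!region,
                           .data$status != "absent_in_reference")
    cond_int <- tibble::as_tibble(cond) |>
      dplyr::select("residue", intensity_cond = "intensity")
    d <- st_ct |>
      dplyr::left_join(dplyr::select(ref_ct, "residue",
                                     intensity_ref = "intensity"),
                       by = "residue") |>
      dplyr::left_join(cond_int, by = "residue") |>
      dplyr::mutate(intensity_cond = dplyr::case_when(
        .data$status == "broadened" ~ 0,
        TRUE ~ .data$intensity_cond
      ))
    if (!broadened_zero) d <- dplyr::filter(d, .data$status == "ok")
    if (nrow(d) == 0) {
      stop("no usable '", region, "' residues at ligand concentration ",
           conc, " uM", call. = FALSE)
    }
    diff <- d$intensity_ref - d$intensity_cond
    tibble::tibble(
      ligand_conc = conc,
      response = mean(diff),
      sem = stats::sd(diff) / sqrt(length(diff)),
      n_residues = length(diff),
      n_broadened = sum(d$status == "broadened")
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "lower_limit") <- any(out$n_broadened > 0) && broadened_zero
  out
}

#' Fit the single-site saturation binding model
#'
#' Fits \eqn{y(L) = B_{max} L / (K_d + L)} to a concentration response
#' by unweighted nonlinear least squares on the per-concentration means
#' (the conventional "regular fit"; per-point errors are carried for
#' reporting, and weighted fitting is available via `weighted = TRUE`).
#' Parameters are bounded non-negative and the optimizer is restarted
#' from jittered starting values until convergence (up to
#' `max_restarts`); a fit that never converges is returned flagged, not
#' as an error. \eqn{y(K_d) = B_{max}/2} by construction.
#'
#' @param response A data frame with columns `ligand_conc` and
#'   `response` (and optionally `sem`), e.g. from
#'   [cterm_intensity_response()].
#' @param weighted Weight points by `1/sem^2` (requires a `sem` column
#'   with positive values); default unweighted.
#' @param max_restarts Maximum jittered restarts after the initial
#'   attempt (default 20).
#' @return A `binding_fit` object: list with `model`, `params`,
#'   `std_errors`, `converged`, `lower_limit`, `residuals`, `data`, and
#'   the underlying `nls` fit. Supports [tidy()], [glance()],
#'   [predict()] and [autoplot()].
#' @examples
#' L <- c(10, 20, 40, 100, 200, 400, 600, 1000)
#' resp <- tibble::tibble(ligand_conc = L, response = L / (100 + L))
#' fit <- fit_saturation(resp)
#' coef(fit)["kd"]  # 100
#' @export
fit_saturation <- function(response, weighted = FALSE, max_restarts = 20) {
  d <- prepare_response(response, value_col = "response", min_points = 3)
  start <- list(bmax = max(d$y), kd = stats::median(d$L))
  lower <- c(bmax = 0, kd = 0)
  upper <- c(bmax = Inf, kd = Inf)
  fit <- multistart_nls(
    y ~ bmax * L / (kd + L), data = d, start = start,
    lower = lower, upper = upper, weights = fit_weights(d, weighted),
    max_restarts = max_restarts
  )
  new_binding_fit("saturation_single_site", fit, d,
                  lower_limit = isTRUE(attr(response, "lower_limit")))
}

#' Fit the Hill cooperativity model to a per-residue shift titration
#'
#' Fits \eqn{\delta(L) = \delta_0 + \Delta\delta_{max} L^n / (K^n + L^n)}
#' to the chemical shift of one residue across the ligand series. The
#' Hill exponent \eqn{n} is bounded to \eqn{[0.1, 20]} and the
#' amplitude to non-negative values; the fit is multimodal in general,
#' so bounded Levenberg--Marquardt is restarted from jittered starting
#' values. With \eqn{n} fixed at 1 the model reduces to single-site
#' saturation plus a baseline. \eqn{n > 1} indicates positive
#' cooperativity (multiple ligand copies binding one chain).
#'
#' @param shifts A data frame with columns `ligand_conc` (µM) and
#'   `shift` (the residue's \eqn{^{15}}N chemical shift, ppm, as
#'   recorded).
#' @param fix_n Optional value at which to fix the Hill exponent
#'   (e.g. 1 to recover the hyperbolic model).
#' @param n_bounds Length-2 bounds for the Hill exponent.
#' @inheritParams fit_saturation
#' @return A `binding_fit` with parameters `delta0`, `ddmax`, `k`,
#'   `hill_n`.
#' @export
fit_hill <- function(shifts, fix_n = NULL, n_bounds = c(0.1, 20),
                     weighted = FALSE, max_restarts = 20) {
  d <- prepare_response(shifts, value_col = "shift", min_points = 4)
  rng <- max(d$y) - min(d$y)
  start <- list(delta0 = min(d$y), ddmax = if (rng > 0) rng else 1,
                k = stats::median(d$L), n = 1)
  lower <- c(delta0 = -Inf, ddmax = 0, k = 0, n = n_bounds[1])
  upper <- c(delta0 = Inf, ddmax = Inf, k = Inf, n = n_bounds[2])
  w <- fit_weights(d, weighted)
  if (!is.null(fix_n)) {
    form <- stats::as.formula(
      sprintf("y ~ delta0 + ddmax * L^%.15g / (k^%.15g + L^%.15g)",
              fix_n, fix_n, fix_n))
    start$n <- NULL
    lower <- lower[c("delta0", "ddmax", "k")]
    upper <- upper[c("delta0", "ddmax", "k")]
    fit <- multistart_nls(form, data = d, start = start, lower = lower,
                          upper = upper, weights = w,
                          max_restarts = max_restarts)
  } else {
    fit <- multistart_nls(
      y ~ delta0 + ddmax * L^n / (k^n + L^n), data = d, start = start,
      lower = lower, upper = upper, weights = w,
      max_restarts = max_restarts
    )
  }
  new_binding_fit("hill", fit, d, fixed_n = fix_n)
}

#' Average the Hill exponent over independent per-residue fits
#'
#' The cooperativity estimate of a titration is the unweighted
#' arithmetic mean of the Hill exponents fitted independently to each
#' reporter residue. Any non-converged fit is an error naming it.
#'
#' @param fits A list of `binding_fit` objects from [fit_hill()] (one or
#'   more).
#' @return A list with `mean_hill_n` and `per_fit` (a tibble with one
#'   row per fit: its label, `hill_n` and standard error).
#' @export
average_hill <- function(fits) {
  if (inherits(fits, "binding_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "binding_fit")))
  bad <- which(!vapply(fits, function(f) f$converged, logical(1)))
  if (length(bad) > 0) {
    stop("non-converged Hill fit(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  per_fit <- purrr::imap(fits, function(f, i) {
    if (!"hill_n" %in% names(f$params)) {
      stop("fit ", i, " is not a Hill fit", call. = FALSE)
    }
    tibble::tibble(fit = i, hill_n = unname(f$params["hill_n"]),
                   std_error = unname(f$std_errors["hill_n"]))
  }) |>
    dplyr::bind_rows()
  list(mean_hill_n = mean(per_fit$hill_n), per_fit = per_fit)
}

# ---- internals --------------------------------------------------------

prepare_response <- function(response, value_col, min_points) {
  d <- tibble::as_tibble(response)
  if (!all(c("ligand_conc", value_col) %in% names(d))) {
    stop("response table must have columns ligand_conc and ", value_col,
         call. = FALSE)
  }
  d <- tibble::tibble(L = as.double(d$ligand_conc),
                      y = as.double(d[[value_col]]),
                      sem = if ("sem" %in% names(d)) as.double(d$sem)
                            else NA_real_)
  d <- d[is.finite(d$L) & is.finite(d$y), , drop = FALSE]
  if (nrow(d) < min_points) {
    stop("need at least ", min_points, " concentrations to fit",
         call. = FALSE)
  }
  if (stats::sd(d$y) == 0) {
    stop("response values are all equal; nothing to fit", call. = FALSE)
  }
  d
}

fit_weights <- function(d, weighted) {
  if (!weighted) return(NULL)
  if (all(is.finite(d$sem)) && all(d$sem > 0)) return(1 / d$sem^2)
  stop("weighted fit requires positive sem values", call. = FALSE)
}

# Bounded Levenberg-Marquardt with jittered multi-start. The fit is
# first attempted from the standard initialization; only when the
# optimizer fails is the start point rescaled by random factors in
# [0.2, 5], up to max_restarts times, before the fit is declared
# non-converged. Restarting is a convergence device, not a global
# search: on shift titrations with few points the Hill least-squares
# surface can have a nearly flat shelf at very large exponents, and a
# best-of-many-starts policy would chase marginal SSR gains onto that
# shelf while the path-following fit from the standard start stays in
# the well-determined basin.
multistart_nls <- function(formula, data, start, lower, upper,
                           weights = NULL, max_restarts = 20) {
  control <- minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                        maxiter = 1000, maxfev = 10000)
  try_one <- function(st) {
    args <- list(formula = formula, data = data, start = st,
                 lower = lower, upper = upper, control = control)
    if (!is.null(weights)) args$weights <- weights
    tryCatch(suppressWarnings(do.call(minpack.lm::nlsLM, args)),
             error = function(e) NULL)
  }
  fit <- try_one(start)
  restarts <- 0
  while (is.null(fit) && restarts < max_restarts) {
    restarts <- restarts + 1
    jitter <- stats::runif(length(start), 0.2, 5)
    st <- purrr::map2(start, jitter, function(s, j) if (s == 0) j - 1 else s * j)
    names(st) <- names(start)
    for (nm in names(st)) {
      st[[nm]] <- min(max(st[[nm]], lower[[nm]] + 1e-9), upper[[nm]])
    }
    fit <- try_one(st)
  }
  fit
}

new_binding_fit <- function(model, fit, data, lower_limit = FALSE,
                            fixed_n = NULL) {
  if (is.null(fit)) {
    params <- se <- stats::setNames(
      rep(NA_real_, if (model == "hill") 4 else 2),
      if (model == "hill") c("delta0", "ddmax", "k", "hill_n")
      else c("bmax", "kd"))
    return(structure(
      list(model = model, params = params, std_errors = se,
           converged = FALSE, lower_limit = lower_limit,
           residuals = tibble::tibble(ligand_conc = data$L,
                                      observed = data$y,
                                      fitted = NA_real_,
                                      residual = NA_real_),
           data = data, fit = NULL),
      class = "binding_fit"
    ))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(
                   rep(NA_real_, length(cf)), names(cf)))
  if (model == "hill") {
    if (!is.null(fixed_n)) {
      cf <- c(cf, n = fixed_n)
      se <- c(se, n = NA_real_)
    }
    names(cf)[names(cf) == "n"] <- "hill_n"
    names(se)[names(se) == "n"] <- "hill_n"
    cf <- cf[c("delta0", "ddmax", "k", "hill_n")]
    se <- se[c("delta0", "ddmax", "k", "hill_n")]
  }
  structure(
    list(model = model, params = cf, std_errors = se, converged = TRUE,
         lower_limit = lower_limit,
         residuals = tibble::tibble(ligand_conc = data$L,
                                    observed = data$y,
                                    fitted = stats::fitted(fit),
                                    residual = stats::resid(fit)),
         data = data, fit = fit),
    class = "binding_fit"
  )
}

#' @export
coef.binding_fit <- function(object, ...) object$params

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  L <- if (is.null(newdata)) object$data$L else newdata$ligand_conc
  p <- object$params
  if (object$model == "saturation_single_site") {
    p[["bmax"]] * L / (p[["kd"]] + L)
  } else {
    p[["delta0"]] + p[["ddmax"]] * L^p[["hill_n"]] /
      (p[["k"]]^p[["hill_n"]] + L^p[["hill_n"]])
  }
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit: %s>%s\n", x$model,
              if (x$converged) "" else " (NOT CONVERGED)"))
  for (nm in names(x$params)) {
    cat(sprintf("  %-8s %12.6g  (se %.4g)\n", nm, x$params[[nm]],
                x$std_errors[[nm]]))
  }
  if (x$lower_limit) {
    cat("  note: broadened residues contributed zero intensities;\n",
        "  the dissociation constant is a lower limit.\n", sep = "")
  }
  invisible(x)
}

#' Tidy a binding fit
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate`, `std.error`.
#' @importFrom generics tidy
#' @export
#' @method tidy binding_fit
tidy.binding_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = unname(x$params),
                 std.error = unname(x$std_errors))
}

#' Glance at a binding fit
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return A one-row tibble with model, convergence, fit size and
#'   residual summaries.
#' @importFrom generics glance
#' @export
#' @method glance binding_fit
glance.binding_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    converged = x$converged,
    n_points = nrow(x$data),
    rss = if (x$converged) sum(x$residuals$residual^2) else NA_real_,
    sigma = if (x$converged) {
      stats::sigma(x$fit)
    } else {
      NA_real_
    },
    lower_limit = x$lower_limit
  )
}
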