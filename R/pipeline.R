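PIPELINE_SCHEMA_VERSION <- "1"

pipeline_defaults <- function() {
  list(
    scale_n = 25,
    noise_floor = 0,
    orange_floor_csp = 0.005,
    orange_floor_intensity = 10,
    dead_band = 0,
    response_region = "C-terminal",
    broadened_zero = TRUE,
    weighted = FALSE,
    n_hill_residues = 2,
    hill_residues = NULL,
    seed = 1L
  )
}

resolve_pipeline_options <- function(opts) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(opts), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown pipeline option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, opts)
}

#' Run the full titration analysis pipeline
#'
#' Ties every stage together for one titration series: per-residue CSP
#' and intensity profiles with significance thresholds for every
#' condition, per-region broadened-signal tallies, line-width difference
#' profiles where line widths are available, the C-terminal
#' intensity-difference response with its single-site saturation fit,
#' and per-residue Hill fits of nitrogen shift titrations with their
#' averaged exponent. Results are written to `out_dir` as per-residue
#' TSV tables plus a versioned JSON summary, together with a manifest
#' echoing the fully resolved configuration (every tunable appears, set
#' or not) and the package version. All numeric JSON output is rounded
#' to 9 significant digits, so a rerun with the same inputs and seed is
#' byte-identical.
#'
#' @param series A [titration_series], or a directory containing a
#'   `series.yaml` manifest (see [write_titration_series()]).
#' @param out_dir Output directory (created if needed).
#' @param map A [region_map].
#' @param ... Pipeline options overriding the defaults: `scale_n`,
#'   `noise_floor`, `orange_floor_csp`, `orange_floor_intensity`,
#'   `dead_band`, `response_region`, `broadened_zero`, `weighted`,
#'   `n_hill_residues`, `hill_residues`, `seed`. Unknown options are an
#'   error, never silently ignored.
#' @return The summary (a nested list, also written as
#'   `summary.json`), invisibly.
#' @export
run_pipeline <- function(series, out_dir, map = default_region_map(), ...) {
  opts <- resolve_pipeline_options(list(...))
  if (is.character(series)) {
    if (!dir.exists(series)) {
      stop("series directory does not exist: ", series, call. = FALSE)
    }
    series <- read_titration_series(series)
  }
  stopifnot(inherits(series, "titration_series"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::local_seed(opts$seed)

  concs <- ligand_concentrations(series)
  per_condition <- purrr::map(series$conditions, function(cond) {
    prof <- perturbation_profile(
      series$reference, cond, map = map, scale_n = opts$scale_n,
      noise_floor = opts$noise_floor,
      replicate_references = series$replicate_references,
      orange_floor_csp = opts$orange_floor_csp,
      orange_floor_intensity = opts$orange_floor_intensity
    )
    lw <- tryCatch(
      compute_linewidth_diff(series$reference, cond,
                             dead_band = opts$dead_band),
      error = function(e) NULL
    )
    if (!is.null(lw)) {
      prof <- dplyr::left_join(
        prof, dplyr::select(lw, "residue", "delta_lw"), by = "residue")
    } else {
      prof$delta_lw <- NA_real_
    }
    prof
  })

  for (i in seq_along(per_condition)) {
    readr::write_tsv(
      per_condition[[i]],
      file.path(out_dir, sprintf("per_residue_%04.0fuM.tsv", concs[i])))
  }

  response <- cterm_intensity_response(
    series, map = map, region = opts$response_region,
    noise_floor = opts$noise_floor, broadened_zero = opts$broadened_zero)
  readr::write_tsv(response, file.path(out_dir, "response.tsv"))
  kd_fit <- fit_saturation(response, weighted = opts$weighted)

  hill <- pipeline_hill_fits(series, map, opts)

  summary <- list(
    schema_version = PIPELINE_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("nmrtitr")),
    ligand_concentrations = concs,
    conditions = purrr::map2(per_condition, concs, function(prof, conc) {
      thr <- attr(prof, "thresholds")
      tally <- attr(prof, "broadened_tally")
      list(
        ligand_conc = conc,
        thresholds = list(
          csp_black_line = signif9(thr$csp$black_line),
          csp_orange_line = signif9(thr$csp$orange_line),
          intensity_black_line = signif9(thr$intensity$black_line),
          intensity_orange_line = signif9(thr$intensity$orange_line)
        ),
        n_significant_csp = sum(prof$significant_csp, na.rm = TRUE),
        n_significant_intensity =
          sum(prof$significant_intensity, na.rm = TRUE),
        broadened_by_region = stats::setNames(
          as.list(tally$n_broadened), as.character(tally$region)),
        n_broadened = sum(tally$n_broadened)
      )
    }),
    kd_fit = binding_fit_report(kd_fit),
    hill_fits = hill
  )
  write_json_report(summary, file.path(out_dir, "summary.json"))

  manifest <- list(
    schema_version = PIPELINE_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("nmrtitr")),
    options = opts[setdiff(names(opts), "hill_residues")],
    hill_residues = hill$residues,
    region_map = purrr::pmap(
      as.data.frame(map)[c("region", "first", "last")], list),
    protein_length = attr(map, "protein_length"),
    n_conditions = length(series$conditions),
    n_replicate_references = length(series$replicate_references)
  )
  write_json_report(manifest, file.path(out_dir, "manifest.json"))
  invisible(summary)
}

# Per-residue 15N shift titrations for the cooperativity estimate: by
# default the reporter residues are the n_hill_residues C-terminal
# residues with the largest CSP at the highest ligand concentration
# that remain observable at every concentration (the titration includes
# the apo point at L = 0).
pipeline_hill_fits <- function(series, map, opts) {
  shifts <- nitrogen_shift_titration(series)
  candidates <- opts$hill_residues
  if (is.null(candidates)) {
    n_cond <- length(series$conditions)
    top <- compute_csp(series$reference,
                       series$conditions[[n_cond]],
                       scale_n = opts$scale_n)
    top$region <- classify_region(top$residue, map)
    complete <- shifts |>
      dplyr::count(.data$residue) |>
      dplyr::filter(.data$n == n_cond + 1)
    top <- top |>
      dplyr::filter(.data$region == opts$response_region,
                    .data$residue %in% complete$residue) |>
      dplyr::arrange(dplyr::desc(.data$csp))
    candidates <- utils::head(top$residue, opts$n_hill_residues)
  }
  if (length(candidates) == 0) {
    return(list(residues = integer(0), fits = list(),
                mean_hill_n = NULL))
  }
  fits <- purrr::map(candidates, function(r) {
    d <- dplyr::filter(shifts, .data$residue == r)
    fit_hill(d, weighted = opts$weighted)
  })
  converged <- vapply(fits, function(f) f$converged, logical(1))
  avg <- if (all(converged)) average_hill(fits) else NULL
  list(
    residues = as.integer(candidates),
    fits = purrr::map2(fits, candidates, function(f, r) {
      c(list(residue = as.integer(r)), binding_fit_report(f))
    }),
    mean_hill_n = if (!is.null(avg)) signif9(avg$mean_hill_n) else NULL
  )
}

#' Per-residue nitrogen shift titration table
#'
#' Long table of \eqn{^{15}}N chemical shifts against ligand
#' concentration (including the apo point at 0 µM), one row per residue
#' and condition in which the residue is observable; input to
#' [fit_hill()].
#'
#' @param series A [titration_series].
#' @return A tibble with columns `residue`, `ligand_conc`, `shift`.
#' @export
nitrogen_shift_titration <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  all_lists <- c(list(series$reference), series$conditions)
  purrr::map(all_lists, function(pl) {
    tibble::tibble(residue = pl$residue,
                   ligand_conc = attr(pl, "ligand_conc"),
                   shift = pl$cs_n_ppm)
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$residue, .data$ligand_conc)
}

binding_fit_report <- function(fit) {
  list(
    model = fit$model,
    converged = fit$converged,
    params = purrr::map(as.list(fit$params), signif9),
    std_errors = purrr::map(as.list(fit$std_errors), signif9),
    lower_limit = fit$lower_limit,
    rss = if (fit$converged) signif9(sum(fit$residuals$residual^2))
          else NULL
  )
}

signif9 <- function(x) signif(x, 9)

write_json_report <- function(x, path) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(9),
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
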