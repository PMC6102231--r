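#' Per-residue chemical shift perturbations
#'
#' Computes the combined amide chemical shift perturbation between an
#' apo reference and a ligand condition for every residue assigned in
#' both lists:
#' \deqn{\Delta\delta_{NH} = \sqrt{\frac{(\Delta\delta H)^2 +
#'   (\Delta\delta N)^2 / s}{2}}}
#' where \eqn{\Delta\delta H} and \eqn{\Delta\delta N} are the proton and
#' nitrogen shift differences (condition minus reference, ppm) and
#' \eqn{s} (default 25) is the conventional scaling factor that brings
#' the wider \eqn{^{15}}N shift range onto the proton scale. The
#' combined value is invariant to the order of the two lists.
#'
#' @param reference Apo [peaklist].
#' @param condition Ligand-containing [peaklist].
#' @param scale_n Positive nitrogen scaling factor (default 25).
#' @return A tibble with one row per residue present in both lists:
#'   `residue`, `aa`, `delta_h`, `delta_n` (signed, condition minus
#'   reference, ppm) and `csp` (ppm, non-negative).
#' @examples
#' ref <- peaklist(tibble::tibble(residue = 1, aa = "A", cs_h_ppm = 8.0,
#'                                cs_n_ppm = 120, intensity = 1))
#' cond <- peaklist(tibble::tibble(residue = 1, aa = "A", cs_h_ppm = 8.02,
#'                                 cs_n_ppm = 120.1, intensity = 1),
#'                  ligand_conc = 600)
#' compute_csp(ref, cond)$csp  # 0.02
#' @export
compute_csp <- function(reference, condition, scale_n = 25) {
  stopifnot(inherits(reference, "peaklist"), inherits(condition, "peaklist"))
  if (!is.numeric(scale_n) || length(scale_n) != 1 || scale_n <= 0) {
    stop("scale_n must be a single positive number", call. = FALSE)
  }
  joined <- dplyr::inner_join(
    tibble::as_tibble(reference), tibble::as_tibble(condition),
    by = "residue", suffix = c("_ref", "_cond")
  )
  if (nrow(joined) == 0) {
    stop("no residues shared between reference and condition", call. = FALSE)
  }
  joined |>
    dplyr::transmute(
      residue = .data$residue,
      aa = .data$aa_ref,
      delta_h = .data$cs_h_ppm_cond - .data$cs_h_ppm_ref,
      delta_n = .data$cs_n_ppm_cond - .data$cs_n_ppm_ref,
      csp = sqrt((.data$delta_h^2 + .data$delta_n^2 / scale_n) / 2)
    )
}

#' Per-residue intensity attenuation
#'
#' The percentage change in peak intensity per residue between the apo
#' reference and a ligand condition, taken as an absolute value:
#' \deqn{|\,(I^\circ - I^L) / I^\circ\,| \times 100} where \eqn{I^\circ}
#' is the reference intensity and \eqn{I^L} the intensity with ligand.
#' Residues with zero reference intensity are excluded (reported in the
#' `excluded` attribute and via a message).
#'
#' @inheritParams compute_csp
#' @return A tibble with columns `residue`, `aa`, `intensity_ref`,
#'   `intensity_cond`, `intensity_change_pct` (non-negative).
#' @export
compute_intensity_change <- function(reference, condition) {
  stopifnot(inherits(reference, "peaklist"), inherits(condition, "peaklist"))
  joined <- dplyr::inner_join(
    tibble::as_tibble(reference), tibble::as_tibble(condition),
    by = "residue", suffix = c("_ref", "_cond")
  )
  if (nrow(joined) == 0) {
    stop("no residues shared between reference and condition", call. = FALSE)
  }
  zero_ref <- joined$intensity_ref == 0
  if (any(zero_ref)) {
    message("excluding ", sum(zero_ref),
            " residue(s) with zero reference intensity: ",
            paste(joined$residue[zero_ref], collapse = ", "))
  }
  out <- joined[!zero_ref, , drop = FALSE] |>
    dplyr::transmute(
      residue = .data$residue,
      aa = .data$aa_ref,
      intensity_ref = .data$intensity_ref,
      intensity_cond = .data$intensity_cond,
      intensity_change_pct =
        abs((.data$intensity_ref - .data$intensity_cond) /
              .data$intensity_ref) * 100
    )
  attr(out, "excluded") <- joined$residue[zero_ref]
  out
}

#' Significance thresholds for a per-residue statistic
#'
#' Two thresholds decide which residues respond significantly. The
#' "black line" is the mean plus one standard deviation of the statistic
#' over residues whose peaks are still observable (status `ok`). The
#' "orange line" captures spectral variability between independent apo
#' samples: when replicate apo lists are supplied it is the maximum of
#' the same statistic computed between every pair of apo lists;
#' otherwise a configured floor stands in. A residue is significant only
#' when its statistic strictly exceeds both lines.
#'
#' @param values Numeric vector of the per-residue statistic (CSP in
#'   ppm, or intensity change in percent) over `ok` residues.
#' @param replicate_values Optional numeric vector of the same statistic
#'   computed between replicate apo spectra (see
#'   [replicate_variability()]); its maximum becomes the orange line.
#' @param orange_floor Fallback orange line when no replicate statistic
#'   is available (defaults: 0.005 ppm for CSP, 10 percent for
#'   intensity, chosen at the pipeline level).
#' @return A list with elements `black_line` and `orange_line`.
#' @export
compute_thresholds <- function(values, replicate_values = NULL,
                               orange_floor = 0) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    stop("need at least 2 observable residues to set thresholds",
         call. = FALSE)
  }
  black <- mean(values) + stats::sd(values)
  orange <- if (!is.null(replicate_values) && length(replicate_values) > 0) {
    max(replicate_values, na.rm = TRUE)
  } else {
    orange_floor
  }
  list(black_line = black, orange_line = orange)
}

#' Apo-to-apo variability of a per-residue statistic
#'
#' Computes the chosen statistic (CSP or intensity change) between every
#' pair of apo peak lists; the maximum of the pooled values is the
#' replicate-variability ("orange line") threshold.
#'
#' @param apo_lists List of two or more apo [peaklist]s (typically the
#'   reference plus replicate references).
#' @param statistic `"csp"` or `"intensity"`.
#' @param scale_n Nitrogen scaling factor for the CSP statistic.
#' @return Numeric vector of pooled pairwise per-residue values.
#' @export
replicate_variability <- function(apo_lists, statistic = c("csp", "intensity"),
                                  scale_n = 25) {
  statistic <- match.arg(statistic)
  if (length(apo_lists) < 2) {
    stop("need at least two apo lists to measure variability", call. = FALSE)
  }
  pairs <- utils::combn(length(apo_lists), 2, simplify = FALSE)
  purrr::map(pairs, function(ij) {
    a <- apo_lists[[ij[1]]]
    b <- apo_lists[[ij[2]]]
    if (statistic == "csp") {
      compute_csp(a, b, scale_n = scale_n)$csp
    } else {
      compute_intensity_change(a, b)$intensity_change_pct
    }
  }) |>
    unlist()
}

#' Classify signals broadened beyond detection
#'
#' A residue observable in the apo reference is classed `broadened` in a
#' ligand condition when its peak is absent from the condition list or
#' its condition intensity falls below the detection floor; remaining
#' residues are `ok`. Residues that appear only in the condition are
#' `absent_in_reference`. The conventional detection floor is three
#' times the spectral noise standard deviation.
#'
#' @inheritParams compute_csp
#' @param noise_floor Non-negative intensity below which a peak counts
#'   as undetectable (default 0: only missing peaks are broadened).
#' @param map Optional [region_map]; when given, a `region` column is
#'   added so tallies can be made per region.
#' @return A tibble with columns `residue`, `status` (factor with levels
#'   ok, broadened, absent_in_reference) and, with a map, `region`.
#' @seealso [tally_broadened()]
#' @export
classify_broadened <- function(reference, condition, noise_floor = 0,
                               map = NULL) {
  stopifnot(inherits(reference, "peaklist"), inherits(condition, "peaklist"))
  if (noise_floor < 0) stop("noise_floor must be >= 0", call. = FALSE)
  joined <- dplyr::full_join(
    dplyr::select(tibble::as_tibble(reference), "residue",
                  intensity_ref = "intensity"),
    dplyr::select(tibble::as_tibble(condition), "residue",
                  intensity_cond = "intensity"),
    by = "residue"
  )
  out <- joined |>
    dplyr::mutate(
      status = factor(
        dplyr::case_when(
          is.na(.data$intensity_ref) ~ "absent_in_reference",
          is.na(.data$intensity_cond) ~ "broadened",
          .data$intensity_cond < noise_floor ~ "broadened",
          TRUE ~ "ok"
        ),
        levels = c("ok", "broadened", "absent_in_reference")
      )
    ) |>
    dplyr::arrange(.data$residue) |>
    dplyr::select("residue", "status")
  if (!is.null(map)) {
    out$region <- classify_region(out$residue, map)
    out <- dplyr::relocate(out, "region", .after = "residue")
  }
  out
}

#' Tally broadened signals per protein region
#'
#' Counts signals broadened beyond detection in each region of the map
#' (the pie-chart summary: N-terminal / NAC / C-terminal in the default
#' architecture). Tallies always sum to the total broadened count.
#'
#' @param status A tibble from [classify_broadened()]; if it lacks a
#'   `region` column, `map` must be supplied.
#' @param map Optional [region_map].
#' @return A tibble with columns `region` and `n_broadened`, one row per
#'   region in map order (zero counts included).
#' @export
tally_broadened <- function(status, map = NULL) {
  if (!"region" %in% names(status)) {
    if (is.null(map)) {
      stop("supply a region map or a status table with a region column",
           call. = FALSE)
    }
    status$region <- classify_region(status$residue, map)
  }
  status |>
    dplyr::filter(.data$status == "broadened") |>
    dplyr::count(region = .data$region, name = "n_broadened",
                 .drop = FALSE) |>
    dplyr::arrange(.data$region)
}

#' Per-residue nitrogen line-width differences
#'
#' Computes \eqn{\Delta LW} = line width in the condition minus line
#' width in the reference (Hz) for every residue reporting a line width
#' in both lists, and classifies each residue as `narrowing`
#' (\eqn{\Delta LW} below minus the dead band), `broadening` (above the
#' dead band) or `unchanged`. Positive values mean slower transverse
#' relaxation decay, i.e. binding, restricted motion or intermediate
#' exchange; negative values mean increased local mobility.
#'
#' @inheritParams compute_csp
#' @param dead_band Non-negative half-width (Hz) of the band around zero
#'   reported as `unchanged` (default 0).
#' @return A tibble with columns `residue`, `aa`, `lw_ref`, `lw_cond`,
#'   `delta_lw`, `classification`.
#' @export
compute_linewidth_diff <- function(reference, condition, dead_band = 0) {
  stopifnot(inherits(reference, "peaklist"), inherits(condition, "peaklist"))
  if (dead_band < 0) stop("dead_band must be >= 0", call. = FALSE)
  joined <- dplyr::inner_join(
    tibble::as_tibble(reference), tibble::as_tibble(condition),
    by = "residue", suffix = c("_ref", "_cond")
  ) |>
    dplyr::filter(!is.na(.data$lw_n_hz_ref), !is.na(.data$lw_n_hz_cond))
  if (nrow(joined) == 0) {
    stop("no residue reports a line width in both lists", call. = FALSE)
  }
  joined |>
    dplyr::transmute(
      residue = .data$residue,
      aa = .data$aa_ref,
      lw_ref = .data$lw_n_hz_ref,
      lw_cond = .data$lw_n_hz_cond,
      delta_lw = .data$lw_n_hz_cond - .data$lw_n_hz_ref,
      classification = factor(
        dplyr::case_when(
          .data$delta_lw > dead_band ~ "broadening",
          .data$delta_lw < -dead_band ~ "narrowing",
          TRUE ~ "unchanged"
        ),
        levels = c("narrowing", "unchanged", "broadening")
      )
    )
}

#' Ligand-observed WaterLOGSY intensity ratios
#'
#' For each 1D ligand signal matched by label across the two
#' experiments, the relative intensity ratio is the signal intensity in
#' the presence of protein divided by the intensity in its absence.
#' Signals present in only one table, or with non-positive intensity in
#' the ligand-alone experiment, are excluded and reported.
#'
#' @param ligand_alone,ligand_with_protein Data frames with columns
#'   `signal_label` and `intensity`.
#' @return A tibble with columns `signal_label`, `intensity_free`,
#'   `intensity_bound`, `ratio`; excluded labels in attribute
#'   `excluded`.
#' @export
waterlogsy_ratio <- function(ligand_alone, ligand_with_protein) {
  a <- tibble::as_tibble(ligand_alone)
  b <- tibble::as_tibble(ligand_with_protein)
  stopifnot(all(c("signal_label", "intensity") %in% names(a)),
            all(c("signal_label", "intensity") %in% names(b)))
  joined <- dplyr::full_join(
    dplyr::select(a, "signal_label", intensity_free = "intensity"),
    dplyr::select(b, "signal_label", intensity_bound = "intensity"),
    by = "signal_label"
  )
  bad <- is.na(joined$intensity_free) | is.na(joined$intensity_bound) |
    joined$intensity_free <= 0
  if (any(bad)) {
    message("excluding ", sum(bad), " signal(s): ",
            paste(joined$signal_label[bad], collapse = ", "))
  }
  out <- joined[!bad, , drop = FALSE] |>
    dplyr::mutate(ratio = .data$intensity_bound / .data$intensity_free)
  attr(out, "excluded") <- joined$signal_label[bad]
  out
}

#' Full per-residue perturbation profile for one condition
#'
#' Convenience wrapper combining [compute_csp()],
#' [compute_intensity_change()], [classify_broadened()] and the
#' significance thresholds into a single per-residue table for one
#' titration point, mirroring the per-residue panels of a titration
#' figure: CSP bars with their black (mean + 1 SD) and orange
#' (replicate-variability) lines, intensity changes with their own pair
#' of lines, and broadened-beyond-detection arrows.
#'
#' @inheritParams compute_csp
#' @inheritParams classify_broadened
#' @param replicate_references Optional list of replicate apo
#'   [peaklist]s for the orange lines.
#' @param orange_floor_csp,orange_floor_intensity Fallback orange lines
#'   when no replicates are available (ppm / percent).
#' @return A tibble with one row per residue of the union of both
#'   lists: `residue`, `region`, `aa`, `delta_h`, `delta_n`, `csp`,
#'   `intensity_change_pct`, `status`, `significant_csp`,
#'   `significant_intensity`. Thresholds are stored in the `thresholds`
#'   attribute (a named list) and broadened tallies in the
#'   `broadened_tally` attribute.
#' @export
perturbation_profile <- function(reference, condition, map = default_region_map(),
                                 scale_n = 25, noise_floor = 0,
                                 replicate_references = NULL,
                                 orange_floor_csp = 0.005,
                                 orange_floor_intensity = 10) {
  status <- classify_broadened(reference, condition,
                               noise_floor = noise_floor, map = map)
  csp <- compute_csp(reference, condition, scale_n = scale_n)
  int <- compute_intensity_change(reference, condition)
  prof <- status |>
    dplyr::left_join(dplyr::select(csp, -"aa"), by = "residue") |>
    dplyr::left_join(dplyr::select(int, "residue", "aa",
                                   "intensity_change_pct"),
                     by = "residue") |>
    dplyr::relocate("aa", .after = "region")

  ok <- prof$status == "ok"
  rep_csp <- rep_int <- NULL
  if (!is.null(replicate_references) && length(replicate_references) > 0) {
    apo <- c(list(reference), replicate_references)
    rep_csp <- replicate_variability(apo, "csp", scale_n = scale_n)
    rep_int <- replicate_variability(apo, "intensity")
  }
  thr_csp <- compute_thresholds(prof$csp[ok], rep_csp,
                                orange_floor = orange_floor_csp)
  thr_int <- compute_thresholds(prof$intensity_change_pct[ok], rep_int,
                                orange_floor = orange_floor_intensity)
  prof <- prof |>
    dplyr::mutate(
      significant_csp = .data$status == "ok" &
        !is.na(.data$csp) &
        .data$csp > thr_csp$black_line & .data$csp > thr_csp$orange_line,
      significant_intensity = .data$status == "ok" &
        !is.na(.data$intensity_change_pct) &
        .data$intensity_change_pct > thr_int$black_line &
        .data$intensity_change_pct > thr_int$orange_line
    )
  attr(prof, "thresholds") <- list(csp = thr_csp, intensity = thr_int)
  attr(prof, "broadened_tally") <- tally_broadened(prof)
  attr(prof, "ligand_conc") <- attr(condition, "ligand_conc")
  prof
}
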