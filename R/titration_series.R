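#' Assemble a ligand titration series
#'
#' Bundles an apo reference peak list with the ligand-containing
#' conditions of a titration (and optional replicate apo lists used to
#' estimate spectral variability). All lists must share the protein
#' concentration and pH within the declared tolerances, and the ligand
#' concentrations must be strictly increasing.
#'
#' @param reference Apo [peaklist] (ligand concentration 0).
#' @param conditions List of [peaklist]s at increasing ligand
#'   concentration.
#' @param replicate_references Optional list of additional apo
#'   [peaklist]s.
#' @param conc_tolerance,ph_tolerance Allowed absolute deviation of
#'   protein concentration (µM) and pH across lists.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(reference, conditions,
                             replicate_references = NULL,
                             conc_tolerance = 1e-6, ph_tolerance = 0.2) {
  stopifnot(inherits(reference, "peaklist"))
  if (length(conditions) == 0) {
    stop("no titration conditions", call. = FALSE)
  }
  ok <- vapply(conditions, inherits, logical(1), what = "peaklist")
  if (!all(ok)) stop("all conditions must be peaklists", call. = FALSE)
  if (!is.null(replicate_references)) {
    ok <- vapply(replicate_references, inherits, logical(1),
                 what = "peaklist")
    if (!all(ok)) stop("replicate references must be peaklists", call. = FALSE)
  }
  concs <- vapply(conditions, attr, numeric(1), which = "ligand_conc")
  conditions <- conditions[order(concs)]
  concs <- sort(concs)
  if (any(diff(concs) <= 0)) {
    stop("ligand concentrations must be strictly increasing across ",
         "conditions", call. = FALSE)
  }
  all_lists <- c(list(reference), conditions, replicate_references)
  pc <- vapply(all_lists, attr, numeric(1), which = "protein_conc")
  ph <- vapply(all_lists, attr, numeric(1), which = "ph")
  if (diff(range(pc)) > conc_tolerance) {
    stop("protein concentrations differ across lists beyond tolerance (",
         paste(unique(pc), collapse = ", "), " uM)", call. = FALSE)
  }
  if (diff(range(ph)) > ph_tolerance) {
    stop("pH differs across lists beyond tolerance (",
         paste(unique(ph), collapse = ", "), ")", call. = FALSE)
  }
  structure(
    list(reference = reference, conditions = conditions,
         replicate_references = replicate_references),
    class = "titration_series"
  )
}

#' @rdname titration_series
#' @param x A `titration_series`.
#' @export
ligand_concentrations <- function(x) {
  stopifnot(inherits(x, "titration_series"))
  vapply(x$conditions, attr, numeric(1), which = "ligand_conc")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series> %d condition(s) at %s uM ligand, %d replicate apo list(s)\n",
    length(x$conditions),
    paste(ligand_concentrations(x), collapse = ", "),
    length(x$replicate_references)
  ))
  invisible(x)
}

#' Write or read a titration series as a directory of peak-list files
#'
#' `write_titration_series()` writes the reference, each condition and
#' any replicate apo lists as peak-list TSV files plus a `series.yaml`
#' manifest; `read_titration_series()` reads the manifest back. This is
#' the interchange layout consumed by the pipeline runner.
#'
#' @param x A [titration_series].
#' @param dir Directory to create/read.
#' @return The directory path (write) or a `titration_series` (read).
#' @export
write_titration_series <- function(x, dir) {
  stopifnot(inherits(x, "titration_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref_file <- "reference.tsv"
  write_peaklist(x$reference, file.path(dir, ref_file))
  cond_files <- sprintf("condition_%04d.tsv", seq_along(x$conditions))
  purrr::walk2(x$conditions, cond_files,
               ~ write_peaklist(.x, file.path(dir, .y)))
  rep_files <- character(0)
  if (length(x$replicate_references) > 0) {
    rep_files <- sprintf("replicate_apo_%02d.tsv",
                         seq_along(x$replicate_references))
    purrr::walk2(x$replicate_references, rep_files,
                 ~ write_peaklist(.x, file.path(dir, .y)))
  }
  manifest <- list(reference = ref_file, conditions = as.list(cond_files),
                   replicate_references = as.list(rep_files))
  yaml::write_yaml(manifest, file.path(dir, "series.yaml"))
  invisible(dir)
}

#' @rdname write_titration_series
#' @export
read_titration_series <- function(dir) {
  manifest_path <- file.path(dir, "series.yaml")
  if (!file.exists(manifest_path)) {
    stop("no series.yaml manifest in ", dir, call. = FALSE)
  }
  manifest <- yaml::read_yaml(manifest_path)
  known <- c("reference", "conditions", "replicate_references")
  unknown <- setdiff(names(manifest), known)
  if (length(unknown) > 0) {
    stop("unknown key(s) in series.yaml: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(manifest$reference)) {
    stop("series.yaml must name a reference peak list", call. = FALSE)
  }
  if (length(manifest$conditions) == 0) {
    stop("no titration conditions", call. = FALSE)
  }
  reference <- read_peaklist(file.path(dir, manifest$reference))
  conditions <- purrr::map(manifest$conditions,
                           ~ read_peaklist(file.path(dir, .x)))
  reps <- NULL
  if (length(manifest$replicate_references) > 0) {
    reps <- purrr::map(manifest$replicate_references,
                       ~ read_peaklist(file.path(dir, .x)))
  }
  titration_series(reference, conditions, replicate_references = reps)
}
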