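#' Construct an assigned peak list for one titration condition
#'
#' A peak list holds the assigned 2D \eqn{^1}H--\eqn{^{15}}N correlation
#' peaks of one sample condition: one row per observable backbone amide
#' (prolines and unassigned residues are simply absent rows). Condition
#' metadata (ligand concentration, protein concentration, pH, label)
#' travels with the table as attributes so that a titration series can be
#' validated for consistent sample conditions.
#'
#' @param peaks A data frame with columns `residue` (1-based index),
#'   `aa` (one-letter amino-acid code, `"X"` if unknown), `cs_h_ppm`
#'   (amide proton shift, ppm), `cs_n_ppm` (nitrogen shift, ppm),
#'   `intensity` (non-negative peak height, arbitrary units) and
#'   optionally `lw_n_hz` (positive \eqn{^{15}}N line width, Hz; `NA`
#'   where not measured).
#' @param label Free-text condition label.
#' @param ligand_conc Ligand concentration in µM; 0 means apo.
#' @param protein_conc Protein concentration in µM (must be positive).
#' @param ph Sample pH.
#'
#' @return A tibble of class `peaklist` with the metadata stored in
#'   attributes `label`, `ligand_conc`, `protein_conc` and `ph`.
#' @examples
#' pl <- peaklist(
#'   tibble::tibble(residue = 1:3, aa = c("M", "D", "V"),
#'                  cs_h_ppm = c(8.1, 8.3, 8.0),
#'                  cs_n_ppm = c(119.2, 121.0, 118.4),
#'                  intensity = c(1.0, 0.9, 1.1)),
#'   label = "apo", ligand_conc = 0)
#' molar_ratio(pl)
#' @export
peaklist <- function(peaks, label = "", ligand_conc = 0,
                     protein_conc = 20, ph = 7.6) {
  peaks <- tibble::as_tibble(peaks)
  if (!"lw_n_hz" %in% names(peaks)) peaks$lw_n_hz <- NA_real_
  if (!"aa" %in% names(peaks)) peaks$aa <- "X"
  required <- c("residue", "aa", "cs_h_ppm", "cs_n_ppm", "intensity")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols) > 0) {
    stop("peak table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  peaks <- dplyr::select(peaks, dplyr::all_of(c(required, "lw_n_hz")))
  peaks$residue <- as.integer(peaks$residue)
  for (col in c("cs_h_ppm", "cs_n_ppm", "intensity", "lw_n_hz")) {
    peaks[[col]] <- as.double(peaks[[col]])
  }
  peaks <- dplyr::arrange(peaks, .data$residue)
  out <- structure(
    peaks,
    label = as.character(label),
    ligand_conc = as.double(ligand_conc),
    protein_conc = as.double(protein_conc),
    ph = as.double(ph),
    class = c("peaklist", class(tibble::tibble()))
  )
  validate_peaklist(out)
}

#' @rdname peaklist
#' @param x A `peaklist`.
#' @export
molar_ratio <- function(x) {
  stopifnot(inherits(x, "peaklist"))
  attr(x, "ligand_conc") / attr(x, "protein_conc")
}

validate_peaklist <- function(x) {
  if (any(duplicated(x$residue))) {
    dup <- unique(x$residue[duplicated(x$residue)])
    stop("duplicate residue index in peak list: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(x$residue < 1L)) {
    stop("residue indices must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(x$intensity)) || any(x$intensity < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  lw <- x$lw_n_hz[!is.na(x$lw_n_hz)]
  if (any(lw <= 0)) {
    stop("lw_n_hz must be positive where present", call. = FALSE)
  }
  if (attr(x, "ligand_conc") < 0) {
    stop("ligand_conc must be >= 0", call. = FALSE)
  }
  if (attr(x, "protein_conc") <= 0) {
    stop("protein_conc must be > 0", call. = FALSE)
  }
  x
}

#' Read or write a peak-list table
#'
#' The on-disk dialect is tab-separated with a header row naming the
#' columns `residue`, `aa`, `cs_h_ppm`, `cs_n_ppm`, `intensity` and
#' optionally `lw_n_hz`. Lines starting with `#` are comments; the
#' writer stores condition metadata in `#key: value` comment lines which
#' the reader recovers, so write/read round-trips reproduce both the
#' numbers (to better than 1e-6) and the metadata.
#'
#' Rows whose chemical shifts are missing are dropped with a message;
#' a duplicated residue index or a malformed numeric cell is an error
#' naming the offender.
#'
#' @param path Path to a peak-list TSV file.
#' @param label,ligand_conc,protein_conc,ph Condition metadata; when `NULL`
#'   the values from the file's `#key: value` header (or the `peaklist()`
#'   defaults) are used.
#' @return `read_peaklist()` returns a [peaklist]; `write_peaklist()`
#'   returns `path` invisibly.
#' @export
read_peaklist <- function(path, label = NULL, ligand_conc = NULL,
                          protein_conc = NULL, ph = NULL) {
  if (!file.exists(path)) {
    stop("peak-list file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  meta <- parse_meta_comments(lines)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 1) stop("no table content in ", path, call. = FALSE)
  header <- strsplit(body[[1]], "\t", fixed = TRUE)[[1]]
  required <- c("residue", "aa", "cs_h_ppm", "cs_n_ppm", "intensity")
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    stop("header of ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- utils::read.table(
    text = paste(body, collapse = "\n"), header = TRUE, sep = "\t",
    colClasses = "character", check.names = FALSE,
    stringsAsFactors = FALSE
  )
  numeric_cols <- intersect(
    c("residue", "cs_h_ppm", "cs_n_ppm", "intensity", "lw_n_hz"),
    names(tab)
  )
  for (col in numeric_cols) {
    raw <- trimws(tab[[col]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & raw != "NA" & is.na(val))
    if (length(bad) > 0) {
      stop("malformed numeric value '", raw[bad[1]], "' in column '", col,
           "', row ", bad[1], " of ", path, call. = FALSE)
    }
    tab[[col]] <- val
  }
  incomplete <- is.na(tab$cs_h_ppm) | is.na(tab$cs_n_ppm)
  if (any(incomplete)) {
    message("dropping ", sum(incomplete),
            " row(s) with missing chemical shifts: residue(s) ",
            paste(tab$residue[incomplete], collapse = ", "))
    tab <- tab[!incomplete, , drop = FALSE]
  }
  peaklist(
    tab,
    label = label %||% meta$label %||% "",
    ligand_conc = ligand_conc %||% meta$ligand_conc %||% 0,
    protein_conc = protein_conc %||% meta$protein_conc %||% 20,
    ph = ph %||% meta$ph %||% 7.6
  )
}

#' @rdname read_peaklist
#' @param x A [peaklist] to serialize.
#' @export
write_peaklist <- function(x, path) {
  stopifnot(inherits(x, "peaklist"))
  meta <- sprintf(
    "#%s: %s",
    c("label", "ligand_conc", "protein_conc", "ph"),
    c(attr(x, "label"),
      format(attr(x, "ligand_conc"), digits = 15),
      format(attr(x, "protein_conc"), digits = 15),
      format(attr(x, "ph"), digits = 15))
  )
  tab <- as.data.frame(x)
  for (col in c("cs_h_ppm", "cs_n_ppm", "intensity", "lw_n_hz")) {
    tab[[col]] <- ifelse(is.na(tab[[col]]), "NA",
                         format(tab[[col]], digits = 15, trim = TRUE,
                                scientific = FALSE))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

parse_meta_comments <- function(lines) {
  meta_lines <- grep("^#[a-z_]+:", lines, value = TRUE)
  out <- list()
  for (ln in meta_lines) {
    key <- sub("^#([a-z_]+):.*$", "\\1", ln)
    val <- trimws(sub("^#[a-z_]+:", "", ln))
    out[[key]] <- val
  }
  for (key in c("ligand_conc", "protein_conc", "ph")) {
    if (!is.null(out[[key]])) out[[key]] <- as.numeric(out[[key]])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf(
    "<peaklist> %s: %d peaks, ligand %g uM, protein %g uM, pH %g\n",
    attr(x, "label"), nrow(x), attr(x, "ligand_conc"),
    attr(x, "protein_conc"), attr(x, "ph")
  ))
  NextMethod()
}
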