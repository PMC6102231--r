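#' Partition a protein sequence into named regions
#'
#' Builds a region map: an ordered set of contiguous, non-overlapping,
#' inclusive residue ranges that cover the whole chain exactly once. The
#' default is the canonical three-segment architecture of the 140-residue
#' disordered protein alpha-synuclein: the amphipathic N-terminal region
#' (residues 1--60), the aggregation-prone NAC region (61--95) and the
#' acidic C-terminal region (96--140).
#'
#' @param boundaries A data frame (or tibble) with columns `region`,
#'   `first`, `last` giving named inclusive ranges, sorted by `first`.
#' @param protein_length Total chain length; defaults to the largest
#'   `last` value.
#' @return A tibble of class `region_map` with columns `region`, `first`,
#'   `last` and attribute `protein_length`.
#' @examples
#' default_region_map()
#' region_map(data.frame(region = "all", first = 1, last = 10))
#' @export
region_map <- function(boundaries, protein_length = NULL) {
  b <- tibble::as_tibble(boundaries)
  stopifnot(all(c("region", "first", "last") %in% names(b)))
  b$first <- as.integer(b$first)
  b$last <- as.integer(b$last)
  b <- dplyr::arrange(b, .data$first)
  protein_length <- as.integer(protein_length %||% max(b$last))
  if (nrow(b) == 0) stop("region map needs at least one segment", call. = FALSE)
  if (b$first[1] != 1L) {
    stop("region map must start at residue 1, got ", b$first[1], call. = FALSE)
  }
  if (b$last[nrow(b)] != protein_length) {
    stop("region map must end at protein_length (", protein_length,
         "), got ", b$last[nrow(b)], call. = FALSE)
  }
  if (any(b$last < b$first)) {
    bad <- which(b$last < b$first)[1]
    stop("segment '", b$region[bad], "' has last < first", call. = FALSE)
  }
  if (nrow(b) > 1) {
    gap <- b$first[-1] - b$last[-nrow(b)]
    if (any(gap > 1)) {
      at <- b$last[which(gap > 1)[1]] + 1L
      stop("gap in region map at residue ", at, call. = FALSE)
    }
    if (any(gap < 1)) {
      at <- b$first[-1][which(gap < 1)[1]]
      stop("overlapping segments in region map at residue ", at,
           call. = FALSE)
    }
  }
  structure(b, protein_length = protein_length,
            class = c("region_map", class(tibble::tibble())))
}

#' @rdname region_map
#' @export
default_region_map <- function() {
  region_map(tibble::tibble(
    region = c("N-terminal", "NAC", "C-terminal"),
    first = c(1L, 61L, 96L),
    last = c(60L, 95L, 140L)
  ))
}

#' Classify residues by region
#'
#' @param residues Integer vector of residue indices.
#' @param map A [region_map].
#' @return A factor of region names, with the map's segment order as
#'   levels; residues outside `1..protein_length` are an error.
#' @examples
#' classify_region(c(1, 61, 140), default_region_map())
#' @export
classify_region <- function(residues, map) {
  stopifnot(inherits(map, "region_map"))
  residues <- as.integer(residues)
  n <- attr(map, "protein_length")
  if (any(residues < 1L | residues > n)) {
    stop("residue index outside 1..", n, call. = FALSE)
  }
  idx <- findInterval(residues, map$first)
  factor(map$region[idx], levels = map$region)
}

#' Restrict a region map to a C-terminally truncated construct
#'
#' Models truncated protein constructs (for example a 1--108 variant of
#' a 140-residue chain, missing the last 32 residues): every segment is
#' clipped at `last_residue` and segments that fall entirely beyond it
#' are kept with zero width so that region tallies remain comparable
#' across constructs.
#'
#' @param map A [region_map].
#' @param last_residue Last residue retained (1-based, inclusive).
#' @return A `region_map` covering `1..last_residue`, with attributes
#'   `removed_residues` (count removed) and `protein_length` updated.
#'   Zero-width segments are dropped from the table but recorded in the
#'   attribute `empty_regions`.
#' @examples
#' tr <- truncate_protein(default_region_map(), 108)
#' attr(tr, "removed_residues")  # 32
#' @export
truncate_protein <- function(map, last_residue) {
  stopifnot(inherits(map, "region_map"))
  n <- attr(map, "protein_length")
  last_residue <- as.integer(last_residue)
  if (last_residue < 1L || last_residue > n) {
    stop("last_residue must be in 1..", n, call. = FALSE)
  }
  keep <- map$first <= last_residue
  b <- map[keep, , drop = FALSE]
  b$last <- pmin(b$last, last_residue)
  out <- region_map(b, protein_length = last_residue)
  attr(out, "removed_residues") <- n - last_residue
  attr(out, "empty_regions") <- setdiff(map$region, b$region)
  out
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> %d residues, %d segment(s)\n",
              attr(x, "protein_length"), nrow(x)))
  NextMethod()
}
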