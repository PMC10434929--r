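#' Read a karyotype table
#'
#' A karyotype table is an fai-like TSV with one row per chromosome:
#' `chrom_id`, `length_bp` and `chrom_class` (`"autosome"` or `"Z"`).
#' An optional `population` column labels the assembly; otherwise the
#' `population` argument is recycled onto every row.
#'
#' @param path Path to a tab-separated karyotype file with a header.
#' @param population Population label used when the file has no
#'   `population` column.
#' @return A tibble with columns `population`, `chrom_id`, `length_bp`
#'   and `chrom_class`, validated by [validate_karyotype()].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom_id\tlength_bp\tchrom_class",
#'              "chr1\t20000000\tautosome",
#'              "chrZ\t15000000\tZ"), tf)
#' read_karyotype(tf, population = "demo")
read_karyotype <- function(path, population = NA_character_) {
  kar <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"population" %in% names(kar)) kar$population <- population
  kar <- dplyr::select(kar, "population", "chrom_id", "length_bp", "chrom_class")
  validate_karyotype(kar)
}

#' Validate a karyotype tibble
#'
#' Checks the invariants every downstream statistic relies on: unique
#' chromosome ids, strictly positive lengths and a known chromosome
#' class. The assembly length is always `sum(length_bp)`; it is never
#' stored, so it cannot go stale.
#'
#' @param karyotype A data frame with columns `chrom_id`, `length_bp`,
#'   `chrom_class` (and optionally `population`).
#' @return The karyotype as a tibble, invisibly unchanged, or an error.
#' @export
validate_karyotype <- function(karyotype) {
  karyotype <- tibble::as_tibble(karyotype)
  stopifnot(all(c("chrom_id", "length_bp", "chrom_class") %in% names(karyotype)))
  if (nrow(karyotype) == 0L) {
    stop("karyotype is empty", call. = FALSE)
  }
  if (anyDuplicated(karyotype$chrom_id)) {
    stop("duplicated chrom_id in karyotype: ",
         paste(unique(karyotype$chrom_id[duplicated(karyotype$chrom_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(karyotype$length_bp) | karyotype$length_bp <= 0)) {
    stop("all chromosome lengths must be positive", call. = FALSE)
  }
  bad <- setdiff(unique(karyotype$chrom_class), c("autosome", "Z"))
  if (length(bad)) {
    stop("unknown chrom_class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  karyotype
}

#' Total assembly length of a karyotype
#'
#' @param karyotype A validated karyotype tibble.
#' @return Assembly length L in bp (sum of chromosome lengths).
#' @export
assembly_length <- function(karyotype) {
  sum(validate_karyotype(karyotype)$length_bp)
}

#' Read a Marey-map marker table
#'
#' Reads a TSV with header columns `population`, `chrom_id`, `phys_bp`
#' and `gen_cm`, sorts markers by physical position within each
#' chromosome, merges duplicated physical positions (mean `gen_cm`;
#' co-locating RAD markers are common), normalizes each chromosome's
#' first marker to 0 cM, and validates the Marey-map invariants.
#'
#' Rows whose `chrom_id` is absent from `karyotype` are dropped with a
#' warning naming them. A marker beyond its chromosome end, or a
#' genetic position that decreases along the physical order, is a hard
#' error naming the chromosome: both indicate a broken map, not noise.
#'
#' @param path Path to the marker TSV.
#' @param karyotype Karyotype tibble for the same assembly.
#' @return A tibble of markers: `population`, `chrom_id`, `phys_bp`,
#'   `gen_cm`, sorted, merged and zero-based in cM.
#' @export
read_map_table <- function(path, karyotype) {
  karyotype <- validate_karyotype(karyotype)
  markers <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("population", "chrom_id", "phys_bp", "gen_cm") %in% names(markers)))
  unknown <- setdiff(unique(markers$chrom_id), karyotype$chrom_id)
  if (length(unknown)) {
    warning("dropping markers on chromosomes absent from karyotype: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    markers <- dplyr::filter(markers, !.data$chrom_id %in% unknown)
  }
  validate_marey(markers, karyotype)
}

#' Validate (and canonicalize) a Marey-map marker tibble
#'
#' Sorting, duplicate merging and zero-offsetting are applied here so
#' that maps constructed in code get the same guarantees as maps read
#' from disk: strictly increasing `phys_bp`, non-decreasing `gen_cm`,
#' first marker at 0 cM, all positions inside the chromosome.
#'
#' @param markers Marker data frame (`population` optional).
#' @param karyotype Karyotype tibble; used for bounds checks.
#' @return Canonical marker tibble.
#' @export
validate_marey <- function(markers, karyotype) {
  markers <- tibble::as_tibble(markers)
  if (!"population" %in% names(markers)) markers$population <- NA_character_
  stopifnot(all(c("chrom_id", "phys_bp", "gen_cm") %in% names(markers)))
  karyotype <- validate_karyotype(karyotype)
  len <- stats::setNames(karyotype$length_bp, karyotype$chrom_id)

  out <- markers |>
    dplyr::group_by(.data$population, .data$chrom_id) |>
    dplyr::arrange(.data$phys_bp, .by_group = TRUE) |>
    # co-located markers collapse to their mean genetic position
    dplyr::group_by(.data$phys_bp, .add = TRUE) |>
    dplyr::summarise(gen_cm = mean(.data$gen_cm), .groups = "drop_last") |>
    dplyr::ungroup()

  check_one <- function(df) {
    chrom <- df$chrom_id[[1]]
    if (any(df$phys_bp < 0) || any(df$phys_bp > len[[chrom]])) {
      stop("marker outside chromosome ", chrom, call. = FALSE)
    }
    if (is.unsorted(df$gen_cm)) {
      stop("non-monotone genetic positions on chromosome ", chrom, call. = FALSE)
    }
    df$gen_cm <- df$gen_cm - df$gen_cm[[1]]
    df
  }
  out |>
    dplyr::group_by(.data$population, .data$chrom_id) |>
    dplyr::group_split() |>
    purrr::map(check_one) |>
    dplyr::bind_rows() |>
    dplyr::select("population", "chrom_id", "phys_bp", "gen_cm")
}

#' Kosambi map function
#'
#' Converts a recombination fraction to map distance under moderate
#' crossover interference: d = 25 * log((1 + 2r) / (1 - 2r)) cM.
#'
#' @param r Recombination fraction(s) in \[0, 0.5).
#' @return Genetic distance in cM.
#' @export
#' @examples
#' kosambi_cm(0.25) # 25 * log(3)
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) {
    stop("recombination fraction must lie in [0, 0.5)", call. = FALSE)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi map function
#'
#' Recovers the recombination fraction from a Kosambi map distance:
#' r = 0.5 * tanh(d / 50). Exact inverse of [kosambi_cm()].
#'
#' @param d Genetic distance(s) in cM, non-negative.
#' @return Recombination fraction(s) in \[0, 0.5).
#' @export
inverse_kosambi_r <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative", call. = FALSE)
  0.5 * tanh(d / 50)
}

#' Interpolated genetic position at a physical coordinate
#'
#' Linear interpolation of the Marey map between flanking markers.
#' Positions outside the marker span clamp to the terminal genetic
#' positions: there is no crossover information beyond the outermost
#' markers, so unmapped terminal sequence is treated as fully linked to
#' the nearest mapped marker.
#'
#' @param map Marker tibble for a single chromosome (`phys_bp`, `gen_cm`).
#' @param bp Physical position(s), 0-based bp.
#' @param chrom_length Optional chromosome length for bounds checking.
#' @return Genetic position(s) in cM.
#' @export
genetic_position_at <- function(map, bp, chrom_length = NULL) {
  stopifnot(length(unique(map$chrom_id)) <= 1L)
  if (any(bp < 0)) stop("physical position must be non-negative", call. = FALSE)
  if (!is.null(chrom_length) && any(bp > chrom_length)) {
    stop("physical position beyond chromosome end", call. = FALSE)
  }
  if (nrow(map) == 1L) {
    return(rep(map$gen_cm[[1]], length(bp)))
  }
  stats::approx(map$phys_bp, map$gen_cm, xout = bp, rule = 2, ties = "ordered")$y
}

#' Per-chromosome map lengths
#'
#' The map length G of a chromosome is its last genetic position minus
#' its first (the first is normalized to 0 by [validate_marey()]).
#'
#' @param markers Marker tibble (one or many chromosomes/populations).
#' @return Tibble with `population`, `chrom_id`, `n_markers`,
#'   `span_bp` (physical marker span) and `map_length_cm`.
#' @export
map_lengths <- function(markers) {
  markers |>
    dplyr::group_by(.data$population, .data$chrom_id) |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      span_bp = max(.data$phys_bp) - min(.data$phys_bp),
      map_length_cm = max(.data$gen_cm) - min(.data$gen_cm),
      .groups = "drop"
    )
}

#' Map length of a single-chromosome map
#'
#' @param map Marker tibble for one chromosome.
#' @return Map length in cM (0 for a single-marker map).
#' @export
map_length <- function(map) {
  stopifnot(length(unique(map$chrom_id)) <= 1L)
  if (nrow(map) == 0L) return(NA_real_)
  max(map$gen_cm) - min(map$gen_cm)
}

#' Write a Marey-map marker table
#'
#' Inverse of [read_map_table()]; round-trips canonical marker tibbles.
#'
#' @param markers Canonical marker tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_map_table <- function(markers, path) {
  readr::write_tsv(markers, path, progress = FALSE)
  invisible(path)
}

#' Write a karyotype table
#'
#' @param karyotype Karyotype tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_karyotype <- function(karyotype, path) {
  readr::write_tsv(validate_karyotype(karyotype), path, progress = FALSE)
  invisible(path)
}
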