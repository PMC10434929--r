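#' Windowed recombination rates from a Marey map
#'
#' The local recombination rate of each marker interval is its genetic
#' span over its physical span (cM/Mb). Window rates are the
#' physical-overlap-weighted mean of interval rates: each interval
#' contributes its rate weighted by the bp it shares with the window.
#' Windows are anchored at coordinate 0 of every chromosome and are
#' half-open `[start, end)`; the trailing partial window is kept.
#' Sequence outside the marker span carries no rate information, so it
#' contributes nothing to `covered_bp`, and windows with
#' `covered_bp == 0` have `NA` rate.
#'
#' @param markers Canonical marker tibble (any number of chromosomes).
#' @param karyotype Karyotype tibble giving chromosome lengths.
#' @param window_bp Window size in bp (default 2 Mb).
#' @return Tibble: `population`, `chrom_id`, `start`, `end`,
#'   `rate_cm_per_mb`, `covered_bp`.
#' @export
windowed_rates <- function(markers, karyotype, window_bp = 2e6) {
  stopifnot(window_bp > 0)
  karyotype <- validate_karyotype(karyotype)
  len <- stats::setNames(karyotype$length_bp, karyotype$chrom_id)

  one_chrom <- function(map) {
    chrom <- map$chrom_id[[1]]
    L <- len[[chrom]]
    starts <- seq(0, max(L - 1, 0), by = window_bp)
    win <- tibble::tibble(
      population = map$population[[1]], chrom_id = chrom,
      start = starts, end = pmin(starts + window_bp, L)
    )
    if (nrow(map) < 2L) {
      return(dplyr::mutate(win, rate_cm_per_mb = NA_real_, covered_bp = 0))
    }
    iv <- tibble::tibble(
      a = map$phys_bp[-nrow(map)], b = map$phys_bp[-1],
      rate = diff(map$gen_cm) / (diff(map$phys_bp) / 1e6)
    )
    agg <- purrr::map2_dfr(win$start, win$end, function(s, e) {
      ov <- pmax(0, pmin(iv$b, e) - pmax(iv$a, s))
      tibble::tibble(covered_bp = sum(ov),
                     cm = sum(ov * iv$rate) / 1e6) # cM accumulated in window
    })
    dplyr::mutate(win,
      rate_cm_per_mb = ifelse(agg$covered_bp > 0,
                              agg$cm / (agg$covered_bp / 1e6), NA_real_),
      covered_bp = agg$covered_bp
    )
  }

  markers |>
    dplyr::group_by(.data$population, .data$chrom_id) |>
    dplyr::group_split() |>
    purrr::map(one_chrom) |>
    dplyr::bind_rows()
}

#' Mean recombination rate of a chromosome
#'
#' Map length divided by the physical marker span, in cM/Mb. Identical
#' to the covered-bp-weighted mean of its window rates.
#'
#' @param markers Canonical marker tibble.
#' @return Tibble: `population`, `chrom_id`, `mean_rate_cm_per_mb`
#'   (`NA` for chromosomes with fewer than two markers).
#' @export
chromosome_mean_rate <- function(markers) {
  map_lengths(markers) |>
    dplyr::mutate(
      mean_rate_cm_per_mb = ifelse(.data$n_markers >= 2 & .data$span_bp > 0,
                                   .data$map_length_cm / (.data$span_bp / 1e6),
                                   NA_real_)
    ) |>
    dplyr::select("population", "chrom_id", "mean_rate_cm_per_mb")
}

#' Excess map length beyond the obligate crossover
#'
#' One crossover per bivalent per meiosis is obligatory, contributing
#' 50 cM; the excess map length G - 50 measures recombination beyond
#' that obligate event. Negative values occur (map lengths below
#' 50 cM are observed when interference suppresses double crossovers
#' and some meioses go unsampled by the marker set).
#'
#' @param markers Canonical marker tibble.
#' @param obligate_cm Map length attributed to the obligate crossover.
#' @return [map_lengths()] output plus `excess_cm`.
#' @export
excess_map_length <- function(markers, obligate_cm = 50) {
  dplyr::mutate(map_lengths(markers), excess_cm = .data$map_length_cm - obligate_cm)
}

#' Expected recombination rate under a fixed crossover count
#'
#' With k crossovers per meiosis a chromosome maps to k * 50 cM, so the
#' expected rate is k * 50 / length-in-Mb. Used to compare observed
#' chromosome means to the one- and two-crossover expectations.
#'
#' @param length_bp Chromosome length(s) in bp.
#' @param n_crossovers Crossovers per meiosis (k >= 1).
#' @return Expected rate(s), cM/Mb.
#' @export
#' @examples
#' expected_rate(18e6, 1:2)
expected_rate <- function(length_bp, n_crossovers = 1) {
  if (any(length_bp <= 0)) stop("chromosome length must be positive", call. = FALSE)
  if (any(n_crossovers < 1)) stop("n_crossovers must be >= 1", call. = FALSE)
  n_crossovers * 50 / (length_bp / 1e6)
}

#' Fold window positions onto the center-to-end axis
#'
#' Maps each window midpoint to `|mid/L - 0.5|`, so 0 is the chromosome
#' center and 0.5 its (either) end, and labels chromosomes as `large`
#' or `small` by a physical size threshold — the length above which
#' more than one crossover per meiosis is typical.
#'
#' @param windows Output of [windowed_rates()].
#' @param karyotype Karyotype tibble.
#' @param size_threshold_bp Large/small boundary (default 18 Mb).
#' @return `windows` plus `folded_pos` and `size_class`.
#' @export
folded_profile <- function(windows, karyotype, size_threshold_bp = 18e6) {
  karyotype <- validate_karyotype(karyotype)
  len <- stats::setNames(karyotype$length_bp, karyotype$chrom_id)
  mid <- (windows$start + windows$end) / 2
  L <- unname(len[windows$chrom_id])
  if (any(is.na(L)) || any(mid < 0 | mid > L)) {
    stop("window midpoint outside chromosome", call. = FALSE)
  }
  dplyr::mutate(windows,
    folded_pos = abs(mid / L - 0.5),
    size_class = ifelse(L > size_threshold_bp, "large", "small")
  )
}

#' LOESS smoothing on an even grid
#'
#' Tricube-weighted local linear regression (`stats::loess`,
#' degree 1), evaluated on an evenly spaced x-grid. Used to draw the
#' folded recombination-rate profiles.
#'
#' @param data Data frame of points.
#' @param x,y Column names (strings) of predictor and response.
#' @param span LOESS span in (0, 1].
#' @param n_grid Number of grid points.
#' @return Tibble with columns `x` (grid) and `y` (fitted).
#' @export
loess_smooth <- function(data, x = "x", y = "y", span = 0.75, n_grid = 100) {
  stopifnot(span > 0, span <= 1)
  df <- tibble::tibble(x = data[[x]], y = data[[y]])
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 5L) stop("need at least 5 points to smooth", call. = FALSE)
  fit <- stats::loess(y ~ x, data = df, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(df$x), max(df$x), length.out = n_grid)
  tibble::tibble(
    x = grid,
    y = unname(stats::predict(fit, newdata = tibble::tibble(x = grid)))
  )
}
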