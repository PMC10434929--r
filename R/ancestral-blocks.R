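#' Per-block recombination, diversity and between-population ratios
#'
#' Ancestral chromosomal units are chromosome segments left intact by
#' the fissions and fusions that distinguish the two karyotypes; each
#' has coordinates in both assemblies. For each block this computes,
#' per population, the recombination rate (map cM spanned by the
#' block, interpolated at its edges, over its physical length in Mb)
#' and the ratio-of-sums diversity over the windows clipped to the
#' block, then forms the ratio coordinates
#' `X = rho_pop2 / rho_pop1` and `Y = pi_pop2 / pi_pop1`.
#'
#' Blocks whose coordinates fall outside the marker span in either
#' population have an undefined rate and are flagged
#' (`defined = FALSE`) rather than silently dropped.
#'
#' @param blocks Tibble: `block_id`, `chrom_pop1`, `start_pop1`,
#'   `end_pop1`, `chrom_pop2`, `start_pop2`, `end_pop2`,
#'   `history_class`.
#' @param markers_pop1,markers_pop2 Canonical marker tibbles.
#' @param div_pop1,div_pop2 [pi_windows()] outputs (pre-filtered to a
#'   single site class, typically intergenic).
#' @param history_classes Which history classes to keep; default keeps
#'   rearranged blocks and breakpoint-reuse/ILS cases, the classes
#'   where the recombination contrast is informative.
#' @return `blocks` with `rho_pop1`, `rho_pop2`, `pi_pop1`, `pi_pop2`,
#'   `X`, `Y`, `defined`.
#' @export
block_summaries <- function(blocks, markers_pop1, markers_pop2,
                            div_pop1, div_pop2,
                            history_classes = c("fission_after_split",
                                                "fusion_after_split",
                                                "ILS_or_breakpoint_reuse")) {
  blocks <- tibble::as_tibble(blocks)
  stopifnot(all(blocks$start_pop1 < blocks$end_pop1),
            all(blocks$start_pop2 < blocks$end_pop2))
  blocks <- dplyr::filter(blocks, .data$history_class %in% history_classes)

  block_rho <- function(markers, chrom, s, e) {
    map <- dplyr::filter(markers, .data$chrom_id == chrom)
    if (nrow(map) < 2L) return(NA_real_)
    lo <- min(map$phys_bp); hi <- max(map$phys_bp)
    if (e <= lo || s >= hi) return(NA_real_) # outside marker span
    cm <- genetic_position_at(map, c(max(s, lo), min(e, hi)))
    (cm[2] - cm[1]) / ((e - s) / 1e6)
  }
  block_pi <- function(div, chrom, s, e) {
    w <- dplyr::filter(div, .data$chrom == !!chrom,
                       .data$start < e, .data$end > s)
    if (nrow(w) == 0L || sum(w$n_comp) == 0) return(NA_real_)
    sum(w$n_diff) / sum(w$n_comp)
  }

  out <- blocks |>
    dplyr::rowwise() |>
    dplyr::mutate(
      rho_pop1 = block_rho(markers_pop1, .data$chrom_pop1,
                           .data$start_pop1, .data$end_pop1),
      rho_pop2 = block_rho(markers_pop2, .data$chrom_pop2,
                           .data$start_pop2, .data$end_pop2),
      pi_pop1 = block_pi(div_pop1, .data$chrom_pop1,
                         .data$start_pop1, .data$end_pop1),
      pi_pop2 = block_pi(div_pop2, .data$chrom_pop2,
                         .data$start_pop2, .data$end_pop2)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      X = .data$rho_pop2 / .data$rho_pop1,
      Y = .data$pi_pop2 / .data$pi_pop1,
      defined = is.finite(.data$X) & is.finite(.data$Y) &
        .data$X > 0 & .data$Y > 0
    )
  n_bad <- sum(!out$defined)
  if (n_bad > 0) message(n_bad, " block(s) with undefined ratios flagged")
  out
}

#' Model II regression of diversity ratio on recombination-rate ratio
#'
#' Both axes are ratios of estimates and carry error, so the slope is
#' read as a model II problem: the fit is ordinary least squares, and
#' significance comes from a permutation test (Y shuffled against X,
#' two-sided on |slope|) rather than from OLS standard errors.
#' The intercept evaluated at X = 1 measures the diversity excess that
#' remains once recombination-rate differences are cancelled out;
#' [excess_at_unity()] extracts it as a percentage.
#'
#' @param data Data frame of per-block ratios (e.g.
#'   [block_summaries()] output with `defined` rows).
#' @param x,y Column names, default `"X"` and `"Y"`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param weights Optional column name of block weights (e.g. block
#'   length); the default, `NULL`, fits unweighted.
#' @return An object of class `model2_fit`: list with `intercept`,
#'   `slope`, `r_squared`, `p_permuted`, `n`, `n_perm`.
#' @export
model2_regression <- function(data, x = "X", y = "Y", n_perm = 1000,
                              seed = 1, weights = NULL) {
  xv <- data[[x]]; yv <- data[[y]]
  wv <- if (is.null(weights)) rep(1, length(xv)) else data[[weights]]
  ok <- stats::complete.cases(xv, yv, wv)
  xv <- xv[ok]; yv <- yv[ok]; wv <- wv[ok]
  if (length(xv) < 3L) stop("need at least 3 blocks", call. = FALSE)
  if (stats::sd(xv) == 0) stop("X is constant", call. = FALSE)
  fit <- stats::lm(yv ~ xv, weights = wv)
  slope <- unname(stats::coef(fit)[2])
  perm_slope <- function(yp) {
    unname(stats::coef(stats::lm(yp ~ xv, weights = wv))[2])
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  perm <- replicate(n_perm, abs(perm_slope(sample(yv))))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(
    list(
      intercept = unname(stats::coef(fit)[1]),
      slope = slope,
      r_squared = summary(fit)$r.squared,
      p_permuted = (1 + sum(perm >= abs(slope))) / (1 + n_perm),
      n = length(xv),
      n_perm = n_perm,
      data = tibble::tibble(X = xv, Y = yv, w = wv)
    ),
    class = "model2_fit"
  )
}

#' Diversity excess implied by a fit at ratio parity
#'
#' Evaluates a fitted (or published) regression `Y = a + b X` at
#' X = 1 and expresses the departure from Y = 1 as a percentage:
#' the residual diversity excess of population 2 over population 1
#' once recombination-rate differences are cancelled out.
#'
#' @param fit A `model2_fit`, or a list/row with `intercept` and
#'   `slope`.
#' @return Percentage excess, e.g. 7.9 for Y(1) = 1.079.
#' @export
excess_at_unity <- function(fit) {
  (fit$intercept + fit$slope - 1) * 100
}

#' @export
print.model2_fit <- function(x, ...) {
  cat(sprintf("model II regression: y = %.3f + %.3fx, R^2 = %.3f, permuted p = %.3g (n = %d, %d permutations)\n",
              x$intercept, x$slope, x$r_squared, x$p_permuted, x$n, x$n_perm))
  invisible(x)
}

#' Tidy a model II regression fit
#'
#' @param x A `model2_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient.
#' @method tidy model2_fit
#' @export
tidy.model2_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept, x$slope)
  )
}

#' Glance at a model II regression fit
#'
#' @param x A `model2_fit`.
#' @param ... Unused.
#' @return One-row tibble: `r_squared`, `p_permuted`, `n`, `n_perm`,
#'   `excess_at_unity_pct`.
#' @method glance model2_fit
#' @export
glance.model2_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    p_permuted = x$p_permuted,
    n = x$n,
    n_perm = x$n_perm,
    excess_at_unity_pct = excess_at_unity(x)
  )
}

#' Plot a model II block regression
#'
#' @param object A `model2_fit`.
#' @param ... Unused.
#' @return A ggplot: per-block ratios with the fitted line and the
#'   X = Y = 1 guides.
#' @method autoplot model2_fit
#' @export
autoplot.model2_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$X, y = .data$Y)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 1, linetype = 3, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "recombination-rate ratio (pop2 / pop1)",
      y = "diversity ratio (pop2 / pop1)",
      subtitle = sprintf("y = %.2f + %.3fx, R² = %.2f, permuted p = %.3g",
                         object$intercept, object$slope, object$r_squared,
                         object$p_permuted)
    ) +
    ggplot2::theme_minimal()
}
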