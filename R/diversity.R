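#' Classify coding positions as 0-fold or 4-fold degenerate
#'
#' A coding position is 0-fold degenerate when every possible base
#' change alters the encoded amino acid, and 4-fold degenerate when no
#' change does. Positions that are neither (2-fold, 3-fold), or whose
#' class conflicts between overlapping transcripts, are excluded —
#' only sites with an unambiguous selective regime enter the
#' diversity contrast.
#'
#' CDS records on the minus strand are handled by complementing the
#' codon; `phase` shifts the reading frame as in GFF3. Transcripts
#' whose concatenated CDS length is not a multiple of 3 after phase
#' adjustment, or that contain an internal stop codon, are skipped
#' with a warning.
#'
#' @param cds Data frame of CDS records: `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), `phase` (0/1/2),
#'   `transcript_id`. [read_cds_gff()] produces this from a GFF3 file.
#' @param genome Named character vector or `Biostrings::DNAStringSet`
#'   of chromosome sequences.
#' @return A tibble `chrom`, `pos` (0-based), `site_class`
#'   (`"zero_fold"`/`"four_fold"`), one row per classified site.
#' @export
classify_degeneracy <- function(cds, genome) {
  cds <- tibble::as_tibble(cds)
  stopifnot(all(c("chrom", "start", "end", "strand", "phase", "transcript_id")
                %in% names(cds)))
  seqs <- if (inherits(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else {
    genome
  }
  missing <- setdiff(unique(cds$chrom), names(seqs))
  if (length(missing)) {
    stop("no sequence for chromosome(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  one_transcript <- function(tx) {
    minus <- tx$strand[[1]] == "-"
    tx <- dplyr::arrange(tx, if (minus) dplyr::desc(.data$start) else .data$start)
    # genomic positions in translation order
    pos <- unlist(purrr::map2(tx$start, tx$end, function(s, e) {
      p <- s:(e - 1L)
      if (minus) rev(p) else p
    }))
    chrom <- tx$chrom[[1]]
    bases <- toupper(substring(seqs[[chrom]], pos + 1L, pos + 1L))
    if (minus) bases <- chartr("ACGT", "TGCA", bases)
    ph <- tx$phase[[1]]
    if (ph > 0) {
      pos <- pos[-seq_len(ph)]
      bases <- bases[-seq_len(ph)]
    }
    if (length(bases) < 3L || length(bases) %% 3L != 0L) {
      warning("CDS length of transcript ", tx$transcript_id[[1]],
              " not a multiple of 3 after phase adjustment; skipped",
              call. = FALSE)
      return(NULL)
    }
    codons <- matrix(bases, nrow = 3L)
    aa <- translate_codons(apply(codons, 2, paste0, collapse = ""))
    if (any(aa[-length(aa)] == "*")) {
      warning("internal stop codon in transcript ", tx$transcript_id[[1]],
              "; skipped", call. = FALSE)
      return(NULL)
    }
    deg <- codon_degeneracy(apply(codons, 2, paste0, collapse = ""))
    cls <- as.vector(deg) # 3 rows (codon positions) x codons, column-major
    keep <- cls %in% c("zero_fold", "four_fold")
    tibble::tibble(chrom = chrom, pos = pos[keep], site_class = cls[keep])
  }

  out <- cds |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::group_split() |>
    purrr::map(one_transcript) |>
    dplyr::bind_rows()
  if (nrow(out) == 0L) return(tibble::tibble(chrom = character(), pos = integer(),
                                             site_class = character()))
  # conflicting classifications across overlapping transcripts are dropped
  out |>
    dplyr::distinct() |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::filter(dplyr::n() == 1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$pos)
}

# Standard genetic code lookup; prefers Biostrings' table when available.
genetic_code <- function() {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    return(Biostrings::GENETIC_CODE)
  }
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  stats::setNames(aas, codons)
}

translate_codons <- function(codons) {
  code <- genetic_code()
  out <- unname(code[codons])
  out[is.na(out)] <- "X" # ambiguous bases
  out
}

# Degeneracy class of each position of each codon: 3 x n character matrix.
codon_degeneracy <- function(codons) {
  code <- genetic_code()
  bases <- c("A", "C", "G", "T")
  vapply(codons, function(cod) {
    if (is.na(code[cod])) return(rep("none", 3L))
    vapply(1:3, function(p) {
      variants <- vapply(bases, function(b) {
        x <- strsplit(cod, "")[[1]]
        x[p] <- b
        paste0(x, collapse = "")
      }, "")
      aa <- code[variants]
      ref <- code[cod]
      if (all(aa == ref)) "four_fold"
      else if (all(aa[variants != cod] != ref)) "zero_fold"
      else "none"
    }, "")
  }, character(3L))
}

#' Read CDS records from a GFF3 file
#'
#' Thin wrapper around `rtracklayer::import` that extracts CDS
#' features into the 0-based half-open tibble [classify_degeneracy()]
#' expects. The transcript id is taken from the `Parent` attribute
#' (falling back to `ID`).
#'
#' @param path GFF3 file.
#' @return Tibble `chrom`, `start`, `end`, `strand`, `phase`,
#'   `transcript_id`.
#' @export
read_cds_gff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to read GFF3", call. = FALSE)
  }
  g <- rtracklayer::import(path)
  g <- g[g$type == "CDS"]
  parent <- if (!is.null(g$Parent)) {
    vapply(as.list(g$Parent), function(p) if (length(p)) p[[1]] else NA_character_, "")
  } else NA_character_
  id <- if (!is.null(g$ID)) as.character(g$ID) else NA_character_
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g) - 1L,
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    phase = as.integer(g$phase),
    transcript_id = dplyr::coalesce(parent, id)
  )
}

#' Windowed nucleotide diversity from allele counts, pixy-style
#'
#' Per site with `k >= 2` called haplotypes and alternate-allele count
#' `a`, the number of differing haplotype pairs is `a * (k - a)` and
#' the number of comparisons `choose(k, 2)`. Window diversity is the
#' ratio of summed differences to summed comparisons over the sites of
#' each class — never a mean of per-site ratios — which keeps the
#' estimator unbiased under missing data and requires invariant sites
#' to be present (or at least counted) in the input.
#'
#' @param genotypes Tibble of per-site counts: `chrom`, `pos` (0-based),
#'   `n_called` (called haplotypes at the site), `alt_count`.
#' @param sites Optional site-class tibble (`chrom`, `pos`,
#'   `site_class`), e.g. from [classify_degeneracy()] or
#'   [mask_to_sites()]; sites absent from it are classed `"all"`.
#'   When `NULL`, every site is classed `"all"`.
#' @param window_bp Window size (default 50 kb).
#' @return Tibble `chrom`, `start`, `end`, `site_class`, `n_sites`,
#'   `n_diff`, `n_comp`, `pi` (`NA` where `n_comp == 0`).
#' @export
pi_windows <- function(genotypes, sites = NULL, window_bp = 5e4) {
  g <- tibble::as_tibble(genotypes)
  stopifnot(all(c("chrom", "pos", "n_called", "alt_count") %in% names(g)))
  if (any(g$alt_count > g$n_called)) {
    stop("alt_count exceeds n_called", call. = FALSE)
  }
  if (is.null(sites)) {
    g$site_class <- "all"
  } else {
    g <- dplyr::left_join(g, sites, by = c("chrom", "pos"))
    g$site_class <- dplyr::coalesce(g$site_class, "all")
  }
  g |>
    dplyr::mutate(
      n_diff = .data$alt_count * (.data$n_called - .data$alt_count),
      n_comp = ifelse(.data$n_called >= 2, choose(.data$n_called, 2), 0),
      start = (.data$pos %/% window_bp) * window_bp
    ) |>
    dplyr::group_by(.data$chrom, .data$start, .data$site_class) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      n_diff = sum(.data$n_diff),
      n_comp = sum(.data$n_comp),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      end = .data$start + window_bp,
      pi = ifelse(.data$n_comp > 0, .data$n_diff / .data$n_comp, NA_real_)
    ) |>
    dplyr::select("chrom", "start", "end", "site_class", "n_sites",
                  "n_diff", "n_comp", "pi")
}

#' Convert BED-style class intervals to per-site classes
#'
#' @param mask Tibble `chrom`, `start`, `end`, `site_class` with
#'   0-based half-open intervals, disjoint within a class.
#' @return Tibble `chrom`, `pos`, `site_class`.
#' @export
mask_to_sites <- function(mask) {
  mask <- tibble::as_tibble(mask)
  stopifnot(all(mask$start < mask$end))
  out <- tidyr::uncount(mask, weights = .data$end - .data$start, .id = "offset") |>
    dplyr::mutate(pos = .data$start + .data$offset - 1L) |>
    dplyr::select("chrom", "pos", "site_class")
  if (anyDuplicated(out[c("chrom", "pos")])) {
    stop("site classes overlap within a chromosome", call. = FALSE)
  }
  out
}

#' Ratio of 0-fold to 4-fold diversity
#'
#' pi0/pi4 as a proxy for the efficacy of purifying selection. Both
#' numerator and denominator are ratio-of-sums over their windows'
#' counts (never means of window ratios).
#'
#' @param windows [pi_windows()] output containing `zero_fold` and
#'   `four_fold` classes.
#' @return One-row tibble `pi0`, `pi4`, `pi0_pi4` (`NA` when pi4 is 0
#'   or undefined).
#' @export
pi0_pi4 <- function(windows) {
  agg <- function(cls) {
    w <- dplyr::filter(windows, .data$site_class == cls)
    if (nrow(w) == 0L || sum(w$n_comp) == 0) return(NA_real_)
    sum(w$n_diff) / sum(w$n_comp)
  }
  p0 <- agg("zero_fold")
  p4 <- agg("four_fold")
  tibble::tibble(
    pi0 = p0, pi4 = p4,
    pi0_pi4 = ifelse(is.na(p4) || p4 == 0, NA_real_, p0 / p4)
  )
}

#' Join diversity windows to recombination windows in common bins
#'
#' Re-aggregates diversity counts (ratio of sums) into bins aligned
#' with the recombination windows and attaches the covered-bp-weighted
#' recombination rate of each bin. Bins lacking either quantity are
#' dropped; the count of dropped bins is reported as an attribute
#' `n_dropped` and a message.
#'
#' @param div_windows [pi_windows()] output.
#' @param rec_windows [windowed_rates()] output (`chrom_id` column).
#' @param bin_bp Bin size, default 2 Mb; must be a multiple of the
#'   diversity window size for clean nesting.
#' @return Tibble `chrom`, `start`, `end`, `site_class`, `pi`,
#'   `rate_cm_per_mb`.
#' @export
join_to_recombination <- function(div_windows, rec_windows, bin_bp = 2e6) {
  dchrom <- unique(div_windows$chrom)
  rchrom <- unique(rec_windows$chrom_id)
  if (!all(dchrom %in% rchrom)) {
    stop("diversity chromosomes absent from recombination windows: ",
         paste(setdiff(dchrom, rchrom), collapse = ", "), call. = FALSE)
  }
  div <- div_windows |>
    dplyr::mutate(bin = (.data$start %/% bin_bp) * bin_bp) |>
    dplyr::group_by(.data$chrom, .data$bin, .data$site_class) |>
    dplyr::summarise(n_diff = sum(.data$n_diff), n_comp = sum(.data$n_comp),
                     .groups = "drop") |>
    dplyr::mutate(pi = ifelse(.data$n_comp > 0, .data$n_diff / .data$n_comp,
                              NA_real_))
  rec <- rec_windows |>
    dplyr::mutate(bin = (.data$start %/% bin_bp) * bin_bp) |>
    dplyr::group_by(chrom = .data$chrom_id, .data$bin) |>
    dplyr::summarise(
      rate_cm_per_mb = ifelse(sum(.data$covered_bp) > 0,
        sum(.data$rate_cm_per_mb * .data$covered_bp, na.rm = TRUE) /
          sum(.data$covered_bp),
        NA_real_),
      .groups = "drop"
    )
  joined <- dplyr::inner_join(div, rec, by = c("chrom", "bin"))
  ok <- !is.na(joined$pi) & !is.na(joined$rate_cm_per_mb)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " bin/class combinations dropped (missing pi or rate)")
  }
  out <- joined[ok, ] |>
    dplyr::mutate(start = .data$bin, end = .data$bin + bin_bp) |>
    dplyr::select("chrom", "start", "end", "site_class", "n_diff", "n_comp",
                  "pi", "rate_cm_per_mb")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' OLS regression with a permutation p-value
#'
#' Fits `y ~ x` by ordinary least squares and assesses the slope by
#' permuting `y` against `x`: p = (1 + #{|slope_perm| >= |slope_obs|})
#' / (1 + n_perm), two-sided, deterministic under `seed`.
#'
#' @param data Data frame.
#' @param x,y Column names (strings).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return One-row tibble `slope`, `intercept`, `r_squared`,
#'   `p_permuted`, `n`, `n_perm`.
#' @export
ols_permutation <- function(data, x, y, n_perm = 1000, seed = 1) {
  xv <- data[[x]]
  yv <- data[[y]]
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (stats::sd(xv) == 0) stop("x is constant", call. = FALSE)
  if (stats::sd(yv) == 0) stop("y is constant; R^2 undefined", call. = FALSE)
  fit <- stats::lm(yv ~ xv)
  slope <- unname(stats::coef(fit)[2])
  # slope under permutation only needs cov(x, y_perm); avoid refitting lm
  vx <- stats::var(xv)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  perm <- withr_seed(
    replicate(n_perm, abs(stats::cov(xv, sample(yv)) / vx))
  )
  tibble::tibble(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    p_permuted = (1 + sum(perm >= abs(slope))) / (1 + n_perm),
    n = length(xv),
    n_perm = n_perm
  )
}

#' Stratified regression above and below a recombination-rate cutoff
#'
#' Runs [ols_permutation()] separately on bins at or below and above
#' the cutoff (default 2 cM/Mb, where the diversity-recombination
#' relationship saturates). Strata with fewer than 3 bins are skipped
#' and reported with `NA` statistics.
#'
#' @param data Output of [join_to_recombination()] (single site class).
#' @param x,y Column names; defaults fit the join output.
#' @param cutoff Rate cutoff in cM/Mb.
#' @inheritParams ols_permutation
#' @return Tibble with a `stratum` column (`"low"`, `"high"`) and the
#'   [ols_permutation()] columns.
#' @export
threshold_split <- function(data, x = "rate_cm_per_mb", y = "pi",
                            cutoff = 2.0, n_perm = 1000, seed = 1) {
  strata <- list(low = data[data[[x]] <= cutoff, ],
                 high = data[data[[x]] > cutoff, ])
  purrr::imap_dfr(strata, function(d, name) {
    skipped <- function(why) {
      message("stratum '", name, "' skipped: ", why)
      tibble::tibble(stratum = name, slope = NA_real_,
                     intercept = NA_real_, r_squared = NA_real_,
                     p_permuted = NA_real_, n = nrow(d), n_perm = n_perm)
    }
    if (nrow(d) < 3L) return(skipped("fewer than 3 windows"))
    tryCatch(
      dplyr::mutate(ols_permutation(d, x, y, n_perm = n_perm, seed = seed),
                    stratum = name, .before = 1),
      error = function(e) skipped(conditionMessage(e))
    )
  })
}

#' Rank-based association tests
#'
#' `spearman_assoc` is Spearman's rank correlation with average-rank
#' ties; `wilcoxon_compare` is the two-sided Wilcoxon rank-sum test
#' with continuity correction. Both return tidy one-row tibbles.
#'
#' @param x,y Numeric vectors (paired for Spearman, two samples for
#'   Wilcoxon).
#' @return One-row tibble with the statistic and two-sided p-value.
#' @export
spearman_assoc <- function(x, y) {
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    stop("all-tied data: rho undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  tibble::tibble(statistic = "spearman_rho", value = unname(ct$estimate),
                 p = ct$p.value, n = sum(stats::complete.cases(x, y)))
}

#' @rdname spearman_assoc
#' @export
wilcoxon_compare <- function(x, y) {
  wt <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  tibble::tibble(statistic = "wilcoxon_W", value = unname(wt$statistic),
                 p = wt$p.value, n = length(x) + length(y))
}

#' Holm correction across site classes
#'
#' @param p Numeric p-values.
#' @return Holm-adjusted p-values (`stats::p.adjust`).
#' @export
adjust_site_class_p <- function(p) stats::p.adjust(p, method = "holm")
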