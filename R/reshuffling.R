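#' Interchromosomal reshuffling from independent assortment
#'
#' The probability that two loci drawn uniformly from the assembly lie
#' on different chromosomes and derive from different grandparental
#' haplotypes after independent assortment:
#' 0.5 * (1 - sum((l_i / L)^2)), with l_i the chromosome lengths and
#' L the assembly length.
#'
#' @param karyotype Karyotype tibble.
#' @return Probability in \[0, 0.5).
#' @export
#' @examples
#' kar <- tibble::tibble(chrom_id = c("a", "b"), length_bp = c(1e7, 1e7),
#'                       chrom_class = "autosome")
#' inter_reshuffling(kar) # 0.25
inter_reshuffling <- function(karyotype) {
  karyotype <- validate_karyotype(karyotype)
  p <- karyotype$length_bp / sum(karyotype$length_bp)
  0.5 * (1 - sum(p^2))
}

#' Expected reshuffling for n equal-sized chromosomes
#'
#' Closed form 0.5 * (1 - 1/n): the trajectory interchromosomal
#' reshuffling would follow if fissions kept all chromosomes equal.
#'
#' @param n Number of chromosomes (>= 1).
#' @return Probability in \[0, 0.5).
#' @export
equal_size_expectation <- function(n) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  0.5 * (1 - 1 / n)
}

#' Mean pairwise recombination fraction over pseudomarker pairs
#'
#' Workhorse shared by the map-based and closed-form intrachromosomal
#' estimators: places `n_pseudo` pseudomarkers evenly over \[0, 1\] in
#' relative physical coordinates and averages a recombination-fraction
#' function over all `choose(n_pseudo, 2)` pairs.
#'
#' @param rec_frac_fun Function of two relative positions in \[0, 1\]
#'   returning the recombination fraction between them (vectorized).
#' @param n_pseudo Number of pseudomarkers (>= 2).
#' @return Mean recombination fraction over pairs.
#' @export
#' @examples
#' # exactly one crossover uniform on the chromosome: r(a, b) = |a - b| / 2
#' pair_reshuffling(function(a, b) abs(a - b) / 2) # -> 1/6
pair_reshuffling <- function(rec_frac_fun, n_pseudo = 1000) {
  stopifnot(n_pseudo >= 2)
  pos <- seq(0, 1, length.out = n_pseudo)
  idx <- utils::combn(n_pseudo, 2)
  mean(rec_frac_fun(pos[idx[1, ]], pos[idx[2, ]]))
}

#' Intrachromosomal reshuffling of one chromosome
#'
#' Places `n_pseudo` evenly spaced pseudomarkers along the full
#' physical chromosome \[0, l\], reads their genetic positions off the
#' Marey map ([genetic_position_at()], clamped at the map ends), turns
#' every pairwise map distance into a recombination fraction with the
#' inverse map function, and averages over all pairs.
#'
#' @param map Canonical marker tibble for one chromosome.
#' @param chrom_length Chromosome length in bp.
#' @param n_pseudo Number of pseudomarkers.
#' @param map_fun `"kosambi"` (default, matching how maps are built) or
#'   `"haldane"`.
#' @return Probability in \[0, 0.5).
#' @export
intra_reshuffling_chrom <- function(map, chrom_length, n_pseudo = 1000,
                                    map_fun = c("kosambi", "haldane")) {
  map_fun <- match.arg(map_fun)
  stopifnot(n_pseudo >= 2, chrom_length > 0)
  if (nrow(map) < 2L || map_length(map) == 0) return(0)
  inv <- switch(map_fun,
    kosambi = inverse_kosambi_r,
    haldane = function(d) 0.5 * (1 - exp(-2 * d / 100))
  )
  bp <- seq(0, chrom_length, length.out = n_pseudo)
  cm <- genetic_position_at(map, bp, chrom_length = chrom_length)
  # mean over pairs of inv(|d_i - d_j|), computed without materializing
  # the full pair matrix
  n <- length(cm)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    tot <- tot + sum(inv(abs(cm[(i + 1L):n] - cm[i])))
  }
  tot / choose(n, 2)
}

#' Genome-wide intrachromosomal reshuffling
#'
#' Sums per-chromosome intrachromosomal reshuffling weighted by the
#' probability that two uniformly drawn loci fall on the same
#' chromosome, (l_c / L)^2. Chromosomes without markers must be
#' declared achiasmatic (zero map) explicitly via `zero_ok`; silently
#' treating a missing map as zero would understate the genome total.
#'
#' @param markers Canonical marker tibble covering the karyotype.
#' @param karyotype Karyotype tibble.
#' @param n_pseudo Pseudomarkers per chromosome.
#' @param map_fun Passed to [intra_reshuffling_chrom()].
#' @param zero_ok Chromosome ids allowed to lack markers (treated as
#'   intra = 0).
#' @return List with `intra_genome` (probability) and `intra_by_chrom`
#'   (tibble `chrom_id`, `intra`, `weight`).
#' @export
genome_intra <- function(markers, karyotype, n_pseudo = 1000,
                         map_fun = "kosambi", zero_ok = character()) {
  karyotype <- validate_karyotype(karyotype)
  L <- sum(karyotype$length_bp)
  missing <- setdiff(karyotype$chrom_id, c(unique(markers$chrom_id), zero_ok))
  if (length(missing)) {
    stop("no map and no zero declaration for chromosome(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  per <- purrr::pmap_dfr(
    list(karyotype$chrom_id, karyotype$length_bp),
    function(chrom, len) {
      map <- dplyr::filter(markers, .data$chrom_id == chrom)
      intra <- if (nrow(map) == 0L) 0 else {
        intra_reshuffling_chrom(map, len, n_pseudo = n_pseudo, map_fun = map_fun)
      }
      tibble::tibble(chrom_id = chrom, intra = intra, weight = (len / L)^2)
    }
  )
  list(intra_genome = sum(per$intra * per$weight), intra_by_chrom = per)
}

#' Full pairwise-reshuffling report
#'
#' Combines the interchromosomal closed form with the pseudomarker
#' intrachromosomal term into the genome-wide reshuffling probability
#' r-bar per sex. Females are achiasmatic (no crossing over), so their
#' total is the interchromosomal term alone; the sex average is the
#' mean of the two totals.
#'
#' @inheritParams genome_intra
#' @param population Label stored in the report (defaults to the
#'   markers' population).
#' @return An object of class `reshuffling_report`: a list with
#'   `population`, `inter`, `intra_genome`, `intra_by_chrom`,
#'   `total_male`, `total_female`, `sex_average`, `n_pseudo`.
#' @export
reshuffling_report <- function(markers, karyotype, n_pseudo = 1000,
                               map_fun = "kosambi", zero_ok = character(),
                               population = NULL) {
  inter <- inter_reshuffling(karyotype)
  gi <- genome_intra(markers, karyotype, n_pseudo = n_pseudo,
                     map_fun = map_fun, zero_ok = zero_ok)
  totals(inter, gi$intra_genome,
         intra_by_chrom = gi$intra_by_chrom, n_pseudo = n_pseudo,
         population = population %||% markers$population[[1]])
}

#' Assemble reshuffling totals from components
#'
#' total_male = inter + intra; total_female = inter (achiasmatic
#' females contribute no intrachromosomal reshuffling); sex average is
#' their mean. A total above 0.5 is impossible for a probability of
#' pairwise difference in origin and raises an error.
#'
#' @param inter Interchromosomal probability.
#' @param intra_genome Genome-wide intrachromosomal probability.
#' @param intra_by_chrom Optional per-chromosome tibble (diagnostic).
#' @param n_pseudo Pseudomarker count used (metadata).
#' @param population Population label.
#' @return A `reshuffling_report` object.
#' @export
totals <- function(inter, intra_genome, intra_by_chrom = NULL,
                   n_pseudo = NA_integer_, population = NA_character_) {
  stopifnot(inter >= 0, inter <= 0.5, intra_genome >= 0)
  total_male <- inter + intra_genome
  if (total_male > 0.5 + 1e-12) {
    stop("total reshuffling exceeds 0.5: impossible under the model",
         call. = FALSE)
  }
  structure(
    list(
      population = population,
      inter = inter,
      intra_genome = intra_genome,
      intra_by_chrom = intra_by_chrom,
      total_male = total_male,
      total_female = inter,
      sex_average = (total_male + inter) / 2,
      n_pseudo = n_pseudo
    ),
    class = "reshuffling_report"
  )
}

#' @export
print.reshuffling_report <- function(x, ...) {
  cat("Pairwise reshuffling report",
      if (!is.na(x$population)) paste0("(", x$population, ")"), "\n")
  cat(sprintf("  inter (assortment): %.4f\n", x$inter))
  cat(sprintf("  intra (crossover) : %.4f\n", x$intra_genome))
  cat(sprintf("  total male  %.4f | total female %.4f | sex average %.4f\n",
              x$total_male, x$total_female, x$sex_average))
  invisible(x)
}

#' Tidy a reshuffling report
#'
#' One row per population in the layout of a published reshuffling
#' table: intra/inter/total per sex plus the sex average, at full
#' precision.
#'
#' @param x A `reshuffling_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy reshuffling_report
#' @export
tidy.reshuffling_report <- function(x, ...) {
  tibble::tibble(
    population = x$population,
    intra_male = x$intra_genome,
    inter_male = x$inter,
    total_male = x$total_male,
    intra_female = 0,
    inter_female = x$total_female,
    sex_average = x$sex_average
  )
}

#' Glance at a reshuffling report
#'
#' @param x A `reshuffling_report`.
#' @param ... Unused.
#' @return One-row tibble of summary quantities, including the
#'   inter/intra ratio.
#' @method glance reshuffling_report
#' @export
glance.reshuffling_report <- function(x, ...) {
  tibble::tibble(
    population = x$population,
    sex_average = x$sex_average,
    inter_intra_ratio = x$inter / x$intra_genome,
    n_pseudo = x$n_pseudo
  )
}

#' Reshuffling of fixed crossover placements
#'
#' For chiasmata at fixed relative positions on a chromosome, the
#' probability that two uniformly drawn loci differ in grandparental
#' origin is 0.5 * P(odd number of chiasmata between them): the parity
#' of intervening chiasmata decides whether the recombinant product
#' switches origin, and the sampled chromatid carries the recombinant
#' pattern with probability 1/2. Computed exactly from the segment
#' lengths between chiasmata. A single chiasma at the center and a
#' pair at the 1/4 and 3/4 points both give 0.25.
#'
#' @param positions Chiasma positions as fractions of chromosome
#'   length, in (0, 1).
#' @return Probability in \[0, 0.5\].
#' @export
reshuffling_from_crossovers <- function(positions) {
  stopifnot(all(positions > 0 & positions < 1))
  cuts <- c(0, sort(positions), 1)
  seg <- diff(cuts)               # segment lengths
  parity <- (seq_along(seg) - 1) %% 2
  p_even <- sum(seg[parity == 0])
  p_odd <- sum(seg[parity == 1])
  # two uniform loci sit across an odd chiasma count iff their segments
  # have different parity: P = 2 * p_even * p_odd
  0.5 * 2 * p_even * p_odd
}

#' Contrasts between two populations' reshuffling components
#'
#' Given a reshuffling table with one row per population (columns
#' `population`, `intra_male`, `inter_male`, `total_male`,
#' `inter_female`, `sex_average`), computes the derived comparisons:
#' the percent excess of one population's male intrachromosomal
#' contribution over the other's, the inter/intra ratio within each
#' population, and the proportional difference in sex-averaged total
#' reshuffling.
#'
#' @param table Two-row reshuffling tibble.
#' @param ref Population treated as the baseline of the contrasts.
#' @return A tibble of named contrasts (`quantity`, `value`).
#' @export
reshuffling_contrasts <- function(table, ref = table$population[[1]]) {
  stopifnot(nrow(table) == 2L, ref %in% table$population)
  other <- setdiff(table$population, ref)
  r <- table[match(ref, table$population), ]
  o <- table[match(other, table$population), ]
  tibble::tibble(
    quantity = c(
      paste0("intra_male_excess_pct_", other, "_over_", ref),
      paste0("inter_intra_ratio_", ref),
      paste0("inter_intra_ratio_", other),
      "sex_average_prop_diff_pct"
    ),
    value = c(
      (o$intra_male - r$intra_male) / r$intra_male * 100,
      r$inter_male / r$intra_male,
      o$inter_male / o$intra_male,
      abs(o$sex_average - r$sex_average) / min(o$sex_average, r$sex_average) * 100
    )
  )
}
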