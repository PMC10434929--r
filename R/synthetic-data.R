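#' Simulate a pair of karyotypes diverged by fissions and fusions
#'
#' Starting from an ancestral karyotype, applies `n_fissions` random
#' fissions (split at a uniform internal point) to one descendant
#' lineage and `n_fusions` random fusions (concatenation of two
#' randomly chosen chromosomes) to the other, conserving total bp.
#' Emits a homology block table mapping each unbroken ancestral
#' segment into both derived assemblies — the substrate for
#' [block_summaries()].
#'
#' @param ancestral Karyotype tibble of the common ancestor.
#' @param n_fissions Fissions applied to lineage 1.
#' @param n_fusions Fusions applied to lineage 2.
#' @param seed Integer seed.
#' @param labels Population labels for the two lineages.
#' @return List: `karyotype_pop1` (fissioned), `karyotype_pop2`
#'   (fused), `blocks` (block table with coordinates in both derived
#'   assemblies and `history_class`).
#' @export
simulate_karyotype_pair <- function(ancestral, n_fissions = 5, n_fusions = 5,
                                    seed = 1,
                                    labels = c("pop1_fission", "pop2_fusion")) {
  ancestral <- validate_karyotype(ancestral)
  set.seed(seed)

  # lineage 1: fissions. Track segments as (anc chrom, anc start/end).
  seg1 <- tibble::tibble(
    anc_chrom = ancestral$chrom_id, anc_start = 0, anc_end = ancestral$length_bp,
    chrom_id = ancestral$chrom_id, chrom_class = ancestral$chrom_class,
    was_split = FALSE
  )
  for (i in seq_len(n_fissions)) {
    splittable <- which(seg1$anc_end - seg1$anc_start >= 2)
    if (!length(splittable)) stop("no chromosome left to split", call. = FALSE)
    j <- sample(splittable, 1)
    len <- seg1$anc_end[j] - seg1$anc_start[j]
    at <- seg1$anc_start[j] + sample.int(len - 1L, 1) # internal, bp-resolution
    top <- seg1[j, ]
    parts <- dplyr::bind_rows(
      dplyr::mutate(top, anc_end = at, chrom_id = paste0(top$chrom_id, "a"),
                    was_split = TRUE),
      dplyr::mutate(top, anc_start = at, chrom_id = paste0(top$chrom_id, "b"),
                    was_split = TRUE)
    )
    seg1 <- dplyr::bind_rows(seg1[-j, ], parts)
  }
  kar1 <- seg1 |>
    dplyr::transmute(population = labels[1], chrom_id = .data$chrom_id,
                     length_bp = .data$anc_end - .data$anc_start,
                     chrom_class = .data$chrom_class)

  # lineage 2: fusions. Each chromosome is a list of ancestral segments.
  chroms2 <- purrr::pmap(
    list(ancestral$chrom_id, ancestral$length_bp, ancestral$chrom_class),
    function(id, len, cls) list(id = id, class = cls,
                                segs = tibble::tibble(anc_chrom = id,
                                                      anc_start = 0,
                                                      anc_end = len))
  )
  for (i in seq_len(n_fusions)) {
    if (length(chroms2) < 2L) stop("fusion requested with one chromosome",
                                   call. = FALSE)
    pick <- sample(length(chroms2), 2)
    a <- chroms2[[pick[1]]]; b <- chroms2[[pick[2]]]
    fused <- list(
      id = paste0(a$id, "+", b$id),
      class = if ("Z" %in% c(a$class, b$class)) "Z" else "autosome",
      segs = dplyr::bind_rows(a$segs, b$segs)
    )
    chroms2 <- c(chroms2[-pick], list(fused))
  }
  kar2 <- purrr::map_dfr(chroms2, function(ch) {
    tibble::tibble(population = labels[2], chrom_id = ch$id,
                   length_bp = sum(ch$segs$anc_end - ch$segs$anc_start),
                   chrom_class = ch$class)
  })

  # homology blocks: intersect lineage-1 breakpoints with lineage-2 layout.
  # Lineage 2 never breaks ancestral chromosomes, so blocks are exactly the
  # lineage-1 segments, located inside the fused chromosomes of lineage 2.
  offsets2 <- purrr::map_dfr(chroms2, function(ch) {
    dplyr::mutate(ch$segs, chrom2 = ch$id, was_fused = nrow(ch$segs) > 1L,
                  offset2 = cumsum(dplyr::lag(.data$anc_end - .data$anc_start,
                                              default = 0)))
  })
  blocks <- seg1 |>
    dplyr::left_join(offsets2, by = "anc_chrom",
                     suffix = c("", "_full")) |>
    dplyr::transmute(
      block_id = paste0("blk_", dplyr::row_number()),
      anc_chrom = .data$anc_chrom,
      chrom_pop1 = .data$chrom_id, start_pop1 = 0,
      end_pop1 = .data$anc_end - .data$anc_start,
      chrom_pop2 = .data$chrom2,
      start_pop2 = .data$offset2 + .data$anc_start,
      end_pop2 = .data$offset2 + .data$anc_end,
      history_class = dplyr::case_when(
        .data$was_split & .data$was_fused ~ "ILS_or_breakpoint_reuse",
        .data$was_split ~ "fission_after_split",
        .data$was_fused ~ "fusion_after_split",
        TRUE ~ "unchanged"
      )
    )
  # start_pop1 must be the segment's offset within its pop1 chromosome;
  # fission pieces are whole pop1 chromosomes, so offset 0 is exact.
  list(karyotype_pop1 = validate_karyotype(kar1),
       karyotype_pop2 = validate_karyotype(kar2),
       blocks = blocks)
}

#' Simulate chiasma positions for one meiosis
#'
#' Returns chiasma positions on the bivalent, on the genetic (cM)
#' scale of a chromosome with map length `genetic_length_cm`. Two
#' models:
#'
#' * `obligate_plus_poisson`: one obligate chiasma uniform on the map
#'   plus `Poisson(max(0, G/50 - 1))` additional ones.
#' * `gamma_renewal`: a stationary gamma renewal process with shape
#'   `nu` and mean inter-chiasma spacing 50 cM; `nu = 1` is the
#'   no-interference Poisson case, larger `nu` gives more regular
#'   spacing (crossover interference).
#'
#' Female meiosis is achiasmatic: always zero chiasmata. Thinning of
#' chiasmata to chromatid crossovers (probability 1/2 each, no
#' chromatid interference) is applied downstream at gamete formation.
#'
#' @param genetic_length_cm Map length G of the bivalent, cM.
#' @param co_model `"gamma_renewal"` (default) or
#'   `"obligate_plus_poisson"`.
#' @param nu Gamma shape (interference strength), >= 1.
#' @param sex `"male"` or `"female"`.
#' @return Numeric vector of chiasma positions in cM (possibly empty).
#' @export
simulate_meiosis <- function(genetic_length_cm,
                             co_model = c("gamma_renewal",
                                          "obligate_plus_poisson"),
                             nu = 5, sex = c("male", "female")) {
  co_model <- match.arg(co_model)
  sex <- match.arg(sex)
  stopifnot(genetic_length_cm >= 0, nu >= 1)
  if (sex == "female" || genetic_length_cm == 0) return(numeric(0))
  G <- genetic_length_cm
  if (co_model == "obligate_plus_poisson") {
    extra <- stats::rpois(1, max(0, G / 50 - 1))
    sort(stats::runif(1 + extra, 0, G))
  } else {
    # stationary renewal: first event from the equilibrium (length-biased
    # residual) distribution, then iid gamma(nu, rate nu/50) spacings
    rate <- nu / 50
    pos <- equilibrium_gamma_residual(1, nu, rate)
    out <- numeric(0)
    while (pos <= G) {
      out <- c(out, pos)
      pos <- pos + stats::rgamma(1, shape = nu, rate = rate)
    }
    out
  }
}

# Residual-life draw for a stationary gamma renewal process: the mixture
# representation Gamma(U + something) is awkward; use the fact that the
# equilibrium density is S(x)/mu and sample by inversion on a fine grid.
equilibrium_gamma_residual <- function(n, shape, rate) {
  mu <- shape / rate
  # residual density f_e(x) = (1 - pgamma(x, shape, rate)) / mu; sample via
  # the mixture identity: X_e ~ Gamma(shape = K, rate) with K uniform on
  # {1, ..., shape} only for integer shape. General shape: numeric inversion.
  u <- stats::runif(n)
  grid <- seq(0, stats::qgamma(1 - 1e-10, shape, rate) * 2, length.out = 4096)
  cdf <- cumsum((1 - stats::pgamma(grid, shape, rate)) / mu) * diff(grid)[1]
  cdf <- cdf / max(cdf) # guard tail truncation
  stats::approx(cdf, grid, xout = u, rule = 2, ties = "ordered")$y
}

#' Simulate pedigree gametes over a karyotype
#'
#' For each offspring gamete and chromosome: sample chiasmata with
#' [simulate_meiosis()] on the chromosome's true map length, thin each
#' chiasma to the sampled chromatid with probability 1/2 (no chromatid
#' interference), map crossover positions from cM to bp through the
#' true Marey map, and record the grandparental origin (0/1) at each
#' marker as the parity of crossovers to its left, started from a
#' random phase. Female-meiosis gametes are non-recombinant on every
#' chromosome.
#'
#' @param karyotype Karyotype tibble.
#' @param maps Canonical marker tibble of the true maps (every
#'   karyotype chromosome present).
#' @param n_offspring Number of gametes.
#' @param seed Integer seed.
#' @param co_model,nu Passed to [simulate_meiosis()].
#' @param sex Meiosis sex for all gametes.
#' @param marker_bp Marker grid: positions per chromosome (defaults to
#'   the map's own marker positions).
#' @param n_grid If `marker_bp` is `NULL` and `n_grid` is given, use
#'   `n_grid` evenly spaced markers per chromosome instead.
#' @return A `gamete_table`: list with `positions` (tibble `chrom_id`,
#'   `marker`, `phys_bp`, `gen_cm`), `origins` (named list per
#'   chromosome of n_offspring x n_marker 0/1 matrices), `sex`,
#'   `seed`.
#' @export
simulate_pedigree_gametes <- function(karyotype, maps, n_offspring,
                                      seed = 1, co_model = "gamma_renewal",
                                      nu = 5, sex = "male",
                                      marker_bp = NULL, n_grid = NULL) {
  karyotype <- validate_karyotype(karyotype)
  set.seed(seed)
  positions <- list()
  origins <- list()
  for (ci in seq_len(nrow(karyotype))) {
    chrom <- karyotype$chrom_id[[ci]]
    len <- karyotype$length_bp[[ci]]
    map <- dplyr::filter(maps, .data$chrom_id == chrom)
    if (nrow(map) == 0L) stop("no map for chromosome ", chrom, call. = FALSE)
    bp <- if (!is.null(marker_bp)) marker_bp[[chrom]]
          else if (!is.null(n_grid)) seq(0, len, length.out = n_grid)
          else map$phys_bp
    cm <- genetic_position_at(map, bp, chrom_length = len)
    G <- map_length(map)
    M <- matrix(0L, nrow = n_offspring, ncol = length(bp))
    for (g in seq_len(n_offspring)) {
      phase <- stats::rbinom(1, 1, 0.5)
      if (sex == "male" && G > 0) {
        chi <- simulate_meiosis(G, co_model = co_model, nu = nu, sex = sex)
        co <- chi[stats::runif(length(chi)) < 0.5] # chromatid thinning
        if (length(co)) {
          n_left <- findInterval(cm, sort(co))
          M[g, ] <- (phase + n_left) %% 2L
          next
        }
      }
      M[g, ] <- phase
    }
    positions[[chrom]] <- tibble::tibble(
      chrom_id = chrom, marker = seq_along(bp), phys_bp = bp, gen_cm = cm
    )
    origins[[chrom]] <- M
  }
  structure(
    list(positions = dplyr::bind_rows(positions), origins = origins,
         sex = sex, seed = seed),
    class = "gamete_table"
  )
}

#' @export
print.gamete_table <- function(x, ...) {
  n_g <- nrow(x$origins[[1]])
  cat("gamete table:", n_g, x$sex, "gametes,",
      length(x$origins), "chromosomes,",
      nrow(x$positions), "markers total (seed ", x$seed, ")\n")
  invisible(x)
}

#' Estimate a linkage map from gamete origins
#'
#' The empirical recombinant fraction of each adjacent marker pair
#' (fraction of gametes whose origin differs between the two markers)
#' is converted to map distance with the Kosambi map function and
#' cumulated along the chromosome. Recombinant fractions at or above
#' 0.49 are capped there with a warning (the map function diverges at
#' 0.5). Monomorphic origin columns carry no information and simply
#' yield zero-length intervals.
#'
#' @param gametes A `gamete_table`.
#' @param population Label for the output maps.
#' @return Canonical marker tibble of estimated maps.
#' @export
estimate_map_from_gametes <- function(gametes, population = "estimated") {
  stopifnot(inherits(gametes, "gamete_table"))
  out <- purrr::imap(gametes$origins, function(M, chrom) {
    if (nrow(M) < 10L) stop("need at least 10 gametes", call. = FALSE)
    pos <- gametes$positions |>
      dplyr::filter(.data$chrom_id == chrom) |>
      dplyr::pull("phys_bp")
    if (ncol(M) < 2L) stop("need at least 2 markers on ", chrom, call. = FALSE)
    rhat <- colMeans(M[, -1L, drop = FALSE] != M[, -ncol(M), drop = FALSE])
    if (any(rhat >= 0.49)) {
      warning("recombinant fraction capped at 0.49 on ", chrom, call. = FALSE)
      rhat <- pmin(rhat, 0.49)
    }
    tibble::tibble(
      population = population, chrom_id = chrom, phys_bp = pos,
      gen_cm = c(0, cumsum(kosambi_cm(rhat)))
    )
  })
  dplyr::bind_rows(out)
}

#' Empirical pairwise reshuffling from simulated gametes
#'
#' The gamete-level oracle for the analytical r-bar: the probability
#' that two random loci differ in grandparental origin, estimated over
#' gametes. Within chromosomes, all marker pairs are enumerated
#' exactly; across chromosomes, the origin correlation reduces to
#' per-chromosome frequencies, so the inter term is computed exactly
#' from per-gamete chromosome origins at marker resolution. Locus
#' pairs are weighted length-proportionally via the chromosome weights
#' (l_c / L), matching the definition of genome-wide r-bar.
#'
#' @param gametes A `gamete_table` (dense marker grid recommended).
#' @param karyotype Karyotype tibble.
#' @return List: `total`, `inter`, `intra_genome`, `intra_by_chrom`
#'   (tibble).
#' @export
rbar_from_gametes <- function(gametes, karyotype) {
  stopifnot(inherits(gametes, "gamete_table"))
  karyotype <- validate_karyotype(karyotype)
  if (!length(gametes$origins)) stop("empty gamete table", call. = FALSE)
  L <- sum(karyotype$length_bp)
  w <- stats::setNames(karyotype$length_bp / L, karyotype$chrom_id)

  # intra: exact enumeration of marker pairs within each chromosome
  intra <- purrr::imap_dfr(gametes$origins, function(M, chrom) {
    m <- ncol(M)
    # mean over gametes and pairs of 1[origin differs]; with 0/1 matrix O,
    # number of differing pairs per gamete = s * (m - s), s = rowSums
    s <- rowSums(M)
    tibble::tibble(chrom_id = chrom,
                   intra = mean(s * (m - s)) / choose(m, 2))
  })
  intra_genome <- sum(intra$intra * unname(w[intra$chrom_id])^2)

  # inter: for loci on different chromosomes c != d, P(origin differs) =
  # mean over gametes of p_c (1 - p_d) + (1 - p_c) p_d at marker resolution
  pc <- purrr::map(gametes$origins, rowMeans) # per gamete mean origin
  chroms <- names(pc)
  inter <- 0
  for (a in seq_along(chroms)) {
    for (b in seq_along(chroms)) {
      if (a == b) next
      pa <- pc[[a]]; pb <- pc[[b]]
      inter <- inter + w[[chroms[a]]] * w[[chroms[b]]] *
        mean(pa * (1 - pb) + (1 - pa) * pb)
    }
  }
  list(total = inter + intra_genome, inter = inter,
       intra_genome = intra_genome, intra_by_chrom = intra)
}

#' Simulate windowed diversity from a recombination landscape
#'
#' Plants a saturating diversity-recombination relationship:
#' pi_w = pop_scaler * pi_max * rho_w / (rho_w + rho_50) * exp(eps),
#' eps ~ Normal(0, sigma^2), emitted as pixy-style difference and
#' comparison counts at a stated per-window comparison depth so that
#' downstream ratio-of-sums aggregation works unchanged. Windows with
#' undefined recombination rate get zero comparisons.
#'
#' @param rec_windows [windowed_rates()] output.
#' @param pi_max Asymptotic diversity at high recombination.
#' @param rho_50 Rate (cM/Mb) at which diversity is half the asymptote.
#' @param sigma Lognormal noise sd (0 for deterministic).
#' @param pop_scaler Multiplicative population effect on diversity.
#' @param comparisons_per_window Comparison depth per window.
#' @param site_class Class label stamped on the windows.
#' @param seed Integer seed.
#' @return [pi_windows()]-shaped tibble.
#' @export
simulate_diversity <- function(rec_windows, pi_max = 0.01, rho_50 = 1.0,
                               sigma = 0.2, pop_scaler = 1.0,
                               comparisons_per_window = 1e6,
                               site_class = "intergenic", seed = 1) {
  set.seed(seed)
  rho <- rec_windows$rate_cm_per_mb
  eps <- stats::rnorm(length(rho), 0, sigma)
  pi <- pop_scaler * pi_max * rho / (rho + rho_50) * exp(eps)
  n_comp <- ifelse(is.na(rho), 0, comparisons_per_window)
  tibble::tibble(
    chrom = rec_windows$chrom_id,
    start = rec_windows$start,
    end = rec_windows$end,
    site_class = site_class,
    n_sites = NA_integer_,
    n_diff = ifelse(is.na(rho), 0, round(pi * comparisons_per_window)),
    n_comp = n_comp,
    pi = ifelse(n_comp > 0, round(pi * comparisons_per_window) / n_comp,
                NA_real_)
  )
}

#' Build a uniform-rate Marey map
#'
#' Convenience generator: `n_markers` evenly spaced markers with a
#' constant recombination rate, i.e. a linear Marey map of total
#' length `length_bp / 1e6 * rate` cM.
#'
#' @param chrom_id Chromosome id.
#' @param length_bp Chromosome length.
#' @param rate Rate in cM/Mb.
#' @param n_markers Number of markers.
#' @param population Population label.
#' @return Canonical marker tibble.
#' @export
linear_map <- function(chrom_id, length_bp, rate = 1, n_markers = 11,
                       population = "sim") {
  bp <- seq(0, length_bp, length.out = n_markers)
  tibble::tibble(population = population, chrom_id = chrom_id,
                 phys_bp = bp, gen_cm = bp / 1e6 * rate)
}
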