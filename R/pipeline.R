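#' Build a pipeline configuration
#'
#' Collects the constants every stage uses. Defaults are the standard
#' analysis settings: 2 Mb recombination windows, 50 kb diversity
#' windows, 1,000 pseudomarkers, 1,000 permutations, 18 Mb
#' large-chromosome threshold, 2 cM/Mb stratification cutoff.
#'
#' @param window_bp_rec Recombination window size (bp).
#' @param window_bp_pi Diversity window size (bp).
#' @param n_pseudo Pseudomarkers per chromosome for reshuffling.
#' @param n_perm Permutations for permutation tests.
#' @param size_threshold_bp Large/small chromosome boundary (bp).
#' @param rate_cutoff Stratification cutoff (cM/Mb).
#' @param include_Z Keep Z chromosomes in genome-wide statistics?
#' @param loess_span LOESS span for profile smoothing.
#' @param seed Integer seed for every stochastic step.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_bp_rec = 2e6, window_bp_pi = 5e4,
                            n_pseudo = 1000, n_perm = 1000,
                            size_threshold_bp = 18e6, rate_cutoff = 2.0,
                            include_Z = TRUE, loess_span = 0.75, seed = 1) {
  stopifnot(window_bp_rec > 0, window_bp_pi > 0, n_pseudo >= 2)
  if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse",
                            call. = FALSE)
  structure(
    list(window_bp_rec = window_bp_rec, window_bp_pi = window_bp_pi,
         n_pseudo = n_pseudo, n_perm = n_perm,
         size_threshold_bp = size_threshold_bp, rate_cutoff = rate_cutoff,
         include_Z = include_Z, loess_span = loess_span, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full two-population analysis
#'
#' Orchestrates the stages — maps, landscape, reshuffling, diversity,
#' blocks — over a two-population input set, writing one TSV/JSON
#' artifact per stage into `outdir` plus a MANIFEST recording seed,
#' config and completion. Stages that lack their inputs are skipped
#' and marked in the MANIFEST; a missing input that was explicitly
#' requested is an error naming the gap.
#'
#' @param inputs Named list with elements per population label:
#'   `karyotype`, `markers`, optionally `genotypes` or `div_windows`
#'   (pre-computed [pi_windows()] output); and optionally a shared
#'   `blocks` table (`pop1`/`pop2` coordinates follow the order of
#'   `inputs$populations`).
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created; must be empty or absent —
#'   artifacts are write-once).
#' @param stages Character vector of stages to run; default all.
#' @return Invisibly, a named list of all stage results.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), outdir,
                         stages = c("landscape", "reshuffle", "diversity",
                                    "blocks")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(outdir) && length(dir(outdir))) {
    stop("outdir exists and is not empty (artifacts are write-once): ",
         outdir, call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pops <- inputs$populations
  stopifnot(length(pops) == 2L)
  results <- list(config = unclass(config))
  manifest <- list(seed = config$seed, stages_completed = character())

  keep_chroms <- function(kar) {
    if (config$include_Z) kar else dplyr::filter(kar, .data$chrom_class != "Z")
  }

  for (p in pops) {
    kar <- keep_chroms(inputs[[p]]$karyotype)
    markers <- dplyr::filter(inputs[[p]]$markers,
                             .data$chrom_id %in% kar$chrom_id)

    if ("landscape" %in% stages) {
      win <- windowed_rates(markers, kar, window_bp = config$window_bp_rec)
      prof <- folded_profile(win, kar,
                             size_threshold_bp = config$size_threshold_bp)
      readr::write_tsv(prof, file.path(outdir, paste0(p, "_landscape.tsv")),
                       progress = FALSE)
      results[[p]]$landscape <- prof
      results[[p]]$chrom_rates <- chromosome_mean_rate(markers)
      results[[p]]$excess <- excess_map_length(markers)
    }

    if ("reshuffle" %in% stages) {
      rep_ <- reshuffling_report(markers, kar, n_pseudo = config$n_pseudo,
                                 population = p)
      jsonlite::write_json(
        rep_[c("population", "inter", "intra_genome", "total_male",
               "total_female", "sex_average")],
        file.path(outdir, paste0(p, "_reshuffling.json")),
        auto_unbox = TRUE, digits = NA)
      results[[p]]$reshuffling <- rep_
    }

    if ("diversity" %in% stages) {
      div <- inputs[[p]]$div_windows
      if (is.null(div) && !is.null(inputs[[p]]$genotypes)) {
        div <- pi_windows(inputs[[p]]$genotypes, sites = inputs[[p]]$sites,
                          window_bp = config$window_bp_pi)
      }
      if (is.null(div)) {
        manifest[[paste0(p, "_diversity")]] <- "skipped: no input"
      } else {
        win <- results[[p]]$landscape %||%
          windowed_rates(markers, kar, window_bp = config$window_bp_rec)
        joined <- join_to_recombination(div, win, bin_bp = config$window_bp_rec)
        readr::write_tsv(joined, file.path(outdir, paste0(p, "_diversity.tsv")),
                         progress = FALSE)
        results[[p]]$diversity <- div
        results[[p]]$joined <- joined
        results[[p]]$assoc <- ols_permutation(joined, "rate_cm_per_mb", "pi",
                                              n_perm = config$n_perm,
                                              seed = config$seed)
        results[[p]]$assoc_split <- threshold_split(
          joined, cutoff = config$rate_cutoff, n_perm = config$n_perm,
          seed = config$seed)
      }
    }
  }

  if ("reshuffle" %in% stages) {
    tab <- dplyr::bind_rows(purrr::map(pops, ~ tidy(results[[.x]]$reshuffling)))
    write_reports(tab, outdir)
    results$reshuffling_table <- tab
  }

  if ("blocks" %in% stages) {
    if (is.null(inputs$blocks)) {
      if (identical(stages, "blocks")) {
        stop("blocks stage requested but no block table provided", call. = FALSE)
      }
      manifest$blocks <- "skipped: no block table"
    } else {
      d1 <- results[[pops[1]]]$diversity %||% inputs[[pops[1]]]$div_windows
      d2 <- results[[pops[2]]]$diversity %||% inputs[[pops[2]]]$div_windows
      bs <- block_summaries(inputs$blocks,
                            inputs[[pops[1]]]$markers,
                            inputs[[pops[2]]]$markers, d1, d2)
      fit <- model2_regression(dplyr::filter(bs, .data$defined),
                               n_perm = config$n_perm, seed = config$seed)
      readr::write_tsv(bs, file.path(outdir, "blocks.tsv"), progress = FALSE)
      jsonlite::write_json(glance(fit), file.path(outdir, "block_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      results$blocks <- bs
      results$block_fit <- fit
    }
  }

  manifest$stages_completed <- stages
  manifest$config <- unclass(config)
  jsonlite::write_json(manifest, file.path(outdir, "MANIFEST.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Write a published-table-shaped reshuffling TSV
#'
#' Rounds reshuffling probabilities to 3 decimals at serialization
#' only; callers keep full precision in memory and in JSON artifacts.
#'
#' @param table Tidy reshuffling table ([tidy.reshuffling_report()]
#'   rows).
#' @param outdir Output directory.
#' @return Path of the written TSV, invisibly.
#' @export
write_reports <- function(table, outdir) {
  rounded <- dplyr::mutate(table, dplyr::across(dplyr::where(is.numeric),
                                                ~ round(.x, 3)))
  path <- file.path(outdir, "reshuffling_table.tsv")
  readr::write_tsv(rounded, path, progress = FALSE)
  invisible(path)
}

#' Published reshuffling estimates for the two study populations
#'
#' The reshuffling decomposition reported for the Catalan
#' (2n = 106-110) and Swedish (2n = 56-57) wood white populations:
#' male intra- and interchromosomal components, per-sex totals and the
#' sex average. Shipped as plain text in `extdata`; used as the input
#' for desk-level contrasts ([reshuffling_contrasts()]).
#'
#' @return Tibble with one row per population.
#' @export
published_reshuffling <- function() {
  readr::read_tsv(
    system.file("extdata", "published_reshuffling.tsv", package = "reshufflr"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Published block-regression coefficients
#'
#' Intercept and slope of the published model II regression of the
#' Catalan/Swedish intergenic-diversity ratio on the recombination-
#' rate ratio across ancestral chromosomal units.
#'
#' @return One-row tibble `intercept`, `slope`.
#' @export
published_block_fit <- function() {
  readr::read_tsv(
    system.file("extdata", "published_block_fit.tsv", package = "reshufflr"),
    show_col_types = FALSE, progress = FALSE
  )
}
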