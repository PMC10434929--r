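test_that("degeneracy classes of canonical codons are correct", {
  # one transcript: ATG GGG TTA TAA on the plus strand
  genome <- c(chr = "ATGGGGTTATAA")
  cds <- tibble::tibble(chrom = "chr", start = 0L, end = 12L, strand = "+",
                        phase = 0L, transcript_id = "t1")
  cls <- classify_degeneracy(cds, genome)
  get <- function(p) cls$site_class[match(p, cls$pos)]
  expect_equal(get(0:2), rep("zero_fold", 3))     # ATG: Met, single codon
  expect_equal(get(3:4), rep("zero_fold", 2))     # GGG positions 1-2
  expect_equal(get(5), "four_fold")               # GGN family
  expect_true(is.na(get(6)))                      # TTA pos 1: 2-fold, excluded
})

test_that("degeneracy classification matches brute force over all 64 codons", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste0, collapse = "")
  # independent oracle via seqinr's translation
  translate1 <- function(cod) seqinr::translate(strsplit(cod, "")[[1]])
  oracle <- sapply(codons, function(cod) {
    sapply(1:3, function(p) {
      ref <- translate1(cod)
      alt <- setdiff(bases, substr(cod, p, p))
      aas <- sapply(alt, function(b) {
        x <- cod; substr(x, p, p) <- b; translate1(x)
      })
      if (all(aas == ref)) "four_fold"
      else if (all(aas != ref)) "zero_fold"
      else "none"
    })
  })
  got <- sapply(codons, function(cod) {
    genome <- c(chr = cod)
    cds <- tibble::tibble(chrom = "chr", start = 0L, end = 3L, strand = "+",
                          phase = 0L, transcript_id = "t")
    res <- suppressWarnings(classify_degeneracy(cds, genome))
    out <- rep("none", 3)
    if (nrow(res)) out[res$pos + 1] <- res$site_class
    out
  })
  # stop codons are skipped by the transcript validator (internal-stop rule
  # does not apply to a terminal stop, which is still classified)
  expect_equal(got, oracle)
  # 8 four-fold codon families -> 32 codons with a 4-fold third position
  expect_equal(sum(oracle == "four_fold"), 32)
})

test_that("minus-strand and phase-shifted CDS classify consistently", {
  # reverse complement of ATGGGG placed on the minus strand
  genome <- c(chr = "CCCCAT")
  cds <- tibble::tibble(chrom = "chr", start = 0L, end = 6L, strand = "-",
                        phase = 0L, transcript_id = "t1")
  cls <- classify_degeneracy(cds, genome)
  # genomic position 0 is the third base of codon GGG -> four-fold
  expect_equal(cls$site_class[cls$pos == 0], "four_fold")
  # phase 1 drops one base and the remainder is not a multiple of 3
  cds2 <- tibble::tibble(chrom = "chr", start = 0L, end = 6L, strand = "+",
                         phase = 1L, transcript_id = "t2")
  expect_warning(classify_degeneracy(cds2, genome), "multiple of 3")
})

test_that("pixy-style pi matches hand enumeration and ignores missing sites", {
  g <- tibble::tibble(
    chrom = "chr", pos = 0:9, n_called = 4L,
    alt_count = c(2L, rep(0L, 9))
  )
  win <- pi_windows(g, window_bp = 5e4)
  # 6 haplotype pairs per site; 2/2 split -> 4 differing pairs
  expect_equal(win$n_diff, 4)
  expect_equal(win$n_comp, 60)
  expect_equal(win$pi, 4 / 60)
  # identical haplotypes -> 0
  g0 <- dplyr::mutate(g, alt_count = 0L)
  expect_equal(pi_windows(g0)$pi, 0)
  # adding fully-missing sites changes nothing
  gm <- dplyr::bind_rows(g, tibble::tibble(chrom = "chr", pos = 10:1009,
                                           n_called = 0L, alt_count = 0L))
  expect_equal(pi_windows(gm)$pi, win$pi)
  # sites with a single called haplotype contribute nothing either
  g1 <- dplyr::bind_rows(g, tibble::tibble(chrom = "chr", pos = 20000L,
                                           n_called = 1L, alt_count = 1L))
  expect_equal(pi_windows(g1)$pi, win$pi)
})

test_that("pi is invariant to relabeling and bounded by member windows", {
  set.seed(21)
  g <- tibble::tibble(chrom = "chr", pos = 0:199,
                      n_called = sample(2:8, 200, replace = TRUE))
  g$alt_count <- vapply(g$n_called, function(k) sample(0:k, 1), 1L)
  win <- pi_windows(g, window_bp = 50)
  # aggregate of all windows lies between min and max window pi
  total <- sum(win$n_diff) / sum(win$n_comp)
  expect_gte(total, min(win$pi))
  expect_lte(total, max(win$pi))
  # swapping ref/alt labels (alt -> k - alt) leaves pi unchanged
  g2 <- dplyr::mutate(g, alt_count = n_called - alt_count)
  expect_equal(pi_windows(g2, window_bp = 50)$pi, win$pi)
})

test_that("pi0/pi4 is a ratio of sums with degenerate-input flags", {
  w <- tibble::tibble(
    chrom = "chr", start = c(0, 0), end = c(5e4, 5e4),
    site_class = c("zero_fold", "four_fold"),
    n_sites = c(10L, 10L), n_diff = c(2, 8), n_comp = c(1000, 1000),
    pi = c(0.002, 0.008)
  )
  expect_equal(pi0_pi4(w)$pi0_pi4, 0.25)
  weq <- dplyr::mutate(w, n_diff = c(5, 5), pi = 0.005)
  expect_equal(pi0_pi4(weq)$pi0_pi4, 1)
  w0 <- dplyr::mutate(w, n_diff = c(2, 0), pi = c(0.002, 0))
  expect_true(is.na(pi0_pi4(w0)$pi0_pi4))  # flag, not an error
})

test_that("mask intervals expand to per-site classes and reject overlap", {
  mask <- tibble::tibble(chrom = "chr", start = c(0L, 5L),
                         end = c(3L, 7L),
                         site_class = c("intron", "intergenic"))
  sites <- mask_to_sites(mask)
  expect_equal(sites$pos, c(0:2, 5:6))
  overlap <- tibble::tibble(chrom = "chr", start = c(0L, 2L), end = c(3L, 5L),
                            site_class = c("intron", "intergenic"))
  expect_error(mask_to_sites(overlap), "overlap")
})

test_that("binning to recombination windows aggregates counts, not ratios", {
  div <- tibble::tibble(
    chrom = "chr", start = c(0, 5e4), end = c(5e4, 1e5),
    site_class = "all", n_sites = 2L,
    n_diff = c(1, 6), n_comp = c(100, 300), pi = c(0.01, 0.02)
  )
  rec <- tibble::tibble(population = "toy", chrom_id = "chr",
                        start = 0, end = 2e6, rate_cm_per_mb = 3,
                        covered_bp = 2e6)
  out <- join_to_recombination(div, rec, bin_bp = 2e6)
  expect_equal(out$pi, 7 / 400)
  expect_equal(out$rate_cm_per_mb, 3)
  # 40 equal windows of pi = p aggregate to p
  div40 <- tibble::tibble(chrom = "chr", start = seq(0, by = 5e4,
                                                     length.out = 40),
                          site_class = "all", n_sites = 1L,
                          n_diff = 5, n_comp = 500, pi = 0.01)
  div40$end <- div40$start + 5e4
  expect_equal(join_to_recombination(div40, rec, bin_bp = 2e6)$pi, 0.01)
  # bins without rate coverage are dropped and counted
  rec_na <- dplyr::mutate(rec, rate_cm_per_mb = NA_real_, covered_bp = 0)
  expect_message(out2 <- join_to_recombination(div, rec_na), "dropped")
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "n_dropped"), 1)
  expect_error(join_to_recombination(
    dplyr::mutate(div, chrom = "other"), rec), "absent")
})

test_that("ols permutation recovers exact fits and flags degenerate input", {
  d3 <- tibble::tibble(x = c(1, 2, 3), y = c(2, 4, 6))
  res3 <- ols_permutation(d3, "x", "y", n_perm = 1000, seed = 2)
  expect_equal(res3$slope, 2)
  expect_equal(res3$r_squared, 1)
  # with n = 10 the chance of a permutation tying the observed slope is
  # 2/10!, so a perfect line attains the minimum attainable p
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  res <- ols_permutation(d, "x", "y", n_perm = 1000, seed = 2)
  expect_equal(res$p_permuted, 1 / 1001)
  expect_error(ols_permutation(tibble::tibble(x = c(1, 1, 1), y = 1:3),
                               "x", "y"), "constant")
  expect_error(ols_permutation(tibble::tibble(x = 1:3, y = c(2, 2, 2)),
                               "x", "y"), "constant")
  # determinism under the seed
  set.seed(999)
  d2 <- tibble::tibble(x = rnorm(30), y = rnorm(30))
  expect_identical(ols_permutation(d2, "x", "y", seed = 7),
                   ols_permutation(d2, "x", "y", seed = 7))
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(31)
  x <- rnorm(25)
  p <- replicate(500, {
    y <- rnorm(25)
    ols_permutation(tibble::tibble(x = x, y = y), "x", "y",
                    n_perm = 99, seed = sample.int(1e6, 1))$p_permuted
  })
  rate <- mean(p <= 0.05)
  # binomial 99% bound around 0.05 with 500 replicates
  expect_lt(abs(rate - 0.05), 2.58 * sqrt(0.05 * 0.95 / 500))
  expect_gte(min(p), 1 / 100)
})

test_that("threshold split finds a slope planted only below the cutoff", {
  set.seed(13)
  low <- tibble::tibble(rate_cm_per_mb = runif(40, 0.2, 2.0))
  low$pi <- 0.002 + 0.003 * low$rate_cm_per_mb + rnorm(40, 0, 0.0008)
  high <- tibble::tibble(rate_cm_per_mb = runif(40, 2.0001, 8))
  high$pi <- 0.008 + rnorm(40, 0, 0.0008)
  tab <- dplyr::bind_rows(low, high)
  res <- threshold_split(tab, cutoff = 2.0, n_perm = 499, seed = 3)
  expect_lt(res$p_permuted[res$stratum == "low"], 0.01)
  expect_gt(res$p_permuted[res$stratum == "high"], 0.05)
  # cutoff above the maximum rate: high stratum skipped, low = global fit
  expect_message(res2 <- threshold_split(tab, cutoff = 100, n_perm = 99,
                                         seed = 3), "skipped")
  expect_true(is.na(res2$p_permuted[res2$stratum == "high"]))
  glob <- ols_permutation(tab, "rate_cm_per_mb", "pi", n_perm = 99, seed = 3)
  expect_equal(res2$slope[res2$stratum == "low"], glob$slope)
})

test_that("rank tests reproduce hand-computed values", {
  expect_equal(spearman_assoc(1:10, 10:1)$value, -1)
  expect_equal(spearman_assoc(c(1, 2, 3, 4), c(1, 3, 2, 4))$value, 0.8)
  expect_error(spearman_assoc(rep(1, 5), 1:5), "all-tied")
  w <- wilcoxon_compare(1:10, 1:10)
  expect_gt(w$p, 0.9)
  expect_equal(adjust_site_class_p(c(0.01, 0.02, 0.03, 0.04)),
               p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "holm"))
})
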