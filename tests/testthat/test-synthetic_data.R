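anc <- function() toy_karyotype(c(A = 3e7, B = 2e7, C = 1e7),
                                classes = c("autosome", "autosome", "Z"),
                                population = "anc")

test_that("fissions and fusions conserve base pairs and chromosome counts", {
  none <- simulate_karyotype_pair(anc(), n_fissions = 0, n_fusions = 0,
                                  seed = 4)
  expect_equal(sort(none$karyotype_pop1$length_bp),
               sort(anc()$length_bp))
  expect_equal(sort(none$karyotype_pop2$length_bp), sort(anc()$length_bp))
  expect_true(all(none$blocks$history_class == "unchanged"))

  sim <- simulate_karyotype_pair(anc(), n_fissions = 3, n_fusions = 1,
                                 seed = 4)
  expect_equal(nrow(sim$karyotype_pop1), nrow(anc()) + 3)
  expect_equal(nrow(sim$karyotype_pop2), nrow(anc()) - 1)
  expect_equal(sum(sim$karyotype_pop1$length_bp), sum(anc()$length_bp))
  expect_equal(sum(sim$karyotype_pop2$length_bp), sum(anc()$length_bp))
  # every block has identical extent in both assemblies
  expect_equal(sim$blocks$end_pop1 - sim$blocks$start_pop1,
               sim$blocks$end_pop2 - sim$blocks$start_pop2)
  # fusion with a single chromosome is impossible
  one <- toy_karyotype(c(A = 1e7))
  expect_error(simulate_karyotype_pair(one, 0, 1, seed = 1), "one chromosome")
})

test_that("karyotype simulation is reproducible under a fixed seed", {
  a <- simulate_karyotype_pair(anc(), 4, 2, seed = 99)
  b <- simulate_karyotype_pair(anc(), 4, 2, seed = 99)
  expect_identical(a, b)
})

test_that("female meiosis is achiasmatic and male counts match the model", {
  expect_length(simulate_meiosis(80, sex = "female"), 0)
  set.seed(12)
  counts <- replicate(2e4, length(simulate_meiosis(
    50, co_model = "obligate_plus_poisson", sex = "male")))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 1), 3 * se + 1e-9) # G = 50: obligate CO only
  expect_true(all(counts >= 1))
  set.seed(13)
  counts2 <- replicate(2e4, length(simulate_meiosis(
    150, co_model = "obligate_plus_poisson", sex = "male")))
  expect_lt(abs(mean(counts2) - 3), 3 * sd(counts2) / sqrt(2e4))
})

test_that("gamma renewal spacing is more regular under strong interference", {
  spacing <- function(nu, seed) {
    set.seed(seed)
    unlist(replicate(4000, diff(simulate_meiosis(
      300, co_model = "gamma_renewal", nu = nu)), simplify = FALSE))
  }
  s1 <- spacing(1, 41)
  s10 <- spacing(10, 42)
  expect_lt(var(s10), var(s1))
  # stationarity: expected event count over G cM is G/50 for any shape
  # (within-window spacings themselves are length-biased, so the mean
  # spacing is checked through the count, not directly)
  count_mean <- function(nu, seed) {
    set.seed(seed)
    mean(replicate(4000, length(simulate_meiosis(
      300, co_model = "gamma_renewal", nu = nu))))
  }
  expect_lt(abs(count_mean(1, 43) - 6), 0.12)
  expect_lt(abs(count_mean(10, 44) - 6), 0.06)
})

test_that("female gametes are constant per chromosome; male assortment is independent", {
  kar <- toy_karyotype(c(A = 1e7, B = 1e7))
  maps <- dplyr::bind_rows(linear_map("A", 1e7, rate = 5),
                           linear_map("B", 1e7, rate = 5))
  fg <- simulate_pedigree_gametes(kar, maps, n_offspring = 200, seed = 6,
                                  sex = "female")
  for (M in fg$origins) {
    expect_true(all(M == M[, 1])) # non-recombinant on every chromosome
  }
  mg <- simulate_pedigree_gametes(kar, maps, n_offspring = 4000, seed = 7,
                                  n_grid = 5)
  # origin at the first marker of A is uncorrelated with that of B
  r <- cor(mg$origins$A[, 1], mg$origins$B[, 1])
  expect_lt(abs(r), 3 / sqrt(4000))
})

test_that("adjacent-marker recombinant fractions follow the map distance", {
  # two markers 27.465 cM apart (Kosambi r = 0.25); gamma interference at
  # the Kosambi-matched shape nu = 2.63
  kar <- toy_karyotype(c(A = 1e7))
  maps <- tibble::tibble(population = "sim", chrom_id = "A",
                         phys_bp = c(0, 1e7), gen_cm = c(0, kosambi_cm(0.25)))
  g <- simulate_pedigree_gametes(kar, maps, n_offspring = 4e4, seed = 8,
                                 co_model = "gamma_renewal", nu = 2.63)
  M <- g$origins$A
  rhat <- mean(M[, 1] != M[, 2])
  se <- sqrt(0.25 * 0.75 / nrow(M))
  # the renewal process approximates, not reproduces, Kosambi: allow 3 SE
  # plus a 0.01 model tolerance
  expect_lt(abs(rhat - 0.25), 3 * se + 0.01)
})

test_that("maps estimated from gametes recover the generating map length", {
  kar <- toy_karyotype(c(A = 2e7))
  maps <- linear_map("A", 2e7, rate = 3, n_markers = 7) # G = 60 cM
  g <- simulate_pedigree_gametes(kar, maps, n_offspring = 500, seed = 9,
                                 co_model = "gamma_renewal", nu = 2.63)
  est <- estimate_map_from_gametes(g)
  G <- map_length(est)
  # binomial error propagated through Kosambi: sd(d_i) = 100/(1-4r^2) sd(r)
  r <- inverse_kosambi_r(10) # per-interval true distance 10 cM
  sd_d <- 100 / (1 - 4 * r^2) * sqrt(r * (1 - r) / 500)
  expect_lt(abs(G - 60), 3 * sqrt(6) * sd_d + 3) # 6 intervals + model slack
  # no recombinants -> flat map
  g0 <- simulate_pedigree_gametes(kar, maps, n_offspring = 50, seed = 10,
                                  sex = "female")
  expect_equal(map_length(estimate_map_from_gametes(g0)), 0)
  # closed-form spot check: 50 recombinants of 200 gametes
  expect_equal(kosambi_cm(50 / 200), 25 * log(3))
})

test_that("gamete-based r-bar matches the analytical decomposition", {
  kar <- toy_karyotype(c(A = 25e6, B = 15e6, C = 8e6))
  maps <- dplyr::bind_rows(
    linear_map("A", 25e6, rate = 60 / 25),
    linear_map("B", 15e6, rate = 52 / 15),
    linear_map("C", 8e6, rate = 50 / 8)
  )
  g <- simulate_pedigree_gametes(kar, maps, n_offspring = 2e4, seed = 11,
                                 co_model = "gamma_renewal", nu = 2.63,
                                 n_grid = 60)
  rb <- rbar_from_gametes(g, kar)
  # interchromosomal part against the closed form
  expect_lt(abs(rb$inter - inter_reshuffling(kar)), 0.005)
  # intrachromosomal part against the pseudomarker estimator; the gamma
  # process approximates Kosambi additivity, so allow a small model term
  # on top of 3 Monte-Carlo SE
  gi <- genome_intra(validate_marey(maps, kar), kar, n_pseudo = 300)
  expect_lt(abs(rb$intra_genome - gi$intra_genome), 0.004)
  expect_equal(rb$total, rb$inter + rb$intra_genome)
  expect_error(rbar_from_gametes(structure(list(origins = list()),
                                           class = "gamete_table"), kar),
               "empty")
})

test_that("a single uniform crossover yields r-bar 1/6 in simulation", {
  # force exactly one chiasma uniform on the map: obligate model with G = 50
  kar <- toy_karyotype(c(A = 1e7))
  maps <- linear_map("A", 1e7, rate = 5) # 50 cM
  g <- simulate_pedigree_gametes(kar, maps, n_offspring = 4e4, seed = 12,
                                 co_model = "obligate_plus_poisson",
                                 n_grid = 200)
  rb <- rbar_from_gametes(g, kar)
  # analytic: per pair P(differ) = P(chiasma between) * 1/2 (chromatid),
  # so r-bar = 0.5 E|a - b| = 1/6
  expect_lt(abs(rb$intra_genome - 1 / 6), 0.01)
})

test_that("simulated diversity follows the saturating curve with planted scaler", {
  rec <- tibble::tibble(population = "p", chrom_id = "c",
                        start = seq(0, 18e6, by = 2e6),
                        end = seq(2e6, 20e6, by = 2e6),
                        rate_cm_per_mb = c(NA, 0.5, 1, 2, 4, 8, 16, 32, 64, 1),
                        covered_bp = 2e6)
  d <- simulate_diversity(rec, pi_max = 0.01, rho_50 = 1, sigma = 0,
                          pop_scaler = 1.08, seed = 3)
  # rho = rho_50 -> half the asymptote (times the scaler)
  expect_equal(d$pi[3], 1.08 * 0.01 / 2, tolerance = 1e-3)
  # saturation: rho = 64 is within 2% of the asymptote
  expect_equal(d$pi[9], 1.08 * 0.01 * 64 / 65, tolerance = 1e-3)
  # undefined rate -> zero comparisons, pi NA
  expect_true(is.na(d$pi[1]))
  expect_equal(d$n_comp[1], 0)
  # bit-for-bit reproducible
  expect_identical(d, simulate_diversity(rec, pi_max = 0.01, rho_50 = 1,
                                         sigma = 0, pop_scaler = 1.08,
                                         seed = 3))
})

test_that("achiasmatic females reduce total reshuffling to the inter term", {
  kar <- toy_karyotype(c(A = 2e7, B = 1e7))
  maps <- dplyr::bind_rows(linear_map("A", 2e7, rate = 3),
                           linear_map("B", 1e7, rate = 5))
  g <- simulate_pedigree_gametes(kar, maps, n_offspring = 5000, seed = 14,
                                 sex = "female", n_grid = 40)
  rb <- rbar_from_gametes(g, kar)
  expect_equal(rb$intra_genome, 0)
  expect_equal(rb$total, rb$inter)
})
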