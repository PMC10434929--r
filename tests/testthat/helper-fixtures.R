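# Fixture builders shared across test files. Everything is generated in
# code; nothing binary ships with the package.

toy_karyotype <- function(lengths = c(a = 2e7, b = 1e7),
                          classes = rep("autosome", length(lengths)),
                          population = "toy") {
  tibble::tibble(population = population,
                 chrom_id = if (is.null(names(lengths))) character(0) else names(lengths),
                 length_bp = unname(lengths),
                 chrom_class = classes)
}

# write a map TSV and read it back through the public reader
write_and_read_map <- function(markers, karyotype) {
  tf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(markers, tf, progress = FALSE)
  read_map_table(tf, karyotype)
}

# Monte-Carlo oracle for interchromosomal reshuffling: loci drawn
# length-proportionally, chromosome origins assorted independently.
mc_inter_reshuffling <- function(karyotype, n = 1e5, seed = 42) {
  set.seed(seed)
  p <- karyotype$length_bp / sum(karyotype$length_bp)
  c1 <- sample.int(length(p), n, replace = TRUE, prob = p)
  c2 <- sample.int(length(p), n, replace = TRUE, prob = p)
  o1 <- stats::rbinom(n, 1, 0.5)
  o2 <- stats::rbinom(n, 1, 0.5)
  est <- mean(c1 != c2 & o1 != o2)
  se <- sqrt(est * (1 - est) / n)
  list(est = est, se = se)
}
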