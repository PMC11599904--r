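test_that("Balding-Nichols draws have the model's mean and variance", {
  # F = 0 is the degenerate limit
  expect_equal(draw_population_frequencies(0.3, 0, 5), rep(0.3, 5))

  p <- 0.3; f <- 0.1; n <- 10000
  x <- draw_population_frequencies(p, f, n, seed = 101)
  target_var <- f * p * (1 - p)                     # 0.021
  se_mean <- sqrt(target_var / n)
  expect_lt(abs(mean(x) - p), 3 * se_mean)
  dev2 <- (x - mean(x))^2
  se_var <- stats::sd(dev2) / sqrt(n)
  expect_lt(abs(stats::var(x) - target_var), 3 * se_var)
  expect_true(all(x >= 0 & x <= 1))

  expect_error(draw_population_frequencies(0, 0.1, 3), "p_anc")
  expect_error(draw_population_frequencies(0.3, 1, 3), "fst")
})

test_that("genotype simulation respects fixed frequencies and missingness", {
  q0 <- matrix(0, 2, 10, dimnames = list(c("a", "b"), NULL))
  g0 <- simulate_genotypes(q0, c(5, 5), seed = 1)
  expect_true(all(g0$dosage == 0))

  q1 <- matrix(1, 2, 10)
  g1 <- simulate_genotypes(q1, c(5, 5), seed = 1)
  expect_true(all(g1$dosage == 2))

  # missing fraction within 3 binomial SEs of the configured rate
  qm <- matrix(0.5, 2, 500)
  gm <- simulate_genotypes(qm, c(50, 50), missing_rate = 0.1, seed = 7)
  n_geno <- length(gm$dosage)
  expect_equal(n_geno, 50000L)
  se <- sqrt(0.1 * 0.9 / n_geno)
  expect_lt(abs(mean(is.na(gm$dosage)) - 0.1), 3 * se)

  expect_error(simulate_genotypes(q1, c(5, 5, 5)), "size per population")
  expect_error(simulate_genotypes(matrix(1.5, 1, 2), 3), "frequencies")
})

test_that("synthetic consequence labels follow the configured weights", {
  only <- synthesize_annotations(50, c("Stop gained" = 2), seed = 1)
  expect_true(all(only == "Stop gained"))

  w <- c("Intronic" = 134, "Synonymous coding" = 40,
         "Non synonymous coding" = 38)
  x <- synthesize_annotations(10000, w, seed = 11)
  tab <- table(factor(x, levels = names(w)))
  gof <- stats::chisq.test(tab, p = w / sum(w))
  expect_gt(gof$p.value, 0.01)

  # default weights reproduce the reference panel's intronic share
  y <- synthesize_annotations(25300, seed = 3)
  se <- sqrt((134 / 253) * (1 - 134 / 253) / 25300)
  expect_lt(abs(mean(y == "Intronic") - 134 / 253), 3 * se)

  expect_error(synthesize_annotations(5, c(frameshift = 1)),
               "unknown consequence")
  expect_error(synthesize_annotations(5, c(Intronic = 0)), "weights")
})

test_that("a fixed seed yields a bit-identical panel", {
  cfg <- simulation_config(population_names = c("A", "B", "C"),
                           population_sizes = c(6, 8, 10),
                           n_variants = 40, seed = 99)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$genotypes$dosage, p2$genotypes$dosage)
  expect_identical(p1$genotypes$variants, p2$genotypes$variants)
  expect_identical(p1$pop_freqs, p2$pop_freqs)

  cfg2 <- simulation_config(population_names = c("A", "B", "C"),
                            population_sizes = c(6, 8, 10),
                            n_variants = 40, seed = 100)
  expect_false(identical(p1$genotypes$dosage,
                         simulate_panel(cfg2)$genotypes$dosage))
})

test_that("simulation_config enforces its invariants", {
  expect_error(simulation_config(population_names = "A",
                                 population_sizes = c(1, 2)), "length")
  expect_error(simulation_config(population_sizes = rep(0, 7)), ">= 1")
  expect_error(simulation_config(ancestral_freq_range = c(0.9, 0.1)),
               "increasing")
  expect_error(simulation_config(fst_per_population = 1), "fst")
  expect_error(simulation_config(missing_rate = 1), "missing_rate")
})

test_that("the default configuration encodes the study design", {
  cfg <- simulation_config()
  expect_equal(cfg$population_sizes, c(5L, 59L, 661L, 347L, 504L, 503L,
                                       489L))
  expect_equal(cfg$n_variants, 253L)
  expect_equal(length(cfg$population_names), 7L)
})

test_that("VCF round-trip preserves dosages, labels and variant ids", {
  cfg <- simulation_config(population_names = c("G1", "G2"),
                           population_sizes = c(5, 7),
                           n_variants = 25, missing_rate = 0.1, seed = 21)
  panel <- simulate_panel(cfg)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  map <- withr::local_tempfile(fileext = ".tsv")
  write_panel_vcf(panel$genotypes, vcf)
  write_population_map(panel$genotypes, map)
  back <- read_genotype_vcf(vcf, map)
  expect_equal(unname(back$dosage), unname(panel$genotypes$dosage))
  expect_equal(colnames(back$dosage), colnames(panel$genotypes$dosage))
  expect_equal(as.character(back$populations),
               as.character(panel$genotypes$populations))
})
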