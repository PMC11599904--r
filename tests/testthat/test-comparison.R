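test_that("allele counting handles full, partial and missing calls", {
  expect_equal(allele_frequency(c(2, 2, 1))$af, 5 / 6)
  part <- allele_frequency(c(0, NA, 0))
  expect_equal(part$af, 0)
  expect_equal(part$called_alleles, 4L)
  # one alternate allele among 42 called genotypes
  expect_equal(round(allele_frequency(c(1, rep(0, 41)))$af, 4), 0.0119)
  expect_error(allele_frequency(c(NA, NA)), "no called alleles")
})

test_that("allele_frequency_table agrees with per-population counting", {
  set.seed(8)
  d <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 6, 10,
              dimnames = list(NULL, sprintf("v%02d", 1:10)))
  geno <- toy_geno(d, rep(c("A", "B"), each = 3))
  tab <- allele_frequency_table(geno)
  expect_equal(nrow(tab), 20L)
  for (i in sample(nrow(tab), 5)) {
    sub <- d[rep(c("A", "B"), each = 3) == tab$population[i],
             tab$variant_id[i]]
    if (all(is.na(sub))) {
      expect_true(is.na(tab$af[i]))
    } else {
      expect_equal(tab$af[i], allele_frequency(sub)$af)
    }
  }
})

test_that("standardization to a fixed allele total conserves the total", {
  expect_equal(unlist(standardize_counts(0)), c(yes = 0L, no = 118L))
  expect_equal(unlist(standardize_counts(0.5)), c(yes = 59L, no = 59L))
  expect_equal(unlist(standardize_counts(0.8243)), c(yes = 97L, no = 21L))
  set.seed(3)
  af <- runif(200)
  std <- standardize_counts(af)
  expect_true(all(std$yes + std$no == 118L))
  expect_error(standardize_counts(1.2), "af")
  expect_error(standardize_counts(0.5, total_alleles = 1), "total_alleles")
})

test_that("two-sided Fisher p matches enumeration oracles", {
  expect_equal(fisher_exact_two_sided(matrix(c(0, 118, 0, 118), 2,
                                             byrow = TRUE)), 1)
  expect_equal(fisher_exact_two_sided(matrix(c(3, 0, 0, 3), 2,
                                             byrow = TRUE)), 0.1)
  set.seed(19)
  for (i in 1:50) {
    r1 <- sample(1:118, 1); r2 <- sample(1:118, 1)
    tab <- matrix(c(sample(0:r1, 1), 0, sample(0:r2, 1), 0), 2)
    tab[, 2] <- c(r1, r2) - tab[, 1]
    p <- fisher_exact_two_sided(tab)
    expect_equal(p, fisher_enum_oracle(tab), tolerance = 1e-9)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    # symmetric under swapping the two rows
    expect_equal(p, fisher_exact_two_sided(tab[2:1, ]), tolerance = 1e-12)
  }
  expect_error(fisher_exact_two_sided(matrix(c(-1, 1, 1, 1), 2)),
               "nonnegative")
})

test_that("Hochberg adjustment matches the step-up oracle and its bounds", {
  expect_equal(hochberg_adjust(0.05), 0.05)
  expect_equal(hochberg_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(hochberg_adjust(numeric(0)), numeric(0))
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- hochberg_adjust(p)
    expect_equal(adj, hochberg_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= pmin(1, length(p) * p) + 1e-12))
  }
  expect_error(hochberg_adjust(c(0.1, 1.2)), "0,1")
})

make_af_table <- function(afs) {
  # afs: named list population -> frequency vector over shared variants
  do.call(rbind, lapply(names(afs), function(p) {
    data.frame(variant_id = sprintf("v%02d", seq_along(afs[[p]])),
               population = p, alt_count = NA_integer_,
               called_alleles = NA_integer_, af = afs[[p]],
               stringsAsFactors = FALSE)
  }))
}

test_that("reference-vs-panel comparison composes counting, testing, signing", {
  af <- make_af_table(list(REF = c(0.8, 0.2, 0.5),
                           C1 = c(0.1, 0.2, 0.6),
                           C2 = c(0.3, 0.9, 0.5)))
  cm <- compare_reference_to_panels(af, "REF", c("C1", "C2"))
  expect_equal(nrow(cm), 6L)

  # identical frequencies: p = 1, sign 0
  row <- cm[cm$variant_id == "v02" & cm$comparator == "C1", ]
  expect_equal(row$p, 1)
  expect_equal(row$sign, "0")
  # direction follows sign(af_ref - af_cmp)
  expect_equal(cm$sign[cm$variant_id == "v01" & cm$comparator == "C1"],
               "+")
  expect_equal(cm$sign[cm$variant_id == "v02" & cm$comparator == "C2"],
               "-")

  # p equals a direct Fisher test on the standardized counts
  for (i in seq_len(nrow(cm))) {
    t_ref <- unlist(standardize_counts(cm$af_ref[i]))
    t_cmp <- unlist(standardize_counts(cm$af_cmp[i]))
    expect_equal(cm$p[i],
                 fisher_exact_two_sided(rbind(t_ref, t_cmp)),
                 tolerance = 1e-12)
  }
  # Hochberg applied within each variant across its comparators
  for (v in unique(cm$variant_id)) {
    sub <- cm[cm$variant_id == v, ]
    expect_equal(sub$p_adj, hochberg_adjust(sub$p))
  }
})

test_that("global adjustment scope spans the whole matrix", {
  af <- make_af_table(list(REF = c(0.9, 0.1), C1 = c(0.1, 0.1),
                           C2 = c(0.85, 0.1)))
  glob <- compare_reference_to_panels(af, "REF", c("C1", "C2"),
                                      adjust_scope = "global")
  expect_equal(glob$p_adj, hochberg_adjust(glob$p))
  expect_true(all(glob$p_adj >= glob$p - 1e-12))
})

test_that("variants missing a population entry are skipped with a warning", {
  af <- make_af_table(list(REF = c(0.5, 0.4), C1 = c(0.5, 0.4)))
  af$af[af$population == "C1" & af$variant_id == "v02"] <- NA
  expect_warning(cm <- compare_reference_to_panels(af, "REF", "C1"),
                 "skipped")
  expect_equal(unique(cm$variant_id), "v01")
  expect_error(compare_reference_to_panels(af, "REF", "C9"), "absent")
})

test_that("the reporting rule enforces both the >=3 count and the tier", {
  comps <- data.frame(
    variant_id = rep(c("a", "b", "c"), each = 6),
    impact = rep(c("Moderate", "Moderate", "Low"), each = 6),
    p = c(rep(0.01, 3), rep(0.5, 3),     # a: 3 significant, Moderate -> in
          rep(0.01, 2), rep(0.5, 4),     # b: 2 significant -> out
          rep(0.001, 6)),                # c: Low tier -> out
    stringsAsFactors = FALSE)
  sel <- select_reportable(comps)
  expect_equal(sel$reportable$variant_id, "a")
  expect_setequal(sel$supplementary$variant_id, c("b", "c"))

  empty <- select_reportable(comps[0, ])
  expect_equal(nrow(empty$reportable), 0L)
})
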