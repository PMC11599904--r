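# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the Fisher oracle works from binomial
# coefficients, the Hochberg oracle is a literal step-up loop, the
# exclusivity oracle a per-variant scan, and the PERMANOVA oracles work
# from raw coordinates or exhaustive label enumeration.

# Two-sided Fisher p by direct enumeration with choose().
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- tab[1, 1] + tab[2, 1]
  n <- tab[1, 2] + tab[2, 2]
  k <- tab[1, 1] + tab[1, 2]
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p0 <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
}

# Literal Hochberg step-up: adjusted(i) = min_{j >= i} (m - j + 1) p(j).
hochberg_oracle <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min((m - seq(i, m) + 1) * ps[seq(i, m)]))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Per-variant scan for exclusivity.
exclusive_oracle <- function(af_counts, targets, refs) {
  hits <- list()
  for (v in unique(af_counts$variant_id)) {
    sub <- af_counts[af_counts$variant_id == v, ]
    ref <- sub[match(refs, sub$population), ]
    if (any(ref$called_alleles == 0)) next
    if (any(ref$alt_count > 0)) next
    for (g in targets) {
      row <- sub[sub$population == g, ]
      if (nrow(row) == 1L && row$alt_count > 0) {
        hits[[length(hits) + 1L]] <- data.frame(population = g,
                                                variant_id = v)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(population = character(), variant_id = character())
}

# One-way pseudo-F from raw coordinates (classical sums of squares).
permanova_f_from_coords <- function(x, groups) {
  x <- as.matrix(x)
  groups <- factor(groups)
  grand <- colMeans(x)
  sst <- sum(sweep(x, 2, grand)^2)
  ssw <- 0
  for (g in levels(groups)) {
    sub <- x[groups == g, , drop = FALSE]
    ssw <- ssw + sum(sweep(sub, 2, colMeans(sub))^2)
  }
  a <- nlevels(groups)
  n <- nrow(x)
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# Exhaustive permutation p over all assignments of 2 equal groups.
permanova_exhaustive_p <- function(d2, n_per_group) {
  n <- 2 * n_per_group
  f_of <- function(idx1) {
    g <- factor(ifelse(seq_len(n) %in% idx1, "a", "b"))
    ssw <- 0
    for (lev in levels(g)) {
      i <- which(g == lev)
      ssw <- ssw + sum(d2[i, i]) / (2 * length(i))
    }
    sst <- sum(d2) / (2 * n)
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  f_obs <- f_of(seq_len(n_per_group))
  combos <- utils::combn(n, n_per_group)
  f_all <- apply(combos, 2, f_of)
  mean(f_all >= f_obs - 1e-12)
}

# Small toy genotype matrix with known dosages.
toy_geno <- function(dosage, pops) {
  genotype_matrix(dosage, pops)
}

# Random per-population allele-count table for property tests.
random_af_counts <- function(n_variants, pops, seed) {
  set.seed(seed)
  grid <- expand.grid(variant_id = sprintf("v%03d", seq_len(n_variants)),
                      population = pops, stringsAsFactors = FALSE)
  grid$called_alleles <- sample(c(0L, 10L, 50L, 100L), nrow(grid),
                                replace = TRUE, prob = c(.05, .3, .4, .25))
  grid$alt_count <- vapply(grid$called_alleles, function(ca) {
    if (ca == 0L) 0L else sample(0:min(ca, 3), 1L, prob = c(.6, rep(.4 / min(ca, 3), min(ca, 3))))
  }, integer(1))
  grid
}
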