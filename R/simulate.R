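# Multi-population genotype simulation under the Balding-Nichols model:
# per-locus ancestral frequencies, Beta-distributed population frequencies
# at tunable divergence F, binomial diploid dosages, i.i.d. missingness.

.study_populations <- c("IND-LLA" = 5, "IND-NLLA" = 59, AFR = 661,
                        AMR = 347, EAS = 504, EUR = 503, SAS = 489)

.study_genes <- c("ABCB1", "ACP1", "ADH1C", "BCL2L11", "BMP7", "CTNNB1",
                  "CXCL12", "DROSHA", "FGFR4", "FOLH1", "GATA3", "GSTA1",
                  "HMMR", "NOS1", "NR3C1", "PNPLA3", "SERPINA6", "SHMT1")

#' Configuration for the multi-population genotype simulator
#'
#' Defaults emulate the study design the package targets: seven populations
#' — two small indigenous cohorts (5 and 59 individuals) and the five 1000
#' Genomes continental panels (661, 347, 504, 503, 489) — typed at 253
#' biallelic variants across 18 glucocorticoid-pathway genes. Ancestral
#' frequencies are Uniform on `ancestral_freq_range`; each population
#' diverges from them under the Balding-Nichols model at its own
#' `fst_per_population` (0.15 for the indigenous cohorts, 0.10 for the
#' continental panels); genotypes go missing i.i.d. at `missing_rate`
#' (0.02).
#'
#' @param population_names character vector of population labels.
#' @param population_sizes integer vector of individuals per population.
#' @param n_variants number of biallelic variants.
#' @param ancestral_freq_range length-2 numeric in (0,1), low < high.
#' @param fst_per_population divergence parameter in \[0,1) per population
#'   (recycled if scalar).
#' @param missing_rate per-genotype missingness probability in \[0,1).
#' @param seed integer master seed; per-stage streams are derived from it.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(population_names = names(.study_populations),
                              population_sizes = unname(.study_populations),
                              n_variants = 253,
                              ancestral_freq_range = c(0.05, 0.95),
                              fst_per_population =
                                ifelse(grepl("^IND", population_names),
                                       0.15, 0.10),
                              missing_rate = 0.02,
                              seed = 1L) {
  if (length(population_names) != length(population_sizes)) {
    stop("population_names and population_sizes differ in length",
         call. = FALSE)
  }
  if (any(population_sizes < 1)) stop("population sizes must be >= 1",
                                      call. = FALSE)
  if (length(ancestral_freq_range) != 2L ||
      ancestral_freq_range[1] >= ancestral_freq_range[2] ||
      any(ancestral_freq_range <= 0) || any(ancestral_freq_range >= 1)) {
    stop("ancestral_freq_range must be an increasing pair inside (0,1)",
         call. = FALSE)
  }
  fst <- rep_len(fst_per_population, length(population_names))
  if (any(fst < 0 | fst >= 1)) stop("fst values must lie in [0,1)",
                                    call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0,1)", call. = FALSE)
  }
  if (!is_count(n_variants) || n_variants < 1) {
    stop("n_variants must be a positive count", call. = FALSE)
  }
  structure(list(population_names = as.character(population_names),
                 population_sizes = as.integer(population_sizes),
                 n_variants = as.integer(n_variants),
                 ancestral_freq_range = as.numeric(ancestral_freq_range),
                 fst_per_population = as.numeric(fst),
                 missing_rate = as.numeric(missing_rate),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Draw population allele frequencies under the Balding-Nichols model
#'
#' Each population's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) around the
#' ancestral frequency `p_anc`, so that the mean is `p_anc` and the
#' variance is `F * p_anc * (1 - p_anc)`; `F` is interpretable as the
#' population's F_ST against the ancestral pool. `F = 0` is the degenerate
#' no-divergence limit (all frequencies exactly `p_anc`).
#'
#' @param p_anc ancestral allele frequency in (0,1).
#' @param fst divergence parameter in \[0,1).
#' @param n_pops number of populations to draw.
#' @param seed optional integer seed (caller RNG state is untouched).
#' @return numeric vector of `n_pops` frequencies in \[0,1\].
#' @examples
#' draw_population_frequencies(0.3, 0.1, 5, seed = 1)
#' @export
draw_population_frequencies <- function(p_anc, fst, n_pops, seed = NULL) {
  if (!is.numeric(p_anc) || length(p_anc) != 1L || p_anc <= 0 || p_anc >= 1) {
    stop("p_anc must be a single value in (0,1)", call. = FALSE)
  }
  if (!is.numeric(fst) || length(fst) != 1L || fst < 0 || fst >= 1) {
    stop("fst must be a single value in [0,1)", call. = FALSE)
  }
  if (fst == 0) return(rep(p_anc, n_pops))
  shape <- (1 - fst) / fst
  with_seed(seed, stats::rbeta(n_pops, p_anc * shape, (1 - p_anc) * shape))
}

# Population x variant frequency matrix for vectors of ancestral
# frequencies and per-population F values.
bn_frequency_matrix <- function(p_anc, fst, seed = NULL) {
  with_seed(seed, {
    out <- matrix(NA_real_, length(fst), length(p_anc))
    for (i in seq_along(fst)) {
      out[i, ] <- if (fst[i] == 0) p_anc else {
        shape <- (1 - fst[i]) / fst[i]
        stats::rbeta(length(p_anc), p_anc * shape, (1 - p_anc) * shape)
      }
    }
    out
  })
}

#' Construct a genotype matrix container
#'
#' Samples x variants matrix of alternate-allele dosages (0/1/2, `NA` for
#' missing), with a population label per sample and an optional per-variant
#' annotation table.
#'
#' @param dosage integer matrix, samples in rows, variants in columns
#'   (column names are variant ids).
#' @param populations vector/factor of population labels, one per sample.
#' @param variants optional data.frame of per-variant records with a
#'   `variant_id` column matching `colnames(dosage)`.
#' @return object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(dosage, populations, variants = NULL) {
  dosage <- as.matrix(dosage)
  if (length(populations) != nrow(dosage)) {
    stop("one population label per sample is required", call. = FALSE)
  }
  if (!all(dosage[!is.na(dosage)] %in% 0:2)) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("var%04d", seq_len(ncol(dosage)))
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  }
  if (!is.null(variants)) {
    stopifnot(is.data.frame(variants), "variant_id" %in% names(variants),
              nrow(variants) == ncol(dosage))
  }
  structure(list(dosage = dosage,
                 populations = factor(populations),
                 variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "variants;", nlevels(x$populations), "populations;",
      sprintf("%.2f%%", 100 * mean(is.na(x$dosage))), "missing\n")
  invisible(x)
}

#' Simulate diploid genotypes from population allele frequencies
#'
#' Dosage of individual *i* at variant *v* is Binomial(2, q) with q the
#' individual's population frequency; each genotype is then independently
#' masked missing with probability `missing_rate`.
#'
#' @param pop_freqs population x variant matrix of alternate-allele
#'   frequencies in \[0,1\] (row names are population labels).
#' @param sizes individuals per population (same order as rows).
#' @param missing_rate per-genotype missingness probability in \[0,1).
#' @param seed optional integer seed.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(pop_freqs, sizes, missing_rate = 0,
                               seed = NULL) {
  pop_freqs <- as.matrix(pop_freqs)
  if (nrow(pop_freqs) != length(sizes)) {
    stop("one size per population row is required", call. = FALSE)
  }
  if (any(pop_freqs < 0 | pop_freqs > 1)) {
    stop("frequencies must lie in [0,1]", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0,1)", call. = FALSE)
  }
  pop_names <- rownames(pop_freqs)
  if (is.null(pop_names)) pop_names <- sprintf("pop%02d", seq_along(sizes))
  v <- ncol(pop_freqs)
  with_seed(seed, {
    blocks <- lapply(seq_along(sizes), function(i) {
      ni <- sizes[i]
      matrix(stats::rbinom(ni * v, 2L, rep(pop_freqs[i, ], each = ni)),
             nrow = ni, ncol = v)
    })
    dosage <- do.call(rbind, blocks)
    if (missing_rate > 0) {
      dosage[stats::runif(length(dosage)) < missing_rate] <- NA_integer_
    }
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
    colnames(dosage) <- colnames(pop_freqs)
    genotype_matrix(dosage, rep(pop_names, sizes))
  })
}

#' Draw consequence labels for simulated variants
#'
#' Labels are drawn i.i.d. from the closed consequence category set with
#' probabilities proportional to `category_weights`; the default weights
#' are the category counts of the packaged annotation summary, so a
#' simulated panel reproduces its composition in expectation.
#'
#' @param n_variants number of labels to draw.
#' @param category_weights named nonnegative vector over (a subset of) the
#'   canonical categories; unknown names are an error.
#' @param seed optional integer seed.
#' @return character vector of canonical consequence labels.
#' @export
synthesize_annotations <- function(n_variants, category_weights = NULL,
                                   seed = NULL) {
  if (is.null(category_weights)) {
    t1 <- load_study_table("table1")
    cons <- t1[t1$dimension == "consequence", ]
    category_weights <- stats::setNames(cons$count, cons$category)
  }
  labels <- normalize_consequence(names(category_weights), strict = TRUE)
  w <- as.numeric(category_weights)
  if (any(w < 0) || all(w == 0)) {
    stop("weights must be nonnegative and not all zero", call. = FALSE)
  }
  with_seed(seed,
            sample(labels, n_variants, replace = TRUE, prob = w / sum(w)))
}

#' Simulate a complete annotated multi-population panel
#'
#' Runs the full generator: ancestral frequencies, Balding-Nichols
#' population frequencies, binomial genotypes with missingness, and
#' synthetic per-variant annotations (gene, chrom/pos, ref/alt alleles,
#' mutation type, region, consequence). All randomness flows from
#' `config$seed` through fixed per-stage streams, so a fixed seed gives a
#' bit-identical panel.
#'
#' @param config a [simulation_config()].
#' @return list of class `"simulated_panel"`: `genotypes` (a
#'   [genotype_matrix()] with the variant table attached), `pop_freqs`,
#'   `p_anc`, `config`.
#' @export
simulate_panel <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- config$seed
  v <- config$n_variants
  p_anc <- with_seed(derive_seed(seed, 1L),
                     stats::runif(v, config$ancestral_freq_range[1],
                                  config$ancestral_freq_range[2]))
  pf <- bn_frequency_matrix(p_anc, config$fst_per_population,
                            derive_seed(seed, 2L))
  rownames(pf) <- config$population_names

  variants <- with_seed(derive_seed(seed, 3L), {
    gene <- sample(.study_genes, v, replace = TRUE)
    chrom <- as.character(match(gene, .study_genes))
    pos <- integer(v)
    for (g in unique(gene)) {       # unique, sorted positions per gene
      idx <- which(gene == g)
      pos[idx] <- sort(sample.int(5e5L, length(idx))) + 1e6L
    }
    consequence <- synthesize_annotations(v)
    region <- {
      t1 <- load_study_table("table1")
      reg <- t1[t1$dimension == "region", ]
      sample(reg$category, v, replace = TRUE, prob = reg$count)
    }
    is_snv <- stats::runif(v) < 226 / 253
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, v, replace = TRUE)
    alt <- vapply(seq_len(v), function(i) {
      if (is_snv[i]) sample(setdiff(bases, ref[i]), 1L)
      else paste0(ref[i], paste(sample(bases, sample(1:3, 1L),
                                       replace = TRUE), collapse = ""))
    }, character(1))
    data.frame(variant_id = paste0(chrom, ":", pos, "_", ref, "/", alt),
               chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
               mutation_type = ifelse(is_snv, "SNV", "INDEL"),
               region = region, consequence = consequence,
               stringsAsFactors = FALSE)
  })
  colnames(pf) <- variants$variant_id

  geno <- simulate_genotypes(pf, config$population_sizes,
                             config$missing_rate, derive_seed(seed, 4L))
  geno$variants <- variants
  structure(list(genotypes = geno, pop_freqs = pf, p_anc = p_anc,
                 config = config),
            class = "simulated_panel")
}

#' Estimate F_ST from population allele frequencies
#'
#' Weir-style ratio-of-sums estimator over loci: with per-locus
#' across-population variance s2 and mean frequency p-bar over K
#' populations, F_ST-hat = sum(s2) / sum(p-bar (1 - p-bar) + s2 / K). The
#' s2/K term corrects the downward bias of p-bar(1-p-bar) as an estimate of
#' the ancestral heterozygosity, making the estimator consistent for the
#' Balding-Nichols divergence parameter.
#'
#' @param pop_freqs population x variant frequency matrix (>= 2 rows).
#' @return scalar F_ST estimate.
#' @export
estimate_fst <- function(pop_freqs) {
  pop_freqs <- as.matrix(pop_freqs)
  if (nrow(pop_freqs) < 2L) stop("need at least two populations",
                                 call. = FALSE)
  k <- nrow(pop_freqs)
  s2 <- apply(pop_freqs, 2, stats::var)
  pbar <- colMeans(pop_freqs)
  sum(s2) / sum(pbar * (1 - pbar) + s2 / k)
}
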