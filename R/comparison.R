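# Allele-frequency contrasts: allele counting, standardization to a fixed
# allele total, two-sided Fisher exact tests, Hochberg step-up adjustment,
# direction signs, and the reporting rule.

#' Allele frequency by allele counting
#'
#' Counts alternate alleles over called genotypes: `alt_count` is the sum
#' of non-missing dosages, `called_alleles` is twice the number of
#' non-missing genotypes.
#'
#' @param dosages numeric vector of diploid dosages (0/1/2, `NA` missing).
#' @param population optional population label carried into the result.
#' @return one-row data.frame: `population`, `alt_count`,
#'   `called_alleles`, `af`.
#' @examples
#' allele_frequency(c(2, 2, 1))            # af = 5/6
#' allele_frequency(c(0, NA, 0))           # af = 0 over 4 alleles
#' @export
allele_frequency <- function(dosages, population = NA_character_) {
  called <- !is.na(dosages)
  if (!any(called)) stop("no called alleles", call. = FALSE)
  alt <- sum(dosages[called])
  ca <- 2L * sum(called)
  data.frame(population = population, alt_count = as.integer(alt),
             called_alleles = as.integer(ca), af = alt / ca,
             stringsAsFactors = FALSE)
}

#' Per-population allele-frequency table for a genotype matrix
#'
#' @param geno a [genotype_matrix()].
#' @return long data.frame with one row per (variant, population):
#'   `variant_id`, `population`, `alt_count`, `called_alleles`, `af` (`NA`
#'   when a population has no called genotype at a variant).
#' @export
allele_frequency_table <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  g <- geno$dosage
  pops <- levels(geno$populations)
  out <- do.call(rbind, lapply(pops, function(p) {
    sub <- g[geno$populations == p, , drop = FALSE]
    alt <- colSums(sub, na.rm = TRUE)
    ca <- 2L * colSums(!is.na(sub))
    data.frame(variant_id = colnames(g), population = p,
               alt_count = as.integer(alt), called_alleles = as.integer(ca),
               af = ifelse(ca > 0, alt / ca, NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Standardize an allele frequency to integer counts out of a fixed total
#'
#' Converts a frequency to "yes"/"no" allele counts out of
#' `total_alleles` (118 by default — the 59-individual reference cohort):
#' yes = round-half-up(af * total), no = total - yes. Rounding to integers
#' is required by the exact test; half-up is the package convention.
#'
#' @param af allele frequency vector, each in \[0,1\].
#' @param total_alleles the fixed allele total (>= 2).
#' @return data.frame with integer columns `yes`, `no` summing to
#'   `total_alleles` row-wise.
#' @examples
#' standardize_counts(0.8243)   # 97 yes, 21 no
#' @export
standardize_counts <- function(af, total_alleles = 118) {
  if (any(af < 0 | af > 1, na.rm = TRUE) || anyNA(af)) {
    stop("af must lie in [0,1]", call. = FALSE)
  }
  if (!is_count(total_alleles) || total_alleles < 2) {
    stop("total_alleles must be a count >= 2", call. = FALSE)
  }
  yes <- as.integer(round_half_up(af * total_alleles))
  data.frame(yes = yes, no = as.integer(total_alleles) - yes)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value by hypergeometric enumeration with all margins fixed:
#' the sum of probabilities of every table whose probability does not
#' exceed the observed table's, with a relative tolerance of 1e-7 guarding
#' floating-point ties — the convention of mainstream exact-test
#' implementations.
#'
#' @param tab 2x2 matrix of nonnegative integer counts (rows are the two
#'   populations, columns the yes/no allele counts).
#' @return p-value in (0, 1\].
#' @examples
#' fisher_exact_two_sided(matrix(c(3, 0, 0, 3), 2, byrow = TRUE))  # 0.1
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) ||
      any(tab != floor(tab))) {
    stop("tab must be a 2x2 matrix of nonnegative integers", call. = FALSE)
  }
  a <- tab[1, 1]
  m <- tab[1, 1] + tab[2, 1]          # first-column margin
  n <- tab[1, 2] + tab[2, 2]          # second-column margin
  k <- tab[1, 1] + tab[1, 2]          # first-row margin
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
}

#' Hochberg step-up adjustment
#'
#' Step-up familywise-error control: with ascending order statistics
#' p(1) <= ... <= p(m), adjusted(i) = min over j >= i of (m - j + 1) p(j),
#' capped at 1, returned in the input order. Uniformly no more conservative
#' than Bonferroni. Delegates to [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in \[0,1\] (empty allowed).
#' @return adjusted p-values, same length and order as the input.
#' @examples
#' hochberg_adjust(c(0.01, 0.02, 0.04))   # 0.03 0.04 0.04
#' @export
hochberg_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0,1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "hochberg")
}

#' Compare a reference population against comparator panels
#'
#' For every variant with usable entries in the reference and all
#' comparators, both allele frequencies are standardized to
#' `total_alleles` via [standardize_counts()], tested with
#' [fisher_exact_two_sided()], and given a direction sign:
#' `"+"` when the reference frequency is higher, `"-"` when lower, `"0"`
#' when equal. Hochberg adjustment is applied either within each variant
#' across its comparators (`adjust_scope = "per_variant"`, the default) or
#' across the whole matrix (`"global"`). Variants lacking a population
#' entry are skipped with a warning.
#'
#' @param af_table long allele-frequency table
#'   ([allele_frequency_table()] layout; `af` may be supplied directly).
#' @param reference reference population label.
#' @param comparators comparator population labels.
#' @param total_alleles standardization total (default 118).
#' @param adjust_scope `"per_variant"` or `"global"`.
#' @return data.frame of class `"comparison_matrix"`, one row per
#'   (variant, comparator): `variant_id`, `comparator`, `af_ref`,
#'   `af_cmp`, `yes_ref`, `yes_cmp`, `p`, `p_adj`, `sign`.
#' @export
compare_reference_to_panels <- function(af_table, reference, comparators,
                                        total_alleles = 118,
                                        adjust_scope = c("per_variant",
                                                         "global")) {
  adjust_scope <- match.arg(adjust_scope)
  need <- c("variant_id", "population", "af")
  if (!all(need %in% names(af_table))) {
    stop("af_table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pops <- c(reference, comparators)
  af <- af_table[af_table$population %in% pops, ]
  wide <- tapply(af$af, list(af$variant_id, af$population),
                 function(x) x[1])
  missing_pop <- setdiff(pops, colnames(wide))
  if (length(missing_pop)) {
    stop("populations absent from af_table: ",
         paste(missing_pop, collapse = ", "), call. = FALSE)
  }
  usable <- rowSums(is.na(wide[, pops, drop = FALSE])) == 0
  if (any(!usable)) {
    warning(sum(!usable), " variant(s) skipped: missing population entry",
            call. = FALSE)
  }
  wide <- wide[usable, , drop = FALSE]
  vids <- rownames(wide)

  rows <- vector("list", length(vids) * length(comparators))
  idx <- 0L
  for (v in vids) {
    std_ref <- standardize_counts(wide[v, reference], total_alleles)
    for (cmp in comparators) {
      std_cmp <- standardize_counts(wide[v, cmp], total_alleles)
      p <- fisher_exact_two_sided(rbind(as.numeric(std_ref),
                                        as.numeric(std_cmp)))
      dsig <- wide[v, reference] - wide[v, cmp]
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        variant_id = v, comparator = cmp,
        af_ref = wide[v, reference], af_cmp = wide[v, cmp],
        yes_ref = std_ref$yes, yes_cmp = std_cmp$yes, p = p,
        sign = if (dsig > 0) "+" else if (dsig < 0) "-" else "0",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(idx)])
  if (is.null(out)) {
    out <- data.frame(variant_id = character(), comparator = character(),
                      af_ref = numeric(), af_cmp = numeric(),
                      yes_ref = integer(), yes_cmp = integer(),
                      p = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
  }
  out$p_adj <- if (nrow(out) == 0L) numeric(0) else
    if (adjust_scope == "global") hochberg_adjust(out$p) else
      stats::ave(out$p, out$variant_id, FUN = hochberg_adjust)
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "total_alleles") <- total_alleles
  attr(out, "adjust_scope") <- adjust_scope
  class(out) <- c("comparison_matrix", "data.frame")
  out
}

#' Select variants passing the reporting rule
#'
#' A variant is reported when its p-value falls below `alpha` in at least
#' `min_populations` of its comparisons and its impact tier is in `tiers`
#' (High or Moderate by default); all others are routed to the
#' supplementary list. Raw p-values are thresholded by default; set
#' `use_adjusted` to threshold Hochberg-adjusted values instead.
#'
#' @param comparisons long data.frame with columns `variant_id`, `impact`
#'   and `p` (plus `p_adj` when `use_adjusted`), e.g. a
#'   `comparison_matrix` merged with per-variant impacts, or
#'   [comparison_long()] of the packaged comparison table.
#' @param alpha significance threshold.
#' @param min_populations minimum number of significant comparisons.
#' @param tiers impact tiers eligible for reporting.
#' @param use_adjusted threshold `p_adj` instead of `p`.
#' @return list with data.frames `reportable` and `supplementary`, each
#'   one row per variant: `variant_id`, `impact`, `n_significant`,
#'   `n_comparisons`.
#' @export
select_reportable <- function(comparisons, alpha = 0.05,
                              min_populations = 3,
                              tiers = c("High", "Moderate"),
                              use_adjusted = FALSE) {
  need <- c("variant_id", "impact", if (use_adjusted) "p_adj" else "p")
  if (!all(need %in% names(comparisons))) {
    stop("comparisons must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(comparisons) == 0L) {
    empty <- data.frame(variant_id = character(), impact = character(),
                        n_significant = integer(),
                        n_comparisons = integer(), stringsAsFactors = FALSE)
    return(list(reportable = empty, supplementary = empty))
  }
  pcol <- if (use_adjusted) "p_adj" else "p"
  vids <- unique(comparisons$variant_id)
  per <- do.call(rbind, lapply(vids, function(v) {
    sub <- comparisons[comparisons$variant_id == v, ]
    data.frame(variant_id = v, impact = as.character(sub$impact[1]),
               n_significant = sum(sub[[pcol]] < alpha),
               n_comparisons = nrow(sub), stringsAsFactors = FALSE)
  }))
  keep <- per$n_significant >= min_populations & per$impact %in% tiers
  list(reportable = per[keep, , drop = FALSE],
       supplementary = per[!keep, , drop = FALSE])
}
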