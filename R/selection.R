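# Variant inclusion filtering and detection of cohort-exclusive variants.

#' Variant inclusion criteria
#'
#' A genotype call is trusted when its read depth reaches `min_coverage`
#' (10 reads by default); a sample is a carrier when it is called and
#' carries at least one alternate allele; a variant is retained when its
#' carrier count reaches `min_carriers` (10 of the 64-individual cohort by
#' default) or, with `novel_overrides`, when it is flagged novel (absent
#' from previously reported populations).
#'
#' @param min_coverage minimum read depth for a genotype to count as
#'   called.
#' @param min_carriers minimum number of carrier individuals.
#' @param cohort_size cohort context, for reporting only.
#' @param novel_overrides should novelty alone retain a variant?
#' @return list of class `"selection_criteria"`.
#' @export
selection_criteria <- function(min_coverage = 10, min_carriers = 10,
                               cohort_size = 64, novel_overrides = TRUE) {
  if (min_coverage < 0) stop("min_coverage must be >= 0", call. = FALSE)
  if (min_carriers < 1) stop("min_carriers must be >= 1", call. = FALSE)
  structure(list(min_coverage = min_coverage, min_carriers = min_carriers,
                 cohort_size = cohort_size,
                 novel_overrides = isTRUE(novel_overrides)),
            class = "selection_criteria")
}

#' Apply carrier-count and novelty inclusion filters
#'
#' @param geno a [genotype_matrix()].
#' @param coverage optional sample x variant read-depth matrix aligned with
#'   the dosage matrix; when absent, every non-missing genotype is treated
#'   as adequately covered (missing genotypes are always below coverage —
#'   the `./.` convention).
#' @param criteria a [selection_criteria()].
#' @param novelty optional logical per variant; `TRUE` retains the variant
#'   regardless of carrier count when `novel_overrides` is set.
#' @return character vector of retained variant ids, in input column order.
#' @export
apply_inclusion_filters <- function(geno, coverage = NULL,
                                    criteria = selection_criteria(),
                                    novelty = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"),
            inherits(criteria, "selection_criteria"))
  g <- geno$dosage
  called <- !is.na(g)
  if (!is.null(coverage)) {
    coverage <- as.matrix(coverage)
    if (!all(dim(coverage) == dim(g))) {
      stop("coverage matrix must align with the dosage matrix",
           call. = FALSE)
    }
    called <- called & coverage >= criteria$min_coverage
  }
  carrier <- called & !is.na(g) & g >= 1
  carriers <- colSums(carrier)
  if (is.null(novelty)) novelty <- rep(FALSE, ncol(g))
  if (length(novelty) != ncol(g)) {
    stop("one novelty flag per variant is required", call. = FALSE)
  }
  keep <- carriers >= criteria$min_carriers |
    (criteria$novel_overrides & novelty)
  colnames(g)[keep]
}

#' Find variants exclusive to target groups
#'
#' A variant is exclusive to target group *g* when its alternate-allele
#' count is positive in *g* and zero — with at least one called allele —
#' in every reference panel. A variant whose reference-panel allele count
#' cannot be assessed (zero called alleles in some panel) is flagged
#' `unassessable` and never reported exclusive. A variant may be listed
#' under several target groups; the deduplicated union is counted by
#' variant id.
#'
#' @param af_counts long data.frame with columns `variant_id`,
#'   `population`, `alt_count`, `called_alleles`; every variant must have a
#'   row for each reference panel.
#' @param target_groups labels of the study groups screened for exclusive
#'   variants.
#' @param reference_panels labels of the panels a variant must be absent
#'   from.
#' @return list of class `"exclusive_report"`: `by_group` (data.frame of
#'   per-group hits with group allele frequency), `union` (distinct variant
#'   ids), `union_count`, `unassessable`.
#' @export
find_exclusive_variants <- function(af_counts, target_groups,
                                    reference_panels) {
  need <- c("variant_id", "population", "alt_count", "called_alleles")
  if (!all(need %in% names(af_counts))) {
    stop("af_counts must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  variants <- unique(af_counts$variant_id)
  cell <- function(col) {
    m <- matrix(NA_real_, length(variants),
                length(unique(af_counts$population)),
                dimnames = list(variants, unique(af_counts$population)))
    m[cbind(match(af_counts$variant_id, variants),
            match(af_counts$population, colnames(m)))] <- af_counts[[col]]
    m
  }
  alt <- cell("alt_count")
  called <- cell("called_alleles")
  miss_ref <- setdiff(reference_panels, colnames(alt))
  if (length(miss_ref)) {
    stop("reference panels absent from af_counts: ",
         paste(miss_ref, collapse = ", "), call. = FALSE)
  }
  ref_alt <- alt[, reference_panels, drop = FALSE]
  ref_called <- called[, reference_panels, drop = FALSE]
  if (anyNA(ref_alt)) {
    stop("every variant needs an entry for every reference panel",
         call. = FALSE)
  }
  unassessable <- variants[rowSums(ref_called == 0) > 0]
  absent_everywhere <- rowSums(ref_alt > 0) == 0 &
    !(variants %in% unassessable)

  rows <- list()
  for (g in target_groups) {
    if (!g %in% colnames(alt)) {
      stop("target group not present in af_counts: ", g, call. = FALSE)
    }
    hit <- which(!is.na(alt[, g]) & alt[, g] > 0 & absent_everywhere)
    if (length(hit)) {
      rows[[g]] <- data.frame(
        population = g,
        variant_id = variants[hit],
        alt_count = as.integer(alt[hit, g]),
        called_alleles = as.integer(called[hit, g]),
        af = alt[hit, g] / called[hit, g],
        stringsAsFactors = FALSE)
    }
  }
  by_group <- if (length(rows)) do.call(rbind, rows) else
    data.frame(population = character(), variant_id = character(),
               alt_count = integer(), called_alleles = integer(),
               af = numeric(), stringsAsFactors = FALSE)
  rownames(by_group) <- NULL
  union_ids <- unique(by_group$variant_id)
  structure(list(by_group = by_group, union = union_ids,
                 union_count = length(union_ids),
                 unassessable = unassessable),
            class = "exclusive_report")
}

#' @export
print.exclusive_report <- function(x, ...) {
  cat("Exclusive-variant report:", x$union_count, "distinct variants (",
      paste(sprintf("%s: %d", names(table(x$by_group$population)),
                    as.integer(table(x$by_group$population))),
            collapse = ", "), ")\n")
  if (length(x$unassessable)) {
    cat("unassessable:", length(x$unassessable), "variants\n")
  }
  invisible(x)
}
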