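# Annotation summary: tabulate a variant panel by mutation type, region,
# consequence and (derived) impact tier.

#' Summarize a variant annotation panel
#'
#' Tabulates variant records along up to four dimensions — mutation type
#' (SNV/INDEL), genomic region, consequence category and the impact tier
#' derived from the consequence via [classify_impact()] — reporting counts
#' and percentages of the panel total. Percentages are rounded half-up to
#' one decimal ([round_half_up()]).
#'
#' `records` needs a `consequence` column; `mutation_type` and `region`
#' columns are tabulated when present. When `mutation_type` is absent but
#' `ref`/`alt` allele columns exist, it is derived (SNV iff both alleles
#' have length 1). An empty panel yields zero counts with `NA` percentages
#' rather than a division error.
#'
#' @param records data.frame of variant records, one row per variant.
#' @return data.frame of class `"annotation_summary"` with columns
#'   `dimension`, `category`, `count`, `percent`; the panel size is in
#'   `attr(, "total")`.
#' @examples
#' recs <- data.frame(consequence = c("Intronic", "Stop gained"),
#'                    mutation_type = c("SNV", "SNV"))
#' summarize_annotations(recs)
#' @export
summarize_annotations <- function(records) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)

  if (n > 0L && !"mutation_type" %in% names(records) &&
      all(c("ref", "alt") %in% names(records))) {
    records$mutation_type <-
      ifelse(nchar(records$ref) == 1L & nchar(records$alt) == 1L,
             "SNV", "INDEL")
  }

  tab_dim <- function(values, levels) {
    counts <- table(factor(values, levels = levels))
    data.frame(category = names(counts),
               count = as.integer(counts),
               percent = if (n > 0L) {
                 round_half_up(100 * as.integer(counts) / n, 1)
               } else NA_real_,
               stringsAsFactors = FALSE)
  }

  pieces <- list()
  if (n == 0L || "mutation_type" %in% names(records)) {
    pieces$mutation_type <- tab_dim(
      if (n > 0L) toupper(records$mutation_type) else character(),
      c("SNV", "INDEL"))
  }
  if (n == 0L || "region" %in% names(records)) {
    pieces$region <- tab_dim(
      if (n > 0L) normalize_region(records$region) else character(),
      region_categories())
  }
  if (n > 0L && !"consequence" %in% names(records)) {
    stop("`records` must contain a `consequence` column", call. = FALSE)
  }
  cons <- if (n > 0L) normalize_consequence(records$consequence) else character()
  pieces$consequence <- tab_dim(cons, consequence_categories())
  pieces$impact <- tab_dim(
    if (n > 0L) as.character(classify_impact(cons)) else character(),
    impact_tiers())

  out <- do.call(rbind, Map(function(dim, df) {
    cbind(dimension = dim, df, stringsAsFactors = FALSE)
  }, names(pieces), pieces))
  rownames(out) <- NULL
  attr(out, "total") <- n
  class(out) <- c("annotation_summary", "data.frame")
  out
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat("Annotation summary of", attr(x, "total"), "variants\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Read and write annotation tables
#'
#' `read_annotations()` reads a TSV of per-variant annotations (at least
#' `variant_id` and `consequence`; `gene`, `region` and allele columns pass
#' through). `write_annotation_summary()` writes the four-dimension summary
#' as TSV with columns `dimension`, `category`, `count`, `percent`.
#'
#' @param path file path.
#' @param x an `annotation_summary`.
#' @return `read_annotations()` a data.frame; the writer returns `path`
#'   invisibly.
#' @export
read_annotations <- function(path) {
  ann <- read_tsv_file(path)
  need <- c("variant_id", "consequence")
  if (!all(need %in% names(ann))) {
    stop("annotation TSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ann
}

#' @rdname read_annotations
#' @export
write_annotation_summary <- function(x, path) {
  stopifnot(inherits(x, "annotation_summary"))
  write_tsv_file(as.data.frame(x), path)
}
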