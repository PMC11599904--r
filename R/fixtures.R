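# Packaged reference tables: hand-transcribed summaries of the indigenous
# glucocorticoid-pathway variant panel and its comparison against the 1000
# Genomes continental populations.

.study_comparators <- c("IND-LLA", "AFR", "AMR", "EAS", "EUR", "SAS")

#' Load a packaged reference table
#'
#' Four reference tables ship with the package as plain TSV:
#' \describe{
#'   \item{`table1`}{annotation summary of the 253-variant panel: counts and
#'     printed percentages by mutation type, region, consequence and impact.}
#'   \item{`table2`}{the 14 records of variants reported only in the two
#'     indigenous cohorts (9 INDG-LLA, 5 INDG-NLLA; one variant shared, so
#'     13 distinct sites), with region detail, impact and cohort frequency.}
#'   \item{`table3`}{the 15-variant frequency-comparison matrix: per variant
#'     a gene, an impact tier and six Fisher p-values with direction signs,
#'     one per comparator population (`IND-LLA`, `AFR`, `AMR`, `EAS`, `EUR`,
#'     `SAS`) against the IND-NLLA reference. `gene_alt` records an
#'     alternative gene attribution where the source material disagrees
#'     with itself (rs11068428: NOS3 vs NOS1).}
#'   \item{`table4`}{the 11 pairwise PERMANOVA rows: population pair,
#'     R-squared, pseudo-F and p-value.}
#' }
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`, `"table4"`.
#' @return data.frame; `table3` is in wide form, see [comparison_long()].
#' @examples
#' load_study_table("table4")
#' @export
load_study_table <- function(name = c("table1", "table2", "table3", "table4")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "pgxpop", mustWork = TRUE)
  tab <- read_tsv_file(path)
  if (name == "table3") tab$gene_alt[tab$gene_alt == "NA"] <- NA_character_
  tab
}

#' Pivot the wide comparison table to one row per (variant, comparator)
#'
#' The wide layout (columns `p_<comparator>` / `sign_<comparator>`) becomes
#' a long data.frame with columns `variant_id`, `gene`, `impact`,
#' `comparator`, `p`, `sign` — the layout consumed by
#' [select_reportable()].
#'
#' @param tab3 the wide table from `load_study_table("table3")`, or any
#'   data.frame with the same column convention.
#' @return long data.frame, six rows per variant.
#' @export
comparison_long <- function(tab3) {
  pcols <- grep("^p_", names(tab3), value = TRUE)
  comps <- sub("^p_", "", pcols)
  out <- do.call(rbind, lapply(comps, function(cc) {
    data.frame(variant_id = tab3$rsid,
               gene = tab3$gene,
               impact = tab3$impact,
               comparator = gsub("_", "-", cc),
               p = as.numeric(tab3[[paste0("p_", cc)]]),
               sign = as.character(tab3[[paste0("sign_", cc)]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(match(out$variant_id, tab3$rsid)), , drop = FALSE]
}

#' Expand the exclusive-variant table into a per-population allele-count table
#'
#' Builds the long `(variant_id, population, alt_count, called_alleles)`
#' table that [find_exclusive_variants()] consumes, from the packaged
#' exclusive-variant records: each record contributes a nonzero alternate
#' count in its own cohort (frequency times the cohort allele total, at
#' least 1), a zero count in the other cohort, and zero counts with fully
#' called alleles in every reference panel.
#'
#' @param tab2 the table from `load_study_table("table2")`.
#' @param group_alleles named vector of called-allele totals for the target
#'   cohorts (defaults: 10 for INDG-LLA, 118 for INDG-NLLA).
#' @param panel_alleles named vector of called-allele totals for the
#'   reference panels (defaults: 2x the 1000 Genomes panel sizes).
#' @return long data.frame with one row per (variant, population).
#' @export
table2_allele_counts <- function(tab2,
                                 group_alleles = c("INDG-LLA" = 10,
                                                   "INDG-NLLA" = 118),
                                 panel_alleles = c(AFR = 1322, AMR = 694,
                                                   EAS = 1008, EUR = 1006,
                                                   SAS = 978)) {
  vid <- paste0(tab2$chrom, ":", tab2$pos, "_", tab2$ref, "/", tab2$alt)
  variants <- unique(vid)
  pops <- c(names(group_alleles), names(panel_alleles))
  alleles <- c(group_alleles, panel_alleles)
  grid <- expand.grid(variant_id = variants, population = pops,
                      stringsAsFactors = FALSE)
  grid$called_alleles <- as.integer(alleles[grid$population])
  grid$alt_count <- 0L
  for (i in seq_along(vid)) {
    hit <- grid$variant_id == vid[i] & grid$population == tab2$population[i]
    grid$alt_count[hit] <- max(
      1L, as.integer(round_half_up(tab2$frequency[i] *
                                     alleles[tab2$population[i]])))
  }
  grid$af <- grid$alt_count / grid$called_alleles
  grid
}
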