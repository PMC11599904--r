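# Closed category sets for variant consequences and impact tiers, plus the
# consequence -> impact mapping.

.consequence_levels <- c(
  "Intragenic",
  "Intronic",
  "Next protein",
  "Non synonymous coding",
  "Non synonymous coding + splice site region",
  "Protein structural interaction locus",
  "Splice site region + intron",
  "Synonymous coding",
  "Stop gained",
  "3'UTR",
  "5'UTR"
)

.impact_levels <- c("High", "Moderate", "Low", "Modifier")

.region_levels <- c("3'UTR", "5'UTR", "Exon (CDS)", "Intragenic",
                    "Intronic", "Others")

# Severity mapping in the SnpEff style. "Protein structural interaction
# locus" sits in High: a stop gain alone cannot account for the six
# high-impact calls in the reference annotation summary (1 + 5 = 6), and the
# remaining tiers then reconcile exactly (38 + 1 = 39 Moderate;
# 40 + 8 + 2 = 50 Low; 8 + 134 + 9 + 7 = 158 Modifier).
.impact_map <- c(
  "stop gained"                                = "High",
  "protein structural interaction locus"       = "High",
  "non synonymous coding"                      = "Moderate",
  "non synonymous coding + splice site region" = "Moderate",
  "synonymous coding"                          = "Low",
  "splice site region + intron"                = "Low",
  "next protein"                               = "Low",
  "intronic"                                   = "Modifier",
  "intragenic"                                 = "Modifier",
  "3'utr"                                      = "Modifier",
  "5'utr"                                      = "Modifier"
)

# Spelling variants seen in annotation exports ("Intron" vs "Intronic",
# "Stop codon" vs "Stop gained", "3'UTR prime" vs "3'UTR").
.consequence_aliases <- c(
  "intron"           = "intronic",
  "stop codon"       = "stop gained",
  "stop_gained"      = "stop gained",
  "3'utr prime"      = "3'utr",
  "5'utr prime"      = "5'utr",
  "3_prime_utr"      = "3'utr",
  "5_prime_utr"      = "5'utr",
  "missense_variant" = "non synonymous coding",
  "synonymous_variant" = "synonymous coding"
)

#' Closed sets of consequence categories, impact tiers and regions
#'
#' The consequence vocabulary is the eleven-category set used by the
#' packaged annotation summary; `impact_tiers()` is the four-level SnpEff
#' severity scale.
#'
#' @return character vector of category labels.
#' @export
consequence_categories <- function() .consequence_levels

#' @rdname consequence_categories
#' @export
impact_tiers <- function() .impact_levels

#' @rdname consequence_categories
#' @export
region_categories <- function() .region_levels

#' Normalize consequence labels to the canonical category set
#'
#' Case-insensitive, with aliases for common spelling variants
#' ("Intron" -> "Intronic", "Stop codon" -> "Stop gained").
#'
#' @param x character vector of consequence labels.
#' @param strict error on labels outside the closed set (default) rather
#'   than returning `NA`.
#' @return character vector of canonical labels.
#' @export
normalize_consequence <- function(x, strict = TRUE) {
  key <- tolower(trimws(as.character(x)))
  key <- ifelse(key %in% names(.consequence_aliases),
                unname(.consequence_aliases[key]), key)
  canon <- .consequence_levels
  names(canon) <- tolower(canon)
  out <- unname(canon[key])
  if (strict && anyNA(out[!is.na(x)])) {
    bad <- unique(x[is.na(out) & !is.na(x)])
    stop("unknown consequence categor",
         if (length(bad) > 1L) "ies: " else "y: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  out
}

#' Classify variant consequences into impact tiers
#'
#' Maps each consequence category to one of the four SnpEff-style severity
#' tiers: stop gains and protein structural interaction loci are High;
#' non-synonymous coding changes (with or without a splice-region overlap)
#' are Moderate; synonymous, splice-region+intron and next-protein changes
#' are Low; intronic, intragenic and UTR changes are Modifier. The mapping
#' is total on the closed category set and errors on anything else; there is
#' no silent default tier.
#'
#' @param consequence character vector of consequence categories (canonical
#'   or recognisable alias spellings).
#' @return factor with levels `impact_tiers()`.
#' @examples
#' classify_impact(c("Stop gained", "Intron", "Synonymous coding"))
#' @export
classify_impact <- function(consequence) {
  canon <- normalize_consequence(consequence, strict = TRUE)
  factor(unname(.impact_map[tolower(canon)]), levels = .impact_levels)
}

normalize_region <- function(x, strict = TRUE) {
  key <- tolower(trimws(as.character(x)))
  key[key %in% c("other", "others")] <- "others"
  key[key %in% c("exon", "exon (cds)", "exon/cds", "cds")] <- "exon (cds)"
  key[key == "intron"] <- "intronic"
  canon <- .region_levels
  names(canon) <- tolower(canon)
  out <- unname(canon[key])
  if (strict && anyNA(out[!is.na(x)])) {
    bad <- unique(x[is.na(out) & !is.na(x)])
    stop("unknown region categor",
         if (length(bad) > 1L) "ies: " else "y: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  out
}
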