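# VCF and TSV interchange for genotype panels.

#' Write a genotype panel as VCF
#'
#' Emits a minimal diploid VCFv4.2 with CHROM, POS, ID, REF, ALT and
#' per-sample unphased GT (missing genotypes as `./.`). Variant fields come
#' from the attached variant table when present, otherwise from the
#' variant ids.
#'
#' @param geno a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  g <- geno$dosage
  v <- geno$variants
  if (is.null(v)) {
    v <- data.frame(variant_id = colnames(g),
                    chrom = "1", pos = seq_len(ncol(g)),
                    ref = "A", alt = "T", stringsAsFactors = FALSE)
  }
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(g), ncol = nrow(g))
  obs <- !is.na(t(g))
  gt[obs] <- gt_code[t(g)[obs] + 1L]
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=pgxpop",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", rownames(g)),
                    collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype panel from VCF
#'
#' Parses the VCF with [vcfR::read.vcfR()], converts GT fields to
#' alternate-allele dosages (`./.` to `NA`), and attaches population
#' labels from a two-column sample/population map.
#'
#' @param vcf_path VCF file path (plain or gzipped).
#' @param pop_map optional data.frame with columns `sample`,
#'   `population`, or a path to such a TSV; samples without an entry get
#'   population `"unknown"`.
#' @return a [genotype_matrix()] with a variant table (`variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `mutation_type`).
#' @export
read_genotype_vcf <- function(vcf_path, pop_map = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    if (is.na(x) || x %in% c("./.", ".|.", ".")) return(NA_integer_)
    sum(strsplit(x, "[/|]")[[1]] == "1")
  }
  codes <- unique(as.vector(gt))
  lut <- vapply(codes, count_alt, integer(1))
  dos <- matrix(lut[match(as.vector(gt), codes)], nrow = nrow(gt),
                dimnames = dimnames(gt))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  vid <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS, "_", fix$REF, "/",
                       fix$ALT),
                fix$ID)
  rownames(dos) <- vid
  dosage <- t(dos)
  if (is.character(pop_map) && length(pop_map) == 1L) {
    pop_map <- read_population_map(pop_map)
  }
  pops <- if (is.null(pop_map)) rep("unknown", nrow(dosage)) else {
    stopifnot(all(c("sample", "population") %in% names(pop_map)))
    idx <- match(rownames(dosage), pop_map$sample)
    ifelse(is.na(idx), "unknown", pop_map$population[idx])
  }
  variants <- data.frame(
    variant_id = vid, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    mutation_type = ifelse(nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L,
                           "SNV", "INDEL"),
    stringsAsFactors = FALSE)
  genotype_matrix(dosage, pops, variants)
}

#' Read and write sample-to-population maps and annotation TSVs
#'
#' The population map is a two-column TSV (`sample`, `population`); the
#' annotation TSV carries one row per variant (`variant_id`, `gene`,
#' `consequence`, plus any extra columns).
#'
#' @param geno a [genotype_matrix()] (writers).
#' @param variants per-variant annotation data.frame.
#' @param path file path.
#' @return readers return a data.frame; writers return `path` invisibly.
#' @export
write_population_map <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  write_tsv_file(data.frame(sample = rownames(geno$dosage),
                            population = as.character(geno$populations),
                            stringsAsFactors = FALSE), path)
}

#' @rdname write_population_map
#' @export
read_population_map <- function(path) {
  pm <- read_tsv_file(path)
  if (!all(c("sample", "population") %in% names(pm))) {
    stop("population map needs columns `sample` and `population`",
         call. = FALSE)
  }
  pm
}

#' @rdname write_population_map
#' @export
write_annotations_tsv <- function(variants, path) {
  stopifnot(is.data.frame(variants), "variant_id" %in% names(variants))
  write_tsv_file(variants, path)
}
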