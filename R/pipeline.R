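# End-to-end orchestration: simulate or ingest a panel, then annotate,
# select, compare and measure divergence, writing one TSV per stage.

#' Pipeline configuration
#'
#' Bundles every stage's settings. Exactly one input mode is active:
#' `"simulate"` draws a panel from [simulate_panel()] under `sim`;
#' `"vcf"` ingests `vcf_path` + `annotation_path` + `population_map_path`.
#'
#' @param mode `"simulate"` or `"vcf"`.
#' @param sim a [simulation_config()] (simulate mode).
#' @param vcf_path,annotation_path,population_map_path input files (vcf
#'   mode).
#' @param reference reference population for the frequency contrasts.
#' @param target_groups populations screened for exclusive variants.
#' @param alpha,min_populations,tiers reporting rule parameters
#'   ([select_reportable()]).
#' @param total_alleles standardization total for the exact tests.
#' @param hochberg_scope `"per_variant"` or `"global"`.
#' @param metric distance metric for MDS and PERMANOVA.
#' @param k MDS dimensions.
#' @param n_permutations PERMANOVA permutations per pair.
#' @param seed integer master seed for the whole run.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(mode = c("simulate", "vcf"),
                            sim = simulation_config(),
                            vcf_path = NULL,
                            annotation_path = NULL,
                            population_map_path = NULL,
                            reference = "IND-NLLA",
                            target_groups = c("IND-LLA", "IND-NLLA"),
                            alpha = 0.05,
                            min_populations = 3,
                            tiers = c("High", "Moderate"),
                            total_alleles = 118,
                            hochberg_scope = "per_variant",
                            metric = "euclidean",
                            k = 2,
                            n_permutations = 999,
                            seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, sim = sim, vcf_path = vcf_path,
                 annotation_path = annotation_path,
                 population_map_path = population_map_path,
                 reference = reference, target_groups = target_groups,
                 alpha = alpha, min_populations = min_populations,
                 tiers = tiers, total_alleles = total_alleles,
                 hochberg_scope = hochberg_scope, metric = metric,
                 k = k, n_permutations = n_permutations,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Returns a data.frame of machine-readable issues (empty when the
#' configuration is valid); validation never throws.
#'
#' @param config a [pipeline_config()].
#' @return data.frame with columns `code`, `message` (zero rows when
#'   valid).
#' @export
validate_config <- function(config) {
  issues <- list()
  add <- function(code, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      code = code, message = message, stringsAsFactors = FALSE)
  }
  if (!inherits(config, "pipeline_config")) {
    add("not_a_config", "object is not a pipeline_config")
  } else {
    if (!config$mode %in% c("simulate", "vcf")) {
      add("invalid_mode", paste("unknown mode:", config$mode))
    }
    if (config$mode == "vcf") {
      for (p in c("vcf_path", "annotation_path", "population_map_path")) {
        if (is.null(config[[p]]) || !file.exists(config[[p]])) {
          add("missing_input", paste(p, "does not exist"))
        }
      }
    }
    if (config$mode == "simulate" &&
        !inherits(config$sim, "simulation_config")) {
      add("invalid_sim_config", "sim is not a simulation_config")
    }
    if (!is.numeric(config$alpha) || config$alpha <= 0 ||
        config$alpha > 1) {
      add("alpha_out_of_range", "alpha must lie in (0, 1]")
    }
    if (config$min_populations < 1) {
      add("min_populations_out_of_range", "min_populations must be >= 1")
    }
    if (!all(config$tiers %in% impact_tiers())) {
      add("unknown_tier", "tiers must be drawn from impact_tiers()")
    }
    if (!is_count(config$total_alleles) || config$total_alleles < 2) {
      add("total_alleles_out_of_range", "total_alleles must be >= 2")
    }
    if (!config$hochberg_scope %in% c("per_variant", "global")) {
      add("invalid_hochberg_scope",
          "hochberg_scope must be per_variant or global")
    }
    if (!config$metric %in% c("euclidean", "manhattan", "bray-curtis")) {
      add("invalid_metric", paste("unknown metric:", config$metric))
    }
    if (config$k < 1) add("k_out_of_range", "k must be >= 1")
    if (config$n_permutations < 1) {
      add("n_permutations_out_of_range", "n_permutations must be >= 1")
    }
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(code = character(), message = character(),
               stringsAsFactors = FALSE)
}

# Write `df` atomically: a .partial file is promoted only on success, so
# an aborted run leaves clearly marked partial output.
write_stage_tsv <- function(df, path) {
  partial <- paste0(path, ".partial")
  write_tsv_file(df, partial)
  file.rename(partial, path)
  invisible(path)
}

#' Run the full comparative analysis pipeline
#'
#' Executes, in order: input acquisition (simulation or VCF ingestion),
#' annotation summary, per-population allele frequencies, exclusive-variant
#' detection, standardized frequency comparison with the reporting rule,
#' population-level MDS, and individual-level pairwise PERMANOVA. Each
#' stage writes one TSV into `out_dir`; the run is deterministic given the
#' configured seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return list of class `"run_report"`: per-stage records of parameters,
#'   counts and files, plus the output file listing.
#' @export
run_analysis <- function(config, out_dir = "pgxpop-output") {
  issues <- validate_config(config)
  if (nrow(issues) > 0L) {
    stop("invalid configuration: ",
         paste(issues$code, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  t_start <- Sys.time()
  run_stage <- function(name, params, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages[[name]] <<- c(list(stage = name, params = params,
                              time = format(Sys.time())), res["counts"],
                         res["files"])
    res$value
  }

  panel <- run_stage("input", list(mode = config$mode), function() {
    if (config$mode == "simulate") {
      sim <- simulate_panel(config$sim)
      geno <- sim$genotypes
    } else {
      geno <- read_genotype_vcf(config$vcf_path,
                                config$population_map_path)
      ann <- read_annotations(config$annotation_path)
      geno$variants <- merge(geno$variants,
                             ann[, setdiff(names(ann),
                                           setdiff(names(geno$variants),
                                                   "variant_id"))],
                             by = "variant_id", sort = FALSE)
      geno$variants <- geno$variants[
        match(colnames(geno$dosage), geno$variants$variant_id), ]
    }
    list(value = geno,
         counts = list(n_samples = nrow(geno$dosage),
                       n_variants = ncol(geno$dosage)),
         files = character())
  })

  f_summary <- file.path(out_dir, "annotation_summary.tsv")
  run_stage("annotation_summary", list(), function() {
    s <- summarize_annotations(panel$variants)
    write_stage_tsv(as.data.frame(s), f_summary)
    list(value = s, counts = list(n_variants = attr(s, "total")),
         files = f_summary)
  })

  af <- run_stage("allele_frequencies", list(), function() {
    af <- allele_frequency_table(panel)
    list(value = af, counts = list(n_rows = nrow(af)), files = character())
  })

  pops <- levels(panel$populations)
  f_excl <- file.path(out_dir, "exclusive_variants.tsv")
  run_stage("exclusive_variants",
            list(targets = config$target_groups), function() {
    targets <- intersect(config$target_groups, pops)
    refs <- setdiff(pops, config$target_groups)
    rep <- find_exclusive_variants(af, targets, refs)
    write_stage_tsv(rep$by_group, f_excl)
    list(value = rep, counts = list(union_count = rep$union_count),
         files = f_excl)
  })

  f_cmp <- file.path(out_dir, "comparison_matrix.tsv")
  f_rep <- file.path(out_dir, "reportable_variants.tsv")
  run_stage("frequency_comparison",
            list(reference = config$reference,
                 total_alleles = config$total_alleles), function() {
    comparators <- setdiff(pops, config$reference)
    cm <- compare_reference_to_panels(af, config$reference, comparators,
                                      config$total_alleles,
                                      config$hochberg_scope)
    impact <- classify_impact(panel$variants$consequence)
    cm$impact <- as.character(
      impact[match(cm$variant_id, panel$variants$variant_id)])
    write_stage_tsv(as.data.frame(cm), f_cmp)
    sel <- select_reportable(cm, config$alpha, config$min_populations,
                             config$tiers)
    write_stage_tsv(sel$reportable, f_rep)
    list(value = cm,
         counts = list(n_comparisons = nrow(cm),
                       n_reportable = nrow(sel$reportable)),
         files = c(f_cmp, f_rep))
  })

  f_mds <- file.path(out_dir, "mds_coordinates.tsv")
  run_stage("mds", list(metric = config$metric, k = config$k), function() {
    profiles <- suppressMessages(population_profile_matrix(af))
    emb <- classical_mds(distance_matrix(profiles, config$metric),
                         config$k)
    coords <- data.frame(entity = rownames(emb$points), emb$points,
                         stringsAsFactors = FALSE)
    coords$eigenvalue <- emb$eig[seq_len(nrow(coords))]
    write_stage_tsv(coords, f_mds)
    list(value = emb, counts = list(n_entities = nrow(emb$points)),
         files = f_mds)
  })

  f_perm <- file.path(out_dir, "permanova_pairs.tsv")
  run_stage("pairwise_permanova",
            list(metric = config$metric,
                 n_permutations = config$n_permutations,
                 seed = config$seed), function() {
    D <- distance_matrix(panel$dosage, config$metric)
    pp <- pairwise_permanova(D, panel$populations,
                             config$n_permutations,
                             seed = derive_seed(config$seed, 7L))
    write_stage_tsv(as.data.frame(pp), f_perm)
    list(value = pp, counts = list(n_pairs = nrow(pp)), files = f_perm)
  })

  files <- unlist(lapply(stages, `[[`, "files"), use.names = FALSE)
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("output files missing at run end: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(stages = stages, files = files, seed = config$seed,
                 config = config, started = format(t_start),
                 finished = format(Sys.time())),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("pgxpop run (seed ", x$seed, "): ", length(x$stages),
      " stages, ", length(x$files), " output files\n", sep = "")
  for (f in x$files) cat("  -", f, "\n")
  invisible(x)
}
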