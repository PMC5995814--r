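#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pathway-network pipeline; the
#' numeric defaults are the standard operating values of the method
#' (enrichment and disease thresholds 0.01, four annotated genes minimum,
#' 99.95% set-cover coverage, 50-threshold edge scan, 100 permutation
#' replicates per disease).
#'
#' @param alpha_go BH-adjusted p threshold for GO-term enrichment.
#' @param alpha_disease Raw p threshold for disease-pathway association.
#' @param min_annotated Minimum annotated genes per pathway.
#' @param coverage_fraction Gene-coverage stop fraction of the proportional
#'   set cover.
#' @param target_size Preferred pathway size for set-cover tie-breaks;
#'   `NULL` means the median size of the candidate set.
#' @param method Term similarity measure, `"wang"` or `"resnik"`.
#' @param aggregation Set aggregation, `"bma"` or `"pairwise"`.
#' @param wang_weights Wang relation decay weights.
#' @param n_thresholds Candidate thresholds in the edge scan.
#' @param disease_reps Random replicates per disease module test.
#' @param exclusion_terms Name-filter term lists (see [filter_by_name()]).
#' @param seed Master seed; stage seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha_go = 0.01,
                            alpha_disease = 0.01,
                            min_annotated = 4L,
                            coverage_fraction = 0.9995,
                            target_size = NULL,
                            method = "wang",
                            aggregation = "bma",
                            wang_weights = c(is_a = 0.8, part_of = 0.6),
                            n_thresholds = 50L,
                            disease_reps = 100L,
                            exclusion_terms = default_exclusion_terms(),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pathway-network pipeline
#'
#' Executes, in order: pathway curation (deduplication, disease-name
#' filtering), annotation loading (evidence filtering, ancestor propagation),
#' annotation-coverage filtering, GO enrichment, functional-profile
#' minimization, proportional set cover, pathway-pathway semantic similarity,
#' threshold scan, edge pruning, network statistics, disease mapping and
#' disease-module clustering tests. Every removal is recorded in the stage
#' log; given fixed inputs and config the result is deterministic.
#'
#' @param obo,gaf,gmt,diseases Inputs as file paths or character vectors of
#'   lines (disease input may be `NULL` to skip disease mapping).
#' @param config A [pipeline_config()].
#' @return List of class `pathnet_result` with elements `dag`, `annotations`,
#'   `pathways` (curated + set-covered [pathway_set()]), `profiles`,
#'   `minimal_profiles`, `similarities`, `scan`, `network`, `network_stats`,
#'   `disease_mapping`, `disease_tests`, `stage_log`.
#' @export
run_pipeline <- function(obo, gaf, gmt, diseases = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dag <- read_obo(obo)
  annot <- propagate_annotations(filter_evidence(read_gaf(gaf)), dag)
  ps <- read_gmt(gmt)
  n0 <- nrow(ps)
  ps <- deduplicate_pathways(ps)
  ps <- filter_by_name(ps, config$exclusion_terms)
  ps <- filter_annotation_coverage(ps, annot,
                                   min_annotated = config$min_annotated)
  profiles <- profile_pathways(ps, annot, alpha = config$alpha_go)
  no_terms <- unprofiled_pathways(profiles)
  ps <- pathway_set(dplyr::filter(ps, !(.data$id %in% no_terms)),
                    curation_log(ps))
  ps <- log_stage(ps, "profile_pathways", length(no_terms),
                  "no enriched GO term")
  minimal <- minimize_profiles(profiles, annot, ps)
  ps <- proportional_set_cover(ps, target_size = config$target_size,
                               coverage_fraction = config$coverage_fraction)
  minimal <- dplyr::filter(minimal, .data$pathway %in% ps$id)
  ic <- if (config$method == "resnik") ic_map(annot, dag) else NULL
  sims <- pathway_similarity(minimal, dag, method = config$method,
                             aggregation = config$aggregation,
                             ic = ic, weights = config$wang_weights)
  scan <- threshold_scan(sims, n_thresholds = config$n_thresholds)
  net <- prune_network(sims, scan$threshold)
  stats_tbl <- glance(net)
  mapping <- NULL
  tests <- NULL
  if (!is.null(diseases)) {
    dset <- read_disease_table(diseases)
    background <- sort(unique(unlist(ps$annotated, use.names = FALSE)))
    mapping <- map_diseases(dset, ps, background,
                            alpha = config$alpha_disease)
    tests <- disease_module_test(net, mapping, reps = config$disease_reps,
                                 seed = derive_seed(config$seed, "disease"))
  }
  log <- curation_log(ps)
  log$retained <- n0 - cumsum(log$removed)
  structure(
    list(dag = dag, annotations = annot, pathways = ps,
         profiles = profiles, minimal_profiles = minimal,
         similarities = sims, scan = scan, network = net,
         network_stats = stats_tbl,
         disease_mapping = mapping, disease_tests = tests,
         stage_log = log, config = config),
    class = "pathnet_result")
}

#' @export
print.pathnet_result <- function(x, ...) {
  cat("<pathnet_result>\n")
  cat(sprintf("  pathways: %d (of %d initial)\n", nrow(x$pathways),
              x$stage_log$retained[1] + x$stage_log$removed[1]))
  cat(sprintf("  network: %d nodes, %d edges at threshold %.4f\n",
              nrow(x$network$nodes), nrow(x$network$edges),
              x$network$threshold))
  if (!is.null(x$disease_tests)) {
    cat(sprintf("  diseases tested: %d (%d clustered at p < 0.01)\n",
                nrow(x$disease_tests),
                sum(x$disease_tests$p < 0.01 & x$disease_tests$clustered)))
  }
  invisible(x)
}

#' @export
glance.pathnet_result <- function(x, ...) {
  dplyr::bind_cols(
    x$network_stats,
    tibble::tibble(
      n_profiled_terms = nrow(x$minimal_profiles),
      n_diseases_tested = if (is.null(x$disease_tests)) 0L
                          else nrow(x$disease_tests)))
}

#' @export
tidy.pathnet_result <- function(x, ...) {
  x$stage_log
}
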