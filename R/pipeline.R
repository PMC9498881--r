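#' Pipeline configuration
#'
#' Collects every input and tuning choice of the end-to-end analysis:
#' input file paths, the case-control cohorts to analyze, covariates to
#' adjust for, similarity measures, the candidate K range, the small-K
#' silhouette tolerance, the seed, and the output directory. One run
#' covers one imaging modality (one phenotype table); cross-modality
#' comparison is scripted over runs.
#'
#' @param genotypes path to the genotype file.
#' @param phenotypes path to the phenotype CSV.
#' @param out_dir output directory for all artifacts.
#' @param cohorts list of [cohort_spec()] objects (at least one).
#' @param snp_gene_map optional path to a SNP-to-gene TSV.
#' @param true_labels optional path to a planted-labels TSV (columns
#'   snp_id, cluster) for recovery scoring of simulated cohorts.
#' @param genotype_dialect `"csv"` or `"plink_raw"`.
#' @param covariates covariate column names used in the regressions.
#' @param measures similarity measures (default: all five).
#' @param k_range candidate numbers of clusters (default 2:9).
#' @param tolerance small-K preference slack (default 0.01).
#' @param seed single integer driving all randomness.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, phenotypes, out_dir,
                            cohorts,
                            snp_gene_map = NULL,
                            true_labels = NULL,
                            genotype_dialect = c("csv", "plink_raw"),
                            covariates = c("age", "sex", "education"),
                            measures = similarity_measures,
                            k_range = 2:9,
                            tolerance = 0.01,
                            seed = 1L) {
  genotype_dialect <- match.arg(genotype_dialect)
  if (missing(genotypes) || is.null(genotypes)) {
    stop("config error: genotype path is required")
  }
  if (missing(phenotypes) || is.null(phenotypes)) {
    stop("config error: phenotype path is required")
  }
  if (missing(out_dir) || is.null(out_dir)) {
    stop("config error: output directory is required")
  }
  if (inherits(cohorts, "cohort_spec")) cohorts <- list(cohorts)
  if (length(cohorts) == 0) stop("config error: at least one cohort required")
  if (!all(vapply(cohorts, inherits, logical(1), "cohort_spec"))) {
    stop("config error: cohorts must be cohort_spec objects")
  }
  if (length(measures) == 0 ||
      !all(measures %in% similarity_measures)) {
    stop("config error: measures must be a nonempty subset of: ",
         paste(similarity_measures, collapse = ", "))
  }
  if (min(k_range) < 2) stop("config error: k_range must start at >= 2")
  for (p in c(genotypes, phenotypes, snp_gene_map, true_labels)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("config error: input file not found: ", p)
    }
  }
  names(cohorts) <- vapply(cohorts, `[[`, character(1), "name")
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 out_dir = out_dir, cohorts = cohorts,
                 snp_gene_map = snp_gene_map, true_labels = true_labels,
                 genotype_dialect = genotype_dialect,
                 covariates = covariates, measures = measures,
                 k_range = k_range, tolerance = tolerance,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full imaging-genetics clustering pipeline
#'
#' Executes, per cohort: covariate-adjusted association mapping, row
#' normalization, construction of the similarity networks; then, over
#' the whole (measure x cohort) grid: the silhouette sweep over K, the
#' multigraph min-max cut at the selected K, and per-cluster annotation
#' exports. Every intermediate artifact is written under `out_dir`,
#' ending with a `summary.json` (selected K, per-cohort cluster sizes and
#' objectives, silhouette curve, and planted-recovery ARI when truth
#' labels were supplied). Identical config and seed give identical
#' outputs; stage failures carry the stage name, and artifacts written
#' before a failure are retained for debugging.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  geno <- stage("read_inputs",
                read_genotypes(config$genotypes, config$genotype_dialect))
  phen <- stage("read_inputs", read_phenotypes(config$phenotypes))
  gene_map <- if (!is.null(config$snp_gene_map)) {
    stage("read_inputs", read_snp_gene_map(config$snp_gene_map))
  } else {
    stats::setNames(character(0), character(0))
  }

  grid <- list()
  maps <- list()
  for (coh in names(config$cohorts)) {
    amap <- stage("associate",
                  association_map(geno, phen, config$cohorts[[coh]],
                                  covariates = config$covariates))
    write_matrix(amap, file.path(out, sprintf("association_map_%s.tsv", coh)),
                 "association_map")
    nmap <- stage("normalize", normalize_rows(amap))
    write_matrix(nmap,
                 file.path(out, sprintf("association_map_%s_normalized.tsv",
                                        coh)),
                 "association_map")
    maps[[coh]] <- nmap
    nets <- stage("networks", similarity_networks(nmap, config$measures))
    for (ms in names(nets)) {
      write_matrix(nets[[ms]],
                   file.path(out, sprintf("network_%s_%s.tsv", coh, ms)),
                   "network")
    }
    grid[[coh]] <- nets
  }

  report <- stage("select_k",
                  select_k(grid, k_range = config$k_range,
                           tolerance = config$tolerance, seed = config$seed))
  jsonlite::write_json(
    list(averaged_score = as.list(report$averaged_score),
         selected_k = report$selected_k, tolerance = report$tolerance,
         per_cell_scores = report$per_cell_scores),
    file.path(out, "silhouette_report.json"),
    auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(k = as.integer(names(report$averaged_score)),
                              averaged_silhouette =
                                sprintf("%.17g", report$averaged_score)),
                   file.path(out, "silhouette_curve.csv"), row.names = FALSE,
                   quote = FALSE)

  truth <- NULL
  if (!is.null(config$true_labels)) {
    tl <- utils::read.table(config$true_labels, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    truth <- stats::setNames(tl[[2]], tl[[1]])
  }

  selected <- as.character(report$selected_k)
  cohorts_summary <- list()
  for (coh in names(config$cohorts)) {
    assignment <- report$assignments[[selected]][[coh]]
    write_assignment(assignment,
                     file.path(out, sprintf("assignment_%s.json", coh)))
    stage("annotate",
          export_annotations(maps[[coh]], assignment, gene_map,
                             file.path(out, "annotations", coh)))
    entry <- list(
      cluster_sizes = as.integer(tabulate(assignment, report$selected_k)),
      hard_objective = minmax_objective(grid[[coh]], assignment,
                                        report$selected_k))
    if (!is.null(truth)) {
      entry$ari <- adjusted_rand_index(assignment[names(truth)], truth)
    }
    cohorts_summary[[coh]] <- entry
  }

  summary <- list(selected_k = report$selected_k,
                  tolerance = report$tolerance,
                  seed = config$seed,
                  measures = config$measures,
                  k_range = as.integer(config$k_range),
                  averaged_silhouette = as.list(report$averaged_score),
                  cohorts = cohorts_summary)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
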