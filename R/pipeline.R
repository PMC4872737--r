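#' Structured configuration for a pipeline run
#'
#' Collects every input path and module setting; validated before any
#' computation and echoed (with a stable fingerprint) into every report the
#' run writes.
#'
#' @param reference Path to the single-record reference FASTA.
#' @param manifest Path to the cohort manifest TSV (see [read_cohort()]).
#' @param output_dir Output directory for artifacts (created if needed).
#' @param catalog Optional known-variant catalog TSV.
#' @param filter A [filter_config()].
#' @param iterations Monte Carlo iterations for the trend tests.
#' @param seed Integer seed governing every stochastic step of the run.
#' @param sidedness,range_mode Passed to the Monte Carlo trend tests.
#' @param distance_model,gamma_shape,bootstrap_replicates,phylo_threshold
#'   Phylogeny settings (see [variant_distances()], [bootstrap_support()],
#'   [build_variant_matrix()]).
#' @param log_level \code{"quiet"}, \code{"info"} or \code{"debug"}.
#' @return A \code{run_config} object.
#' @export
run_config <- function(reference, manifest, output_dir,
                       catalog = NULL, filter = filter_config(),
                       iterations = 10000L, seed = 1L,
                       sidedness = "two_sided", range_mode = "pooled",
                       distance_model = "jc_gamma", gamma_shape = 0.75,
                       bootstrap_replicates = 1000L,
                       phylo_threshold = 0.01,
                       log_level = "info") {
  for (p in c(reference, manifest, catalog))
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  stopifnot(inherits(filter, "filter_config"), iterations >= 1,
            bootstrap_replicates >= 1)
  cfg <- structure(list(reference = reference, manifest = manifest,
                        output_dir = output_dir, catalog = catalog,
                        filter = filter, iterations = as.integer(iterations),
                        seed = as.integer(seed), sidedness = sidedness,
                        range_mode = range_mode,
                        distance_model = distance_model,
                        gamma_shape = gamma_shape,
                        bootstrap_replicates = as.integer(bootstrap_replicates),
                        phylo_threshold = phylo_threshold,
                        log_level = log_level),
                   class = "run_config")
  cfg
}

# stable fingerprint of the scientific configuration (polynomial byte hash);
# the output location and verbosity do not change what is computed
config_hash <- function(config) {
  x <- unclass(config)
  x$output_dir <- NULL
  x$log_level <- NULL
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# logging to stderr only; artifacts never share a stream with log lines
log_msg <- function(config, level, ...) {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[config$log_level]] >= lv[[level]])
    message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
}

config_echo <- function(config) {
  list(reference = config$reference, manifest = config$manifest,
       catalog = config$catalog,
       filter = unclass(config$filter), iterations = config$iterations,
       seed = config$seed, sidedness = config$sidedness,
       range_mode = config$range_mode,
       distance_model = config$distance_model,
       gamma_shape = config$gamma_shape,
       bootstrap_replicates = config$bootstrap_replicates,
       phylo_threshold = config$phylo_threshold,
       config_hash = config_hash(config))
}

write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Classify a cohort and write classification artifacts
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-loaded cohort (list of [patient_triplet()]);
#'   read from the manifest otherwise.
#' @return Invisibly, a list with the classified table, the per-patient
#'   counts and the summary.
#' @export
run_classify <- function(config, cohort = NULL) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- read_mt_reference(config$reference)
  if (is.null(cohort)) cohort <- read_cohort(config$manifest, ref)
  log_msg(config, "info", "classifying ", length(cohort), " patients")
  classified <- classify_cohort(cohort, config$filter)
  catalog <- if (!is.null(config$catalog)) read_catalog(config$catalog)
  classified <- annotate_known(classified, catalog)
  counts <- count_table(classified)
  summary <- count_summary(counts)
  utils::write.table(classified,
                     file.path(config$output_dir, "classified_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(counts, file.path(config$output_dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_report(c(summary, list(config = config_echo(config))),
               file.path(config$output_dir, "classification_summary.json"))
  invisible(list(classified = classified, counts = counts,
                 summary = summary, cohort = cohort, reference = ref))
}

mc_report <- function(test) {
  list(statistic = test$statistic, observed_mean = test$observed_mean,
       p_value = test$p_value, iterations = test$iterations,
       seed = test$seed, sidedness = test$sidedness,
       range_mode = test$range_mode, ranges = test$ranges)
}

#' Run both trend tests and write the dynamics report
#'
#' @param config A [run_config()].
#' @param counts Per-patient counts ([count_table()] output); computed via
#'   [run_classify()] when omitted.
#' @return Invisibly, a list with the two \code{mc_trend_test} results.
#' @export
run_dynamics <- function(config, counts = NULL) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(counts)) counts <- run_classify(config)$counts
  if (nrow(counts) < 2L) {
    log_msg(config, "info",
            "fewer than 2 patients; trend tests skipped")
    return(invisible(NULL))
  }
  log_msg(config, "info", "Monte Carlo trend tests (",
          config$iterations, " iterations)")
  diff_test <- mc_difference_test(counts$ts_primary, counts$ts_relapse,
                                  iterations = config$iterations,
                                  seed = config$seed,
                                  sidedness = config$sidedness,
                                  range_mode = config$range_mode)
  slope_test <- if ("gl_normal" %in% names(counts))
    mc_slope_test(counts$gl_normal, counts$gl_primary, counts$gl_relapse,
                  iterations = config$iterations, seed = config$seed + 1L,
                  sidedness = config$sidedness,
                  range_mode = config$range_mode)
  report <- list(difference = mc_report(diff_test),
                 slope = if (!is.null(slope_test)) mc_report(slope_test),
                 config = config_echo(config))
  write_report(report, file.path(config$output_dir, "dynamics.json"))
  invisible(list(difference = diff_test, slope = slope_test))
}

#' Reconstruct bootstrapped phylogenies for multi-relapse patients
#'
#' For every patient with at least two relapse samples: dynamics-filters the
#' tumor samples, builds the variant-site matrix, reconstructs the
#' Neighbor-Joining tree under the configured distance model and writes the
#' Newick tree, the distance matrix and run metadata.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-loaded cohort.
#' @return Invisibly, a named list of [bootstrap_support()] results (empty
#'   when no patient has enough samples).
#' @export
run_phylo <- function(config, cohort = NULL) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- read_mt_reference(config$reference)
  if (is.null(cohort)) cohort <- read_cohort(config$manifest, ref)
  eligible <- Filter(function(tr) length(tr$relapses) >= 2L, cohort)
  out <- list()
  for (tr in eligible) {
    log_msg(config, "info", "phylogeny for patient ", tr$patient_id)
    tumors <- c(list(P = tr$primary), tr$relapses)
    tumors <- lapply(tumors, apply_filters, cfg = config$filter,
                     purpose = "dynamics")
    vm <- build_variant_matrix(tumors, threshold = config$phylo_threshold)
    bt <- bootstrap_support(vm, replicates = config$bootstrap_replicates,
                            model = config$distance_model,
                            shape = config$gamma_shape,
                            seed = config$seed)
    stem <- file.path(config$output_dir, paste0("phylo_", tr$patient_id))
    write_newick(bt, paste0(stem, ".nwk"))
    D <- variant_distances(vm, config$distance_model, config$gamma_shape)
    utils::write.table(cbind(sample = rownames(D), as.data.frame(D)),
                       paste0(stem, "_distances.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_report(list(patient = tr$patient_id, n_sites = nrow(vm$sites),
                      threshold = config$phylo_threshold,
                      distance_model = config$distance_model,
                      gamma_shape = config$gamma_shape,
                      replicates_used = bt$replicates_used,
                      skipped = bt$skipped,
                      support = as.list(stats::setNames(
                        bt$support, paste0("node", seq_along(bt$support)))),
                      config = config_echo(config)),
                 paste0(stem, ".json"))
    out[[tr$patient_id]] <- bt
  }
  if (!length(eligible))
    log_msg(config, "info", "no patient with >= 2 relapses; phylogeny skipped")
  invisible(out)
}

#' Compute and write primary and relapse mutation spectra
#'
#' Tumor-specific SNVs are pooled across patients into a primary-tumor
#' group (present in P) and a relapse group (present in any relapse);
#' variants present in both contribute to both groups.
#'
#' @param config A [run_config()].
#' @param classified Optional pre-computed classification table.
#' @return Invisibly, a list with the two profiles and their comparison.
#' @export
run_spectrum <- function(config, classified = NULL) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- read_mt_reference(config$reference)
  if (is.null(classified)) classified <- run_classify(config)$classified
  ts <- classified[classified$category == "tumor_specific", , drop = FALSE]
  grp <- function(rows, label) mutation_spectrum(rows, ref, label)
  primary <- grp(ts[in_occurrence(ts$occurrence, "P"), ], "primary")
  relapse <- grp(ts[any_relapse(ts$occurrence), ], "relapse")
  cmp <- compare_spectra(primary, relapse)
  tab <- data.frame(category = primary$categories,
                    raw_primary = primary$raw,
                    normalized_primary = primary$normalized,
                    raw_relapse = relapse$raw,
                    normalized_relapse = relapse$normalized)
  utils::write.table(tab, file.path(config$output_dir, "spectrum.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_report(list(cosine_similarity = cmp$cosine_similarity,
                    classes = as.data.frame(cmp$classes),
                    n_primary = primary$total, n_relapse = relapse$total,
                    config = config_echo(config)),
               file.path(config$output_dir, "spectrum.json"))
  invisible(list(primary = primary, relapse = relapse, comparison = cmp))
}

#' Simulate a cohort and write it (plus its reference) to disk
#'
#' @param output_dir Output directory.
#' @param spec A [cohort_spec()].
#' @param multirelapse If TRUE, use [simulate_multirelapse()].
#' @param reference_length Length of the simulated reference genome.
#' @param seed Seed for reference and cohort generation (overrides
#'   \code{spec$seed}).
#' @return Invisibly, a list with the cohort, the reference and the paths.
#' @export
run_simulate <- function(output_dir, spec = cohort_spec(),
                         multirelapse = FALSE, reference_length = 16569L,
                         seed = 1L) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(reference_length, seed = seed)
  spec$seed <- seed + 1L
  cohort <- if (multirelapse) simulate_multirelapse(spec, ref)
            else simulate_cohort(spec, ref)
  manifest <- write_cohort(cohort, output_dir)
  fasta <- file.path(output_dir, "reference.fasta")
  writeLines(c(paste0(">", ref$name),
               substring(ref$sequence,
                         seq(1, ref$length, 70),
                         pmin(seq(1, ref$length, 70) + 69, ref$length))),
             fasta)
  invisible(list(cohort = cohort, reference = ref,
                 manifest = manifest, reference_path = fasta))
}

#' Run the whole pipeline end-to-end
#'
#' Chains classification, trend tests, per-patient phylogenies (patients
#' with at least two relapses) and the mutation-spectrum comparison, writing
#' every module's artifacts plus a run manifest into the output directory.
#' Reports carry the seed and a configuration fingerprint but no
#' timestamps, so identical configurations and seeds produce byte-identical
#' artifacts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every module's results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cls <- run_classify(config)
  dyn <- run_dynamics(config, cls$counts)
  phy <- run_phylo(config, cls$cohort)
  spc <- run_spectrum(config, cls$classified)
  write_report(list(package_version =
                      as.character(utils::packageVersion("mtrelapse")),
                    seed = config$seed,
                    n_patients = length(cls$cohort),
                    artifacts = c("classified_variants.tsv", "counts.tsv",
                                  "classification_summary.json",
                                  "dynamics.json", "spectrum.tsv",
                                  "spectrum.json",
                                  if (length(phy)) paste0(
                                    "phylo_", names(phy), ".nwk")),
                    config = config_echo(config)),
               file.path(config$output_dir, "run_manifest.json"))
  log_msg(config, "info", "run complete: ", config$output_dir)
  invisible(list(classify = cls, dynamics = dyn, phylo = phy,
                 spectrum = spc))
}
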