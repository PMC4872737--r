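#' Default replication-type substitution weights for the 96 bins
#'
#' Transition-dominated weights (C>T and T>C enriched), the pattern expected
#' from replication-associated damage of the mitochondrial genome rather
#' than from reactive-oxygen damage (which would enrich C>A/G>T). Weights
#' are uniform across flanking contexts within each class and sum to 1.
#'
#' @param class_weights Named length-6 vector of per-class weights
#'   (normalized internally).
#' @return Named 96-bin numeric vector summing to 1.
#' @export
replication_spectrum_weights <- function(class_weights = c(
    "C>A" = 0.06, "C>G" = 0.04, "C>T" = 0.40,
    "T>A" = 0.04, "T>C" = 0.40, "T>G" = 0.06)) {
  stopifnot(identical(sort(names(class_weights)), sort(SUB_CLASSES)))
  class_weights <- class_weights / sum(class_weights)
  cats <- spectrum_categories()
  cl <- substr(cats, 3, 5)
  stats::setNames(as.numeric(class_weights[cl] / 16), cats)
}

#' Simulate a circular mitochondrial-like reference genome
#'
#' A synthetic stand-in for a human mt genome: 16,569 bp by default, with a
#' base composition close to the human mtDNA heavy strand. This is not the
#' rCRS sequence; it is generated, and labelled as synthetic.
#'
#' @param length Genome length in bp (default 16569).
#' @param seed Optional integer seed.
#' @param base_probs Sampling probabilities for A, C, G, T.
#' @return An [mt_reference] named \code{"synthetic_mt"}.
#' @export
simulate_reference <- function(length = 16569L, seed = NULL,
                               base_probs = c(A = 0.31, C = 0.31,
                                              G = 0.13, T = 0.25)) {
  if (!is.null(seed)) set.seed(seed)
  seqc <- sample(BASES, length, replace = TRUE,
                 prob = base_probs[BASES] / sum(base_probs))
  mt_reference(paste(seqc, collapse = ""), name = "synthetic_mt")
}

#' Specification of a synthetic normal/primary/relapse cohort
#'
#' Defaults mirror the scale of a published 16-patient neuroblastoma
#' relapse cohort: roughly 112 germline variants per patient subject to
#' stage-wise drift/loss, a handful of tumor-specific variants gained
#' preferentially at relapse, germline heteroplasmy fractions high and
#' tumor-specific fractions low, read depth around a mean coverage of 212,
#' and a replication-type (transition-enriched) substitution spectrum.
#'
#' @param n_patients Number of patients (default 16).
#' @param relapses_per_patient Relapse samples per patient (default 1).
#' @param germline_rate Expected germline variants per patient (Poisson
#'   mean, default 112).
#' @param germline_loss Probability that a germline variant is lost at each
#'   stage transition (normal to primary, primary to first relapse, and on
#'   along successive relapses; default 0.12).
#' @param ts_rate_primary Expected tumor-specific variants gained in the
#'   primary tumor (default 3).
#' @param ts_rate_relapse Expected tumor-specific variants gained per
#'   relapse sample (default 6).
#' @param ts_persist Probability that a tumor-specific variant persists
#'   across each later stage transition (default 0.8).
#' @param af_germline,af_tumor Uniform ranges for baseline heteroplasmy
#'   fractions (germline high, tumor-specific low).
#' @param af_jitter Per-sample multiplicative jitter range around the
#'   baseline fraction.
#' @param depth_mean,depth_sd Normal parameters for per-call read depth.
#' @param spectrum_weights 96-bin sampling weights
#'   (default [replication_spectrum_weights()]).
#' @param seed Optional integer seed recorded in the spec.
#' @return A \code{cohort_spec} object.
#' @export
cohort_spec <- function(n_patients = 16L, relapses_per_patient = 1L,
                        germline_rate = 112, germline_loss = 0.12,
                        ts_rate_primary = 3, ts_rate_relapse = 6,
                        ts_persist = 0.8,
                        af_germline = c(0.30, 1.00),
                        af_tumor = c(0.05, 0.35),
                        af_jitter = c(0.9, 1.1),
                        depth_mean = 212, depth_sd = 40,
                        spectrum_weights = replication_spectrum_weights(),
                        seed = NULL) {
  stopifnot(n_patients >= 1, relapses_per_patient >= 1,
            germline_rate >= 0, ts_rate_primary >= 0, ts_rate_relapse >= 0,
            germline_loss >= 0, germline_loss <= 1,
            ts_persist >= 0, ts_persist <= 1,
            length(spectrum_weights) == 96,
            abs(sum(spectrum_weights) - 1) < 1e-8)
  structure(as.list(environment()), class = "cohort_spec")
}

# pyrimidine-frame context of every position, and an index context -> positions
context_index <- function(ref) {
  pos <- seq_len(ref$length)
  ctx <- context_at(ref, pos)
  centre <- substr(ctx, 2, 2)
  pyr_ctx <- ifelse(centre %in% c("C", "T"), ctx, revcomp(ctx))
  ok <- !grepl("N", ctx, fixed = TRUE)
  split(pos[ok], pyr_ctx[ok])
}

# draw k distinct variant positions + alleles following the 96-bin weights
draw_variants <- function(k, ref, weights, ctx_idx, used) {
  cats <- names(weights)
  ctxs <- category_context(cats)
  avail <- ctxs %in% names(ctx_idx)
  w <- weights * avail
  if (sum(w) == 0) stop("no reference positions available for any weighted context")
  out <- data.frame(pos = integer(0), ref = character(0), alt = character(0))
  guard <- 0L
  while (nrow(out) < k) {
    guard <- guard + 1L
    if (guard > 50L)
      stop("variant rates too high for this reference: cannot place ",
           k, " distinct variants")
    need <- k - nrow(out)
    bins <- sample(cats, need, replace = TRUE, prob = w)
    pos <- vapply(category_context(bins), function(cc) {
      p <- ctx_idx[[cc]]
      p[sample.int(length(p), 1L)]
    }, integer(1), USE.NAMES = FALSE)
    keep <- !(pos %in% used) & !duplicated(pos)
    if (!any(keep)) next
    bins <- bins[keep]; pos <- pos[keep]
    rb <- substring(ref$sequence, pos, pos)
    pyr_alt <- substr(bins, 5, 5)
    alt <- ifelse(rb %in% c("C", "T"), pyr_alt, complement(pyr_alt))
    out <- rbind(out, data.frame(pos = pos, ref = rb, alt = alt,
                                 stringsAsFactors = FALSE))
    used <- c(used, pos)
  }
  out
}

sample_depth <- function(n, spec) {
  pmax(1, round(stats::rnorm(n, spec$depth_mean, spec$depth_sd)))
}

jittered_af <- function(base_af, spec) {
  pmin(1, base_af * stats::runif(length(base_af), spec$af_jitter[1],
                                 spec$af_jitter[2]))
}

make_sample_table <- function(sample_id, variants, base_af, present, spec) {
  idx <- which(present)
  data.frame(sample = rep_len(sample_id, length(idx)),
             pos = variants$pos[idx], ref = variants$ref[idx],
             alt = variants$alt[idx],
             af = jittered_af(base_af[idx], spec),
             dp = sample_depth(length(idx), spec),
             stringsAsFactors = FALSE)
}

simulate_patient <- function(patient_id, spec, ref, ctx_idx) {
  nrel <- spec$relapses_per_patient
  stages <- c("N", "P", paste0("R", seq_len(nrel)))
  n_stage <- length(stages)

  n_gl <- stats::rpois(1, spec$germline_rate)
  n_tp <- stats::rpois(1, spec$ts_rate_primary)
  n_tr <- stats::rpois(nrel, spec$ts_rate_relapse)
  total <- n_gl + n_tp + sum(n_tr)
  if (total > 0.5 * ref$length)
    stop("variant rates imply more variants (", total,
         ") than half the reference length")

  vars <- draw_variants(total, ref, spec$spectrum_weights, ctx_idx,
                        used = integer(0))
  origin <- rep(c("germline", "P", paste0("R", seq_len(nrel))),
                times = c(n_gl, n_tp, n_tr))
  category <- ifelse(origin == "germline", "germline", "tumor_specific")
  base_af <- ifelse(category == "germline",
                    stats::runif(total, spec$af_germline[1], spec$af_germline[2]),
                    stats::runif(total, spec$af_tumor[1], spec$af_tumor[2]))

  # presence matrix over stages: germline Markov loss from N on; tumor-specific
  # gained at its origin stage and persisting with ts_persist thereafter
  pres <- matrix(FALSE, total, n_stage, dimnames = list(NULL, stages))
  if (total) {
    pres[category == "germline", 1] <- TRUE
    start <- match(origin, stages)        # NA for germline
    for (s in seq_len(n_stage)[-1]) {
      carry <- ifelse(category == "germline",
                      pres[, s - 1] &
                        stats::runif(total) >= spec$germline_loss,
                      pres[, s - 1] & stats::runif(total) <= spec$ts_persist)
      gained <- !is.na(start) & start == s
      pres[, s] <- carry | gained
    }
  }

  tabs <- lapply(seq_len(n_stage), function(s)
    make_sample_table(paste0(patient_id, "_", stages[s]), vars, base_af,
                      pres[, s], spec))
  names(tabs) <- stages
  truth <- data.frame(patient_id = rep_len(patient_id, total),
                      pos = vars$pos,
                      ref = vars$ref, alt = vars$alt, category = category,
                      origin = origin,
                      stages = vapply(seq_len(total), function(i)
                        paste(stages[pres[i, ]], collapse = ","),
                        character(1)),
                      stringsAsFactors = FALSE)
  list(triplet = patient_triplet(patient_id, tabs$N, tabs$P,
                                 tabs[paste0("R", seq_len(nrel))]),
       truth = truth)
}

#' Simulate a cohort of normal/primary/relapse variant tables
#'
#' Variant counts per category are Poisson; positions are drawn to follow
#' the spec's 96-bin substitution weights (a bin is drawn first, then a
#' position uniformly among reference positions carrying that pyrimidine-
#' frame trinucleotide context); germline variants are carried through the
#' stage chain with independent per-transition loss; tumor-specific variants
#' are gained at the primary tumor or at a relapse and persist onward with
#' the spec's persistence probability. Ground truth is recorded for every
#' generated variant.
#'
#' @param spec A [cohort_spec()].
#' @param ref An [mt_reference] (e.g. [simulate_reference()]).
#' @return \code{mt_cohort} object: \code{patients} (list of
#'   [patient_triplet()]), \code{truth} (per-variant ground-truth
#'   data.frame), \code{manifest} and the \code{spec}.
#' @export
simulate_cohort <- function(spec, ref) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(ref, "mt_reference"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ctx_idx <- context_index(ref)
  ids <- sprintf("PT%02d", seq_len(spec$n_patients))
  sims <- lapply(ids, simulate_patient, spec = spec, ref = ref,
                 ctx_idx = ctx_idx)
  patients <- lapply(sims, `[[`, "triplet")
  names(patients) <- ids
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  manifest <- do.call(rbind, lapply(patients, function(tr) {
    roles <- c("normal", "primary",
               paste0("relapse_", seq_along(tr$relapses)))
    samples <- c(tr$normal$sample[1], tr$primary$sample[1],
                 vapply(tr$relapses, function(t) t$sample[1], character(1)))
    # empty tables still need a sample id
    stage <- c("N", "P", paste0("R", seq_along(tr$relapses)))
    samples[is.na(samples)] <- paste0(tr$patient_id, "_",
                                      stage[is.na(samples)])
    data.frame(patient_id = tr$patient_id, sample_id = samples,
               role = roles, stringsAsFactors = FALSE)
  }))
  rownames(manifest) <- NULL
  structure(list(patients = patients, truth = truth, manifest = manifest,
                 spec = spec, reference_name = ref$name),
            class = "mt_cohort")
}

#' @export
print.mt_cohort <- function(x, ...) {
  cat("mt_cohort:", length(x$patients), "patients,",
      nrow(x$truth), "true variants\n")
  invisible(x)
}

#' Simulate a multi-relapse patient with two planted relapse lineages
#'
#' Emulates a patient with one primary tumor and several relapses whose
#' tumor-specific variants split the relapses into two lineages carrying
#' mutually exclusive private variants, on top of the usual germline
#' background and per-sample private noise variants.
#'
#' @param spec A [cohort_spec()] with \code{relapses_per_patient >= 3}; its
#'   germline, allele-fraction and depth settings are reused.
#' @param ref An [mt_reference].
#' @param lineage_a Indices of the relapses forming the first lineage; the
#'   remaining relapses form the second. Defaults to \code{c(1, 2, 4, 5)}
#'   with five relapses (a locoregional lineage plus a distant singleton),
#'   otherwise to all relapses but the last.
#' @param lineage_rate Expected lineage-private shared variants per lineage
#'   (default 25).
#' @param private_rate Expected private variants per individual tumor
#'   sample (default 4).
#' @return \code{mt_cohort} with a single patient plus \code{lineages} (the
#'   sample names of each lineage) and \code{planted_bipartition} (the
#'   first lineage's relapse sample names, the split a phylogeny should
#'   recover).
#' @export
simulate_multirelapse <- function(spec, ref, lineage_a = NULL,
                                  lineage_rate = 25, private_rate = 4) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(ref, "mt_reference"))
  nrel <- spec$relapses_per_patient
  if (nrel < 3L) stop("multi-relapse simulation needs >= 3 relapses")
  if (is.null(lineage_a))
    lineage_a <- if (nrel == 5L) c(1, 2, 4, 5) else seq_len(nrel - 1L)
  lineage_a <- sort(unique(as.integer(lineage_a)))
  if (any(lineage_a < 1 | lineage_a > nrel))
    stop("lineage_a indices out of range 1..", nrel)
  lineage_b <- setdiff(seq_len(nrel), lineage_a)
  if (!length(lineage_b)) stop("second lineage is empty")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ctx_idx <- context_index(ref)
  patient_id <- "PT01"
  stages <- c("N", "P", paste0("R", seq_len(nrel)))
  tumor_stages <- stages[-1]

  n_gl <- stats::rpois(1, spec$germline_rate)
  n_la <- stats::rpois(1, lineage_rate)
  n_lb <- stats::rpois(1, lineage_rate)
  n_pri <- stats::rpois(length(tumor_stages), private_rate)
  total <- n_gl + n_la + n_lb + sum(n_pri)
  vars <- draw_variants(total, ref, spec$spectrum_weights, ctx_idx,
                        used = integer(0))
  origin <- rep(c("germline", "lineage_a", "lineage_b", tumor_stages),
                times = c(n_gl, n_la, n_lb, n_pri))
  category <- ifelse(origin == "germline", "germline", "tumor_specific")
  base_af <- ifelse(category == "germline",
                    stats::runif(total, spec$af_germline[1], spec$af_germline[2]),
                    stats::runif(total, spec$af_tumor[1], spec$af_tumor[2]))

  pres <- matrix(FALSE, total, length(stages),
                 dimnames = list(NULL, stages))
  pres[origin == "germline", ] <- TRUE  # stable background for the tree
  ra <- paste0("R", lineage_a); rb <- paste0("R", lineage_b)
  pres[origin == "lineage_a", match(ra, stages)] <- TRUE
  pres[origin == "lineage_b", match(rb, stages)] <- TRUE
  for (s in tumor_stages)
    pres[origin == s, match(s, stages)] <- TRUE

  tabs <- lapply(seq_along(stages), function(s)
    make_sample_table(paste0(patient_id, "_", stages[s]), vars, base_af,
                      pres[, s], spec))
  names(tabs) <- stages
  truth <- data.frame(patient_id = rep_len(patient_id, total),
                      pos = vars$pos,
                      ref = vars$ref, alt = vars$alt, category = category,
                      origin = origin,
                      stages = vapply(seq_len(total), function(i)
                        paste(stages[pres[i, ]], collapse = ","),
                        character(1)),
                      stringsAsFactors = FALSE)
  triplet <- patient_triplet(patient_id, tabs$N, tabs$P,
                             tabs[paste0("R", seq_len(nrel))])
  manifest <- data.frame(
    patient_id = patient_id,
    sample_id = paste0(patient_id, "_", stages),
    role = c("normal", "primary", paste0("relapse_", seq_len(nrel))),
    stringsAsFactors = FALSE)
  structure(list(patients = stats::setNames(list(triplet), patient_id),
                 truth = truth, manifest = manifest, spec = spec,
                 reference_name = ref$name,
                 lineages = list(a = ra, b = rb),
                 planted_bipartition = ra),
            class = "mt_cohort")
}

#' Write a simulated cohort to disk in the package's TSV dialect
#'
#' Emits one variant TSV per sample, a \code{manifest.tsv} mapping samples
#' to patients and roles, and a \code{truth.tsv} with the generated ground
#' truth — exactly the inputs the reading side of the pipeline consumes.
#'
#' @param cohort An [simulate_cohort()] / [simulate_multirelapse()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mt_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_one <- function(tab, sample_id) {
    path <- file.path(dir, paste0(sample_id, ".tsv"))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  manifest <- cohort$manifest
  manifest$file <- NA_character_
  for (i in seq_len(nrow(manifest))) {
    tr <- cohort$patients[[manifest$patient_id[i]]]
    tab <- switch(sub("_.*", "", manifest$role[i]),
                  normal = tr$normal, primary = tr$primary,
                  relapse = tr$relapses[[as.integer(
                    sub("relapse_", "", manifest$role[i]))]])
    tab$sample <- manifest$sample_id[i]
    manifest$file[i] <- basename(write_one(tab, manifest$sample_id[i]))
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

#' Read a cohort from a manifest and per-sample variant tables
#'
#' @param manifest_path TSV with columns \code{patient_id, sample_id, role}
#'   (\code{normal} / \code{primary} / \code{relapse_k}) and \code{file}
#'   (paths relative to the manifest's directory unless absolute).
#' @param reference Optional [mt_reference] for position validation.
#' @return List of [patient_triplet()] objects, named by patient.
#' @export
read_cohort <- function(manifest_path, reference = NULL) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("patient_id", "sample_id", "role", "file"), names(man))
  if (length(miss))
    stop("manifest missing columns: ", paste(miss, collapse = ", "))
  base <- dirname(manifest_path)
  man$path <- ifelse(grepl("^(/|[A-Za-z]:)", man$file), man$file,
                     file.path(base, man$file))
  out <- lapply(split(man, man$patient_id), function(m) {
    get_tab <- function(rows) {
      tabs <- lapply(seq_len(nrow(rows)), function(i)
        read_variant_table(rows$path[i], sample_id = rows$sample_id[i],
                           reference = reference))
      tabs
    }
    nr <- m[m$role == "normal", , drop = FALSE]
    pr <- m[m$role == "primary", , drop = FALSE]
    rl <- m[startsWith(m$role, "relapse"), , drop = FALSE]
    if (nrow(nr) != 1L || nrow(pr) != 1L)
      stop("patient ", m$patient_id[1],
           ": exactly one normal and one primary sample required")
    if (!nrow(rl))
      stop("patient ", m$patient_id[1], ": no relapse sample in manifest")
    ord <- order(suppressWarnings(as.integer(sub("relapse_?", "", rl$role))),
                 rl$sample_id)
    rl <- rl[ord, , drop = FALSE]
    rel <- get_tab(rl)
    names(rel) <- paste0("R", seq_along(rel))
    patient_triplet(m$patient_id[1], get_tab(nr)[[1]], get_tab(pr)[[1]], rel)
  })
  out[unique(man$patient_id)]
}
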