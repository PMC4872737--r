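#' Filtering thresholds for mitochondrial variant calls
#'
#' Two heteroplasmy-abundance thresholds are carried: a stricter one used to
#' classify variants as germline or tumor-specific, and a permissive one used
#' when following changes of variants over disease stages (trend statistics,
#' phylogeny site selection).
#'
#' @param min_depth Minimum read depth; calls must exceed it strictly
#'   (default 50, i.e. depth >= 51 passes).
#' @param abundance_classify Minimum alt-allele fraction for
#'   germline/tumor-specific classification (default 0.02).
#' @param abundance_dynamics Minimum alt-allele fraction when tracking
#'   variant dynamics (default 0.01).
#' @return A \code{filter_config} object.
#' @export
filter_config <- function(min_depth = 50L, abundance_classify = 0.02,
                          abundance_dynamics = 0.01) {
  if (min_depth < 0) stop("min_depth must be >= 0")
  if (!(abundance_dynamics > 0 && abundance_dynamics <= abundance_classify &&
        abundance_classify < 1))
    stop("need 0 < abundance_dynamics <= abundance_classify < 1")
  structure(list(min_depth = as.integer(min_depth),
                 abundance_classify = abundance_classify,
                 abundance_dynamics = abundance_dynamics),
            class = "filter_config")
}

variant_key <- function(position, ref, alt) {
  paste(position, ref, alt, sep = ":")
}

validate_variant_table <- function(tab, sample_id, where = "variant table") {
  need <- c("sample", "pos", "ref", "alt", "af", "dp")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(where, ": missing columns ", paste(miss, collapse = ", "))
  tab$pos <- as.integer(tab$pos)
  tab$af <- as.numeric(tab$af)
  tab$dp <- as.numeric(tab$dp)
  tab$ref <- toupper(as.character(tab$ref))
  tab$alt <- toupper(as.character(tab$alt))
  bad <- which(is.na(tab$pos) | tab$pos < 1L)
  if (length(bad))
    stop(where, ": invalid position at row(s) ", paste(bad, collapse = ", "))
  bad <- which(is.na(tab$af) | tab$af < 0 | tab$af > 1)
  if (length(bad))
    stop(where, ": allele fraction outside [0,1] at row(s) ",
         paste(bad, collapse = ", "))
  bad <- which(is.na(tab$dp) | tab$dp < 0)
  if (length(bad))
    stop(where, ": negative or missing depth at row(s) ",
         paste(bad, collapse = ", "))
  bad <- which(tab$ref == tab$alt)
  if (length(bad))
    stop(where, ": ref allele equals alt allele at row(s) ",
         paste(bad, collapse = ", "))
  key <- variant_key(tab$pos, tab$ref, tab$alt)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))
    stop(where, ": duplicate variant key within sample at row(s) ",
         paste(d, collapse = ", "), " (", paste(unique(key[d]), collapse = ", "), ")")
  }
  if (!is.null(sample_id)) tab$sample <- sample_id
  rownames(tab) <- NULL
  tab[c("sample", "pos", "ref", "alt", "af", "dp")]
}

read_variant_tsv <- function(path, sample_id) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty variant table: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "")
  names(tab) <- tolower(names(tab))
  validate_variant_table(tab, sample_id, where = path)
}

read_variant_vcf <- function(path, sample_id) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) {
    tab <- data.frame(sample = character(), pos = integer(), ref = character(),
                      alt = character(), af = numeric(), dp = numeric())
    return(validate_variant_table(tab, sample_id, where = path))
  }
  af <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "AF")))
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "DP")))
  # fall back to the first sample's FORMAT fields
  if ((anyNA(af) || anyNA(dp)) && ncol(vcf@gt) >= 2L) {
    gaf <- suppressWarnings(as.numeric(vcfR::extract.gt(vcf, "AF")[, 1]))
    gdp <- suppressWarnings(as.numeric(vcfR::extract.gt(vcf, "DP")[, 1]))
    af <- ifelse(is.na(af), gaf, af)
    dp <- ifelse(is.na(dp), gdp, dp)
  }
  if (anyNA(af) || anyNA(dp))
    stop(path, ": VCF records lack AF/DP in INFO or FORMAT at record(s) ",
         paste(which(is.na(af) | is.na(dp)), collapse = ", "))
  tab <- data.frame(sample = if (is.null(sample_id)) "sample1" else sample_id,
                    pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                    alt = fix[, "ALT"], af = af, dp = dp,
                    stringsAsFactors = FALSE)
  validate_variant_table(tab, sample_id, where = path)
}

#' Read a per-sample mitochondrial variant-call table
#'
#' Accepts the package's TSV dialect (comma- or tab-delimited, mandatory
#' header with columns \code{sample, pos, ref, alt, af, dp}) or a minimal
#' single-sample VCF whose AF and DP live in INFO or FORMAT fields. This is
#' the shape of tabular output produced by mitochondrial variant screens of
#' exome data (e.g. MitoSeek); variant calling itself is out of scope.
#'
#' @param path Input file.
#' @param sample_id Optional sample identifier overriding the file's own.
#' @param format One of \code{"auto"} (by extension), \code{"tsv"},
#'   \code{"vcf"}.
#' @param reference Optional [mt_reference]; positions are checked against
#'   its length when supplied.
#' @return data.frame with columns \code{sample, pos, ref, alt, af, dp}, one
#'   row per variant call, unique by (pos, ref, alt).
#' @export
read_variant_table <- function(path, sample_id = NULL,
                               format = c("auto", "tsv", "vcf"),
                               reference = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("variant table not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  tab <- if (format == "vcf") read_variant_vcf(path, sample_id)
         else read_variant_tsv(path, sample_id)
  if (!is.null(reference)) {
    bad <- which(tab$pos > reference$length)
    if (length(bad))
      stop(path, ": position beyond reference length ", reference$length,
           " at row(s) ", paste(bad, collapse = ", "))
  }
  tab
}

#' Apply coverage and abundance filters to a variant table
#'
#' Depth must strictly exceed \code{min_depth}; the alt-allele fraction must
#' be at least the threshold selected by \code{purpose}
#' (\code{abundance_classify} or \code{abundance_dynamics}).
#'
#' @param tab Variant table as returned by [read_variant_table()].
#' @param cfg A [filter_config()].
#' @param purpose \code{"classify"} or \code{"dynamics"}.
#' @return Filtered table; attribute \code{"removed"} records how many calls
#'   failed the depth and abundance rules.
#' @export
apply_filters <- function(tab, cfg = filter_config(),
                          purpose = c("classify", "dynamics")) {
  purpose <- match.arg(purpose)
  thr <- if (purpose == "classify") cfg$abundance_classify else cfg$abundance_dynamics
  keep_dp <- tab$dp > cfg$min_depth
  keep_af <- tab$af >= thr
  out <- tab[keep_dp & keep_af, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(low_depth = sum(!keep_dp),
                            low_abundance = sum(keep_dp & !keep_af))
  out
}

#' Bundle a patient's matched samples
#'
#' @param patient_id Patient identifier.
#' @param normal,primary Variant tables for the normal-tissue and primary
#'   (diagnostic) tumor samples.
#' @param relapses List of variant tables for relapse tumor samples, ordered
#'   by clinical time (named R1, R2, ... if unnamed).
#' @return A \code{patient_triplet} object.
#' @export
patient_triplet <- function(patient_id, normal, primary, relapses) {
  if (is.data.frame(relapses)) relapses <- list(relapses)
  if (!length(relapses)) stop("patient ", patient_id, ": at least one relapse sample required")
  if (is.null(names(relapses)) || any(!nzchar(names(relapses))))
    names(relapses) <- paste0("R", seq_along(relapses))
  structure(list(patient_id = patient_id, normal = normal,
                 primary = primary, relapses = relapses),
            class = "patient_triplet")
}

#' @export
print.patient_triplet <- function(x, ...) {
  cat("patient_triplet '", x$patient_id, "': N(", nrow(x$normal),
      " calls), P(", nrow(x$primary), " calls), ",
      length(x$relapses), " relapse(s)\n", sep = "")
  invisible(x)
}

lookup_call <- function(tab, keys) {
  idx <- match(keys, variant_key(tab$pos, tab$ref, tab$alt))
  data.frame(af = ifelse(is.na(idx), NA_real_, tab$af[idx]),
             dp = ifelse(is.na(idx), NA_real_, tab$dp[idx]))
}

#' Classify a patient's variants as germline or tumor-specific
#'
#' Every variant key observed in any of the patient's samples is assigned to
#' exactly one of three classes:
#' \describe{
#'   \item{germline}{present in normal tissue at or above the classification
#'     abundance threshold, with passing depth;}
#'   \item{tumor_specific}{below threshold or absent in normal (with passing
#'     depth, or assumed covered, see below) and present in at least one
#'     tumor sample at or above threshold with passing depth;}
#'   \item{uninformative}{the normal sample lacks passing depth at the
#'     position, so germline status cannot be assessed.}
#' }
#' The occurrence pattern lists the tumor samples (\code{P}, \code{R1}, ...)
#' where the variant passes the classification filters.
#'
#' A variant key absent from the normal table is taken as absent with
#' adequate coverage unless \code{normal_depth} (a named numeric vector,
#' names = positions) reports a sub-threshold depth there. Call tables may
#' also carry explicit \code{af = 0} rows whose depth is then used directly.
#'
#' @param triplet A [patient_triplet()]. Tables may be raw; filters are
#'   applied internally (idempotent on pre-filtered input).
#' @param cfg A [filter_config()].
#' @param normal_depth Optional per-position depth lookup for the normal
#'   sample.
#' @return data.frame with one row per variant key: \code{patient_id, pos,
#'   ref, alt, category, occurrence, known_status} plus per-sample
#'   \code{af_*} and \code{dp_*} columns (\code{N}, \code{P}, \code{R1},
#'   ...). \code{known_status} is \code{"unannotated"} until
#'   [annotate_known()] is applied.
#' @export
classify_patient <- function(triplet, cfg = filter_config(),
                             normal_depth = NULL) {
  stopifnot(inherits(triplet, "patient_triplet"))
  tumors <- c(list(P = triplet$primary), triplet$relapses)
  ftum <- lapply(tumors, apply_filters, cfg = cfg, purpose = "classify")
  fnorm <- apply_filters(triplet$normal, cfg, "classify")

  keys <- unique(c(variant_key(fnorm$pos, fnorm$ref, fnorm$alt),
                   unlist(lapply(ftum, function(t)
                     variant_key(t$pos, t$ref, t$alt)))))
  if (!length(keys)) {
    out <- data.frame(patient_id = character(), pos = integer(),
                      ref = character(), alt = character(),
                      category = character(), occurrence = character(),
                      known_status = character())
    out$af_N <- numeric(); out$dp_N <- numeric()
    return(out)
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  pos <- as.integer(vapply(parts, `[[`, character(1), 1))
  ref <- vapply(parts, `[[`, character(1), 2)
  alt <- vapply(parts, `[[`, character(1), 3)

  ncall <- lookup_call(triplet$normal, keys)
  # occurrence among tumor samples, post-filter
  occ <- vapply(seq_along(keys), function(i) {
    hit <- names(ftum)[vapply(ftum, function(t)
      keys[i] %in% variant_key(t$pos, t$ref, t$alt), logical(1))]
    paste(hit, collapse = ",")
  }, character(1))

  category <- character(length(keys))
  for (i in seq_along(keys)) {
    af_n <- ncall$af[i]; dp_n <- ncall$dp[i]
    if (!is.na(dp_n) && dp_n <= cfg$min_depth) {
      category[i] <- "uninformative"
    } else if (!is.na(af_n) && dp_n > cfg$min_depth &&
               af_n >= cfg$abundance_classify) {
      category[i] <- "germline"
    } else {
      # absent/below threshold in normal; coverage adequate or assumed
      if (is.na(dp_n) && !is.null(normal_depth)) {
        d <- normal_depth[as.character(pos[i])]
        if (!is.na(d) && d <= cfg$min_depth) {
          category[i] <- "uninformative"
          next
        }
      }
      category[i] <- if (nzchar(occ[i])) "tumor_specific" else "uninformative"
    }
  }

  out <- data.frame(patient_id = triplet$patient_id, pos = pos, ref = ref,
                    alt = alt, category = category, occurrence = occ,
                    known_status = "unannotated", stringsAsFactors = FALSE)
  out$af_N <- ncall$af; out$dp_N <- ncall$dp
  for (s in names(tumors)) {
    cc <- lookup_call(tumors[[s]], keys)
    out[[paste0("af_", s)]] <- cc$af
    out[[paste0("dp_", s)]] <- cc$dp
  }
  out <- out[order(out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify every patient of a cohort
#'
#' @param cohort List of [patient_triplet()] objects.
#' @inheritParams classify_patient
#' @return A single data.frame (rows from all patients; per-sample columns
#'   are filled with NA where a patient lacks that sample).
#' @export
classify_cohort <- function(cohort, cfg = filter_config()) {
  res <- lapply(cohort, classify_patient, cfg = cfg)
  cols <- unique(unlist(lapply(res, names)))
  res <- lapply(res, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[cols]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read a known-variant catalog
#'
#' A local stand-in for MITOMAP/mtDB-style lookups: a delimited table keyed
#' by (pos, ref, alt) with an optional \code{id} column.
#'
#' @param path TSV/CSV file with header columns \code{pos, ref, alt}
#'   (optionally \code{id}).
#' @return data.frame catalog.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  cat_ <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  names(cat_) <- tolower(names(cat_))
  miss <- setdiff(c("pos", "ref", "alt"), names(cat_))
  if (length(miss))
    stop("malformed catalog '", path, "': missing columns ",
         paste(miss, collapse = ", "))
  cat_$pos <- as.integer(cat_$pos)
  if (anyNA(cat_$pos)) stop("malformed catalog '", path, "': non-integer pos")
  cat_$ref <- toupper(cat_$ref); cat_$alt <- toupper(cat_$alt)
  cat_
}

#' Annotate classified variants against a known-variant catalog
#'
#' @param classified Output of [classify_patient()] / [classify_cohort()].
#' @param catalog data.frame from [read_catalog()], or NULL.
#' @return Same table with \code{known_status} set to \code{"known"} /
#'   \code{"novel"} (or left \code{"unannotated"} when no catalog is given).
#' @export
annotate_known <- function(classified, catalog = NULL) {
  if (is.null(catalog)) return(classified)
  ck <- variant_key(catalog$pos, catalog$ref, catalog$alt)
  vk <- variant_key(classified$pos, classified$ref, classified$alt)
  classified$known_status <- ifelse(vk %in% ck, "known", "novel")
  classified
}

in_occurrence <- function(occurrence, sample) {
  vapply(strsplit(occurrence, ",", fixed = TRUE),
         function(z) sample %in% z, logical(1))
}

any_relapse <- function(occurrence) {
  vapply(strsplit(occurrence, ",", fixed = TRUE),
         function(z) any(startsWith(z, "R")), logical(1))
}

#' Per-patient variant counts
#'
#' Collapses a classified cohort into one row per patient with
#' tumor-specific and germline counts in the primary tumor and in relapse
#' (union over relapse samples unless \code{per_relapse = TRUE}).
#' \code{difference} is the relapse-minus-primary count of tumor-specific
#' variants.
#'
#' @param classified Output of [classify_cohort()] (or a single patient's
#'   [classify_patient()]).
#' @param per_relapse If TRUE, emit one tumor-specific/germline count column
#'   pair per relapse sample instead of the union.
#' @return data.frame with columns \code{patient, ts_primary, ts_relapse,
#'   difference, gl_normal, gl_primary, gl_relapse}.
#' @export
count_table <- function(classified, per_relapse = FALSE) {
  pats <- unique(classified$patient_id)
  rows <- lapply(pats, function(p) {
    d <- classified[classified$patient_id == p, , drop = FALSE]
    ts <- d$category == "tumor_specific"
    gl <- d$category == "germline"
    base <- data.frame(patient = p,
                       ts_primary = sum(ts & in_occurrence(d$occurrence, "P")),
                       ts_relapse = sum(ts & any_relapse(d$occurrence)),
                       gl_normal = sum(gl),
                       gl_primary = sum(gl & in_occurrence(d$occurrence, "P")),
                       gl_relapse = sum(gl & any_relapse(d$occurrence)),
                       stringsAsFactors = FALSE)
    if (per_relapse) {
      rl <- unique(unlist(lapply(strsplit(d$occurrence, ","), function(z)
        z[startsWith(z, "R")])))
      for (r in sort(rl)) {
        base[[paste0("ts_", r)]] <- sum(ts & in_occurrence(d$occurrence, r))
        base[[paste0("gl_", r)]] <- sum(gl & in_occurrence(d$occurrence, r))
      }
    }
    base
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- 0L
    d[cols]
  })
  out <- do.call(rbind, rows)
  out$difference <- out$ts_relapse - out$ts_primary
  rownames(out) <- NULL
  out
}

#' Cohort-level summary of variant counts
#'
#' Aggregates a per-patient count table (from [count_table()] or a published
#' fixture): per-tumor means and ranges over all primary and relapse tumor
#' samples, the number of patients with at least one tumor-specific variant,
#' and the paired-difference summary.
#'
#' @param counts data.frame with columns \code{patient, ts_primary,
#'   ts_relapse, gl_primary, gl_relapse} (and optionally
#'   \code{difference}, recomputed regardless).
#' @return Named list of cohort statistics.
#' @export
count_summary <- function(counts) {
  need <- c("patient", "ts_primary", "ts_relapse", "gl_primary", "gl_relapse")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("counts table missing columns: ", paste(miss, collapse = ", "))
  ts <- c(counts$ts_primary, counts$ts_relapse)
  gl <- c(counts$gl_primary, counts$gl_relapse)
  diffs <- counts$ts_relapse - counts$ts_primary
  list(
    n_patients = nrow(counts),
    n_tumors = length(ts),
    patients_with_ts = sum(counts$ts_primary > 0 | counts$ts_relapse > 0),
    pct_patients_with_ts =
      100 * mean(counts$ts_primary > 0 | counts$ts_relapse > 0),
    ts_mean = mean(ts), ts_min = min(ts), ts_max = max(ts),
    gl_mean = mean(gl), gl_min = min(gl), gl_max = max(gl),
    n_positive_difference = sum(diffs > 0),
    mean_difference = mean(diffs)
  )
}

#' Published 16-patient neuroblastoma relapse cohort counts
#'
#' Per-patient counts of tumor-specific and germline mitochondrial variants
#' in primary (P) and relapse (R) tumors from a published cohort of 16
#' neuroblastoma patients with matched normal / primary / relapse exome
#' data, together with the published paired difference (R − P of
#' tumor-specific counts) and the per-patient linear-regression coefficient
#' of germline counts over the normal, primary, relapse stages.
#'
#' @return data.frame with columns \code{patient, ts_primary, ts_relapse,
#'   difference, gl_primary, gl_relapse, coefficient}.
#' @export
nb_cohort_counts <- function() {
  path <- system.file("extdata", "nb_relapse_cohort_counts.tsv",
                      package = "mtrelapse", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
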