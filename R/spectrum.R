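BASES <- c("A", "C", "G", "T")
SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 substitution-in-context categories
#'
#' Pyrimidine-centric (COSMIC-style) ordering: the six substitution classes
#' \code{C>A, C>G, C>T, T>A, T>C, T>G}, each within the 16 combinations of
#' 5' and 3' flanking bases, labelled \code{"X[R>A]Y"}.
#'
#' @return Character vector of 96 category labels.
#' @export
spectrum_categories <- function() {
  unlist(lapply(SUB_CLASSES, function(cl) {
    unlist(lapply(BASES, function(x)
      paste0(x, "[", cl, "]", BASES)))
  }))
}

complement <- function(b) chartr("ACGTN", "TGCAN", b)

#' Assign an SNV to its substitution-in-context category
#'
#' The reference base at the variant position must match the variant's ref
#' allele. If the ref allele is a purine, the substitution and its flanking
#' context are reverse-complemented into the pyrimidine frame.
#'
#' @param ref An [mt_reference].
#' @param pos,ref_allele,alt_allele Vectors describing single-base
#'   substitutions.
#' @return Character vector of category labels (\code{NA} where the
#'   trinucleotide context contains an N).
#' @export
bin_variant <- function(ref, pos, ref_allele, alt_allele) {
  stopifnot(inherits(ref, "mt_reference"))
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  if (any(nchar(ref_allele) != 1L | nchar(alt_allele) != 1L |
          !ref_allele %in% BASES | !alt_allele %in% BASES))
    stop("bin_variant handles single-base substitutions over A,C,G,T only")
  ctx <- context_at(ref, pos)
  centre <- substr(ctx, 2, 2)
  bad <- which(centre != ref_allele)
  if (length(bad))
    stop("ref allele disagrees with the reference genome at position(s) ",
         paste(pos[bad], collapse = ", "), " (reference has ",
         paste(centre[bad], collapse = ", "), ")")
  out <- rep(NA_character_, length(pos))
  hasN <- grepl("N", ctx, fixed = TRUE)
  pyr <- ref_allele %in% c("C", "T")
  i <- which(pyr & !hasN)
  out[i] <- paste0(substr(ctx[i], 1, 1), "[", ref_allele[i], ">",
                   alt_allele[i], "]", substr(ctx[i], 3, 3))
  i <- which(!pyr & !hasN)
  if (length(i)) {
    rc <- revcomp(ctx[i])
    out[i] <- paste0(substr(rc, 1, 1), "[", complement(ref_allele[i]), ">",
                     complement(alt_allele[i]), "]", substr(rc, 3, 3))
  }
  out
}

category_context <- function(categories) {
  paste0(substr(categories, 1, 1), substr(categories, 3, 3),
         substr(categories, 7, 7))
}

#' Reference-normalized 96-context mutation spectrum
#'
#' Counts a group's tumor-specific SNVs in the 96 pyrimidine-framed
#' substitution-in-context categories, divides each bin by the frequency of
#' the corresponding reference trinucleotide context (both strands pooled:
#' the pyrimidine-frame context plus its reverse complement), and rescales
#' the result to percentages summing to 100.
#'
#' @param variants data.frame with columns \code{pos, ref, alt}; non-SNV
#'   rows (indels) are dropped, and SNVs whose context contains an N are
#'   excluded and counted in the result.
#' @param ref An [mt_reference] — the same genome the variants were called
#'   against.
#' @param group Label for the profile (e.g. \code{"primary"}).
#' @return \code{spectrum_profile} object: \code{group}, \code{categories},
#'   \code{raw} (counts), \code{normalized} (percentages), \code{total},
#'   \code{n_excluded} (indels + N contexts), \code{empty} flag.
#' @export
mutation_spectrum <- function(variants, ref, group = "all") {
  stopifnot(inherits(ref, "mt_reference"))
  cats <- spectrum_categories()
  is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% BASES & variants$alt %in% BASES
  snv <- variants[is_snv, , drop = FALSE]
  binned <- if (nrow(snv)) bin_variant(ref, snv$pos, snv$ref, snv$alt)
            else character(0)
  n_ctx_excluded <- sum(is.na(binned))
  binned <- binned[!is.na(binned)]
  raw <- table(factor(binned, levels = cats))
  raw <- stats::setNames(as.integer(raw), cats)

  tf <- trinucleotide_frequencies(ref)
  ctx <- category_context(cats)
  freq <- unname(ifelse(is.na(tf[ctx]), 0, tf[ctx])) +
          unname(ifelse(is.na(tf[revcomp(ctx)]), 0, tf[revcomp(ctx)]))
  impossible <- which(raw > 0 & freq == 0)
  if (length(impossible))
    stop("bin(s) with observed counts but zero reference context frequency: ",
         paste(cats[impossible], collapse = ", "),
         " — variants are inconsistent with this reference")
  w <- ifelse(freq > 0, raw / freq, 0)
  total <- sum(raw)
  normalized <- if (total > 0) 100 * w / sum(w) else w * 0
  structure(list(group = group, categories = cats, raw = raw,
                 normalized = stats::setNames(normalized, cats),
                 total = total,
                 n_excluded = sum(!is_snv) + n_ctx_excluded,
                 empty = total == 0L),
            class = "spectrum_profile")
}

#' @export
print.spectrum_profile <- function(x, ...) {
  cat("spectrum_profile '", x$group, "': ", x$total, " SNVs",
      if (x$empty) " (empty)", "\n", sep = "")
  cls <- aggregate_classes(x)
  print(round(cls, 2))
  invisible(x)
}

aggregate_classes <- function(profile) {
  cl <- substr(profile$categories, 3, 5)
  vapply(SUB_CLASSES, function(k) sum(profile$normalized[cl == k]),
         numeric(1))
}

#' Compare two mutation-spectrum profiles
#'
#' Reports the cosine similarity of the normalized 96-bin profiles and the
#' per-class (6 substitution classes) aggregated percentages side by side.
#' No hypothesis test is attached.
#'
#' @param a,b \code{spectrum_profile} objects on the same bin order.
#' @return List with \code{cosine_similarity} and a 6 x 2 \code{classes}
#'   matrix of aggregated percentages.
#' @export
compare_spectra <- function(a, b) {
  stopifnot(inherits(a, "spectrum_profile"), inherits(b, "spectrum_profile"))
  if (!identical(a$categories, b$categories))
    stop("profiles have mismatched bin order")
  na <- sqrt(sum(a$normalized^2)); nb <- sqrt(sum(b$normalized^2))
  cs <- if (na == 0 || nb == 0) NA_real_
        else sum(a$normalized * b$normalized) / (na * nb)
  classes <- cbind(aggregate_classes(a), aggregate_classes(b))
  colnames(classes) <- c(a$group, b$group)
  list(cosine_similarity = cs, classes = classes)
}

#' Bar plot of a 96-context mutation spectrum
#'
#' @param profile A [mutation_spectrum()] result.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_spectrum <- function(profile, ...) {
  stopifnot(inherits(profile, "spectrum_profile"))
  cl <- substr(profile$categories, 3, 5)
  cols <- c("C>A" = "deepskyblue", "C>G" = "black", "C>T" = "red",
            "T>A" = "grey60", "T>C" = "seagreen3", "T>G" = "lightpink2")
  mids <- graphics::barplot(profile$normalized, col = cols[cl], border = NA,
                            names.arg = rep("", 96), las = 2,
                            ylab = "normalized frequency (%)",
                            main = profile$group, ...)
  invisible(mids)
}
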