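#' Build a variant-site allele matrix for a patient's tumor samples
#'
#' Encodes each sample as a pseudo-sequence over the variant sites: the alt
#' base where the variant is present (alt fraction at or above the
#' threshold), the ref base otherwise. Sites are the SNV keys passing the
#' threshold in at least one sample, ordered by genomic position then alt
#' allele; indels are excluded. A site where every sample carries the alt
#' allele is retained (it differs from the reference) but is uninformative
#' for topology.
#'
#' @param samples Named list of variant tables (e.g. \code{list(P = ...,
#'   R1 = ..., ...)}); at least 3 samples (Neighbor-Joining needs >= 3
#'   leaves).
#' @param threshold Minimum alt fraction for presence (default 0.01, the
#'   dynamics abundance threshold).
#' @return \code{variant_matrix} object: \code{sample_ids}, \code{sites}
#'   (data.frame pos/ref/alt) and \code{alleles} (character matrix, samples
#'   x sites).
#' @export
build_variant_matrix <- function(samples, threshold = 0.01) {
  if (length(samples) < 3L)
    stop("Neighbor-Joining needs >= 3 samples, got ", length(samples))
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("'samples' must be a named list")
  snv_only <- function(t) {
    t[nchar(t$ref) == 1L & nchar(t$alt) == 1L &
      t$ref %in% c("A", "C", "G", "T") & t$alt %in% c("A", "C", "G", "T"), ,
      drop = FALSE]
  }
  samples <- lapply(samples, snv_only)
  present <- lapply(samples, function(t) t[t$af >= threshold, , drop = FALSE])
  sites <- unique(do.call(rbind, lapply(present, function(t)
    t[c("pos", "ref", "alt")])))
  if (!nrow(sites)) {
    mat <- matrix(character(0), nrow = length(samples), ncol = 0,
                  dimnames = list(names(samples), NULL))
    return(structure(list(sample_ids = names(samples), sites = sites,
                          alleles = mat, threshold = threshold),
                     class = "variant_matrix"))
  }
  sites <- sites[order(sites$pos, sites$alt), , drop = FALSE]
  rownames(sites) <- NULL
  keys <- variant_key(sites$pos, sites$ref, sites$alt)
  mat <- do.call(rbind, lapply(present, function(t) {
    hit <- keys %in% variant_key(t$pos, t$ref, t$alt)
    ifelse(hit, sites$alt, sites$ref)
  }))
  dimnames(mat) <- list(names(samples), keys)
  structure(list(sample_ids = names(samples), sites = sites, alleles = mat,
                 threshold = threshold),
            class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat("variant_matrix:", length(x$sample_ids), "samples x",
      nrow(x$sites), "variant sites (threshold", x$threshold, ")\n")
  invisible(x)
}

#' Jukes-Cantor distance
#'
#' One-parameter substitution-model correction of the observed proportion of
#' differing sites: \code{d = -(3/4) * log(1 - 4p/3)}, in substitutions per
#' site.
#'
#' @param p Proportion of differing sites, in \code{[0, 3/4)}.
#' @return Numeric distance(s).
#' @export
jc_distance <- function(p) {
  if (any(p < 0 | p >= 0.75))
    stop("Jukes-Cantor saturation: proportion of differing sites must be in [0, 0.75)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Jukes-Cantor distance with gamma rate variation among sites
#'
#' \code{d = (3a/4) * ((1 - 4p/3)^(-1/a) - 1)} with gamma shape parameter
#' \code{a}; converges to [jc_distance()] as \code{a} grows.
#'
#' @inheritParams jc_distance
#' @param shape Gamma shape parameter, > 0 (default 0.75).
#' @return Numeric distance(s).
#' @export
jc_gamma_distance <- function(p, shape = 0.75) {
  if (shape <= 0) stop("gamma shape must be > 0")
  if (any(p < 0 | p >= 0.75))
    stop("Jukes-Cantor saturation: proportion of differing sites must be in [0, 0.75)")
  (3 * shape / 4) * ((1 - 4 * p / 3)^(-1 / shape) - 1)
}

#' Pairwise distances from a variant matrix
#'
#' Computes the proportion of differing sites for every sample pair over the
#' complete site columns and applies the chosen distance model.
#'
#' @param vm A [build_variant_matrix()] result.
#' @param model \code{"p"} (raw proportion), \code{"jc"} or
#'   \code{"jc_gamma"} (default, matching a shape-0.75 gamma correction).
#' @param shape Gamma shape for \code{model = "jc_gamma"}.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
variant_distances <- function(vm, model = c("jc_gamma", "jc", "p"),
                              shape = 0.75) {
  model <- match.arg(model)
  stopifnot(inherits(vm, "variant_matrix"))
  m <- vm$alleles
  k <- ncol(m)
  ns <- nrow(m)
  D <- matrix(0, ns, ns, dimnames = list(rownames(m), rownames(m)))
  if (k == 0L) return(D)
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    p <- sum(m[i, ] != m[j, ]) / k
    d <- switch(model, p = p, jc = jc_distance(p),
                jc_gamma = jc_gamma_distance(p, shape))
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-Joining tree reconstruction
#'
#' Classic agglomerative Neighbor-Joining: repeatedly joins the pair of
#' active nodes minimizing the Q criterion
#' \code{Q(i,j) = (m-2) d(i,j) - r_i - r_j}, computes branch lengths to the
#' new node and reduces the matrix, until three nodes remain and are
#' resolved by the three-point formulas. Ties in Q are broken
#' deterministically by the lowest (row, column) index pair. On an additive
#' matrix the leaf-to-leaf path lengths of the returned tree reproduce the
#' input exactly.
#'
#' @param d Symmetric distance matrix (or \code{dist}) with zero diagonal
#'   and non-negative entries; row names are used as leaf labels.
#' @param clamp_negative If TRUE (default), a negative branch length
#'   produced by a join is set to 0 and its deficit moved to the sibling
#'   branch, preserving the distance between the joined nodes.
#' @return An unrooted \code{ape::phylo} tree with branch lengths in the
#'   units of \code{d}.
#' @export
neighbor_joining <- function(d, clamp_negative = TRUE) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3L) stop("Neighbor-Joining needs >= 3 taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  labels <- rownames(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(D < 0)) stop("distance matrix must be non-negative")

  ids <- seq_len(n)                 # tree node ids of active clusters
  next_internal <- 2L * n - 2L      # pair-join internals: 2n-2 down to n+2
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  add_edge <- function(u, v, l) {
    parent <<- c(parent, u); child <<- c(child, v)
    elen <<- c(elen, unname(l))
  }

  while (length(ids) > 3L) {
    m <- length(ids)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (clamp_negative) {
      if (li < 0) { lj <- lj + li; li <- 0 }
      if (lj < 0) { li <- li + lj; lj <- 0 }
    }
    u <- next_internal; next_internal <- next_internal - 1L
    add_edge(u, ids[i], li); add_edge(u, ids[j], lj)
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    ids <- c(ids[keep], u)
  }

  u <- n + 1L
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (clamp_negative) { la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0) }
  add_edge(u, ids[1], la); add_edge(u, ids[2], lb); add_edge(u, ids[3], lc)

  tree <- structure(list(edge = cbind(parent, child, deparse.level = 0),
                         edge.length = elen, Nnode = n - 2L,
                         tip.label = labels),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

#' Site-bootstrap support for a Neighbor-Joining tree
#'
#' Resamples the variant-site columns with replacement, rebuilds the
#' distance matrix and the Neighbor-Joining tree for each replicate, and
#' reports for every interior branch of the full-data tree the percentage
#' of replicate trees containing the same leaf bipartition. Replicates in
#' which a pair of samples saturates the distance model (proportion of
#' differing sites >= 3/4) are skipped and counted; a warning is issued when
#' more than 10\% are skipped.
#'
#' @param vm A [build_variant_matrix()] result with at least one site.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param model,shape Distance model, as in [variant_distances()].
#' @param seed Optional integer seed.
#' @param clamp_negative Passed to [neighbor_joining()].
#' @return \code{boot_phylo} object: \code{tree} (with supports as node
#'   labels), \code{support} (percentage per internal node),
#'   \code{replicates_used}, \code{skipped}, and the configuration.
#' @export
bootstrap_support <- function(vm, replicates = 1000L,
                              model = c("jc_gamma", "jc", "p"), shape = 0.75,
                              seed = NULL, clamp_negative = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(vm, "variant_matrix"))
  if (replicates < 1L) stop("replicates must be >= 1")
  k <- ncol(vm$alleles)
  if (k == 0L) stop("variant matrix has no sites")
  if (!is.null(seed)) set.seed(seed)
  main <- neighbor_joining(variant_distances(vm, model, shape),
                           clamp_negative)
  boots <- vector("list", replicates)
  skipped <- 0L
  for (b in seq_len(replicates)) {
    idx <- sample.int(k, k, replace = TRUE)
    sub <- vm
    sub$alleles <- vm$alleles[, idx, drop = FALSE]
    tr <- tryCatch(
      neighbor_joining(variant_distances(sub, model, shape), clamp_negative),
      error = function(e) NULL)
    if (is.null(tr)) skipped <- skipped + 1L else boots[[b]] <- tr
  }
  boots <- boots[!vapply(boots, is.null, logical(1))]
  used <- length(boots)
  if (skipped > 0.1 * replicates)
    warning(skipped, " of ", replicates,
            " bootstrap replicates skipped (distance saturation)")
  if (!used) stop("all bootstrap replicates saturated")
  cnt <- ape::prop.clades(main, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  support <- 100 * cnt / used
  main$node.label <- formatC(support, format = "f", digits = 1)
  structure(list(tree = main, support = support, replicates_used = used,
                 skipped = skipped, model = model, shape = shape,
                 seed = seed),
            class = "boot_phylo")
}

#' @export
print.boot_phylo <- function(x, ...) {
  cat("Neighbor-Joining tree with bootstrap supports (", x$model,
      if (x$model == "jc_gamma") paste0(", shape=", x$shape), "; ",
      x$replicates_used, " replicates used, ", x$skipped, " skipped)\n",
      sep = "")
  print(x$tree)
  invisible(x)
}

#' Bootstrap support of a specific leaf bipartition
#'
#' Looks up the interior branch of a bootstrapped tree that splits exactly
#' the given samples from the rest and returns its support percentage.
#'
#' @param bt A [bootstrap_support()] result.
#' @param samples Character vector of leaf labels on one side of the split.
#' @return Support percentage, or \code{NA} if the tree contains no branch
#'   inducing that bipartition.
#' @export
bipartition_support <- function(bt, samples) {
  stopifnot(inherits(bt, "boot_phylo"))
  tips <- bt$tree$tip.label
  want <- sort(match(samples, tips))
  if (anyNA(want)) stop("unknown sample label(s): ",
                        paste(samples[is.na(match(samples, tips))],
                              collapse = ", "))
  clades <- ape::prop.part(bt$tree)
  for (i in seq_along(clades)) {
    cl <- sort(clades[[i]])
    if (identical(cl, want) ||
        identical(cl, sort(setdiff(seq_along(tips), want))))
      return(bt$support[i])
  }
  NA_real_
}

#' Write a tree to Newick format
#'
#' Branch lengths are emitted; bootstrap supports (when present) appear as
#' internal node labels. The output round-trips through standard Newick
#' parsers.
#'
#' @param tree An \code{ape::phylo} or [bootstrap_support()] result.
#' @param file Output path, or \code{NULL} to return the text only.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  if (inherits(tree, "boot_phylo")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
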