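# Small builders used across the suite; everything is generated in code.

calls <- function(pos, ref, alt, af, dp, sample = "S") {
  data.frame(sample = rep_len(sample, length(pos)), pos = pos,
             ref = rep_len(ref, length(pos)), alt = rep_len(alt, length(pos)),
             af = rep_len(af, length(pos)), dp = rep_len(dp, length(pos)),
             stringsAsFactors = FALSE)
}

# a three-sample patient with hand-placed variants
toy_triplet <- function(patient_id = "pt1") {
  normal <- calls(c(100, 200), c("A", "C"), c("G", "T"),
                  c(0.50, 0.45), c(200, 180), "pt1_N")
  primary <- calls(c(100, 200, 300), c("A", "C", "G"), c("G", "T", "A"),
                   c(0.52, 0.40, 0.05), c(210, 150, 220), "pt1_P")
  relapse <- calls(c(100, 300, 400), c("A", "G", "T"), c("G", "A", "C"),
                   c(0.48, 0.08, 0.10), c(190, 240, 160), "pt1_R")
  patient_triplet(patient_id, normal, primary, relapse)
}

# de Bruijn sequence B(4,3): every 3-mer over ACGT appears exactly once
# circularly (greedy prefer-largest construction, self-checked)
debruijn_mt <- function() {
  k <- 4L; n <- 3L
  seqv <- rep(1L, n)
  seen <- new.env()
  assign(paste(seqv, collapse = ""), TRUE, envir = seen)
  total <- k^n
  while (length(ls(seen)) < total) {
    placed <- FALSE
    for (s in k:1) {
      cand <- c(seqv[(length(seqv) - n + 2):length(seqv)], s)
      key <- paste(cand, collapse = "")
      if (!exists(key, envir = seen)) {
        seqv <- c(seqv, s)
        assign(key, TRUE, envir = seen)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("greedy de Bruijn construction failed")
  }
  seqv <- seqv[1:(k^n)]   # drop the wrap-around prefix; treat as circular
  mt_reference(paste(c("A", "C", "G", "T")[seqv], collapse = ""),
               name = "debruijn")
}

# random additive distance matrix from a random unrooted tree
random_additive <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
  list(tree = tr, D = stats::cophenetic(tr))
}

truth_key <- function(d) paste(d$patient_id, d$pos, d$ref, d$alt)
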