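test_that("SNVs are binned in the pyrimidine frame", {
  ref <- mt_reference("AACAATGAA")   # pos 3 = C in ACA; pos 7 = G in TGA
  expect_equal(bin_variant(ref, 3, "C", "T"), "A[C>T]A")
  # purine ref: G>A in TGA reverse-complements to C>T with flipped flanks
  expect_equal(bin_variant(ref, 7, "G", "A"), "T[C>T]A")
  expect_error(bin_variant(ref, 3, "A", "T"), "disagrees with the reference")
  expect_error(bin_variant(ref, 3, "C", "CT"), "single-base")
  # context touching an N is excluded (NA), not mis-binned
  refn <- mt_reference("ANCAA")
  expect_true(is.na(bin_variant(refn, 3, "C", "T")))
})

test_that("category order has 96 bins in six classes of sixteen", {
  cats <- spectrum_categories()
  expect_length(cats, 96)
  expect_equal(anyDuplicated(cats), 0L)
  cl <- substr(cats, 3, 5)
  expect_equal(unname(table(cl)[c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")]),
               rep(16L, 6), ignore_attr = TRUE)
})

test_that("spectrum normalizes to 100 percent and flags empties", {
  ref <- mt_reference("AACAATGAA")
  prof <- mutation_spectrum(data.frame(pos = 3, ref = "C", alt = "T"),
                            ref, "one")
  expect_equal(sum(prof$normalized), 100, tolerance = 1e-9)
  expect_equal(unname(prof$normalized["A[C>T]A"]), 100)
  expect_false(prof$empty)

  nothing <- mutation_spectrum(data.frame(pos = integer(0),
                                          ref = character(0),
                                          alt = character(0)), ref)
  expect_true(nothing$empty)
  expect_true(all(nothing$normalized == 0))
})

test_that("uniform counts on a context-uniform reference give uniform bins", {
  ref <- debruijn_mt()
  tf <- trinucleotide_frequencies(ref)
  expect_true(all(abs(tf - 1 / 64) < 1e-12))  # self-check of the construction
  # one variant per bin: find a position carrying each pyrimidine context
  ctx <- context_at(ref, seq_len(ref$length))
  cats <- spectrum_categories()
  centre <- substr(ctx, 2, 2)
  pyr <- ifelse(centre %in% c("C", "T"), ctx, revcomp(ctx))
  vars <- do.call(rbind, lapply(cats, function(cc) {
    want <- paste0(substr(cc, 1, 1), substr(cc, 3, 3), substr(cc, 7, 7))
    p <- which(pyr == want)[1]
    rb <- substr(ctx[p], 2, 2)
    alt <- if (rb %in% c("C", "T")) substr(cc, 5, 5)
           else chartr("ACGT", "TGCA", substr(cc, 5, 5))
    data.frame(pos = p, ref = rb, alt = alt)
  }))
  prof <- mutation_spectrum(vars, ref, "uniform")
  expect_equal(unname(prof$raw), rep(1L, 96))
  expect_equal(unname(prof$normalized), rep(100 / 96, 96),
               tolerance = 1e-9)
})

test_that("the profile is invariant under reverse-complementing everything", {
  set.seed(17)
  ref <- simulate_reference(3000, seed = 17)
  spec <- cohort_spec(n_patients = 1, germline_rate = 150, seed = 18)
  co <- simulate_cohort(spec, ref)
  v <- co$truth[, c("pos", "ref", "alt")]
  p1 <- mutation_spectrum(v, ref)
  rc_ref <- mt_reference(revcomp(ref$sequence), "rc")
  v2 <- data.frame(pos = ref$length + 1 - v$pos,
                   ref = chartr("ACGT", "TGCA", v$ref),
                   alt = chartr("ACGT", "TGCA", v$alt))
  p2 <- mutation_spectrum(v2, rc_ref)
  expect_equal(p1$raw, p2$raw)
  expect_equal(p1$normalized, p2$normalized, tolerance = 1e-9)
})

test_that("comparison is scale-invariant with the expected extremes", {
  ref <- mt_reference("AACAATGAA")
  a <- mutation_spectrum(data.frame(pos = 3, ref = "C", alt = "T"), ref, "a")
  expect_equal(compare_spectra(a, a)$cosine_similarity, 1.0)
  b <- mutation_spectrum(data.frame(pos = 3, ref = "C", alt = "G"), ref, "b")
  expect_equal(compare_spectra(a, b)$cosine_similarity, 0.0)
  # doubling every count leaves the normalized profile unchanged
  aa <- mutation_spectrum(data.frame(pos = c(3, 3), ref = "C", alt = "T"),
                          ref, "a2")
  expect_equal(unname(aa$raw["A[C>T]A"]), 2L)
  expect_equal(compare_spectra(a, aa)$cosine_similarity, 1.0)
  bad <- a
  bad$categories <- rev(bad$categories)
  expect_error(compare_spectra(a, bad), "mismatched bin order")
})

test_that("variants inconsistent with the reference are rejected", {
  ref <- mt_reference("AACAATGAA")
  expect_error(mutation_spectrum(data.frame(pos = 3, ref = "G", alt = "T"),
                                 ref),
               "disagrees with the reference")
})
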