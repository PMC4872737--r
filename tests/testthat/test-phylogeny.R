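test_that("variant matrix encodes presence as alt, absence as ref", {
  s <- list(
    A = calls(10, "A", "G", 0.00, 100, "A"),
    B = calls(10, "A", "G", 0.20, 100, "B"),
    C = calls(10, "A", "G", 0.005, 100, "C"))
  vm <- build_variant_matrix(s, threshold = 0.01)
  expect_equal(unname(vm$alleles[, 1]), c("A", "G", "A"))  # 0.5% is ref
  expect_error(build_variant_matrix(s[1:2]), ">= 3 samples")

  # all-alt site retained (differs from ref, uninformative for topology)
  s2 <- lapply(s, function(t) { t$af <- 0.5; t })
  vm2 <- build_variant_matrix(s2)
  expect_equal(ncol(vm2$alleles), 1L)
  expect_true(all(vm2$alleles == "G"))

  # indels are excluded
  s3 <- list(A = calls(5, "A", "AT", 0.5, 100),
             B = calls(5, "A", "AT", 0.5, 100),
             C = calls(5, "A", "AT", 0.5, 100))
  expect_equal(nrow(build_variant_matrix(s3)$sites), 0L)
})

test_that("Jukes-Cantor distances match the closed forms", {
  expect_equal(jc_distance(0), 0)
  # frozen from independent evaluation of -(3/4)ln(1-4p/3) at p=0.1
  expect_equal(jc_distance(0.1), 0.1073256, tolerance = 1e-6)
  expect_error(jc_distance(0.75), "saturation")
  expect_error(jc_distance(-0.1), "saturation")

  expect_equal(jc_gamma_distance(0), 0)
  # frozen from independent evaluation of (3a/4)[(1-4p/3)^(-1/a)-1]
  expect_equal(jc_gamma_distance(0.0075, 0.75), 0.00758848,
               tolerance = 1e-6)
  expect_error(jc_gamma_distance(0.8), "saturation")
  expect_error(jc_gamma_distance(0.1, shape = 0), "shape")
  # large-shape limit recovers plain Jukes-Cantor
  expect_equal(jc_gamma_distance(0.2, shape = 1e6), jc_distance(0.2),
               tolerance = 1e-6)
})

test_that("gamma correction dominates and both distances increase in p", {
  p <- seq(0.01, 0.7, by = 0.01)
  for (a in c(0.1, 0.75, 5)) {
    expect_true(all(jc_gamma_distance(p, a) > jc_distance(p)))
    expect_true(all(diff(jc_gamma_distance(p, a)) > 0))
  }
  expect_true(all(diff(jc_distance(p)) > 0))
})

test_that("three-taxon NJ solves the three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_s3_class(tr, "phylo")
  pl <- stats::cophenetic(tr)[rownames(D), colnames(D)]
  expect_equal(pl, D, tolerance = 1e-12)
  lens <- tr$edge.length[match(match(c("a", "b", "c"), tr$tip.label),
                               tr$edge[, 2])]
  expect_equal(sort(lens), c(1, 2, 3))
})

test_that("NJ recovers additive matrices exactly", {
  for (seed in 1:10) {
    ra <- random_additive(sample(5:8, 1), seed)
    tr <- neighbor_joining(ra$D)
    pl <- stats::cophenetic(tr)[rownames(ra$D), colnames(ra$D)]
    expect_equal(pl, ra$D, tolerance = 1e-9)
    # independent implementation agrees on the topology
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::nj(ra$D)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ validates its input and breaks ties deterministically", {
  D <- matrix(runif(16), 4, 4)
  expect_error(neighbor_joining(D), "symmetric")
  D2 <- matrix(0, 3, 3); D2[1, 2] <- D2[2, 1] <- -1
  expect_error(neighbor_joining(D2), "non-negative")
  # fully tied Q: lowest-index pair joined first, output reproducible
  De <- matrix(1, 4, 4) - diag(4)
  dimnames(De) <- list(letters[1:4], letters[1:4])
  t1 <- neighbor_joining(De)
  t2 <- neighbor_joining(De)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  # a and b share the first cherry under the lowest-index rule
  pp <- ape::prop.part(t1)
  expect_true(any(vapply(pp, function(z)
    setequal(t1$tip.label[z], c("c", "d")) ||
    setequal(t1$tip.label[z], c("a", "b")), logical(1))))
})

test_that("negative NJ branches are clamped with the deficit on the sibling", {
  # classic non-additive matrix producing a negative branch
  D <- matrix(c(0, 2, 10, 10,
                2, 0, 10, 2,
                10, 10, 0, 2,
                10, 2, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D, clamp_negative = TRUE)
  expect_true(all(tr$edge.length >= 0))
  tr2 <- neighbor_joining(D, clamp_negative = FALSE)
  expect_true(any(tr2$edge.length < 0))
  expect_setequal(tr$tip.label, letters[1:4])
})

test_that("bootstrap support is 100 for a clean split and degenerate for one site", {
  mk <- function(af) calls(1:8, "A", "G", af, 100)
  s <- list(A = mk(rep(c(0.5, 0), each = 4)), B = mk(rep(c(0.5, 0), each = 4)),
            C = mk(rep(c(0, 0.5), each = 4)), D = mk(rep(c(0, 0.5), each = 4)))
  vm <- build_variant_matrix(s)
  bt <- bootstrap_support(vm, replicates = 100, model = "p", seed = 1)
  expect_equal(bipartition_support(bt, c("A", "B")), 100)

  one <- list(A = calls(1, "A", "G", 0.5, 100),
              B = calls(1, "A", "G", 0.5, 100),
              C = calls(1, "A", "G", 0, 100))
  vm1 <- build_variant_matrix(one)
  bt1 <- bootstrap_support(vm1, replicates = 50, model = "p", seed = 1)
  expect_true(all(bt1$support %in% c(0, 100)))
})

test_that("bootstrap supports survive sample-order permutation", {
  set.seed(21)
  spec <- cohort_spec(relapses_per_patient = 5, seed = 21)
  ref <- simulate_reference(4000, seed = 21)
  co <- simulate_multirelapse(spec, ref)
  tr <- co$patients[[1]]
  tumors <- c(list(P = tr$primary), tr$relapses)
  vm <- build_variant_matrix(tumors)
  vmp <- build_variant_matrix(tumors[c(3, 1, 6, 2, 5, 4)])
  b1 <- bootstrap_support(vm, replicates = 100, seed = 4)
  b2 <- bootstrap_support(vmp, replicates = 100, seed = 4)
  expect_equal(bipartition_support(b1, co$planted_bipartition),
               bipartition_support(b2, co$planted_bipartition),
               tolerance = 12)  # resampling streams differ; signal must not
})

test_that("Newick output round-trips through a generic parser", {
  ra <- random_additive(6, 99)
  tr <- neighbor_joining(ra$D)
  txt <- write_newick(tr)
  back <- ape::read.tree(text = txt)
  expect_equal(ape::dist.topo(back, ape::unroot(tr)), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-8)
  d <- withr::local_tempdir()
  f <- file.path(d, "t.nwk")
  write_newick(tr, f)
  expect_equal(readLines(f), txt)
  # supports appear as internal node labels
  s <- list(A = calls(1:4, "A", "G", 0.5, 100),
            B = calls(1:4, "A", "G", 0.5, 100),
            C = calls(1:4, "A", "G", 0, 100),
            D = calls(1:4, "A", "G", 0, 100))
  bt <- bootstrap_support(build_variant_matrix(s), replicates = 20,
                          model = "p", seed = 2)
  expect_match(write_newick(bt), "\\)100")
})
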