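test_that("TSV dialect round-trips with delimiter auto-detection", {
  d <- withr::local_tempdir()
  tsv <- file.path(d, "s1.tsv")
  writeLines(c("sample\tpos\tref\talt\taf\tdp",
               "S1\t100\tA\tG\t0.05\t200"), tsv)
  tab <- read_variant_table(tsv)
  expect_equal(tab$pos, 100L)
  expect_equal(tab$af, 0.05)
  expect_equal(tab$dp, 200)

  csv <- file.path(d, "s1.csv")
  writeLines(c("sample,pos,ref,alt,af,dp", "S1,100,A,G,0.05,200"), csv)
  expect_equal(read_variant_table(csv), tab)

  dup <- file.path(d, "dup.tsv")
  writeLines(c("sample\tpos\tref\talt\taf\tdp",
               "S1\t100\tA\tG\t0.05\t200",
               "S1\t100\tA\tG\t0.10\t150"), dup)
  expect_error(read_variant_table(dup), "duplicate variant key.*row")

  bad <- file.path(d, "bad.tsv")
  writeLines(c("sample\tpos\tref\talt\taf\tdp",
               "S1\t100\tA\tG\t1.5\t200"), bad)
  expect_error(read_variant_table(bad), "allele fraction.*row")
})

test_that("minimal VCF records map onto equivalent variant calls", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "s1.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chrM\t100\t.\tA\tG\t.\tPASS\tAF=0.5;DP=80"), vcf)
  tab <- read_variant_table(vcf, sample_id = "S1")
  expect_equal(tab$sample, "S1")
  expect_equal(tab$pos, 100L)
  expect_equal(tab$af, 0.5)
  expect_equal(tab$dp, 80)

  fmt <- file.path(d, "fmt.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "chrM\t42\t.\tC\tT\t.\tPASS\t.\tAF:DP\t0.12:99"), fmt)
  tab2 <- read_variant_table(fmt, sample_id = "S1")
  expect_equal(tab2$af, 0.12)
  expect_equal(tab2$dp, 99)
})

test_that("position validation against a reference", {
  d <- withr::local_tempdir()
  tsv <- file.path(d, "s.tsv")
  writeLines(c("sample\tpos\tref\talt\taf\tdp", "S\t50\tA\tG\t0.1\t100"), tsv)
  expect_error(read_variant_table(tsv, reference = mt_reference("ACGT")),
               "beyond reference length")
})

test_that("depth is exclusive at the threshold and abundance depends on purpose", {
  cfg <- filter_config()
  tab <- calls(c(1, 2, 3), "A", "G",
               af = c(0.10, 0.015, 0.015), dp = c(50, 100, 100))
  cl <- apply_filters(tab, cfg, "classify")
  expect_equal(cl$pos, integer(0))  # dp=50 fails (> 50 required); af 1.5% fails 2%
  dy <- apply_filters(tab, cfg, "dynamics")
  expect_equal(dy$pos, c(2L, 3L))   # 1.5% passes the 1% dynamics threshold
  expect_equal(unname(attr(cl, "removed")), c(1L, 2L))
  empty <- apply_filters(tab[0, ], cfg, "classify")
  expect_equal(nrow(empty), 0L)
})

test_that("filters are monotone in their thresholds", {
  set.seed(11)
  tab <- calls(1:200, "A", "G", af = runif(200), dp = rpois(200, 80))
  kept <- function(md, ab) nrow(apply_filters(
    tab, filter_config(min_depth = md, abundance_classify = ab), "classify"))
  for (i in 1:20) {
    md <- sample(0:120, 2); ab <- sort(runif(2, 0.01, 0.9))
    expect_gte(kept(min(md), ab[1]), kept(max(md), ab[1]))
    expect_gte(kept(md[1], ab[1]), kept(md[1], ab[2]))
  }
})

test_that("classification assigns the definitional categories", {
  # tumor-specific: absent in normal, present in both tumors
  tr <- patient_triplet("p",
    normal = calls(integer(0), character(0), character(0), numeric(0), numeric(0)),
    primary = calls(500, "A", "G", 0.05, 200, "P"),
    relapses = calls(500, "A", "G", 0.08, 200, "R"))
  cv <- classify_patient(tr)
  expect_equal(cv$category, "tumor_specific")
  expect_equal(cv$occurrence, "P,R1")

  # germline: 50% in all three samples
  tr2 <- patient_triplet("p",
    normal = calls(500, "A", "G", 0.50, 200, "N"),
    primary = calls(500, "A", "G", 0.50, 200, "P"),
    relapses = calls(500, "A", "G", 0.50, 200, "R"))
  cv2 <- classify_patient(tr2)
  expect_equal(cv2$category, "germline")
  expect_equal(cv2$occurrence, "P,R1")

  # normal depth 30 at the site: uninformative, in neither category
  tr3 <- patient_triplet("p",
    normal = calls(500, "A", "G", 0.00, 30, "N"),
    primary = calls(500, "A", "G", 0.05, 200, "P"),
    relapses = calls(500, "A", "G", 0.08, 200, "R"))
  cv3 <- classify_patient(tr3)
  expect_equal(cv3$category, "uninformative")

  # same via an explicit depth lookup for an unlisted position
  cv3b <- classify_patient(tr, normal_depth = c("500" = 30))
  expect_equal(cv3b$category, "uninformative")

  # present only in normal: germline with empty tumor occurrence
  tr4 <- patient_triplet("p",
    normal = calls(500, "A", "G", 0.50, 200, "N"),
    primary = calls(integer(0), character(0), character(0), numeric(0), numeric(0)),
    relapses = calls(integer(0), character(0), character(0), numeric(0), numeric(0)))
  cv4 <- classify_patient(tr4)
  expect_equal(cv4$category, "germline")
  expect_equal(cv4$occurrence, "")
})

test_that("categories partition the observed variant keys", {
  cv <- classify_patient(toy_triplet())
  expect_true(all(cv$category %in%
                  c("germline", "tumor_specific", "uninformative")))
  expect_equal(anyDuplicated(paste(cv$pos, cv$ref, cv$alt)), 0L)
  # every key observed in any sample (post-classify-filter) is covered
  expect_setequal(cv$pos, c(100, 200, 300, 400))
  expect_equal(sort(cv$category[match(c(100, 200), cv$pos)]),
               c("germline", "germline"))
  expect_equal(sort(unique(cv$category[match(c(300, 400), cv$pos)])),
               "tumor_specific")
})

test_that("known-variant annotation distinguishes known, novel, unannotated", {
  cv <- classify_patient(toy_triplet())
  expect_true(all(cv$known_status == "unannotated"))
  d <- withr::local_tempdir()
  cat_path <- file.path(d, "catalog.tsv")
  writeLines(c("pos\tref\talt\tid", "100\tA\tG\tmt100AG"), cat_path)
  ann <- annotate_known(cv, read_catalog(cat_path))
  expect_equal(ann$known_status[ann$pos == 100], "known")
  expect_true(all(ann$known_status[ann$pos != 100] == "novel"))
  bad <- file.path(d, "bad.tsv")
  writeLines(c("position\tid", "1\tx"), bad)
  expect_error(read_catalog(bad), "malformed catalog")
})

test_that("count tables collapse occurrence patterns per patient", {
  cv <- classify_patient(toy_triplet())
  ct <- count_table(cv)
  expect_equal(ct$ts_primary, 1L)   # pos 300 at 5% in P
  expect_equal(ct$ts_relapse, 2L)   # pos 300 and 400 in R
  expect_equal(ct$difference, 1L)
  expect_equal(ct$gl_normal, 2L)
  s <- count_summary(data.frame(patient = "x", ts_primary = 0,
                                ts_relapse = 0, gl_primary = 0,
                                gl_relapse = 0))
  expect_equal(s$patients_with_ts, 0L)
  expect_equal(s$ts_mean, 0)
})

test_that("published cohort fixture is internally consistent", {
  d <- nb_cohort_counts()
  expect_equal(nrow(d), 16L)
  expect_equal(d$difference, d$ts_relapse - d$ts_primary)
})
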