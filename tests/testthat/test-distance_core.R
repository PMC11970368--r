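test_that("per-site scores follow the unphased multiset and phased positional rules", {
  u <- function(...) list(alleles = c(...), phased = FALSE)
  p <- function(...) list(alleles = c(...), phased = TRUE)
  expect_equal(score_pair(u(0L, 0L), u(0L, 1L)), 0.5)
  expect_equal(score_pair(u(0L, 0L), u(1L, 1L)), 1)
  expect_equal(score_pair(u(0L, 0L), u(0L, 0L)), 0)
  expect_equal(score_pair(u(0L, 1L), u(0L, 1L)), 0)
  expect_equal(score_pair(p(1L, 0L), p(0L, 1L)), 1)
  expect_equal(score_pair(p(0L, 1L), p(0L, 1L)), 0)
  # phased order only matters when both calls carry phase
  expect_equal(score_pair(p(1L, 0L), u(0L, 1L)), 0)
  # multiallelic multiset rule: shared {2} of ploidy 2
  expect_equal(score_pair(u(1L, 2L), u(0L, 2L)), 0.5)
  # haploid
  expect_equal(score_pair(u(0L), u(0L)), 0)
  expect_equal(score_pair(u(0L), u(1L)), 1)
  # mixed ploidy is unscorable
  expect_true(is.na(score_pair(u(0L), u(0L, 0L))))
})

test_that("accumulation sums per-site scores with pairwise deletion", {
  f <- tempfile(fileext = ".vcf")
  tok <- matrix(c("0/0", "0/0", "0/0", "0/0",
                  "0/1", "1/1", "./.", "0/0"), nrow = 2, byrow = TRUE)
  write_tokens_vcf(tok, rep(2L, 4), f)
  st <- vcf_site_stream(f)
  acc <- accumulate_sites(st)
  expect_equal(acc$sum_d, 1.5)   # 0.5 + 1 + (skipped) + 0
  expect_equal(acc$used, 3)
  D <- finalize_distances(acc, st$names)
  expect_equal(unname(D[1, 2]), 0.5)
  expect_equal(unname(attr(D, "used_sites")[1, 2]), 3)
})

test_that("a missing call excludes only the pairs that involve it", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
               "chr1\t1\t.\tA\tC\t.\t.\t.\tGT\t0/0\t.\t1/1"), f)
  st <- vcf_site_stream(f)
  D <- finalize_distances(accumulate_sites(st), st$names)
  U <- attr(D, "used_sites")
  expect_equal(unname(U[1, 2]), 0)
  expect_equal(unname(U[2, 3]), 0)
  expect_equal(unname(U[1, 3]), 1)
  expect_true(is.na(D[1, 2]))
  expect_equal(unname(D[1, 3]), 1)
})

test_that("mixed-ploidy pairs skip the site and are counted", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
               "chr1\t1\t.\tA\tC\t.\t.\t.\tGT\t0\t0/1",
               "chr1\t2\t.\tA\tC\t.\t.\t.\tGT\t1\t0"), f)
  st <- vcf_site_stream(f)
  acc <- accumulate_sites(st)
  expect_equal(acc$mixed_skips, 1)
  expect_equal(acc$used, 1)
  expect_equal(acc$sum_d, 1)
})

test_that("merging block accumulators equals accumulating the full stream", {
  gen <- rand_gt_tokens(8, 120, seed = 5)
  f_all <- tempfile(fileext = ".vcf")
  f_a <- tempfile(fileext = ".vcf")
  f_b <- tempfile(fileext = ".vcf")
  write_tokens_vcf(gen$tokens, gen$n_alleles, f_all)
  write_tokens_vcf(gen$tokens[, 1:50], gen$n_alleles[1:50], f_a)
  write_tokens_vcf(gen$tokens[, 51:120], gen$n_alleles[51:120], f_b)
  full <- accumulate_sites(vcf_site_stream(f_all))
  merged <- merge_accumulators(accumulate_sites(vcf_site_stream(f_a)),
                               accumulate_sites(vcf_site_stream(f_b)))
  expect_identical(full$sum_d, merged$sum_d)
  expect_identical(full$used, merged$used)
})

test_that("masking additional genotypes never increases used_sites", {
  gen <- rand_gt_tokens(6, 80, seed = 11, missing_rate = 0.1)
  f1 <- tempfile(fileext = ".vcf")
  write_tokens_vcf(gen$tokens, gen$n_alleles, f1)
  U1 <- attr(pkg_p_matrix(f1), "used_sites")
  tok2 <- gen$tokens
  set.seed(12)
  tok2[runif(length(tok2)) < 0.2] <- "./."
  f2 <- tempfile(fileext = ".vcf")
  write_tokens_vcf(tok2, gen$n_alleles, f2)
  U2 <- attr(pkg_p_matrix(f2), "used_sites")
  expect_true(all(U2 <= U1))
})

test_that("permuting sample order permutes the matrix identically", {
  gen <- rand_gt_tokens(7, 90, seed = 21, missing_rate = 0.1)
  f <- tempfile(fileext = ".vcf")
  write_tokens_vcf(gen$tokens, gen$n_alleles, f)
  D <- pkg_p_matrix(f)
  perm <- c("S4", "S1", "S7", "S3", "S6", "S2", "S5")
  lst <- tempfile()
  writeLines(perm, lst)
  Dp <- pkg_p_matrix(f, read_sample_list(lst))
  expect_equal(Dp, D[perm, perm], tolerance = 0, ignore_attr = TRUE)
})

test_that("Phylip matrix output matches the documented layout and round-trips", {
  D <- matrix(c(0, 0.375, 0.375, 0), 2, 2,
              dimnames = list(c("S1", "S2"), c("S1", "S2")))
  f <- tempfile()
  write_phylip_matrix(D, f)
  lines <- readLines(f)
  expect_equal(lines[1], "2")
  expect_match(lines[2], "^S1\\s+0\\.000000 0\\.375000$")
  expect_match(lines[3], "^S2\\s+0\\.375000 0\\.000000$")
  expect_equal(read_phylip_matrix(f), D, ignore_attr = TRUE)

  # n-sample file has n + 1 lines
  gen <- rand_gt_tokens(9, 50, seed = 2, missing_rate = 0)
  fv <- tempfile(fileext = ".vcf")
  write_tokens_vcf(gen$tokens, gen$n_alleles, fv)
  Dv <- pkg_p_matrix(fv)
  write_phylip_matrix(Dv, f)
  expect_length(readLines(f), 10L)
  expect_equal(read_phylip_matrix(f), unname(`attr<-`(Dv, "used_sites", NULL)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("undefined pairs survive the sentinel round-trip as NA", {
  D <- matrix(c(0, NA, NA, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  f <- tempfile()
  write_phylip_matrix(D, f)
  expect_match(readLines(f)[2], "-1\\.000000")
  expect_true(is.na(read_phylip_matrix(f)["a", "b"]))
})

test_that("lower-triangle matrices read the same as their square form", {
  sq <- c("3",
          "A 0.000000 0.100000 0.200000",
          "B 0.100000 0.000000 0.300000",
          "C 0.200000 0.300000 0.000000")
  lo <- c("3", "A", "B 0.100000", "C 0.200000 0.300000")
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(sq, f1); writeLines(lo, f2)
  expect_equal(read_phylip_matrix(f1), read_phylip_matrix(f2))
  bad <- sq
  bad[2] <- "A 0.000000 0.100000 0.200000"
  bad[3] <- "B 0.200000 0.000000 0.300000"   # 0.1 vs 0.2 asymmetric
  writeLines(bad, f1)
  expect_error(read_phylip_matrix(f1), "asymmetric")
})
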