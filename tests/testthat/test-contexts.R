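test_that("context key universes have the expected sizes and are disjoint", {
  expect_length(snv_context_keys(), 96)
  expect_length(indel_context_keys(), 30)
  expect_length(sv_context_keys(), 16)
  expect_length(context_keys(), 142)
  expect_false(anyDuplicated(context_keys()) > 0)
})

test_that("SNV classification reads off the trinucleotide context", {
  g <- ref_genome(c(chr1 = "TTACGTTAGCTAGCATTTTT"))
  # pos 4 is C with 5' A and 3' G
  expect_identical(classify_snv_context("chr1", 4, "C", "T", g), "A[C>T]G")
  # purine reference: G>A at pos 5 (5' C, 3' T) is the same context on the
  # opposite strand
  expect_identical(classify_snv_context("chr1", 5, "G", "A", g), "A[C>T]G")
  expect_error(classify_snv_context("chr1", 4, "C", "C", g), "ref == alt")
  # flank off the contig end -> skippable NA
  expect_true(is.na(classify_snv_context("chr1", 1, "T", "A", g)))
})

test_that("SNV classification is strand symmetric", {
  g <- fixture_genome()
  chrom <- names(g$seqs)[1]
  gs <- g$seqs[[chrom]]
  n <- nchar(gs)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- paste(rev(comp[strsplit(gs, "")[[1]]]), collapse = "")
  g_rc <- ref_genome(setNames(rc, chrom))
  set.seed(5)
  pos <- sample(seq(10, n - 10), 200)
  for (p in pos[1:50]) {
    ref <- substr(gs, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    k1 <- classify_snv_context(chrom, p, ref, alt, g)
    k2 <- classify_snv_context(chrom, n - p + 1, comp[[ref]], comp[[alt]],
                               g_rc)
    expect_identical(k1, k2)
  }
})

test_that("indel classification follows the repeat and microhomology rules", {
  #            123456789012345678901234
  g <- ref_genome(c(c1 = "GGGGCTATAGCAAGCAGTTGGCCA"))
  # deletion of TA at 6-7 with downstream TA -> repeat, length 2
  expect_identical(classify_indel_context("c1", 5, "CTA", "C", g),
                   "del.rep.len.2")
  # deletion of AGC at 12-14 with downstream AGC? genome 12..14 = AAG;
  # construct 2 bp identity instead: deletion of AGC at 13-15, downstream
  # AGT (2 bp identity, no full copy) -> del.mh bimh 2
  g2 <- ref_genome(c(c1 = "GGGGGGTTAGCAGTTTGGGGGG"))
  # delete AGC at 9-11 (0-based 8..10), downstream AGT
  expect_identical(classify_indel_context("c1", 8, "TAGC", "T", g2),
                   "del.mh.bimh.2")
  # insertion of G between T and T with upstream A -> no identity anywhere
  g3 <- ref_genome(c(c1 = "CCCCAATTCCCC"))
  expect_identical(classify_indel_context("c1", 6, "A", "AG", g3),
                   "ins.none.len.1")
  # mixed substitution/indel allele is rejected
  expect_error(classify_indel_context("c1", 6, "AT", "GC", g3), "mixed")
})

test_that("indel classification matches the brute-force scanner", {
  g <- fixture_genome()
  gs <- g$seqs[[1]]
  recs <- random_indel_records(g, 250, seed = 31)
  for (r in recs) {
    got <- classify_indel_context(r$chrom, r$pos, r$ref, r$alt, g)
    want <- oracle_indel_class(gs, r$d0, r$type, r$s)
    expect_identical(got, want)
  }
})

test_that("SV contexts bin by type and length, dropping sub-kb events", {
  expect_identical(classify_sv_context("DUP", 50000), "DUP_1e04_1e05_bp")
  expect_identical(classify_sv_context("DUP", 5000), "DUP_1e03_1e04_bp")
  expect_identical(classify_sv_context("DEL", 5e6), "DEL_1e06_1e07_bp")
  expect_identical(classify_sv_context("INV", 2e8), "INV_1e07_Inf_bp")
  expect_identical(classify_sv_context("TRA"), "TRA")
  expect_true(is.na(classify_sv_context("DEL", 500)))
  expect_error(classify_sv_context("DEL", NA), "length")
})

test_that("profiles are complete, additive and deterministic", {
  g <- fixture_genome()
  empty <- extract_profile(NULL, NULL, g)
  expect_length(empty, 142)
  expect_true(all(empty == 0))

  pl <- plant_variants(g, c("del.mh.bimh.2" = 10, "del.rep.len.1" = 5,
                            "DUP_1e03_1e04_bp" = 3), seed = 17)
  prof <- extract_profile(pl$small_variants, pl$svs, g)
  expect_identical(unname(prof["del.mh.bimh.2"]), 10L)
  expect_identical(unname(prof["del.rep.len.1"]), 5L)
  expect_identical(unname(prof["DUP_1e03_1e04_bp"]), 3L)
  expect_identical(sum(prof), 18L)
  # every accepted record increments exactly one key
  expect_identical(sum(prof), attr(prof, "n_accepted"))
  # determinism
  prof2 <- extract_profile(pl$small_variants, pl$svs, g)
  expect_identical(unclass(prof), unclass(prof2))
  # individually bad records are skipped, never the batch
  bad <- rbind(pl$small_variants[, 1:4],
               data.frame(chrom = pl$small_variants$chrom[1], pos = 1e7,
                          ref = "A", alt = "T"))
  prof3 <- extract_profile(bad, NULL, g)
  expect_identical(attr(prof3, "n_skipped"), 1L)
})

test_that("MSI detection uses a strict repeat-indel threshold", {
  prof <- setNames(rep(0L, 142), context_keys())
  prof["del.rep.len.1"] <- 14000L
  expect_false(detect_msi(prof))
  prof["ins.rep.len.3"] <- 1L
  expect_true(detect_msi(prof))
  expect_false(detect_msi(setNames(rep(0L, 142), context_keys())))
})
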