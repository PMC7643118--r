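GENE <- data.frame(gene = "BRCA2", chrom = "chr13",
                   start = 32315474, end = 32400266)

seg <- function(total, minor, gene = GENE) {
  data.frame(chrom = gene$chrom,
             start = c(0, gene$start - 50, gene$end + 50),
             end = c(gene$start - 50, gene$end + 50, gene$end + 1e6),
             total_cn = c(2, total, 2), minor_cn = c(1, minor, 1))
}

gvar <- function(origin, clinvar = NA, effect = NA, pos = 32350000,
                 common = FALSE) {
  data.frame(chrom = "chr13", pos = pos, ref = "A", alt = "T",
             origin = origin, clinvar_class = clinvar, effect_class = effect,
             common_germline = common, stringsAsFactors = FALSE)
}

test_that("P-scores follow clinical annotation with effect-class fallback", {
  expect_identical(assign_p_score("pathogenic"), 5L)
  expect_identical(assign_p_score("likely_pathogenic"), 4L)
  expect_identical(assign_p_score("VUS"), 3L)
  expect_identical(assign_p_score(NA, "frameshift_oof"), 5L)
  expect_identical(assign_p_score(NA, "nonsense"), 4L)
  expect_identical(assign_p_score(NA, "missense"), 3L)
  expect_identical(assign_p_score(NA, "other"), 2L)
  # clinical annotation takes precedence over the effect class
  expect_identical(assign_p_score("benign", "frameshift_oof"), 1L)
  # high-frequency germline variants are forced benign
  expect_identical(assign_p_score("pathogenic", common_germline = TRUE), 0L)
  expect_error(assign_p_score(), "no annotation")
})

test_that("deep deletion and LOH use strict copy-number boundaries", {
  expect_true(detect_deep_deletion(GENE, seg(0.1, 0)))
  expect_false(detect_deep_deletion(GENE, seg(0.3, 0)))
  expect_false(detect_deep_deletion(GENE, seg(2.0, 1)))
  expect_true(detect_loh(GENE, seg(2.0, 0.0)))    # copy-neutral LOH
  expect_false(detect_loh(GENE, seg(2.0, 0.2)))
  expect_false(detect_loh(GENE, seg(2.0, 1.0)))
  no_cover <- data.frame(chrom = "chr1", start = 0, end = 100,
                         total_cn = 2, minor_cn = 1)
  expect_error(detect_deep_deletion(GENE, no_cover), "coverage gap")
})

test_that("biallelic status takes the highest-scoring event pair", {
  # deep deletion dominates: BP 10
  st <- determine_biallelic_status(GENE, seg(0.1, 0))
  expect_identical(st$bp_score, 10L)
  expect_true(st$deficient)
  expect_identical(st$event_a$type, "deep_deletion")
  # LOH + germline pathogenic: 5 + 5
  st2 <- determine_biallelic_status(GENE, seg(1, 0),
                                    gvar("germline", "pathogenic"))
  expect_identical(st2$bp_score, 10L)
  expect_true(st2$deficient)
  expect_identical(st2$event_a$type, "LOH")
  # two somatic VUS: 3 + 3
  st3 <- determine_biallelic_status(
    GENE, seg(2, 1),
    rbind(gvar("somatic", effect = "missense", pos = 32350000),
          gvar("somatic", effect = "missense", pos = 32360000)))
  expect_identical(st3$bp_score, 6L)
  expect_false(st3$deficient)
  # two germline variants never form a biallelic pair
  st4 <- determine_biallelic_status(
    GENE, seg(2, 1),
    rbind(gvar("germline", "pathogenic", pos = 32350000),
          gvar("germline", "pathogenic", pos = 32360000)))
  expect_false(st4$biallelic)
  # LOH alone is monoallelic
  st5 <- determine_biallelic_status(GENE, seg(2, 0))
  expect_false(st5$biallelic)
  expect_identical(st5$bp_score, 5L)
})

test_that("training labels require BP = 10, no MSI, and clean proficiency", {
  st_def <- determine_biallelic_status(GENE, seg(0.1, 0))
  st_prof <- determine_biallelic_status(GENE, seg(2, 1),
                                        gvar("germline", "benign"))
  st_vus <- determine_biallelic_status(GENE, seg(2, 1),
                                       gvar("somatic", effect = "missense"))
  st_loh <- determine_biallelic_status(GENE, seg(2, 0))
  labs <- label_training_samples(
    status_brca1 = list(st_prof, st_prof, st_def, st_prof, st_prof),
    status_brca2 = list(st_def, st_def, st_prof, st_vus, st_loh),
    msi = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(labs, c("BRCA2", NA, "BRCA1", "none", NA))
})

test_that("cause calling applies the looser biallelic-loss thresholds", {
  # LOH + germline P>=4
  expect_true(call_hrd_cause(GENE, seg(1, 0),
                             gvar("germline", "likely_pathogenic"))$biallelic)
  # LOH + germline P=3 is below the germline threshold
  expect_false(call_hrd_cause(GENE, seg(1, 0),
                              gvar("germline", "VUS"))$biallelic)
  # LOH + somatic P>=3 qualifies
  r <- call_hrd_cause(GENE, seg(1, 0), gvar("somatic", "VUS"))
  expect_true(r$biallelic)
  expect_identical(r$rule, "loh_somatic")
  # two pathogenic variants (germline + somatic)
  r2 <- call_hrd_cause(
    GENE, seg(2, 1),
    rbind(gvar("germline", "pathogenic", pos = 32350000),
          gvar("somatic", effect = "frameshift_oof", pos = 32360000)))
  expect_true(r2$biallelic)
  expect_identical(r2$rule, "two_pathogenic")
  expect_true(r2$germline_involved)
  # cause thresholds are a superset of the training definition
  st <- determine_biallelic_status(GENE, seg(1, 0),
                                   gvar("germline", "pathogenic"))
  expect_true(st$deficient)
  expect_true(call_hrd_cause(GENE, seg(1, 0),
                             gvar("germline", "pathogenic"))$biallelic)
})

test_that("planted gene events are recovered exactly", {
  events <- c("deep_deletion", "loh_germline_pathogenic",
              "loh_somatic_frameshift", "pathogenic_pair",
              "somatic_vus_pair", "benign_only", "none")
  for (ev in events) {
    pl <- plant_gene_events(GENE, ev, seed = 5)
    st <- determine_biallelic_status(GENE, pl$segments, pl$variants)
    expect_identical(st$bp_score, pl$expected$bp_score, label = ev)
    expect_identical(st$deficient, pl$expected$deficient, label = ev)
  }
})
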