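test_that("enrichment p-values equal the hypergeometric tail sum", {
  # HRD 8/10 deficient vs HRP 1/10
  def <- matrix(FALSE, 20, 2, dimnames = list(NULL, c("g1", "g2")))
  def[1:8, 1] <- TRUE; def[11, 1] <- TRUE
  hrd <- rep(c(TRUE, FALSE), each = 10)
  res <- enrichment_test(def, hrd)
  p_or <- oracle_fisher_greater(a = 8, K = 9, n = 10, N = 20)
  expect_equal(res$p[res$gene == "g1"], p_or, tolerance = 1e-12)
  # a gene deficient in no sample: degenerate table, p = 1
  expect_equal(res$p[res$gene == "g2"], 1)
  expect_error(enrichment_test(def, rep(TRUE, 20)), "HRP")
})

test_that("Fisher p-values match enumeration across many small tables", {
  for (N in c(10, 20, 40)) {
    for (K in seq(0, N, by = max(2, N / 5))) {
      for (n in seq(2, N - 2, by = max(2, N / 5))) {
        for (a in max(0, n - (N - K)):min(K, n)) {
          m <- matrix(c(a, n - a, K - a, N - K - n + a), nrow = 2)
          if (any(m < 0)) next
          p_pkg <- if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
            1
          } else {
            fisher.test(m, alternative = "greater")$p.value
          }
          expect_equal(p_pkg, oracle_fisher_greater(a, K, n, N),
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("Hochberg adjustment matches the hand-computed step-up", {
  p <- c(0.001, 0.013, 0.04, 0.02, 0.7)
  # step-up by hand: sort increasingly, q_(i) = min over j >= i of
  # (m - j + 1) * p_(j), capped at 1, mapped back to input order
  o <- order(p)
  ps <- p[o]
  m <- length(p)
  q_sorted <- rev(cummin(rev((m - seq_len(m) + 1) * ps)))
  q_hand <- numeric(m)
  q_hand[o] <- pmin(q_sorted, 1)
  expect_equal(p.adjust(p, method = "hochberg"), q_hand)
  # q >= p and invariant to input ordering
  def <- matrix(runif(100) < 0.3, 20, 5,
                dimnames = list(NULL, paste0("g", 1:5)))
  hrd <- rep(c(TRUE, FALSE), 10)
  r1 <- enrichment_test(def, hrd)
  expect_true(all(r1$q >= r1$p))
  perm <- c(3, 1, 5, 2, 4)
  r2 <- enrichment_test(def[, perm], hrd)
  expect_equal(r1[order(r1$gene), c("p", "q")],
               r2[order(r2$gene), c("p", "q")], ignore_attr = TRUE)
})

test_that("CNA co-occurrence flags positional confounds", {
  set.seed(33)
  n <- 60
  anchor <- runif(n) < 0.3
  neighbor <- anchor                      # always co-altered (same locus)
  indep <- runif(n) < 0.3
  cna <- cbind(BRCA1 = anchor, NF1 = neighbor, OTHER = indep)
  res <- cna_cooccurrence_test(cna, anchors = "BRCA1")
  q <- setNames(res$q, res$gene)
  expect_lt(q[["NF1"]], 0.01)
  expect_gt(q[["OTHER"]], 0.05)
  # the anchor against itself is maximally co-occurrent
  expect_equal(min(res$p), res$p[res$gene == "BRCA1"])
})

test_that("HRD sample clustering reproduces the hand-traced layout", {
  call_row <- function(s, sub, gene, bp, pmax, pmin, ev) {
    data.frame(sample = s, subtype = sub, gene = gene, bp_score = bp,
               p_max = pmax, p_min = pmin, event_class = ev,
               stringsAsFactors = FALSE)
  }
  blank <- function(s, sub) {
    do.call(rbind, lapply(c("BRCA2", "BRCA1", "RAD51C", "PALB2"),
                          function(g) call_row(s, sub, g, 0, 0, 0, "none")))
  }
  with_hit <- function(s, sub, gene, ev) {
    rows <- blank(s, sub)
    rows[rows$gene == gene, c("bp_score", "p_max", "p_min")] <-
      list(10, 5, 5)
    rows$event_class[rows$gene == gene] <- ev
    rows
  }
  calls <- rbind(
    with_hit("s1", "BRCA2-type", "BRCA2", "loh_frameshift"),
    with_hit("s2", "BRCA2-type", "BRCA2", "deep_deletion"),
    with_hit("s3", "BRCA2-type", "RAD51C", "loh_other"),
    with_hit("s4", "BRCA1-type", "BRCA1", "loh_frameshift"),
    blank("s5", "BRCA2-type"),
    blank("s6", "BRCA1-type")
  )
  res <- cluster_hrd_samples(calls)
  # expected: cluster 1 = BRCA2 (s2 first: deep deletion ranks above
  # LOH+frameshift), 2 = RAD51C, 3 = BRCA2-type unknown, 4 = BRCA1,
  # 5 = BRCA1-type unknown
  expect_identical(res$sample, c("s2", "s1", "s3", "s5", "s4", "s6"))
  expect_identical(res$cluster, c(1L, 1L, 2L, 3L, 4L, 5L))
  expect_identical(res$gene, c("BRCA2", "BRCA2", "RAD51C", NA, "BRCA1", NA))
  # every sample appears exactly once
  expect_identical(sort(res$sample), paste0("s", 1:6))

  # all samples lacking impactful events: exactly one cluster per subtype
  calls2 <- rbind(blank("a", "BRCA2-type"), blank("b", "BRCA2-type"),
                  blank("c", "BRCA1-type"))
  res2 <- cluster_hrd_samples(calls2)
  expect_identical(unique(res2$cluster[res2$subtype == "BRCA2-type"]), 1L)
  expect_identical(unique(res2$cluster[res2$subtype == "BRCA1-type"]), 2L)

  # permuting input rows leaves the clustering unchanged
  set.seed(2)
  res3 <- cluster_hrd_samples(calls[sample(nrow(calls)), ])
  expect_identical(res, res3)
})
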