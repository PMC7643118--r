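# Cohort-level statistics: gene-deficiency enrichment in HRD vs HRP
# samples, copy-number-alteration co-occurrence confound testing, and the
# clustered sample ordering of HRD samples by causal gene.

.one_tailed_fisher <- function(in_a_and_b, in_a, in_b, n) {
  m <- matrix(c(in_a_and_b, in_b - in_a_and_b,
                in_a - in_a_and_b, n - in_a - in_b + in_a_and_b), nrow = 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  fisher.test(m, alternative = "greater")$p.value
}

#' Test per-gene deficiency enrichment in HRD vs HRP samples
#'
#' For each gene, a one-tailed Fisher's exact test of whether biallelic
#' inactivation occurs more often among HRD-classified than HRP-classified
#' samples, with step-up Hochberg correction across all tested genes.
#' Degenerate tables (e.g. a gene deficient in no sample) give p = 1.
#'
#' @param deficiency Samples-by-genes logical matrix (`TRUE` = biallelic
#'   inactivation detected).
#' @param hrd Logical vector, `TRUE` for HRD-classified samples.
#' @return `data.frame` with one row per gene: deficiency counts in each
#'   group, one-tailed `p`, and Hochberg-adjusted `q`, sorted by `p`.
#' @export
enrichment_test <- function(deficiency, hrd) {
  deficiency <- as.matrix(deficiency)
  hrd <- as.logical(hrd)
  stopifnot(nrow(deficiency) == length(hrd))
  if (!any(hrd) || all(hrd)) stop("need at least one HRD and one HRP sample")
  n <- length(hrd)
  p <- vapply(seq_len(ncol(deficiency)), function(j) {
    d <- deficiency[, j]
    .one_tailed_fisher(sum(d & hrd), sum(d), sum(hrd), n)
  }, numeric(1))
  out <- data.frame(
    gene = colnames(deficiency),
    n_def_hrd = colSums(deficiency & hrd),
    n_def_hrp = colSums(deficiency & !hrd),
    n_hrd = sum(hrd), n_hrp = sum(!hrd),
    p = p, q = p.adjust(p, method = "hochberg"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(out$p, out$gene), ]
}

#' Test co-occurrence of copy-number alterations with an anchor gene
#'
#' Genes that merely neighbor a driver on the same chromosome arm inherit
#' its deep deletions and LOH; their apparent enrichment is a positional
#' confound. For each gene, a one-tailed Fisher's exact test asks whether a
#' copy-number alteration (deep deletion or LOH) co-occurs with an
#' alteration in the anchor gene more often than expected, with Hochberg
#' correction per anchor.
#'
#' @param cna Samples-by-genes logical matrix of copy-number alterations.
#' @param anchors Character vector of anchor gene names (columns of `cna`).
#' @return `data.frame` with columns `anchor`, `gene`, co-occurrence
#'   counts, `p` and `q` (Hochberg within anchor).
#' @export
cna_cooccurrence_test <- function(cna, anchors = c("BRCA1", "BRCA2")) {
  cna <- as.matrix(cna)
  stopifnot(all(anchors %in% colnames(cna)))
  n <- nrow(cna)
  res <- lapply(anchors, function(anchor) {
    a <- cna[, anchor]
    p <- vapply(seq_len(ncol(cna)), function(j) {
      g <- cna[, j]
      .one_tailed_fisher(sum(g & a), sum(g), sum(a), n)
    }, numeric(1))
    data.frame(anchor = anchor, gene = colnames(cna),
               n_both = colSums(cna & a), n_gene = colSums(cna),
               n_anchor = sum(a), p = p,
               q = p.adjust(p, method = "hochberg"),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$anchor, out$p, out$gene), ]
}

.HRD_GENE_PRIORITY <- c("BRCA2", "BRCA1", "RAD51C", "PALB2")

.EVENT_RANK <- c(deep_deletion = 1, loh_frameshift = 2, loh_other = 3,
                 variant_pair = 4, none = 5)

#' Cluster HRD samples by causal gene
#'
#' Orders HRD-classified samples into the clustered layout used to display
#' the genetic causes of HRD. Samples are split into four groups by HRD
#' subtype and by whether they carry an impactful biallelic event (a
#' best-pair P-score combination of 5 and >= 3 in any HRD-associated gene).
#' Within each impactful group the gene with the maximal BP-score is
#' greedily assigned per sample, with ties resolved by the priority
#' BRCA2 > BRCA1 > RAD51C > PALB2 (highest to lowest cohort enrichment);
#' sorting the resulting 0/1 assignment matrix groups consecutive samples
#' of the same gene into clusters, with a cosmetic within-cluster ranking
#' of deep deletions first, then LOH + frameshift, then LOH + other
#' variants. Each non-impactful group (unknown cause) forms one cluster.
#' Group order: BRCA2-type impactful, BRCA2-type unknown, BRCA1-type
#' impactful, BRCA1-type unknown.
#'
#' @param calls `data.frame` with one row per sample-gene combination:
#'   columns `sample`, `subtype` (`"BRCA1-type"`/`"BRCA2-type"`), `gene`,
#'   `bp_score`, `p_max`, `p_min` (the best pair's two P-scores) and
#'   `event_class` (one of `"deep_deletion"`, `"loh_frameshift"`,
#'   `"loh_other"`, `"variant_pair"`, `"none"`).
#' @param genes Gene priority order.
#' @return `data.frame` with one row per sample: `sample`, `subtype`,
#'   `gene` (assigned causal gene or `NA` for unknown-cause clusters) and
#'   `cluster` (integer id), in display order.
#' @export
cluster_hrd_samples <- function(calls, genes = .HRD_GENE_PRIORITY) {
  stopifnot(all(c("sample", "subtype", "gene", "bp_score",
                  "p_max", "p_min", "event_class") %in% names(calls)))
  calls <- calls[calls$gene %in% genes, , drop = FALSE]
  samples <- sort(unique(calls$sample))
  per_sample <- lapply(samples, function(s) {
    cs <- calls[calls$sample == s, , drop = FALSE]
    bp <- setNames(rep(0, length(genes)), genes)
    ev <- setNames(rep("none", length(genes)), genes)
    bp[cs$gene] <- cs$bp_score
    ev[cs$gene] <- cs$event_class
    impactful <- any(cs$p_max == 5 & cs$p_min >= 3, na.rm = TRUE)
    assigned <- genes[which.max(bp)]  # ties: first in priority order
    list(sample = s, subtype = cs$subtype[1], impactful = impactful,
         gene = assigned, gene_idx = which.max(bp),
         rank = unname(.EVENT_RANK[ev[assigned]]))
  })
  df <- do.call(rbind, lapply(per_sample, function(x) {
    data.frame(sample = x$sample, subtype = x$subtype,
               impactful = x$impactful, gene = x$gene,
               gene_idx = x$gene_idx, rank = x$rank,
               stringsAsFactors = FALSE)
  }))
  groups <- list(
    list(subtype = "BRCA2-type", impactful = TRUE),
    list(subtype = "BRCA2-type", impactful = FALSE),
    list(subtype = "BRCA1-type", impactful = TRUE),
    list(subtype = "BRCA1-type", impactful = FALSE)
  )
  out <- list()
  cluster_id <- 0L
  for (g in groups) {
    sub <- df[df$subtype == g$subtype & df$impactful == g$impactful, ,
              drop = FALSE]
    if (nrow(sub) == 0) next
    if (g$impactful) {
      sub <- sub[order(sub$gene_idx, sub$rank, sub$sample), , drop = FALSE]
      runs <- rle(sub$gene)
      sub$cluster <- cluster_id + rep(seq_along(runs$lengths), runs$lengths)
      cluster_id <- cluster_id + length(runs$lengths)
    } else {
      sub <- sub[order(sub$sample), , drop = FALSE]
      cluster_id <- cluster_id + 1L
      sub$cluster <- cluster_id
      sub$gene <- NA_character_  # unknown cause
    }
    out[[length(out) + 1L]] <- sub
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("sample", "subtype", "gene", "cluster")]
}
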