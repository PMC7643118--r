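# Per-gene biallelic inactivation: copy-number events (deep deletion, LOH),
# variant pathogenicity P-scores, biallelic pathogenicity (BP) scores,
# training-label derivation and HRD cause calling.

.CLINVAR_P <- c(pathogenic = 5, likely_pathogenic = 4, VUS = 3,
                likely_benign = 2, benign = 1)
.EFFECT_P <- c(frameshift_oof = 5, nonsense = 4, splice = 4,
               missense = 3, essential_splice = 3, inframe = 3, other = 2)

#' Assign a pathogenicity score (P-score) to an annotated variant
#'
#' Scores run from 1 (benign) to 5 (pathogenic). A clinical-database
#' annotation takes precedence: pathogenic = 5, likely pathogenic = 4,
#' VUS = 3, likely benign = 2, benign = 1. Without one, the predicted
#' effect class is used: out-of-frame frameshift = 5, nonsense/splice = 4,
#' missense/essential splice/inframe = 3, other low-impact types = 2.
#' High-frequency germline variants pre-marked as common are forced to 0.
#'
#' @param clinvar_class `"pathogenic"`, `"likely_pathogenic"`, `"VUS"`,
#'   `"likely_benign"`, `"benign"`, or `NA`/`"absent"` for no entry.
#' @param effect_class `"frameshift_oof"`, `"nonsense"`, `"splice"`,
#'   `"missense"`, `"essential_splice"`, `"inframe"`, `"other"`, or `NA`.
#' @param common_germline Logical; `TRUE` marks a high-frequency germline
#'   variant (scored 0 regardless of annotation).
#' @return Integer P-score in 0..5. At least one annotation is required.
#' @export
assign_p_score <- function(clinvar_class = NA, effect_class = NA,
                           common_germline = FALSE) {
  if (isTRUE(common_germline)) return(0L)
  cv <- if (!is.na(clinvar_class) && clinvar_class != "absent") {
    clinvar_class
  } else NA
  if (!is.na(cv)) {
    if (!cv %in% names(.CLINVAR_P)) stop("unknown clinical class: ", cv)
    return(as.integer(.CLINVAR_P[[cv]]))
  }
  if (is.na(effect_class)) stop("variant carries no annotation at all")
  if (!effect_class %in% names(.EFFECT_P)) {
    stop("unknown effect class: ", effect_class)
  }
  as.integer(.EFFECT_P[[effect_class]])
}

# Add a p_score column to a variants data.frame (recognizes an optional
# logical `common_germline` column for the cohort-frequency benign rule).
.score_variants <- function(variants) {
  if (is.null(variants) || nrow(variants) == 0) {
    return(cbind(variants, p_score = integer(0)))
  }
  cg <- if ("common_germline" %in% names(variants)) {
    variants$common_germline
  } else rep(FALSE, nrow(variants))
  cvc <- if ("clinvar_class" %in% names(variants)) {
    variants$clinvar_class
  } else rep(NA_character_, nrow(variants))
  efc <- if ("effect_class" %in% names(variants)) {
    variants$effect_class
  } else rep(NA_character_, nrow(variants))
  variants$p_score <- vapply(seq_len(nrow(variants)), function(i) {
    assign_p_score(cvc[i], efc[i], isTRUE(cg[i]))
  }, integer(1))
  variants
}

.gene_segments <- function(gene, segments) {
  hit <- segments$chrom == gene$chrom &
    segments$end > gene$start & segments$start < gene$end
  if (!any(hit)) {
    stop("no copy-number segment overlaps gene ", gene$gene,
         " (coverage gap)")
  }
  segments[hit, , drop = FALSE]
}

#' Detect a deep deletion over a gene region
#'
#' A gene is deeply deleted (both copies lost) when the minimum total copy
#' number over the segments overlapping its transcript span falls below
#' `threshold` (default 0.3, strict inequality); partial overlap counts.
#' A gene with no overlapping segment is a coverage-gap error.
#'
#' @param gene One-row `data.frame` with `gene`, `chrom`, `start`, `end`.
#' @param segments Copy-number segments (`chrom`, `start`, `end`,
#'   `total_cn`, `minor_cn`).
#' @param threshold Copy-number threshold.
#' @return Logical.
#' @export
detect_deep_deletion <- function(gene, segments, threshold = 0.3) {
  min(.gene_segments(gene, segments)$total_cn) < threshold
}

#' Detect loss of heterozygosity over a gene region
#'
#' LOH (including copy-neutral LOH) is called when the minimum minor-allele
#' copy number over the segments overlapping the gene falls below
#' `threshold` (default 0.2, strict inequality).
#'
#' @inheritParams detect_deep_deletion
#' @return Logical.
#' @export
detect_loh <- function(gene, segments, threshold = 0.2) {
  min(.gene_segments(gene, segments)$minor_cn) < threshold
}

.event_label <- function(ev) {
  if (ev$type == "deep_deletion") return("deep_deletion")
  if (ev$type == "LOH") return("LOH")
  paste0("variant(", ev$origin, ", P=", ev$p, ")")
}

#' Determine the biallelic status of a gene in one sample
#'
#' A deep deletion inactivates both alleles and scores BP = 10 directly.
#' Otherwise the gene is screened for two-event combinations: LOH (scored
#' P = 5) paired with a germline or somatic SNV/indel, a germline plus a
#' somatic SNV/indel, or two somatic SNV/indels. The pair P-scores are
#' summed into the biallelic pathogenicity score (BP-score, max 10) and the
#' highest-scoring pair is taken; equal scores are broken greedily in the
#' order deep deletion > LOH + frameshift > LOH + other variant > variant
#' pairs. With fewer than two events the gene is monoallelic and the
#' BP-score is the best single event's P-score.
#'
#' @inheritParams detect_deep_deletion
#' @param variants `data.frame` of annotated small variants with columns
#'   `chrom`, `pos`, `origin` (`"germline"`/`"somatic"`) and annotation
#'   columns understood by [assign_p_score()] (or a precomputed `p_score`).
#'   Variants outside the gene span are ignored.
#' @param cn_deep,cn_loh Copy-number thresholds for deep deletion and LOH.
#' @return List of class `gene_status`: `gene`, `bp_score`, `deficient`
#'   (BP = 10), `biallelic`, `event_a`/`event_b`, and the raw flags
#'   `deep_deletion`, `loh`, `max_variant_p` used by the training-label
#'   rules.
#' @export
determine_biallelic_status <- function(gene, segments, variants = NULL,
                                       cn_deep = 0.3, cn_loh = 0.2) {
  deep <- detect_deep_deletion(gene, segments, cn_deep)
  loh <- detect_loh(gene, segments, cn_loh)
  if (!is.null(variants) && nrow(variants) > 0) {
    keep <- variants$chrom == gene$chrom &
      variants$pos >= gene$start & variants$pos <= gene$end
    variants <- variants[keep, , drop = FALSE]
  }
  variants <- .score_variants(variants)
  nv <- if (is.null(variants)) 0L else nrow(variants)
  max_p <- if (nv > 0) max(variants$p_score) else 0L
  res <- list(gene = gene$gene, deep_deletion = deep, loh = loh,
              n_variants = nv, max_variant_p = max_p)

  mkvar <- function(i) list(type = "variant", origin = variants$origin[i],
                            p = variants$p_score[i], index = i)
  if (deep) {
    res <- c(res, list(bp_score = 10L, deficient = TRUE, biallelic = TRUE,
                       event_a = list(type = "deep_deletion", p = 5L),
                       event_b = list(type = "deep_deletion", p = 5L)))
    class(res) <- "gene_status"
    return(res)
  }
  # candidate pairs in greedy tie-break order
  pairs <- list()
  if (loh && nv > 0) {
    fs <- which(!is.na(variants$effect_class) &
                  variants$effect_class == "frameshift_oof")
    rest <- setdiff(seq_len(nv), fs)
    ord <- c(fs[order(-variants$p_score[fs])],
             rest[order(-variants$p_score[rest])])
    for (i in ord) {
      pairs[[length(pairs) + 1L]] <-
        list(a = list(type = "LOH", p = 5L), b = mkvar(i))
    }
  }
  if (nv > 1) {
    for (i in seq_len(nv - 1)) for (j in (i + 1):nv) {
      if (variants$origin[i] == "germline" &&
          variants$origin[j] == "germline") next  # two germline: one allele
      pairs[[length(pairs) + 1L]] <- list(a = mkvar(i), b = mkvar(j))
    }
  }
  if (length(pairs) > 0) {
    scores <- vapply(pairs, function(p) p$a$p + p$b$p, numeric(1))
    best <- pairs[[which.max(scores)]]  # first max: greedy order above
    bp <- as.integer(max(scores))
    res <- c(res, list(bp_score = bp, deficient = bp == 10L,
                       biallelic = TRUE, event_a = best$a, event_b = best$b))
  } else {
    # monoallelic (or no event at all)
    single <- if (loh) {
      list(type = "LOH", p = 5L)
    } else if (nv > 0) {
      mkvar(which.max(variants$p_score))
    } else NULL
    res <- c(res, list(bp_score = if (is.null(single)) 0L else single$p,
                       deficient = FALSE, biallelic = FALSE,
                       event_a = single, event_b = NULL))
  }
  class(res) <- "gene_status"
  res
}

#' @export
print.gene_status <- function(x, ...) {
  cat("Gene", x$gene, "- BP-score", x$bp_score,
      if (x$deficient) "(biallelically inactivated)"
      else if (x$biallelic) "(biallelic events, sub-pathogenic)"
      else "(no biallelic event)", "\n")
  if (!is.null(x$event_a)) cat("  event A:", .event_label(x$event_a), "\n")
  if (!is.null(x$event_b)) cat("  event B:", .event_label(x$event_b), "\n")
  invisible(x)
}

#' Derive training labels from BRCA1/2 gene status
#'
#' A sample is labeled `"BRCA1"` or `"BRCA2"` when exactly one of the two
#' genes is biallelically inactivated (BP-score = 10) and the sample is not
#' microsatellite-instable. It is labeled `"none"` (HR proficient) when both
#' genes show no deep deletion, no LOH, and no variant with P-score above 3
#' (variant of unknown significance or lower). All other samples — MSI,
#' intermediate evidence, or deficiency of both genes — are left unlabeled
#' (`NA`) and excluded from training.
#'
#' @param status_brca1,status_brca2 Lists of [determine_biallelic_status()]
#'   results, one element per sample.
#' @param msi Logical vector of per-sample MSI flags (see [detect_msi()]).
#' @return Character vector of `"BRCA1"`, `"BRCA2"`, `"none"` or `NA`.
#' @export
label_training_samples <- function(status_brca1, status_brca2, msi) {
  stopifnot(length(status_brca1) == length(status_brca2),
            length(msi) == length(status_brca1))
  vapply(seq_along(msi), function(i) {
    b1 <- status_brca1[[i]]; b2 <- status_brca2[[i]]
    if (b1$deficient || b2$deficient) {
      if (isTRUE(msi[i])) return(NA_character_)
      if (b1$deficient && b2$deficient) return(NA_character_)
      return(if (b1$deficient) "BRCA1" else "BRCA2")
    }
    proficient <- function(g) {
      !g$deep_deletion && !g$loh && g$max_variant_p <= 3
    }
    if (proficient(b1) && proficient(b2)) return("none")
    NA_character_
  }, character(1))
}

#' Screen a gene for biallelic loss under the HRD cause-calling rules
#'
#' The thresholds used to explain the genetic cause of HRD are looser than
#' the training-set definition: biallelic loss is called for (i) a deep
#' deletion; (ii) LOH with a germline SNV/indel of P-score >= 4; (iii) LOH
#' with a somatic SNV/indel of P-score >= 3; or (iv) two SNV/indels
#' (germline + somatic, or two somatic) both with P-score = 5.
#' High-frequency germline variants should be pre-marked via the
#' `common_germline` column (scored 0).
#'
#' @inheritParams determine_biallelic_status
#' @return List: `gene`, `biallelic` (logical), `rule` (one of
#'   `"deep_deletion"`, `"loh_germline"`, `"loh_somatic"`,
#'   `"two_pathogenic"`, or `NA`), `germline_involved`, and the monoallelic
#'   evidence when no rule fires.
#' @export
call_hrd_cause <- function(gene, segments, variants = NULL,
                           cn_deep = 0.3, cn_loh = 0.2) {
  deep <- detect_deep_deletion(gene, segments, cn_deep)
  loh <- detect_loh(gene, segments, cn_loh)
  if (!is.null(variants) && nrow(variants) > 0) {
    keep <- variants$chrom == gene$chrom &
      variants$pos >= gene$start & variants$pos <= gene$end
    variants <- variants[keep, , drop = FALSE]
  }
  variants <- .score_variants(variants)
  nv <- if (is.null(variants)) 0L else nrow(variants)
  germ <- if (nv) variants$origin == "germline" else logical(0)
  p <- if (nv) variants$p_score else integer(0)

  out <- list(gene = gene$gene, biallelic = FALSE, rule = NA_character_,
              germline_involved = NA)
  if (deep) {
    out$biallelic <- TRUE; out$rule <- "deep_deletion"
    out$germline_involved <- FALSE
    return(out)
  }
  if (loh && any(germ & p >= 4)) {
    out$biallelic <- TRUE; out$rule <- "loh_germline"
    out$germline_involved <- TRUE
    return(out)
  }
  if (loh && any(!germ & p >= 3)) {
    out$biallelic <- TRUE; out$rule <- "loh_somatic"
    out$germline_involved <- FALSE
    return(out)
  }
  if (nv > 1) {
    i5 <- which(p == 5)
    # at least one valid pair: two somatic, or germline + somatic
    if (length(i5) >= 2 && sum(!germ[i5]) >= 1) {
      out$biallelic <- TRUE; out$rule <- "two_pathogenic"
      out$germline_involved <- any(germ[i5])
      return(out)
    }
  }
  out$monoallelic <- if (loh) "LOH" else if (nv && max(p) >= 4) {
    "pathogenic_variant"
  } else NA_character_
  out
}
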