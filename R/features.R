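# Collapse 142-category context profiles into the relative-contribution
# feature vectors used by the classifier.

#' Classifier feature names
#'
#' The 29 features: 6 base-substitution fractions, 7 indel fractions
#' (microhomology deletions split at 1 bp vs >= 2 bp of flanking homology;
#' the `del.mh.bimh.2.5` name denotes the 2-to->=5 bp bin), and the 16 SV
#' context fractions. Relative contributions are computed separately within
#' each of the three mutation classes, so each block sums to 1 (or is
#' all-zero when the sample has no mutations of that class). Feature order
#' is fixed (SNV, indel, SV blocks) so persisted models are portable.
#'
#' @param merge_mh If `TRUE`, return the 28 names of the variant with all
#'   microhomology deletions merged into a single `del.mh` feature.
#' @return Character vector of length 29 (or 28).
#' @export
hrd_feature_names <- function(merge_mh = FALSE) {
  snv6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  indel <- if (merge_mh) {
    c("del.mh", "ins.mh", "del.rep", "ins.rep", "del.none", "ins.none")
  } else {
    c("del.mh.bimh.1", "del.mh.bimh.2.5", "ins.mh",
      "del.rep", "ins.rep", "del.none", "ins.none")
  }
  c(snv6, indel, sv_context_keys())
}

.norm_block <- function(x) {
  tot <- sum(x)
  if (tot > 0) x / tot else x * 0
}

.collapse_profile <- function(profile, merge_mh = FALSE) {
  profile <- unclass(profile)
  snv_keys <- snv_context_keys()
  snv6 <- vapply(c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"), function(s) {
    sum(profile[snv_keys[substr(snv_keys, 3, 5) == s]])
  }, numeric(1))
  ik <- function(p) sum(profile[grep(p, indel_context_keys(), value = TRUE)])
  indel <- if (merge_mh) {
    c(del.mh = ik("^del\\.mh\\."), ins.mh = ik("^ins\\.mh\\."),
      del.rep = ik("^del\\.rep\\."), ins.rep = ik("^ins\\.rep\\."),
      del.none = ik("^del\\.none\\."), ins.none = ik("^ins\\.none\\."))
  } else {
    c(del.mh.bimh.1 = unname(profile["del.mh.bimh.1"]),
      del.mh.bimh.2.5 = sum(profile[paste0("del.mh.bimh.", 2:5)]),
      ins.mh = ik("^ins\\.mh\\."),
      del.rep = ik("^del\\.rep\\."), ins.rep = ik("^ins\\.rep\\."),
      del.none = ik("^del\\.none\\."), ins.none = ik("^ins\\.none\\."))
  }
  sv <- profile[sv_context_keys()]
  c(.norm_block(snv6), .norm_block(indel), .norm_block(sv))
}

#' Build the relative-contribution feature vector of a sample
#'
#' Collapses a 142-category context profile into the classifier features:
#' the 96 trinucleotide contexts are simplified to the six substitution
#' types, the 30 indel contexts to seven indel types (with microhomology
#' deletions split into 1 bp vs >= 2 bp homology bins), and the 16 SV
#' contexts are kept. Each block is then normalized by its own total, which
#' accounts for differences in mutational load across samples. An empty
#' mutation class yields an all-zero block (never `NaN`); the downstream QC
#' gate handles such samples.
#'
#' @param profile A [extract_profile()] result, or a samples-by-142 matrix
#'   of counts (rows are samples).
#' @return Named numeric vector of length 29 (or a samples-by-29 matrix).
#' @seealso [build_merged_mh_features()] for the 28-feature variant with a
#'   single merged `del.mh` feature.
#' @export
build_hrd_features <- function(profile) {
  .build_features(profile, merge_mh = FALSE)
}

#' Build the merged-microhomology feature variant
#'
#' As [build_hrd_features()] but with all microhomology deletions merged
#' into a single `del.mh` feature (28 features). Splitting by homology
#' length slightly reduces false positives from radiotherapy-induced 1 bp
#' homology deletions; this variant exists to quantify that effect.
#'
#' @inheritParams build_hrd_features
#' @return Named numeric vector of length 28 (or a samples-by-28 matrix).
#' @export
build_merged_mh_features <- function(profile) {
  .build_features(profile, merge_mh = TRUE)
}

.build_features <- function(profile, merge_mh) {
  if (is.matrix(profile) || is.data.frame(profile)) {
    profile <- as.matrix(profile)
    stopifnot(all(context_keys() %in% colnames(profile)))
    out <- t(apply(profile[, context_keys(), drop = FALSE], 1,
                   .collapse_profile, merge_mh = merge_mh))
    colnames(out) <- hrd_feature_names(merge_mh)
    return(out)
  }
  stopifnot(all(context_keys() %in% names(profile)))
  setNames(.collapse_profile(profile, merge_mh), hrd_feature_names(merge_mh))
}

#' Fit reference signatures to a mutation catalog by non-negative least squares
#'
#' Finds non-negative signature contributions minimizing the least-squares
#' residual between `signatures %*% x` and the catalog. Used by the
#' signature-based classifier variant, which replaces the SNV and SV context
#' blocks by fitted signature contributions (indel contexts are retained).
#'
#' @param catalog Non-negative numeric vector of context counts.
#' @param signatures Numeric matrix, contexts in rows (same order as
#'   `catalog`), signature profiles in columns.
#' @return Named non-negative vector of contributions (one per signature).
#' @export
fit_signatures_nnls <- function(catalog, signatures) {
  signatures <- as.matrix(signatures)
  if (length(catalog) != nrow(signatures)) {
    stop("catalog and signature matrix dimensions do not match")
  }
  if (any(catalog < 0)) stop("catalog counts must be non-negative")
  if (!is.null(names(catalog)) && !is.null(rownames(signatures)) &&
      !identical(names(catalog), rownames(signatures))) {
    stop("catalog and signature rows must share the same context ordering")
  }
  fit <- pracma::lsqnonneg(signatures, as.numeric(catalog))
  setNames(fit$x, colnames(signatures))
}

#' Build signature-based features for a sample
#'
#' The signature-variant feature construction: SNV context counts are fitted
#' to reference single-base-substitution signatures and SV context counts to
#' reference SV signatures by [fit_signatures_nnls()]; the seven indel-type
#' fractions are retained as-is. Each of the three blocks is normalized by
#' its own total.
#'
#' @param profile A [extract_profile()] result.
#' @param snv_signatures Matrix of SBS signatures over the 96 SNV contexts
#'   (rows in [snv_context_keys()] order).
#' @param sv_signatures Matrix of SV signatures over the 16 SV contexts
#'   (rows in [sv_context_keys()] order).
#' @return Named numeric feature vector.
#' @export
build_signature_features <- function(profile, snv_signatures, sv_signatures) {
  snv <- fit_signatures_nnls(unclass(profile)[snv_context_keys()],
                             snv_signatures)
  sv <- fit_signatures_nnls(unclass(profile)[sv_context_keys()],
                            sv_signatures)
  indel <- .collapse_profile(profile)[hrd_feature_names()[7:13]]
  c(.norm_block(snv), indel, .norm_block(sv))
}
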