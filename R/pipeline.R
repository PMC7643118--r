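# End-to-end pipeline: per-sample VCFs -> context profiles -> features ->
# HRD predictions (+ QC), optional biallelic gene status and enrichment,
# with a machine-readable run manifest.

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    lines <- readLines(config)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    config <- setNames(lapply(kv, function(x) {
      trimws(paste(x[-1], collapse = "="))
    }), trimws(vapply(kv, `[[`, character(1), 1)))
  }
  config
}

#' Run the end-to-end HRD pipeline
#'
#' Wires the modules together for a cohort: reads per-sample small-variant
#' and SV VCFs, extracts context profiles, builds the 29 features, predicts
#' HR status with a fitted model, applies the QC gate, optionally calls
#' per-gene biallelic status (when a gene table and per-sample copy-number
#' files are provided) and tests gene-deficiency enrichment in HRD vs HRP
#' samples. All stage outputs are written as TSV plus a JSON run manifest
#' (inputs, seed, thresholds, package version) so a rerun with the same
#' manifest reproduces identical outputs.
#'
#' @param config Named list (or path to a flat `key = value` file) with
#'   entries: `ref` (FASTA path or [ref_genome()]), `sample_sheet` (path to
#'   a TSV with columns `sample`, `vcf`, `sv_vcf`, and optionally `cn` for
#'   copy-number TSVs), `model` (path to a model written by
#'   [write_hrdforest()], or an `hrdforest` object), `out_dir`, and
#'   optionally `gene_table` (path) and `seed`.
#' @return Invisible list with the per-stage tables and output paths.
#' @export
run_pipeline <- function(config) {
  config <- .read_config(config)
  for (need in c("ref", "sample_sheet", "model", "out_dir")) {
    if (is.null(config[[need]])) stop("config is missing '", need, "'")
  }
  genome <- ref_genome(config$ref)
  sheet <- if (is.data.frame(config$sample_sheet)) {
    config$sample_sheet
  } else {
    read.delim(config$sample_sheet, stringsAsFactors = FALSE)
  }
  model <- if (inherits(config$model, "hrdforest")) {
    config$model
  } else {
    read_hrdforest(config$model)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  profiles <- matrix(0L, nrow = nrow(sheet), ncol = length(context_keys()),
                     dimnames = list(sheet$sample, context_keys()))
  skipped <- integer(nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    sv <- read_small_variant_vcf(sheet$vcf[i])
    svs <- if (!is.null(sheet$sv_vcf) && nzchar(sheet$sv_vcf[i])) {
      read_sv_vcf(sheet$sv_vcf[i])
    } else NULL
    prof <- extract_profile(sv, svs, genome)
    profiles[i, ] <- prof
    skipped[i] <- attr(prof, "n_skipped") + attr(sv, "n_skipped") +
      if (is.null(svs)) 0L else attr(svs, "n_skipped")
  }
  features <- build_hrd_features(profiles)
  preds <- predict(model, features)
  preds$qc <- vapply(seq_len(nrow(sheet)), function(i) {
    flags <- apply_qc(profiles[i, ], preds$hr_status[i])
    if (length(flags)) paste(flags, collapse = ";") else "PASS"
  }, character(1))

  write_profile_tsv(profiles, file.path(out_dir, "profiles.tsv"))
  write.table(data.frame(sample = rownames(features), features,
                         check.names = FALSE),
              file.path(out_dir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(preds, file.path(out_dir, "predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  gene_status <- NULL
  enrichment <- NULL
  if (!is.null(config$gene_table) && !is.null(sheet$cn)) {
    genes <- if (is.data.frame(config$gene_table)) {
      config$gene_table
    } else {
      read_gene_table(config$gene_table)
    }
    rows <- list()
    for (i in seq_len(nrow(sheet))) {
      segs <- read_copynumber_tsv(sheet$cn[i])
      variants <- read_small_variant_vcf(sheet$vcf[i])
      variants$origin <- "somatic"
      variants$effect_class <- "other"
      for (gi in seq_len(nrow(genes))) {
        st <- tryCatch(
          determine_biallelic_status(genes[gi, ], segs, variants),
          error = function(e) NULL)
        if (is.null(st)) next
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sheet$sample[i], gene = st$gene,
          bp_score = st$bp_score, deficient = st$deficient,
          stringsAsFactors = FALSE)
      }
    }
    gene_status <- do.call(rbind, rows)
    write.table(gene_status, file.path(out_dir, "gene_status.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    def <- with(gene_status,
                tapply(deficient, list(sample, gene), any))
    def <- def[sheet$sample, , drop = FALSE]
    def[is.na(def)] <- FALSE
    hrd <- preds$hr_status == "HRD"
    if (any(hrd) && !all(hrd)) {
      enrichment <- enrichment_test(def, hrd)
      write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- list(
    package = "hrdforest",
    version = as.character(packageVersion("hrdforest")),
    seed = config$seed,
    n_samples = nrow(sheet),
    n_skipped_records = sum(skipped),
    cutoff = model$cutoff,
    model_features = model$features,
    inputs = list(sample_sheet = if (is.character(config$sample_sheet)) {
      config$sample_sheet
    } else "in-memory",
      ref = if (is.character(config$ref)) config$ref else "in-memory")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(profiles = profiles, features = features,
                 predictions = preds, gene_status = gene_status,
                 enrichment = enrichment, out_dir = out_dir))
}
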