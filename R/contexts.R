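# Mutation-context classification: 96 SNV trinucleotide contexts, 30 indel
# contexts (microhomology / tandem-repeat / neither, binned by homology length
# or indel length), and 16 SV type-by-length contexts.

.BASES <- c("A", "C", "G", "T")

.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  paste(rev(.comp[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

#' Context key enumerations
#'
#' The fixed category universes used throughout the package: 96 single
#' nucleotide variant (SNV) trinucleotide contexts (pyrimidine reference,
#' e.g. `"A[C>T]G"`), 30 indel contexts (`del.mh`/`ins.mh` binned by number
#' of bases in microhomology, `del.rep`/`ins.rep`/`del.none`/`ins.none`
#' binned by indel length; bin 5 means "5 or more"), and 16 structural
#' variant (SV) contexts (DEL/DUP/INV by length decade from 1 kb to >10 Mb,
#' plus TRA). `context_keys()` concatenates all 142 in canonical order.
#'
#' @return Character vector of category keys.
#' @export
snv_context_keys <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) for (f in .BASES) for (t in .BASES) {
    out <- c(out, paste0(f, "[", s, "]", t))
  }
  out
}

#' @rdname snv_context_keys
#' @export
indel_context_keys <- function() {
  b <- 1:5
  c(paste0("del.mh.bimh.", b), paste0("ins.mh.bimh.", b),
    paste0("del.rep.len.", b), paste0("ins.rep.len.", b),
    paste0("del.none.len.", b), paste0("ins.none.len.", b))
}

#' @rdname snv_context_keys
#' @export
sv_context_keys <- function() {
  bins <- c("1e03_1e04_bp", "1e04_1e05_bp", "1e05_1e06_bp",
            "1e06_1e07_bp", "1e07_Inf_bp")
  c(paste0("DEL_", bins), paste0("DUP_", bins), paste0("INV_", bins), "TRA")
}

#' @rdname snv_context_keys
#' @export
context_keys <- function() {
  c(snv_context_keys(), indel_context_keys(), sv_context_keys())
}

#' Reference sequence store
#'
#' Wraps a reference genome as named uppercase character strings with a
#' 0-based half-open substring accessor. Accepts a named character vector,
#' a [Biostrings::DNAStringSet], or a path to a FASTA file.
#'
#' @param x Named character vector of contig sequences, `DNAStringSet`, or
#'   FASTA path.
#' @return An object of class `ref_genome`.
#' @export
ref_genome <- function(x) {
  if (inherits(x, "ref_genome")) return(x)
  if (is.character(x) && length(x) == 1 && is.null(names(x)) && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (inherits(x, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(x))
    x <- setNames(as.character(x), nm)
  }
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("ref_genome() needs named contig sequences")
  }
  structure(list(seqs = toupper(x)), class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("Reference sequence store:", length(x$seqs), "contig(s)\n")
  for (nm in names(x$seqs)) cat(" ", nm, ":", nchar(x$seqs[[nm]]), "bp\n")
  invisible(x)
}

#' Extract a reference subsequence
#'
#' Coordinates are 0-based half-open (converted from 1-based VCF coordinates
#' at the I/O boundary only). Out-of-range portions are clipped, so the
#' returned string may be shorter than `end - start` at contig edges.
#'
#' @param genome A [ref_genome()].
#' @param chrom Contig name.
#' @param start,end 0-based half-open interval.
#' @return Uppercase sequence string.
#' @export
get_seq <- function(genome, chrom, start, end) {
  genome <- ref_genome(genome)
  s <- genome$seqs[[chrom]]
  if (is.null(s)) stop("unknown contig: ", chrom)
  n <- nchar(s)
  start <- max(0L, as.integer(start))
  end <- min(n, as.integer(end))
  if (start >= end) return("")
  substr(s, start + 1L, end)
}

.valid_seq <- function(x) nzchar(x) && !grepl("[^ACGT]", x)

#' Classify an SNV into its trinucleotide context
#'
#' Purine reference bases are reverse-complemented (substitution and both
#' flanks) so that the reference base is always C or T. Variants whose
#' flanks fall off the contig or contain non-ACGT bases return `NA` (they
#' are skipped and counted by [extract_profile()]).
#'
#' @param chrom,pos Contig and 1-based position of the substituted base.
#' @param ref,alt Single-base reference and alternate alleles.
#' @param genome A [ref_genome()].
#' @return One of the 96 keys from [snv_context_keys()], or `NA_character_`
#'   for a skippable record.
#' @export
classify_snv_context <- function(chrom, pos, ref, alt, genome) {
  if (!is.character(ref) || !is.character(alt) ||
      nchar(ref) != 1 || nchar(alt) != 1) {
    stop("classify_snv_context() expects single-base ref and alt")
  }
  if (ref == alt) stop("invalid variant: ref == alt")
  if (!ref %in% .BASES || !alt %in% .BASES) stop("alleles must be A/C/G/T")
  p <- as.integer(pos) - 1L  # 0-based
  five <- get_seq(genome, chrom, p - 1L, p)
  refg <- get_seq(genome, chrom, p, p + 1L)
  three <- get_seq(genome, chrom, p + 1L, p + 2L)
  if (!.valid_seq(five) || !.valid_seq(three) || refg != ref) {
    return(NA_character_)
  }
  if (ref %in% c("A", "G")) {  # purine: take reverse-complement strand
    tmp <- five
    five <- .comp[[three]]
    three <- .comp[[tmp]]
    ref <- .comp[[ref]]
    alt <- .comp[[alt]]
  }
  paste0(five, "[", ref, ">", alt, "]", three)
}

# Normalize a VCF-style record to a pure indel: strip shared suffix/prefix
# padding, then left-align. Returns list(type, pos0, seq) where pos0 is the
# 0-based index of the first deleted base (deletions) or of the insertion
# point (insertions; sequence inserted before that index).
.normalize_indel <- function(chrom, pos, ref, alt, genome) {
  p <- as.integer(pos) - 1L
  r <- toupper(ref); a <- toupper(alt)
  # shared suffix
  while (nchar(r) > 1 && nchar(a) > 1 &&
         substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
    r <- substr(r, 1, nchar(r) - 1L)
    a <- substr(a, 1, nchar(a) - 1L)
  }
  # shared prefix (VCF padding base included)
  while (nchar(r) > 0 && nchar(a) > 0 && substr(r, 1, 1) == substr(a, 1, 1)) {
    r <- substr(r, 2, nchar(r))
    a <- substr(a, 2, nchar(a))
    p <- p + 1L
  }
  if (nchar(r) > 0 && nchar(a) > 0) {
    stop("mixed substitution/indel allele rejected")
  }
  if (nchar(r) == 0 && nchar(a) == 0) stop("invalid variant: ref == alt")
  type <- if (nchar(r) > 0) "del" else "ins"
  s <- if (type == "del") r else a
  if (grepl("[^ACGT]", s)) return(NULL)  # skippable (N in allele)
  # left-align against the reference
  repeat {
    prev <- get_seq(genome, chrom, p - 1L, p)
    last <- substr(s, nchar(s), nchar(s))
    if (!nzchar(prev) || prev != last) break
    p <- p - 1L
    s <- paste0(last, substr(s, 1, nchar(s) - 1L))
  }
  if (type == "del") {
    refseq <- get_seq(genome, chrom, p, p + nchar(s))
    if (refseq != s) return(NULL)  # reference mismatch: skip record
  }
  list(type = type, pos0 = p, seq = s)
}

.shared_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(a, "", fixed = TRUE)[[1]][seq_len(n)]
  bv <- strsplit(b, "", fixed = TRUE)[[1]][seq_len(n)]
  neq <- which(av != bv)
  if (length(neq) == 0) n else neq[1] - 1L
}

.shared_suffix <- function(a, b) {
  # longest shared suffix of a and b
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- rev(strsplit(a, "", fixed = TRUE)[[1]])[seq_len(n)]
  bv <- rev(strsplit(b, "", fixed = TRUE)[[1]])[seq_len(n)]
  neq <- which(av != bv)
  if (length(neq) == 0) n else neq[1] - 1L
}

#' Classify an indel into its repeat/microhomology context
#'
#' After stripping the shared VCF padding base and left-aligning, the indel
#' sequence is compared with its reference flanks. An indel is in a repeat
#' region when at least one full copy of the indel sequence lies immediately
#' downstream (3') and the indel is shorter than 50 bp. Otherwise flanking
#' microhomology is called when (i) the indel is 50 bp or longer and a full
#' copy lies in a flank, (ii) at least 2 bp of the indel sequence are
#' identical to a flank, or (iii) at least 1 bp is identical and the indel
#' is 3 bp or longer. The homology search window up- and downstream equals
#' the indel length; the number of bases in microhomology (bimh) is the
#' larger of the downstream prefix match and the upstream suffix match.
#'
#' @inheritParams classify_snv_context
#' @param ref,alt VCF-style alleles (with padding base); exactly one of the
#'   stripped alleles must be empty.
#' @return One of the 30 keys from [indel_context_keys()], or `NA_character_`
#'   for a skippable record. Mixed substitution/indel alleles are an error.
#' @export
classify_indel_context <- function(chrom, pos, ref, alt, genome) {
  nv <- .normalize_indel(chrom, pos, ref, alt, genome)
  if (is.null(nv)) return(NA_character_)
  s <- nv$seq
  L <- nchar(s)
  dstart <- if (nv$type == "del") nv$pos0 + L else nv$pos0
  down <- get_seq(genome, chrom, dstart, dstart + L)
  up <- get_seq(genome, chrom, nv$pos0 - L, nv$pos0)
  if (grepl("[^ACGT]", down) || grepl("[^ACGT]", up)) return(NA_character_)
  full_copy_down <- nchar(down) == L && down == s
  bimh <- max(.shared_prefix(s, down), .shared_suffix(s, up))
  if (L < 50 && full_copy_down) {
    kind <- "rep"
  } else if (bimh >= 2 || (bimh >= 1 && L >= 3)) {
    kind <- "mh"
  } else {
    kind <- "none"
  }
  bin <- if (kind == "mh") min(bimh, 5L) else min(L, 5L)
  suffix <- if (kind == "mh") "bimh" else "len"
  paste0(nv$type, ".", kind, ".", suffix, ".", bin)
}

#' Classify a structural variant into its type/length context
#'
#' Sixteen contexts: DEL, DUP and INV stratified into length decades
#' (1-10 kb, 10-100 kb, 100 kb-1 Mb, 1-10 Mb, >10 Mb) plus length-less TRA.
#' SVs shorter than 1 kb fall outside the binning and return `NA`
#' (skipped and counted).
#'
#' @param sv_type One of `"DEL"`, `"DUP"`, `"INV"`, `"TRA"`.
#' @param length SV length in bp; ignored (may be `NA`) for TRA.
#' @return One of the 16 keys from [sv_context_keys()], or `NA_character_`.
#' @export
classify_sv_context <- function(sv_type, length = NA) {
  sv_type <- toupper(sv_type)
  if (!sv_type %in% c("DEL", "DUP", "INV", "TRA")) {
    stop("unknown SV type: ", sv_type)
  }
  if (sv_type == "TRA") return("TRA")
  if (is.na(length) || length <= 0) stop("non-TRA SV requires a positive length")
  if (length < 1e3) return(NA_character_)
  lo <- c(1e3, 1e4, 1e5, 1e6, 1e7)
  bin <- findInterval(length, lo)
  bins <- c("1e03_1e04_bp", "1e04_1e05_bp", "1e05_1e06_bp",
            "1e06_1e07_bp", "1e07_Inf_bp")
  paste0(sv_type, "_", bins[bin])
}

#' Accumulate a per-sample mutation-context count profile
#'
#' Classifies every somatic small variant and SV and increments exactly one
#' of the 142 context categories per accepted record. Records that cannot be
#' classified (flanking N, reference mismatch, sub-kb SV, malformed allele)
#' are skipped individually and counted; the batch never fails.
#'
#' @param small_variants `data.frame` with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt` (VCF-style alleles). May be `NULL` or empty.
#' @param svs `data.frame` with columns `sv_type` and `length` (bp; `NA` for
#'   TRA). May be `NULL` or empty.
#' @param genome A [ref_genome()].
#' @return Integer vector of class `context_profile` with the 142 keys of
#'   [context_keys()], with attributes `n_accepted` and `n_skipped`.
#' @export
extract_profile <- function(small_variants = NULL, svs = NULL, genome = NULL) {
  keys <- context_keys()
  prof <- setNames(integer(length(keys)), keys)
  skipped <- 0L
  accepted <- 0L
  if (!is.null(small_variants) && nrow(small_variants) > 0) {
    if (is.null(genome)) stop("small-variant classification needs a genome")
    genome <- ref_genome(genome)
    for (i in seq_len(nrow(small_variants))) {
      v <- small_variants[i, ]
      key <- tryCatch({
        if (nchar(v$ref) == 1 && nchar(v$alt) == 1) {
          classify_snv_context(v$chrom, v$pos, v$ref, v$alt, genome)
        } else {
          classify_indel_context(v$chrom, v$pos, v$ref, v$alt, genome)
        }
      }, error = function(e) NA_character_)
      if (is.na(key)) {
        skipped <- skipped + 1L
      } else {
        prof[key] <- prof[key] + 1L
        accepted <- accepted + 1L
      }
    }
  }
  if (!is.null(svs) && nrow(svs) > 0) {
    for (i in seq_len(nrow(svs))) {
      key <- tryCatch(
        classify_sv_context(svs$sv_type[i], svs$length[i]),
        error = function(e) NA_character_
      )
      if (is.na(key)) {
        skipped <- skipped + 1L
      } else {
        prof[key] <- prof[key] + 1L
        accepted <- accepted + 1L
      }
    }
  }
  structure(prof, class = "context_profile",
            n_accepted = accepted, n_skipped = skipped)
}

#' @export
print.context_profile <- function(x, ...) {
  cat("Mutation context profile (", sum(x[snv_context_keys()]), " SNVs, ",
      sum(x[indel_context_keys()]), " indels, ",
      sum(x[sv_context_keys()]), " SVs; ",
      attr(x, "n_skipped"), " record(s) skipped)\n", sep = "")
  nz <- x[x > 0]
  if (length(nz)) print(unclass(nz)) else cat("  all categories zero\n")
  invisible(x)
}

#' Flag microsatellite instability
#'
#' A sample is considered microsatellite-instable (MSI) when its absolute
#' number of indels within repeat regions exceeds the threshold (default
#' 14,000, strict inequality). MSI hypermutation of repeat indels masks the
#' microhomology-deletion signal and such samples are removed from training
#' and flagged by QC.
#'
#' @param profile A [extract_profile()] result (or any named count vector
#'   containing the 30 indel keys).
#' @param threshold Repeat-indel count above which MSI is called.
#' @return Logical.
#' @export
detect_msi <- function(profile, threshold = 14000) {
  rep_keys <- grep("\\.rep\\.", indel_context_keys(), value = TRUE)
  sum(profile[rep_keys]) > threshold
}
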