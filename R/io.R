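# Readers and writers for the standard formats. VCF coordinates are
# 1-based; internal coordinates are 0-based half-open, converted only at
# these I/O boundaries. Malformed records are counted and skipped;
# malformed headers are hard errors.

.read_vcf_fix <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (!is.matrix(fx)) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(CHROM = character(0), POS = integer(0),
                      REF = character(0), ALT = character(0),
                      INFO = character(0)))
  }
  fix$INFO <- vcfR::getINFO(v)
  fix
}

#' Read somatic small variants from a VCF
#'
#' Returns one row per allele: multi-allelic records are decomposed by
#' splitting `ALT` on commas. Records with a non-numeric position, missing
#' alleles, or symbolic/breakend ALT are counted and skipped (SVs belong in
#' [read_sv_vcf()]).
#'
#' @param path VCF 4.x file.
#' @return `data.frame` with `chrom`, `pos`, `ref`, `alt`; attribute
#'   `n_skipped` counts malformed records.
#' @export
read_small_variant_vcf <- function(path) {
  fix <- .read_vcf_fix(path)
  skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    pos <- suppressWarnings(as.integer(fix$POS[i]))
    ref <- toupper(fix$REF[i])
    alt_field <- fix$ALT[i]
    if (is.na(pos) || is.na(ref) || !nzchar(ref) ||
        is.na(alt_field) || !nzchar(alt_field) ||
        grepl("[^ACGTN]", ref)) {
      skipped <- skipped + 1L
      next
    }
    for (alt in strsplit(toupper(alt_field), ",", fixed = TRUE)[[1]]) {
      if (!nzchar(alt) || grepl("[^ACGTN]", alt)) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = pos, ref = ref, alt = alt,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0))
  }
  attr(out, "n_skipped") <- skipped
  out
}

.info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
  if (length(m) == 0 || !nzchar(m)) return(NA_character_)
  sub(paste0("^;?", key, "="), "", m)
}

# Parse a breakend ALT: returns mate chrom/pos and the junction geometry.
# "side" is whether the local breakend joins rightward (sequence continues
# after the local base: "t[p[", "t]p]") and "mate_fwd" whether the mate is
# joined on its forward strand ("[": join to sequence right of mate pos).
.parse_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec("^([ACGTN]*)([][])([^:]+):([0-9]+)([][])([ACGTN]*)$", alt))[[1]]
  if (length(m) == 0) return(NULL)
  bracket <- m[3]
  list(mate_chrom = m[4], mate_pos = as.integer(m[5]),
       local_first = nzchar(m[2]),   # base precedes bracket: local side is 5'
       bracket = bracket)
}

#' Read somatic structural variants from a VCF
#'
#' Supports both common SV dialects: symbolic ALT records
#' (`<DEL>`/`<DUP>`/`<INV>`/`<TRA>` with `INFO/END` or `SVLEN`), and
#' breakend (BND) mate pairs. Same-chromosome mate pairs are typed by their
#' junction orientation — taking the lower-coordinate record, `t[p[`
#' (deletion-type junction) gives DEL, `]p]t` gives DUP, and `t]p]` /
#' `[p[t` give INV — with length equal to the coordinate span;
#' inter-chromosomal pairs give one TRA. Malformed records are counted and
#' skipped.
#'
#' @param path VCF 4.x file.
#' @return `data.frame` with `sv_type`, `length`, `chrom`, `pos`;
#'   attribute `n_skipped`.
#' @export
read_sv_vcf <- function(path) {
  fix <- .read_vcf_fix(path)
  rows <- list()
  skipped <- 0L
  bnds <- list()
  for (i in seq_len(nrow(fix))) {
    pos <- suppressWarnings(as.integer(fix$POS[i]))
    alt <- fix$ALT[i]
    info <- fix$INFO[i]
    if (is.na(pos) || is.na(alt) || !nzchar(alt)) {
      skipped <- skipped + 1L
      next
    }
    svtype <- .info_field(info, "SVTYPE")
    if (grepl("^<", alt)) {
      type <- sub("^<([A-Z]+)>$", "\\1", alt)
      if (type %in% c("DEL", "DUP", "INV")) {
        end <- suppressWarnings(as.integer(.info_field(info, "END")))
        len <- if (!is.na(end)) {
          end - pos
        } else {
          abs(suppressWarnings(as.integer(.info_field(info, "SVLEN"))))
        }
        if (is.na(len) || len <= 0) {
          skipped <- skipped + 1L
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sv_type = type, length = len, chrom = fix$CHROM[i], pos = pos,
          stringsAsFactors = FALSE)
      } else if (type %in% c("TRA", "BND")) {
        rows[[length(rows) + 1L]] <- data.frame(
          sv_type = "TRA", length = NA_real_, chrom = fix$CHROM[i],
          pos = pos, stringsAsFactors = FALSE)
      } else {
        skipped <- skipped + 1L
      }
    } else if (grepl("[][]", alt)) {
      b <- .parse_bnd_alt(alt)
      if (is.null(b)) {
        skipped <- skipped + 1L
        next
      }
      bnds[[length(bnds) + 1L]] <- c(b, list(chrom = fix$CHROM[i], pos = pos))
    } else {
      skipped <- skipped + 1L
    }
  }
  # pair breakend mates by reciprocal coordinates
  seen <- rep(FALSE, length(bnds))
  for (i in seq_along(bnds)) {
    if (seen[i]) next
    a <- bnds[[i]]
    j <- NULL
    for (k in seq_along(bnds)) {
      if (k == i || seen[k]) next
      b <- bnds[[k]]
      if (b$chrom == a$mate_chrom && b$pos == a$mate_pos &&
          b$mate_chrom == a$chrom && b$mate_pos == a$pos) {
        j <- k
        break
      }
    }
    seen[i] <- TRUE
    if (!is.null(j)) seen[j] <- TRUE
    if (a$chrom != a$mate_chrom) {
      rows[[length(rows) + 1L]] <- data.frame(
        sv_type = "TRA", length = NA_real_, chrom = a$chrom, pos = a$pos,
        stringsAsFactors = FALSE)
    } else {
      lower <- if (a$pos <= a$mate_pos) {
        a
      } else if (!is.null(j)) {
        bnds[[j]]
      } else {
        # only the upper mate present: flip its geometry
        list(chrom = a$mate_chrom, pos = a$mate_pos, mate_pos = a$pos,
             local_first = a$bracket == "]", bracket = if (a$local_first) "]" else "[")
      }
      type <- if (lower$local_first && lower$bracket == "[") {
        "DEL"
      } else if (!lower$local_first && lower$bracket == "]") {
        "DUP"
      } else {
        "INV"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sv_type = type, length = abs(a$mate_pos - a$pos),
        chrom = lower$chrom, pos = lower$pos, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(sv_type = character(0), length = numeric(0),
               chrom = character(0), pos = integer(0))
  }
  attr(out, "n_skipped") <- skipped
  out
}

.vcf_header <- function(genome = NULL) {
  h <- c("##fileformat=VCFv4.2", "##source=hrdforest")
  if (!is.null(genome)) {
    genome <- ref_genome(genome)
    h <- c(h, sprintf("##contig=<ID=%s,length=%d>", names(genome$seqs),
                      nchar(genome$seqs)))
  }
  c(h, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
               "INFO"), collapse = "\t"))
}

#' Write fixture variants as VCF
#'
#' Minimal VCF 4.2 writers for the fixture generator. SVs are written with
#' symbolic ALT and `INFO/SVTYPE;END`; translocations are written as
#' inter-chromosomal breakend mate pairs when the genome has at least two
#' contigs (symbolic `<TRA>` otherwise).
#'
#' @param variants `data.frame` with `chrom`, `pos`, `ref`, `alt`.
#' @param svs `data.frame` with `sv_type`, `length` (and optionally
#'   `chrom`, `pos`; fixture positions are synthesized when absent).
#' @param path Output path.
#' @param genome A [ref_genome()] for the contig header lines.
#' @return The path, invisibly.
#' @export
write_small_variant_vcf <- function(variants, path, genome = NULL) {
  lines <- .vcf_header(genome)
  if (!is.null(variants) && nrow(variants) > 0) {
    v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                              v$chrom, as.integer(v$pos), v$ref, v$alt))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_small_variant_vcf
#' @export
write_sv_vcf <- function(svs, path, genome = NULL) {
  lines <- .vcf_header(genome)
  contigs <- if (!is.null(genome)) names(ref_genome(genome)$seqs) else "chr_fix1"
  body <- character(0)
  if (!is.null(svs) && nrow(svs) > 0) {
    pos0 <- 1000L
    for (i in seq_len(nrow(svs))) {
      chrom <- if (!is.null(svs$chrom)) svs$chrom[i] else contigs[1]
      pos <- if (!is.null(svs$pos)) svs$pos[i] else pos0 + 10L * i
      if (svs$sv_type[i] == "TRA") {
        if (length(contigs) >= 2) {
          c2 <- contigs[2]
          p2 <- 5000L + 10L * i
          id1 <- sprintf("bnd_%d_a", i); id2 <- sprintf("bnd_%d_b", i)
          body <- c(body,
                    sprintf("%s\t%d\t%s\tN\tN[%s:%d[\t.\tPASS\tSVTYPE=BND;MATEID=%s",
                            chrom, pos, id1, c2, p2, id2),
                    sprintf("%s\t%d\t%s\tN\tN]%s:%d]\t.\tPASS\tSVTYPE=BND;MATEID=%s",
                            c2, p2, id2, chrom, pos, id1))
        } else {
          body <- c(body, sprintf("%s\t%d\t.\tN\t<TRA>\t.\tPASS\tSVTYPE=TRA",
                                  chrom, pos))
        }
      } else {
        body <- c(body, sprintf("%s\t%d\t.\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d",
                                chrom, pos, svs$sv_type[i], svs$sv_type[i],
                                pos + as.integer(svs$length[i])))
      }
    }
  }
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read tabular inputs
#'
#' `read_copynumber_tsv()` expects `chrom`, `start`, `end`, `total_cn`,
#' `minor_cn`; `read_gene_table()` expects `gene`, `chrom`, `start`, `end`;
#' `read_annotation_tsv()` expects `chrom`, `pos`, `ref`, `alt` and at
#' least one of `clinvar_class` / `effect_class`.
#'
#' @param path TSV file with a header line.
#' @return `data.frame`.
#' @export
read_copynumber_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "total_cn", "minor_cn")
  if (!all(need %in% names(x))) {
    stop("copy-number table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(x$total_cn < 0, na.rm = TRUE)) stop("negative total copy number")
  x
}

#' @rdname read_copynumber_tsv
#' @export
read_gene_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(x))) {
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(x$start >= x$end)) stop("gene start must be < end")
  x
}

#' @rdname read_copynumber_tsv
#' @export
read_annotation_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(x)) ||
      !any(c("clinvar_class", "effect_class") %in% names(x))) {
    stop("annotation table needs chrom/pos/ref/alt and an annotation column")
  }
  x
}

#' Write / read context profiles as TSV
#'
#' One row per sample, a `sample` column plus the 142 named context
#' columns.
#'
#' @param profiles A single [extract_profile()] result or a samples-by-142
#'   matrix.
#' @param path TSV path.
#' @return `read_profile_tsv()` returns a samples-by-142 integer matrix.
#' @export
write_profile_tsv <- function(profiles, path) {
  if (is.null(dim(profiles))) {
    profiles <- matrix(unclass(profiles), nrow = 1,
                       dimnames = list("sample_1", names(profiles)))
  }
  df <- data.frame(sample = rownames(profiles), profiles,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(context_keys() %in% names(df))) {
    stop("profile table is missing context columns")
  }
  m <- as.matrix(df[, context_keys(), drop = FALSE])
  rownames(m) <- df$sample
  storage.mode(m) <- "integer"
  m
}
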