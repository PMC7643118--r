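# Synthetic fixtures: deterministic random genomes, VCFs with planted
# mutation-context counts, copy-number profiles with planted gene events,
# and labeled cohorts with HRD-like class structure. The module's core
# contract is round-trip identity: what the generator plants is exactly
# what extraction / status calling recovers.

#' Generate a deterministic fixture genome
#'
#' Random reference sequence with a configurable GC fraction, optionally
#' written to an indexed FASTA file.
#'
#' @param lengths Named integer vector of contig lengths (>= 1 kb each);
#'   unnamed contigs are named `chr_fix1`, `chr_fix2`, ...
#' @param gc Target GC fraction.
#' @param seed Integer seed.
#' @param path Optional FASTA path; when given the sequence is written with
#'   [Biostrings::writeXStringSet()] and indexed with [Rsamtools::indexFa()].
#' @return A [ref_genome()].
#' @export
make_fixture_genome <- function(lengths = c(chr_fix1 = 1e5), gc = 0.4,
                                seed = 1, path = NULL) {
  if (any(lengths < 1000)) stop("contig length must be >= 1 kb")
  if (is.null(names(lengths)) || any(!nzchar(names(lengths)))) {
    names(lengths) <- paste0("chr_fix", seq_along(lengths))
  }
  set.seed(seed)
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lengths, function(n) {
    paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
  g <- ref_genome(seqs)
  if (!is.null(path)) {
    dss <- Biostrings::DNAStringSet(g$seqs)
    Biostrings::writeXStringSet(dss, path)
    Rsamtools::indexFa(path)
  }
  g
}

# prefix-match length between s and the L bases following the deleted span,
# for every candidate 1-based start i in 1..m (deletion of [i, i+L))
.del_prefix_runs <- function(ch, L) {
  n <- length(ch)
  m <- n - 2L * L
  if (m < 1) return(integer(0))
  pm <- rep(0L, m)
  alive <- rep(TRUE, m)
  for (k in 0:(L - 1L)) {
    idx <- alive & ch[(1:m) + k] == ch[(1:m) + L + k]
    pm[idx] <- pm[idx] + 1L
    alive <- idx
  }
  pm
}

.rand_base <- function(not = NULL) {
  pool <- setdiff(c("A", "C", "G", "T"), not)
  pool[sample.int(length(pool), 1)]
}

# single planting attempt for one indel key; returns record or NULL
.propose_indel <- function(key, chrom, seq, sites_env) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  type <- parts[1]; kind <- parts[2]; bin <- as.integer(parts[4])
  n <- nchar(seq)
  if (type == "del") {
    cache_key <- paste0(kind, bin)
    if (is.null(sites_env[[cache_key]])) {
      L <- switch(kind,
                  rep = if (bin < 5) bin else 5L,
                  mh = if (bin < 5) max(3L, bin + 2L) else 7L,
                  none = bin)
      pm <- .del_prefix_runs(strsplit(seq, "")[[1]], L)
      ok <- switch(kind,
                   rep = pm == L,
                   mh = if (bin < 5) pm == bin else pm >= 5 & pm < L,
                   none = pm == 0L)
      cand <- which(ok)
      cand <- cand[cand >= 2]  # room for the VCF padding base
      sites_env[[cache_key]] <- list(L = L, cand = sample(cand))
    }
    st <- sites_env[[cache_key]]
    if (length(st$cand) == 0) return(NULL)
    i <- st$cand[1]
    sites_env[[cache_key]]$cand <- st$cand[-1]
    d0 <- i - 1L  # 0-based first deleted base
    pad <- substr(seq, d0, d0)
    list(chrom = chrom, pos = d0,  # 1-based position of padding base
         ref = paste0(pad, substr(seq, d0 + 1L, d0 + st$L)), alt = pad)
  } else {
    L <- switch(kind,
                rep = if (bin < 5) bin else 5L,
                mh = if (bin < 5) max(3L, bin + 2L) else 7L,
                none = bin)
    i0 <- sample(seq.int(L + 2L, n - 2L * L), 1)  # 0-based insertion point
    d <- substr(seq, i0 + 1L, i0 + L)
    dch <- strsplit(d, "")[[1]]
    s <- switch(kind,
                rep = d,
                mh = {
                  keep <- if (bin < 5) bin else 5L
                  paste(c(dch[seq_len(keep)],
                          vapply((keep + 1L):L, function(j) {
                            .rand_base(not = dch[j])
                          }, character(1))), collapse = "")
                },
                none = paste(vapply(seq_len(L), function(j) {
                  .rand_base(not = dch[j])
                }, character(1)), collapse = ""))
    pad <- substr(seq, i0, i0)
    list(chrom = chrom, pos = i0, ref = pad, alt = paste0(pad, s))
  }
}

.snv_sites <- function(ch, five, refb, three) {
  n <- length(ch)
  i <- 2:(n - 1)
  i[ch[i - 1] == five & ch[i] == refb & ch[i + 1] == three]
}

#' Plant variants with prescribed mutation contexts
#'
#' Engineers SNVs, indels and SVs on a fixture genome so that
#' [extract_profile()] recovers exactly the requested per-context counts.
#' SNV sites are found by scanning for the required trinucleotide (on
#' either strand); deletions are placed by scanning for positions whose
#' flanking homology structure produces the target category; insertions are
#' constructed from the downstream reference sequence. Every placement is
#' verified by classifying the resulting VCF-style record, and placements
#' whose flanks would create an unintended context (e.g. extra upstream
#' homology) are rejected and re-drawn, so the planting log is exact by
#' construction.
#'
#' @param genome A [ref_genome()] (use [make_fixture_genome()]).
#' @param spec Named integer vector: context key (any of [context_keys()])
#'   to desired count.
#' @param seed Integer seed.
#' @param max_tries Attempts per requested record before giving up.
#' @param out_dir Optional directory; when given, `variants.vcf` and
#'   `svs.vcf` are written there.
#' @return List with `small_variants` (chrom, pos, ref, alt, key), `svs`
#'   (sv_type, length, key), `log` (the planting log), and the VCF paths
#'   when `out_dir` is given.
#' @export
plant_variants <- function(genome, spec, seed = 1, max_tries = 5000,
                           out_dir = NULL) {
  genome <- ref_genome(genome)
  spec <- spec[spec > 0]
  bad <- setdiff(names(spec), context_keys())
  if (length(bad)) stop("unknown context keys: ", paste(bad, collapse = ", "))
  set.seed(seed)
  chroms <- names(genome$seqs)
  sv_keys <- intersect(names(spec), sv_context_keys())
  small_keys <- setdiff(names(spec), sv_keys)

  used <- character(0)
  recs <- list()
  for (key in small_keys) {
    needed <- spec[[key]]
    chrom <- chroms[1]
    seq <- genome$seqs[[chrom]]
    if (key %in% snv_context_keys()) {
      five <- substr(key, 1, 1); refb <- substr(key, 3, 3)
      alt <- substr(key, 5, 5); three <- substr(key, 7, 7)
      ch <- strsplit(seq, "")[[1]]
      fwd <- .snv_sites(ch, five, refb, three)
      rcv <- .snv_sites(ch, .comp[[three]], .comp[[refb]], .comp[[five]])
      cand <- sample(c(fwd, rcv))
      is_fwd <- cand %in% fwd
      got <- 0L
      for (ii in seq_along(cand)) {
        if (got == needed) break
        pos <- cand[ii]
        uk <- paste0(chrom, ":", pos)
        if (uk %in% used) next
        r <- if (is_fwd[ii]) refb else .comp[[refb]]
        a <- if (is_fwd[ii]) alt else .comp[[alt]]
        if (!identical(classify_snv_context(chrom, pos, r, a, genome), key)) next
        used <- c(used, uk)
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = chrom, pos = pos, ref = r, alt = a, key = key,
          stringsAsFactors = FALSE)
        got <- got + 1L
      }
      if (got < needed) {
        stop("fixture genome cannot accommodate ", needed, " x ", key)
      }
    } else {
      sites_env <- new.env(parent = emptyenv())
      got <- 0L
      tries <- 0L
      while (got < needed) {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop("fixture genome cannot accommodate ", needed, " x ", key)
        }
        cand <- .propose_indel(key, chrom, seq, sites_env)
        if (is.null(cand)) {
          stop("fixture genome cannot accommodate ", needed, " x ", key)
        }
        uk <- paste0(chrom, ":", cand$pos)
        if (uk %in% used) next
        ok <- tryCatch(
          identical(classify_indel_context(cand$chrom, cand$pos, cand$ref,
                                           cand$alt, genome), key),
          error = function(e) FALSE)
        if (!ok) next
        used <- c(used, uk)
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = cand$chrom, pos = cand$pos, ref = cand$ref,
          alt = cand$alt, key = key, stringsAsFactors = FALSE)
        got <- got + 1L
      }
    }
  }
  small_variants <- if (length(recs)) {
    do.call(rbind, recs)
  } else {
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), key = character(0))
  }

  sv_rows <- list()
  bounds <- list("1e03_1e04_bp" = c(3, 4), "1e04_1e05_bp" = c(4, 5),
                 "1e05_1e06_bp" = c(5, 6), "1e06_1e07_bp" = c(6, 7),
                 "1e07_Inf_bp" = c(7, 7.7))
  for (key in sv_keys) {
    needed <- spec[[key]]
    if (key == "TRA") {
      sv_rows[[length(sv_rows) + 1L]] <- data.frame(
        sv_type = rep("TRA", needed), length = NA_real_, key = key,
        stringsAsFactors = FALSE)
    } else {
      type <- sub("_.*$", "", key)
      b <- bounds[[sub("^[A-Z]+_", "", key)]]
      len <- round(10^runif(needed, b[1], b[2]))
      len <- pmin(pmax(len, 10^b[1]), 10^b[2] - 1)  # guard rounding at edges
      sv_rows[[length(sv_rows) + 1L]] <- data.frame(
        sv_type = type, length = len, key = key, stringsAsFactors = FALSE)
    }
  }
  svs <- if (length(sv_rows)) {
    do.call(rbind, sv_rows)
  } else {
    data.frame(sv_type = character(0), length = numeric(0),
               key = character(0))
  }

  out <- list(small_variants = small_variants, svs = svs,
              log = rbind(
                if (nrow(small_variants)) {
                  data.frame(record = "small", key = small_variants$key)
                },
                if (nrow(svs)) data.frame(record = "sv", key = svs$key)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out$vcf <- file.path(out_dir, "variants.vcf")
    out$sv_vcf <- file.path(out_dir, "svs.vcf")
    write_small_variant_vcf(small_variants, out$vcf, genome)
    write_sv_vcf(svs, out$sv_vcf, genome)
  }
  out
}

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = pmax(alpha, 1e-8))
  g / sum(g)
}

#' Cohort effect configuration
#'
#' Class-conditional generative parameters for [simulate_cohort()]:
#' mean context proportions and mutation loads per class, mirroring the
#' HRD mutational-scar structure. Both deficient classes are enriched in
#' microhomology deletions with >= 2 bp homology (the dominant HRD marker);
#' the BRCA1 class is additionally enriched in 1-10 kb and 10-100 kb
#' duplications, which is what separates the two HRD subtypes; the
#' proficient class carries the baseline profile. `effect_scale`
#' interpolates the deficient-class parameters toward the baseline
#' (0 = no class differences, for null simulations).
#'
#' @param effect_scale Multiplier on all class differences.
#' @param concentration Dirichlet concentration controlling between-sample
#'   variability around each class mean (larger = tighter).
#' @return List with per-class context proportions (length 142) and
#'   negative-binomial load parameters, consumed by [simulate_cohort()].
#' @export
hrd_effect_config <- function(effect_scale = 1, concentration = 60) {
  bins5 <- function(w) w / sum(w)
  # within-type bin weights
  len_w <- bins5(c(.45, .25, .15, .10, .05))
  mh_w_none <- bins5(c(.60, .25, .10, .04, .01))
  mh_w_hrd <- bins5(c(.18, .40, .22, .12, .08))
  indel_props <- function(tp, mh_w) {
    c(tp[["del.mh"]] * mh_w, tp[["ins.mh"]] * mh_w_none,
      tp[["del.rep"]] * len_w, tp[["ins.rep"]] * len_w,
      tp[["del.none"]] * len_w, tp[["ins.none"]] * len_w)
  }
  type_none <- c(del.mh = .05, ins.mh = .04, del.rep = .22, ins.rep = .28,
                 del.none = .21, ins.none = .20)
  type_hrd <- c(del.mh = .45, ins.mh = .05, del.rep = .12, ins.rep = .13,
                del.none = .13, ins.none = .12)
  sv_none <- c(c(.10, .08, .05, .03, .02),        # DEL
               c(.03, .03, .02, .01, .01),        # DUP
               c(.14, .10, .08, .05, .03), .22)   # INV, TRA
  sv_b2 <- c(c(.18, .14, .08, .04, .02),
             c(.025, .025, .015, .01, .005),
             c(.10, .08, .06, .04, .02), .16)
  sv_b1 <- c(c(.08, .06, .04, .02, .01),
             c(.28, .18, .04, .02, .01),
             c(.06, .05, .04, .02, .01), .08)
  snv_flat <- rep(1 / 96, 96)
  lerp <- function(base, x) base + effect_scale * (x - base)
  mk <- function(indel, sv, loads) {
    props <- setNames(c(snv_flat, indel / sum(indel), sv / sum(sv)),
                      context_keys())
    list(props = props, loads = loads)
  }
  none_indel <- indel_props(type_none, mh_w_none)
  loads_none <- c(snv = 8000, indel = 400, sv = 120)
  loads_hrd <- c(snv = 8000,
                 indel = lerp(400, 1500), sv = lerp(120, 250))
  list(
    concentration = concentration,
    classes = list(
      none = mk(none_indel, sv_none, loads_none),
      BRCA1 = mk(lerp(none_indel, indel_props(type_hrd, mh_w_hrd)),
                 lerp(sv_none, sv_b1), loads_hrd),
      BRCA2 = mk(lerp(none_indel, indel_props(type_hrd, mh_w_hrd)),
                 lerp(sv_none, sv_b2), loads_hrd)
    )
  )
}

#' Simulate a labeled cohort of context profiles
#'
#' Draws per-sample context-count profiles from class-conditional
#' multinomials whose proportions vary around the class means
#' (Dirichlet-distributed, see [hrd_effect_config()]) and whose per-class
#' mutation loads are negative-binomial. Class sizes default to the
#' training-set composition (35 BRCA1-deficient, 89 BRCA2-deficient, 1902
#' proficient).
#'
#' @param n_brca1,n_brca2,n_none Samples per class.
#' @param effects See [hrd_effect_config()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return List: `profiles` (samples x 142 counts), `features` (samples x
#'   29, via [build_hrd_features()]), `labels` (factor).
#' @export
simulate_cohort <- function(n_brca1 = 35, n_brca2 = 89, n_none = 1902,
                            effects = hrd_effect_config(), seed = 1) {
  stopifnot(n_brca1 >= 0, n_brca2 >= 0, n_none >= 0)
  set.seed(seed)
  labels <- factor(rep(c("BRCA1", "BRCA2", "none"),
                       c(n_brca1, n_brca2, n_none)),
                   levels = c("BRCA1", "BRCA2", "none"))
  keys <- context_keys()
  blocks <- list(snv = snv_context_keys(), indel = indel_context_keys(),
                 sv = sv_context_keys())
  n <- length(labels)
  profiles <- matrix(0L, nrow = n, ncol = length(keys),
                     dimnames = list(sprintf("S%04d_%s", seq_len(n), labels),
                                     keys))
  conc <- effects$concentration
  for (i in seq_len(n)) {
    cfg <- effects$classes[[as.character(labels[i])]]
    for (b in names(blocks)) {
      bk <- blocks[[b]]
      pr <- .rdirichlet1(conc * cfg$props[bk] /
                           max(sum(cfg$props[bk]), 1e-12))
      tot <- rnbinom(1, size = 8, mu = cfg$loads[[b]])
      if (tot > 0) {
        profiles[i, bk] <- as.integer(rmultinom(1, tot, pr))
      }
    }
  }
  list(profiles = profiles, features = build_hrd_features(profiles),
       labels = labels)
}

#' Plant a biallelic (or benign) gene event
#'
#' Builds a copy-number profile and annotated variant table for one sample
#' such that [determine_biallelic_status()] recovers exactly the planted
#' event with the expected BP-score.
#'
#' @param gene One-row `data.frame` with `gene`, `chrom`, `start`, `end`.
#' @param event One of `"deep_deletion"`, `"loh_germline_pathogenic"`,
#'   `"loh_somatic_frameshift"`, `"pathogenic_pair"`, `"somatic_vus_pair"`,
#'   `"benign_only"`, `"none"`.
#' @param seed Integer seed (variant placement within the gene).
#' @return List: `segments`, `variants`, and `expected` (`event`,
#'   `bp_score`, `deficient`).
#' @export
plant_gene_events <- function(gene, event = "deep_deletion", seed = 1) {
  set.seed(seed)
  span <- gene$end - gene$start
  vpos <- function() gene$start + sample.int(max(span - 1, 1), 1)
  base_seg <- function(total, minor) {
    data.frame(chrom = gene$chrom,
               start = c(0, gene$start - 100, gene$end + 100),
               end = c(gene$start - 100, gene$end + 100, gene$end + 1e6),
               total_cn = c(2, total, 2), minor_cn = c(1, minor, 1))
  }
  mkvar <- function(origin, clinvar = NA, effect = NA) {
    data.frame(chrom = gene$chrom, pos = vpos(), ref = "A", alt = "T",
               origin = origin, clinvar_class = clinvar,
               effect_class = effect, stringsAsFactors = FALSE)
  }
  out <- switch(
    event,
    deep_deletion = list(
      segments = base_seg(0.1, 0),
      variants = NULL,
      expected = list(event = "deep_deletion", bp_score = 10L,
                      deficient = TRUE)),
    loh_germline_pathogenic = list(
      segments = base_seg(1.0, 0.0),  # one copy lost
      variants = mkvar("germline", clinvar = "pathogenic"),
      expected = list(event = "LOH+variant", bp_score = 10L,
                      deficient = TRUE)),
    loh_somatic_frameshift = list(
      segments = base_seg(2.0, 0.0),  # copy-neutral LOH
      variants = mkvar("somatic", effect = "frameshift_oof"),
      expected = list(event = "LOH+variant", bp_score = 10L,
                      deficient = TRUE)),
    pathogenic_pair = list(
      segments = base_seg(2.0, 1.0),
      variants = rbind(mkvar("germline", clinvar = "pathogenic"),
                       mkvar("somatic", effect = "frameshift_oof")),
      expected = list(event = "variant_pair", bp_score = 10L,
                      deficient = TRUE)),
    somatic_vus_pair = list(
      segments = base_seg(2.0, 1.0),
      variants = rbind(mkvar("somatic", effect = "missense"),
                       mkvar("somatic", effect = "missense")),
      expected = list(event = "variant_pair", bp_score = 6L,
                      deficient = FALSE)),
    benign_only = list(
      segments = base_seg(2.0, 1.0),
      variants = mkvar("germline", clinvar = "benign"),
      expected = list(event = "none", bp_score = 1L, deficient = FALSE)),
    none = list(
      segments = base_seg(2.0, 1.0),
      variants = NULL,
      expected = list(event = "none", bp_score = 0L, deficient = FALSE)),
    stop("unknown event type: ", event)
  )
  # two variants at the same position would collapse to one allele pair
  if (!is.null(out$variants) && nrow(out$variants) > 1) {
    while (anyDuplicated(out$variants$pos)) {
      out$variants$pos[duplicated(out$variants$pos)] <- vpos()
    }
  }
  out
}
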