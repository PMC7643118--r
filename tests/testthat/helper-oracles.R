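# Independent brute-force oracles used to validate the implementation, plus
# shared fixtures. The oracles are written as literal transcriptions of the
# classification / statistic definitions and never call package internals.

# --- naive indel classifier ------------------------------------------------
# Operates on a plain genome string and a normalized indel (0-based
# breakpoint, type, indel sequence); performs its own left-alignment and
# then applies the repeat / microhomology rules by direct string scanning.
oracle_indel_class <- function(genome_str, d0, type, s) {
  n <- nchar(genome_str)
  # left-align
  repeat {
    if (d0 < 1) break
    prev <- substr(genome_str, d0, d0)
    if (prev != substr(s, nchar(s), nchar(s))) break
    d0 <- d0 - 1
    s <- paste0(prev, substr(s, 1, nchar(s) - 1))
  }
  L <- nchar(s)
  down_start <- if (type == "del") d0 + L else d0
  down <- substr(genome_str, down_start + 1, min(n, down_start + L))
  up_from <- max(1, d0 - L + 1)
  up <- if (d0 >= 1) substr(genome_str, up_from, d0) else ""
  count_prefix <- function(a, b) {
    k <- 0
    while (k < min(nchar(a), nchar(b)) &&
           substr(a, k + 1, k + 1) == substr(b, k + 1, k + 1)) k <- k + 1
    k
  }
  count_suffix <- function(a, b) {
    k <- 0
    while (k < min(nchar(a), nchar(b)) &&
           substr(a, nchar(a) - k, nchar(a) - k) ==
           substr(b, nchar(b) - k, nchar(b) - k)) k <- k + 1
    k
  }
  full_down <- nchar(down) == L && down == s
  full_up <- nchar(up) == L && up == s
  bimh <- max(count_prefix(s, down), count_suffix(s, up))
  if (L < 50 && full_down) {
    return(paste0(type, ".rep.len.", min(L, 5)))
  }
  is_mh <- (L >= 50 && (full_down || full_up)) ||
    bimh >= 2 || (bimh >= 1 && L >= 3)
  if (is_mh) return(paste0(type, ".mh.bimh.", min(bimh, 5)))
  paste0(type, ".none.len.", min(L, 5))
}

# --- AUROC by exhaustive pair counting (Mann-Whitney form) -----------------
oracle_auroc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}

# --- one-tailed Fisher p by hypergeometric tail enumeration ----------------
# a = successes in group, K = total successes, n = group size, N = total
oracle_fisher_greater <- function(a, K, n, N) {
  ks <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= a])
}

# --- one-sided Wilcoxon p by exhaustive rank enumeration -------------------
# P(rank sum of group x >= observed) under the permutation null; ties
# handled by midranks.
oracle_wilcoxon_greater <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n)])
  combs <- utils::combn(n + m, n)
  tot <- 0
  for (j in seq_len(ncol(combs))) {
    if (sum(r[combs[, j]]) >= obs) tot <- tot + 1
  }
  tot / ncol(combs)
}

# --- shared fixtures -------------------------------------------------------
# A moderately sized two-contig fixture genome reused across test files.
fixture_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- make_fixture_genome(c(fixA = 3e4, fixB = 6e3),
                                              gc = 0.42, seed = 424242)
    g
  }
})

# Random VCF-style indel records on a genome, for oracle comparisons.
random_indel_records <- function(genome, n, seed) {
  set.seed(seed)
  chrom <- names(genome$seqs)[1]
  gs <- genome$seqs[[chrom]]
  glen <- nchar(gs)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    L <- sample(c(1:8, 52), 1, prob = c(rep(0.11, 8), 0.12))
    d0 <- sample(seq(100, glen - 200), 1)  # 0-based breakpoint
    type <- sample(c("del", "ins"), 1)
    if (type == "del") {
      s <- substr(gs, d0 + 1, d0 + L)
    } else {
      # mix of random sequence and copies of the downstream flank, so that
      # rep/mh insertion categories are exercised
      s <- if (runif(1) < 0.4) {
        substr(gs, d0 + 1, d0 + L)
      } else {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = "")
      }
    }
    pad <- substr(gs, d0, d0)
    recs[[i]] <- list(
      chrom = chrom, d0 = d0, type = type, s = s,
      pos = d0,  # 1-based position of the padding base
      ref = if (type == "del") paste0(pad, s) else pad,
      alt = if (type == "del") pad else paste0(pad, s))
  }
  recs
}

# A small cohort shared by classifier tests (generated once per run).
fixture_cohort <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) sim <<- simulate_cohort(n_brca1 = 25, n_brca2 = 30,
                                              n_none = 110, seed = 777)
    sim
  }
})

expect_block_normalized <- function(fv, blocks) {
  for (b in blocks) {
    s <- sum(fv[b])
    expect_true(abs(s - 1) < 1e-9 || s == 0)
  }
}
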