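# Independent oracles used to validate the package's own implementations.
# These are deliberately written from first principles (recursion /
# exhaustive enumeration), not by calling the code paths they check.

# --- exhaustive chain enumeration -------------------------------------
# Maximum total score over all chains of anchors with strictly increasing
# rank_a, strictly monotone rank_b (either direction), and rank gap
# <= max_gap on both sides between consecutive anchors. DFS over all
# extensions; feasible for <= 12 anchors.
oracle_best_chain_score <- function(anchors, max_gap) {
  n <- nrow(anchors)
  if (n == 0L) {
    return(0)
  }
  ra <- anchors$rank_a
  rb <- anchors$rank_b
  sc <- anchors$score
  best <- max(sc)  # single-anchor chains are valid
  extend <- function(last, total, dir) {
    for (nxt in seq_len(n)) {
      da <- ra[nxt] - ra[last]
      db <- rb[nxt] - rb[last]
      if (da <= 0L || da > max_gap) next
      if (db == 0L || abs(db) > max_gap) next
      ndir <- sign(db)
      if (!is.na(dir) && ndir != dir) next
      tot <- total + sc[nxt]
      if (tot > best) best <<- tot
      extend(nxt, tot, ndir)
    }
  }
  for (s in seq_len(n)) {
    extend(s, sc[s], NA)
  }
  best
}

random_anchor_set <- function(n, rank_max = 30L) {
  data.frame(
    gene_a = paste0("a", seq_len(n)), gene_b = paste0("b", seq_len(n)),
    chr_a = "c1", chr_b = "c2",
    rank_a = sample.int(rank_max, n, replace = TRUE),
    rank_b = sample.int(rank_max, n, replace = TRUE),
    score = round(runif(n, 1, 100), 2), stringsAsFactors = FALSE)
}

# --- brute-force Nei-Gojobori (1986) ----------------------------------
# Recomputes S/N sites and path-averaged differences directly from codon
# strings with recursive path enumeration; no lookup tables shared with
# the package implementation.
.oracle_gc <- as.list(Biostrings::GENETIC_CODE)

oracle_syn_sites <- function(codon) {
  aa <- .oracle_gc[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (base in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) == base) next
      mut <- codon
      substr(mut, pos, pos) <- base
      if (.oracle_gc[[mut]] == aa) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

# all orders of applying the differing positions; returns matrix of
# (syn, nonsyn) per unblocked path
oracle_paths <- function(ca, cb) {
  dpos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  res <- list()
  walk <- function(cur, remaining, s, n) {
    if (length(remaining) == 0L) {
      res[[length(res) + 1L]] <<- c(s, n)
      return(invisible())
    }
    for (k in seq_along(remaining)) {
      pos <- remaining[k]
      nxt <- cur
      substr(nxt, pos, pos) <- substr(cb, pos, pos)
      if (.oracle_gc[[nxt]] == "*") next
      if (.oracle_gc[[nxt]] == .oracle_gc[[cur]]) {
        walk(nxt, remaining[-k], s + 1, n)
      } else {
        walk(nxt, remaining[-k], s, n + 1)
      }
    }
  }
  walk(ca, dpos, 0, 0)
  res
}

# ca, cb: equal-length vectors of codon strings (no gaps). Returns the
# same quantities as ng86().
oracle_ng86 <- function(ca, cb) {
  usable <- logical(length(ca))
  sd <- nd <- 0
  S1 <- S2 <- 0
  for (i in seq_along(ca)) {
    if (.oracle_gc[[ca[i]]] == "*" || .oracle_gc[[cb[i]]] == "*") next
    paths <- oracle_paths(ca[i], cb[i])
    if (ca[i] != cb[i] && length(paths) == 0L) next  # fully blocked
    usable[i] <- TRUE
    S1 <- S1 + oracle_syn_sites(ca[i])
    S2 <- S2 + oracle_syn_sites(cb[i])
    if (ca[i] != cb[i]) {
      m <- do.call(rbind, paths)
      sd <- sd + mean(m[, 1])
      nd <- nd + mean(m[, 2])
    }
  }
  u <- sum(usable)
  S <- (S1 + S2) / 2
  N <- 3 * u - S
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, sd = sd, nd = nd, ps = ps, pn = pn,
       Ks = if (ps >= 0.75) NA_real_ else jc(ps),
       Ka = if (pn >= 0.75) NA_real_ else jc(pn),
       n_codons = u)
}

random_codon_pair <- function(n_codons, n_mut = NULL) {
  gc_ok <- names(.oracle_gc)[unlist(.oracle_gc) != "*"]
  ca <- sample(gc_ok, n_codons, replace = TRUE)
  cb <- ca
  if (is.null(n_mut)) {
    n_mut <- rpois(1, n_codons / 4)
  }
  for (k in seq_len(n_mut)) {
    i <- sample.int(n_codons, 1)
    pos <- sample.int(3, 1)
    base <- sample(c("A", "C", "G", "T"), 1)
    mut <- cb[i]
    substr(mut, pos, pos) <- base
    if (.oracle_gc[[mut]] != "*") {
      cb[i] <- mut
    }
  }
  list(a = ca, b = cb)
}

# literal codon-by-codon translation (no initiation-codon special-casing)
oracle_translate <- function(cds) {
  n <- nchar(cds)
  starts <- seq.int(1L, n, by = 3L)
  aa <- unlist(.oracle_gc[substring(cds, starts, starts + 2L)])
  if (aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
  }
  paste(aa, collapse = "")
}

# --- quadratic-space affine (Gotoh) global aligner --------------------
# Biostrings convention: a gap of length L costs gapOpening + L *
# gapExtension. Returns only the optimal score.
oracle_align_score <- function(a, b, mat, gap_open = 10, gap_ext = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (a aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    X[i + 1, 1] <- -(gap_open + i * gap_ext)
  }
  for (j in seq_len(m)) {
    Y[1, j + 1] <- -(gap_open + j * gap_ext)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- brute-force k-mer multiset intersection --------------------------
oracle_kmer_score <- function(a, b, k) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }
  ta <- table(kmers(a))
  tb <- table(kmers(b))
  shared <- intersect(names(ta), names(tb))
  if (length(shared) == 0L) {
    return(0)
  }
  sum(pmin(ta[shared], tb[shared]))
}

# --- exact permutation-null p by exhaustive enumeration ---------------
# chr / rank: the genome's slots. Enumerates every placement of ka + kb
# distinct labels over the slots and returns P(min cross-family
# intervening distance <= obs).
oracle_exact_perm_p <- function(chr, rank, ka, kb, obs) {
  G <- length(chr)
  stat_of <- function(ia, ib) {
    best <- Inf
    for (i in ia) {
      for (j in ib) {
        if (chr[i] == chr[j]) {
          best <- min(best, max(abs(rank[i] - rank[j]) - 1L, 0L))
        }
      }
    }
    best
  }
  hits <- 0L
  total <- 0L
  for (A in utils::combn(G, ka, simplify = FALSE)) {
    rest <- setdiff(seq_len(G), A)
    for (B in utils::combn(length(rest), kb, simplify = FALSE)) {
      total <- total + 1L
      if (stat_of(A, rest[B]) <= obs) {
        hits <- hits + 1L
      }
    }
  }
  hits / total
}
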