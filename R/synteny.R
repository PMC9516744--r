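# Anchor construction, tandem collapsing, syntenic-block chaining by
# sparse dynamic programming, self-synteny, and duplicate-mode calls.

#' Build anchors from filtered pairs
#'
#' Attaches chromosome and rank coordinates from the two genomes to
#' C-score-filtered pairs, orienting each pair so `gene_a` belongs to
#' `genome_a`. Pairs whose genes are missing from either annotation are
#' dropped. For a self comparison pass the same genome twice; each
#' unordered pair is kept once, oriented so side a precedes side b in
#' (chromosome, rank) order.
#'
#' @param pairs Output of [cscore_filter()].
#' @param genome_a,genome_b [genome_annotation()] objects.
#' @return `data.frame` of anchors: `gene_a`, `gene_b`, `chr_a`, `chr_b`,
#'   `rank_a`, `rank_b`, `score`.
#' @export
make_anchors <- function(pairs, genome_a, genome_b) {
  p <- as.data.table(pairs)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      chr_a = character(), chr_b = character(),
                      rank_a = integer(), rank_b = integer(),
                      score = numeric())
  if (nrow(p) == 0L) {
    return(empty)
  }
  ga <- genome_a$genes
  gb <- genome_b$genes
  self_cmp <- identical(genome_a$species_id, genome_b$species_id)
  orient <- function(x, y) {
    ia <- match(x, ga$gene_id)
    ib <- match(y, gb$gene_id)
    list(ia = ia, ib = ib)
  }
  o1 <- orient(p$gene_a, p$gene_b)
  if (self_cmp) {
    ok <- !is.na(o1$ia) & !is.na(o1$ib)
    p <- p[ok]
    ia <- o1$ia[ok]
    ib <- o1$ib[ok]
    # canonical orientation: (chr, rank) of side a <= side b
    swap <- (ga$chromosome[ia] > gb$chromosome[ib]) |
      (ga$chromosome[ia] == gb$chromosome[ib] & ga$rank[ia] > gb$rank[ib])
    tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
    tmp <- p$gene_a[swap]; p$gene_a[swap] <- p$gene_b[swap]
    p$gene_b[swap] <- tmp
  } else {
    # try both orientations: gene_a in genome_a, or swapped
    o2 <- orient(p$gene_b, p$gene_a)
    use2 <- is.na(o1$ia) | is.na(o1$ib)
    ia <- ifelse(use2, o2$ia, o1$ia)
    ib <- ifelse(use2, o2$ib, o1$ib)
    swapped <- use2 & !is.na(o2$ia) & !is.na(o2$ib)
    tmp <- p$gene_a[swapped]
    p$gene_a[swapped] <- p$gene_b[swapped]
    p$gene_b[swapped] <- tmp
    ok <- !is.na(ia) & !is.na(ib)
    p <- p[ok]
    ia <- ia[ok]
    ib <- ib[ok]
  }
  if (nrow(p) == 0L) {
    return(empty)
  }
  out <- data.table(gene_a = p$gene_a, gene_b = p$gene_b,
                    chr_a = ga$chromosome[ia], chr_b = gb$chromosome[ib],
                    rank_a = ga$rank[ia], rank_b = gb$rank[ib],
                    score = p$score)
  out <- unique(out)
  setorder(out, chr_a, chr_b, rank_a, rank_b)
  as.data.frame(out)
}

#' Collapse tandem arrays before chaining
#'
#' Within either genome, hits from members of a tandem array (same-partner
#' hits whose members lie within `max_tandem_gap` ranks of one another on
#' one chromosome) are collapsed to the single highest-scoring
#' representative, so an array contributes one anchor instead of a cloud.
#' Arrays found on each side are recorded in the `"tandem_arrays"`
#' attribute.
#'
#' @param anchors Anchor `data.frame` from [make_anchors()].
#' @param max_tandem_gap Maximum rank gap between array members (default 5).
#' @return Collapsed anchors `data.frame`.
#' @export
collapse_tandem <- function(anchors, max_tandem_gap = 5L) {
  a <- as.data.table(anchors)
  arrays <- list()
  collapse_side <- function(a, rank_col, chr_col, gene_col, partner_col) {
    setorderv(a, c(partner_col, chr_col, rank_col))
    grp_chr <- a[[chr_col]]
    grp_part <- a[[partner_col]]
    r <- a[[rank_col]]
    n <- nrow(a)
    if (n <= 1L) {
      a[, cl := seq_len(.N)]
    } else {
      new_grp <- c(TRUE, grp_part[-1] != grp_part[-n] |
                     grp_chr[-1] != grp_chr[-n] |
                     (r[-1] - r[-n]) > max_tandem_gap)
      a[, cl := cumsum(new_grp)]
    }
    members <- a[, .N, by = cl]
    arrays[[length(arrays) + 1L]] <<-
      a[cl %in% members$cl[members$N > 1L],
        .(side = rank_col, members = paste(sort(unique(get(gene_col))),
                                           collapse = ",")),
        by = cl][, cl := NULL][]
    setorderv(a, c("cl", "score", rank_col), order = c(1L, -1L, 1L))
    out <- a[, .SD[1], by = cl]
    out[, cl := NULL]
    out
  }
  if (nrow(a) > 1L) {
    a <- collapse_side(a, "rank_a", "chr_a", "gene_a", "gene_b")
    a <- collapse_side(a, "rank_b", "chr_b", "gene_b", "gene_a")
  }
  setorder(a, chr_a, chr_b, rank_a, rank_b)
  out <- as.data.frame(a)
  attr(out, "tandem_arrays") <- unique(rbindlist(arrays))
  out
}

# Max-scoring monotone chain over one anchor group and one orientation.
# Anchors: data.table with rank_a, rank_b, score, row id. Returns integer
# row indices of the best chain (possibly length 1) and its score.
best_chain <- function(rank_a, rank_b, score, max_gap, orientation) {
  n <- length(rank_a)
  rb <- if (orientation == "+") rank_b else -rank_b
  ord <- order(rank_a, rb)
  ra <- rank_a[ord]
  rb <- rb[ord]
  sc <- score[ord]
  dp <- sc
  prev <- rep.int(0L, n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      db <- rb[i] - rb[j]
      if (da > 0L && da <= max_gap && db > 0L && db <= max_gap) {
        cand <- dp[j] + sc[i]
        if (cand > dp[i]) {
          dp[i] <- cand
          prev[i] <- j
        }
      }
    }
  }
  end <- which.max(dp)
  chain <- integer(0)
  i <- end
  while (i != 0L) {
    chain <- c(i, chain)
    i <- prev[i]
  }
  list(rows = ord[chain], score = dp[end])
}

#' Chain anchors into syntenic blocks
#'
#' Anchors are grouped by chromosome pair and chained by dynamic
#' programming, separately for forward (+) and reverse (-) orientation:
#' within a block the a-side ranks are strictly increasing and the b-side
#' ranks strictly monotone, with the rank gap between consecutive anchors
#' at most `max_gap` on both sides (DAGchainer-style gap semantics — chains
#' may skip genes). A block's score is the sum of its anchor scores. Blocks
#' are extracted greedily by descending chain score (ties by chromosome
#' pair and start rank), each anchor is used in at most one block, and
#' chains with fewer than `min_pairs` anchors are discarded. Output order
#' is deterministic: (chr_a, chr_b, a-side start rank).
#'
#' @param anchors Anchor `data.frame` (see [make_anchors()]).
#' @param min_pairs Minimum anchors per block (default 5).
#' @param max_gap Maximum rank gap between consecutive anchors (default 20).
#' @return A list of class `SyntenicBlocks` with elements `blocks` (one row
#'   per block: `block_id`, `chr_a`, `chr_b`, `orientation`, `n_anchors`,
#'   `score`, `start_a`, `end_a`, `start_b`, `end_b`) and `anchors` (the
#'   input anchors of retained blocks with a `block_id` column).
#' @export
chain_anchors <- function(anchors, min_pairs = 5L, max_gap = 20L) {
  a <- as.data.table(anchors)
  empty_blocks <- data.frame(
    block_id = character(), chr_a = character(), chr_b = character(),
    orientation = character(), n_anchors = integer(), score = numeric(),
    start_a = integer(), end_a = integer(), start_b = integer(),
    end_b = integer())
  empty_anchors <- cbind(as.data.frame(a[0]), block_id = character())
  if (nrow(a) == 0L) {
    return(structure(list(blocks = empty_blocks, anchors = empty_anchors),
                     class = "SyntenicBlocks"))
  }
  a[, row_id := seq_len(.N)]
  chains <- list()
  for (grp in split(a, by = c("chr_a", "chr_b"))) {
    active <- rep.int(TRUE, nrow(grp))
    repeat {
      idx <- which(active)
      if (length(idx) == 0L) break
      sub <- grp[idx]
      best <- NULL
      for (orient in c("+", "-")) {
        ch <- best_chain(sub$rank_a, sub$rank_b, sub$score, max_gap, orient)
        cand <- list(rows = idx[ch$rows], score = ch$score,
                     orientation = orient,
                     start_a = min(sub$rank_a[ch$rows]))
        if (is.null(best) || cand$score > best$score ||
            (cand$score == best$score && cand$start_a < best$start_a)) {
          best <- cand
        }
      }
      active[best$rows] <- FALSE
      chains[[length(chains) + 1L]] <-
        list(rows = grp$row_id[best$rows], score = best$score,
             orientation = best$orientation,
             chr_a = grp$chr_a[1], chr_b = grp$chr_b[1])
    }
  }
  chains <- Filter(function(ch) length(ch$rows) >= min_pairs, chains)
  if (length(chains) == 0L) {
    return(structure(list(blocks = empty_blocks, anchors = empty_anchors),
                     class = "SyntenicBlocks"))
  }
  binfo <- rbindlist(lapply(chains, function(ch) {
    sub <- a[ch$rows]
    data.table(chr_a = ch$chr_a, chr_b = ch$chr_b,
               orientation = ch$orientation,
               n_anchors = length(ch$rows), score = ch$score,
               start_a = min(sub$rank_a), end_a = max(sub$rank_a),
               start_b = min(sub$rank_b), end_b = max(sub$rank_b),
               rows = list(ch$rows))
  }))
  setorder(binfo, chr_a, chr_b, start_a, start_b)
  binfo[, block_id := sprintf("%s:%s:%03d", chr_a, chr_b,
                              seq_len(.N)), by = .(chr_a, chr_b)]
  anch <- rbindlist(lapply(seq_len(nrow(binfo)), function(i) {
    sub <- a[binfo$rows[[i]]]
    sub[, block_id := binfo$block_id[i]]
    setorder(sub, rank_a)
    sub
  }))
  anch[, row_id := NULL]
  blocks <- as.data.frame(binfo[, .(block_id, chr_a, chr_b, orientation,
                                    n_anchors, score, start_a, end_a,
                                    start_b, end_b)])
  structure(list(blocks = blocks, anchors = as.data.frame(anch)),
            class = "SyntenicBlocks")
}

#' @export
print.SyntenicBlocks <- function(x, ...) {
  cat("SyntenicBlocks: ", nrow(x$blocks), " blocks, ",
      nrow(x$anchors), " anchors\n", sep = "")
  invisible(x)
}

#' Within-genome (self) synteny
#'
#' Chains within-genome homolog pairs into syntenic paralog blocks after
#' removing near-diagonal anchors (same chromosome and
#' `|rank_a - rank_b| < min_diag_offset`), which would otherwise chain the
#' trivial self-identity and tandem arrays into spurious blocks. Each
#' unordered pair is counted once.
#'
#' @param genome A [genome_annotation()] object.
#' @param pairs Within-genome filtered pairs from [cscore_filter()].
#' @param min_diag_offset Diagonal exclusion half-width in ranks
#'   (default 30).
#' @param min_pairs,max_gap Chaining parameters (see [chain_anchors()]).
#' @param max_tandem_gap Tandem collapsing gap (see [collapse_tandem()]).
#' @return A `SyntenicBlocks` object.
#' @export
self_synteny <- function(genome, pairs, min_diag_offset = 30L,
                         min_pairs = 5L, max_gap = 20L,
                         max_tandem_gap = 5L) {
  anchors <- make_anchors(pairs, genome, genome)
  if (nrow(anchors) > 0L) {
    keep <- !(anchors$chr_a == anchors$chr_b &
                abs(anchors$rank_a - anchors$rank_b) < min_diag_offset)
    anchors <- anchors[keep, , drop = FALSE]
  }
  anchors <- collapse_tandem(anchors, max_tandem_gap = max_tandem_gap)
  chain_anchors(anchors, min_pairs = min_pairs, max_gap = max_gap)
}

#' Classify the duplication mode of family copies
#'
#' A family copy is `syntenic` if it participates in an anchor of any
#' retained block; otherwise `tandem` if another copy of the same family
#' lies within `max_tandem_gap` ranks on the same chromosome; otherwise
#' `dispersed`.
#'
#' @param assignments Family assignments (possibly merged).
#' @param blocks A `SyntenicBlocks` object (or a list of them).
#' @param genome The [genome_annotation()] object.
#' @param max_tandem_gap Rank distance defining a tandem pair (default 5).
#' @return The assignments `data.frame` with a `mode` column.
#' @export
classify_duplicate_mode <- function(assignments, blocks, genome,
                                    max_tandem_gap = 5L) {
  if (inherits(blocks, "SyntenicBlocks")) {
    blocks <- list(blocks)
  }
  anchor_genes <- unique(unlist(lapply(blocks, function(b) {
    c(b$anchors$gene_a, b$anchors$gene_b)
  })))
  # merged units count as syntenic if any member is anchored
  members <- function(gene_id, merged_from) {
    if (!is.na(merged_from)) strsplit(merged_from, ",")[[1]] else gene_id
  }
  a <- as.data.frame(assignments)
  n <- nrow(a)
  mode <- character(n)
  for (i in seq_len(n)) {
    mem <- members(a$gene_id[i], a$merged_from[i])
    if (any(mem %in% anchor_genes)) {
      mode[i] <- "syntenic"
      next
    }
    same <- which(a$family == a$family[i] &
                    a$chromosome == a$chromosome[i] &
                    seq_len(n) != i)
    near <- any(abs(a$rank[same] - a$rank[i]) <= max_tandem_gap |
                  abs(a$rank_hi[same] - a$rank[i]) <= max_tandem_gap |
                  abs(a$rank[same] - a$rank_hi[i]) <= max_tandem_gap)
    mode[i] <- if (length(same) && near) "tandem" else "dispersed"
  }
  a$mode <- mode
  a
}
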