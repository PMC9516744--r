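# Tandem collapsing, anchor chaining, self-synteny, duplicate modes.

diag_anchors <- function(n, chr_a = "A1", chr_b = "B1", start_a = 0L,
                         start_b = 0L, step_b = 1L, score = 10) {
  if (n == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      chr_a = character(), chr_b = character(),
                      rank_a = integer(), rank_b = integer(),
                      score = numeric()))
  }
  data.frame(gene_a = paste0(chr_a, "_", seq_len(n)),
             gene_b = paste0(chr_b, "_", seq_len(n)),
             chr_a = chr_a, chr_b = chr_b,
             rank_a = start_a + seq_len(n) - 1L,
             rank_b = start_b + (seq_len(n) - 1L) * step_b,
             score = score, stringsAsFactors = FALSE)
}

test_that("tandem arrays collapse to their best-scoring member", {
  a <- rbind(
    data.frame(gene_a = c("t1", "t2"), gene_b = "p1", chr_a = "c1",
               chr_b = "c2", rank_a = c(10L, 11L), rank_b = 5L,
               score = c(40, 60), stringsAsFactors = FALSE),
    data.frame(gene_a = c("u1", "u2"), gene_b = "p2", chr_a = "c1",
               chr_b = "c2", rank_a = c(30L, 50L), rank_b = 9L,
               score = c(70, 30), stringsAsFactors = FALSE))
  out <- collapse_tandem(a, max_tandem_gap = 5)
  expect_equal(sort(out$gene_a), c("t2", "u1", "u2"))  # t1/t2 collapsed
  expect_equal(out$score[out$gene_a == "t2"], 60)      # max member kept
  arr <- attr(out, "tandem_arrays")
  expect_true(any(grepl("t1", arr$members)))
  # random configurations: representative is always the max-score member
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    cfg <- data.frame(
      gene_a = paste0("g", seq_len(n)), gene_b = "partner",
      chr_a = "c1", chr_b = "c2",
      rank_a = sort(sample.int(30, n)), rank_b = 1L,
      score = round(runif(n, 1, 100), 3), stringsAsFactors = FALSE)
    got <- collapse_tandem(cfg, max_tandem_gap = 5)
    # brute-force clustering on rank gaps
    brk <- cumsum(c(1L, as.integer(diff(cfg$rank_a) > 5)))
    expected <- vapply(split(cfg$score, brk), max, numeric(1))
    expect_equal(sort(got$score), sort(unname(expected)))
  }
})

test_that("five collinear anchors chain into one block, four do not", {
  b5 <- chain_anchors(diag_anchors(5), min_pairs = 5, max_gap = 20)
  expect_equal(nrow(b5$blocks), 1L)
  expect_equal(b5$blocks$n_anchors, 5L)
  expect_equal(b5$blocks$orientation, "+")
  expect_equal(b5$blocks$score, 50)
  b4 <- chain_anchors(diag_anchors(4), min_pairs = 5, max_gap = 20)
  expect_equal(nrow(b4$blocks), 0L)
  # reverse orientation is detected
  rev5 <- diag_anchors(5, step_b = -1L, start_b = 10L)
  br <- chain_anchors(rev5, min_pairs = 5, max_gap = 20)
  expect_equal(br$blocks$orientation, "-")
  # empty input
  expect_equal(nrow(chain_anchors(diag_anchors(0))$blocks), 0L)
})

test_that("emitted blocks satisfy the monotonicity invariant", {
  set.seed(21)
  for (rep in 1:10) {
    anchors <- random_anchor_set(40, rank_max = 60)
    res <- chain_anchors(anchors, min_pairs = 3, max_gap = 10)
    if (nrow(res$blocks) == 0L) next
    for (b in res$blocks$block_id) {
      sub <- res$anchors[res$anchors$block_id == b, ]
      sub <- sub[order(sub$rank_a), ]
      expect_true(all(diff(sub$rank_a) > 0))
      expect_true(all(diff(sub$rank_a) <= 10))
      db <- diff(sub$rank_b)
      expect_true(all(db > 0) || all(db < 0))
      expect_true(all(abs(db) <= 10))
    }
    # each anchor is used in at most one block
    key <- paste(res$anchors$gene_a, res$anchors$gene_b)
    expect_false(anyDuplicated(key) > 0)
  }
})

test_that("chaining is optimal against exhaustive enumeration", {
  set.seed(33)
  for (rep in 1:60) {
    anchors <- random_anchor_set(sample(2:12, 1), rank_max = 15)
    res <- chain_anchors(anchors, min_pairs = 1, max_gap = 6)
    got <- max(res$blocks$score)
    expect_equal(got, oracle_best_chain_score(anchors, max_gap = 6))
  }
})

test_that("identical inputs give identical blocks and order", {
  set.seed(5)
  anchors <- random_anchor_set(30, rank_max = 40)
  r1 <- chain_anchors(anchors, min_pairs = 2, max_gap = 10)
  r2 <- chain_anchors(anchors, min_pairs = 2, max_gap = 10)
  expect_identical(r1, r2)
})

test_that("self-synteny excludes the diagonal and finds duplicated segments", {
  set.seed(14)
  # genome whose only homology is the identity mapping: no blocks
  g <- toy_genome(c(c1 = 40))
  sc <- builtin_score(g$proteins, g$proteins, k = 4)
  pr <- cscore_filter(rbind(sc, data.frame(query_id = g$genes$gene_id,
                                           subject_id = g$genes$gene_id,
                                           score = 100)), 0.7)
  expect_equal(nrow(self_synteny(g, pr)$blocks), 0L)
  # a 10-gene segment duplicated onto another chromosome: one block pair
  base <- toy_genome(c(c1 = 40, c2 = 30))
  prot <- base$proteins
  src <- base$genes$gene_id[base$genes$chromosome == "c1"][11:20]
  dst <- base$genes$gene_id[base$genes$chromosome == "c2"][5:14]
  prot[dst] <- prot[src]
  g2 <- genome_annotation("dup", base$genes, prot)
  sc2 <- builtin_score(g2$proteins, g2$proteins, k = 4)
  pr2 <- cscore_filter(sc2, 0.7)
  blocks <- self_synteny(g2, pr2, min_diag_offset = 30)
  expect_equal(nrow(blocks$blocks), 1L)
  expect_equal(blocks$blocks$n_anchors, 10L)
  expect_setequal(unique(c(blocks$anchors$chr_a, blocks$anchors$chr_b)),
                  c("c1", "c2"))
})

test_that("a simulated unfractionated WGD yields one block per segment pair", {
  cfg <- sim_config(n_genes = 120, n_chromosomes = 2,
                    events = list(ev_wgd(2, "w"), ev_diverge(0.1)),
                    seed = 8)
  sim <- simulate_clade(cfg)
  g <- sim$species$sp1
  sc <- builtin_score(g$proteins, g$proteins, k = 4)
  pr <- cscore_filter(sc, 0.7)
  blocks <- self_synteny(g, pr, min_diag_offset = 30)
  # each ancestral chromosome gives exactly one A-vs-B block
  expect_equal(nrow(blocks$blocks), 2L)
  expect_true(all(blocks$blocks$n_anchors >= 55))
  expect_true(all(substr(blocks$blocks$chr_a, 1, 5) ==
                    substr(blocks$blocks$chr_b, 1, 5)))
})

test_that("duplicate modes separate syntenic, tandem and dispersed copies", {
  g <- toy_genome(c(c1 = 30, c2 = 30))
  ids1 <- g$genes$gene_id[g$genes$chromosome == "c1"]
  ids2 <- g$genes$gene_id[g$genes$chromosome == "c2"]
  a <- toy_assignments(g, stats::setNames(
    c("LHY/CCA1", "LHY/CCA1", "LHY/CCA1", "PRR5/9"),
    c(ids1[5], ids1[7], ids2[20], ids2[3])))
  fake_blocks <- list(blocks = data.frame(block_id = "b1"),
                      anchors = data.frame(gene_a = ids1[5],
                                           gene_b = ids2[28]))
  out <- classify_duplicate_mode(a, structure(fake_blocks,
                                              class = "SyntenicBlocks"),
                                 g, max_tandem_gap = 5)
  modes <- stats::setNames(out$mode, out$gene_id)
  expect_equal(unname(modes[ids1[5]]), "syntenic")
  expect_equal(unname(modes[ids1[7]]), "tandem")   # 2 ranks from ids1[5]
  expect_equal(unname(modes[ids2[20]]), "dispersed")
  expect_equal(unname(modes[ids2[3]]), "dispersed")
})
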