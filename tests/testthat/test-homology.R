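# Similarity ingest, k-mer scoring, C-score filtering, family assignment.

test_that("12-column tabular alignment files parse with max/self rules", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "hits.tsv")
  row <- function(q, s, score) {
    paste(q, s, "90.1", "100", "5", "1", "1", "100", "1", "100", "1e-50",
          score, sep = "\t")
  }
  writeLines(c(row("g1", "g2", "250.3"),
               row("g2", "g3", "90"),
               row("g2", "g3", "110"),
               row("g4", "g4", "500")), path)
  rec <- read_pairwise_scores(path)
  expect_equal(rec$score[rec$query_id == "g1"], 250.3)
  expect_equal(rec$score[rec$query_id == "g2" & rec$subject_id == "g3"], 110)
  expect_false(any(rec$query_id == rec$subject_id))
  writeLines(c(row("g1", "g2", "10"), "g1\tg2\tshort"), path)
  expect_error(read_pairwise_scores(path), "line 2")
})

test_that("k-mer scorer counts shared k-mer multisets", {
  set.seed(7)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  p <- paste(sample(aa, 100, replace = TRUE), collapse = "")
  sc <- builtin_score(c(x = p), c(y = p), k = 4)
  expect_equal(sc$score, 97)  # n - k + 1
  # zero shared k-mers -> pair omitted
  sc2 <- builtin_score(c(x = strrep("A", 30)), c(y = strrep("W", 30)), k = 4)
  expect_equal(nrow(sc2), 0L)
  expect_error(builtin_score(character(0), c(y = p)), "empty proteome")
  expect_error(builtin_score(c(x = p), c(y = p), k = 2), "k must be >= 3")
  # oracle comparison on random proteins
  pa <- stats::setNames(vapply(1:10, function(i) {
    paste(sample(aa, sample(20:60, 1), replace = TRUE), collapse = "")
  }, character(1)), paste0("a", 1:10))
  pb <- stats::setNames(vapply(1:10, function(i) {
    paste(sample(aa, sample(20:60, 1), replace = TRUE), collapse = "")
  }, character(1)), paste0("b", 1:10))
  sc3 <- builtin_score(pa, pb, k = 3, min_score = 1)
  for (i in names(pa)) {
    for (j in names(pb)) {
      expected <- oracle_kmer_score(pa[[i]], pb[[j]], 3)
      got <- sc3$score[sc3$query_id == i & sc3$subject_id == j]
      if (expected == 0) {
        expect_length(got, 0L)
      } else {
        expect_equal(got, as.numeric(expected))
      }
    }
  }
  # the default noise floor drops singleton chance hits
  sc4 <- builtin_score(pa, pb, k = 3)
  expect_true(all(sc4$score >= 2))
})

test_that("C-score filter keeps relative best hits, boundary inclusive", {
  rec <- data.frame(
    query_id = c("a", "a", "b", "c", "d"),
    subject_id = c("b", "c", "c", "d", "e"),
    score = c(100, 60, 80, 70, 100), stringsAsFactors = FALSE)
  # best(a)=100, best(b)=100, best(c)=80, best(d)=100, best(e)=100
  out <- cscore_filter(rec, threshold = 0.7)
  expect_true(all(c("a", "b") %in% c(out$gene_a, out$gene_b)))
  ab <- out[out$gene_a == "a" & out$gene_b == "b", ]
  expect_equal(ab$c_score, 1.0)               # 100 / max(100,100)
  expect_false(any(out$gene_a == "a" & out$gene_b == "c"))  # 60/100 = 0.6
  cd <- out[out$gene_a == "c" & out$gene_b == "d", ]
  expect_equal(nrow(cd), 1L)                  # 70/100 = 0.7, inclusive
  expect_equal(cd$c_score, 0.7)
  expect_error(cscore_filter(rec, threshold = 0), "\\(0, 1\\]")
  expect_error(cscore_filter(rec, threshold = 1.2), "\\(0, 1\\]")
})

test_that("C-score is symmetric and the filter is anti-monotone", {
  set.seed(42)
  genes <- paste0("g", 1:12)
  rec <- expand.grid(query_id = genes, subject_id = genes,
                     stringsAsFactors = FALSE)
  rec <- rec[rec$query_id != rec$subject_id, ]
  rec$score <- round(runif(nrow(rec), 10, 200), 1)
  # symmetry: filtering the reversed records gives the same pairs
  fwd <- cscore_filter(rec, 0.5)
  rev <- cscore_filter(data.frame(query_id = rec$subject_id,
                                  subject_id = rec$query_id,
                                  score = rec$score), 0.5)
  expect_equal(fwd, rev)
  # raising the threshold never adds pairs
  key <- function(d) paste(d$gene_a, d$gene_b)
  prev <- key(cscore_filter(rec, 0.3))
  for (th in c(0.5, 0.7, 0.9, 1.0)) {
    cur <- key(cscore_filter(rec, th))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("family assignment anchors to the best seed and flags ties", {
  set.seed(3)
  g <- toy_genome(c(c1 = 6))
  ids <- g$genes$gene_id
  panel <- data.frame(
    family = c("LHY/CCA1", "PRR5/9", "PRR3/7"),
    seed_id = c("s_lhy", "s_prr59", "s_prr37"),
    sequence = c(g$proteins[[ids[2]]],      # exact copy of gene 2
                 paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                              60, TRUE), collapse = ""),
                 paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                              60, TRUE), collapse = "")),
    stringsAsFactors = FALSE)
  out <- assign_families(g, panel, min_c = 0.3)
  expect_equal(out$gene_id, ids[2])
  expect_equal(out$family, "LHY/CCA1")
  expect_equal(out$c_score, 1.0)
  # a gene matching two families equally well is ambiguous
  g2 <- g
  g2$proteins[ids[4]] <- panel$sequence[2]
  panel2 <- panel
  panel2$sequence[3] <- panel$sequence[2]  # PRR3/7 seed identical to PRR5/9
  out2 <- assign_families(g2, panel2, min_c = 0.3)
  expect_false(ids[4] %in% out2$gene_id)
  expect_true(ids[4] %in% attr(out2, "ambiguous")$gene_id)
  # input order invariance
  shuf <- g$genes[sample(nrow(g$genes)), ]
  g3 <- genome_annotation("toy", shuf, g$proteins)
  expect_equal(assign_families(g3, panel, min_c = 0.3), out,
               ignore_attr = TRUE)
  # a family without any seed protein is an error
  panel3 <- panel
  panel3$sequence[1] <- ""
  expect_error(assign_families(g, panel3), "without seed protein")
})

test_that("split gene models merge into compound units", {
  g <- toy_genome(c(c1 = 10))
  ids <- g$genes$gene_id
  a <- toy_assignments(g, stats::setNames(
    c("PRR5/9", "PRR5/9", "LHY/CCA1", "PRR3/7"),
    c(ids[3], ids[4], ids[6], ids[9])))
  m <- merge_split_models(a, g, max_gap_ranks = 1)
  merged <- m[m$family == "PRR5/9", ]
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$gene_id, paste(ids[3], ids[4], sep = "_"))
  expect_equal(merged$rank, 2L)
  expect_equal(merged$rank_hi, 3L)
  expect_equal(merged$merged_from, paste(ids[3], ids[4], collapse = ","
                                         , sep = ","))
  expect_equal(nrow(m), 3L)
  # members 5 ranks apart do not merge
  a2 <- toy_assignments(g, stats::setNames(c("PRR5/9", "PRR5/9"),
                                           c(ids[1], ids[6])))
  expect_equal(nrow(merge_split_models(a2, g, 1)), 2L)
  # three consecutive members collapse transitively into one unit
  a3 <- toy_assignments(g, stats::setNames(rep("PRR5/9", 3), ids[4:6]))
  m3 <- merge_split_models(a3, g, 1)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$gene_id, paste(ids[4:6], collapse = "_"))
  expect_equal(m3$start, min(a3$start))
  expect_equal(m3$end, max(a3$end))
})
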