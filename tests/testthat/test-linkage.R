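# Intervening-gene distances, linkage scans, combination labels,
# retention summaries, permutation null.

test_that("intervening-gene counts follow the strict between rule", {
  g <- toy_genome(c(c1 = 20, c2 = 5))
  ids <- g$genes$gene_id[g$genes$chromosome == "c1"]
  expect_equal(count_intervening(g, ids[11], ids[15]), 3L)  # ranks 10, 14
  expect_equal(count_intervening(g, ids[15], ids[11]), 3L)  # symmetric
  expect_equal(count_intervening(g, ids[3], ids[4]), 0L)    # adjacent
  other <- g$genes$gene_id[g$genes$chromosome == "c2"][1]
  expect_error(count_intervening(g, ids[1], other), "different chromosomes")
  # merged units count as one gene: members are not intervening
  a <- toy_assignments(g, stats::setNames(c("PRR5/9", "PRR5/9", "LHY/CCA1"),
                                          c(ids[5], ids[6], ids[9])))
  m <- merge_split_models(a, g, 1)
  unit <- m$gene_id[m$family == "PRR5/9"]
  expect_equal(count_intervening(g, unit, ids[9], assignments = m), 2L)
})

test_that("linkage scan respects thresholds and reports pairs once", {
  g <- toy_genome(c(c1 = 30, c2 = 10))
  ids <- g$genes$gene_id[g$genes$chromosome == "c1"]
  a <- toy_assignments(g, stats::setNames(
    c("LHY/CCA1", "PRR5/9", "PRR5/9"), c(ids[6], ids[10], ids[25])))
  hits <- find_linkages(g, a, "LHY/CCA1", "PRR5/9", max_intervening = 12)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$n_intervening, 3L)  # ranks 5 and 9
  expect_equal(hits$combination, "LHY/CCA1-PRR5/9")
  expect_true(hits$canonical)
  # both thresholds absent is an error
  expect_error(find_linkages(g, a, "LHY/CCA1", "PRR5/9"),
               "at least one")
  # families on different chromosomes give an empty result
  b <- toy_assignments(g, stats::setNames(
    c("LHY/CCA1", "PRR5/9"),
    c(ids[1], g$genes$gene_id[g$genes$chromosome == "c2"][1])))
  expect_equal(nrow(find_linkages(g, b, "LHY/CCA1", "PRR5/9",
                                  max_intervening = 12)), 0L)
  # bp mode: genes 8 Mb apart pass a 12 Mb cap with no gene-count cap
  wide <- data.frame(
    gene_id = c("w1", "w2"), chromosome = "LG04",
    start = c(1000000L, 9000000L), end = c(1005000L, 9005000L),
    strand = "+", stringsAsFactors = FALSE)
  gw <- genome_annotation("moss", wide,
                          stats::setNames(c("MSEQ", "WSEQ"), wide$gene_id))
  aw <- toy_assignments(gw, stats::setNames(c("LHY/CCA1", "PRR3/7"),
                                            c("w1", "w2")))
  hw <- find_linkages(gw, aw, "LHY/CCA1", "PRR3/7", max_bp = 12e6)
  expect_equal(nrow(hw), 1L)
  expect_equal(hw$bp_distance, 8000000L)
  expect_false(hw$canonical)  # cross-clade combination, flagged
})

test_that("linkage scan is monotone in the gene-count threshold", {
  set.seed(77)
  g <- toy_genome(c(c1 = 60, c2 = 60))
  for (rep in 1:10) {
    picks <- sample(g$genes$gene_id, 8)
    a <- toy_assignments(g, stats::setNames(
      rep(c("LHY/CCA1", "PRR5/9"), each = 4), picks))
    prev <- 0L
    for (th in c(0, 2, 5, 12, 40)) {
      n <- nrow(find_linkages(g, a, "LHY/CCA1", "PRR5/9",
                              max_intervening = th))
      expect_gte(n, prev)
      prev <- n
    }
  }
})

test_that("combination labels put the sMYB first and flag non-canonical", {
  expect_equal(classify_combination("LHY", "PRR5"),
               list(label = "LHY-PRR5", canonical = TRUE))
  expect_equal(classify_combination("PRR5", "LHY")$label, "LHY-PRR5")
  expect_equal(classify_combination("RVE8", "PRR3"),
               list(label = "RVE8-PRR3", canonical = TRUE))
  sph <- classify_combination("LHY/CCA1", "PRR3/7")
  expect_equal(sph$label, "LHY/CCA1-PRR3/7")
  expect_false(sph$canonical)
  expect_true(classify_combination("PIF3", "PHYA")$canonical)
  expect_error(classify_combination("LHY", "NOTAFAM"), "unknown family")
  expect_length(canonical_combinations(), 8L)
  # all eight enumerated combinations classify as canonical
  for (cmb in canonical_combinations()) {
    parts <- strsplit(cmb, "-")[[1]]
    expect_true(classify_combination(parts[1], parts[2])$canonical)
  }
})

test_that("copy table counts merged units once and flags absences", {
  g <- toy_genome(c(c1 = 12, c2 = 12))
  ids <- g$genes$gene_id
  a1 <- merge_split_models(toy_assignments(g, stats::setNames(
    c("LHY/CCA1", "LHY/CCA1", "PRR5/9", "PRR5/9"),
    c(ids[1], ids[15], ids[5], ids[6]))), g, 1)
  a2 <- toy_assignments(g, stats::setNames("LHY/CCA1", ids[3]))
  tab <- family_copy_table(list(sp1 = a1, sp2 = a2))
  expect_equal(tab[tab$species == "sp1", "LHY/CCA1"], 2L)
  expect_equal(tab[tab$species == "sp1", "PRR5/9"], 1L)  # merged once
  expect_equal(tab[tab$species == "sp2", "PRR5/9"], 0L)  # PAV candidate
  loc <- attr(tab, "locations")
  expect_true(all(c("species", "chromosome", "rank") %in% names(loc)))
  # simulated clade with known copy history matches the truth labels
  sim <- simulate_clade(easy_regime_config(seed = 31, n_genes = 150))
  res_assign <- lapply(sim$species, function(gn) {
    merge_split_models(assign_families(gn, sim$seed_panel, 0.3), gn, 1)
  })
  got <- family_copy_table(res_assign)
  truth_counts <- table(sim$truth$gene_map$species,
                        sim$truth$gene_map$family)
  for (sp in rownames(truth_counts)) {
    for (f in colnames(truth_counts)) {
      expect_equal(got[got$species == sp, f],
                   unname(truth_counts[sp, f]),
                   label = paste(sp, f))
    }
  }
})

test_that("retention summary fractions match an independent recount", {
  mk <- function(fa, fb) {
    data.frame(species = "x", chromosome = "c", gene_a = "a", gene_b = "b",
               family_a = fa, family_b = fb, n_intervening = 1L,
               bp_distance = 100L, combination = paste0(fa, "-", fb),
               canonical = TRUE, in_syntenic_block = NA,
               members_a = "a", members_b = "b", stringsAsFactors = FALSE)
  }
  none <- mk("LHY/CCA1", "PRR5/9")[0, ]
  hits <- list(
    s1 = rbind(mk("LHY/CCA1", "PRR5/9"), mk("RVE4/8", "PRR3/7")),
    s2 = mk("LHY/CCA1", "PRR5/9"),
    s3 = none,
    s4 = rbind(mk("RVE4/8", "PRR3/7"), mk("RVE4/8", "PRR3/7")))
  out <- retention_summary(hits)
  expect_equal(out$summary$pct_at_least_one, 75.0)
  expect_equal(out$summary$pct_both, 25.0)
  expect_equal(out$summary$pct_more_than_one, 25.0)
  expect_error(retention_summary(list()), "empty species set")
  # brute-force recount over random hit tables
  set.seed(12)
  fams <- list(c("LHY", "PRR9"), c("RVE8", "PRR7"), c("LHY", "PRR5"))
  for (rep in 1:10) {
    hb <- lapply(1:6, function(i) {
      n <- sample(0:3, 1)
      if (n == 0) return(none)
      do.call(rbind, lapply(seq_len(n), function(j) {
        f <- fams[[sample.int(3, 1)]]
        mk(f[1], f[2])
      }))
    })
    names(hb) <- paste0("sp", 1:6)
    out <- retention_summary(hb)
    classes <- c("LHY/CCA1-PRR5/9", "RVE4/8-PRR3/7")
    cls_of <- function(h) {
      if (nrow(h) == 0) return(character(0))
      vapply(seq_len(nrow(h)), function(i) {
        if (h$family_a[i] %in% c("LHY", "CCA1")) "LHY/CCA1-PRR5/9"
        else "RVE4/8-PRR3/7"
      }, character(1))
    }
    manual_any <- mean(vapply(hb, function(h) length(cls_of(h)) > 0,
                              logical(1)))
    manual_both <- mean(vapply(hb, function(h) {
      all(classes %in% cls_of(h))
    }, logical(1)))
    manual_multi <- mean(vapply(hb, function(h) {
      any(table(cls_of(h)) > 1)
    }, logical(1)))
    expect_equal(out$summary$pct_at_least_one, round(100 * manual_any, 1))
    expect_equal(out$summary$pct_both, round(100 * manual_both, 1))
    expect_equal(out$summary$pct_more_than_one,
                 round(100 * manual_multi, 1))
  }
})

test_that("permutation null handles the degenerate two-gene genome", {
  g <- toy_genome(c(c1 = 2))
  ids <- g$genes$gene_id
  a <- toy_assignments(g, stats::setNames(c("LHY/CCA1", "PRR5/9"), ids))
  res <- permutation_null(g, a, "LHY/CCA1", "PRR5/9", n_perm = 100,
                          seed = 4)
  expect_equal(res$p_value, 1.0)
  expect_equal(res$observed_min_distance, 0)
  expect_error(permutation_null(g, a, "LHY/CCA1", "RVE4/8", 100, 1),
               "absent")
  expect_error(permutation_null(g, a, "LHY/CCA1", "PRR5/9", n_perm = 10),
               ">= 100")
})

test_that("sampled p agrees with exhaustive enumeration on toy genomes", {
  configs <- list(
    list(sizes = c(c1 = 6), fam_at = c(1, 3)),
    list(sizes = c(c1 = 4, c2 = 2), fam_at = c(1, 2)),
    list(sizes = c(c1 = 3, c2 = 3), fam_at = c(2, 5)))
  n_perm <- 400
  for (cfg in configs) {
    g <- toy_genome(cfg$sizes)
    ids <- g$genes$gene_id
    a <- toy_assignments(g, stats::setNames(c("LHY/CCA1", "PRR5/9"),
                                            ids[cfg$fam_at]))
    res <- permutation_null(g, a, "LHY/CCA1", "PRR5/9", n_perm = n_perm,
                            seed = 99)
    exact <- oracle_exact_perm_p(g$genes$chromosome, g$genes$rank, 1, 1,
                                 res$observed_min_distance)
    se <- sqrt(exact * (1 - exact) / n_perm)
    expect_lt(abs(res$p_value - exact), 3 * se + 2 / (n_perm + 1))
  }
  # determinism: same seed, same p
  g <- toy_genome(c(c1 = 6))
  a <- toy_assignments(g, stats::setNames(c("LHY/CCA1", "PRR5/9"),
                                          g$genes$gene_id[c(1, 4)]))
  r1 <- permutation_null(g, a, "LHY/CCA1", "PRR5/9", 200, seed = 7)
  r2 <- permutation_null(g, a, "LHY/CCA1", "PRR5/9", 200, seed = 7)
  expect_identical(r1, r2)
})
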