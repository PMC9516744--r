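# Same-chromosome genetic linkage between gene families: intervening-gene
# counts, combination labels, cross-species retention, permutation null.

# Family vocabulary for the canonical clock linkage classes. Merged labels
# (e.g. "PRR5/9") are used when orthology cannot resolve the Arabidopsis
# paralogs, as in species outside the Brassicaceae.
.fam_groups <- list(
  smyb_lhy = c("LHY", "CCA1", "LHY/CCA1", "CCA1/LHY"),
  smyb_rve = c("RVE4", "RVE8", "RVE4/8", "RVE8/4"),
  prr59 = c("PRR5", "PRR9", "PRR5/9", "PRR9/5"),
  prr37 = c("PRR3", "PRR7", "PRR3/7", "PRR7/3"),
  pif = "PIF3",
  phy = "PHYA")

fam_group <- function(label) {
  hit <- vapply(.fam_groups, function(v) label %in% v, logical(1))
  if (!any(hit)) {
    return(NA_character_)
  }
  names(.fam_groups)[which(hit)[1]]
}

#' The eight canonical sMYB-PRR combinations
#'
#' The LHY/CCA1-PRR5/9 and RVE4/8-PRR3/7 linkage classes each comprise four
#' resolvable gene-pair combinations, eight in total.
#'
#' @return Character vector of the eight canonical labels.
#' @export
canonical_combinations <- function() {
  c("LHY-PRR5", "LHY-PRR9", "CCA1-PRR5", "CCA1-PRR9",
    "RVE4-PRR3", "RVE4-PRR7", "RVE8-PRR3", "RVE8-PRR7")
}

#' Classify a family-pair combination
#'
#' Produces the canonical `"A-B"` label with the sMYB (or PIF) member
#' first. A combination is canonical when the two families belong to
#' matched sub-clades: LHY/CCA1 with PRR5/9, RVE4/8 with PRR3/7, or PIF3
#' with PHYA. Cross-clade pairs (e.g. the Sphagnum-style LHY/CCA1-PRR3/7)
#' are labeled but flagged non-canonical.
#'
#' @param family_a,family_b Family labels from the sub-clade vocabulary
#'   (LHY, CCA1, RVE4, RVE8, PRR3, PRR5, PRR7, PRR9, merged forms such as
#'   "LHY/CCA1" or "PRR5/9", PIF3, PHYA).
#' @return List with elements `label` and `canonical`.
#' @export
classify_combination <- function(family_a, family_b) {
  ga <- fam_group(family_a)
  gb <- fam_group(family_b)
  if (is.na(ga)) {
    stop("unknown family label: ", family_a)
  }
  if (is.na(gb)) {
    stop("unknown family label: ", family_b)
  }
  first_groups <- c("smyb_lhy", "smyb_rve", "pif")
  if (ga %in% first_groups == (gb %in% first_groups)) {
    # two sMYB-side or two PRR-side labels: keep given order, non-canonical
    return(list(label = paste0(family_a, "-", family_b), canonical = FALSE))
  }
  if (gb %in% first_groups) {
    tmp <- family_a; family_a <- family_b; family_b <- tmp
    tmp <- ga; ga <- gb; gb <- tmp
  }
  canonical <- (ga == "smyb_lhy" && gb == "prr59") ||
    (ga == "smyb_rve" && gb == "prr37") ||
    (ga == "pif" && gb == "phy")
  list(label = paste0(family_a, "-", family_b), canonical = canonical)
}

# Linkage class of a family pair: "LHY/CCA1-PRR5/9", "RVE4/8-PRR3/7",
# "PIF3-PHYA" or NA for cross-clade / unknown combinations.
linkage_class <- function(family_a, family_b) {
  ga <- fam_group(family_a)
  gb <- fam_group(family_b)
  g <- sort(c(ga, gb))
  if (identical(g, sort(c("smyb_lhy", "prr59")))) {
    "LHY/CCA1-PRR5/9"
  } else if (identical(g, sort(c("smyb_rve", "prr37")))) {
    "RVE4/8-PRR3/7"
  } else if (identical(g, sort(c("pif", "phy")))) {
    "PIF3-PHYA"
  } else {
    NA_character_
  }
}

# Genes strictly between two rank spans (merged units count as one gene and
# their members are not intervening).
intervening_from_spans <- function(lo_a, hi_a, lo_b, hi_b) {
  if (lo_a > hi_b) {
    lo_a - hi_b - 1L
  } else if (lo_b > hi_a) {
    lo_b - hi_a - 1L
  } else {
    0L  # overlapping spans
  }
}

#' Count protein-coding genes between two loci
#'
#' The paper's measure of genetic-linkage tightness: the number of
#' protein-coding genes strictly between two loci on one chromosome
#' (`|rank_a - rank_b| - 1` for simple genes; adjacent genes are 0 apart).
#' Merged split models count as one gene and their members are excluded.
#' Symmetric in its arguments.
#'
#' @param genome A [genome_annotation()] object.
#' @param gene_a,gene_b Gene ids (compound ids of merged models allowed
#'   when `assignments` is supplied).
#' @param assignments Optional assignments table carrying merged units.
#' @return Integer count of intervening genes.
#' @export
count_intervening <- function(genome, gene_a, gene_b, assignments = NULL) {
  span_of <- function(g) {
    if (!is.null(assignments) && g %in% assignments$gene_id) {
      i <- match(g, assignments$gene_id)
      list(chr = assignments$chromosome[i],
           lo = assignments$rank[i], hi = assignments$rank_hi[i])
    } else {
      r <- gene_row(genome, g)
      list(chr = r$chromosome, lo = r$rank, hi = r$rank)
    }
  }
  a <- span_of(gene_a)
  b <- span_of(gene_b)
  if (!identical(a$chr, b$chr)) {
    stop("distance undefined: ", gene_a, " (", a$chr, ") and ", gene_b,
         " (", b$chr, ") are on different chromosomes")
  }
  intervening_from_spans(a$lo, a$hi, b$lo, b$hi)
}

#' Find same-chromosome linkages between two families
#'
#' Reports every cross-family same-chromosome pair that passes all supplied
#' thresholds: `max_intervening` (gene-count mode, the angiosperm screen)
#' and/or `max_bp` (physical mode for Mb-scale linkage in bryophyte and
#' gymnosperm genomes). At least one threshold must be given. Each
#' unordered pair is reported once, sorted by (chromosome, smaller rank).
#'
#' @param genome A [genome_annotation()] object.
#' @param assignments Family assignments (after [merge_split_models()]).
#' @param family_a,family_b Family labels to scan.
#' @param max_intervening Maximum intervening protein-coding genes.
#' @param max_bp Maximum start-to-start distance in base pairs.
#' @param blocks Optional `SyntenicBlocks` (or list) used to flag hits
#'   inside retained blocks.
#' @return `data.frame` of linkage hits: `species`, `chromosome`, `gene_a`,
#'   `gene_b`, `family_a`, `family_b`, `n_intervening`, `bp_distance`,
#'   `combination`, `canonical`, `in_syntenic_block`.
#' @export
find_linkages <- function(genome, assignments, family_a, family_b,
                          max_intervening = NULL, max_bp = NULL,
                          blocks = NULL) {
  if (is.null(max_intervening) && is.null(max_bp)) {
    stop("at least one of max_intervening and max_bp must be given")
  }
  empty <- data.frame(species = character(), chromosome = character(),
                      gene_a = character(), gene_b = character(),
                      family_a = character(), family_b = character(),
                      n_intervening = integer(), bp_distance = integer(),
                      combination = character(), canonical = logical(),
                      in_syntenic_block = logical(),
                      members_a = character(), members_b = character())
  a <- assignments[assignments$family == family_a, , drop = FALSE]
  b <- assignments[assignments$family == family_b, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(empty)
  }
  anchor_genes <- character(0)
  if (!is.null(blocks)) {
    if (inherits(blocks, "SyntenicBlocks")) blocks <- list(blocks)
    anchor_genes <- unique(unlist(lapply(blocks, function(x) {
      c(x$anchors$gene_a, x$anchors$gene_b)
    })))
  }
  rows <- list()
  seen <- character(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$gene_id[i] == b$gene_id[j]) next
      if (a$chromosome[i] != b$chromosome[j]) next
      key <- paste(sort(c(a$gene_id[i], b$gene_id[j])), collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      n_int <- intervening_from_spans(a$rank[i], a$rank_hi[i],
                                      b$rank[j], b$rank_hi[j])
      bp <- abs(a$start[i] - b$start[j])
      if (!is.null(max_intervening) && n_int > max_intervening) next
      if (!is.null(max_bp) && bp > max_bp) next
      comb <- tryCatch(classify_combination(family_a, family_b),
                       error = function(e) list(
                         label = paste0(family_a, "-", family_b),
                         canonical = NA))
      in_block <- length(anchor_genes) > 0 &&
        any(c(strsplit(c(a$merged_from[i], a$gene_id[i]), ",")[[1]],
              a$gene_id[i]) %in% anchor_genes) &&
        any(c(strsplit(c(b$merged_from[j], b$gene_id[j]), ",")[[1]],
              b$gene_id[j]) %in% anchor_genes)
      mem <- function(tab, k) {
        if (!is.na(tab$merged_from[k])) tab$merged_from[k]
        else tab$gene_id[k]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        species = genome$species_id, chromosome = a$chromosome[i],
        gene_a = a$gene_id[i], gene_b = b$gene_id[j],
        family_a = family_a, family_b = family_b,
        n_intervening = n_int, bp_distance = bp,
        combination = comb$label, canonical = comb$canonical,
        in_syntenic_block = if (is.null(blocks)) NA else in_block,
        members_a = mem(a, i), members_b = mem(b, j),
        min_rank = min(a$rank[i], b$rank[j]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(empty)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chromosome, out$min_rank), , drop = FALSE]
  out$min_rank <- NULL
  rownames(out) <- NULL
  out
}

#' Per-species family copy-number table
#'
#' Counts assigned copies of each family per species (merged split models
#' count once). Zero counts flag presence/absence-variation candidates.
#' Chromosome locations are attached as the `"locations"` attribute.
#'
#' @param assignments_list Named list (by species) of assignment tables.
#' @param families Optional family labels fixing column order; defaults to
#'   all families observed.
#' @return `data.frame`: one row per species, one integer column per
#'   family, plus `species`.
#' @export
family_copy_table <- function(assignments_list, families = NULL) {
  if (length(assignments_list) == 0L) {
    stop("empty species set")
  }
  if (is.null(families)) {
    families <- sort(unique(unlist(lapply(assignments_list,
                                          function(a) a$family))))
  }
  counts <- t(vapply(assignments_list, function(a) {
    vapply(families, function(f) sum(a$family == f), integer(1))
  }, integer(length(families))))
  if (length(families) == 1L) counts <- matrix(counts, ncol = 1L)
  out <- data.frame(species = names(assignments_list), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  loc <- do.call(rbind, lapply(names(assignments_list), function(sp) {
    a <- assignments_list[[sp]]
    if (nrow(a) == 0L) return(NULL)
    data.frame(species = sp, family = a$family, gene_id = a$gene_id,
               chromosome = a$chromosome, rank = a$rank,
               stringsAsFactors = FALSE)
  }))
  attr(out, "locations") <- loc
  out
}

#' Cross-species retention summary
#'
#' Summarizes how many species retain the linkage classes: the fraction
#' with at least one hit in any class, the fraction with hits in both
#' sMYB-PRR classes, and the fraction with more than one hit in any single
#' class. Fractions are reported as percentages to 0.1.
#'
#' @param hits_by_species Named list (by species) of linkage-hit tables
#'   from [find_linkages()] (zero-row tables allowed).
#' @param classes The linkage classes considered (default the two sMYB-PRR
#'   classes).
#' @return List with `per_species` (`data.frame` of per-class hit counts)
#'   and `summary` (`data.frame` with percentages `pct_at_least_one`,
#'   `pct_both`, `pct_more_than_one`).
#' @export
retention_summary <- function(hits_by_species,
                              classes = c("LHY/CCA1-PRR5/9",
                                          "RVE4/8-PRR3/7")) {
  if (length(hits_by_species) == 0L) {
    stop("empty species set")
  }
  per <- do.call(rbind, lapply(names(hits_by_species), function(sp) {
    h <- hits_by_species[[sp]]
    cls <- if (nrow(h)) {
      mapply(linkage_class, h$family_a, h$family_b)
    } else {
      character(0)
    }
    cnt <- vapply(classes, function(cl) sum(!is.na(cls) & cls == cl),
                  integer(1))
    d <- data.frame(species = sp, t(cnt), check.names = FALSE,
                    stringsAsFactors = FALSE)
    d
  }))
  rownames(per) <- NULL
  cnts <- as.matrix(per[, classes, drop = FALSE])
  at_least_one <- rowSums(cnts) >= 1L
  both <- rowSums(cnts >= 1L) == length(classes)
  more_than_one <- apply(cnts, 1L, function(x) any(x > 1L))
  pct <- function(x) round(100 * mean(x), 1)
  list(per_species = per,
       summary = data.frame(n_species = nrow(per),
                            pct_at_least_one = pct(at_least_one),
                            pct_both = pct(both),
                            pct_more_than_one = pct(more_than_one)))
}

# Minimum cross-family intervening distance given rank/chromosome vectors;
# Inf when the families are never co-chromosomal.
min_cross_distance <- function(chr_a, rank_a, chr_b, rank_b) {
  best <- Inf
  for (i in seq_along(chr_a)) {
    same <- which(chr_b == chr_a[i])
    if (length(same)) {
      d <- abs(rank_b[same] - rank_a[i]) - 1L
      d[d < 0L] <- 0L
      best <- min(best, d)
    }
  }
  best
}

#' Permutation null for family proximity
#'
#' Tests whether two families are closer on the genome than expected by
#' chance. Family labels are shuffled uniformly over all rank slots
#' genome-wide (family sizes and chromosome gene counts preserved); the
#' statistic is the minimum cross-family intervening-gene distance
#' (infinite when the families never share a chromosome, which compares as
#' larger than any finite value). The p-value uses the add-one estimator
#' `p = (1 + #{perm <= obs}) / (n_perm + 1)`, so p is never 0.
#'
#' @param genome A [genome_annotation()] object.
#' @param assignments Family assignments.
#' @param family_a,family_b Family labels (each must have >= 1 copy).
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed; identical seed and inputs give identical p.
#' @return List of class `NullResult`: `observed_min_distance`, `n_perm`,
#'   `p_value`, `seed`.
#' @export
permutation_null <- function(genome, assignments, family_a, family_b,
                             n_perm = 999L, seed = 1L) {
  if (n_perm < 100L) {
    stop("n_perm must be >= 100")
  }
  a <- assignments[assignments$family == family_a, , drop = FALSE]
  b <- assignments[assignments$family == family_b, , drop = FALSE]
  if (nrow(a) == 0L) {
    stop("family absent from genome: ", family_a)
  }
  if (nrow(b) == 0L) {
    stop("family absent from genome: ", family_b)
  }
  obs <- min_cross_distance(a$chromosome, a$rank, b$chromosome, b$rank)
  slots_chr <- genome$genes$chromosome
  slots_rank <- genome$genes$rank
  G <- length(slots_chr)
  ka <- nrow(a)
  kb <- nrow(b)
  count <- with_seed(seed, {
    hits <- 0L
    for (p in seq_len(n_perm)) {
      idx <- sample.int(G, ka + kb)
      ia <- idx[seq_len(ka)]
      ib <- idx[ka + seq_len(kb)]
      stat <- min_cross_distance(slots_chr[ia], slots_rank[ia],
                                 slots_chr[ib], slots_rank[ib])
      if (stat <= obs) hits <- hits + 1L
    }
    hits
  })
  structure(list(observed_min_distance = obs, n_perm = n_perm,
                 p_value = (1 + count) / (n_perm + 1), seed = seed),
            class = "NullResult")
}

#' @export
print.NullResult <- function(x, ...) {
  cat("Permutation null: observed min distance = ",
      x$observed_min_distance, " genes, p = ",
      format(x$p_value, digits = 4), " (", x$n_perm,
      " permutations, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
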