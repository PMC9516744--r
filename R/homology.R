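# Pairwise protein similarity, C-score (relative-best-hit) filtering,
# seed-panel family assignment, and split-gene-model merging.

#' Read a 12-column tabular alignment file
#'
#' Accepts the standard 12-column tabular alignment dialect (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, e-value, bit score). Column 12 is taken as the similarity
#' score. Self-hits are dropped and duplicate (query, subject) rows keep the
#' maximum score.
#'
#' @param path Path to the tabular file.
#' @return `data.frame` with columns `query_id`, `subject_id`, `score`.
#' @export
read_pairwise_scores <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !(lines == "" | startsWith(lines, "#"))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- which(keep)[which(nf < 12L)[1]]
    stop("expected >= 12 tab-separated columns at line ", bad, " of ", path)
  }
  dt <- data.table(
    query_id = vapply(fields, `[`, character(1), 1L),
    subject_id = vapply(fields, `[`, character(1), 2L),
    score = as.numeric(vapply(fields, `[`, character(1), 12L)))
  if (anyNA(dt$score)) {
    bad <- which(keep)[which(is.na(dt$score))[1]]
    stop("non-numeric score at line ", bad, " of ", path)
  }
  dt <- dt[query_id != subject_id]
  dt <- dt[, .(score = max(score)), by = .(query_id, subject_id)]
  as.data.frame(dt)
}

# Long table of amino-acid k-mer multiset counts: (id, kmer, n)
kmer_counts <- function(proteins, k) {
  if (length(proteins) == 0L) {
    stop("empty proteome")
  }
  if (is.null(names(proteins)) || any(names(proteins) == "")) {
    stop("proteins must be a named character vector")
  }
  seqs <- sub("\\*$", "", unname(proteins))
  n <- nchar(seqs)
  keep <- which(n >= k)
  if (length(keep) == 0L) {
    return(data.table(id = character(), kmer = character(), n = integer()))
  }
  parts <- lapply(keep, function(i) {
    nk <- n[i] - k + 1L
    data.table(id = names(proteins)[i],
               kmer = substring(seqs[i], 1:nk, k:n[i]))
  })
  dt <- rbindlist(parts)
  dt[, .(n = .N), by = .(id, kmer)]
}

#' Built-in k-mer protein similarity scorer
#'
#' Desk-scale all-by-all scorer: the score of a protein pair is the size of
#' the multiset intersection of their amino-acid k-mers. Identical proteins
#' of length L score L - k + 1. Pairs sharing no k-mer are omitted, as are
#' self-hits and pairs below the `min_score` noise floor (unrelated
#' proteins share the odd k-mer by chance; such singleton hits would
#' otherwise count as a gene's best hit and pass any relative-best-hit
#' filter). Deterministic.
#'
#' This scorer is intended for simulated proteomes and tests; real analyses
#' normally supply an external aligner's 12-column table via
#' [read_pairwise_scores()].
#'
#' @param proteins_a,proteins_b Named character vectors of protein
#'   sequences. For a within-genome (self) comparison pass the same vector
#'   twice.
#' @param k K-mer length (>= 3, default 4).
#' @param min_score Minimum shared k-mer count to report a pair
#'   (default 2).
#' @return `data.frame` with columns `query_id`, `subject_id`, `score`.
#' @export
builtin_score <- function(proteins_a, proteins_b, k = 4L, min_score = 2) {
  if (k < 3L) {
    stop("k must be >= 3")
  }
  ka <- kmer_counts(proteins_a, k)
  kb <- kmer_counts(proteins_b, k)
  m <- merge(ka, kb, by = "kmer", allow.cartesian = TRUE,
             suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      score = numeric()))
  }
  sc <- m[, .(score = as.numeric(sum(pmin(n_a, n_b)))),
          by = .(query_id = id_a, subject_id = id_b)]
  sc <- sc[query_id != subject_id & score >= min_score & score > 0]
  setorder(sc, query_id, subject_id)
  as.data.frame(sc)
}

#' C-score filter for homolog pairs
#'
#' The C-score of a pair is its alignment score divided by the larger of the
#' two genes' best scores against any partner:
#' `c = score(a,b) / max(best(a), best(b))`. Pairs with C-score at or above
#' `threshold` (boundary inclusive) are retained; a pair that is the best
#' hit of both genes has C-score 1. Records are symmetrized, so (a,b) and
#' (b,a) rows collapse to one pair.
#'
#' @param records `data.frame` with `query_id`, `subject_id`, `score`
#'   (from [read_pairwise_scores()] or [builtin_score()]).
#' @param threshold C-score cutoff in (0, 1]; default 0.7.
#' @return `data.frame` of filtered pairs: `gene_a`, `gene_b`, `score`,
#'   `c_score`, with `gene_a < gene_b` lexicographically.
#' @export
cscore_filter <- function(records, threshold = 0.7) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]")
  }
  dt <- as.data.table(records)
  dt <- dt[query_id != subject_id]
  if (nrow(dt) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), c_score = numeric()))
  }
  dt[, `:=`(gene_a = pmin(query_id, subject_id),
            gene_b = pmax(query_id, subject_id))]
  pairs <- dt[, .(score = max(score)), by = .(gene_a, gene_b)]
  best <- rbindlist(list(pairs[, .(gene = gene_a, score)],
                         pairs[, .(gene = gene_b, score)]))
  best <- best[, .(best = max(score)), by = gene]
  pairs[best, on = .(gene_a = gene), best_a := i.best]
  pairs[best, on = .(gene_b = gene), best_b := i.best]
  pairs[, c_score := score / pmax(best_a, best_b)]
  out <- pairs[c_score >= threshold - 1e-12,
               .(gene_a, gene_b, score, c_score)]
  setorder(out, gene_a, gene_b)
  as.data.frame(out)
}

#' Assign genes to curated families from a seed panel
#'
#' Each gene is scored against every seed protein with the k-mer scorer and
#' assigned to the family of its best-C-score seed when that C-score reaches
#' `min_c`. C-scores here use the gene-vs-panel comparison: the denominator
#' is the larger of the gene's best score against any seed and that seed's
#' best score against any gene. Genes tying (within 1e-9) across two
#' different families are left unassigned and reported in the
#' `"ambiguous"` attribute of the result.
#'
#' @param genome A [genome_annotation()] object.
#' @param seed_panel `data.frame` with columns `family`, `seed_id`,
#'   `sequence` (amino acids); see [read_seed_panel()].
#' @param min_c Minimum C-score for assignment (default 0.3).
#' @param k K-mer length for the scorer.
#' @return `data.frame` of assignments: `gene_id`, `family`, `seed_id`,
#'   `c_score`, `chromosome`, `rank`, `rank_hi`, `start`, `end`,
#'   `merged_from` (NA until [merge_split_models()]).
#' @export
assign_families <- function(genome, seed_panel, min_c = 0.3, k = 4L) {
  seed_panel <- as.data.frame(seed_panel, stringsAsFactors = FALSE)
  need <- c("family", "seed_id", "sequence")
  if (!all(need %in% names(seed_panel))) {
    stop("seed_panel needs columns: ", paste(need, collapse = ", "))
  }
  empty_fam <- unique(seed_panel$family[is.na(seed_panel$sequence) |
                                          seed_panel$sequence == ""])
  if (length(empty_fam)) {
    stop("family without seed protein: ", paste(empty_fam, collapse = ", "))
  }
  seeds <- stats::setNames(seed_panel$sequence, seed_panel$seed_id)
  sc <- as.data.table(builtin_score(genome$proteins, seeds, k = k))
  empty_out <- data.frame(gene_id = character(), family = character(),
                          seed_id = character(), c_score = numeric(),
                          chromosome = character(), rank = integer(),
                          rank_hi = integer(), start = integer(),
                          end = integer(), merged_from = character())
  if (nrow(sc) == 0L) {
    attr(empty_out, "ambiguous") <- empty_out
    return(empty_out)
  }
  setnames(sc, c("query_id", "subject_id"), c("gene_id", "seed_id"))
  best_gene <- sc[, .(best_g = max(score)), by = gene_id]
  best_seed <- sc[, .(best_s = max(score)), by = seed_id]
  sc[best_gene, on = "gene_id", best_g := i.best_g]
  sc[best_seed, on = "seed_id", best_s := i.best_s]
  sc[, c_score := score / pmax(best_g, best_s)]
  sc[, family := seed_panel$family[match(seed_id, seed_panel$seed_id)]]
  # best seed per gene; deterministic tie-break by seed_id within a family
  setorder(sc, gene_id, -c_score, seed_id)
  top <- sc[, .SD[1], by = gene_id]
  runner <- sc[, {
    other <- .SD[family != .SD$family[1]]
    .(second_c = if (nrow(other)) other$c_score[1] else -Inf)
  }, by = gene_id]
  top[runner, on = "gene_id", second_c := i.second_c]
  top[, ambiguous := is.finite(second_c) & abs(c_score - second_c) <= 1e-9]
  top <- top[c_score >= min_c - 1e-12]
  gi <- genome$genes
  top[, `:=`(chromosome = gi$chromosome[match(gene_id, gi$gene_id)],
             rank = gi$rank[match(gene_id, gi$gene_id)],
             start = gi$start[match(gene_id, gi$gene_id)],
             end = gi$end[match(gene_id, gi$gene_id)])]
  top[, rank_hi := rank]
  top[, merged_from := NA_character_]
  cols <- c("gene_id", "family", "seed_id", "c_score", "chromosome",
            "rank", "rank_hi", "start", "end", "merged_from")
  amb <- as.data.frame(top[ambiguous == TRUE, ..cols])
  out <- top[ambiguous == FALSE, ..cols]
  setorder(out, chromosome, rank)
  out <- as.data.frame(out)
  attr(out, "ambiguous") <- amb
  out
}

#' Merge split gene models
#'
#' Runs of same-family genes whose consecutive members are within
#' `max_gap_ranks` ranks of each other on one chromosome are merged into a
#' single assignment with compound id `"A_B"` (members joined by `_` in rank
#' order). The merged unit inherits the minimum start, maximum end and the
#' rank span of its members, and counts as one gene in distance
#' computations. This recovers loci split into consecutive gene models
#' during gene prediction.
#'
#' @param assignments Output of [assign_families()].
#' @param genome The matching [genome_annotation()] object.
#' @param max_gap_ranks Maximum rank difference between consecutive members
#'   of a run (default 1 = adjacent genes).
#' @return Assignments `data.frame` with merged rows replacing their
#'   members; `merged_from` lists constituent gene ids comma-separated.
#' @export
merge_split_models <- function(assignments, genome, max_gap_ranks = 1L) {
  a <- as.data.table(assignments)
  if (nrow(a) == 0L) {
    return(assignments)
  }
  setorder(a, chromosome, rank)
  a[, run := cumsum(c(1L, (family[-1] != family[-.N]) |
                        (chromosome[-1] != chromosome[-.N]) |
                        (rank[-1] - rank_hi[-.N] > max_gap_ranks))),
    ]
  merged <- a[, {
    if (.N == 1L) {
      .SD
    } else {
      data.table(gene_id = paste(gene_id, collapse = "_"),
                 family = family[1],
                 seed_id = seed_id[which.max(c_score)],
                 c_score = max(c_score),
                 chromosome = chromosome[1],
                 rank = min(rank),
                 rank_hi = max(rank_hi),
                 start = min(start),
                 end = max(end),
                 merged_from = paste(gene_id, collapse = ","))
    }
  }, by = run]
  merged[, run := NULL]
  setorder(merged, chromosome, rank)
  out <- as.data.frame(merged)
  attr(out, "ambiguous") <- attr(assignments, "ambiguous")
  out
}

#' Read a seed gene panel
#'
#' A seed panel TSV has columns `family_label`, `seed_gene_id`,
#' `seed_source_species`. Seed protein sequences are resolved from the
#' supplied proteomes (named list of [genome_annotation()] objects keyed by
#' species, or a named character vector of sequences keyed by gene id).
#'
#' @param path Path to the panel TSV.
#' @param proteomes Source of seed protein sequences.
#' @return `data.frame` with columns `family`, `seed_id`, `species`,
#'   `sequence`, ready for [assign_families()].
#' @export
read_seed_panel <- function(path, proteomes) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("family_label", "seed_gene_id", "seed_source_species")
  if (!all(need %in% names(tab))) {
    stop("seed panel needs columns: ", paste(need, collapse = ", "))
  }
  get_seq <- function(species, gene) {
    if (is.character(proteomes)) {
      return(proteomes[[gene]])
    }
    gn <- proteomes[[species]]
    if (is.null(gn)) {
      stop("seed source species not supplied: ", species)
    }
    seqs <- if (inherits(gn, "GenomeAnnotation")) gn$proteins else gn
    seqs[[gene]]
  }
  seq <- mapply(get_seq, tab$seed_source_species, tab$seed_gene_id)
  if (any(vapply(seq, is.null, logical(1)))) {
    miss <- tab$seed_gene_id[vapply(seq, is.null, logical(1))]
    stop("seed proteins not found: ", paste(head(miss, 10), collapse = ", "))
  }
  data.frame(family = tab$family_label, seed_id = tab$seed_gene_id,
             species = tab$seed_source_species,
             sequence = unlist(seq, use.names = FALSE),
             stringsAsFactors = FALSE)
}
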