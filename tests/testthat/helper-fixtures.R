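# In-code fixtures: small genomes and assignment tables built directly,
# plus the reference "easy" simulation regime used in several tests.

# A toy genome: genes g<chr>_<i> at 10kb spacing, dummy proteins unless
# supplied. chr_sizes: named integer vector (chromosome -> gene count).
toy_genome <- function(chr_sizes, species = "toy", proteins = NULL,
                       cds = NULL) {
  rows <- list()
  for (chr in names(chr_sizes)) {
    n <- chr_sizes[[chr]]
    rows[[chr]] <- data.frame(
      gene_id = sprintf("%s_%s_g%03d", species, chr, seq_len(n)),
      chromosome = chr,
      start = seq_len(n) * 10000L,
      end = seq_len(n) * 10000L + 2999L,
      strand = "+", stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  if (is.null(proteins)) {
    proteins <- stats::setNames(
      vapply(seq_len(nrow(genes)), function(i) {
        paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 50,
                     replace = TRUE), collapse = "")
      }, character(1)),
      genes$gene_id)
  }
  genome_annotation(species, genes, proteins, cds)
}

# Assignment table for chosen genes of a toy genome: fam is a named
# character vector gene_id -> family.
toy_assignments <- function(genome, fam) {
  g <- genome$genes[match(names(fam), genome$genes$gene_id), , drop = FALSE]
  data.frame(gene_id = g$gene_id, family = unname(fam),
             seed_id = paste0("seed_", unname(fam)), c_score = 1,
             chromosome = g$chromosome, rank = g$rank, rank_hi = g$rank,
             start = g$start, end = g$end, merged_from = NA_character_,
             stringsAsFactors = FALSE)
}

# The reference validation regime: two species descending from a shared
# WGD, lineage-specific biased fractionation with full preservation of
# the designated clock-family linkages, moderate sequence divergence, no
# rearrangement.
easy_regime_config <- function(seed = 1L, n_genes = 400L) {
  branch <- function() {
    list(ev_fractionate(0.4, bias = 0.7, linkage_preservation = 1),
         ev_diverge(0.3))
  }
  chr_len <- n_genes %/% 4L
  sim_config(
    n_genes = n_genes, n_chromosomes = 4L,
    family_placements = rbind(
      linked_placement("LHY/CCA1", "PRR5/9", 1, chr_len %/% 4L, 3),
      linked_placement("RVE4/8", "PRR3/7", 2, chr_len %/% 2L, 5)),
    events = list(ev_wgd(2L, "wgd1"),
                  ev_speciate(spA = branch(), spB = branch())),
    seed = seed)
}

# random CDS (codon-valid, ATG start, no internal stops) of n codons
random_cds <- function(n_codons) {
  gc <- as.list(Biostrings::GENETIC_CODE)
  ok <- names(gc)[unlist(gc) != "*"]
  paste(c("ATG", sample(ok, n_codons - 1L, replace = TRUE)), collapse = "")
}
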