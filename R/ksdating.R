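# Codon-aware pairwise alignment and Nei-Gojobori (1986) Ka/Ks with
# Jukes-Cantor correction, plus block-level Ks dating against WGD bins.

#' Protein-guided codon alignment
#'
#' Globally aligns the two proteins (affine gaps, substitution matrix by
#' name) with `Biostrings::pairwiseAlignment()` and back-translates the
#' alignment codon-wise onto the CDS. Columns containing a gap are flagged
#' and excluded from downstream counting. Each CDS must translate to its
#' protein (a final stop codon is trimmed first).
#'
#' @param protein_a,protein_b Amino-acid sequences.
#' @param cds_a,cds_b Matching coding sequences.
#' @param gap_open,gap_extend Affine gap penalties (defaults 10, 0.5).
#' @param substitution_matrix Matrix name (default `"BLOSUM62"`).
#' @param gene_a,gene_b Ids carried through to the result.
#' @return List of class `CodonAlignment`: `codon_a`, `codon_b` (codon
#'   strings, `"---"` at gaps), `gap` (logical), `score`, `n_codons`.
#' @export
codon_align <- function(protein_a, protein_b, cds_a, cds_b,
                        gap_open = 10, gap_extend = 0.5,
                        substitution_matrix = "BLOSUM62",
                        gene_a = "a", gene_b = "b") {
  prep <- function(prot, cds, id) {
    idx <- codon_indices(cds)
    tabs <- codon_tables()
    n <- length(idx)
    if (n > 0L && !is.na(idx[n]) && tabs$is_stop[idx[n]]) {
      idx <- idx[-n]
    }
    aa <- tryCatch(translate_codons(idx, id),
                   error = function(e) stop(conditionMessage(e)))
    prot <- sub("\\*$", "", prot)
    if (!identical(aa, prot)) {
      av <- strsplit(aa, "")[[1]]
      pv <- strsplit(prot, "")[[1]]
      pos <- if (length(av) == length(pv)) which(av != pv)[1] else NA
      stop("CDS of ", id, " does not translate to its protein",
           if (!is.na(pos)) paste0(" (mismatch at residue ", pos, ")")
           else paste0(" (", length(av), " vs ", length(pv), " residues)"))
    }
    list(prot = prot, codons = tabs$codons[idx])
  }
  pa <- prep(protein_a, cds_a, gene_a)
  pb <- prep(protein_b, cds_b, gene_b)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa$prot), Biostrings::AAString(pb$prot),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  sa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  back <- function(chars, codons) {
    out <- rep.int("---", length(chars))
    out[chars != "-"] <- codons
    out
  }
  codon_a <- back(sa, pa$codons)
  codon_b <- back(sb, pb$codons)
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 codon_a = codon_a, codon_b = codon_b,
                 gap = sa == "-" | sb == "-",
                 score = Biostrings::score(al),
                 n_codons = length(codon_a)),
            class = "CodonAlignment")
}

#' Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction
#'
#' Potential synonymous (S) and nonsynonymous (N) sites are counted per
#' codon (each position contributes the fraction of its three possible
#' changes that are synonymous; changes to stop codons count as
#' nonsynonymous, so S + N = 3 x usable codon columns exactly) and
#' averaged over the two sequences. Observed differences are averaged over
#' all shortest mutational paths between each codon pair, excluding paths
#' through stop codons; codons whose paths are all blocked are skipped and
#' counted in `n_blocked`. Proportions are Jukes-Cantor corrected:
#' `K = -(3/4) log(1 - (4/3) p)`; `ps >= 3/4` sets `saturated = TRUE` and
#' leaves Ks unset.
#'
#' @param alignment A [codon_align()] result.
#' @param min_codons Minimum usable (non-gap, non-blocked) codon columns
#'   (default 10).
#' @return List of class `KsEstimate`: `S`, `N`, `sd`, `nd`, `ps`, `pn`,
#'   `Ks`, `Ka`, `saturated`, `n_codons`, `n_blocked`.
#' @export
ng86 <- function(alignment, min_codons = 10L) {
  tabs <- codon_tables()
  ia <- match(alignment$codon_a, tabs$codons)
  ib <- match(alignment$codon_b, tabs$codons)
  valid <- !alignment$gap & !is.na(ia) & !is.na(ib)
  valid[valid] <- !tabs$is_stop[ia[valid]] & !tabs$is_stop[ib[valid]]
  blocked <- valid & !tabs$ok_tab[cbind(ia, ib)]
  usable <- valid & !blocked
  u <- sum(usable)
  if (u < min_codons) {
    stop("too few usable codon columns (", u, " < ", min_codons, ")")
  }
  S <- (sum(tabs$syn_frac[ia[usable]]) + sum(tabs$syn_frac[ib[usable]])) / 2
  N <- 3 * u - S
  sd <- sum(tabs$sd_tab[cbind(ia[usable], ib[usable])])
  nd <- sum(tabs$nd_tab[cbind(ia[usable], ib[usable])])
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  saturated <- ps >= 0.75
  structure(list(gene_a = alignment$gene_a, gene_b = alignment$gene_b,
                 S = S, N = N, sd = sd, nd = nd, ps = ps, pn = pn,
                 Ks = if (saturated) NA_real_ else jc(ps),
                 Ka = if (pn >= 0.75) NA_real_ else jc(pn),
                 saturated = saturated, n_codons = u,
                 n_blocked = sum(blocked)),
            class = "KsEstimate")
}

#' @export
print.KsEstimate <- function(x, ...) {
  cat("KsEstimate ", x$gene_a, " vs ", x$gene_b, ": Ks = ",
      if (x$saturated) "saturated" else format(x$Ks, digits = 4),
      ", Ka = ", format(x$Ka, digits = 4), " (", x$n_codons,
      " codons)\n", sep = "")
  invisible(x)
}

# Convenience: Ks for one gene pair straight from two annotations.
pair_ks <- function(genome_a, genome_b, gene_a, gene_b, ...) {
  if (is.null(genome_a$cds) || is.null(genome_b$cds)) {
    stop("CDS required for Ks: missing for species ",
         if (is.null(genome_a$cds)) genome_a$species_id
         else genome_b$species_id)
  }
  al <- codon_align(genome_a$proteins[[gene_a]], genome_b$proteins[[gene_b]],
                    genome_a$cds[[gene_a]], genome_b$cds[[gene_b]],
                    gene_a = gene_a, gene_b = gene_b, ...)
  ng86(al)
}

#' Read a WGD bin configuration
#'
#' Bins map Ks intervals `[lo, hi)` to named duplication events (optionally
#' with an age in million years). Intervals must not overlap. Ks cutoffs
#' for named WGD events are genome- and method-specific and must be
#' calibrated by the user; any shipped example intervals are illustrative
#' only.
#'
#' @param path TSV with columns `label`, `lo`, `hi` and optionally `mya`.
#' @return Validated `data.frame` of bins.
#' @export
read_wgd_bins <- function(path) {
  bins <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  validate_wgd_bins(bins)
}

validate_wgd_bins <- function(bins) {
  if (!all(c("label", "lo", "hi") %in% names(bins))) {
    stop("bins need columns label, lo, hi")
  }
  if (any(bins$lo >= bins$hi)) {
    stop("bin with lo >= hi: ", bins$label[bins$lo >= bins$hi][1])
  }
  b <- bins[order(bins$lo), , drop = FALSE]
  if (nrow(b) > 1L && any(b$lo[-1] < b$hi[-nrow(b)])) {
    stop("overlapping Ks bins")
  }
  bins
}

#' Date a syntenic block by its anchor Ks values
#'
#' The block Ks is the median over non-saturated anchor Ks estimates; at
#' least `min_anchors` usable anchors are required, otherwise the block is
#' left unlabeled with a reason. When bins are supplied the block is
#' assigned to the bin whose interval `[lo, hi)` contains the block Ks.
#'
#' @param block_anchors Anchor rows of one block (columns `gene_a`,
#'   `gene_b`).
#' @param genome_a,genome_b Annotations with CDS.
#' @param bins Optional WGD bins (see [read_wgd_bins()]).
#' @param min_anchors Minimum usable anchors (default 3).
#' @return List: `ks` (block median Ks or NA), `label` (bin label or NA),
#'   `n_usable`, `reason` (NA when labeled).
#' @export
block_ks <- function(block_anchors, genome_a, genome_b, bins = NULL,
                     min_anchors = 3L) {
  if (!is.null(bins)) {
    bins <- validate_wgd_bins(bins)
  }
  ks <- numeric(0)
  for (i in seq_len(nrow(block_anchors))) {
    est <- tryCatch(
      pair_ks(genome_a, genome_b,
              block_anchors$gene_a[i], block_anchors$gene_b[i]),
      error = function(e) NULL)
    if (!is.null(est) && !est$saturated) {
      ks <- c(ks, est$Ks)
    }
  }
  if (length(ks) < min_anchors) {
    return(list(ks = NA_real_, label = NA_character_,
                n_usable = length(ks),
                reason = paste0("only ", length(ks),
                                " usable anchors (need ", min_anchors, ")")))
  }
  med <- stats::median(ks)
  label <- NA_character_
  if (!is.null(bins)) {
    hit <- which(bins$lo <= med & med < bins$hi)
    if (length(hit)) label <- bins$label[hit[1]]
  }
  list(ks = med, label = label, n_usable = length(ks), reason = NA_character_)
}
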