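# Reading and normalizing genome annotations into a ranked gene-order
# model, plus deterministic tabular report I/O.

#' Construct a GenomeAnnotation
#'
#' A `GenomeAnnotation` holds the ranked protein-coding gene models of one
#' genome together with their protein (and optionally CDS) sequences. Gene
#' coordinates are 1-based inclusive (GFF3 convention); ranks are 0-based
#' ordinals among protein-coding genes on a chromosome, ordered by start
#' position then gene id.
#'
#' @param species_id Character scalar identifying the genome.
#' @param genes `data.frame` with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`. A `rank` column is (re)computed.
#' @param proteins Named character vector of amino-acid sequences, one per
#'   gene.
#' @param cds Optional named character vector of coding sequences; each must
#'   be a multiple of 3 long and translate to the protein (final stop codon
#'   trimmed).
#' @return An object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(species_id, genes, proteins, cds = NULL) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "start", "end", "strand")
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols)) {
    stop("genes table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(genes$start > genes$end)) {
    bad <- genes$gene_id[genes$start > genes$end][1]
    stop("gene ", bad, " has start > end")
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicated gene ids: ",
         paste(head(genes$gene_id[duplicated(genes$gene_id)], 10),
               collapse = ", "))
  }
  ord <- order(genes$chromosome, genes$start, genes$gene_id)
  genes <- genes[ord, need, drop = FALSE]
  genes$rank <- as.integer(stats::ave(genes$start, genes$chromosome,
                                      FUN = seq_along)) - 1L
  rownames(genes) <- NULL

  no_prot <- setdiff(genes$gene_id, names(proteins))
  if (length(no_prot)) {
    stop("genes without protein sequence: ",
         paste(head(no_prot, 10), collapse = ", "))
  }
  proteins <- proteins[genes$gene_id]
  if (!is.null(cds)) {
    no_cds <- setdiff(genes$gene_id, names(cds))
    if (length(no_cds)) {
      stop("genes without CDS sequence: ",
           paste(head(no_cds, 10), collapse = ", "))
    }
    cds <- cds[genes$gene_id]
    for (g in genes$gene_id) {
      aa <- tryCatch(translate_codons(codon_indices(cds[[g]]), g),
                     error = function(e) stop("CDS of gene ", g, ": ",
                                              conditionMessage(e)))
      prot <- sub("\\*$", "", proteins[[g]])
      if (!identical(aa, prot)) {
        pos <- which(strsplit(aa, "")[[1]] != strsplit(prot, "")[[1]])[1]
        stop("CDS of gene ", g, " does not translate to its protein",
             if (!is.na(pos)) paste0(" (first mismatch at residue ", pos, ")")
             else " (length mismatch)")
      }
    }
  }
  structure(list(species_id = species_id, genes = genes,
                 proteins = proteins, cds = cds),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation '", x$species_id, "': ", nrow(x$genes),
      " protein-coding genes on ", length(unique(x$genes$chromosome)),
      " chromosomes", if (!is.null(x$cds)) ", with CDS" else "", "\n",
      sep = "")
  invisible(x)
}

# gene_id -> row lookup
gene_row <- function(genome, gene_id) {
  i <- match(gene_id, genome$genes$gene_id)
  if (anyNA(i)) {
    stop("gene(s) not in annotation: ",
         paste(gene_id[is.na(i)], collapse = ", "))
  }
  genome$genes[i, , drop = FALSE]
}

#' Read a genome annotation from GFF3 and FASTA
#'
#' Parses gene/mRNA/CDS features, keeps one representative transcript per
#' gene locus (longest summed CDS; ties broken by lexicographically smallest
#' transcript id), and assigns 0-based ranks to protein-coding genes per
#' chromosome ordered by start position. Genes without any mRNA+CDS are
#' treated as non-coding and excluded from ranking.
#'
#' FASTA records are matched to genes by gene id or by the representative
#' transcript id (first whitespace-delimited token of the FASTA header,
#' optionally post-processed with `id_clean`).
#'
#' @param gff3_path Path to a GFF3 annotation.
#' @param protein_fasta_path Path to the protein FASTA.
#' @param cds_fasta_path Optional path to the CDS FASTA (required for Ks).
#' @param species_id Species label; defaults to the GFF3 file name.
#' @param id_clean Optional regular expression; the first capture group is
#'   extracted from each FASTA id before matching (e.g. `"^(.*)\\.p$"` to
#'   strip a trailing `.p`).
#' @return A [genome_annotation()] object.
#' @export
read_annotation <- function(gff3_path, protein_fasta_path,
                            cds_fasta_path = NULL, species_id = NULL,
                            id_clean = NULL) {
  if (is.null(species_id)) {
    species_id <- sub("\\.gff3?(\\.gz)?$", "", basename(gff3_path))
  }
  check_gff3_coordinates(gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  type <- as.character(gr$type)
  ids <- gr$ID
  parents <- gr$Parent

  genes <- gr[type == "gene"]
  mrna <- gr[type == "mRNA"]
  cdsf <- gr[type == "CDS"]
  if (length(genes) == 0L || length(mrna) == 0L || length(cdsf) == 0L) {
    stop("GFF3 must contain gene, mRNA and CDS features: ", gff3_path)
  }
  mrna_parent <- vapply(mrna$Parent, function(p) p[1], character(1))
  cds_parent <- vapply(cdsf$Parent, function(p) p[1], character(1))
  cds_len <- tapply(BiocGenerics::width(cdsf), cds_parent, sum)
  tx <- data.table(tx_id = mrna$ID, gene_id = mrna_parent)
  tx[, cds_len := as.numeric(cds_len[tx_id])]
  tx <- tx[!is.na(cds_len)]
  if (nrow(tx) == 0L) {
    stop("no mRNA with CDS found in ", gff3_path)
  }
  setorder(tx, gene_id, -cds_len, tx_id)
  rep_tx <- tx[, .SD[1], by = gene_id]

  keep <- !is.na(match(genes$ID, rep_tx$gene_id))
  genes <- genes[keep]
  gtab <- data.frame(gene_id = genes$ID,
                     chromosome = as.character(GenomicRanges::seqnames(genes)),
                     start = BiocGenerics::start(genes),
                     end = BiocGenerics::end(genes),
                     strand = as.character(BiocGenerics::strand(genes)),
                     stringsAsFactors = FALSE)
  gtab$strand[!gtab$strand %in% c("+", "-")] <- "+"
  tx_of <- stats::setNames(rep_tx$tx_id, rep_tx$gene_id)

  read_fasta_map <- function(path, reader) {
    seqs <- reader(path)
    nm <- sub("\\s.*$", "", names(seqs))
    if (!is.null(id_clean)) {
      nm <- sub(id_clean, "\\1", nm)
    }
    stats::setNames(as.character(seqs), nm)
  }
  prot_map <- read_fasta_map(protein_fasta_path, Biostrings::readAAStringSet)
  resolve <- function(map, what) {
    hit <- ifelse(gtab$gene_id %in% names(map), gtab$gene_id,
                  ifelse(tx_of[gtab$gene_id] %in% names(map),
                         tx_of[gtab$gene_id], NA_character_))
    if (anyNA(hit)) {
      stop("cannot resolve ", what, " FASTA ids for genes: ",
           paste(head(gtab$gene_id[is.na(hit)], 10), collapse = ", "))
    }
    stats::setNames(unname(map[hit]), gtab$gene_id)
  }
  proteins <- resolve(prot_map, "protein")
  cds <- NULL
  if (!is.null(cds_fasta_path)) {
    cds_map <- read_fasta_map(cds_fasta_path, Biostrings::readDNAStringSet)
    cds <- resolve(cds_map, "CDS")
  }
  genome_annotation(species_id, gtab, proteins, cds)
}

# Light pre-validation so malformed coordinates are reported with a line
# number rather than an opaque parser error.
check_gff3_coordinates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) {
      stop("malformed GFF3 record (", length(f), " fields) at line ", i,
           " of ", path)
    }
    s <- suppressWarnings(as.integer(f[4]))
    e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || s < 1L || e < s) {
      stop("malformed coordinates at line ", i, " of ", path)
    }
  }
  invisible(TRUE)
}

#' Write (and read back) a deterministic tabular report
#'
#' Rows are sorted lexicographically by all columns left to right, so the
#' same records always produce byte-identical files. TSV and JSON
#' round-trip losslessly through [read_table()].
#'
#' @param records A `data.frame` of records of one type.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) > 1L) {
    records <- records[do.call(order, unname(as.list(records))), ,
                       drop = FALSE]
  }
  rownames(records) <- NULL
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (format == "tsv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(names(records), collapse = "\t"), con)
    if (nrow(records) > 0L) {
      cells <- vapply(records, function(col) {
        if (is.numeric(col)) format(col, digits = 15, trim = TRUE,
                                    scientific = FALSE)
        else as.character(col)
      }, character(nrow(records)))
      if (nrow(records) == 1L) cells <- matrix(cells, nrow = 1L)
      writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
    }
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                    na.strings = "NA"))
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
}

#' Write a GenomeAnnotation as GFF3 + FASTA
#'
#' Emits `<species>.gff3`, `<species>.prot.fa` and (when CDS are present)
#' `<species>.cds.fa` under `dir`, in the exact layout [read_annotation()]
#' consumes, so simulated genomes flow through the pipeline identically to
#' real ones. Each gene is written as a single-exon gene/mRNA/CDS trio.
#'
#' @param genome A [genome_annotation()] object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_genome_files <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- genome$genes
  mk <- function(type, ids, parent = NULL) {
    gr <- GenomicRanges::GRanges(
      seqnames = g$chromosome,
      ranges = IRanges::IRanges(g$start, g$end),
      strand = g$strand)
    gr$source <- "syntlink"
    gr$type <- type
    gr$ID <- ids
    gr$Parent <- if (is.null(parent)) {
      IRanges::CharacterList(rep(list(character(0)), length(gr)))
    } else {
      IRanges::CharacterList(as.list(parent))
    }
    gr$phase <- if (type == "CDS") 0L else NA_integer_
    gr
  }
  tx_ids <- paste0(g$gene_id, ".1")
  gr <- c(mk("gene", g$gene_id),
          mk("mRNA", tx_ids, g$gene_id),
          mk("CDS", paste0(tx_ids, ".cds"), tx_ids))
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 BiocGenerics::start(gr),
                 match(as.character(gr$type), c("gene", "mRNA", "CDS")))]
  paths <- c(gff3 = file.path(dir, paste0(genome$species_id, ".gff3")),
             protein = file.path(dir, paste0(genome$species_id, ".prot.fa")),
             cds = file.path(dir, paste0(genome$species_id, ".cds.fa")))
  rtracklayer::export(gr, paths[["gff3"]], format = "gff3")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(genome$proteins), paths[["protein"]])
  if (!is.null(genome$cds)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(genome$cds), paths[["cds"]])
  } else {
    paths <- paths[c("gff3", "protein")]
  }
  invisible(paths)
}
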