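# End-to-end workflow: homology -> synteny -> linkage (-> Ks), with
# deterministic tabular outputs and a machine-readable manifest.

#' Default scan parameters
#'
#' @return Named list of the pipeline thresholds with their defaults:
#'   `cscore` 0.7 (relative-best-hit cutoff), `k` 4 (k-mer length of the
#'   built-in scorer), `min_pairs` 5 and `max_gap` 20 (block chaining),
#'   `max_tandem_gap` 5, `min_diag_offset` 30 (self-synteny diagonal
#'   exclusion), `max_intervening` 12 (gene-count linkage screen),
#'   `max_bp` NULL (physical-distance mode off), `min_family_c` 0.3,
#'   `merge_gap` 1 (split-model merging), `n_perm` 999.
#' @export
scan_defaults <- function() {
  list(cscore = 0.7, k = 4L, min_pairs = 5L, max_gap = 20L,
       max_tandem_gap = 5L, min_diag_offset = 30L, max_intervening = 12L,
       max_bp = NULL, min_family_c = 0.3, merge_gap = 1L, n_perm = 999L)
}

#' Run the full linkage scan
#'
#' Executes the pipeline for a set of genomes: family assignment from the
#' seed panel (with split-model merging), within-genome self-synteny,
#' cross-species block detection (C-score filter, tandem collapsing,
#' anchor chaining), same-chromosome linkage scans for the requested
#' family pairs, the per-species copy table, the cross-species retention
#' summary, and a permutation null per species and family pair. All
#' tables are written under `out_dir` together with a manifest recording
#' package version, parameters and seed; rerunning with the same inputs
#' and seed reproduces the manifest digest.
#'
#' @param genomes Named list of [genome_annotation()] objects (or a
#'   `SimResult`, whose species and seed panel are used directly).
#' @param seed_panel Seed panel `data.frame` (see [read_seed_panel()]);
#'   ignored when `genomes` is a `SimResult`.
#' @param class_pairs List of 2-vectors of family labels to scan; defaults
#'   to all unordered pairs of panel families that share a linkage class,
#'   or all pairs when none do.
#' @param params Parameter overrides (see [scan_defaults()]).
#' @param scores Optional named list of precomputed similarity tables
#'   (names `"spA|spB"`); otherwise [builtin_score()] is used.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param seed Seed for the permutation nulls.
#' @return List of class `ScanResult`: `assignments`, `self_blocks`,
#'   `cross_blocks`, `linkages`, `copy_table`, `retention`, `nulls`,
#'   `manifest`.
#' @export
run_scan <- function(genomes, seed_panel = NULL, class_pairs = NULL,
                     params = list(), scores = NULL, out_dir = NULL,
                     seed = 1L) {
  if (inherits(genomes, "SimResult")) {
    if (is.null(seed_panel)) {
      seed_panel <- genomes$seed_panel
    }
    genomes <- genomes$species
  }
  if (is.null(names(genomes)) || any(names(genomes) == "")) {
    stop("genomes must be a named list")
  }
  p <- utils::modifyList(scan_defaults(), params)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("scan failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  assignments <- list()
  self_blocks <- list()
  for (sp in names(genomes)) {
    gn <- genomes[[sp]]
    assignments[[sp]] <- stage(paste0("assign_families:", sp), {
      a <- assign_families(gn, seed_panel, min_c = p$min_family_c, k = p$k)
      merge_split_models(a, gn, max_gap_ranks = p$merge_gap)
    })
    self_blocks[[sp]] <- stage(paste0("self_synteny:", sp), {
      sc <- builtin_score(gn$proteins, gn$proteins, k = p$k)
      pr <- cscore_filter(sc, threshold = p$cscore)
      self_synteny(gn, pr, min_diag_offset = p$min_diag_offset,
                   min_pairs = p$min_pairs, max_gap = p$max_gap,
                   max_tandem_gap = p$max_tandem_gap)
    })
  }

  cross_blocks <- list()
  sps <- names(genomes)
  if (length(sps) > 1L) {
    for (i in seq_len(length(sps) - 1L)) {
      for (j in (i + 1L):length(sps)) {
        key <- paste(sps[i], sps[j], sep = "|")
        cross_blocks[[key]] <- stage(paste0("synteny:", key), {
          raw <- if (!is.null(scores) && key %in% names(scores)) {
            scores[[key]]
          } else {
            builtin_score(genomes[[sps[i]]]$proteins,
                          genomes[[sps[j]]]$proteins, k = p$k)
          }
          pr <- cscore_filter(raw, threshold = p$cscore)
          an <- make_anchors(pr, genomes[[sps[i]]], genomes[[sps[j]]])
          an <- collapse_tandem(an, max_tandem_gap = p$max_tandem_gap)
          chain_anchors(an, min_pairs = p$min_pairs, max_gap = p$max_gap)
        })
      }
    }
  }

  if (is.null(class_pairs)) {
    fams <- sort(unique(seed_panel$family))
    class_pairs <- list()
    if (length(fams) > 1L) {
      for (i in seq_len(length(fams) - 1L)) {
        for (j in (i + 1L):length(fams)) {
          cls <- linkage_class(fams[i], fams[j])
          class_pairs[[length(class_pairs) + 1L]] <-
            c(fams[i], fams[j], class = cls)
        }
      }
      with_class <- Filter(function(x) !is.na(x[3]), class_pairs)
      if (length(with_class)) class_pairs <- with_class
      class_pairs <- lapply(class_pairs, function(x) x[1:2])
    }
  }

  linkages <- list()
  nulls <- list()
  for (sp in names(genomes)) {
    hits <- list()
    for (cp in class_pairs) {
      h <- stage(paste0("linkage:", sp), {
        find_linkages(genomes[[sp]], assignments[[sp]], cp[1], cp[2],
                      max_intervening = p$max_intervening,
                      max_bp = p$max_bp, blocks = self_blocks[[sp]])
      })
      hits[[paste(cp, collapse = "|")]] <- h
      a_has <- any(assignments[[sp]]$family == cp[1])
      b_has <- any(assignments[[sp]]$family == cp[2])
      if (a_has && b_has) {
        nulls[[paste(sp, cp[1], cp[2], sep = "|")]] <-
          stage(paste0("null:", sp), {
            permutation_null(genomes[[sp]], assignments[[sp]], cp[1],
                             cp[2], n_perm = p$n_perm, seed = seed)
          })
      }
    }
    linkages[[sp]] <- do.call(rbind, hits)
    rownames(linkages[[sp]]) <- NULL
  }

  copy_table <- family_copy_table(assignments)
  retention <- retention_summary(linkages)

  manifest <- list(
    package = "syntlink",
    version = as.character(utils::packageVersion("syntlink")),
    species = sps,
    parameters = p[!vapply(p, is.null, logical(1))],
    seed = seed)
  result <- structure(
    list(assignments = assignments, self_blocks = self_blocks,
         cross_blocks = cross_blocks, linkages = linkages,
         copy_table = copy_table, retention = retention, nulls = nulls,
         manifest = manifest),
    class = "ScanResult")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sp in sps) {
      write_table(assignments[[sp]],
                  file.path(out_dir, paste0("families_", sp, ".tsv")))
      write_table(self_blocks[[sp]]$blocks,
                  file.path(out_dir, paste0("self_blocks_", sp, ".tsv")))
    }
    for (key in names(cross_blocks)) {
      fn <- gsub("|", "_", key, fixed = TRUE)
      write_table(cross_blocks[[key]]$blocks,
                  file.path(out_dir, paste0("blocks_", fn, ".tsv")))
      write_table(cross_blocks[[key]]$anchors,
                  file.path(out_dir, paste0("anchors_", fn, ".tsv")))
    }
    all_hits <- do.call(rbind, unname(linkages))
    write_table(all_hits, file.path(out_dir, "linkages.tsv"))
    write_table(copy_table, file.path(out_dir, "copy_table.tsv"))
    write_table(retention$summary, file.path(out_dir, "retention.tsv"))
    jsonlite::write_json(
      lapply(nulls, unclass), file.path(out_dir, "null_tests.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- list.files(out_dir, full.names = TRUE)
    digest <- tools::md5sum(files)
    names(digest) <- basename(names(digest))
    result$manifest$files <- as.list(digest)
    jsonlite::write_json(result$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.ScanResult <- function(x, ...) {
  cat("ScanResult: ", length(x$assignments), " species, ",
      sum(vapply(x$linkages, nrow, integer(1))), " linkage hits\n",
      sep = "")
  invisible(x)
}
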