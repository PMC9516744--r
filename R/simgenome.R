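# Genome-evolution simulator: a clade of annotated genomes under
# speciation, WGD/WGT, biased fractionation, rearrangement and codon-level
# divergence, with full ground truth so the pipeline can be validated
# end-to-end without external data.

#' Event constructors for the simulator script
#'
#' A simulation applies an ordered list of events to the root lineage.
#' `ev_speciate()` splits the lineage into named children, each with its
#' own subsequent event list; the tree shape therefore lives in the
#' nesting. `ev_wgd()` duplicates (or triplicates) every chromosome;
#' `ev_fractionate()` removes duplicate-pair members (singletons are
#' immune); `ev_diverge()` evolves every coding sequence along the current
#' branch; `ev_invert()`, `ev_translocate()` and `ev_tandem()` rearrange
#' gene order.
#'
#' @param multiplier 2 (WGD) or 3 (WGT).
#' @param name Optional event label recorded in the truth set.
#' @param loss_rate Per-duplicate-copy loss probability in `[0, 1]`.
#' @param bias Probability that the victim comes from the disfavored
#'   subgenome in `[0, 1]` (0.5 = unbiased).
#' @param linkage_preservation Probability that a loss hitting a gene
#'   participating in a designated family linkage is vetoed, in `[0, 1]`.
#'   This is the simulator's explicit handle on preferential retention of
#'   linked clock genes.
#' @param linkage_window Ranks within which a partner-family gene must lie
#'   for a gene to count as linkage-participating (default 50).
#' @param ds Expected synonymous substitutions per synonymous site along
#'   the branch.
#' @param dnds Ratio of nonsynonymous to synonymous acceptance (defaults to
#'   the config-level `dnds`).
#' @param n_events Number of inversions/translocations.
#' @param mean_span Mean affected span in genes.
#' @param rate Per-gene tandem duplication probability.
#' @param ... Named child event lists for `ev_speciate()`.
#' @return An event list element.
#' @name sim_events
NULL

#' @rdname sim_events
#' @export
ev_wgd <- function(multiplier = 2L, name = NULL) {
  if (!multiplier %in% c(2L, 3L)) {
    stop("multiplier must be 2 or 3")
  }
  list(op = "wgd", multiplier = as.integer(multiplier), name = name)
}

#' @rdname sim_events
#' @export
ev_fractionate <- function(loss_rate, bias = 0.5, linkage_preservation = 0,
                           linkage_window = 50L) {
  stopifnot(loss_rate >= 0, loss_rate <= 1, bias >= 0, bias <= 1,
            linkage_preservation >= 0, linkage_preservation <= 1)
  list(op = "fractionate", loss_rate = loss_rate, bias = bias,
       linkage_preservation = linkage_preservation,
       linkage_window = as.integer(linkage_window))
}

#' @rdname sim_events
#' @export
ev_diverge <- function(ds, dnds = NULL) {
  if (ds < 0) {
    stop("ds must be >= 0")
  }
  list(op = "diverge", ds = ds, dnds = dnds)
}

#' @rdname sim_events
#' @export
ev_invert <- function(n_events = 1L, mean_span = 10) {
  list(op = "invert", n_events = as.integer(n_events),
       mean_span = mean_span)
}

#' @rdname sim_events
#' @export
ev_translocate <- function(n_events = 1L, mean_span = 10) {
  list(op = "translocate", n_events = as.integer(n_events),
       mean_span = mean_span)
}

#' @rdname sim_events
#' @export
ev_tandem <- function(rate) {
  stopifnot(rate >= 0, rate <= 1)
  list(op = "tandem", rate = rate)
}

#' @rdname sim_events
#' @export
ev_speciate <- function(...) {
  children <- list(...)
  if (length(children) < 2L || is.null(names(children)) ||
      any(names(children) == "")) {
    stop("ev_speciate needs >= 2 named child event lists")
  }
  list(op = "speciate", children = children)
}

#' Simulation configuration
#'
#' @param n_genes Ancestral protein-coding gene count.
#' @param n_chromosomes Ancestral chromosome count.
#' @param family_placements `data.frame` with columns `family`,
#'   `chromosome` (1-based index), `rank` (0-based) giving ancestral
#'   positions of designated family genes; see [linked_placement()] for
#'   placing a family pair at a chosen proximity.
#' @param events Ordered event list (see [sim_events]).
#' @param dnds Default nonsynonymous/synonymous acceptance ratio.
#' @param gene_codons Range of gene lengths in codons.
#' @param intergenic_bp Range of intergenic spacer lengths.
#' @param seed Integer seed; the whole simulation is deterministic under
#'   it.
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(n_genes = 400L, n_chromosomes = 4L,
                       family_placements = NULL, events = list(),
                       dnds = 0.2, gene_codons = c(100L, 300L),
                       intergenic_bp = c(200L, 2000L), seed = 1L) {
  stopifnot(n_genes >= n_chromosomes, n_chromosomes >= 1L, dnds >= 0)
  if (!is.null(family_placements)) {
    fp <- as.data.frame(family_placements)
    stopifnot(all(c("family", "chromosome", "rank") %in% names(fp)))
    if (any(fp$chromosome > n_chromosomes)) {
      stop("family placement on nonexistent chromosome")
    }
  }
  # fractionation requires an earlier wgd somewhere up the event script
  check_order <- function(evts, seen_wgd) {
    for (e in evts) {
      if (e$op == "wgd") seen_wgd <- TRUE
      if (e$op == "fractionate" && !seen_wgd) {
        stop("inconsistent script: fractionate before any wgd")
      }
      if (e$op == "speciate") {
        for (ch in e$children) check_order(ch, seen_wgd)
      }
    }
    seen_wgd
  }
  check_order(events, FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_chromosomes = as.integer(n_chromosomes),
                 family_placements = family_placements, events = events,
                 dnds = dnds, gene_codons = as.integer(gene_codons),
                 intergenic_bp = as.integer(intergenic_bp),
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Place two linked families on an ancestral chromosome
#'
#' Convenience builder for `family_placements`: puts one member of each
#' family on the same chromosome with `gap` intervening genes.
#'
#' @param family_a,family_b Family labels.
#' @param chromosome 1-based ancestral chromosome index.
#' @param rank 0-based rank of the first family member.
#' @param gap Intervening genes between the two members.
#' @return Two-row placement `data.frame`.
#' @export
linked_placement <- function(family_a, family_b, chromosome, rank, gap) {
  data.frame(family = c(family_a, family_b),
             chromosome = chromosome,
             rank = c(rank, rank + gap + 1L),
             stringsAsFactors = FALSE)
}

# Internal: evolve a codon-index vector. Substitution events are proposed
# one nucleotide at a time; proposals creating stop codons are rejected,
# synonymous proposals are always accepted and nonsynonymous ones accepted
# with probability omega. Evolution stops once the number of accepted
# synonymous events reaches a Poisson draw with mean ds * S (S = NG86
# synonymous site count of the starting sequence), so ds is the expected
# number of synonymous substitutions per synonymous site including
# multiple hits.
evolve_codons <- function(cod, ds, omega) {
  tabs <- codon_tables()
  if (ds == 0) {
    return(cod)
  }
  S <- sum(tabs$syn_frac[cod])
  target <- rpois(1L, ds * S)
  if (target == 0L) {
    return(cod)
  }
  n <- length(cod)
  nsyn <- 0L
  guard <- 0L
  max_guard <- 1000L * target + 10000L
  while (nsyn < target && guard < max_guard) {
    guard <- guard + 1L
    i <- sample.int(n, 1L)
    p <- sample.int(3L, 1L)
    j <- sample.int(3L, 1L)
    new <- tabs$nbr[cod[i], p, j]
    if (tabs$is_stop[new]) next
    if (tabs$aa[new] == tabs$aa[cod[i]]) {
      cod[i] <- new
      nsyn <- nsyn + 1L
    } else if (omega > 0 && runif(1L) < omega) {
      cod[i] <- new
    }
  }
  cod
}

#' Evolve a coding sequence to a target synonymous divergence
#'
#' Accumulates per-codon substitutions until the expected synonymous
#' divergence reaches `dS_target` (substitutions per synonymous site,
#' multiple hits included). Proposals creating stop codons are rejected;
#' nonsynonymous proposals are accepted with probability `dN_dS`, so
#' `dN_dS = 0` leaves the translated protein unchanged. Deterministic
#' under `seed`.
#'
#' @param parent_cds CDS string (valid codons, no internal stops).
#' @param dS_target Target synonymous divergence (>= 0).
#' @param dN_dS Nonsynonymous acceptance ratio.
#' @param seed Integer seed.
#' @return The evolved CDS string.
#' @export
evolve_sequences <- function(parent_cds, dS_target, dN_dS = 0.2, seed = 1L) {
  if (dS_target < 0) {
    stop("dS_target must be >= 0")
  }
  cod <- codon_indices(parent_cds)
  translate_codons(cod, "parent_cds")  # validates (no internal stops)
  tabs <- codon_tables()
  if (length(cod) > 0L && tabs$is_stop[cod[length(cod)]]) {
    body <- cod[-length(cod)]
    tail_stop <- cod[length(cod)]
  } else {
    body <- cod
    tail_stop <- integer(0)
  }
  out <- with_seed(seed, evolve_codons(body, dS_target, dN_dS))
  codon_string(c(out, tail_stop))
}

# ---- lineage state ---------------------------------------------------

# A lineage is a data.table of genes plus a list of codon vectors keyed by
# uid. The truth registry (environment) records every uid's parent and the
# event that created it.

new_truth <- function() {
  tr <- new.env(parent = emptyenv())
  tr$parent <- integer(0)     # parent uid per uid (0 = root gene)
  tr$event <- character(0)    # event that created the uid
  tr$next_uid <- 1L
  tr$wgd_groups <- list()     # per wgd event: list of uid vectors
  tr$nodes <- list()          # per speciation node: alive uid set
  tr$node_children <- list()  # node id -> tip species below it
  tr$tandem <- list()
  tr$branch_ds <- list()
  tr
}

new_uid <- function(tr, n, parent, event) {
  ids <- seq.int(tr$next_uid, length.out = n)
  tr$next_uid <- tr$next_uid + n
  tr$parent[ids] <- parent
  tr$event[ids] <- event
  ids
}

# Follow parent pointers until reaching a uid in `alive` (or a root).
ancestor_in <- function(tr, uid, alive) {
  while (!(uid %in% alive)) {
    p <- tr$parent[uid]
    if (is.na(p) || p == 0L) {
      return(NA_integer_)
    }
    uid <- p
  }
  uid
}

recompute_ranks <- function(genes) {
  setorder(genes, chromosome, rank)
  genes[, rank := seq_len(.N) - 1L, by = chromosome]
  genes
}

# gene participates in a designated linkage if a partner-family gene sits
# within linkage_window ranks on the same chromosome
linkage_participants <- function(genes, partner_of, window) {
  part <- rep.int(FALSE, nrow(genes))
  fam_rows <- which(!is.na(genes$family))
  for (i in fam_rows) {
    partners <- partner_of[[genes$family[i]]]
    if (is.null(partners)) next
    j <- fam_rows[genes$family[fam_rows] %in% partners &
                    genes$chromosome[fam_rows] == genes$chromosome[i] &
                    abs(genes$rank[fam_rows] - genes$rank[i]) <= window]
    if (length(j)) {
      part[i] <- TRUE
    }
  }
  part
}

apply_wgd <- function(state, ev, tr, ev_label) {
  m <- ev$multiplier
  genes <- state$genes
  sub_letters <- LETTERS[seq_len(m)]
  copies <- vector("list", m)
  groups <- vector("list", nrow(genes))
  for (k in seq_len(m)) {
    cp <- copy(genes)
    cp[, chromosome := paste0(chromosome, sub_letters[k])]
    cp[, subgenome := k]
    uids <- new_uid(tr, nrow(cp), cp$uid, ev_label)
    for (g in seq_len(nrow(cp))) {
      state$cds[[as.character(uids[g])]] <-
        state$cds[[as.character(cp$uid[g])]]
      groups[[g]] <- c(groups[[g]], uids[g])
    }
    cp[, uid := uids]
    copies[[k]] <- cp
  }
  # drop the parents' sequences
  for (u in genes$uid) state$cds[[as.character(u)]] <- NULL
  state$genes <- recompute_ranks(rbindlist(copies))
  state$dup_groups <- c(state$dup_groups,
                        lapply(groups, function(g) {
                          list(uids = g, event = ev_label)
                        }))
  tr$wgd_groups[[ev_label]] <- c(tr$wgd_groups[[ev_label]], groups)
  state
}

apply_fractionate <- function(state, ev, partner_of) {
  genes <- state$genes
  lost <- integer(0)
  part <- linkage_participants(genes, partner_of, ev$linkage_window)
  names(part) <- as.character(genes$uid)
  for (grp in state$dup_groups) {
    alive <- grp$uids[grp$uids %in% genes$uid & !grp$uids %in% lost]
    n_extra <- length(grp$uids) - 1L
    for (t in seq_len(n_extra)) {
      if (length(alive) <= 1L) break
      if (runif(1L) >= ev$loss_rate) next
      sub <- genes$subgenome[match(alive, genes$uid)]
      disfav <- alive[sub != min(sub)]
      fav <- alive[sub == min(sub)]
      pool <- if (length(disfav) && runif(1L) < ev$bias) disfav
              else if (length(fav)) fav else disfav
      victim <- if (length(pool) == 1L) pool else
        pool[sample.int(length(pool), 1L)]
      if (isTRUE(part[[as.character(victim)]]) &&
          runif(1L) < ev$linkage_preservation) {
        next  # loss vetoed: linkage preserved
      }
      lost <- c(lost, victim)
      alive <- setdiff(alive, victim)
    }
  }
  if (length(lost)) {
    for (u in lost) state$cds[[as.character(u)]] <- NULL
    state$genes <- recompute_ranks(genes[!uid %in% lost])
  }
  state
}

apply_invert <- function(state, ev) {
  genes <- state$genes
  for (t in seq_len(ev$n_events)) {
    chrs <- unique(genes$chromosome)
    chr <- chrs[sample.int(length(chrs), 1L)]
    idx <- which(genes$chromosome == chr)
    nc <- length(idx)
    if (nc < 2L) next
    span <- min(nc, 2L + rpois(1L, max(ev$mean_span - 2, 0)))
    s <- sample.int(nc - span + 1L, 1L)
    seg <- idx[order(genes$rank[idx])][s:(s + span - 1L)]
    genes$rank[seg] <- rev(genes$rank[seg])
    genes$strand[seg] <- ifelse(genes$strand[seg] == "+", "-", "+")
  }
  state$genes <- recompute_ranks(genes)
  state
}

apply_translocate <- function(state, ev) {
  genes <- state$genes
  for (t in seq_len(ev$n_events)) {
    chrs <- unique(genes$chromosome)
    if (length(chrs) < 2L) break
    src <- chrs[sample.int(length(chrs), 1L)]
    dst <- sample(setdiff(chrs, src), 1L)
    idx <- which(genes$chromosome == src)
    nc <- length(idx)
    if (nc < 2L) next
    span <- min(nc - 1L, 1L + rpois(1L, max(ev$mean_span - 1, 0)))
    s <- sample.int(nc - span + 1L, 1L)
    seg <- idx[order(genes$rank[idx])][s:(s + span - 1L)]
    n_dst <- sum(genes$chromosome == dst)
    at <- sample.int(n_dst + 1L, 1L) - 1L  # insertion rank
    genes$chromosome[seg] <- dst
    genes$rank[genes$chromosome == dst & genes$rank >= at &
                 !(seq_len(nrow(genes)) %in% seg)] <-
      genes$rank[genes$chromosome == dst & genes$rank >= at &
                   !(seq_len(nrow(genes)) %in% seg)] + span
    genes$rank[seg] <- at + seq_len(span) - 1L
    genes <- recompute_ranks(genes)
  }
  state$genes <- recompute_ranks(genes)
  state
}

apply_tandem <- function(state, ev, tr) {
  genes <- state$genes
  dup <- which(runif(nrow(genes)) < ev$rate)
  if (length(dup)) {
    new_rows <- copy(genes[dup])
    uids <- new_uid(tr, length(dup), genes$uid[dup], "tandem")
    new_rows[, uid := uids]
    # copies share the parent's rank; the stable re-sort in
    # recompute_ranks slots each copy directly after its parent
    for (g in seq_along(dup)) {
      state$cds[[as.character(uids[g])]] <-
        state$cds[[as.character(genes$uid[dup[g]])]]
      tr$tandem[[length(tr$tandem) + 1L]] <-
        c(parent = genes$uid[dup[g]], copy = uids[g])
    }
    genes <- rbindlist(list(genes, new_rows))
  }
  state$genes <- recompute_ranks(genes)
  state
}

apply_diverge <- function(state, ev, tr, lineage, default_dnds) {
  omega <- if (is.null(ev$dnds)) default_dnds else ev$dnds
  for (u in state$genes$uid) {
    key <- as.character(u)
    state$cds[[key]] <- evolve_codons(state$cds[[key]], ev$ds, omega)
  }
  tr$branch_ds[[length(tr$branch_ds) + 1L]] <-
    data.frame(lineage = lineage, ds = ev$ds, dnds = omega,
               stringsAsFactors = FALSE)
  state
}

apply_events <- function(state, events, lineage, tr, default_dnds) {
  for (k in seq_along(events)) {
    ev <- events[[k]]
    if (ev$op == "speciate") {
      node_id <- paste0(lineage, "/node", k)
      tr$nodes[[node_id]] <- state$genes$uid
      tips <- list()
      for (ch in names(ev$children)) {
        child_state <- list(genes = copy(state$genes),
                            cds = as.list(state$cds),
                            dup_groups = state$dup_groups,
                            partner_of = state$partner_of)
        tips <- c(tips, apply_events(child_state, ev$children[[ch]],
                                     ch, tr, default_dnds))
      }
      tr$node_children[[node_id]] <- names(tips)
      # events after a speciate would be ambiguous; forbid silently by spec
      if (k < length(events)) {
        stop("speciate must be the last event of its list")
      }
      return(tips)
    }
    state <- switch(
      ev$op,
      wgd = {
        label <- if (is.null(ev$name)) {
          paste0("wgd_", lineage, "_", k)
        } else {
          ev$name
        }
        apply_wgd(state, ev, tr, label)
      },
      fractionate = apply_fractionate(state, ev, state$partner_of),
      invert = apply_invert(state, ev),
      translocate = apply_translocate(state, ev),
      tandem = apply_tandem(state, ev, tr),
      diverge = apply_diverge(state, ev, tr, lineage, default_dnds),
      stop("unknown event op: ", ev$op))
  }
  stats::setNames(list(state), lineage)
}

# ---- top-level simulate ----------------------------------------------

#' Simulate a clade of annotated genomes with ground truth
#'
#' Builds an ancestral genome, places designated family genes, applies the
#' event script (speciation, WGD/WGT, biased fractionation with optional
#' linkage preservation, inversions, translocations, tandem duplication,
#' codon-level divergence), and emits one [genome_annotation()] per tip
#' species together with a truth set and a seed panel of the ancestral
#' family proteins. Deterministic under the config seed.
#'
#' @param config A [sim_config()] object.
#' @return List of class `SimResult` with elements `species` (named list
#'   of `GenomeAnnotation`), `truth` (see [truth_orthologs()],
#'   [truth_blocks()], [truth_linkages()]) and `seed_panel` (ready for
#'   [assign_families()]).
#' @export
simulate_clade <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  with_seed(config$seed, simulate_clade_impl(config))
}

simulate_clade_impl <- function(config) {
  tabs <- codon_tables()
  tr <- new_truth()
  n <- config$n_genes
  n_chr <- config$n_chromosomes
  chr_of <- sort(rep_len(seq_len(n_chr), n))
  genes <- data.table(
    uid = new_uid(tr, n, 0L, "root"),
    chromosome = sprintf("chr%02d", chr_of),
    rank = unlist(lapply(table(chr_of), seq_len)) - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    family = NA_character_,
    subgenome = 1L)
  non_stop <- which(!tabs$is_stop)
  atg <- match("ATG", tabs$codons)
  cds <- vector("list", n)
  lens <- sample(config$gene_codons[1]:config$gene_codons[2], n,
                 replace = TRUE)
  for (g in seq_len(n)) {
    cds[[g]] <- c(atg, sample(non_stop, lens[g] - 1L, replace = TRUE))
  }
  names(cds) <- as.character(genes$uid)

  partner_of <- list()
  if (!is.null(config$family_placements)) {
    fp <- as.data.frame(config$family_placements)
    for (i in seq_len(nrow(fp))) {
      chr <- sprintf("chr%02d", fp$chromosome[i])
      row <- which(genes$chromosome == chr & genes$rank == fp$rank[i])
      if (length(row) != 1L) {
        stop("family placement outside chromosome: ", fp$family[i])
      }
      genes$family[row] <- fp$family[i]
    }
    # families co-placed on one ancestral chromosome are designated
    # linkage partners
    for (chr in unique(fp$chromosome)) {
      fams <- unique(fp$family[fp$chromosome == chr])
      if (length(fams) >= 2L) {
        for (f in fams) {
          partner_of[[f]] <- union(partner_of[[f]], setdiff(fams, f))
        }
      }
    }
  }

  seed_panel <- NULL
  fam_rows <- which(!is.na(genes$family))
  if (length(fam_rows)) {
    seed_panel <- data.frame(
      family = genes$family[fam_rows],
      seed_id = paste0("seed_", genes$family[fam_rows], "_",
                       genes$uid[fam_rows]),
      species = "ancestor",
      sequence = vapply(fam_rows, function(g) {
        paste(tabs$aa[cds[[as.character(genes$uid[g])]]], collapse = "")
      }, character(1)),
      stringsAsFactors = FALSE)
  }

  state <- list(genes = genes, cds = cds, dup_groups = list(),
                partner_of = partner_of)
  tips <- apply_events(state, config$events, "sp1", tr, config$dnds)

  species <- list()
  gene_map <- list()
  for (sp in names(tips)) {
    st <- tips[[sp]]
    g <- recompute_ranks(st$genes)
    setorder(g, chromosome, rank)
    g[, gene_id := sprintf("%s_g%05d", sp, seq_len(.N))]
    lens_bp <- vapply(as.character(g$uid),
                      function(k) 3L * length(st$cds[[k]]), integer(1))
    spacer <- sample(config$intergenic_bp[1]:config$intergenic_bp[2],
                     nrow(g), replace = TRUE)
    g[, start := {
      s <- integer(.N)
      pos <- 1L
      for (i in seq_len(.N)) {
        pos <- pos + spacer[.I[i]]
        s[i] <- pos
        pos <- pos + lens_bp[.I[i]]
      }
      s
    }, by = chromosome]
    g[, end := start + lens_bp[match(as.character(uid),
                                     names(lens_bp))] - 1L]
    prot <- vapply(as.character(g$uid), function(k) {
      paste(tabs$aa[st$cds[[k]]], collapse = "")
    }, character(1))
    cds_str <- vapply(as.character(g$uid), function(k) {
      paste(tabs$codons[st$cds[[k]]], collapse = "")
    }, character(1))
    ann <- genome_annotation(
      sp,
      data.frame(gene_id = g$gene_id, chromosome = g$chromosome,
                 start = g$start, end = g$end, strand = g$strand,
                 stringsAsFactors = FALSE),
      stats::setNames(prot, g$gene_id))
    ann$cds <- stats::setNames(cds_str, g$gene_id)
    species[[sp]] <- ann
    gene_map[[sp]] <- data.frame(
      species = sp, gene_id = g$gene_id, uid = g$uid, family = g$family,
      chromosome = g$chromosome, rank = ann$genes$rank[
        match(g$gene_id, ann$genes$gene_id)],
      subgenome = g$subgenome, stringsAsFactors = FALSE)
  }

  truth <- list(registry = tr, gene_map = do.call(rbind, gene_map),
                partner_of = partner_of,
                branch_ds = if (length(tr$branch_ds)) {
                  do.call(rbind, tr$branch_ds)
                } else {
                  NULL
                })
  structure(list(species = species, truth = truth,
                 seed_panel = seed_panel, config = config),
            class = "SimResult")
}

#' @export
print.SimResult <- function(x, ...) {
  cat("SimResult: ", length(x$species), " species (",
      paste(names(x$species), collapse = ", "), "), seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

# ---- truth queries ---------------------------------------------------

# lineage root mapping: every uid's earliest ancestor (root gene)
root_origin <- function(tr, uid) {
  repeat {
    p <- tr$parent[uid]
    if (is.na(p) || p == 0L) {
      return(uid)
    }
    uid <- p
  }
}

# find the node whose tip set contains both species and is minimal
mrca_node <- function(tr, sp_a, sp_b) {
  cands <- names(tr$node_children)[vapply(tr$node_children, function(ch) {
    sp_a %in% ch && sp_b %in% ch
  }, logical(1))]
  if (length(cands) == 0L) {
    return(NULL)
  }
  sizes <- vapply(tr$node_children[cands], length, integer(1))
  cands[which.min(sizes)]
}

#' True ortholog pairs between two simulated species
#'
#' Two tip genes are orthologs when they descend from the same gene copy
#' alive at the species pair's most recent common ancestor (many-to-many
#' after lineage-specific duplication).
#'
#' @param truth The `truth` element of a [simulate_clade()] result.
#' @param sp_a,sp_b Species ids.
#' @return `data.frame`: `gene_a`, `gene_b`, `chr_a`, `chr_b`, `rank_a`,
#'   `rank_b`, `ancestor_uid`.
#' @export
truth_orthologs <- function(truth, sp_a, sp_b) {
  tr <- truth$registry
  gm <- truth$gene_map
  node <- mrca_node(tr, sp_a, sp_b)
  if (is.null(node)) {
    stop("species do not share a speciation node: ", sp_a, ", ", sp_b)
  }
  alive <- tr$nodes[[node]]
  map_up <- function(sp) {
    g <- gm[gm$species == sp, , drop = FALSE]
    g$anc <- vapply(g$uid, function(u) ancestor_in(tr, u, alive),
                    integer(1))
    g[!is.na(g$anc), , drop = FALSE]
  }
  ga <- map_up(sp_a)
  gb <- map_up(sp_b)
  m <- merge(as.data.table(ga)[, .(gene_a = gene_id, chr_a = chromosome,
                                   rank_a = rank, anc)],
             as.data.table(gb)[, .(gene_b = gene_id, chr_b = chromosome,
                                   rank_b = rank, anc)],
             by = "anc", allow.cartesian = TRUE)
  setnames(m, "anc", "ancestor_uid")
  setorder(m, chr_a, rank_a, chr_b, rank_b)
  as.data.frame(m[, .(gene_a, gene_b, chr_a, chr_b, rank_a, rank_b,
                      ancestor_uid)])
}

# All homologous tip-gene pairs between two species (same root origin):
# orthologs plus homoeologs from WGDs predating either tip.
truth_homolog_pairs <- function(truth, sp_a, sp_b) {
  tr <- truth$registry
  gm <- truth$gene_map
  ga <- gm[gm$species == sp_a, , drop = FALSE]
  gb <- gm[gm$species == sp_b, , drop = FALSE]
  ga$root <- vapply(ga$uid, function(u) root_origin(tr, u), integer(1))
  gb$root <- vapply(gb$uid, function(u) root_origin(tr, u), integer(1))
  m <- merge(as.data.table(ga)[, .(gene_a = gene_id, chr_a = chromosome,
                                   rank_a = rank, root)],
             as.data.table(gb)[, .(gene_b = gene_id, chr_b = chromosome,
                                   rank_b = rank, root)],
             by = "root", allow.cartesian = TRUE)
  if (sp_a == sp_b) {
    m <- m[gene_a < gene_b]
  }
  as.data.frame(m)
}

#' True syntenic blocks between two simulated species
#'
#' Derived from true ortholog pairs: anchors are grouped by chromosome
#' pair, ordered along side a, and split into runs wherever the rank gap
#' on either side exceeds `max_gap` or the b-side direction reverses; runs
#' with at least `min_pairs` anchors are true blocks.
#'
#' @param truth Truth set from [simulate_clade()].
#' @param sp_a,sp_b Species ids.
#' @param min_pairs,max_gap Block definition parameters (defaults 5, 20).
#' @return `data.frame` of blocks: `chr_a`, `chr_b`, `start_a`, `end_a`,
#'   `start_b`, `end_b`, `n_anchors`.
#' @export
truth_blocks <- function(truth, sp_a, sp_b, min_pairs = 5L, max_gap = 20L) {
  orth <- as.data.table(truth_orthologs(truth, sp_a, sp_b))
  empty <- data.frame(chr_a = character(), chr_b = character(),
                      start_a = integer(), end_a = integer(),
                      start_b = integer(), end_b = integer(),
                      n_anchors = integer())
  if (nrow(orth) == 0L) {
    return(empty)
  }
  setorder(orth, chr_a, chr_b, rank_a, rank_b)
  out <- list()
  for (grp in split(orth, by = c("chr_a", "chr_b"))) {
    n <- nrow(grp)
    if (n == 0L) next
    if (n == 1L) {
      run <- 1L
    } else {
      da <- diff(grp$rank_a)
      db <- diff(grp$rank_b)
      step_brk <- da > max_gap | abs(db) > max_gap
      dirs <- sign(db)
      flip <- if (n > 2L) c(FALSE, dirs[-1] != dirs[-(n - 1L)]) else FALSE
      run <- cumsum(c(TRUE, step_brk | flip))
    }
    for (r in unique(run)) {
      sub <- grp[run == r]
      if (nrow(sub) >= min_pairs) {
        out[[length(out) + 1L]] <- data.frame(
          chr_a = sub$chr_a[1], chr_b = sub$chr_b[1],
          start_a = min(sub$rank_a), end_a = max(sub$rank_a),
          start_b = min(sub$rank_b), end_b = max(sub$rank_b),
          n_anchors = nrow(sub), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(empty)
  }
  do.call(rbind, out)
}

#' True family linkage states per simulated species
#'
#' All same-chromosome cross-family pairs of designated family genes, with
#' their intervening-gene counts, from the simulator's own family labels
#' (no homology detection involved).
#'
#' @param truth Truth set from [simulate_clade()].
#' @param max_intervening Optional cap on intervening genes.
#' @return `data.frame`: `species`, `family_a`, `family_b`, `gene_a`,
#'   `gene_b`, `chromosome`, `n_intervening`.
#' @export
truth_linkages <- function(truth, max_intervening = NULL) {
  gm <- truth$gene_map
  fam <- gm[!is.na(gm$family), , drop = FALSE]
  rows <- list()
  for (sp in unique(fam$species)) {
    f <- fam[fam$species == sp, , drop = FALSE]
    if (nrow(f) < 2L) next
    for (i in seq_len(nrow(f) - 1L)) {
      for (j in (i + 1L):nrow(f)) {
        if (f$family[i] == f$family[j]) next
        if (f$chromosome[i] != f$chromosome[j]) next
        n_int <- abs(f$rank[i] - f$rank[j]) - 1L
        if (!is.null(max_intervening) && n_int > max_intervening) next
        ord <- order(c(f$family[i], f$family[j]))
        fams <- c(f$family[i], f$family[j])[ord]
        gns <- c(f$gene_id[i], f$gene_id[j])[ord]
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, family_a = fams[1], family_b = fams[2],
          gene_a = gns[1], gene_b = gns[2],
          chromosome = f$chromosome[i], n_intervening = n_int,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(species = character(), family_a = character(),
                      family_b = character(), gene_a = character(),
                      gene_b = character(), chromosome = character(),
                      n_intervening = integer()))
  }
  do.call(rbind, rows)
}

# span Jaccard of two rank intervals
span_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0L, min(e1, e2) - max(s1, s2) + 1L)
  uni <- max(e1, e2) - min(s1, s2) + 1L
  inter / uni
}

#' Precision and recall of pipeline output against simulation truth
#'
#' Scores detection at three levels. Anchors: a detected anchor is correct
#' when its two genes share descent from one ancestral gene (any homolog
#' pair); recall is measured against true ortholog pairs. Blocks: a true
#' block is recovered when a detected block on the same chromosome pair
#' overlaps it with span Jaccard >= 0.5 on both sides; block precision
#' counts detected blocks that match a true homolog-derived block the same
#' way. Linkages: gene-pair identity against [truth_linkages()]. When
#' nothing is detected, precision is reported as `NA` (not applicable).
#'
#' @param sim A [simulate_clade()] result.
#' @param detected_blocks `SyntenicBlocks` between `sp_a` and `sp_b`.
#' @param detected_linkages Linkage hits across species (rbind of
#'   [find_linkages()] outputs).
#' @param sp_a,sp_b The species pair the blocks refer to.
#' @param min_pairs,max_gap Truth block definition (match the detection
#'   settings).
#' @param max_intervening Truth linkage threshold (match the detection
#'   setting).
#' @return `data.frame` with rows anchor/block/linkage and columns
#'   `precision`, `recall`, `n_truth`, `n_detected`.
#' @export
evaluate_recovery <- function(sim, detected_blocks, detected_linkages,
                              sp_a, sp_b, min_pairs = 5L, max_gap = 20L,
                              max_intervening = 12L) {
  truth <- sim$truth
  known <- unique(truth$gene_map$species)
  if (!all(c(sp_a, sp_b) %in% known)) {
    stop("species mismatch: truth covers ",
         paste(known, collapse = ", "))
  }
  orth <- truth_orthologs(truth, sp_a, sp_b)
  homol <- truth_homolog_pairs(truth, sp_a, sp_b)
  key <- function(a, b) paste(a, b, sep = "\r")
  det_anch <- detected_blocks$anchors
  anchor_prec <- anchor_rec <- NA_real_
  if (nrow(det_anch)) {
    det_keys <- key(det_anch$gene_a, det_anch$gene_b)
    hom_keys <- c(key(homol$gene_a, homol$gene_b),
                  key(homol$gene_b, homol$gene_a))
    anchor_prec <- mean(det_keys %in% hom_keys)
    orth_keys <- unique(key(orth$gene_a, orth$gene_b))
    det_both <- c(det_keys, key(det_anch$gene_b, det_anch$gene_a))
    anchor_rec <- mean(orth_keys %in% det_both)
  } else if (nrow(orth)) {
    anchor_rec <- 0
  }

  tb <- truth_blocks(truth, sp_a, sp_b, min_pairs, max_gap)
  db <- detected_blocks$blocks
  match_block <- function(b, cand) {
    hit <- cand[cand$chr_a == b$chr_a & cand$chr_b == b$chr_b, ,
                drop = FALSE]
    any(vapply(seq_len(nrow(hit)), function(i) {
      min(span_jaccard(b$start_a, b$end_a, hit$start_a[i], hit$end_a[i]),
          span_jaccard(b$start_b, b$end_b, hit$start_b[i],
                       hit$end_b[i])) >= 0.5
    }, logical(1)))
  }
  block_rec <- if (nrow(tb) == 0L) NA_real_ else {
    mean(vapply(seq_len(nrow(tb)), function(i) {
      match_block(tb[i, ], db)
    }, logical(1)))
  }
  # homolog-derived blocks for precision: blocks of any shared descent
  hb <- truth_blocks_from_pairs(homol, min_pairs, max_gap)
  block_prec <- if (nrow(db) == 0L) NA_real_ else {
    mean(vapply(seq_len(nrow(db)), function(i) {
      match_block(db[i, ], hb)
    }, logical(1)))
  }

  tl <- truth_linkages(truth, max_intervening)
  tl <- tl[tl$species %in% c(sp_a, sp_b), , drop = FALSE]
  dl <- detected_linkages
  # a detected hit matches a true linkage when, in the same species, each
  # side of the true pair appears among the hit's member genes (merged
  # detections list their members)
  det_members <- if (!is.null(dl) && nrow(dl)) {
    lapply(seq_len(nrow(dl)), function(i) {
      ma <- if ("members_a" %in% names(dl) && !is.na(dl$members_a[i])) {
        strsplit(dl$members_a[i], ",")[[1]]
      } else {
        dl$gene_a[i]
      }
      mb <- if ("members_b" %in% names(dl) && !is.na(dl$members_b[i])) {
        strsplit(dl$members_b[i], ",")[[1]]
      } else {
        dl$gene_b[i]
      }
      list(species = dl$species[i], a = ma, b = mb)
    })
  } else {
    list()
  }
  matches_truth <- function(i) {
    any(vapply(det_members, function(m) {
      m$species == tl$species[i] &&
        ((tl$gene_a[i] %in% m$a && tl$gene_b[i] %in% m$b) ||
           (tl$gene_a[i] %in% m$b && tl$gene_b[i] %in% m$a))
    }, logical(1)))
  }
  matches_det <- function(m) {
    if (nrow(tl) == 0L) return(FALSE)
    any(vapply(seq_len(nrow(tl)), function(i) {
      m$species == tl$species[i] &&
        ((tl$gene_a[i] %in% m$a && tl$gene_b[i] %in% m$b) ||
           (tl$gene_a[i] %in% m$b && tl$gene_b[i] %in% m$a))
    }, logical(1)))
  }
  link_rec <- if (nrow(tl) == 0L) NA_real_ else {
    mean(vapply(seq_len(nrow(tl)), matches_truth, logical(1)))
  }
  link_prec <- if (length(det_members) == 0L) NA_real_ else {
    mean(vapply(det_members, matches_det, logical(1)))
  }

  data.frame(
    class = c("anchor", "block", "linkage"),
    precision = c(anchor_prec, block_prec, link_prec),
    recall = c(anchor_rec, block_rec, link_rec),
    n_truth = c(nrow(orth), nrow(tb), nrow(tl)),
    n_detected = c(nrow(det_anch), nrow(db),
                   if (is.null(dl)) 0L else nrow(dl)),
    stringsAsFactors = FALSE)
}

truth_blocks_from_pairs <- function(pairs, min_pairs, max_gap) {
  p <- as.data.table(pairs)
  empty <- data.frame(chr_a = character(), chr_b = character(),
                      start_a = integer(), end_a = integer(),
                      start_b = integer(), end_b = integer(),
                      n_anchors = integer())
  if (nrow(p) == 0L) {
    return(empty)
  }
  setorder(p, chr_a, chr_b, rank_a, rank_b)
  out <- list()
  for (grp in split(p, by = c("chr_a", "chr_b"))) {
    n <- nrow(grp)
    if (n == 0L) next
    if (n == 1L) {
      run <- 1L
    } else {
      da <- diff(grp$rank_a)
      db <- diff(grp$rank_b)
      brk <- da > max_gap | abs(db) > max_gap
      run <- cumsum(c(FALSE, brk)) + 1L
    }
    for (r in unique(run)) {
      sub <- grp[run == r]
      if (nrow(sub) >= min_pairs) {
        out[[length(out) + 1L]] <- data.frame(
          chr_a = sub$chr_a[1], chr_b = sub$chr_b[1],
          start_a = min(sub$rank_a), end_a = max(sub$rank_a),
          start_b = min(sub$rank_b), end_b = max(sub$rank_b),
          n_anchors = nrow(sub), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(empty)
  }
  do.call(rbind, out)
}
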