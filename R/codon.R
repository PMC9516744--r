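# Codon-level machinery shared by the Ks estimator and the sequence
# simulator. All tables are built once per session and cached.

.syntlink <- new.env(parent = emptyenv())

# Evaluate `code` under a temporary RNG state so package functions with a
# `seed` argument do not perturb the caller's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Codon lookup tables (standard genetic code):
#   codons   : the 64 codon strings, index = (b1-1)*16 + (b2-1)*4 + b3 with
#              bases ordered A,C,G,T
#   aa       : translated amino acid ("*" = stop)
#   is_stop  : logical
#   syn_frac : per-codon count of potential synonymous sites (NG86 style;
#              each position contributes n_synonymous_changes/3, mutations
#              to stop codons counted as nonsynonymous so that per-codon
#              synonymous + nonsynonymous sites always sum to 3)
#   nbr      : 64 x 3 x 3 integer array; nbr[c,p,j] = codon after replacing
#              position p of codon c with its j-th alternative base
#   sd_tab, nd_tab : 64 x 64 path-averaged synonymous / nonsynonymous
#              difference counts (all shortest mutational paths, paths
#              through stop codons excluded)
#   ok_tab   : FALSE where every path between the two codons is blocked
codon_tables <- function() {
  if (!is.null(.syntlink$codon)) {
    return(.syntlink$codon)
  }
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$b1, grid$b2, grid$b3)
  aa <- as.character(Biostrings::GENETIC_CODE[codons])
  is_stop <- aa == "*"

  base_idx <- cbind(match(substr(codons, 1L, 1L), bases),
                    match(substr(codons, 2L, 2L), bases),
                    match(substr(codons, 3L, 3L), bases))
  mult <- c(16L, 4L, 1L)
  nbr <- array(0L, dim = c(64L, 3L, 3L))
  for (ci in 1:64) {
    for (p in 1:3) {
      others <- setdiff(1:4, base_idx[ci, p])
      nbr[ci, p, ] <- ci + (others - base_idx[ci, p]) * mult[p]
    }
  }

  syn_frac <- numeric(64L)
  for (ci in 1:64) {
    if (is_stop[ci]) {
      syn_frac[ci] <- NA_real_
      next
    }
    nsyn <- 0L
    for (p in 1:3) {
      nsyn <- nsyn + sum(aa[nbr[ci, p, ]] == aa[ci])
    }
    syn_frac[ci] <- nsyn / 3
  }

  perms <- list(list(1L),
                list(c(1L, 2L), c(2L, 1L)),
                list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                     c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  sd_tab <- matrix(0, 64L, 64L)
  nd_tab <- matrix(0, 64L, 64L)
  ok_tab <- matrix(TRUE, 64L, 64L)
  for (i in 1:64) {
    if (is_stop[i]) next
    for (j in 1:64) {
      if (is_stop[j] || i == j) next
      dpos <- which(base_idx[i, ] != base_idx[j, ])
      nd_diff <- length(dpos)
      if (nd_diff == 0L) next
      s_paths <- n_paths <- numeric(0)
      for (ord in perms[[nd_diff]]) {
        cur <- i
        s <- n <- 0L
        valid <- TRUE
        for (p in dpos[ord]) {
          nxt <- cur + (base_idx[j, p] - base_idx[cur, p]) * mult[p]
          if (is_stop[nxt]) {
            valid <- FALSE
            break
          }
          if (aa[nxt] == aa[cur]) s <- s + 1L else n <- n + 1L
          cur <- nxt
        }
        if (valid) {
          s_paths <- c(s_paths, s)
          n_paths <- c(n_paths, n)
        }
      }
      if (length(s_paths) == 0L) {
        ok_tab[i, j] <- FALSE
      } else {
        sd_tab[i, j] <- mean(s_paths)
        nd_tab[i, j] <- mean(n_paths)
      }
    }
  }

  .syntlink$codon <- list(bases = bases, codons = codons, aa = aa,
                          is_stop = is_stop, base_idx = base_idx,
                          mult = mult, nbr = nbr, syn_frac = syn_frac,
                          sd_tab = sd_tab, nd_tab = nd_tab, ok_tab = ok_tab)
  .syntlink$codon
}

# Split a CDS string into codon indices (1..64); NA for codons containing
# characters outside ACGT.
codon_indices <- function(cds) {
  tabs <- codon_tables()
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length ", n, " is not a multiple of 3")
  }
  starts <- seq.int(1L, n, by = 3L)
  match(substring(cds, starts, starts + 2L), tabs$codons)
}

codon_string <- function(idx) {
  tabs <- codon_tables()
  paste(tabs$codons[idx], collapse = "")
}

# Translate codon indices to an amino-acid string, trimming one trailing
# stop codon if present. Internal stops are an error.
translate_codons <- function(idx, id = "sequence") {
  tabs <- codon_tables()
  if (anyNA(idx)) {
    stop("non-ACGT codon in CDS of ", id)
  }
  n <- length(idx)
  if (n > 0L && tabs$is_stop[idx[n]]) {
    idx <- idx[-n]
    n <- n - 1L
  }
  if (n > 0L && any(tabs$is_stop[idx])) {
    stop("internal stop codon at codon ", which(tabs$is_stop[idx])[1],
         " in CDS of ", id)
  }
  paste(tabs$aa[idx], collapse = "")
}
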