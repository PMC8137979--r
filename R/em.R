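# EM (gene-counting) estimation of multi-locus allelic haplotype
# frequencies from unphased genotypes. Gene absence is carried as the
# pseudo-allele ABSENT, so presence/absence variation and allele-level
# variation are estimated in one model; individuals with more than two
# copies of an included locus are excluded (diploid pair enumeration is
# undefined for them) and reported.

.ABSENT <- "ABSENT"
.HAP_SEP <- "~"

# Build per-individual, per-locus diploid allele pairs from a long genotype
# table (columns individual, gene, allele; one row per gene copy). Copy
# number < 2 pads with ABSENT. Returns list(pairs = list of 2 x L matrices,
# excluded = ids with > 2 copies at some locus).
.diploid_pairs <- function(genotypes, loci) {
  ids <- unique(genotypes$individual)
  gt <- genotypes[genotypes$gene %in% loci, , drop = FALSE]
  gi <- match(gt$individual, ids)
  gj <- match(gt$gene, loci)
  o <- order(gi, gj)
  gi <- gi[o]; gj <- gj[o]
  al <- as.character(gt$allele)[o]
  grp <- (gi - 1L) * length(loci) + gj
  copy <- if (length(grp)) sequence(rle(grp)$lengths) else integer(0)

  A1 <- matrix(.ABSENT, length(ids), length(loci))
  A2 <- matrix(.ABSENT, length(ids), length(loci))
  s1 <- copy == 1L
  s2 <- copy == 2L
  A1[cbind(gi[s1], gj[s1])] <- al[s1]
  A2[cbind(gi[s2], gj[s2])] <- al[s2]
  swp <- A1 > A2
  tmp <- A1[swp]; A1[swp] <- A2[swp]; A2[swp] <- tmp

  over <- unique(gi[copy > 2L])
  keep <- setdiff(seq_along(ids), over)
  pairs <- lapply(keep, function(i) {
    m <- rbind(A1[i, ], A2[i, ])
    colnames(m) <- loci
    m
  })
  names(pairs) <- ids[keep]
  list(pairs = pairs, excluded = ids[over])
}

# Collapse identical multi-locus genotypes into classes and enumerate, per
# class, every haplotype pair consistent with the genotype. Returns a flat
# pair table for vectorized EM.
.pair_table <- function(pairs, loci) {
  keys <- vapply(pairs, function(p) paste(p[1, ], p[2, ], sep = "/", collapse = "|"), "")
  tab <- table(keys)
  class_keys <- names(tab)
  n_class <- as.integer(tab)
  rep_idx <- match(class_keys, keys)

  hap_env <- new.env(parent = emptyenv())
  hap_names <- character(0)
  hap_id <- function(labels) {
    out <- integer(length(labels))
    for (k in seq_along(labels)) {
      v <- hap_env[[labels[k]]]
      if (is.null(v)) {
        hap_names[[length(hap_names) + 1]] <<- labels[k]
        v <- length(hap_names)
        assign(labels[k], v, envir = hap_env)
      }
      out[k] <- v
    }
    out
  }

  rows_class <- integer(0); rows_a <- integer(0); rows_b <- integer(0)
  rows_mult <- integer(0)
  for (ci in seq_along(class_keys)) {
    p <- pairs[[rep_idx[ci]]]
    het <- which(p[1, ] != p[2, ])
    if (length(het) == 0) {
      lab <- paste(p[1, ], collapse = .HAP_SEP)
      idx <- hap_id(lab)
      rows_class <- c(rows_class, ci); rows_a <- c(rows_a, idx)
      rows_b <- c(rows_b, idx); rows_mult <- c(rows_mult, 1L)
      next
    }
    # fix the first heterozygous locus on haplotype A to avoid double
    # counting unordered pairs
    free <- het[-1]
    combos <- if (length(free) == 0) {
      matrix(logical(0), nrow = 1, ncol = 0)
    } else {
      as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(free))))
    }
    for (r in seq_len(nrow(combos))) {
      a <- p[1, ]; b <- p[2, ]
      a[het[1]] <- p[1, het[1]]; b[het[1]] <- p[2, het[1]]
      if (length(free) > 0) {
        swap <- free[combos[r, ]]
        a[swap] <- p[2, swap]; b[swap] <- p[1, swap]
      }
      la <- paste(a, collapse = .HAP_SEP)
      lb <- paste(b, collapse = .HAP_SEP)
      ia <- hap_id(la); ib <- hap_id(lb)
      rows_class <- c(rows_class, ci); rows_a <- c(rows_a, ia)
      rows_b <- c(rows_b, ib); rows_mult <- c(rows_mult, 2L)
    }
  }
  list(class_n = n_class, pair_class = rows_class, pair_a = rows_a,
       pair_b = rows_b, pair_mult = rows_mult, hap_names = hap_names)
}

# One EM run from a given initial frequency vector. Returns frequencies,
# loglik trace, convergence flag.
.em_run <- function(pt, f0, tol, max_iter) {
  n <- sum(pt$class_n)
  f <- f0 / sum(f0)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- pt$pair_mult * f[pt$pair_a] * f[pt$pair_b]
    sw <- rowsum(w, pt$pair_class)[, 1]
    if (any(sw <= 0)) {
      # a class lost all support under current frequencies; reseed the
      # offending haplotypes with a tiny mass
      f[f == 0] <- .Machine$double.eps
      f <- f / sum(f)
      w <- pt$pair_mult * f[pt$pair_a] * f[pt$pair_b]
      sw <- rowsum(w, pt$pair_class)[, 1]
    }
    ll <- sum(pt$class_n * log(sw))
    trace <- c(trace, ll)
    post <- w / sw[pt$pair_class] * pt$class_n[pt$pair_class]
    cnt <- rowsum(c(post, post), c(pt$pair_a, pt$pair_b))[, 1]
    fnew <- numeric(length(f))
    fnew[as.integer(names(cnt))] <- cnt / (2 * n)
    names(fnew) <- names(f)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + tol)) {
      converged <- TRUE
      f <- fnew
      break
    }
    ll_prev <- ll
    f <- fnew
  }
  list(f = f, loglik = ll, trace = trace, converged = converged,
       n_iter = length(trace))
}

#' EM estimation of allelic haplotype frequencies
#'
#' Standard gene-counting EM over unphased multi-locus genotypes: the E-step
#' enumerates, per individual, every haplotype pair consistent with the
#' genotype and weights it by the product of current frequencies (doubled
#' for heterozygous pairs); the M-step sets each haplotype frequency to its
#' expected count over `2n`. Iteration stops when the relative change in
#' log-likelihood falls below `tol`. The best of `restarts` initializations
#' is returned: restart 1 starts from the product of observed allele
#' frequencies, later restarts perturb it with seeded Dirichlet noise to
#' escape symmetric local maxima.
#'
#' Individuals with more than two copies at any included locus are excluded
#' and counted in the `n_excluded` attribute. Haplotypes with estimated
#' frequency below `1/(4n)` (the counting noise floor) are pruned from the
#' returned table but retained in the `frequencies` attribute.
#'
#' @param genotypes Long genotype table: data.frame with columns
#'   `individual`, `gene`, `allele`, one row per gene copy.
#' @param loci Character vector of loci to include, in order.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param restarts Number of initializations.
#' @param seed Integer seed for the restart perturbations.
#' @return A data.frame of class `kir_haplotable` with columns `haplotype`
#'   (allele names joined by `"~"` in `loci` order) and `frequency`, sorted
#'   by decreasing frequency; attributes `loci`, `loglik`, `trace`,
#'   `n_iter`, `converged`, `n_individuals`, `n_excluded`, `excluded_ids`,
#'   `frequencies` (full unpruned named vector).
#' @export
em_haplotype_frequencies <- function(genotypes, loci, tol = 1e-8,
                                     max_iter = 1000, restarts = 10,
                                     seed = 1) {
  dp <- .diploid_pairs(genotypes, loci)
  if (length(dp$pairs) == 0) {
    stop("no EM-eligible individuals for loci ", paste(loci, collapse = ", "),
         call. = FALSE)
  }
  pt <- .pair_table(dp$pairs, loci)
  H <- length(pt$hap_names)
  n <- sum(pt$class_n)

  # restart 1: product of observed allele frequencies
  allele_mat <- do.call(rbind, strsplit(pt$hap_names, .HAP_SEP, fixed = TRUE))
  f0 <- rep(1, H)
  for (j in seq_along(loci)) {
    obs <- unlist(lapply(dp$pairs, function(p) p[, j]))
    af <- table(obs) / length(obs)
    f0 <- f0 * as.numeric(af[allele_mat[, j]])
  }
  f0[is.na(f0) | f0 <= 0] <- .Machine$double.eps
  names(f0) <- pt$hap_names

  best <- NULL
  for (r in seq_len(max(1L, restarts))) {
    fr <- if (r == 1) f0 else {
      set.seed((seed * 1009L + r) %% .Machine$integer.max)
      noise <- stats::rgamma(H, shape = 1)
      f0 * noise
    }
    run <- .em_run(pt, fr, tol, max_iter)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (!best$converged) {
    warning("EM did not converge within ", max_iter,
            " iterations; best state returned")
  }
  f <- best$f
  names(f) <- pt$hap_names
  floor_f <- 1 / (4 * n)
  keep <- f >= floor_f
  out <- data.frame(haplotype = pt$hap_names[keep],
                    frequency = unname(f[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$haplotype), ]
  rownames(out) <- NULL
  structure(out, class = c("kir_haplotable", "data.frame"),
            loci = loci, loglik = best$loglik, trace = best$trace,
            n_iter = best$n_iter, converged = best$converged,
            n_individuals = n, n_excluded = length(dp$excluded),
            excluded_ids = dp$excluded, frequencies = f)
}

#' Posterior phase probabilities for one individual
#'
#' Enumerates the haplotype pairs consistent with one individual's genotype
#' and weights them by the estimated haplotype frequencies.
#'
#' @param genotype Genotype of one individual: data.frame with columns
#'   `gene` and `allele` (one row per copy) covering the table's loci.
#' @param table A `kir_haplotable` from [em_haplotype_frequencies()].
#' @return data.frame with columns `hap1`, `hap2`, `posterior`, sorted by
#'   decreasing posterior. If every consistent pair has zero estimated
#'   frequency the individual is flagged: a warning is raised and the
#'   `flagged` attribute is `TRUE` with uniform posteriors over the pairs.
#' @export
phase_posteriors <- function(genotype, table) {
  loci <- attr(table, "loci")
  freqs <- attr(table, "frequencies")
  genotype$individual <- "x"
  dp <- .diploid_pairs(genotype, loci)
  if (length(dp$pairs) == 0) {
    stop("individual has more than two copies at an included locus",
         call. = FALSE)
  }
  pt <- .pair_table(dp$pairs, loci)
  get_f <- function(h) ifelse(is.na(freqs[h]), 0, freqs[h])
  ha <- pt$hap_names[pt$pair_a]
  hb <- pt$hap_names[pt$pair_b]
  w <- pt$pair_mult * get_f(ha) * get_f(hb)
  flagged <- FALSE
  if (sum(w) <= 0) {
    warning("all consistent haplotype pairs have zero estimated frequency; ",
            "individual flagged")
    flagged <- TRUE
    w <- rep(1, length(w))
  }
  out <- data.frame(hap1 = ha, hap2 = hb, posterior = unname(w / sum(w)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$posterior, out$hap1, out$hap2), ]
  rownames(out) <- NULL
  structure(out, flagged = flagged)
}

#' Ranked table of the most frequent allelic haplotypes
#'
#' @param table A `kir_haplotable`.
#' @param top_k Number of rows to keep.
#' @return data.frame with columns `rank`, `haplotype`, `frequency`; ties in
#'   frequency are broken lexicographically by haplotype name.
#' @export
haplotype_report <- function(table, top_k = 20) {
  stopifnot(nrow(table) > 0)
  tab <- table[order(-table$frequency, table$haplotype), , drop = FALSE]
  tab <- utils::head(tab, top_k)
  data.frame(rank = seq_len(nrow(tab)), haplotype = tab$haplotype,
             frequency = tab$frequency, stringsAsFactors = FALSE)
}

#' Structural haplotype assignment of phased chromosomes
#'
#' Maps each phased chromosome to the gene-content haplotype whose
#' presence/absence pattern over the phased loci matches the chromosome's
#' non-ABSENT alleles. Only haplotypes of the matching region are
#' considered; chromosomes matching no catalog pattern get `NA`.
#'
#' @param phased data.frame with columns `individual`, `chrom`, `gene`,
#'   `allele` (ABSENT rows included, one row per locus per chromosome, or
#'   omitted loci treated as absent).
#' @param catalog A `kir_catalog`.
#' @return data.frame with columns `individual`, `chrom`, `haplotype`.
#' @export
assign_structural_phase <- function(phased, catalog) {
  genes <- sort(unique(phased$gene))
  cm_counts <- .content_matrix(catalog, genes)
  # a phased chromosome carries at most one allele per locus, so catalog
  # haplotypes with internal duplications over these loci cannot match
  cm <- cm_counts[apply(cm_counts, 1, max) <= 1, , drop = FALSE] > 0
  pat_key <- apply(cm, 1, function(x) paste(as.integer(x), collapse = ""))
  chroms <- unique(phased[, c("individual", "chrom")])
  out_hap <- character(nrow(chroms))
  for (k in seq_len(nrow(chroms))) {
    sub <- phased[phased$individual == chroms$individual[k] &
                    phased$chrom == chroms$chrom[k], ]
    present <- genes %in% sub$gene[sub$allele != .ABSENT]
    key <- paste(as.integer(present), collapse = "")
    hits <- names(pat_key)[pat_key == key]
    out_hap[k] <- if (length(hits) == 1) hits else NA_character_
  }
  data.frame(individual = chroms$individual, chrom = chroms$chrom,
             haplotype = out_hap, stringsAsFactors = FALSE)
}

#' Alleles restricted to specific gene-content haplotypes
#'
#' Cross-tabulates phased allele observations against structural haplotype
#' assignments and reports, per haplotype, the alleles whose observations
#' fall entirely (`exclusive`) or predominantly (`predominant`, at least
#' `predominance` of all observations of that allele) on that haplotype.
#'
#' @param phased data.frame with columns `individual`, `chrom`, `gene`,
#'   `allele`.
#' @param structure data.frame with columns `individual`, `chrom`,
#'   `haplotype` (e.g. from [assign_structural_phase()] or simulation truth).
#' @param exclusivity Share at or above which an allele is called exclusive.
#' @param predominance Share at or above which an allele is reported.
#' @return data.frame with columns `haplotype`, `gene`, `allele`, `n_obs`,
#'   `total_obs`, `share`, `status`.
#' @export
haplotype_restricted_alleles <- function(phased, structure,
                                         exclusivity = 1.0,
                                         predominance = 0.95) {
  m <- merge(phased, structure, by = c("individual", "chrom"))
  m <- m[!is.na(m$haplotype) & m$allele != .ABSENT, ]
  if (nrow(m) == 0) {
    return(data.frame(haplotype = character(0), gene = character(0),
                      allele = character(0), n_obs = integer(0),
                      total_obs = integer(0), share = numeric(0),
                      status = character(0), stringsAsFactors = FALSE))
  }
  tot <- stats::aggregate(list(total_obs = m$allele),
                          by = list(gene = m$gene, allele = m$allele), FUN = length)
  cnt <- stats::aggregate(list(n_obs = m$allele),
                          by = list(haplotype = m$haplotype, gene = m$gene,
                                    allele = m$allele), FUN = length)
  out <- merge(cnt, tot, by = c("gene", "allele"))
  out$share <- out$n_obs / out$total_obs
  out$status <- ifelse(out$share >= exclusivity, "exclusive",
                       ifelse(out$share >= predominance, "predominant", NA))
  out <- out[!is.na(out$status), c("haplotype", "gene", "allele", "n_obs",
                                   "total_obs", "share", "status")]
  out <- out[order(out$haplotype, out$gene, out$allele), ]
  rownames(out) <- NULL
  out
}
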