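# Pairwise linkage disequilibrium between KIR loci from EM-estimated
# two-locus haplotype frequencies. LD is reported per allele pair (each
# allele against the rest, a 2x2 collapse of the joint matrix), the way
# allele-level D'/r-squared are reported for multi-allelic loci. ABSENT
# participates as an allele, so gene presence/absence LD falls out of the
# same machinery.

#' Two-locus haplotype frequency matrix
#'
#' Runs the gene-counting EM on the genotypes of one locus pair and folds
#' the converged haplotype frequencies into a joint allele-by-allele
#' frequency matrix (rows: `locusA` alleles; columns: `locusB` alleles;
#' ABSENT included).
#'
#' @param genotypes Long genotype table (`individual`, `gene`, `allele`).
#' @param locusA,locusB Locus names.
#' @param ... Passed to [em_haplotype_frequencies()] (`tol`, `restarts`,
#'   `seed`, ...).
#' @return Numeric matrix with non-negative entries summing to 1;
#'   attributes `loglik`, `n_individuals`, `degenerate` (TRUE when a locus
#'   has fewer than 2 observed alleles, in which case LD is undefined).
#' @export
two_locus_frequencies <- function(genotypes, locusA, locusB, ...) {
  tab <- em_haplotype_frequencies(genotypes, c(locusA, locusB), ...)
  f <- attr(tab, "frequencies")
  parts <- do.call(rbind, strsplit(names(f), .HAP_SEP, fixed = TRUE))
  a_levels <- sort(unique(parts[, 1]))
  b_levels <- sort(unique(parts[, 2]))
  m <- matrix(0, length(a_levels), length(b_levels),
              dimnames = list(a_levels, b_levels))
  m[cbind(parts[, 1], parts[, 2])] <- unname(f)
  m <- m / sum(m)
  degenerate <- length(a_levels) < 2 || length(b_levels) < 2
  if (degenerate) {
    warning("fewer than 2 alleles at ", if (length(a_levels) < 2) locusA else locusB,
            "; LD undefined for this pair")
  }
  structure(m, loglik = attr(tab, "loglik"),
            n_individuals = attr(tab, "n_individuals"),
            locusA = locusA, locusB = locusB, degenerate = degenerate)
}

#' Allele-pair linkage disequilibrium from a joint frequency matrix
#'
#' For every cell of the joint matrix, collapses to a 2x2 table (allele
#' versus rest at each locus) and computes `D = p_ij - p_i q_j`, `D'` (D
#' over its attainable extreme given the margins) and
#' `r2 = D^2 / (p_i (1 - p_i) q_j (1 - q_j))`. A monomorphic margin
#' (`Dmax = 0`) yields `D' = 0` with `degenerate = TRUE` rather than an
#' error.
#'
#' @param joint Joint frequency matrix (e.g. from
#'   [two_locus_frequencies()]); dimnames are the allele names.
#' @param locusA,locusB Optional locus labels (defaults taken from the
#'   matrix attributes when present).
#' @return data.frame with columns `locusA`, `locusB`, `alleleA`,
#'   `alleleB`, `p_ij`, `p_i`, `q_j`, `D`, `D_prime`, `r2`, `degenerate`,
#'   `p_value` (NA until filled by [permutation_pvalue()]).
#' @export
ld_from_frequencies <- function(joint, locusA = NULL, locusB = NULL) {
  if (is.null(locusA)) locusA <- attr(joint, "locusA") %||% "locusA"
  if (is.null(locusB)) locusB <- attr(joint, "locusB") %||% "locusB"
  p_i <- rowSums(joint)
  q_j <- colSums(joint)
  rows <- expand.grid(a = rownames(joint), b = colnames(joint),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(k) {
    a <- rows$a[k]; b <- rows$b[k]
    pij <- joint[a, b]; pi <- p_i[[a]]; qj <- q_j[[b]]
    D <- pij - pi * qj
    dmax <- if (D < 0) min(pi * qj, (1 - pi) * (1 - qj))
            else min(pi * (1 - qj), (1 - pi) * qj)
    degen <- dmax <= .Machine$double.eps^0.5 && abs(D) <= .Machine$double.eps^0.5
    dp <- if (dmax > 0) D / dmax else 0
    denom <- pi * (1 - pi) * qj * (1 - qj)
    r2 <- if (denom > 0) D^2 / denom else 0
    data.frame(locusA = locusA, locusB = locusB, alleleA = a, alleleB = b,
               p_ij = pij, p_i = pi, q_j = qj, D = D, D_prime = dp, r2 = r2,
               degenerate = degen, p_value = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Log-likelihood of the genotypes of a locus pair under independence
# (joint haplotype frequency = product of single-locus allele frequencies).
.indep_loglik <- function(pt, loci_n = 2) {
  parts <- do.call(rbind, strsplit(pt$hap_names, .HAP_SEP, fixed = TRUE))
  # expected haplotype counts under the saturated per-locus allele model:
  # allele frequencies are direct counts (each genotype contributes its two
  # alleles), independent across loci
  f <- rep(1, length(pt$hap_names))
  n2 <- 2 * sum(pt$class_n)
  for (j in seq_len(ncol(parts))) {
    # any consistent pair of a class carries the same allele multiset per
    # locus, so counting one representative pair per class counts genotypes
    first <- !duplicated(pt$pair_class)
    al <- c(parts[pt$pair_a[first], j], parts[pt$pair_b[first], j])
    wt <- rep(pt$class_n, 2)
    af <- rowsum(wt, al)[, 1] / n2
    f <- f * af[parts[, j]]
  }
  w <- pt$pair_mult * f[pt$pair_a] * f[pt$pair_b]
  sw <- rowsum(w, pt$pair_class)[, 1]
  sum(pt$class_n * log(sw))
}

#' Permutation p-value for linkage disequilibrium of a locus pair
#'
#' The test statistic is the converged two-locus EM log-likelihood minus
#' the log-likelihood under independence (joint frequencies equal to the
#' product of single-locus allele frequencies). The null distribution is
#' generated by permuting one locus's genotypes (the per-individual allele
#' pair moves as a unit) across individuals;
#' `p = (1 + #permuted >= observed) / (n_perm + 1)`.
#'
#' @param genotypes Long genotype table.
#' @param locusA,locusB Locus names.
#' @param n_perm Number of permutations (at least 1).
#' @param seed Integer seed.
#' @param tol,max_iter,restarts EM settings (restarts default 1 here: the
#'   two-locus likelihood surface is well-behaved and the permutation loop
#'   dominates cost).
#' @return List with `p_value`, `statistic`, `n_perm`.
#' @export
permutation_pvalue <- function(genotypes, locusA, locusB, n_perm = 999,
                               seed = 1, tol = 1e-8, max_iter = 1000,
                               restarts = 1) {
  stopifnot(n_perm >= 1)
  loci <- c(locusA, locusB)
  dp <- .diploid_pairs(genotypes, loci)
  if (length(dp$pairs) == 0) stop("no EM-eligible individuals", call. = FALSE)

  stat_of <- function(pairs) {
    pt <- .pair_table(pairs, loci)
    allele_mat <- do.call(rbind, strsplit(pt$hap_names, .HAP_SEP, fixed = TRUE))
    f0 <- rep(1, length(pt$hap_names))
    run <- .em_run(pt, f0, tol, max_iter)
    run$loglik - .indep_loglik(pt)
  }
  obs <- stat_of(dp$pairs)

  set.seed(seed %% .Machine$integer.max)
  n <- length(dp$pairs)
  count_ge <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    pairs_b <- lapply(seq_len(n), function(i) {
      m <- dp$pairs[[i]]
      m[, 2] <- dp$pairs[[perm[i]]][, 2]
      m
    })
    if (stat_of(pairs_b) >= obs - 1e-9) count_ge <- count_ge + 1L
  }
  list(p_value = (1 + count_ge) / (n_perm + 1), statistic = obs,
       n_perm = n_perm)
}

#' Filter LD records the way strong-LD figures are drawn
#'
#' Keeps allele pairs with `r2` strictly above `r2_min`, `D'` strictly
#' above `dprime_min`, and (when a p-value is present) `p_value` at most
#' `p_max`; records with no p-value pass the p filter only if `p_max` is
#' `NA`. Output is sorted by `r2` descending.
#'
#' @param records data.frame from [ld_from_frequencies()].
#' @param r2_min,dprime_min Strict lower bounds.
#' @param p_max Maximum p-value, or `NA` to skip the p filter.
#' @return Filtered, sorted data.frame.
#' @export
filter_ld <- function(records, r2_min = 0.2, dprime_min = 0.7,
                      p_max = 1e-5) {
  keep <- records$r2 > r2_min & records$D_prime > dprime_min
  if (!is.na(p_max)) {
    keep <- keep & !is.na(records$p_value) & records$p_value <= p_max
  }
  out <- records[keep, , drop = FALSE]
  out <- out[order(-out$r2, out$alleleA, out$alleleB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locus-level LD summary (frequency-weighted mean absolute D')
#'
#' A convenience summary of a locus pair's allele-level records: the mean
#' of `|D'|` weighted by `p_i * q_j`. This is a package-level summary
#' statistic, not a figure-for-figure analog of any published quantity.
#'
#' @param records data.frame from [ld_from_frequencies()] for one locus
#'   pair.
#' @return One-row data.frame with `locusA`, `locusB`, `mean_abs_dprime`.
#' @export
ld_locus_summary <- function(records) {
  w <- records$p_i * records$q_j
  data.frame(locusA = records$locusA[1], locusB = records$locusB[1],
             mean_abs_dprime = sum(abs(records$D_prime) * w) / sum(w))
}
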