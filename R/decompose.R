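# Decomposition of per-individual copy-number profiles into unordered pairs
# of gene-content haplotypes, frequency-weighted disambiguation, and
# frequency tables with an explicit undetermined fraction.
#
# The centromeric and telomeric regions are resolved independently (the
# framework-gene split). Telomeric insertion haplotypes may carry copies of
# centromeric loci (KIR3DP1 in the new1/new2 blocks); the telomeric region
# is therefore resolved first and the resolved telomeric pair's
# centromeric-locus content is subtracted from the profile before the
# centromeric decomposition.

#' Enumerate exact decompositions of a copy-number profile
#'
#' Returns every unordered pair of catalog haplotypes of the given region
#' whose region-locus contents sum exactly to the profile. An empty list
#' means the profile cannot be explained by the catalog.
#'
#' @param profile Named integer vector of copy numbers; must cover the
#'   region's loci (a full 15-locus profile is fine).
#' @param catalog A `kir_catalog`.
#' @param region `"centromeric"` or `"telomeric"`.
#' @return List of length-2 character vectors (haplotype names, pair sorted
#'   lexicographically; list sorted likewise).
#' @export
enumerate_decompositions <- function(profile, catalog, region) {
  loci <- region_loci(region)
  cat_r <- catalog_region(catalog, region)
  if (length(cat_r) == 0) return(list())
  cm <- .content_matrix(cat_r, loci)
  prof <- profile[loci]
  if (anyNA(prof)) {
    stop("profile is missing loci: ",
         paste(loci[is.na(prof)], collapse = ", "), call. = FALSE)
  }
  keys <- apply(cm, 1, paste, collapse = ",")
  lookup <- split(seq_len(nrow(cm)), keys)
  pairs <- list()
  for (i in seq_len(nrow(cm))) {
    resid <- prof - cm[i, ]
    if (any(resid < 0)) next
    js <- lookup[[paste(resid, collapse = ",")]]
    for (j in js) {
      if (j >= i) pairs[[length(pairs) + 1]] <- sort(rownames(cm)[c(i, j)])
    }
  }
  if (length(pairs) > 1) {
    ord <- order(vapply(pairs, paste, "", collapse = "|"))
    pairs <- pairs[ord]
  }
  pairs
}

# EM over gene-content haplotype frequencies given per-individual candidate
# pair lists. Returns converged frequencies and per-individual posteriors.
.structure_em <- function(pair_lists, hap_names, max_iter = 500, tol = 1e-10) {
  has <- lengths(pair_lists) > 0
  idx <- lapply(pair_lists[has], function(pl) {
    cbind(match(vapply(pl, `[`, "", 1), hap_names),
          match(vapply(pl, `[`, "", 2), hap_names))
  })
  pair_ind <- rep(seq_along(idx), vapply(idx, nrow, 0L))
  pa <- unlist(lapply(idx, `[`, , 1))
  pb <- unlist(lapply(idx, `[`, , 2))
  mult <- ifelse(pa == pb, 1, 2)
  n <- length(idx)
  f <- rep(1 / length(hap_names), length(hap_names))
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    w <- mult * f[pa] * f[pb]
    sw <- rowsum(w, pair_ind)[, 1]
    ll <- sum(log(sw))
    post <- w / sw[pair_ind]
    cnt <- rowsum(c(post, post), c(pa, pb))[, 1]
    fnew <- numeric(length(f))
    fnew[as.integer(names(cnt))] <- cnt / (2 * n)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll_prev) + tol)) {
      f <- fnew; break
    }
    ll_prev <- ll
    f <- fnew
  }
  post <- (mult * f[pa] * f[pb])
  sw <- rowsum(post, pair_ind)[, 1]
  post <- post / sw[pair_ind]
  list(f = setNames(f, hap_names), pair_ind = pair_ind, pa = pa, pb = pb,
       posterior = post, eligible = which(has))
}

#' Resolve a cohort of copy-number profiles into haplotype pairs
#'
#' For each region, enumerates every exact catalog decomposition of each
#' individual's profile, then runs an iterative frequency-weighted
#' disambiguation: haplotype frequencies start uniform, each individual's
#' candidate pairs are scored by the product of current frequencies (doubled
#' for heterozygous pairs), fractional counts re-estimate the frequencies,
#' and at convergence an individual is `resolved` if its top pair holds a
#' posterior share of at least `ratio_threshold`, `ambiguous` otherwise, and
#' `undetermined` if no catalog pair reproduces its profile. Reported counts
#' use hard assignments of resolved individuals only; everything else
#' aggregates into the undetermined fraction.
#'
#' @param profiles Copy-number table: data.frame with column `individual`
#'   plus one integer column per locus (all 15 loci).
#' @param catalog A `kir_catalog`.
#' @param ratio_threshold Posterior share needed to call an individual
#'   resolved.
#' @param couplings Optional list of centromeric-to-telomeric phase
#'   couplings (e.g. `list(c("cB04", "tB03"))`) used when pairing regional
#'   haplotypes into full haplotypes.
#' @return List of class `kir_resolution` with elements `centromeric` and
#'   `telomeric`, each a list with `resolution` (data.frame: `individual`,
#'   `status`, `hap1`, `hap2`, `posterior`, `n_candidates`) and `freq_table`
#'   (see [structure_freq_table()]); plus `full` (data.frame of full
#'   haplotype pairs where phase is determinable).
#' @export
resolve_cohort <- function(profiles, catalog, ratio_threshold = 0.95,
                           couplings = list(c("cB04", "tB03"),
                                            c("cA03", "tB02"))) {
  loci_all <- region_loci("full")
  stopifnot(all(loci_all %in% names(profiles)))
  n <- nrow(profiles)
  prof_mat <- as.matrix(profiles[, loci_all])
  rownames(prof_mat) <- profiles$individual

  out <- list()
  adj <- prof_mat
  for (region in c("telomeric", "centromeric")) {
    cat_r <- catalog_region(catalog, region)
    pair_lists <- lapply(seq_len(n), function(i) {
      enumerate_decompositions(adj[i, ], catalog, region)
    })
    hap_names <- names(cat_r)
    res <- data.frame(individual = profiles$individual,
                      status = "undetermined",
                      hap1 = NA_character_, hap2 = NA_character_,
                      posterior = NA_real_,
                      n_candidates = lengths(pair_lists),
                      stringsAsFactors = FALSE)
    if (any(lengths(pair_lists) > 0)) {
      em <- .structure_em(pair_lists, hap_names)
      for (k in seq_along(em$eligible)) {
        i <- em$eligible[k]
        sel <- em$pair_ind == k
        po <- em$posterior[sel]
        a <- hap_names[em$pa[sel]]; b <- hap_names[em$pb[sel]]
        # deterministic tie-break: highest posterior, then lexicographic pair
        ord <- order(-po, a, b)
        top <- ord[1]
        res$hap1[i] <- a[top]; res$hap2[i] <- b[top]
        res$posterior[i] <- po[top]
        res$status[i] <- if (po[top] >= ratio_threshold) "resolved" else "ambiguous"
      }
    }
    ft <- structure_freq_table(res, region, n)
    out[[region]] <- list(resolution = res, freq_table = ft)
    if (region == "telomeric") {
      # subtract resolved telomeric spillover into centromeric loci
      cen_loci <- region_loci("centromeric")
      for (i in which(res$status == "resolved")) {
        spill <- cat_r[[res$hap1[i]]]$content[cen_loci] +
          cat_r[[res$hap2[i]]]$content[cen_loci]
        adj[i, cen_loci] <- adj[i, cen_loci] - spill
      }
    }
  }

  full <- .pair_full_haplotypes(out$centromeric$resolution,
                                out$telomeric$resolution, couplings)
  structure(list(centromeric = out$centromeric, telomeric = out$telomeric,
                 full = full, n_individuals = n,
                 ratio_threshold = ratio_threshold),
            class = "kir_resolution")
}

# Pair resolved regional haplotypes into full haplotypes where the phase is
# determinable: when either region is homozygous, or when a configured
# coupling (e.g. cB04~tB03) identifies the phase.
.pair_full_haplotypes <- function(res_cen, res_tel, couplings) {
  n <- nrow(res_cen)
  full1 <- rep(NA_character_, n); full2 <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (res_cen$status[i] != "resolved" || res_tel$status[i] != "resolved") next
    c1 <- res_cen$hap1[i]; c2 <- res_cen$hap2[i]
    t1 <- res_tel$hap1[i]; t2 <- res_tel$hap2[i]
    phase <- NULL
    if (c1 == c2 || t1 == t2) {
      phase <- c(paste0(c1, "~", t1), paste0(c2, "~", t2))
    } else {
      for (cp in couplings) {
        if (cp[1] %in% c(c1, c2) && cp[2] %in% c(t1, t2)) {
          ca <- cp[1]; ta <- cp[2]
          cb <- if (c1 == ca) c2 else c1
          tb <- if (t1 == ta) t2 else t1
          phase <- c(paste0(ca, "~", ta), paste0(cb, "~", tb))
          break
        }
      }
    }
    if (!is.null(phase)) { full1[i] <- phase[1]; full2[i] <- phase[2] }
  }
  data.frame(individual = res_cen$individual, full1 = full1, full2 = full2,
             stringsAsFactors = FALSE)
}

#' Haplotype frequency table by direct counting of resolved individuals
#'
#' Frequencies follow the counting convention `f = count / (2 n)`: each
#' individual contributes two haplotypes to the denominator, and haplotypes
#' of ambiguous or undetermined individuals aggregate into the undetermined
#' fraction, so frequencies plus the undetermined fraction sum to one.
#'
#' @param resolution A per-individual resolution data.frame (see
#'   [resolve_cohort()]).
#' @param region Region label carried on the table.
#' @param n_individuals Cohort size (denominator is `2 * n_individuals`).
#' @return data.frame of class `kir_freq_table` with columns `haplotype`,
#'   `count`, `frequency`, and attributes `region`, `undetermined_fraction`,
#'   `n_individuals`.
#' @export
structure_freq_table <- function(resolution, region, n_individuals) {
  resolved <- resolution[resolution$status == "resolved", ]
  haps <- c(resolved$hap1, resolved$hap2)
  tab <- sort(table(haps), decreasing = TRUE)
  out <- data.frame(haplotype = names(tab), count = as.integer(tab),
                    frequency = as.integer(tab) / (2 * n_individuals),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  undet <- 1 - sum(out$frequency)
  structure(out, class = c("kir_freq_table", "data.frame"), region = region,
            undetermined_fraction = undet, n_individuals = n_individuals)
}

#' Discover candidate novel gene-content haplotypes
#'
#' Implements the residual rule: for every unresolved profile and every
#' common haplotype (frequency at or above `common_freq_threshold`) whose
#' content fits inside the profile, the residual `profile - content` is a
#' candidate haplotype; identical residuals recurring in at least
#' `min_support` individuals are returned and can be appended to the catalog
#' for a second resolution pass.
#'
#' @param profiles Copy-number table restricted to unresolved individuals
#'   (data.frame with `individual` plus locus columns).
#' @param catalog A `kir_catalog`.
#' @param freq_table A `kir_freq_table` for the region (supplies the
#'   "common" haplotype frequencies).
#' @param region `"centromeric"` or `"telomeric"`.
#' @param min_support Minimum number of distinct individuals sharing a
#'   residual.
#' @param common_freq_threshold Frequency at or above which a haplotype
#'   counts as common.
#' @return A `kir_catalog` of discovered haplotypes (possibly empty), named
#'   `discovered:<hash>`, with `provenance = "discovered"` and a `support`
#'   attribute (data.frame: name, support, donor).
#' @export
discover_novel_structures <- function(profiles, catalog, freq_table, region,
                                      min_support = 2,
                                      common_freq_threshold = 0.01) {
  loci <- region_loci(region)
  cat_r <- catalog_region(catalog, region)
  common <- freq_table$haplotype[freq_table$frequency >= common_freq_threshold]
  common <- intersect(common, names(cat_r))
  found <- list()  # key -> list(content, ids, donor)
  for (i in seq_len(nrow(profiles))) {
    prof <- unlist(profiles[i, loci])
    for (h in common) {
      resid <- prof - cat_r[[h]]$content[loci]
      if (any(resid < 0)) next
      key <- paste(resid, collapse = ",")
      if (is.null(found[[key]])) {
        found[[key]] <- list(content = resid, ids = character(0), donor = h)
      }
      found[[key]]$ids <- union(found[[key]]$ids, profiles$individual[i])
    }
  }
  keep <- Filter(function(x) length(x$ids) >= min_support, found)
  if (length(keep) == 0) {
    return(structure(list(), class = "kir_catalog",
                     support = data.frame(name = character(0),
                                          support = integer(0),
                                          donor = character(0))))
  }
  haps <- lapply(keep, function(x) {
    genes <- rep(loci, times = x$content)
    kir_haplotype(paste0("discovered:", .content_hash(x$content)),
                  region, genes, provenance = "discovered")
  })
  names(haps) <- vapply(haps, `[[`, "", "name")
  # deterministic order
  haps <- haps[order(names(haps))]
  support <- data.frame(
    name = vapply(keep, function(x) paste0("discovered:", .content_hash(x$content)), ""),
    support = vapply(keep, function(x) length(x$ids), 0L),
    donor = vapply(keep, function(x) x$donor, ""),
    stringsAsFactors = FALSE)
  support <- support[order(support$name), ]
  rownames(support) <- NULL
  structure(haps, class = "kir_catalog", support = support)
}

# Short deterministic hash of a content vector (for discovered-haplotype
# names).
.content_hash <- function(content) {
  s <- paste(names(content), content, sep = ":", collapse = ";")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  sprintf("%08x", h)
}

#' Per-gene copy-number summary
#'
#' @param profiles Copy-number table (data.frame with `individual` plus
#'   locus columns).
#' @param max_copy Highest copy-number bin.
#' @return data.frame with columns `gene`, `copies`, `count`, `percent`
#'   (rounded to 1 decimal); per gene the counts sum to the cohort size.
#' @export
copy_number_summary <- function(profiles, max_copy = 4) {
  loci <- intersect(region_loci("full"), names(profiles))
  n <- nrow(profiles)
  rows <- lapply(loci, function(g) {
    cts <- factor(profiles[[g]], levels = 0:max_copy)
    tab <- table(cts)
    data.frame(gene = g, copies = 0:max_copy, count = as.integer(tab),
               percent = round(100 * as.integer(tab) / n, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Co-deletion summary for two loci
#'
#' Among individuals carrying a single copy of `primary` (one deleted
#' chromosome), reports how many also have at most one copy of `secondary`,
#' i.e. how often the secondary locus is deleted on the same haplotypes.
#'
#' @param profiles Copy-number table.
#' @param primary,secondary Locus names.
#' @return One-row data.frame with `n_deletion`, `n_co_deleted`, `percent`
#'   (rounded to 1 decimal).
#' @export
codeletion_summary <- function(profiles, primary = "KIR2DL4",
                               secondary = "KIR3DP1") {
  del <- profiles[[primary]] == 1
  co <- del & profiles[[secondary]] <= 1
  data.frame(n_deletion = sum(del), n_co_deleted = sum(co),
             percent = round(100 * sum(co) / max(1, sum(del)), 1))
}
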