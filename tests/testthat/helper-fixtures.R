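# Shared fixtures and independent oracles, all built in code.

# Assemble a kir_catalog from kir_haplotype objects.
make_catalog <- function(...) {
  haps <- list(...)
  names(haps) <- vapply(haps, `[[`, "", "name")
  structure(haps, class = "kir_catalog")
}

# A zero profile over all 15 loci.
zero_profile <- function() {
  stats::setNames(integer(15), region_loci("full"))
}

# Brute-force decomposition oracle: plain double loop over the catalog.
oracle_decompositions <- function(profile, catalog, region) {
  loci <- region_loci(region)
  cat_r <- catalog[vapply(catalog, `[[`, "", "region") == region]
  nm <- names(cat_r)
  out <- list()
  for (i in seq_along(cat_r)) {
    for (j in i:length(cat_r)) {
      if (j > length(cat_r) || i > length(cat_r)) next
      s <- cat_r[[i]]$content[loci] + cat_r[[j]]$content[loci]
      if (all(s == profile[loci])) {
        out[[length(out) + 1]] <- sort(c(nm[i], nm[j]))
      }
    }
  }
  out
}

# Canonical string form of a pair list, for set comparison.
pair_key <- function(pairs) {
  sort(vapply(pairs, paste, "", collapse = "|"))
}

# Independent two-locus biallelic genotype log-likelihood given haplotype
# frequencies (hand enumeration of the 4 x 4 ordered haplotype pairs).
# geno: data.frame with columns a1, a2, b1, b2 (allele characters).
biallelic_loglik <- function(geno, f) {
  haps <- names(f)
  stopifnot(length(haps) == 4)
  al <- do.call(rbind, strsplit(haps, "", fixed = TRUE))
  ll <- 0
  for (i in seq_len(nrow(geno))) {
    p <- 0
    for (x in 1:4) for (y in 1:4) {
      okA <- identical(sort(c(al[x, 1], al[y, 1])),
                       sort(c(geno$a1[i], geno$a2[i])))
      okB <- identical(sort(c(al[x, 2], al[y, 2])),
                       sort(c(geno$b1[i], geno$b2[i])))
      if (okA && okB) p <- p + f[x] * f[y]
    }
    ll <- ll + log(p)
  }
  ll
}

# Grid-search oracle for the two-locus biallelic EM: allele margins are
# fixed at their counted values (the ML property of gene counting) and the
# single free parameter f_AB is scanned on a grid.
grid_oracle_biallelic <- function(geno, step = 0.001) {
  n2 <- 2 * nrow(geno)
  pA <- sum(c(geno$a1, geno$a2) == "A") / n2
  pB <- sum(c(geno$b1, geno$b2) == "B") / n2
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, by = step)
  best <- NULL
  for (fab in grid) {
    f <- c(AB = fab, Ab = pA - fab, aB = pB - fab, ab = 1 - pA - pB + fab)
    if (any(f < -1e-12)) next
    f[f < 0] <- 0
    ll <- biallelic_loglik(geno, f)
    if (is.null(best) || ll > best$ll) best <- list(ll = ll, f = f)
  }
  best
}

# Draw unphased two-locus genotypes from haplotype frequencies.
draw_biallelic_genotypes <- function(n, f, seed) {
  set.seed(seed)
  haps <- names(f)
  h1 <- sample(haps, n, replace = TRUE, prob = f)
  h2 <- sample(haps, n, replace = TRUE, prob = f)
  data.frame(a1 = substr(h1, 1, 1), a2 = substr(h2, 1, 1),
             b1 = substr(h1, 2, 2), b2 = substr(h2, 2, 2),
             stringsAsFactors = FALSE)
}

# Long genotype table for the package EM from biallelic draws, using two
# real locus names so the registry checks pass. "A"/"a" become allele
# labels at locusA etc.
biallelic_to_long <- function(geno, locusA = "KIR2DL4", locusB = "KIR3DL2") {
  n <- nrow(geno)
  ids <- sprintf("s%04d", seq_len(n))
  data.frame(
    individual = rep(ids, 4),
    gene = rep(c(locusA, locusA, locusB, locusB), each = n),
    allele = c(geno$a1, geno$a2, geno$b1, geno$b2),
    stringsAsFactors = FALSE)
}

# A tiny in-code allele database for classification tests: one gene, four
# sites. Built through the public loader via temp files so the validation
# path is exercised.
tiny_db <- function() {
  site_rows <- expand.grid(allele = c("KIR2DL4*00101", "KIR2DL4*00201",
                                      "KIR2DL4*00301"),
                           position = c(10, 20, 30, 40),
                           stringsAsFactors = FALSE)
  bases <- rbind(`KIR2DL4*00101` = c("A", "C", "G", "T"),
                 `KIR2DL4*00201` = c("G", "C", "G", "T"),
                 `KIR2DL4*00301` = c("A", "T", "C", "T"))
  site_rows$base <- bases[cbind(match(site_rows$allele, rownames(bases)),
                                match(site_rows$position, c(10, 20, 30, 40)))]
  site_rows$gene <- "KIR2DL4"
  f <- tempfile(fileext = ".tsv")
  utils::write.table(site_rows[, c("gene", "allele", "position", "base")],
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  load_allele_db(f, cds_fasta_path = NULL, version = "tiny-test-db")
}

# Memoised mid-size default-config cohort shared across test files.
.cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function(n = 400, seed = 20) {
  key <- paste0("n", n, "s", seed)
  if (is.null(.cohort_cache[[key]])) {
    cfg <- load_sim_config()
    cfg$n_individuals <- n
    k <- max(1, round(n / 15))
    cfg$novel_injection[[1]]$count <- k
    cfg$novel_injection[[2]]$count <- max(1, round(n / 200))
    cfg$novel_injection[[3]]$count <- max(1, round(n / 250))
    .cohort_cache[[key]] <- simulate_cohort(cfg, seed = seed)
  }
  .cohort_cache[[key]]
}

# Expected marginal regional haplotype frequencies of a sim config.
config_region_freqs <- function(cfg, region = c("centromeric", "telomeric")) {
  region <- match.arg(region)
  field <- if (region == "centromeric") "cen" else "tel"
  haps <- vapply(cfg$haplotype_pairs, `[[`, "", field)
  fr <- vapply(cfg$haplotype_pairs, function(p) as.numeric(p$frequency), 0)
  tapply(fr, haps, sum)
}
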