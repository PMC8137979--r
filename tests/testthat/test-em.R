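test_that("EM equals direct counting when every individual is homozygous", {
  gt <- data.frame(
    individual = rep(c("a", "b", "c", "d"), each = 4),
    gene = rep(c("KIR2DL4", "KIR2DL4", "KIR3DL2", "KIR3DL2"), 4),
    allele = c("x", "x", "u", "u",  "x", "x", "u", "u",
               "y", "y", "v", "v",  "x", "x", "u", "u"))
  tab <- em_haplotype_frequencies(gt, c("KIR2DL4", "KIR3DL2"), restarts = 1)
  f <- attr(tab, "frequencies")
  expect_equal(unname(f[["x~u"]]), 0.75)
  expect_equal(unname(f[["y~v"]]), 0.25)
  expect_equal(sum(f), 1)
})

test_that("EM matches the grid-search oracle on two-locus biallelic data", {
  truth <- c(AB = 0.30, Ab = 0, aB = 7 / 60, ab = 35 / 60)
  geno <- draw_biallelic_genotypes(100, truth, seed = 101)
  gt <- biallelic_to_long(geno)
  tab <- em_haplotype_frequencies(gt, c("KIR2DL4", "KIR3DL2"),
                                  restarts = 3, seed = 1)
  oracle <- grid_oracle_biallelic(geno, step = 0.001)
  expect_lt(abs(attr(tab, "loglik") - oracle$ll), 0.01)
  f <- attr(tab, "frequencies")
  est <- c(AB = unname(f["A~B"]), Ab = unname(f["A~b"]),
           aB = unname(f["a~B"]), ab = unname(f["a~b"]))
  est[is.na(est)] <- 0
  expect_lt(max(abs(est - oracle$f)), 0.002)
})

test_that("log-likelihood is non-decreasing and frequencies stay normalized", {
  set.seed(7)
  for (trial in 1:6) {
    nall <- sample(2:3, 2, replace = TRUE)
    haps <- as.vector(outer(letters[1:nall[1]], LETTERS[1:nall[2]], paste0))
    f <- stats::rgamma(length(haps), 1); f <- f / sum(f)
    names(f) <- haps
    geno <- draw_biallelic_genotypes(40, f, seed = 200 + trial)
    gt <- biallelic_to_long(geno)
    tab <- em_haplotype_frequencies(gt, c("KIR2DL4", "KIR3DL2"),
                                    restarts = 2, seed = trial)
    trace <- attr(tab, "trace")
    expect_true(all(diff(trace) >= -1e-9))
    expect_equal(sum(attr(tab, "frequencies")), 1, tolerance = 1e-9)
  }
})

test_that("EM recovers generating frequencies within 0.02 at n = 2000", {
  truth <- c(AB = 0.30, Ab = 0, aB = 7 / 60, ab = 35 / 60)
  errs <- vapply(1:20, function(s) {
    geno <- draw_biallelic_genotypes(2000, truth, seed = 300 + s)
    gt <- biallelic_to_long(geno)
    tab <- em_haplotype_frequencies(gt, c("KIR2DL4", "KIR3DL2"),
                                    restarts = 1, seed = s)
    f <- attr(tab, "frequencies")
    est <- c(unname(f["A~B"]), unname(f["A~b"]), unname(f["a~B"]),
             unname(f["a~b"]))
    est[is.na(est)] <- 0
    max(abs(est - unname(truth)))
  }, 0)
  expect_lt(stats::median(errs), 0.02)
})

test_that("individuals with a duplicated locus are excluded and reported", {
  gt <- data.frame(
    individual = c(rep("a", 3), rep("b", 2)),
    gene = "KIR2DL4",
    allele = c("x", "x", "y", "x", "y"))
  tab <- em_haplotype_frequencies(gt, "KIR2DL4", restarts = 1)
  expect_equal(attr(tab, "n_excluded"), 1)
  expect_equal(attr(tab, "excluded_ids"), "a")
  expect_equal(attr(tab, "n_individuals"), 1)
})

test_that("phase posteriors follow the frequency table", {
  # hand-built two-locus table {AB .30, Ab 0, aB 7/60, ab 35/60}
  f <- c(`A~B` = 0.30, `A~b` = 0, `a~B` = 7 / 60, `a~b` = 35 / 60)
  tab <- structure(
    data.frame(haplotype = names(f), frequency = unname(f)),
    class = c("kir_haplotable", "data.frame"),
    loci = c("KIR2DL4", "KIR3DL2"), frequencies = f)
  dbl_het <- data.frame(gene = c("KIR2DL4", "KIR2DL4", "KIR3DL2", "KIR3DL2"),
                        allele = c("A", "a", "B", "b"))
  pp <- phase_posteriors(dbl_het, tab)
  # (A~B, a~b) posterior = 2*.3*(35/60) / (2*.3*(35/60) + 2*0*(7/60)) = 1
  expect_equal(pp$posterior[pp$hap1 == "A~B" & pp$hap2 == "a~b"], 1)
  expect_equal(sum(pp$posterior), 1)

  hom <- data.frame(gene = c("KIR2DL4", "KIR2DL4", "KIR3DL2", "KIR3DL2"),
                    allele = c("a", "a", "b", "b"))
  pp <- phase_posteriors(hom, tab)
  expect_equal(nrow(pp), 1)
  expect_equal(pp$posterior, 1)

  # equal-frequency table: double heterozygote splits 50/50
  f2 <- c(`A~B` = 0.25, `A~b` = 0.25, `a~B` = 0.25, `a~b` = 0.25)
  tab2 <- structure(
    data.frame(haplotype = names(f2), frequency = unname(f2)),
    class = c("kir_haplotable", "data.frame"),
    loci = c("KIR2DL4", "KIR3DL2"), frequencies = f2)
  pp <- phase_posteriors(dbl_het, tab2)
  expect_equal(pp$posterior, c(0.5, 0.5))
})

test_that("haplotype report ranks by frequency with lexicographic ties", {
  tab <- structure(
    data.frame(haplotype = c("b~x", "a~x", "c~x"),
               frequency = c(0.25, 0.25, 0.5)),
    class = c("kir_haplotable", "data.frame"),
    loci = c("KIR2DL4", "KIR3DL2"))
  rep3 <- haplotype_report(tab, top_k = 20)
  expect_equal(nrow(rep3), 3)
  expect_equal(rep3$haplotype, c("c~x", "a~x", "b~x"))
  expect_equal(haplotype_report(tab, top_k = 2)$haplotype, c("c~x", "a~x"))
})

test_that("haplotype-restricted alleles are detected from phased truth", {
  coh <- default_cohort()
  phased <- coh$truth$phased
  structure_df <- unique(phased[, c("individual", "chrom")])
  # region haplotype of each chromosome from truth (telomeric loci only)
  tel <- phased[phased$gene %in% region_loci("telomeric"), ]
  key <- paste(tel$individual, tel$chrom)
  structure_df$haplotype <- tel$region_hap[match(
    paste(structure_df$individual, structure_df$chrom), key)]
  restricted <- haplotype_restricted_alleles(tel, structure_df)
  # KIR3DL2*00701 is simulated only on tB01
  row <- restricted[restricted$allele == "KIR3DL2*00701", ]
  expect_equal(row$haplotype, "tB01")
  expect_equal(row$status, "exclusive")
  # KIR2DL4*00501 is on tB01 in 99.4% of draws but also on new2 insertions
  row <- restricted[restricted$allele == "KIR2DL4*00501" &
                      restricted$haplotype == "tB01", ]
  if (nrow(row) == 1) expect_gte(row$share, 0.95)
})

test_that("structural phase assignment recovers the simulated haplotypes", {
  coh <- default_cohort()
  phased <- coh$truth$phased
  tel <- phased[phased$gene %in% region_loci("telomeric") &
                  phased$gene != "KIR3DP1", ]
  # EM-eligible chromosomes only: drop individuals with duplicated loci
  dup <- unique(tel$individual[tel$copy > 1])
  tel <- tel[!tel$individual %in% dup, ]
  assigned <- assign_structural_phase(tel, coh$catalog)
  key <- paste(tel$individual, tel$chrom)
  truth_hap <- tel$region_hap[match(paste(assigned$individual,
                                          assigned$chrom), key)]
  ok <- !is.na(assigned$haplotype)
  expect_gt(mean(ok), 0.95)
  expect_true(all(assigned$haplotype[ok] == truth_hap[ok]))
})
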