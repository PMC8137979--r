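test_that("D, D-prime and r-squared match exact fractions", {
  joint <- matrix(c(3 / 10, 7 / 60, 0, 35 / 60), 2, 2,
                  dimnames = list(c("A", "a"), c("B", "b")))
  rec <- ld_from_frequencies(joint, "KIR2DL4", "KIR3DL1S1")
  row <- rec[rec$alleleA == "A" & rec$alleleB == "B", ]
  expect_equal(row$D, 7 / 40)
  expect_equal(row$D_prime, 1)
  expect_equal(row$r2, 0.6)
  # the complementary cells carry the same magnitude
  expect_equal(abs(rec$D), rep(7 / 40, 4))
  expect_equal(rec$r2, rep(0.6, 4))
})

test_that("independent and completely associated tables give the closed forms", {
  p <- c(0.3, 0.7); q <- c(0.4, 0.6)
  indep <- outer(p, q)
  dimnames(indep) <- list(c("A", "a"), c("B", "b"))
  rec <- ld_from_frequencies(indep)
  expect_true(all(abs(rec$D) < 1e-12))
  expect_true(all(abs(rec$D_prime) < 1e-12))
  expect_true(all(rec$r2 < 1e-20))

  assoc <- matrix(c(0.5, 0, 0, 0.5), 2, 2,
                  dimnames = list(c("A", "a"), c("B", "b")))
  rec <- ld_from_frequencies(assoc)
  expect_true(all(rec$D_prime == c(1, -1, -1, 1)))
  expect_true(all(rec$r2 == 1))
})

test_that("LD statistics are symmetric under locus swap and stay in bounds", {
  set.seed(11)
  for (trial in 1:20) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    m <- matrix(stats::rgamma(nr * nc, 1), nr, nc)
    m <- m / sum(m)
    dimnames(m) <- list(paste0("r", 1:nr), paste0("c", 1:nc))
    rec <- ld_from_frequencies(m, "KIR2DL4", "KIR3DL2")
    expect_true(all(abs(rec$D_prime) <= 1 + 1e-12))
    expect_true(all(rec$r2 >= 0 & rec$r2 <= 1 + 1e-12))
    rec_t <- ld_from_frequencies(t(m), "KIR3DL2", "KIR2DL4")
    key <- paste(rec$alleleA, rec$alleleB)
    key_t <- paste(rec_t$alleleB, rec_t$alleleA)
    o <- match(key, key_t)
    expect_equal(abs(rec$D), abs(rec_t$D[o]))
    expect_equal(abs(rec$D_prime), abs(rec_t$D_prime[o]))
    expect_equal(rec$r2, rec_t$r2[o])
  }
})

test_that("zero D implies zero D-prime and r-squared", {
  joint <- matrix(c(0.25, 0.25, 0.25, 0.25), 2, 2,
                  dimnames = list(c("A", "a"), c("B", "b")))
  rec <- ld_from_frequencies(joint)
  expect_true(all(rec$D == 0 & rec$D_prime == 0 & rec$r2 == 0))
})

test_that("two-locus EM frequencies recover the generating table", {
  truth <- c(AB = 0.30, Ab = 0, aB = 7 / 60, ab = 35 / 60)
  errs_f <- numeric(20); errs_ld <- numeric(20)
  for (s in 1:20) {
    geno <- draw_biallelic_genotypes(2000, truth, seed = 400 + s)
    gt <- biallelic_to_long(geno)
    joint <- two_locus_frequencies(gt, "KIR2DL4", "KIR3DL2", restarts = 1)
    est <- c(joint["A", "B"], joint["A", "b"], joint["a", "B"],
             joint["a", "b"])
    errs_f[s] <- max(abs(est - unname(truth)))
    rec <- ld_from_frequencies(joint)
    row <- rec[rec$alleleA == "A" & rec$alleleB == "B", ]
    errs_ld[s] <- max(abs(row$D_prime - 1), abs(row$r2 - 0.6))
  }
  expect_lt(stats::median(errs_f), 0.02)
  expect_lt(stats::median(errs_ld), 0.05)
})

test_that("permutation p-values behave at the boundaries", {
  truth <- c(AB = 0.5, Ab = 0, aB = 0, ab = 0.5)  # complete association
  geno <- draw_biallelic_genotypes(200, truth, seed = 500)
  gt <- biallelic_to_long(geno)
  pv <- permutation_pvalue(gt, "KIR2DL4", "KIR3DL2", n_perm = 499, seed = 1)
  expect_equal(pv$p_value, 1 / 500)

  # n_perm = 1 can only give 0.5 or 1
  pv1 <- permutation_pvalue(gt, "KIR2DL4", "KIR3DL2", n_perm = 1, seed = 1)
  expect_true(pv1$p_value %in% c(0.5, 1))
})

test_that("permutation p-values are calibrated under independence", {
  indep <- c(AB = 0.35 * 0.6, Ab = 0.35 * 0.4, aB = 0.65 * 0.6,
             ab = 0.65 * 0.4)
  ps <- vapply(1:20, function(s) {
    geno <- draw_biallelic_genotypes(120, indep, seed = 600 + s)
    gt <- biallelic_to_long(geno)
    permutation_pvalue(gt, "KIR2DL4", "KIR3DL2", n_perm = 99,
                       seed = s)$p_value
  }, 0)
  # roughly uniform: most seeds should clear 0.05
  expect_gte(sum(ps > 0.05), 15)
})

test_that("the strong-LD filter applies strict bounds and sorts by r2", {
  rec <- data.frame(
    locusA = "KIR2DL4", locusB = "KIR3DL1S1",
    alleleA = c("x", "y", "z", "w"), alleleB = c("p", "q", "r", "s"),
    p_ij = 0.1, p_i = 0.2, q_j = 0.2, D = 0.05,
    D_prime = c(0.70, 0.99, 0.95, 0.90),
    r2 = c(0.30, 0.85, 0.73, 0.10),
    degenerate = FALSE,
    p_value = c(1e-6, 1e-6, 1e-6, 1e-6))
  out <- filter_ld(rec)
  # D' = 0.70 fails the strict bound; r2 = 0.10 fails; order is r2 desc
  expect_equal(out$alleleA, c("y", "z"))
  expect_equal(filter_ld(rec[0, ]), rec[0, ])
  # missing p-values drop records unless the p filter is disabled
  rec$p_value <- NA_real_
  expect_equal(nrow(filter_ld(rec)), 0)
  expect_equal(nrow(filter_ld(rec, p_max = NA)), 2)
})

test_that("degenerate loci are flagged", {
  gt <- data.frame(individual = rep(c("a", "b"), each = 4),
                   gene = rep(c("KIR2DL4", "KIR2DL4", "KIR3DL2", "KIR3DL2"), 2),
                   allele = c("x", "x", "u", "v", "x", "x", "u", "u"))
  expect_warning(two_locus_frequencies(gt, "KIR2DL4", "KIR3DL2",
                                       restarts = 1),
                 "fewer than 2 alleles")
})
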