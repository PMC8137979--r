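test_that("doubling and simple telomeric profiles decompose uniquely", {
  cat0 <- load_haplotype_catalog()
  # homozygous cA01
  prof <- 2L * content_vector(cat0$cA01)
  single <- make_catalog(cat0$cA01)
  expect_equal(enumerate_decompositions(prof, single, "centromeric"),
               list(c("cA01", "cA01")))
  # tA01 + 3DL2-only
  prof <- zero_profile()
  prof[c("KIR2DL4", "KIR3DL1S1", "KIR2DS4")] <- 1L
  prof["KIR3DL2"] <- 2L
  expect_equal(enumerate_decompositions(prof, cat0, "telomeric"),
               list(c("t3DL2", "tA01")))
  # the new1 insertion profile pairs with tA01
  prof <- content_vector(cat0$new1) + content_vector(cat0$tA01)
  pairs <- enumerate_decompositions(prof, cat0, "telomeric")
  expect_true(any(vapply(pairs, function(p) all(p == c("new1", "tA01")), TRUE)))
  # inconsistent profile: empty list
  prof <- zero_profile(); prof["KIR2DL4"] <- 1L
  expect_equal(length(enumerate_decompositions(prof, cat0, "telomeric")), 0)
})

test_that("enumeration agrees with the brute-force pairing oracle", {
  set.seed(42)
  tel <- region_loci("telomeric")
  for (trial in 1:25) {
    k <- sample(3:20, 1)
    haps <- lapply(seq_len(k), function(i) {
      genes <- tel[stats::runif(length(tel)) < 0.6]
      genes <- c(genes, tel[stats::runif(length(tel)) < 0.1])  # duplications
      kir_haplotype(sprintf("h%02d", i), "telomeric", genes)
    })
    cat_r <- do.call(make_catalog, haps)
    # half the profiles are true sums, half are random noise
    if (trial %% 2 == 0) {
      ij <- sample(k, 2, replace = TRUE)
      prof <- cat_r[[ij[1]]]$content + cat_r[[ij[2]]]$content
    } else {
      prof <- zero_profile()
      prof[tel] <- sample(0:3, length(tel), replace = TRUE)
    }
    expect_equal(pair_key(enumerate_decompositions(prof, cat_r, "telomeric")),
                 pair_key(oracle_decompositions(prof, cat_r, "telomeric")))
  }
})

test_that("every resolved pair reproduces its profile exactly", {
  coh <- default_cohort()
  cat0 <- coh$catalog
  res <- resolve_cohort(coh$profiles, cat0)
  for (region in c("centromeric", "telomeric")) {
    r <- res[[region]]$resolution
    loci <- region_loci(region)
    resolved <- which(r$status == "resolved")
    expect_gt(length(resolved), 0)
    for (i in resolved[seq_len(min(40, length(resolved)))]) {
      s <- cat0[[r$hap1[i]]]$content[loci] + cat0[[r$hap2[i]]]$content[loci]
      prof <- unlist(coh$profiles[i, loci])
      if (region == "centromeric") {
        # subtract telomeric spillover into centromeric loci
        rt <- res$telomeric$resolution
        if (rt$status[i] == "resolved") {
          spill <- cat0[[rt$hap1[i]]]$content[loci] +
            cat0[[rt$hap2[i]]]$content[loci]
          prof <- prof - spill
        }
      }
      expect_equal(s, prof)
    }
  }
})

test_that("frequencies plus the undetermined fraction sum to one", {
  coh <- default_cohort()
  res <- resolve_cohort(coh$profiles, coh$catalog)
  for (region in c("centromeric", "telomeric")) {
    ft <- res[[region]]$freq_table
    expect_equal(sum(ft$frequency) + attr(ft, "undetermined_fraction"), 1,
                 tolerance = 1e-9)
    expect_true(all(ft$count == as.integer(ft$count)))
  }
})

test_that("resolution is exact on a noise-free uniquely decomposable cohort", {
  coh <- default_cohort()
  res <- resolve_cohort(coh$profiles, coh$catalog)
  th <- coh$truth$haplotypes
  for (region in c("centromeric", "telomeric")) {
    r <- res[[region]]$resolution
    cols <- if (region == "centromeric") c("cen1", "cen2") else c("tel1", "tel2")
    ok <- vapply(seq_len(nrow(r)), function(i) {
      r$status[i] == "resolved" &&
        setequal(c(r$hap1[i], r$hap2[i]), unlist(th[i, cols])) &&
        identical(sort(c(r$hap1[i], r$hap2[i])),
                  sort(unlist(th[i, cols], use.names = FALSE)))
    }, TRUE)
    expect_equal(mean(ok), 1)
  }
})

test_that("estimated haplotype frequencies recover the generating values at n = 2000", {
  cfg <- load_sim_config()
  cfg$n_individuals <- 2000
  coh <- simulate_cohort(cfg, seed = 77)
  res <- resolve_cohort(coh$profiles, coh$catalog)
  for (region in c("centromeric", "telomeric")) {
    truth <- config_region_freqs(cfg, region)
    ft <- res[[region]]$freq_table
    est <- stats::setNames(ft$frequency, ft$haplotype)
    for (h in names(truth)) {
      e <- if (h %in% names(est)) est[[h]] else 0
      expect_lt(abs(e - truth[[h]]), 0.02)
    }
  }
})

test_that("ambiguous profiles are reported, not forced", {
  tel <- region_loci("telomeric")
  cat_r <- make_catalog(
    kir_haplotype("hA", "telomeric", "KIR2DL4"),
    kir_haplotype("hB", "telomeric", "KIR3DL2"),
    kir_haplotype("hAB", "telomeric", c("KIR2DL4", "KIR3DL2")),
    kir_haplotype("h0", "telomeric", character(0)))
  prof <- data.frame(individual = "amb", t(zero_profile()),
                     check.names = FALSE)
  prof$KIR2DL4 <- 1L; prof$KIR3DL2 <- 1L
  res <- resolve_cohort(prof, cat_r)
  r <- res$telomeric$resolution
  expect_equal(r$status, "ambiguous")
  expect_equal(r$n_candidates, 2L)
  expect_equal(attr(res$telomeric$freq_table, "undetermined_fraction"), 1)
})

test_that("copy-number and co-deletion summaries count correctly", {
  prof <- default_cohort()$profiles
  cns <- copy_number_summary(prof)
  for (g in region_loci("full")) {
    expect_equal(sum(cns$count[cns$gene == g]), nrow(prof))
  }
  all2 <- prof
  for (g in region_loci("full")) all2[[g]] <- 2L
  cns2 <- copy_number_summary(all2)
  expect_true(all(cns2$percent[cns2$copies == 2] == 100))
  expect_true(all(cns2$percent[cns2$copies != 2] == 0))
})

test_that("full haplotypes are phased through homozygosity and couplings", {
  cfg <- load_sim_config()
  cfg$n_individuals <- 300
  coh <- simulate_cohort(cfg, seed = 55)
  res <- resolve_cohort(coh$profiles, coh$catalog)
  th <- coh$truth$haplotypes
  full_truth <- cbind(paste0(th$cen1, "~", th$tel1),
                      paste0(th$cen2, "~", th$tel2))
  done <- !is.na(res$full$full1)
  expect_gt(mean(done), 0.5)  # most individuals are homozygous in a region
  for (i in which(done)) {
    expect_setequal(c(res$full$full1[i], res$full$full2[i]), full_truth[i, ])
  }
})
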