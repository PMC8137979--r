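test_that("exact matches, recombinants and novel SNVs are distinguished", {
  db <- tiny_db()
  # known: identical to 00301
  obs <- c(`10` = "A", `20` = "T", `30` = "C", `40` = "T")
  cl <- classify_allele(obs, db, "KIR2DL4")
  expect_equal(cl$status, "known")
  expect_equal(cl$matched_allele, "KIR2DL4*00301")

  # recombinant: 00201's site-10 state combined with 00301's site-20 state
  obs <- c(`10` = "G", `20` = "T", `30` = "G", `40` = "T")
  cl <- classify_allele(obs, db, "KIR2DL4")
  expect_equal(cl$status, "recombinant")
  expect_null(cl$novel_sites)

  # novel SNV: a state never seen at site 40
  obs <- c(`10` = "A", `20` = "C", `30` = "G", `40` = "C")
  cl <- classify_allele(obs, db, "KIR2DL4")
  expect_equal(cl$status, "novel_snv")
  expect_equal(cl$novel_sites$position, 40)
  expect_equal(cl$novel_sites$base, "C")
  expect_equal(cl$nearest_allele, "KIR2DL4*00101")

  # missing a database position is an input error naming it
  expect_error(classify_allele(c(`10` = "A", `20` = "C", `30` = "G"),
                               db, "KIR2DL4"), "position\\(s\\): 40")
})

test_that("every vector receives exactly one status (brute-force scan)", {
  db <- tiny_db()
  m <- db$KIR2DL4$sites
  seen <- apply(m, 2, unique, simplify = FALSE)
  known_keys <- apply(m, 1, paste, collapse = "")
  bases <- c("A", "C", "G", "T")
  set.seed(3)
  for (trial in 1:200) {
    obs <- setNames(sample(bases, ncol(m), replace = TRUE), colnames(m))
    cl <- classify_allele(obs, db, "KIR2DL4")
    key <- paste(obs, collapse = "")
    any_unseen <- any(vapply(seq_along(obs),
                             function(j) !obs[j] %in% seen[[j]], TRUE))
    expected <- if (key %in% known_keys) "known"
    else if (any_unseen) "novel_snv" else "recombinant"
    expect_equal(cl$status, expected)
  }
})

test_that("nearest allele minimizes Hamming distance with name-order ties", {
  db <- tiny_db()
  # one mismatch to 00201, two or more to the others
  obs <- c(`10` = "G", `20` = "C", `30` = "T", `40` = "T")
  cl <- classify_allele(obs, db, "KIR2DL4")
  expect_equal(cl$nearest_allele, "KIR2DL4*00201")
  # 00101 and 00201 differ only at site 10; an unseen state there is
  # equidistant from both and the name order picks 00101
  obs <- c(`10` = "T", `20` = "C", `30` = "G", `40` = "T")
  cl <- classify_allele(obs, db, "KIR2DL4")
  expect_equal(cl$status, "novel_snv")
  expect_equal(cl$nearest_allele, "KIR2DL4*00101")
})

test_that("variant annotation reproduces exon, mature position and Grantham", {
  db <- load_allele_db()
  model <- db$KIR2DL1$model

  # the exon-5 C>G at the codon mapping to mature position 151: Pro>Arg, 103
  a <- annotate_variant(model, 515, "G")
  expect_equal(a$exon, 5)
  expect_equal(a$mature_protein, "151")
  expect_equal(a$aa_change, "Pro>Arg")
  expect_equal(a$grantham, 103)
  expect_false(a$synonymous)

  # a signal-peptide variant: codon 1 A>G is Met>Val (Grantham 21)
  a <- annotate_variant(model, 1, "G")
  expect_equal(a$exon, 1)
  expect_equal(a$mature_protein, "signal peptide")
  expect_equal(a$aa_change, "Met>Val")
  expect_equal(a$grantham, 21)

  # signal-peptide T>G at codon 10: Cys>Gly (Grantham 159)
  a <- annotate_variant(model, 28, "G")
  expect_equal(a$mature_protein, "signal peptide")
  expect_equal(a$aa_change, "Cys>Gly")
  expect_equal(a$grantham, 159)

  # third-position change preserving the amino acid is synonymous, no score
  a <- annotate_variant(model, 534, "T")
  expect_equal(a$mature_protein, "157")
  expect_true(a$synonymous)
  expect_equal(a$aa_change, "synonymous")
  expect_true(is.na(a$grantham))

  # KIR3DL1S1 exon-3 G>T at mature position 12: Ala>Ser (99)
  a <- annotate_variant(db$KIR3DL1S1$model, 88, "T")
  expect_equal(a$exon, 3)
  expect_equal(a$mature_protein, "12")
  expect_equal(a$aa_change, "Ala>Ser")
  expect_equal(a$grantham, 99)

  expect_error(annotate_variant(model, 99999, "A"), "outside the CDS")
  expect_error(annotate_variant(model, 515, "C"), "equals the reference")
})

test_that("re-translating the mutated CDS reproduces the alternate residue", {
  db <- load_allele_db()
  model <- db$KIR2DL1$model
  set.seed(5)
  for (trial in 1:25) {
    pos <- sample(nchar(model$cds), 1)
    ref <- substr(model$cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    a <- annotate_variant(model, pos, alt)
    mutated <- model$cds
    substr(mutated, pos, pos) <- alt
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(mutated), no.init.codon = TRUE))
    expect_equal(substr(prot, a$codon, a$codon), a$aa_alt)
  }
})

test_that("carrier summaries follow the individuals-once-per-locus convention", {
  cls <- data.frame(
    individual = c(sprintf("i%03d", 1:154), sprintf("i%03d", 1:57), "i001",
                   "i900"),
    gene = c(rep("KIR3DL1S1", 154), rep("KIR3DL2", 57), "KIR3DL1S1",
             "KIR2DL4"),
    status = c(rep("recombinant", 154), rep("novel_snv", 57),
               "novel_snv",  # second flagged copy of i001 at the same locus
               "known"))
  out <- novel_carrier_summary(cls, 2130)
  expect_equal(out$gene, c("KIR3DL1S1", "KIR3DL2"))
  expect_equal(out$n, c(154L, 57L))
  expect_equal(out$f_percent, c(7.23, 2.68))
  # no non-known calls: empty table
  expect_equal(nrow(novel_carrier_summary(
    data.frame(individual = "a", gene = "KIR2DL4", status = "known"), 10)), 0)
})

test_that("injected variants are recovered perfectly on noise-free cohorts", {
  cfg <- load_sim_config()
  cfg$n_individuals <- 250
  cfg$novel_injection[[1]]$count <- 17
  cfg$novel_injection[[2]]$count <- 3
  cfg$novel_injection[[3]]$count <- 2
  coh <- simulate_cohort(cfg, seed = 21)
  db <- load_allele_db()
  coh <- inject_novel_variants(coh, db)
  cls <- classify_cohort(coh$site_vectors, db)
  truth <- coh$truth$novel
  m <- merge(cls, truth, by = c("individual", "gene", "copy"), all.x = TRUE)
  m$classification[is.na(m$classification)] <- "known"
  # sensitivity and specificity both 100%
  expect_equal(m$status, m$classification)
  expect_equal(sum(m$status == "recombinant"), 17)
  expect_equal(sum(m$status == "novel_snv"), 5)
})
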