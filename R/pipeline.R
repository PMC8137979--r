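# End-to-end driver: simulate (or load) a cohort, resolve gene-content
# haplotypes, estimate allelic haplotypes, compute LD, classify novel
# variants, and write the report bundle plus a run manifest that makes
# every output reproducible.

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate the cohort (or read `input_dir`), write the
#' cohort files, resolve copy-number profiles into gene-content haplotype
#' pairs (regional frequency tables with undetermined fractions, copy-number
#' summary), estimate allelic haplotype frequencies per region by EM
#' (top-20 reports), compute pairwise LD over the configured locus pairs
#' with permutation p-values, classify observed site vectors against the
#' allele database (classification table, carrier summary, and annotation
#' of novel SNV sites), and write a YAML run manifest of every effective
#' option. Identical config and seed give byte-identical outputs.
#'
#' @param config A `kir_sim_config`, a path to one, or `NULL` for the
#'   packaged default.
#' @param outdir Output directory.
#' @param seed Master seed (overrides the config seed).
#' @param catalog A `kir_catalog` (default packaged).
#' @param db A `kir_allele_db` (default packaged synthetic).
#' @param em_loci Named list with `centromeric` and `telomeric` locus
#'   vectors for the allelic EM (defaults: the loci each region's common
#'   haplotypes vary at).
#' @param options List of stage options: `ratio_threshold`, `top_k`,
#'   `ld_pairs` (list of locus pairs), `n_perm`, `p_max`, `r2_min`,
#'   `dprime_min`, `em_restarts`.
#' @return Invisible list with every stage result and `files` (named vector
#'   of written paths).
#' @export
run_pipeline <- function(config = NULL, outdir, seed = 1,
                         catalog = load_haplotype_catalog(),
                         db = load_allele_db(),
                         em_loci = list(
                           centromeric = c("KIR3DL3", "KIR2DL23", "KIR2DL1"),
                           telomeric = c("KIR2DL4", "KIR3DL1S1", "KIR3DL2")),
                         options = list()) {
  opts <- utils::modifyList(
    list(ratio_threshold = 0.95, top_k = 20,
         ld_pairs = list(c("KIR2DL4", "KIR3DL1S1"),
                         c("KIR2DL4", "KIR3DL2"),
                         c("KIR2DL1", "KIR2DS3")),
         n_perm = 199, p_max = 0.05, r2_min = 0.2, dprime_min = 0.7,
         em_restarts = 5),
    options)
  if (is.null(config)) config <- load_sim_config()
  if (is.character(config)) config <- load_sim_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(outdir, name)
    .write_tsv(df, p)
    files[[name]] <<- p
    p
  }

  # --- simulate -------------------------------------------------------
  cohort <- simulate_cohort(config, catalog, seed = seed)
  cohort <- inject_novel_variants(cohort, db)
  cohort_files <- write_cohort(cohort, file.path(outdir, "cohort"))
  message(sprintf("[simulate] %d individuals, %d genotype rows, %d injected copies",
                  nrow(cohort$profiles), nrow(cohort$genotypes),
                  nrow(cohort$truth$novel)))

  # --- structure ------------------------------------------------------
  res <- resolve_cohort(cohort$profiles, catalog,
                        ratio_threshold = opts$ratio_threshold)
  for (region in c("centromeric", "telomeric")) {
    ft <- res[[region]]$freq_table
    tab <- data.frame(haplotype = ft$haplotype, count = ft$count,
                      frequency = round(ft$frequency, 3))
    tab <- rbind(tab, data.frame(haplotype = "undetermined", count = NA,
                                 frequency = round(attr(ft, "undetermined_fraction"), 3)))
    put(tab, paste0("haplotype_freq_", region, ".tsv"))
    put(res[[region]]$resolution, paste0("resolution_", region, ".tsv"))
    message(sprintf("[structure] %s: %d/%d resolved, undetermined fraction %.3f",
                    region, sum(res[[region]]$resolution$status == "resolved"),
                    nrow(cohort$profiles), attr(ft, "undetermined_fraction")))
  }
  put(copy_number_summary(cohort$profiles), "copy_number_summary.tsv")

  # --- phase ----------------------------------------------------------
  em_tables <- list()
  for (region in names(em_loci)) {
    tab <- em_haplotype_frequencies(cohort$genotypes, em_loci[[region]],
                                    restarts = opts$em_restarts, seed = seed)
    em_tables[[region]] <- tab
    rep_tab <- haplotype_report(tab, top_k = opts$top_k)
    rep_tab$frequency <- round(rep_tab$frequency, 3)
    put(rep_tab, paste0("allelic_haplotypes_", region, ".tsv"))
    message(sprintf("[phase] %s: logL %.2f after %d iterations (%d excluded)",
                    region, attr(tab, "loglik"), attr(tab, "n_iter"),
                    attr(tab, "n_excluded")))
  }

  # --- ld -------------------------------------------------------------
  ld_all <- list()
  for (pair in opts$ld_pairs) {
    joint <- two_locus_frequencies(cohort$genotypes, pair[1], pair[2],
                                   restarts = 1, seed = seed)
    rec <- ld_from_frequencies(joint)
    if (opts$n_perm > 0) {
      pv <- permutation_pvalue(cohort$genotypes, pair[1], pair[2],
                               n_perm = opts$n_perm, seed = seed)
      rec$p_value <- pv$p_value
    }
    ld_all[[paste(pair, collapse = "~")]] <- rec
  }
  ld_tab <- do.call(rbind, ld_all)
  rownames(ld_tab) <- NULL
  put(ld_tab, "ld_records.tsv")
  strong <- filter_ld(ld_tab, r2_min = opts$r2_min,
                      dprime_min = opts$dprime_min,
                      p_max = if (opts$n_perm > 0) opts$p_max else NA)
  put(strong, "ld_strong.tsv")
  message(sprintf("[ld] %d locus pairs, %d allele pairs, %d strong",
                  length(opts$ld_pairs), nrow(ld_tab), nrow(strong)))

  # --- novel ----------------------------------------------------------
  cls <- classify_cohort(cohort$site_vectors, db)
  put(cls, "classifications.tsv")
  carriers <- novel_carrier_summary(cls, nrow(cohort$profiles))
  put(carriers, "novel_carriers.tsv")
  snv <- cls[cls$status == "novel_snv" & cls$novel_sites != "", ]
  ann <- list()
  seen <- character(0)
  for (r in seq_len(nrow(snv))) {
    for (tok in strsplit(snv$novel_sites[r], ";")[[1]]) {
      keyv <- paste(snv$gene[r], tok)
      if (keyv %in% seen) next
      seen <- c(seen, keyv)
      pos_base <- strsplit(tok, ">")[[1]]
      model <- db[[snv$gene[r]]]$model
      if (!is.null(model)) {
        a <- annotate_variant(model, as.integer(pos_base[1]), pos_base[2])
        a$n <- sum(snv$gene == snv$gene[r] & grepl(tok, snv$novel_sites,
                                                   fixed = TRUE))
        ann[[keyv]] <- a
      }
    }
  }
  ann_tab <- if (length(ann)) do.call(rbind, ann) else
    annotate_empty()
  rownames(ann_tab) <- NULL
  put(ann_tab, "novel_annotations.tsv")
  message(sprintf("[novel] %d calls non-known, %d loci with carriers, db %s",
                  sum(cls$status != "known"), nrow(carriers),
                  attr(cls, "db_version")))

  # --- manifest -------------------------------------------------------
  manifest <- list(
    seed = seed,
    n_individuals = config$n_individuals,
    db_version = attr(db, "version"),
    options = opts[c("ratio_threshold", "top_k", "n_perm", "p_max",
                     "r2_min", "dprime_min", "em_restarts")],
    em_loci = em_loci,
    ld_pairs = lapply(opts$ld_pairs, as.list),
    # paths relative to the output directory, so re-runs into different
    # directories produce identical manifests
    files = as.list(c(stats::setNames(names(files), names(files)),
                      stats::setNames(file.path("cohort",
                                                basename(cohort_files)),
                                      names(cohort_files)))),
    rounding = list(haplotype_frequency = 3, carrier_percent = 2,
                    copy_number_percent = 1)
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  files[["manifest.yaml"]] <- file.path(outdir, "manifest.yaml")

  invisible(list(cohort = cohort, resolution = res, em = em_tables,
                 ld = ld_tab, ld_strong = strong, classifications = cls,
                 carriers = carriers, annotations = ann_tab,
                 files = c(files, cohort_files)))
}

annotate_empty <- function() {
  data.frame(gene = character(0), position = integer(0), ref = character(0),
             alt = character(0), exon = integer(0), codon = integer(0),
             mature_protein = character(0), aa_ref = character(0),
             aa_alt = character(0), change = character(0),
             aa_change = character(0), synonymous = logical(0),
             grantham = integer(0), rsid = character(0), n = integer(0),
             stringsAsFactors = FALSE)
}
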