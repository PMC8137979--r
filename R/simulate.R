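# Synthetic cohort generator. Samples full haplotypes as (centromeric,
# telomeric) pairs -- never independently -- so phase couplings (cB04~tB03,
# cA03~tB02) and haplotype-restricted alleles are representable; assigns
# alleles per gene copy from haplotype-conditional tables; supports exact
# carrier counts and seeded novel-variant injection with truth labels.

#' Load a cohort simulation configuration
#'
#' Reads a YAML simulation config with fields `n_individuals`, `seed`,
#' `haplotype_pairs` (list of `{cen, tel, frequency}`), `allele_tables`
#' (per haplotype name, per gene: either one map allele -> probability
#' applied independently to every copy, or a list of such maps, one per
#' copy), `deterministic_counts` (map of haplotype name, or `"cen~tel"`
#' pair name, to exact carrier count) and `novel_injection` (list of
#' `{gene, kind, base_allele, edits: {position: base}, count}` entries).
#' The packaged default emulates a European-descent cohort: 2,130
#' individuals, cA01~tA01 at frequency 0.58, the cB04~tB03 and cA03~tB02
#' phase couplings, the new1/new2 insertion haplotypes, and
#' haplotype-restricted alleles such as KIR2DL4*00501 on 99.4% of tB01 and
#' KIR3DL2*00701 only on tB01.
#'
#' @param path YAML path, or `NULL` for the packaged default.
#' @return A list of class `kir_sim_config` (validated).
#' @export
load_sim_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "kir_sim_default.yaml",
                        package = "kirpop", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg A config list (see [load_sim_config()]).
#' @return The config, classed `kir_sim_config`; errors describe the
#'   offending entry.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$n_individuals), cfg$n_individuals >= 0)
  freqs <- vapply(cfg$haplotype_pairs, function(p) as.numeric(p$frequency), 0)
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("haplotype pair frequencies sum to ", sum(freqs), ", not 1",
         call. = FALSE)
  }
  for (hap in names(cfg$allele_tables)) {
    for (gene in names(cfg$allele_tables[[hap]])) {
      .check_genes(gene, where = sprintf("allele table '%s'", hap))
      entry <- cfg$allele_tables[[hap]][[gene]]
      dists <- if (.is_percopy(entry)) entry else list(entry)
      for (d in dists) {
        s <- sum(unlist(d))
        if (abs(s - 1) > 1e-9) {
          stop(sprintf("allele probabilities for (%s, %s) sum to %g, not 1",
                       hap, gene, s), call. = FALSE)
        }
      }
    }
  }
  if (!is.null(cfg$deterministic_counts)) {
    total <- sum(unlist(cfg$deterministic_counts))
    if (total > cfg$n_individuals) {
      stop("deterministic counts exceed n_individuals", call. = FALSE)
    }
  }
  structure(cfg, class = c("kir_sim_config", "list"))
}

.is_percopy <- function(entry) {
  is.list(entry) && length(entry) > 0 && is.null(names(entry))
}

# Derive independent sub-seeds for the named RNG streams from the master
# seed, so any stage can be re-run in isolation.
.stream_seeds <- function(seed) {
  set.seed(seed %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, 3L)
  list(haplotype = s[1], allele = s[2], injection = s[3])
}

# Does deterministic-count key match a (cen, tel) pair?
.key_matches <- function(key, cen, tel) {
  key == cen | key == tel | key == paste0(cen, "~", tel)
}

#' Simulate a cohort of KIR genotypes with truth labels
#'
#' Draws two full haplotypes per individual from the configured
#' (centromeric, telomeric) pair table, assigns alleles per gene copy from
#' the haplotype-conditional allele tables, and emits copy-number profiles,
#' an unphased long genotype table, and truth records. Entries in
#' `deterministic_counts` fix the exact number of carriers of a haplotype
#' (or full pair): carriers are the first k individuals after a seeded
#' shuffle, drawn from the pair table conditioned on carrying the target,
#' with their second chromosome (and everyone else) conditioned on not
#' carrying it. Fully reproducible from the seed; haplotype sampling,
#' allele sampling and injection use independent derived RNG streams.
#'
#' @param config A `kir_sim_config` (or a list; validated on entry).
#' @param catalog A `kir_catalog`; defaults to the packaged catalog.
#' @param seed Optional override of `config$seed`.
#' @return List of class `kir_cohort`: `profiles` (wide copy-number
#'   data.frame), `genotypes` (long data.frame `individual`, `gene`,
#'   `allele`), `truth` (list: `haplotypes` data.frame with the two full
#'   haplotypes per individual; `phased` long data.frame `individual`,
#'   `chrom`, `region_hap`, `gene`, `copy`, `allele`; `novel` empty
#'   data.frame until [inject_novel_variants()]), `config`, `catalog`.
#' @export
simulate_cohort <- function(config, catalog = load_haplotype_catalog(),
                            seed = NULL) {
  cfg <- validate_sim_config(config)
  n <- as.integer(cfg$n_individuals)
  if (is.null(seed)) seed <- cfg$seed %||% 1
  streams <- .stream_seeds(seed)

  pairs <- data.frame(
    cen = vapply(cfg$haplotype_pairs, `[[`, "", "cen"),
    tel = vapply(cfg$haplotype_pairs, `[[`, "", "tel"),
    freq = vapply(cfg$haplotype_pairs, function(p) as.numeric(p$frequency), 0),
    stringsAsFactors = FALSE)
  for (h in unique(c(pairs$cen, pairs$tel))) {
    if (!h %in% names(catalog)) {
      stop("haplotype '", h, "' in config is not in the catalog", call. = FALSE)
    }
  }

  ids <- sprintf("ind%05d", seq_len(n))
  chrom1 <- integer(n); chrom2 <- integer(n)

  set.seed(streams$haplotype)
  det <- cfg$deterministic_counts
  if (!is.null(det) && length(det) > 0 && n > 0) {
    shuffled <- sample.int(n)
    pos <- 1L
    carried <- rep(NA_character_, n)
    for (key in names(det)) {
      k <- as.integer(det[[key]])
      hit <- .key_matches(key, pairs$cen, pairs$tel)
      if (!any(hit)) stop("deterministic count names unknown haplotype: ",
                          key, call. = FALSE)
      block <- shuffled[seq.int(pos, length.out = k)]
      pos <- pos + k
      carried[block] <- key
    }
    all_keys <- names(det)
    none <- !Reduce(`|`, lapply(all_keys, .key_matches,
                                cen = pairs$cen, tel = pairs$tel))
    if (!any(none)) stop("deterministic counts leave no background pairs",
                         call. = FALSE)
    for (i in seq_len(n)) {
      if (is.na(carried[i])) {
        chrom1[i] <- sample.int(nrow(pairs), 1, prob = pairs$freq * none)
        chrom2[i] <- sample.int(nrow(pairs), 1, prob = pairs$freq * none)
      } else {
        hit <- .key_matches(carried[i], pairs$cen, pairs$tel)
        chrom1[i] <- sample.int(nrow(pairs), 1, prob = pairs$freq * hit)
        chrom2[i] <- sample.int(nrow(pairs), 1, prob = pairs$freq * none)
      }
    }
  } else if (n > 0) {
    chrom1 <- sample.int(nrow(pairs), n, replace = TRUE, prob = pairs$freq)
    chrom2 <- sample.int(nrow(pairs), n, replace = TRUE, prob = pairs$freq)
  }

  loci <- region_loci("full")
  hap_content <- function(cen, tel) {
    catalog[[cen]]$content + catalog[[tel]]$content
  }
  prof_mat <- matrix(0L, n, length(loci), dimnames = list(NULL, loci))
  for (i in seq_len(n)) {
    prof_mat[i, ] <- hap_content(pairs$cen[chrom1[i]], pairs$tel[chrom1[i]]) +
      hap_content(pairs$cen[chrom2[i]], pairs$tel[chrom2[i]])
  }
  profiles <- data.frame(individual = ids, prof_mat, check.names = FALSE,
                         stringsAsFactors = FALSE)

  # allele assignment per chromosome, per region haplotype, per gene copy
  set.seed(streams$allele)
  draw_allele <- function(dist) {
    alleles <- names(dist)
    p <- unlist(dist)
    alleles[sample.int(length(alleles), 1, prob = p)]
  }
  cap <- max(1L, 2L * n * length(loci))
  p_ind <- character(cap); p_chrom <- integer(cap); p_hap <- character(cap)
  p_gene <- character(cap); p_copy <- integer(cap); p_allele <- character(cap)
  pk <- 0L
  for (i in seq_len(n)) {
    for (ch in 1:2) {
      pair_idx <- if (ch == 1) chrom1[i] else chrom2[i]
      for (reg_hap in c(pairs$cen[pair_idx], pairs$tel[pair_idx])) {
        content <- catalog[[reg_hap]]$content
        genes <- names(content)[content > 0]
        for (g in genes) {
          tabs <- cfg$allele_tables[[reg_hap]][[g]]
          if (is.null(tabs)) {
            stop(sprintf("no allele table for haplotype '%s', gene %s",
                         reg_hap, g), call. = FALSE)
          }
          k <- content[[g]]
          dists <- if (.is_percopy(tabs)) tabs else rep(list(tabs), k)
          if (length(dists) != k) {
            stop(sprintf("allele table for (%s, %s) has %d per-copy entries, need %d",
                         reg_hap, g, length(dists), k), call. = FALSE)
          }
          for (cp in seq_len(k)) {
            pk <- pk + 1L
            p_ind[pk] <- ids[i]; p_chrom[pk] <- ch; p_hap[pk] <- reg_hap
            p_gene[pk] <- g; p_copy[pk] <- cp
            p_allele[pk] <- draw_allele(dists[[cp]])
          }
        }
      }
    }
  }
  sel <- seq_len(pk)
  phased <- data.frame(individual = p_ind[sel], chrom = p_chrom[sel],
                       region_hap = p_hap[sel], gene = p_gene[sel],
                       copy = p_copy[sel], allele = p_allele[sel],
                       stringsAsFactors = FALSE)

  genotypes <- phased[order(match(phased$individual, ids),
                            match(phased$gene, loci), phased$chrom,
                            phased$copy),
                      c("individual", "gene", "allele")]
  rownames(genotypes) <- NULL

  truth_haps <- data.frame(
    individual = ids,
    cen1 = pairs$cen[chrom1], tel1 = pairs$tel[chrom1],
    cen2 = pairs$cen[chrom2], tel2 = pairs$tel[chrom2],
    stringsAsFactors = FALSE)

  structure(list(profiles = profiles, genotypes = genotypes,
                 truth = list(haplotypes = truth_haps, phased = phased,
                              novel = .empty_novel_truth()),
                 config = cfg, catalog = catalog, seed = seed),
            class = "kir_cohort")
}

.empty_novel_truth <- function() {
  data.frame(individual = character(0), gene = character(0),
             copy = integer(0), classification = character(0),
             base_allele = character(0), edits = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.kir_cohort <- function(x, ...) {
  cat(sprintf("<kir_cohort> %d individuals, %d genotype rows, %d injected novel copies\n",
              nrow(x$profiles), nrow(x$genotypes), nrow(x$truth$novel)))
  invisible(x)
}

#' Inject novel variants into a simulated cohort
#'
#' Emits, for every (individual, gene, copy) whose gene is in the allele
#' database, the observed variable-site vector: the database vector of the
#' assigned allele, except for injected copies, which carry an edited
#' vector. Each injection entry names a `gene`, a `kind` (`"recombinant"`:
#' the edited vector must match no database allele while every site state
#' is individually known; `"snv"`: at least one edited site carries a state
#' unseen at that site), a `base_allele`, `edits` (map position -> base)
#' and either `count` (exact number of carrier individuals) or `rate`.
#' Carriers are drawn (seeded) among individuals carrying the gene that are
#' not already injected at it; one gene copy per carrier is edited.
#'
#' @param cohort A `kir_cohort` from [simulate_cohort()].
#' @param db A `kir_allele_db`.
#' @param injections List of injection entries (default: the cohort
#'   config's `novel_injection`).
#' @param seed Seed for carrier selection (default: the cohort's injection
#'   stream).
#' @return The cohort with `site_vectors` (long data.frame `individual`,
#'   `gene`, `copy`, `position`, `base`) and updated `truth$novel`.
#' @export
inject_novel_variants <- function(cohort, db, injections = NULL, seed = NULL) {
  if (is.null(injections)) injections <- cohort$config$novel_injection
  if (is.null(seed)) seed <- .stream_seeds(cohort$seed)$injection
  phased <- cohort$truth$phased
  copies <- phased[phased$gene %in% names(db), , drop = FALSE]
  # per-individual running copy index (chromosomes concatenated)
  if (nrow(copies) > 0) {
    o <- order(copies$individual, copies$gene, copies$chrom, copies$copy)
    copies <- copies[o, ]
    key <- paste(copies$individual, copies$gene, sep = "\r")
    copies$copy_all <- stats::ave(seq_len(nrow(copies)), key,
                                  FUN = seq_along)
  } else {
    copies$copy_all <- integer(0)
  }

  vec_of <- function(gene, allele) {
    m <- db[[gene]]$sites
    if (!allele %in% rownames(m)) {
      stop("allele ", allele, " assigned in the cohort is not in the database for ",
           gene, call. = FALSE)
    }
    m[allele, ]
  }

  sv <- list()
  for (g in intersect(names(db), unique(copies$gene))) {
    sub <- copies[copies$gene == g, , drop = FALSE]
    m <- db[[g]]$sites
    bad <- setdiff(unique(sub$allele), rownames(m))
    if (length(bad) > 0) {
      stop("allele(s) assigned in the cohort are not in the database for ",
           g, ": ", paste(bad, collapse = ", "), call. = FALSE)
    }
    npos <- ncol(m)
    bases <- m[sub$allele, , drop = FALSE]
    sv[[g]] <- data.frame(
      individual = rep(sub$individual, each = npos),
      gene = g,
      copy = rep(sub$copy_all, each = npos),
      position = rep(as.integer(colnames(m)), times = nrow(sub)),
      base = as.vector(t(bases)),
      stringsAsFactors = FALSE)
  }
  site_vectors <- if (length(sv)) do.call(rbind, sv) else
    data.frame(individual = character(0), gene = character(0),
               copy = integer(0), position = integer(0), base = character(0))
  rownames(site_vectors) <- NULL

  novel_truth <- cohort$truth$novel
  set.seed(seed %% .Machine$integer.max)
  for (entry in injections) {
    gene <- entry$gene
    kind <- match.arg(entry$kind, c("recombinant", "snv"))
    if (!gene %in% names(db)) {
      stop("injection names gene absent from database: ", gene, call. = FALSE)
    }
    base_vec <- vec_of(gene, entry$base_allele)
    edited <- base_vec
    for (pos in names(entry$edits)) {
      if (!pos %in% names(edited)) {
        stop("injection edit at position ", pos,
             " outside the site domain of ", gene, call. = FALSE)
      }
      edited[pos] <- entry$edits[[pos]]
    }
    cl <- classify_allele(edited, db, gene)
    want <- if (kind == "snv") "novel_snv" else "recombinant"
    if (cl$status != want) {
      stop(sprintf("injection for %s requested kind '%s' but the edited vector classifies as '%s'%s",
                   gene, kind, cl$status,
                   if (cl$status == "known")
                     paste0(" (collides with ", cl$matched_allele, ")") else ""),
           call. = FALSE)
    }
    eligible <- unique(copies$individual[copies$gene == gene])
    already <- unique(novel_truth$individual[novel_truth$gene == gene])
    eligible <- setdiff(eligible, already)
    k <- if (!is.null(entry$count)) as.integer(entry$count) else
      stats::rbinom(1, length(eligible), entry$rate)
    if (k > length(eligible)) {
      stop(sprintf("injection for %s asks for %d carriers but only %d eligible individuals",
                   gene, k, length(eligible)), call. = FALSE)
    }
    carriers <- sample(eligible, k)
    for (id in carriers) {
      rows <- which(copies$individual == id & copies$gene == gene)
      pick <- copies$copy_all[rows[sample.int(length(rows), 1)]]
      sel <- site_vectors$individual == id & site_vectors$gene == gene &
        site_vectors$copy == pick
      site_vectors$base[sel] <-
        unname(edited[as.character(site_vectors$position[sel])])
      novel_truth <- rbind(novel_truth, data.frame(
        individual = id, gene = gene, copy = pick,
        classification = want, base_allele = entry$base_allele,
        edits = paste(names(entry$edits), unlist(entry$edits), sep = ">",
                      collapse = ";"),
        stringsAsFactors = FALSE))
    }
  }
  cohort$site_vectors <- site_vectors
  cohort$truth$novel <- novel_truth
  cohort
}
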