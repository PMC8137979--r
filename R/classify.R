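# Classification of observed per-copy variable-site vectors against the
# allele database, and annotation of single-nucleotide changes to
# exon/codon/mature-protein coordinates with Grantham scoring.

#' Classify an observed variable-site vector
#'
#' An observed vector is `known` when it matches a database allele exactly;
#' `novel_snv` when at least one site carries a state never observed at that
#' site in any database allele of the gene; and `recombinant` when it
#' matches no allele although every site state is individually known (a new
#' phasing combination of known variable sites). The nearest allele is the
#' database allele at minimum Hamming distance, ties broken by allele-name
#' order.
#'
#' @param observed Named character vector: names are aligned CDS positions,
#'   values bases. The position domain must equal the gene's database
#'   domain.
#' @param db A `kir_allele_db`.
#' @param gene Locus name (must be present in `db`).
#' @return List of class `kir_classification` with fields `gene`, `status`
#'   (`"known"`, `"recombinant"`, `"novel_snv"`), `matched_allele` (known
#'   only), `nearest_allele`, `differing_sites` (positions), `novel_sites`
#'   (data.frame position/base, novel_snv only).
#' @export
classify_allele <- function(observed, db, gene) {
  if (!gene %in% names(db)) stop("no database entry for gene ", gene, call. = FALSE)
  m <- db[[gene]]$sites
  if (nrow(m) == 0) stop("empty database for gene ", gene, call. = FALSE)
  dom <- colnames(m)
  obs <- observed[dom]
  missing <- dom[is.na(obs)]
  if (length(missing) > 0) {
    stop("observed vector for ", gene, " is missing database position(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  obs <- as.character(obs)

  hits <- which(colSums(t(m) != obs) == 0)
  if (length(hits) == 1) {
    return(structure(list(gene = gene, status = "known",
                          matched_allele = rownames(m)[hits],
                          nearest_allele = rownames(m)[hits],
                          differing_sites = integer(0),
                          novel_sites = NULL),
                     class = "kir_classification"))
  }
  unseen <- vapply(seq_along(dom), function(j) !obs[j] %in% m[, j], TRUE)
  dists <- rowSums(t(t(m) != obs))
  ord <- order(dists, rownames(m))
  nearest <- rownames(m)[ord[1]]
  differing <- as.integer(dom[m[nearest, ] != obs])
  status <- if (any(unseen)) "novel_snv" else "recombinant"
  novel_sites <- if (any(unseen)) {
    data.frame(position = as.integer(dom[unseen]), base = obs[unseen],
               stringsAsFactors = FALSE)
  } else NULL
  structure(list(gene = gene, status = status, matched_allele = NA_character_,
                 nearest_allele = nearest, differing_sites = differing,
                 novel_sites = novel_sites),
            class = "kir_classification")
}

#' @export
print.kir_classification <- function(x, ...) {
  cat(sprintf("<kir_classification> %s: %s (nearest %s)\n",
              x$gene, x$status, x$nearest_allele))
  invisible(x)
}

#' Classify every observed vector of a cohort
#'
#' @param site_vectors Long table of observed site vectors: data.frame with
#'   columns `individual`, `gene`, `copy`, `position`, `base`.
#' @param db A `kir_allele_db`.
#' @return data.frame with one row per (individual, gene, copy): columns
#'   `individual`, `gene`, `copy`, `status`, `matched_allele`,
#'   `nearest_allele`, `n_differing`, `novel_sites` (";"-joined
#'   `pos>base`, empty for non-SNV), plus attribute `db_version`.
#' @export
classify_cohort <- function(site_vectors, db) {
  key <- paste(site_vectors$individual, site_vectors$gene,
               site_vectors$copy, sep = "\r")
  sv <- split(seq_len(nrow(site_vectors)), key)
  first <- vapply(sv, `[`, 0L, 1L)
  keys <- site_vectors[first, c("individual", "gene", "copy")]
  nk <- length(sv)
  status <- character(nk); matched <- character(nk); nearest <- character(nk)
  n_diff <- integer(nk); novel <- character(nk)
  for (k in seq_len(nk)) {
    rows <- sv[[k]]
    obs <- setNames(site_vectors$base[rows],
                    as.character(site_vectors$position[rows]))
    cl <- classify_allele(obs, db, keys$gene[k])
    status[k] <- cl$status
    matched[k] <- cl$matched_allele
    nearest[k] <- cl$nearest_allele
    n_diff[k] <- length(cl$differing_sites)
    novel[k] <- if (is.null(cl$novel_sites)) "" else
      paste(cl$novel_sites$position, cl$novel_sites$base, sep = ">",
            collapse = ";")
  }
  out <- data.frame(individual = keys$individual, gene = keys$gene,
                    copy = keys$copy, status = status,
                    matched_allele = matched, nearest_allele = nearest,
                    n_differing = n_diff, novel_sites = novel,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, db_version = attr(db, "version"))
}

#' Annotate a coding single-nucleotide change
#'
#' Maps a CDS position to exon, codon and mature-protein coordinates and
#' scores the amino-acid substitution on the Grantham scale. Mature-protein
#' numbering subtracts the gene's signal peptide length; changes inside the
#' signal peptide are tagged `"signal peptide"`.
#'
#' @param model A `kir_gene_model`.
#' @param position 1-based position on the spliced CDS.
#' @param alt Alternate base (must differ from the reference base).
#' @param rsid Optional dbSNP label, carried through untouched.
#' @return One-row data.frame with columns `gene`, `position`, `ref`,
#'   `alt`, `exon`, `codon`, `mature_protein` (character: mature position
#'   or `"signal peptide"`), `aa_ref`, `aa_alt`, `change` (e.g. `"C>G"`),
#'   `aa_change` (e.g. `"Pro>Arg"` or `"synonymous"`), `synonymous`,
#'   `grantham` (NA when synonymous), `rsid`.
#' @export
annotate_variant <- function(model, position, alt, rsid = NA_character_) {
  stopifnot(inherits(model, "kir_gene_model"))
  position <- as.integer(position)
  if (position < 1 || position > nchar(model$cds)) {
    stop("position ", position, " outside the CDS of ", model$gene,
         " (length ", nchar(model$cds), ")", call. = FALSE)
  }
  ref <- substr(model$cds, position, position)
  alt <- toupper(alt)
  if (alt == ref) stop("alt base equals the reference base at position ",
                       position, call. = FALSE)
  exon <- model$exons$exon[model$exons$start <= position &
                             model$exons$end >= position]
  codon_index <- ceiling(position / 3)
  codon_ref <- .codon_at(model, codon_index)
  offset <- position - 3 * (codon_index - 1)
  codon_alt <- codon_ref
  substr(codon_alt, offset, offset) <- alt
  aa_ref <- .translate_codon(codon_ref)
  aa_alt <- .translate_codon(codon_alt)
  syn <- aa_ref == aa_alt
  has_stop <- aa_ref == "*" || aa_alt == "*"
  mature_num <- codon_index - model$signal_peptide_length
  mature <- if (mature_num > 0) as.character(mature_num) else "signal peptide"
  .AA1TO3 <- setNames(names(.AA3TO1), unname(.AA3TO1))
  aa3 <- function(a) if (a %in% names(.AA1TO3)) .AA1TO3[[a]] else
    if (a == "*") "Ter" else a
  data.frame(gene = model$gene, position = position, ref = ref, alt = alt,
             exon = exon, codon = codon_index, mature_protein = mature,
             aa_ref = aa_ref, aa_alt = aa_alt,
             change = paste0(ref, ">", alt),
             aa_change = if (syn) "synonymous" else
               paste0(aa3(aa_ref), ">", aa3(aa_alt)),
             synonymous = syn,
             grantham = if (syn || has_stop) NA_integer_ else
               grantham_distance(aa_ref, aa_alt),
             rsid = rsid, stringsAsFactors = FALSE)
}

#' Per-locus summary of novel-allele carriers
#'
#' Counts, per locus, the individuals carrying at least one non-known
#' (recombinant or novel SNV) allele call; an individual counts once per
#' locus regardless of how many copies are flagged.
#'
#' @param classifications data.frame from [classify_cohort()] (columns
#'   `individual`, `gene`, `status`).
#' @param n_individuals Cohort size (denominator of the carrier frequency).
#' @return data.frame with columns `gene`, `n`, `f_percent` (carriers as a
#'   percentage of the cohort, 2 decimals), sorted by `n` descending; loci
#'   with no carriers are omitted.
#' @export
novel_carrier_summary <- function(classifications, n_individuals) {
  flagged <- classifications[classifications$status != "known", ]
  if (nrow(flagged) == 0) {
    return(data.frame(gene = character(0), n = integer(0),
                      f_percent = numeric(0), stringsAsFactors = FALSE))
  }
  carriers <- unique(flagged[, c("individual", "gene")])
  tab <- sort(table(carriers$gene), decreasing = TRUE)
  data.frame(gene = names(tab), n = as.integer(tab),
             f_percent = round(100 * as.integer(tab) / n_individuals, 2),
             stringsAsFactors = FALSE)
}
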