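# Allele database: per-gene variable-site matrices over aligned CDS
# positions, plus a CDS/exon gene model for annotation. "Novel" is always
# relative to a loaded database version, so the version string travels with
# the object and into every report.

#' Load an allele database
#'
#' Reads the three files that define an allele database: a variable-site
#' table (TSV with columns `gene`, `allele`, `position`, `base`; positions
#' are 1-based on the spliced CDS), a CDS FASTA (one record per gene, named
#' by gene), and an exon map (TSV with columns `gene`, `exon`, `start`,
#' `end`, `signal_peptide_length`; `start`/`end` are 1-based inclusive CDS
#' coordinates). Validates that every allele of a gene covers the same
#' position domain, that no two alleles of a gene share a site vector, that
#' exons tile the CDS, and that site positions fall inside the CDS.
#'
#' The packaged default (`kir_sites_synthetic.tsv` and friends) is a small
#' synthetic database for KIR2DL1 and KIR3DL1S1; it is a constructed
#' stand-in whose coordinates and exon layout mimic the real genes but whose
#' sequences are generated.
#'
#' @param site_table_path,cds_fasta_path,exon_map_path File paths, or all
#'   `NULL` for the packaged synthetic database.
#' @param version Version string recorded on the database (defaults to the
#'   site table file name).
#' @return An object of class `kir_allele_db`: a named list with one entry
#'   per gene, each a list with `sites` (character matrix, alleles x
#'   positions) and `model` (list with `cds`, `exons`,
#'   `signal_peptide_length`, or `NULL` if the gene has no model); plus a
#'   `version` attribute.
#' @export
load_allele_db <- function(site_table_path = NULL, cds_fasta_path = NULL,
                           exon_map_path = NULL, version = NULL) {
  if (is.null(site_table_path)) {
    site_table_path <- system.file("extdata", "kir_sites_synthetic.tsv",
                                   package = "kirpop", mustWork = TRUE)
    cds_fasta_path <- system.file("extdata", "kir_cds_synthetic.fasta",
                                  package = "kirpop", mustWork = TRUE)
    exon_map_path <- system.file("extdata", "kir_exons_synthetic.tsv",
                                 package = "kirpop", mustWork = TRUE)
  }
  if (is.null(version)) version <- basename(site_table_path)

  sites <- utils::read.delim(site_table_path, stringsAsFactors = FALSE)
  need <- c("gene", "allele", "position", "base")
  if (!all(need %in% names(sites))) {
    stop("site table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  .check_genes(unique(sites$gene), where = "site table")

  models <- list()
  if (!is.null(cds_fasta_path)) {
    cds_set <- Biostrings::readDNAStringSet(cds_fasta_path)
    names(cds_set) <- sub("\\s.*$", "", names(cds_set))
    exons <- utils::read.delim(exon_map_path, stringsAsFactors = FALSE)
    for (g in unique(exons$gene)) {
      if (!g %in% names(cds_set)) {
        stop("exon map references gene absent from CDS FASTA: ", g,
             call. = FALSE)
      }
      ex <- exons[exons$gene == g, ]
      ex <- ex[order(ex$exon), ]
      cds <- as.character(cds_set[[g]])
      models[[g]] <- kir_gene_model(
        gene = g, cds = cds,
        exons = ex[, c("exon", "start", "end")],
        signal_peptide_length = unique(ex$signal_peptide_length)
      )
    }
  }

  db <- list()
  for (g in unique(sites$gene)) {
    sg <- sites[sites$gene == g, ]
    positions <- sort(unique(sg$position))
    alleles <- unique(sg$allele)
    m <- matrix(NA_character_, nrow = length(alleles), ncol = length(positions),
                dimnames = list(alleles, as.character(positions)))
    m[cbind(match(sg$allele, alleles), match(sg$position, positions))] <- sg$base
    if (anyNA(m)) {
      miss <- which(is.na(m), arr.ind = TRUE)
      stop(sprintf(
        "gene %s: allele %s does not declare position %s (all alleles of a gene must share the site domain)",
        g, rownames(m)[miss[1, 1]], colnames(m)[miss[1, 2]]), call. = FALSE)
    }
    dup_rows <- duplicated(apply(m, 1, paste, collapse = "|"))
    if (any(dup_rows)) {
      key <- apply(m, 1, paste, collapse = "|")
      coll <- rownames(m)[key %in% key[dup_rows]]
      stop(sprintf("gene %s: alleles with identical site vectors: %s",
                   g, paste(coll, collapse = ", ")), call. = FALSE)
    }
    model <- models[[g]]
    if (!is.null(model)) {
      if (any(positions < 1 | positions > nchar(model$cds))) {
        stop(sprintf("gene %s: site position outside the CDS (length %d)",
                     g, nchar(model$cds)), call. = FALSE)
      }
    }
    db[[g]] <- list(sites = m, model = model)
  }
  structure(db, class = "kir_allele_db", version = version)
}

#' @export
print.kir_allele_db <- function(x, ...) {
  cat(sprintf("<kir_allele_db> version %s\n", attr(x, "version")))
  for (g in names(x)) {
    cat(sprintf("  %s: %d alleles over %d variable sites%s\n",
                g, nrow(x[[g]]$sites), ncol(x[[g]]$sites),
                if (is.null(x[[g]]$model)) "" else " (+ gene model)"))
  }
  invisible(x)
}

#' Construct a gene model
#'
#' @param gene Locus name.
#' @param cds Spliced coding sequence (character, length divisible by 3).
#' @param exons data.frame with columns `exon`, `start`, `end` (1-based
#'   inclusive CDS coordinates); exons must tile the CDS without gaps or
#'   overlap.
#' @param signal_peptide_length Signal peptide length in amino acids; mature
#'   protein numbering is codon index minus this value.
#' @return A list of class `kir_gene_model`.
#' @export
kir_gene_model <- function(gene, cds, exons, signal_peptide_length) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length for ", gene, " is not divisible by 3", call. = FALSE)
  }
  exons <- exons[order(exons$exon), ]
  expected_start <- c(1L, utils::head(exons$end, -1) + 1L)
  if (!all(exons$start == expected_start) ||
      exons$end[nrow(exons)] != nchar(cds)) {
    stop("exons for ", gene, " do not tile the CDS", call. = FALSE)
  }
  structure(list(gene = gene, cds = cds, exons = exons,
                 signal_peptide_length = as.integer(signal_peptide_length)),
            class = "kir_gene_model")
}

# Codon (character of length 3) at 1-based codon index.
.codon_at <- function(model, codon_index) {
  substr(model$cds, 3 * (codon_index - 1) + 1, 3 * codon_index)
}

.translate_codon <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

#' Write an allele database's site table
#'
#' Writes the variable-site table of a database back to TSV; reloading with
#' the same CDS/exon files reproduces identical site matrices.
#'
#' @param db A `kir_allele_db`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(db, path) {
  rows <- do.call(rbind, lapply(names(db), function(g) {
    m <- db[[g]]$sites
    data.frame(gene = g,
               allele = rep(rownames(m), times = ncol(m)),
               position = rep(as.integer(colnames(m)), each = nrow(m)),
               base = as.vector(m),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$gene, rows$allele, rows$position), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
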