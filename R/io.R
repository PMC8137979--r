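# Tabular I/O. One dialect throughout: tab-separated, UTF-8, header row,
# "." for missing. Parse errors report the offending line (1-based,
# counting the header).

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = ".", comment.char = "#")
}

.write_tsv <- function(df, path) {
  df[] <- lapply(df, function(col) {
    col[is.na(col)] <- "."
    col
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.require_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

#' Read / write a copy-number table
#'
#' Wide TSV: column `individual` plus one integer column per KIR locus
#' (all 15 required on read).
#'
#' @param path File path.
#' @return data.frame with `individual` and the 15 locus columns.
#' @export
read_copy_number_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("individual", region_loci("full")), path)
  if (anyDuplicated(df$individual)) {
    stop("duplicate individual ids in ", path, call. = FALSE)
  }
  for (g in region_loci("full")) {
    v <- suppressWarnings(as.numeric(df[[g]]))
    bad <- which(is.na(v) | (v %% 1 != 0) | (v < 0))
    if (length(bad) > 0) {
      stop(sprintf("%s: non-integer or negative copy number for %s at line %d",
                   path, g, bad[1] + 1L), call. = FALSE)
    }
    df[[g]] <- as.integer(v)
  }
  df[, c("individual", region_loci("full"))]
}

#' @rdname read_copy_number_table
#' @param profiles Copy-number data.frame.
#' @export
write_copy_number_table <- function(profiles, path) {
  .write_tsv(profiles, path)
}

#' Read / write a long genotype table
#'
#' Long TSV with columns `individual`, `gene`, `allele`; one row per gene
#' copy.
#'
#' @param path File path.
#' @return data.frame `individual`, `gene`, `allele`.
#' @export
read_genotype_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("individual", "gene", "allele"), path)
  bad <- which(!df$gene %in% region_loci("full"))
  if (length(bad) > 0) {
    stop(sprintf("%s: unknown gene '%s' at line %d", path, df$gene[bad[1]],
                 bad[1] + 1L), call. = FALSE)
  }
  df[, c("individual", "gene", "allele")]
}

#' @rdname read_genotype_table
#' @param genotypes Long genotype data.frame.
#' @export
write_genotype_table <- function(genotypes, path) {
  .write_tsv(genotypes[, c("individual", "gene", "allele")], path)
}

#' Read / write observed site vectors
#'
#' Long TSV with columns `individual`, `gene`, `copy`, `position`, `base`.
#'
#' @param path File path.
#' @return data.frame with those columns.
#' @export
read_site_vectors <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("individual", "gene", "copy", "position", "base"),
                   path)
  df$copy <- as.integer(df$copy)
  df$position <- as.integer(df$position)
  df
}

#' @rdname read_site_vectors
#' @param site_vectors data.frame of observed site vectors.
#' @export
write_site_vectors <- function(site_vectors, path) {
  .write_tsv(site_vectors, path)
}

#' Write a simulated cohort to a directory
#'
#' Writes `copy_number.tsv`, `genotypes.tsv`, `site_vectors.tsv` (when
#' present), and the truth files `truth_haplotypes.tsv`, `truth_phased.tsv`
#' and `truth_novel.tsv` (each prefixed with a schema comment line).
#' Re-reading reproduces the in-memory tables.
#'
#' @param cohort A `kir_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(copy_number = file.path(dir, "copy_number.tsv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             truth_haplotypes = file.path(dir, "truth_haplotypes.tsv"),
             truth_phased = file.path(dir, "truth_phased.tsv"),
             truth_novel = file.path(dir, "truth_novel.tsv"))
  write_copy_number_table(cohort$profiles, paths["copy_number"])
  write_genotype_table(cohort$genotypes, paths["genotypes"])
  .write_truth <- function(df, path) {
    con <- file(path, "w")
    writeLines("# kirpop truth schema 1", con)
    close(con)
    suppressWarnings(
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE))
    invisible(path)
  }
  .write_truth(cohort$truth$haplotypes, paths["truth_haplotypes"])
  .write_truth(cohort$truth$phased, paths["truth_phased"])
  .write_truth(cohort$truth$novel, paths["truth_novel"])
  if (!is.null(cohort$site_vectors)) {
    paths["site_vectors"] <- file.path(dir, "site_vectors.tsv")
    write_site_vectors(cohort$site_vectors, paths["site_vectors"])
  }
  invisible(paths)
}
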