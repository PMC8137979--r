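# Gene-content haplotype catalogs. A haplotype is identified by its content
# vector (counts over the 15 loci) plus a name; the gene list carries display
# order only -- copy-number data cannot resolve order, so inference never
# uses it.

#' Construct a gene-content haplotype
#'
#' @param name Haplotype label, e.g. `"cA01"`, `"tB01"`, `"new1"`.
#' @param region `"centromeric"`, `"telomeric"` or `"full"`. The region is
#'   where the haplotype segregates; a telomeric haplotype may still carry
#'   copies of centromeric loci (multi-locus insertions such as the
#'   KIR3DP1~KIR2DL4~KIR3DS1 block do exactly that).
#' @param genes Character vector of locus names in display order; repeats
#'   encode duplications.
#' @param provenance `"reference"` (catalog) or `"discovered"`.
#' @param frequency Optional population frequency in `[0, 1]`, or `NA`.
#' @return An object of class `kir_haplotype` with fields `name`, `region`,
#'   `genes`, `content` (named integer vector over all 15 loci),
#'   `provenance`, `frequency`.
#' @export
kir_haplotype <- function(name, region, genes,
                          provenance = "reference", frequency = NA_real_) {
  region <- match.arg(region, c("centromeric", "telomeric", "full"))
  genes <- as.character(genes)
  .check_genes(genes, where = sprintf("haplotype '%s'", name))
  content <- setNames(integer(length(.KIR_LOCI)), .KIR_LOCI)
  if (length(genes) > 0) {
    tab <- table(genes)
    content[names(tab)] <- as.integer(tab)
  }
  structure(
    list(name = name, region = region, genes = genes, content = content,
         provenance = provenance, frequency = frequency),
    class = "kir_haplotype"
  )
}

#' @export
print.kir_haplotype <- function(x, ...) {
  cat(sprintf("<kir_haplotype> %s [%s, %s]\n  %s\n",
              x$name, x$region, x$provenance,
              if (length(x$genes)) paste(x$genes, collapse = "~") else "(empty)"))
  invisible(x)
}

#' Content vector of a haplotype
#'
#' @param h A `kir_haplotype`.
#' @return Named integer vector of copy counts over all 15 loci (zeros
#'   included), in genomic order.
#' @export
content_vector <- function(h) {
  stopifnot(inherits(h, "kir_haplotype"))
  h$content
}

#' Combine a centromeric and a telomeric haplotype into a full haplotype
#'
#' The full haplotype's content is the locus-wise sum of the two regional
#' contents; its name joins the two names with `"~"`.
#'
#' @param cen,tel `kir_haplotype` objects with matching regions.
#' @return A `kir_haplotype` with `region = "full"`.
#' @export
full_haplotype <- function(cen, tel) {
  stopifnot(cen$region == "centromeric", tel$region == "telomeric")
  h <- kir_haplotype(paste0(cen$name, "~", tel$name), "full",
                     c(cen$genes, tel$genes),
                     provenance = "reference")
  h
}

#' Load a gene-content haplotype catalog
#'
#' Reads a YAML catalog of named gene-content haplotypes. The packaged
#' default describes the common European-American centromeric and telomeric
#' haplotypes, the deletion haplotypes lacking KIR2DL4~KIR3DL1S1 (tB02, tB03
#' and the telomere carrying only KIR3DL2), and the two multi-locus
#' insertion haplotypes (`new1`: KIR3DP1~KIR2DL4~KIR3DS1 inserted into tA01;
#' `new2`: a seven-locus block inserted into tA01). Haplotype interiors that
#' are not fixed by copy-number arithmetic are configuration, not code:
#' supply your own file to override them.
#'
#' @param path Path to a YAML catalog, or `NULL` for the packaged default.
#' @return An object of class `kir_catalog`: a named list of
#'   [kir_haplotype()] objects.
#' @export
load_haplotype_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "kir_haplotype_catalog.yaml",
                        package = "kirpop", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$haplotypes)) {
    stop("catalog file has no 'haplotypes' entry: ", path, call. = FALSE)
  }
  haps <- lapply(cfg$haplotypes, function(e) {
    for (f in c("name", "region")) {
      if (is.null(e[[f]])) stop("catalog entry missing field '", f, "'", call. = FALSE)
    }
    kir_haplotype(e$name, e$region, unlist(e$genes),
                  provenance = if (is.null(e$provenance)) "reference" else e$provenance,
                  frequency = if (is.null(e$frequency)) NA_real_ else as.numeric(e$frequency))
  })
  names(haps) <- vapply(haps, `[[`, "", "name")
  if (anyDuplicated(names(haps))) {
    stop("duplicate haplotype names in catalog: ",
         paste(unique(names(haps)[duplicated(names(haps))]), collapse = ", "),
         call. = FALSE)
  }
  structure(haps, class = "kir_catalog")
}

#' @export
print.kir_catalog <- function(x, ...) {
  cat(sprintf("<kir_catalog> %d haplotypes (%d centromeric, %d telomeric)\n",
              length(x),
              sum(vapply(x, `[[`, "", "region") == "centromeric"),
              sum(vapply(x, `[[`, "", "region") == "telomeric")))
  invisible(x)
}

#' Write a haplotype catalog back to YAML
#'
#' Inverse of [load_haplotype_catalog()]; a written catalog reloads with
#' identical content vectors.
#'
#' @param catalog A `kir_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_haplotype_catalog <- function(catalog, path) {
  entries <- lapply(unname(catalog), function(h) {
    e <- list(name = h$name, region = h$region, genes = as.list(h$genes),
              provenance = h$provenance)
    if (!is.na(h$frequency)) e$frequency <- h$frequency
    e
  })
  yaml::write_yaml(list(haplotypes = entries), path)
  invisible(path)
}

#' Subset a catalog to one region
#'
#' @param catalog A `kir_catalog`.
#' @param region `"centromeric"` or `"telomeric"`.
#' @return A `kir_catalog` containing only that region's haplotypes.
#' @export
catalog_region <- function(catalog, region) {
  region <- match.arg(region, c("centromeric", "telomeric"))
  keep <- vapply(catalog, `[[`, "", "region") == region
  structure(catalog[keep], class = "kir_catalog")
}

# Matrix of content vectors restricted to `loci` (haplotypes x loci).
.content_matrix <- function(catalog, loci = .KIR_LOCI) {
  m <- t(vapply(catalog, function(h) h$content[loci], integer(length(loci))))
  if (length(loci) == 1L) m <- matrix(m, ncol = 1L,
                                      dimnames = list(names(catalog), loci))
  m
}
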