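# The 15 KIR loci in genomic order. KIR2DL2/KIR2DL3 segregate as alleles of
# one locus (KIR2DL23), as do KIR3DL1/KIR3DS1 (KIR3DL1S1); KIR2DL5A and
# KIR2DL5B are positional paralogs and kept distinct.
.KIR_LOCI <- c(
  "KIR3DL3", "KIR2DS2", "KIR2DL23", "KIR2DL5B", "KIR2DS3", "KIR2DP1",
  "KIR2DL1", "KIR3DP1",
  "KIR2DL4", "KIR3DL1S1", "KIR2DL5A", "KIR2DS5", "KIR2DS1", "KIR2DS4",
  "KIR3DL2"
)

.KIR_FRAMEWORK <- c("KIR3DL3", "KIR3DP1", "KIR2DL4", "KIR3DL2")

#' KIR locus registry
#'
#' Returns the registry of the 15 KIR loci: 13 genes plus the two pseudogenes
#' (KIR2DP1, KIR3DP1), in genomic order. The centromeric region runs from
#' KIR3DL3 to KIR3DP1 and the telomeric region from KIR2DL4 to KIR3DL2; the
#' two regions are bounded by the four framework genes (KIR3DL3, KIR3DP1,
#' KIR2DL4, KIR3DL2), which are present on nearly all haplotypes.
#'
#' @return A data.frame with one row per locus and columns `gene`, `region`
#'   (`"centromeric"` or `"telomeric"`), `framework` (logical) and `order`
#'   (integer genomic rank).
#' @examples
#' reg <- kir_loci()
#' subset(reg, framework)$gene
#' @export
kir_loci <- function() {
  idx_3dp1 <- match("KIR3DP1", .KIR_LOCI)
  data.frame(
    gene = .KIR_LOCI,
    region = ifelse(seq_along(.KIR_LOCI) <= idx_3dp1, "centromeric", "telomeric"),
    framework = .KIR_LOCI %in% .KIR_FRAMEWORK,
    order = seq_along(.KIR_LOCI),
    stringsAsFactors = FALSE
  )
}

#' Loci belonging to one region
#'
#' @param region `"centromeric"`, `"telomeric"` or `"full"` (all 15 loci).
#' @return Character vector of locus names in genomic order.
#' @export
region_loci <- function(region = c("full", "centromeric", "telomeric")) {
  region <- match.arg(region)
  reg <- kir_loci()
  if (region == "full") reg$gene else reg$gene[reg$region == region]
}

.check_genes <- function(genes, where = "input") {
  bad <- setdiff(genes, .KIR_LOCI)
  if (length(bad) > 0) {
    stop(sprintf("unknown KIR gene name(s) in %s: %s",
                 where, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(genes)
}
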