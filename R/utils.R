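#' @importFrom rlang %||% .data
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

# Genome-unit identifier: diploids are their own unit, allotetraploids
# contribute one unit per subgenome (A/B).
unit_id <- function(species_id, subgenome) {
  sg <- ifelse(is.na(subgenome) | subgenome %in% c("", "none"), "", subgenome)
  ifelse(sg == "", species_id, paste(species_id, sg, sep = "_"))
}

# Feature keys shared between the event detector and the count simulator.
# `body` features count reads on the variable element itself (retained
# intron, skipped exon, extended segment); `junc` features count reads on
# the splice junction of the exclusion form.
body_key <- function(chrom, start, end) sprintf("body:%s:%d-%d", chrom, start, end)
junc_key <- function(chrom, start, end) sprintf("junc:%s:%d-%d", chrom, start, end)

#' Build a deterministic alternative-splicing event identifier
#'
#' Event identifiers are a pure function of the gene, event type and the
#' defining genomic coordinates, so the same event found from different
#' transcript pairs (or planted by the synthetic generator) collapses to a
#' single record.
#'
#' @param gene_id Gene identifier.
#' @param type One of `"IR"`, `"ES"`, `"A5"`, `"A3"`.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param coords Integer vector of defining coordinates (type-specific).
#' @return Character event id.
#' @export
make_event_id <- function(gene_id, type, chrom, strand, coords) {
  paste(gene_id, type, chrom, strand, paste(coords, collapse = "-"), sep = ":")
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
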