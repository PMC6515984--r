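#' Bundled microoxia differential-expression summary table
#'
#' A curated summary of the top differentially expressed proteins of
#' *B. diazoefficiens* 110spc4 grown microoxically versus oxically,
#' shipped as plain tab-separated text.  Rows are grouped as `core_up`
#' (significantly induced at adjusted p <= 0.2), `core_down`
#' (significantly repressed), and `expanded_extra` (additionally induced
#' at log2 FC >= 1 at both the transcript and protein layer).  Columns
#' carry the protein-layer log2 fold change, the transcript-layer and
#' soybean-bacteroid fold changes where the gene was differentially
#' expressed (empty otherwise), and regulon membership flags for the
#' NifA+RpoN and FixK2 regulons.
#'
#' @return data.frame with columns `locus_tag`, `product`, `gene`,
#'   `usda110_query`, `log2fc_protein`, `fc_transcript`, `fc_bacteroid`,
#'   `nifa_rpon`, `fixk2`, `group`.
#' @export
microoxiaDiffTable <- function() {
  path <- system.file("extdata", "bdiazoefficiens_microoxia_diffexp.tsv",
                      package = "microxia", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(rep("character", 4), rep("numeric", 3),
                            rep("logical", 2), "character"))
}
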