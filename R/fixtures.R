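# Packaged fixtures.

#' Load the packaged 70-gene venom-protein expression fixture
#'
#' A 70-row table of printed venom-gland and carcass FPKM values, the
#' printed log2 ratio (with `Inf` for division by zero), the curated
#' functional category, and the best-hit annotation text for a published
#' parasitoid venom-protein set.
#'
#' @return data.frame with columns `gene`, `vg_fpkm`, `carcass_fpkm`,
#'   `printed_log2`, `category`, `annotation`.
#' @export
load_venom_fixture <- function() {
  path <- system.file("extdata", "table2_fpkm.tsv", package = "venomics",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
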