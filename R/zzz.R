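#' @useDynLib sparseDMR, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom data.table := .I
#' @importFrom stats setNames
#' @import GenomicRanges
NULL

.datatable.aware <- TRUE

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c("read_id", "methCall", "call"))
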