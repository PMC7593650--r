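#' @useDynLib kneefem, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
NULL

.datatable.aware <- TRUE
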