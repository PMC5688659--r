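#' @useDynLib ncRNAscout, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats glm binomial predict quantile sd setNames
#' @importFrom utils read.table write.table
NULL
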