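#' @keywords internal
#' @useDynLib exmrecon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom data.table data.table setorderv .N
#' @importFrom randomForest randomForest
#' @importFrom stats predict
"_PACKAGE"

.datatable.aware <- TRUE
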