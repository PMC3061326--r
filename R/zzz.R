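#' @useDynLib dipoleTrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm var cov dist as.dist
#' @importFrom utils read.table write.table modifyList
NULL
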