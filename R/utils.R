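`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance
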