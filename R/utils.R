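#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
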