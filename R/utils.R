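#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif sd cor aov t.test cor.test pt qnorm quantile median
#' @importFrom utils head tail
NULL

# round half away from zero (kernel sizes in samples)
round_half_up <- function(x) floor(x + 0.5)

# derive a reproducible child seed from a base seed and a stream label,
# staying inside the 32-bit integer range
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(paste0(stream)) * seq_along(utf8ToInt(paste0(stream))))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483629)
}
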