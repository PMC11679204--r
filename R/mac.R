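# Multiply-accumulate (MAC) accounting for convolutional layers. MAC is
# the standard arithmetic-cost proxy for CNNs (FLOPs are roughly 1-2x MAC).

check_mac_args <- function(...) {
  args <- c(...)
  assert_that(all(is.finite(args)) && all(args > 0) && all(args == round(args)),
              "all MAC arguments must be positive integers")
}

#' MAC count of a standard 2-d convolution
#'
#' `K1 x K2 x Cin x Cout x Hout x Wout`: one multiply-accumulate per kernel
#' tap, input map, output map and output position.
#'
#' @param K1,K2 Kernel height and width.
#' @param Cin,Cout Input and output feature maps.
#' @param Hout,Wout Output spatial size.
#' @return Exact integer-valued count (as a double to avoid overflow).
#' @export
mac_conv2d <- function(K1, K2, Cin, Cout, Hout, Wout) {
  check_mac_args(K1, K2, Cin, Cout, Hout, Wout)
  K1 * K2 * Cin * Cout * Hout * Wout
}

#' MAC count of a separable 2-d convolution
#'
#' Depthwise pass (`K1 x K2` taps per input map) plus pointwise pass
#' (`Cout` taps per input map): `(K1 x K2 + Cout) x Cin x Hout x Wout`.
#'
#' @inheritParams mac_conv2d
#' @export
mac_separable_conv2d <- function(K1, K2, Cin, Cout, Hout, Wout) {
  check_mac_args(K1, K2, Cin, Cout, Hout, Wout)
  (K1 * K2 + Cout) * Cin * Hout * Wout
}

#' MAC count of a depthwise 2-d convolution
#'
#' `K1 x K2 x Cin x D x Hout x Wout` with depth multiplier `D`.
#'
#' @inheritParams mac_conv2d
#' @param D Depth multiplier.
#' @export
mac_depthwise_conv2d <- function(K1, K2, Cin, D, Hout, Wout) {
  check_mac_args(K1, K2, Cin, D, Hout, Wout)
  K1 * K2 * Cin * D * Hout * Wout
}
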