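#' Count trainable parameters
#'
#' Exact count of trainable scalars (convolution and linear weights, biases,
#' instance-norm gains and shifts) of a built generator or discriminator.
#'
#' @param model a `usgan_generator` or `usgan_discriminator`.
#' @return integer-valued numeric.
#' @export
count_parameters <- function(model) {
  if (is.null(model$params)) return(0)
  sum(vapply(model$params, length, 0L))
}

#' Analytic FLOP count
#'
#' Counts floating-point operations of the convolution and linear layers
#' under the convention: one multiply-accumulate is 2 operations, so a
#' convolution costs `out_pixels * cout * (k^2 * cin) * 2` plus one
#' operation per output element for the bias. Transposed convolutions are
#' charged as their dual convolution evaluated at the upsampled output.
#' Normalisation and activation layers are excluded. Counts are per image.
#'
#' @param model a `usgan_generator` or `usgan_discriminator`.
#' @param input_resolution input side length for a discriminator; the
#'   generator uses its own output resolution and ignores this argument.
#' @return numeric FLOP count.
#' @export
count_flops <- function(model, input_resolution = NULL) {
  arch <- model$arch
  if (is.null(arch) || length(arch) == 0L) return(0)
  is_gen <- inherits(model, "usgan_generator")
  if (!is_gen && is.null(input_resolution))
    input_resolution <- model$spec$input_resolution
  total <- 0
  for (l in arch) {
    if (l$kind == "linear") {
      total <- total + 2 * l$cin * l$cout + l$cout
    } else {
      side <- if (is_gen) l$res else l$res * input_resolution
      out_elems <- side^2 * l$cout
      total <- total + out_elems * (2 * l$k^2 * l$cin) + out_elems
    }
  }
  total
}

#' Model statistics
#'
#' @param model a built network.
#' @param input_resolution see [count_flops()].
#' @return list with `n_parameters` and `flops`.
#' @export
model_stats <- function(model, input_resolution = NULL) {
  list(n_parameters = count_parameters(model),
       flops = count_flops(model, input_resolution))
}
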