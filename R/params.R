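#' Leaky integrate-and-fire neuron parameters
#'
#' Container for the parameters of the leaky integrate-and-fire (LIF) neuron
#' underlying both the moment activation and the spiking simulator. The
#' membrane potential obeys \eqn{dV/dt = -L V + I(t)}; a spike is emitted when
#' \eqn{V} crosses `V_th`, after which \eqn{V} is reset to `V_res` and clamped
#' for the refractory period `T_ref`.
#'
#' @param L Leak conductance (1/ms). Must be positive.
#' @param V_th Firing threshold (mV). Must exceed `V_res`.
#' @param V_res Reset potential (mV).
#' @param T_ref Refractory period (ms). Non-negative; bounds the firing rate
#'   by `1/T_ref`.
#'
#' @return An object of class `lif_params`.
#' @examples
#' p <- lif_params()
#' p$V_th
#' @export
lif_params <- function(L = 0.05, V_th = 20, V_res = 0, T_ref = 5) {
  stopifnot(is.numeric(L), length(L) == 1L, is.finite(L), L > 0)
  stopifnot(is.numeric(V_th), length(V_th) == 1L, is.finite(V_th))
  stopifnot(is.numeric(V_res), length(V_res) == 1L, is.finite(V_res))
  stopifnot(V_th > V_res)
  stopifnot(is.numeric(T_ref), length(T_ref) == 1L, is.finite(T_ref), T_ref >= 0)
  structure(list(L = L, V_th = V_th, V_res = V_res, T_ref = T_ref),
            class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf(
    "LIF parameters: L = %g /ms, V_th = %g mV, V_res = %g mV, T_ref = %g ms\n",
    x$L, x$V_th, x$V_res, x$T_ref))
  invisible(x)
}

# Noise floor on the input current std below which the diffusion integrals are
# numerically singular; the noise-free closed form is used instead.
SIGMA_FLOOR <- 1e-3
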