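# Bijections between native parameter boxes and unconstrained fitting
# space: logistic for unit-interval parameters, 2*logistic for beta
# (range (0, 2]), and 2*logistic - 1 for theta and gamma (range [-1, 1]).

transform_forward <- function(name, x) {
  switch(name,
         beta = qlogis(x / 2),
         theta = , gamma = qlogis((x + 1) / 2),
         qlogis(x))
}

transform_backward <- function(name, z) {
  switch(name,
         beta = 2 * plogis(z),
         theta = , gamma = 2 * plogis(z) - 1,
         plogis(z))
}

#' Map a parameter set to the unconstrained space of a model
#'
#' Only the model's free parameters are mapped; values must lie strictly
#' inside their boxes (boundary values have no finite image).
#'
#' @param params a [parameter_set()].
#' @param spec a [model_spec()] or model id.
#' @return Named numeric vector over `spec$free_params`.
#' @export
to_unconstrained <- function(params, spec) {
  spec <- model_spec(spec)
  z <- vapply(spec$free_params,
              function(nm) transform_forward(nm, params[[nm]]), 0.0)
  if (any(!is.finite(z)))
    stop("transform-domain error: parameter on its box boundary: ",
         paste(spec$free_params[!is.finite(z)], collapse = ", "),
         call. = FALSE)
  z
}

#' Map an unconstrained vector back to a full parameter set
#'
#' Inactive parameters take the model's fixed values (e.g. `omega = 0.5`
#' for fixed-weighting models, clamped learning rates for the null
#' models).
#'
#' @param z named or positional numeric vector over `spec$free_params`.
#' @param spec a [model_spec()] or model id.
#' @return A [parameter_set()].
#' @export
to_constrained <- function(z, spec) {
  spec <- model_spec(spec)
  stopifnot(length(z) == length(spec$free_params))
  p <- parameter_set()
  for (i in seq_along(spec$free_params)) {
    nm <- spec$free_params[i]
    p[[nm]] <- transform_backward(nm, z[[i]])
  }
  effective_parameters(p, spec)
}
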