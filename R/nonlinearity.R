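#' Input-output nonlinearity of a rate unit
#'
#' Constructs the scalar nonlinearity \eqn{\phi} mapping synaptic input to
#' firing rate. Four kinds are supported: `tanh` (the default throughout the
#' package), `rectified_linear` (\eqn{\phi(z) = \max(floor, z)}, with a
#' negative floor so that homeostatic rules can depress rates), `sign` (the
#' infinitely steep limit, used by the reduced and discrete-time models), and
#' `tanh_gain` (\eqn{\phi(z) = \tanh(g z)} for steepness studies).
#'
#' @param kind one of `"tanh"`, `"rectified_linear"`, `"sign"`, `"tanh_gain"`.
#' @param gain positive gain, used by `tanh_gain` only.
#' @param floor lower bound of the rectified-linear unit (default -5).
#' @return an object of class `dynmem_phi`.
#' @examples
#' phi <- nonlinearity("rectified_linear")
#' apply_phi(c(-10, 3), phi)
#' @export
nonlinearity <- function(kind = c("tanh", "rectified_linear", "sign", "tanh_gain"),
                         gain = 1, floor = -5) {
  if (length(kind) != 1L && !identical(kind, eval(formals(nonlinearity)$kind))) {
    kind <- kind[1L]
  }
  kind <- match.arg(kind)
  if (kind == "tanh_gain" && (!is.numeric(gain) || gain <= 0)) {
    stop("`gain` must be a positive number for kind = 'tanh_gain'", call. = FALSE)
  }
  structure(list(kind = kind, gain = gain, floor = floor), class = "dynmem_phi")
}

#' Apply a nonlinearity elementwise
#'
#' @param x numeric vector of synaptic inputs.
#' @param phi a [nonlinearity()] object (a bare string is also accepted).
#' @return numeric vector of rates, same length as `x`.
#' @export
apply_phi <- function(x, phi) {
  if (is.character(phi)) phi <- nonlinearity(phi)
  if (!inherits(phi, "dynmem_phi")) {
    stop("`phi` must be a nonlinearity object", call. = FALSE)
  }
  switch(phi$kind,
    tanh = tanh(x),
    rectified_linear = pmax(phi$floor, x),
    sign = sign(x),
    tanh_gain = tanh(phi$gain * x),
    stop("unknown nonlinearity kind: ", phi$kind, call. = FALSE)
  )
}

#' @export
print.dynmem_phi <- function(x, ...) {
  extra <- switch(x$kind,
    tanh_gain = sprintf(" (gain = %g)", x$gain),
    rectified_linear = sprintf(" (floor = %g)", x$floor),
    ""
  )
  cat(sprintf("<nonlinearity: %s%s>\n", x$kind, extra))
  invisible(x)
}
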