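#' Canonical model tags
#'
#' The four models handled by the package, in the canonical comparison order
#' used for tie-breaking: the zero-parameter guessing baseline, the elemental
#' Rescorla-Wagner model (\code{"rw"}), the configural Rescorla-Wagner model
#' with pairwise conjunction cues (\code{"crw"}) and the Pearce configural
#' model (\code{"pearce"}).
#'
#' @return Character vector of model tags.
#' @export
model_tags <- function() c("guess", "rw", "crw", "pearce")

#' Free parameters of a model
#'
#' @param model model tag (see \code{\link{model_tags}}).
#' @return Character vector of parameter names, in canonical order.
#' @export
#' @examples
#' model_params("rw")    # 5 parameters
#' model_params("crw")   # 6 parameters
#' model_params("pearce")
model_params <- function(model) {
  switch(match.arg(model, model_tags()),
    guess  = character(0),
    rw     = c("alpha_ctx", "alpha_cue", "beta_us", "beta_nous", "g"),
    crw    = c("alpha_ctx", "alpha_cue", "alpha_cfg", "beta_us", "beta_nous", "g"),
    pearce = c("alpha_pat", "beta_us", "beta_nous", "d", "g")
  )
}

#' Box constraints for a model's parameters
#'
#' All learning rates (the alphas and betas) are constrained to
#' [0.0001, 0.75], the SoftMax sensitivity \code{g} to [0.0001, 15] and the
#' Pearce discrimination exponent \code{d} to [0.0001, 20].
#'
#' @param model model tag.
#' @return A 2-row matrix (\code{lower}, \code{upper}) with one column per
#'   parameter.
#' @export
param_box <- function(model) {
  pars <- model_params(model)
  lo <- rep(1e-4, length(pars))
  hi <- vapply(pars, function(p) {
    if (p == "g") 15 else if (p == "d") 20 else 0.75
  }, numeric(1))
  box <- rbind(lower = lo, upper = hi)
  colnames(box) <- pars
  box
}

#' Validate (and name-order) a parameter vector
#'
#' @param model model tag.
#' @param params named numeric vector or list.
#' @return Named numeric vector in canonical order.
#' @keywords internal
check_params <- function(model, params) {
  pars <- model_params(model)
  if (length(pars) == 0L) return(numeric(0))
  params <- unlist(params)
  if (is.null(names(params)) && length(params) == length(pars)) {
    names(params) <- pars
  }
  if (!all(pars %in% names(params))) {
    stop("missing parameters for model '", model, "': ",
         paste(setdiff(pars, names(params)), collapse = ", "))
  }
  theta <- params[pars]
  box <- param_box(model)
  bad <- theta < box["lower", ] - 1e-12 | theta > box["upper", ] + 1e-12
  if (any(bad)) {
    stop("parameters outside their constraint box: ",
         paste(pars[bad], collapse = ", "))
  }
  theta
}

# uniform draw inside the box
random_params <- function(model) {
  box <- param_box(model)
  theta <- stats::runif(ncol(box), box["lower", ], box["upper", ])
  names(theta) <- colnames(box)
  theta
}
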