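#' Symmetric substitution models
#'
#' The likelihood engine works with symmetric k-state models: all
#' exchangeabilities equal and stationary frequencies uniform, with the rate
#' matrix scaled to a mean rate of one so branch lengths are expected
#' substitutions per site. For nucleotides this is the Jukes-Cantor (JC)
#' model; for amino acids its 20-state analogue, the Poisson model.
#' Transition probabilities have the closed form
#' \deqn{P_{same}(t) = 1/k + (k-1)/k\, e^{-kt/(k-1)}, \quad
#'       P_{diff}(t) = (1 - e^{-kt/(k-1)})/k.}
#'
#' @param name model name, `"JC"` (4 states) or `"Poisson"` (20 states).
#' @return an object of class `subst_model` with elements `name`, `k`
#'   (number of states) and `type` (`"DNA"` or `"AA"`, the corresponding
#'   [phangorn::phyDat] data type).
#' @examples
#' jc_model()
#' poisson_model()
#' @export
subst_model <- function(name = c("JC", "Poisson")) {
  name <- match.arg(name)
  out <- switch(name,
    JC      = list(name = "JC", k = 4L, type = "DNA"),
    Poisson = list(name = "Poisson", k = 20L, type = "AA"))
  class(out) <- "subst_model"
  out
}

#' @rdname subst_model
#' @export
jc_model <- function() subst_model("JC")

#' @rdname subst_model
#' @export
poisson_model <- function() subst_model("Poisson")

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("%s substitution model: %d states, uniform rates/frequencies, mean rate 1\n",
              x$name, x$k))
  invisible(x)
}

#' Transition probability of a symmetric model
#'
#' Probability of observing the same or a different state after a branch of
#' length `t` expected substitutions per site.
#'
#' @param model a [subst_model].
#' @param t branch length (non-negative).
#' @return list with `same` and `diff` probabilities.
#' @keywords internal
#' @export
transition_prob <- function(model, t) {
  k <- model$k
  e <- exp(-k * t / (k - 1))
  list(same = 1 / k + (k - 1) / k * e, diff = (1 - e) / k)
}
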