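# AdamW over arbitrarily nested lists of numeric arrays.

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}

# Matches named list elements by name (subtrees may be built in a
# different order than the parameter tree), unnamed ones by position.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    nms <- names(a)
    by_name <- !is.null(nms) && all(nzchar(nms)) && !is.null(names(b))
    for (i in seq_along(a)) {
      bi <- if (by_name) b[[nms[i]]] else b[[i]]
      out[[i]] <- tree_map2(f, a[[i]], bi)
    }
    out
  } else {
    f(a, b)
  }
}

tree_zeros_like <- function(x) tree_map(function(v) v * 0, x)

#' Create an AdamW optimizer state
#'
#' @param params Nested parameter list (as held by a `deprex_model`).
#' @param lr Learning rate.
#' @param beta1,beta2 Moment decay rates.
#' @param eps Numerical floor in the update denominator.
#' @param weight_decay Decoupled weight decay coefficient.
#' @return An `adamw` state object.
#' @export
adamw_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  structure(
    list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L,
         lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
         weight_decay = weight_decay),
    class = "adamw"
  )
}

#' One AdamW update step
#'
#' Standard Adam moment updates with bias correction and decoupled weight
#' decay applied directly to the parameters.
#'
#' @param params Nested parameter list.
#' @param grads Gradients with the same structure.
#' @param state State from [adamw_init()].
#' @return List with updated `params` and `state`.
#' @export
adamw_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) state$beta1 * m + (1 - state$beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) state$beta2 * v + (1 - state$beta2) * g^2, state$v, grads)
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + state$eps), state$m, state$v)
  params <- tree_map2(
    function(p, u) p - state$lr * (u + state$weight_decay * p),
    params, upd
  )
  list(params = params, state = state)
}

tree_add <- function(a, b) tree_map2(`+`, a, b)
tree_scale <- function(x, s) tree_map(function(v) v * s, x)
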