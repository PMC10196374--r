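# Adam optimizer over the flat named-parameter representation of a network.

#' Create an Adam optimizer state for a network
#'
#' Defaults follow the conditional-GAN convention: learning rate 2e-4 and
#' momentum parameters beta = (0.5, 0.999).
#'
#' @param net network handle.
#' @param lr learning rate.
#' @param beta1,beta2 exponential decay rates of the moment estimates.
#' @param eps numerical stabilizer.
#' @return an optimizer state list.
#' @export
adam_init <- function(net, lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  params <- net_params(net)
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

#' Apply one Adam update
#'
#' @param net network handle.
#' @param grads flat named list of gradients (same names as [net_params()]).
#' @param opt optimizer state from [adam_init()].
#' @return `list(net, opt)` with updated parameters and moments.
#' @export
adam_step <- function(net, grads, opt) {
  params <- net_params(net)
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (any(!is.finite(g)))
      stop("non-finite gradient in parameter ", nm, call. = FALSE)
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(net = net_set_params(net, params), opt = opt)
}
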