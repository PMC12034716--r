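# Adam / AdamW on a named list of numeric arrays. Weight decay is
# decoupled (applied directly to the parameters, not through the moments).

adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(t = 0L, m = zeros, v = zeros)
}

adam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (k in names(params)) {
    g <- grads[[k]]
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * g
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * g * g
    step <- lr * (opt$m[[k]] / bc1) / (sqrt(opt$v[[k]] / bc2) + eps)
    if (weight_decay > 0)
      params[[k]] <- params[[k]] - lr * weight_decay * params[[k]]
    params[[k]] <- params[[k]] - step
  }
  list(params = params, opt = opt)
}
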