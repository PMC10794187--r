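# Minimal CNN engine. Activations are dense double arrays with layout
# [H, W, N, C]; every layer is an environment holding its parameters,
# cached forward state, and parameter gradients. Convolutions run as one
# GEMM against the im2col patch matrix (src/conv_ops.cpp); batch
# normalization and the heads are plain matrix algebra. Layers with
# parameters keep them in `params` and write matching `grads`, which is
# all the Adam step needs to know.

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  class(e) <- c(paste0("lcnet_", type), "lcnet_layer")
  e
}

# He-normal fan-in init; caller controls the RNG stream.
conv_layer <- function(k, cin, cout, bias = FALSE) {
  l <- new_layer("conv")
  l$k <- as.integer(k)
  l$cin <- as.integer(cin)
  l$cout <- as.integer(cout)
  sd <- sqrt(2 / (k * k * cin))
  l$params$W <- matrix(rnorm(k * k * cin * cout, sd = sd), k * k * cin, cout)
  if (bias) l$params$b <- numeric(cout)
  l
}

bn_layer <- function(C, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("bn")
  l$C <- as.integer(C)
  l$momentum <- momentum
  l$eps <- eps
  l$params$gamma <- rep(1, C)
  l$params$beta <- numeric(C)
  l$running_mean <- numeric(C)
  l$running_var <- rep(1, C)
  l
}

relu_layer <- function() new_layer("relu")
sigmoid_layer <- function() new_layer("sigmoid")
pool_layer <- function() new_layer("pool")

unpool_layer <- function(partner) {
  l <- new_layer("unpool")
  l$partner <- partner
  l
}

gap_layer <- function() new_layer("gap")

linear_layer <- function(cin, cout = 1L) {
  l <- new_layer("linear")
  l$params$W <- matrix(rnorm(cin * cout, sd = sqrt(1 / cin)), cin, cout)
  l$params$b <- numeric(cout)
  l
}

layer_forward <- function(l, x, training = FALSE) {
  switch(l$type,
    conv = {
      d <- dim(x)
      l$in_dim <- d
      P <- d[1] * d[2] * d[3]
      if (l$k == 1L) {
        xm <- matrix(x, P, d[4])
        if (training) l$cache <- xm
        out <- xm %*% l$params$W
      } else {
        cols <- im2col_hwnc(x, d[1], d[2], d[3], d[4], l$k, (l$k - 1L) %/% 2L)
        if (training) l$cache <- cols
        out <- cols %*% l$params$W
      }
      if (!is.null(l$params$b)) out <- out + rep(l$params$b, each = P)
      dim(out) <- c(d[1], d[2], d[3], l$cout)
      out
    },
    bn = {
      d <- dim(x)
      M <- d[1] * d[2] * d[3]
      C <- d[4]
      m <- matrix(x, M, C)
      if (training) {
        mu <- .colMeans(m, M, C)
        xc <- m - rep(mu, each = M)
        v <- .colMeans(xc * xc, M, C)
        l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * mu
        l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * v
      } else {
        mu <- l$running_mean
        v <- l$running_var
        xc <- m - rep(mu, each = M)
      }
      invstd <- 1 / sqrt(v + l$eps)
      xhat <- xc * rep(invstd, each = M)
      out <- xhat * rep(l$params$gamma, each = M) +
        rep(l$params$beta, each = M)
      if (training) {
        l$cache <- list(xhat = xhat, invstd = invstd, M = M, dims = d)
      }
      dim(out) <- d
      out
    },
    relu = {
      out <- x
      out[out < 0] <- 0
      if (training) l$cache <- out
      out
    },
    sigmoid = {
      out <- 1 / (1 + exp(-x))
      if (training) l$cache <- out
      out
    },
    pool = {
      d <- dim(x)
      l$in_dim <- d
      r <- maxpool2x2(x, d[1], d[2], d[3], d[4])
      l$idx <- r$idx
      r$out
    },
    unpool = {
      d <- l$partner$in_dim
      l$in_dim <- dim(x)
      unpool2x2(x, l$partner$idx, d[1], d[2], d[3], d[4])
    },
    gap = {
      d <- dim(x)
      l$in_dim <- d
      HW <- d[1] * d[2]
      cm <- .colMeans(matrix(x, HW, d[3] * d[4]), HW, d[3] * d[4])
      matrix(cm, d[3], d[4])
    },
    linear = {
      l$cache <- x
      sweep(x %*% l$params$W, 2, l$params$b, "+")
    },
    stop("unknown layer type: ", l$type)
  )
}

layer_backward <- function(l, dy, need_dx = TRUE) {
  switch(l$type,
    conv = {
      d <- l$in_dim
      P <- d[1] * d[2] * d[3]
      dym <- matrix(dy, P, l$cout)
      l$grads$W <- crossprod(l$cache, dym)
      l$cache <- NULL
      if (!is.null(l$params$b)) l$grads$b <- colSums(dym)
      if (!need_dx) return(NULL)
      if (l$k == 1L) {
        dx <- dym %*% t(l$params$W)
        dim(dx) <- d
        dx
      } else {
        dcols <- dym %*% t(l$params$W)
        col2im_hwnc(dcols, d[1], d[2], d[3], d[4], l$k, (l$k - 1L) %/% 2L)
      }
    },
    bn = {
      cc <- l$cache
      M <- cc$M
      C <- length(l$params$gamma)
      dym <- matrix(dy, M, C)
      l$grads$gamma <- colSums(dym * cc$xhat)
      l$grads$beta <- colSums(dym)
      dxhat <- dym * rep(l$params$gamma, each = M)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * cc$xhat)
      dx <- (dxhat - rep(s1 / M, each = M) -
             cc$xhat * rep(s2 / M, each = M)) * rep(cc$invstd, each = M)
      l$cache <- NULL
      dim(dx) <- cc$dims
      dx
    },
    relu = {
      dx <- dy
      dx[l$cache <= 0] <- 0
      l$cache <- NULL
      dx
    },
    sigmoid = {
      dy * l$cache * (1 - l$cache)
    },
    pool = {
      d <- l$in_dim
      dx <- maxpool2x2_backward(dy, l$idx, d[1], d[2], d[3], d[4])
      l$idx <- NULL
      dx
    },
    unpool = {
      d <- l$in_dim
      unpool2x2_backward(dy, l$partner$idx, d[1], d[2], d[3], d[4])
    },
    gap = {
      d <- l$in_dim
      HW <- d[1] * d[2]
      dx <- rep(as.numeric(dy) / HW, each = HW)
      dim(dx) <- d
      dx
    },
    linear = {
      l$grads$W <- crossprod(l$cache, dy)
      l$grads$b <- colSums(dy)
      dy %*% t(l$params$W)
    },
    stop("unknown layer type: ", l$type)
  )
}

nn_forward <- function(model, x, training = FALSE) {
  for (l in model$layers) x <- layer_forward(l, x, training)
  x
}

# Inference in chunks along the batch dimension to bound peak memory;
# outputs are reassembled in input order.
nn_infer <- function(model, x, chunk = 32L) {
  n <- dim(x)[3]
  if (n <= chunk) return(nn_forward(model, x, training = FALSE))
  starts <- seq(1L, n, by = chunk)
  parts <- lapply(starts, function(s) {
    sel <- s:min(s + chunk - 1L, n)
    nn_forward(model, x[, , sel, , drop = FALSE], training = FALSE)
  })
  if (is.matrix(parts[[1]])) return(do.call(rbind, parts))
  d <- dim(parts[[1]])
  out <- array(0, c(d[1], d[2], n, d[4]))
  at <- 1L
  for (p in parts) {
    np <- dim(p)[3]
    out[, , at:(at + np - 1L), ] <- p
    at <- at + np
  }
  out
}

# Backpropagate from layer index `from` down to the input; `from` defaults
# to the last layer. Training loops that fuse the loss with the final
# sigmoid start one layer earlier with the logit gradient.
nn_backward <- function(model, dy, from = length(model$layers)) {
  for (i in seq(from, 1L)) {
    dy <- layer_backward(model$layers[[i]], dy, need_dx = i > 1L)
  }
  invisible(dy)
}

# Drop cached activations/patch matrices so a trained model is cheap to
# keep around or serialize.
nn_clear_cache <- function(model) {
  for (l in model$layers) {
    l$cache <- NULL
    l$idx <- NULL
  }
  invisible(model)
}

nn_adam_init <- function(model) {
  model$adam <- list(t = 0L)
  for (l in model$layers) {
    if (length(l$params)) {
      l$adam_m <- lapply(l$params, function(p) p * 0)
      l$adam_v <- lapply(l$params, function(p) p * 0)
    }
  }
  invisible(model)
}

nn_adam_step <- function(model, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  model$adam$t <- model$adam$t + 1L
  t <- model$adam$t
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (l in model$layers) {
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      l$adam_m[[nm]] <- beta1 * l$adam_m[[nm]] + (1 - beta1) * g
      l$adam_v[[nm]] <- beta2 * l$adam_v[[nm]] + (1 - beta2) * g * g
      mhat <- l$adam_m[[nm]] / corr1
      vhat <- l$adam_v[[nm]] / corr2
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(model)
}

#' Count trainable parameters of a model
#'
#' Sums the sizes of all trainable tensors: convolution kernels (and
#' biases where present), batch-normalization scale/shift pairs, and the
#' weights and bias of the linear head. Batch-normalization running
#' statistics are buffers, not parameters, and are excluded.
#'
#' @param model A model built by [build_segnet()] or [build_lcnet()].
#' @return Non-negative integer parameter count.
#' @examples
#' m <- build_lcnet(count_config(input_size = c(32, 32),
#'                               stages = list(c(4, 8))))
#' count_parameters(m)
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "lcnet_model"))
  sum(vapply(model$layers,
             function(l) sum(vapply(l$params, length, 1L)), 1))
}

new_model <- function(layers, config, type) {
  m <- new.env(parent = emptyenv())
  m$layers <- layers
  m$config <- config
  m$type <- type
  class(m) <- c(paste0("lcnet_", type), "lcnet_model")
  m
}

#' @export
print.lcnet_model <- function(x, ...) {
  cat(sprintf("<%s model>  input %s  |  %s trainable parameters\n",
              x$type,
              paste(x$config$input_size, collapse = "x"),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# Stack images (list of [H,W,C] arrays, or one such array) into the
# [H,W,N,C] activation layout.
stack_batch <- function(images) {
  if (!is.list(images)) images <- list(images)
  d <- dim(images[[1]])
  if (length(d) == 2L) d <- c(d, 1L)
  n <- length(images)
  out <- array(0, c(d[1], d[2], n, d[3]))
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    out[, , i, ] <- img
  }
  out
}

# Extract sample n of a [H,W,N,C] batch as an [H,W,C] array.
unstack_one <- function(batch, n) {
  d <- dim(batch)
  out <- batch[, , n, , drop = FALSE]
  dim(out) <- d[c(1, 2, 4)]
  out
}
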