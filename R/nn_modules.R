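# Differentiable attention / BPP / fusion modules and optimizers (internal).
# Forward math is identical to the exported functional ops (channel_attention,
# spatial_attention, bpp_forward, edge_fuse); these variants add hand-derived
# backward passes and learnable state.

nn_channel_attn <- function() {
  ly <- new.env()
  ly$omega <- nn_param(0)           # learning factor, zero-init: identity start
  ly$params <- list(ly$omega)
  cache <- new.env(parent = emptyenv())
  ly$fwd <- function(x, train = TRUE) {
    x <- .as_fmap(x); d <- dim(x)
    M <- matrix(x, d[1] * d[2], d[3])
    G <- crossprod(M)
    A <- .row_softmax(G)
    P <- M %*% t(A)
    if (train) { cache$M <- M; cache$A <- A; cache$P <- P; cache$d <- d }
    array(as.numeric(ly$omega$val) * P + M, dim = d)
  }
  ly$bwd <- function(dy) {
    d <- cache$d
    dY <- matrix(dy, d[1] * d[2], d[3])
    M <- cache$M; A <- cache$A
    ly$omega$grad <- ly$omega$grad + sum(dY * cache$P)
    dP <- as.numeric(ly$omega$val) * dY
    dM <- dY + dP %*% A
    dA <- t(dP) %*% M
    dG <- A * (dA - rowSums(dA * A))
    dM <- dM + M %*% (dG + t(dG))
    array(dM, dim = d)
  }
  ly
}

nn_spatial_attn <- function(C, seed = NULL) {
  ly <- new.env()
  Cr <- floor(C / 8)
  if (Cr < 1) stop("spatial attention needs floor(C/8) >= 1 channels")
  init <- if (is.null(seed)) spatial_attention_params(C, seed = sample.int(1e6, 1))
          else spatial_attention_params(C, seed = seed)
  ly$Wq <- nn_param(init$Wq); ly$Ws <- nn_param(init$Ws); ly$Wv <- nn_param(init$Wv)
  ly$bq <- nn_param(init$bq); ly$bs <- nn_param(init$bs); ly$bv <- nn_param(init$bv)
  ly$Wo <- nn_param(init$Wo); ly$bo <- nn_param(init$bo)
  ly$phi <- nn_param(0)
  ly$params <- list(ly$Wq, ly$Ws, ly$Wv, ly$bq, ly$bs, ly$bv, ly$Wo, ly$bo, ly$phi)
  cache <- new.env(parent = emptyenv())
  ly$fwd <- function(x, train = TRUE) {
    x <- .as_fmap(x); d <- dim(x)
    M <- matrix(x, d[1] * d[2], d[3])
    Q <- sweep(M %*% ly$Wq$val, 2, ly$bq$val, `+`)
    S <- sweep(M %*% ly$Ws$val, 2, ly$bs$val, `+`)
    V <- sweep(M %*% ly$Wv$val, 2, ly$bv$val, `+`)
    E <- .row_softmax(S %*% t(Q))
    O <- E %*% V
    P <- sweep(O %*% ly$Wo$val, 2, ly$bo$val, `+`)
    if (train) {
      cache$M <- M; cache$Q <- Q; cache$S <- S; cache$V <- V
      cache$E <- E; cache$O <- O; cache$P <- P; cache$d <- d
    }
    array(as.numeric(ly$phi$val) * P + M, dim = d)
  }
  ly$bwd <- function(dy) {
    d <- cache$d
    dY <- matrix(dy, d[1] * d[2], d[3])
    M <- cache$M; E <- cache$E
    ly$phi$grad <- ly$phi$grad + sum(dY * cache$P)
    dPp <- as.numeric(ly$phi$val) * dY
    ly$Wo$grad <- ly$Wo$grad + crossprod(cache$O, dPp)
    ly$bo$grad <- ly$bo$grad + colSums(dPp)
    dO <- dPp %*% t(ly$Wo$val)
    dE <- dO %*% t(cache$V)
    dV <- crossprod(E, dO)
    dL <- E * (dE - rowSums(dE * E))
    dS <- dL %*% cache$Q
    dQ <- crossprod(dL, cache$S)
    ly$Wq$grad <- ly$Wq$grad + crossprod(M, dQ)
    ly$Ws$grad <- ly$Ws$grad + crossprod(M, dS)
    ly$Wv$grad <- ly$Wv$grad + crossprod(M, dV)
    ly$bq$grad <- ly$bq$grad + colSums(dQ)
    ly$bs$grad <- ly$bs$grad + colSums(dS)
    ly$bv$grad <- ly$bv$grad + colSums(dV)
    dM <- dY + dQ %*% t(ly$Wq$val) + dS %*% t(ly$Ws$val) + dV %*% t(ly$Wv$val)
    array(dM, dim = d)
  }
  ly
}

# Mixed attention wrapper honoring the parallel / serial ablation wiring and
# the CA / SA on-off flags.
nn_mixed_attn <- function(C, mode = "parallel", use_ca = TRUE, use_sa = TRUE,
                          seed = NULL) {
  ly <- new.env()
  ly$mode <- mode; ly$use_ca <- use_ca; ly$use_sa <- use_sa
  ly$ca <- if (use_ca) nn_channel_attn() else NULL
  ly$sa <- if (use_sa) nn_spatial_attn(C, seed = seed) else NULL
  ly$params <- c(if (use_ca) ly$ca$params, if (use_sa) ly$sa$params)
  cache <- new.env(parent = emptyenv())
  ly$fwd <- function(x, train = TRUE) {
    if (!ly$use_ca && !ly$use_sa) { cache$kind <- "none"; return(x) }
    if (ly$use_ca && ly$use_sa && ly$mode == "parallel") {
      cache$kind <- "parallel"
      return(ly$ca$fwd(x, train) + ly$sa$fwd(x, train))
    }
    order <- if (!ly$use_ca) list(ly$sa)
      else if (!ly$use_sa) list(ly$ca)
      else if (ly$mode == "channel_then_spatial") list(ly$ca, ly$sa)
      else list(ly$sa, ly$ca)
    cache$kind <- "serial"; cache$order <- order
    for (l in order) x <- l$fwd(x, train)
    x
  }
  ly$bwd <- function(dy) {
    if (cache$kind == "none") return(dy)
    if (cache$kind == "parallel") return(ly$ca$bwd(dy) + ly$sa$bwd(dy))
    for (l in rev(cache$order)) dy <- l$bwd(dy)
    dy
  }
  ly
}

# Boundary points proposal head: parallel multi-branch dilated convolutions.
nn_bpp <- function(Cin, config = bpp_config()) {
  ly <- new.env()
  Cr <- config$reduce_channels
  mk_branch <- function(rate) {
    layers <- list(nn_conv2d(Cin, Cr, k = 1L, pad = 0L))
    if (config$use_batchnorm) layers <- c(layers, list(nn_bn(Cr)))
    layers <- c(layers, list(nn_relu()))
    if (!is.na(rate)) {
      layers <- c(layers, list(nn_conv2d(Cr, Cr, k = 3L, dilation = rate)))
      if (config$use_batchnorm) layers <- c(layers, list(nn_bn(Cr)))
      layers <- c(layers, list(nn_relu()))
    }
    do.call(nn_seq, layers)
  }
  ly$branches <- c(list(mk_branch(NA)), lapply(config$dilation_rates, mk_branch))
  ly$proj <- nn_conv2d(length(ly$branches) * Cr, 1L, k = 1L, pad = 0L)
  ly$sig <- nn_sigmoid()
  ly$Cr <- Cr
  ly$params <- c(do.call(c, lapply(ly$branches, function(b) b$params)),
                 ly$proj$params)
  ly$fwd <- function(x, train = TRUE) {
    outs <- lapply(ly$branches, function(b) b$fwd(x, train))
    cat_ <- array(0, dim = c(dim(outs[[1]])[1:2], length(outs) * ly$Cr))
    for (i in seq_along(outs))
      cat_[, , (i - 1) * ly$Cr + seq_len(ly$Cr)] <- outs[[i]]
    ly$sig$fwd(ly$proj$fwd(cat_, train), train)
  }
  ly$bwd <- function(dy) {
    dcat <- ly$proj$bwd(ly$sig$bwd(dy))
    dx <- 0
    for (i in seq_along(ly$branches)) {
      sl <- dcat[, , (i - 1) * ly$Cr + seq_len(ly$Cr), drop = FALSE]
      dx <- dx + ly$branches[[i]]$bwd(sl)
    }
    dx
  }
  ly
}

# Residual edge-attention fusion F_edge = F_tumor * (1 + F_points).
nn_edge_fuse <- function() {
  ly <- new.env(); ly$params <- list()
  cache <- new.env(parent = emptyenv())
  ly$fwd <- function(f_tumor, f_points, train = TRUE) {
    f_tumor <- .as_fmap(f_tumor); f_points <- .as_fmap(f_points)
    if (train) { cache$ft <- f_tumor; cache$fp <- f_points }
    f_tumor * (1 + as.vector(f_points))
  }
  ly$bwd <- function(dy) {
    dft <- dy * (1 + as.vector(cache$fp))
    dfp_full <- dy * cache$ft
    dfp <- array(apply(dfp_full, c(1, 2), sum), dim = dim(cache$fp))
    list(d_tumor = dft, d_points = dfp)
  }
  ly
}

# Optimizers ----------------------------------------------------------------

# Decoupled-weight-decay Adam (default) or SGD with momentum.
make_optimizer <- function(params, kind = c("adamw", "sgd"), lr = 1e-3,
                           momentum = 0.9, weight_decay = 1e-4,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  kind <- match.arg(kind)
  st <- new.env()
  st$t <- 0L
  for (p in params) { p$m <- p$val * 0; p$v <- p$val * 0 }
  step <- function() {
    st$t <- st$t + 1L
    if (kind == "adamw") {
      bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
      for (p in params) {
        p$m <- beta1 * p$m + (1 - beta1) * p$grad
        p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
        p$val <- p$val - lr * ((p$m / bc1) / (sqrt(p$v / bc2) + eps) +
                                 weight_decay * p$val)
      }
    } else {
      for (p in params) {
        p$m <- momentum * p$m + p$grad + weight_decay * p$val
        p$val <- p$val - lr * p$m
      }
    }
    .zero_grads(params)
  }
  list(step = step, state = st)
}

# Serializable snapshot of all parameters + optimizer moments.
params_snapshot <- function(params) {
  lapply(params, function(p) list(val = p$val, m = p$m, v = p$v))
}

params_restore <- function(params, snap) {
  stopifnot(length(params) == length(snap))
  for (i in seq_along(params)) {
    params[[i]]$val <- snap[[i]]$val
    params[[i]]$m <- snap[[i]]$m
    params[[i]]$v <- snap[[i]]$v
    params[[i]]$grad[] <- 0
  }
  invisible(NULL)
}

n_trainable <- function(params) sum(vapply(params, function(p) length(p$val), 0))
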