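# Minimal reverse-mode layer engine (internal).
#
# Feature tensors are H x W x C arrays, batch size 1 per call (batches are
# formed by accumulating gradients across images before an optimizer step).
# Every layer is an environment with $fwd(x, train), $bwd(dy) -> dx, and
# $params (list of parameter environments holding $val and $grad). All
# backward passes are checked against central-difference numerical gradients
# in the test suite.

nn_param <- function(val) {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- array(0, dim = if (is.null(dim(val))) length(val) else dim(val))
  p
}

.zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

# im2col gather plan for a padded input of size Hp x Wp x Cin.
.im2col_plan <- function(H, W, Cin, k, stride, pad, dilation) {
  keff <- (k - 1) * dilation + 1
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  Ho <- (Hp - keff) %/% stride + 1L
  Wo <- (Wp - keff) %/% stride + 1L
  if (Ho < 1 || Wo < 1)
    stop("dilation/kernel too large for the (padded) input extent")
  ho <- rep(seq_len(Ho), times = Wo); wo <- rep(seq_len(Wo), each = Ho)
  base <- (ho - 1) * stride + 1 + Hp * ((wo - 1) * stride)
  ki <- rep(seq_len(k), times = k * Cin)
  kj <- rep(rep(seq_len(k), each = k), times = Cin)
  ci <- rep(seq_len(Cin), each = k * k)
  offs <- (ki - 1) * dilation + Hp * ((kj - 1) * dilation) + Hp * Wp * (ci - 1)
  idx <- outer(base, offs, `+`)
  list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
}

.pad_zero <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

# Stateless functional conv (shared by the BPP functional forward).
conv2d_fn <- function(x, Wk, b = NULL, stride = 1L, dilation = 1L,
                      pad = (dim(Wk)[1] - 1) %/% 2 * dilation) {
  x <- .as_fmap(x)
  k <- dim(Wk)[1]; Cin <- dim(Wk)[3]; Cout <- dim(Wk)[4]
  stopifnot(dim(x)[3] == Cin)
  pl <- .im2col_plan(dim(x)[1], dim(x)[2], Cin, k, stride, pad, dilation)
  xp <- .pad_zero(x, pad)
  cols <- matrix(xp[pl$idx], nrow(pl$idx), ncol(pl$idx))
  Y <- cols %*% matrix(Wk, k * k * Cin, Cout)
  if (!is.null(b)) Y <- sweep(Y, 2, b, `+`)
  array(Y, dim = c(pl$Ho, pl$Wo, Cout))
}

nn_conv2d <- function(Cin, Cout, k = 3L, stride = 1L, dilation = 1L,
                      pad = (k - 1) %/% 2 * dilation, bias = TRUE,
                      init_gain = 1) {
  ly <- new.env()
  fan_in <- k * k * Cin
  ly$W <- nn_param(array(stats::rnorm(fan_in * Cout, 0,
                                      init_gain * sqrt(2 / fan_in)),
                         dim = c(k, k, Cin, Cout)))
  ly$b <- if (bias) nn_param(rep(0, Cout)) else NULL
  ly$params <- c(list(ly$W), if (bias) list(ly$b))
  ly$meta <- list(k = k, stride = stride, dilation = dilation, pad = pad,
                  Cin = Cin, Cout = Cout)
  cache <- new.env(parent = emptyenv())
  ly$fwd <- function(x, train = TRUE) {
    x <- .as_fmap(x)
    m <- ly$meta
    key <- paste(dim(x), collapse = "x")
    if (is.null(cache$key) || cache$key != key) {
      cache$pl <- .im2col_plan(dim(x)[1], dim(x)[2], m$Cin, m$k, m$stride,
                               m$pad, m$dilation)
      cache$key <- key
      cache$d_in <- dim(x)
    }
    pl <- cache$pl
    xp <- .pad_zero(x, m$pad)
    cols <- matrix(xp[pl$idx], nrow(pl$idx), ncol(pl$idx))
    if (train) cache$cols <- cols
    Y <- cols %*% matrix(ly$W$val, m$k * m$k * m$Cin, m$Cout)
    if (!is.null(ly$b)) Y <- sweep(Y, 2, ly$b$val, `+`)
    array(Y, dim = c(pl$Ho, pl$Wo, m$Cout))
  }
  ly$bwd <- function(dy) {
    m <- ly$meta; pl <- cache$pl
    dY <- matrix(dy, nrow(pl$idx), m$Cout)
    ly$W$grad <- ly$W$grad + array(crossprod(cache$cols, dY), dim = dim(ly$W$val))
    if (!is.null(ly$b)) ly$b$grad <- ly$b$grad + colSums(dY)
    dcols <- dY %*% t(matrix(ly$W$val, m$k * m$k * m$Cin, m$Cout))
    dxp <- numeric(pl$Hp * pl$Wp * m$Cin)
    for (j in seq_len(ncol(pl$idx)))
      dxp[pl$idx[, j]] <- dxp[pl$idx[, j]] + dcols[, j]
    dxp <- array(dxp, dim = c(pl$Hp, pl$Wp, m$Cin))
    d <- cache$d_in
    if (m$pad > 0)
      dxp <- dxp[m$pad + seq_len(d[1]), m$pad + seq_len(d[2]), , drop = FALSE]
    dxp
  }
  ly
}

nn_bn <- function(C, eps = 1e-5, momentum = 0.1) {
  ly <- new.env()
  ly$gamma <- nn_param(rep(1, C)); ly$beta <- nn_param(rep(0, C))
  ly$params <- list(ly$gamma, ly$beta)
  ly$run_mean <- rep(0, C); ly$run_var <- rep(1, C)
  cache <- new.env(parent = emptyenv())
  ly$fwd <- function(x, train = TRUE) {
    x <- .as_fmap(x)
    d <- dim(x); N <- d[1] * d[2]
    M <- matrix(x, N, d[3])
    if (train) {
      mu <- colMeans(M)
      v <- colMeans(M^2) - mu^2
      ly$run_mean <- (1 - momentum) * ly$run_mean + momentum * mu
      ly$run_var <- (1 - momentum) * ly$run_var + momentum * v
    } else {
      mu <- ly$run_mean; v <- ly$run_var
    }
    inv <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(M, 2, mu, `-`), 2, inv, `*`)
    if (train) { cache$xhat <- xhat; cache$inv <- inv; cache$d <- d }
    Y <- sweep(sweep(xhat, 2, ly$gamma$val, `*`), 2, ly$beta$val, `+`)
    array(Y, dim = d)
  }
  ly$bwd <- function(dy) {
    d <- cache$d; N <- d[1] * d[2]
    dY <- matrix(dy, N, d[3])
    xhat <- cache$xhat
    ly$gamma$grad <- ly$gamma$grad + colSums(dY * xhat)
    ly$beta$grad <- ly$beta$grad + colSums(dY)
    dxhat <- sweep(dY, 2, ly$gamma$val, `*`)
    m1 <- colMeans(dxhat); m2 <- colMeans(dxhat * xhat)
    dx <- sweep(dxhat, 2, m1, `-`) - sweep(xhat, 2, m2, `*`)
    dx <- sweep(dx, 2, cache$inv, `*`)
    array(dx, dim = d)
  }
  ly
}

nn_relu <- function() {
  ly <- new.env(); ly$params <- list()
  cache <- new.env(parent = emptyenv())
  ly$fwd <- function(x, train = TRUE) {
    if (train) cache$pos <- x > 0
    x * (x > 0)
  }
  ly$bwd <- function(dy) dy * cache$pos
  ly
}

nn_sigmoid <- function() {
  ly <- new.env(); ly$params <- list()
  cache <- new.env(parent = emptyenv())
  ly$fwd <- function(x, train = TRUE) {
    y <- 1 / (1 + exp(-x))
    if (train) cache$y <- y
    y
  }
  ly$bwd <- function(dy) dy * cache$y * (1 - cache$y)
  ly
}

nn_linear <- function(nin, nout, init_gain = 1) {
  ly <- new.env()
  ly$W <- nn_param(matrix(stats::rnorm(nin * nout, 0, init_gain * sqrt(2 / nin)),
                          nin, nout))
  ly$b <- nn_param(rep(0, nout))
  ly$params <- list(ly$W, ly$b)
  cache <- new.env(parent = emptyenv())
  ly$fwd <- function(x, train = TRUE) {
    x <- matrix(x, nrow = if (is.matrix(x)) nrow(x) else 1)
    if (train) cache$x <- x
    sweep(x %*% ly$W$val, 2, ly$b$val, `+`)
  }
  ly$bwd <- function(dy) {
    dy <- matrix(dy, nrow = nrow(cache$x))
    ly$W$grad <- ly$W$grad + crossprod(cache$x, dy)
    ly$b$grad <- ly$b$grad + colSums(dy)
    dy %*% t(ly$W$val)
  }
  ly
}

nn_seq <- function(...) {
  ly <- new.env()
  ly$layers <- list(...)
  ly$params <- do.call(c, c(lapply(ly$layers, function(l) l$params), list(list())))
  ly$fwd <- function(x, train = TRUE) {
    for (l in ly$layers) x <- l$fwd(x, train)
    x
  }
  ly$bwd <- function(dy) {
    for (l in rev(ly$layers)) dy <- l$bwd(dy)
    dy
  }
  ly
}

# Nearest / bilinear resize to a fixed output size, linear in the input.
nn_upsample <- function(out_h, out_w) {
  ly <- new.env(); ly$params <- list()
  cache <- new.env(parent = emptyenv())
  plan <- function(H, W) {
    sy <- H / out_h; sx <- W / out_w
    ys <- clamp((seq_len(out_h) - 0.5) * sy - 0.5, 0, H - 1)
    xs <- clamp((seq_len(out_w) - 0.5) * sx - 0.5, 0, W - 1)
    y0 <- pmin(floor(ys), max(H - 2, 0)); x0 <- pmin(floor(xs), max(W - 2, 0))
    fy <- if (H == 1) rep(0, out_h) else ys - y0
    fx <- if (W == 1) rep(0, out_w) else xs - x0
    gy0 <- rep(y0 + 1, times = out_w); gfy <- rep(fy, times = out_w)
    gx0 <- rep(x0 + 1, each = out_h);  gfx <- rep(fx, each = out_h)
    i00 <- gy0 + H * (gx0 - 1)
    i10 <- pmin(gy0 + 1, H) + H * (gx0 - 1)
    i01 <- gy0 + H * (pmin(gx0, W - 1))
    i11 <- pmin(gy0 + 1, H) + H * (pmin(gx0, W - 1))
    list(i = cbind(i00, i10, i01, i11),
         w = cbind((1 - gfy) * (1 - gfx), gfy * (1 - gfx),
                   (1 - gfy) * gfx, gfy * gfx),
         H = H, W = W)
  }
  ly$fwd <- function(x, train = TRUE) {
    x <- .as_fmap(x)
    d <- dim(x)
    key <- paste(d[1], d[2])
    if (is.null(cache$key) || cache$key != key) {
      pl <- plan(d[1], d[2])
      # precompute grouped scatter plans for the backward pass
      pl$groups <- lapply(1:4, function(jj) {
        g <- pl$i[, jj]
        list(rows = sort(unique(g)), g = g)
      })
      cache$pl <- pl; cache$key <- key
    }
    pl <- cache$pl
    xm <- matrix(x, d[1] * d[2], d[3])
    out <- pl$w[, 1] * xm[pl$i[, 1], , drop = FALSE] +
      pl$w[, 2] * xm[pl$i[, 2], , drop = FALSE] +
      pl$w[, 3] * xm[pl$i[, 3], , drop = FALSE] +
      pl$w[, 4] * xm[pl$i[, 4], , drop = FALSE]
    cache$C <- d[3]
    array(out, dim = c(out_h, out_w, d[3]))
  }
  ly$bwd <- function(dy) {
    pl <- cache$pl
    dym <- matrix(dy, out_h * out_w, cache$C)
    dxm <- matrix(0, pl$H * pl$W, cache$C)
    for (jj in 1:4) {
      gp <- pl$groups[[jj]]
      rs <- rowsum(pl$w[, jj] * dym, gp$g, reorder = TRUE)
      dxm[gp$rows, ] <- dxm[gp$rows, , drop = FALSE] + rs
    }
    array(dxm, dim = c(pl$H, pl$W, cache$C))
  }
  ly
}

# RoI Align as a differentiable layer; gradient flows to the feature map
# (boxes are treated as constants, as in standard detector training).
# aligned = FALSE rounds sample coordinates to integers — the quantized
# pooling used by the no-alignment ablation.
nn_roi_align <- function(out_size = c(7L, 7L), samples_per_bin = 4L,
                         aligned = TRUE) {
  ly <- new.env(); ly$params <- list()
  cache <- new.env(parent = emptyenv())
  ly$fwd <- function(x, box, train = TRUE) {
    x <- .as_fmap(x)
    d <- dim(x)
    pl <- .roi_align_plan(d[1], d[2], box, out_size, samples_per_bin,
                          aligned = aligned)
    H <- d[1]; W <- d[2]
    xq <- clamp(pl$x, 0, W - 1); yq <- clamp(pl$y, 0, H - 1)
    x0 <- pmin(floor(xq), max(W - 2, 0)); y0 <- pmin(floor(yq), max(H - 2, 0))
    fx <- if (W == 1) rep(0, length(xq)) else xq - x0
    fy <- if (H == 1) rep(0, length(yq)) else yq - y0
    iw <- list(i = cbind((y0 + 1) + H * x0,
                         pmin(y0 + 2, H) + H * x0,
                         (y0 + 1) + H * pmin(x0 + 1, W - 1),
                         pmin(y0 + 2, H) + H * pmin(x0 + 1, W - 1)),
               w = cbind((1 - fy) * (1 - fx), fy * (1 - fx),
                         (1 - fy) * fx, fy * fx))
    s <- pl$s; ns <- s * s
    # sample row r (ordered sub_row, bin_row, sub_col, bin_col) -> bin index
    nsmp <- length(xq)
    sub_r <- ((seq_len(nsmp) - 1) %% s)
    bin_r <- (((seq_len(nsmp) - 1) %/% s) %% pl$oh)
    bin_c <- ((seq_len(nsmp) - 1) %/% (s * pl$oh * s))
    sb <- bin_r + pl$oh * bin_c + 1L
    xm <- matrix(x, H * W, d[3])
    v <- iw$w[, 1] * xm[iw$i[, 1], , drop = FALSE] +
      iw$w[, 2] * xm[iw$i[, 2], , drop = FALSE] +
      iw$w[, 3] * xm[iw$i[, 3], , drop = FALSE] +
      iw$w[, 4] * xm[iw$i[, 4], , drop = FALSE]
    out <- rowsum(v, sb, reorder = TRUE) / ns
    if (train) { cache$iw <- iw; cache$pl <- pl; cache$d <- d; cache$sb <- sb }
    array(out, dim = c(pl$oh, pl$ow, d[3]))
  }
  ly$bwd <- function(dy) {
    pl <- cache$pl; iw <- cache$iw; d <- cache$d
    ns <- pl$s * pl$s
    dym <- matrix(dy, pl$oh * pl$ow, d[3])
    dv <- dym[cache$sb, , drop = FALSE] / ns
    dxm <- matrix(0, d[1] * d[2], d[3])
    for (jj in 1:4) {
      g <- iw$i[, jj]
      rows <- sort(unique(g))
      rs <- rowsum(iw$w[, jj] * dv, g, reorder = TRUE)
      dxm[rows, ] <- dxm[rows, , drop = FALSE] + rs
    }
    array(dxm, dim = d)
  }
  ly
}

# 2x2 stride-2 max pooling (used for the coarsest pyramid level).
nn_maxpool2 <- function() {
  ly <- new.env(); ly$params <- list()
  cache <- new.env(parent = emptyenv())
  ly$fwd <- function(x, train = TRUE) {
    x <- .as_fmap(x)
    d <- dim(x)
    Ho <- d[1] %/% 2L; Wo <- d[2] %/% 2L
    x <- x[seq_len(2 * Ho), seq_len(2 * Wo), , drop = FALSE]
    a <- x[seq(1, 2 * Ho, 2), seq(1, 2 * Wo, 2), , drop = FALSE]
    b <- x[seq(2, 2 * Ho, 2), seq(1, 2 * Wo, 2), , drop = FALSE]
    cc <- x[seq(1, 2 * Ho, 2), seq(2, 2 * Wo, 2), , drop = FALSE]
    dd <- x[seq(2, 2 * Ho, 2), seq(2, 2 * Wo, 2), , drop = FALSE]
    y <- pmax(a, b, cc, dd)
    if (train) {
      cache$d <- d; cache$which <- (a >= y) + 2 * (b >= y & a < y) +
        3 * (cc >= y & a < y & b < y) * 0  # placeholder, not used
      cache$parts <- list(a = a, b = b, cc = cc, dd = dd, y = y)
    }
    y
  }
  ly$bwd <- function(dy) {
    d <- cache$d; p <- cache$parts
    Ho <- dim(p$y)[1]; Wo <- dim(p$y)[2]
    dx <- array(0, dim = d)
    sel_a <- p$a == p$y
    sel_b <- p$b == p$y & !sel_a
    sel_c <- p$cc == p$y & !sel_a & !sel_b
    sel_d <- !(sel_a | sel_b | sel_c)
    dx[seq(1, 2 * Ho, 2), seq(1, 2 * Wo, 2), ] <- dy * sel_a
    dx[seq(2, 2 * Ho, 2), seq(1, 2 * Wo, 2), ] <-
      dx[seq(2, 2 * Ho, 2), seq(1, 2 * Wo, 2), , drop = FALSE] + dy * sel_b
    dx[seq(1, 2 * Ho, 2), seq(2, 2 * Wo, 2), ] <-
      dx[seq(1, 2 * Ho, 2), seq(2, 2 * Wo, 2), , drop = FALSE] + dy * sel_c
    dx[seq(2, 2 * Ho, 2), seq(2, 2 * Wo, 2), ] <-
      dx[seq(2, 2 * Ho, 2), seq(2, 2 * Wo, 2), , drop = FALSE] + dy * sel_d
    dx
  }
  ly
}

# Two-conv residual block with projection skip when shape changes.
nn_resblock <- function(Cin, Cout, stride = 1L) {
  ly <- new.env()
  ly$c1 <- nn_conv2d(Cin, Cout, k = 3L, stride = stride)
  ly$n1 <- nn_bn(Cout); ly$r1 <- nn_relu()
  ly$c2 <- nn_conv2d(Cout, Cout, k = 3L)
  ly$n2 <- nn_bn(Cout)
  ly$proj <- if (stride != 1L || Cin != Cout) nn_conv2d(Cin, Cout, k = 1L, stride = stride, pad = 0L) else NULL
  ly$rout <- nn_relu()
  ly$params <- c(ly$c1$params, ly$n1$params, ly$c2$params, ly$n2$params,
                 if (!is.null(ly$proj)) ly$proj$params)
  ly$fwd <- function(x, train = TRUE) {
    h <- ly$r1$fwd(ly$n1$fwd(ly$c1$fwd(x, train), train), train)
    h <- ly$n2$fwd(ly$c2$fwd(h, train), train)
    sk <- if (is.null(ly$proj)) x else ly$proj$fwd(x, train)
    ly$rout$fwd(h + sk, train)
  }
  ly$bwd <- function(dy) {
    dsum <- ly$rout$bwd(dy)
    dh <- ly$c2$bwd(ly$n2$bwd(dsum))
    dh <- ly$c1$bwd(ly$n1$bwd(ly$r1$bwd(dh)))
    dsk <- if (is.null(ly$proj)) dsum else ly$proj$bwd(dsum)
    dh + dsk
  }
  ly
}
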