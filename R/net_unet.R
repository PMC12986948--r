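## Hybrid window-attention / state-space denoising U-Net: configuration,
## initialization, batched forward pass and hand-written backward pass.
## Shallow and intermediate stages use (shifted-)window attention pairs;
## the deepest stage and the bottleneck use bidirectional state-space blocks.
## Conditions (voltage map, prior image) enter as input channels and are
## additionally fused into the decoder skips through gated fusion units.

#' Denoiser U-Net configuration
#'
#' @param res input resolution (image edge length).
#' @param in_ch input channels (noisy image + condition channels).
#' @param widths per-stage channel widths (stage s runs at res / 2^(s-1)).
#' @param types per-stage block type: `"swin"` or `"bimamba"`; state-space
#'   blocks are only allowed in the deepest two stages.
#' @param window per-stage attention window size (NA for bimamba stages);
#'   stage resolution must be at least twice the window.
#' @param heads per-stage attention head count.
#' @param temb_dim sinusoidal time-embedding width.
#' @param mlp_ratio hidden expansion of the per-token MLPs.
#' @param ssm_state state dimension per channel of the state-space blocks.
#' @param cond_channels number of spatial condition channels fused into the
#'   decoder (voltage map + prior image = 2).
#' @param mask_vol,mask_gn zero out the voltage / prior condition channel
#'   (the single-source ablations: data-constrained only, physics-guided
#'   only, or the full multi-source model).
#' @return a `unet_config` list.
#' @export
unet_config <- function(res = 32L, in_ch = 3L,
                        widths = c(32L, 64L, 128L),
                        types = c("swin", "swin", "bimamba"),
                        window = c(8L, 4L, NA),
                        heads = c(4L, 4L, NA),
                        temb_dim = 64L, mlp_ratio = 2, ssm_state = 4L,
                        cond_channels = 2L,
                        mask_vol = FALSE, mask_gn = FALSE) {
  S <- length(widths)
  stopifnot(length(types) == S, length(window) == S, length(heads) == S)
  for (s in seq_len(S)) {
    r <- res / 2^(s - 1)
    if (r != round(r)) stop("resolution not divisible across stages", call. = FALSE)
    if (types[s] == "swin") {
      if (is.na(window[s]) || r < 2 * window[s]) {
        stop("window stages need resolution >= 2 * window", call. = FALSE)
      }
      if (r %% window[s] != 0) stop("window must divide stage resolution", call. = FALSE)
    } else if (types[s] == "bimamba") {
      if (s < S - 1) stop("state-space blocks only in the deepest two stages",
                          call. = FALSE)
    } else stop("unknown block type", call. = FALSE)
  }
  structure(list(res = res, in_ch = in_ch, widths = widths, types = types,
                 window = window, heads = heads, temb_dim = temb_dim,
                 mlp_ratio = mlp_ratio, ssm_state = ssm_state,
                 cond_channels = cond_channels,
                 mask_vol = mask_vol, mask_gn = mask_gn, n_stages = S),
            class = "unet_config")
}

## tiny preset used throughout the scaled-down experiments
#' @rdname unet_config
#' @export
unet_config_tiny <- function(...) {
  unet_config(res = 32L, in_ch = 3L, widths = c(24L, 48L, 96L),
              types = c("swin", "swin", "bimamba"),
              window = c(4L, 4L, NA), heads = c(4L, 4L, NA), ...)
}

.rnm <- function(n, m, sd = 0.02) matrix(stats::rnorm(n * m, sd = sd), n, m)

.swin_block_init <- function(C, M, heads, temb_dim, mlp_ratio, shift) {
  rC <- as.integer(mlp_ratio * C)
  list(type = "swin", shift = shift, M = M,
       ln1 = list(g = rep(1, C), b = numeric(C)),
       tW = .rnm(temb_dim, C), tb = numeric(C),
       attn = attention_params_init(C, M, heads,
                                    seed = sample.int(1e8, 1)),
       ln2 = list(g = rep(1, C), b = numeric(C)),
       mlp = list(W1 = .rnm(C, rC), b1 = numeric(rC),
                  W2 = matrix(0, rC, C), b2 = numeric(C)))
}

.bimamba_block_init <- function(C, N, temb_dim, mlp_ratio) {
  rC <- as.integer(mlp_ratio * C)
  list(type = "bimamba",
       ln1 = list(g = rep(1, C), b = numeric(C)),
       tW = .rnm(temb_dim, C), tb = numeric(C),
       Win = .rnm(C, C) + diag(C), bin = numeric(C),
       ssm_f = ssm_params_init(C, N, seed = sample.int(1e8, 1)),
       ssm_b = ssm_params_init(C, N, seed = sample.int(1e8, 1)),
       W_fuse = matrix(0, 2 * C, C), b_fuse = numeric(C),
       ln2 = list(g = rep(1, C), b = numeric(C)),
       mlp = list(W1 = .rnm(C, rC), b1 = numeric(rC),
                  W2 = matrix(0, rC, C), b2 = numeric(C)))
}

.stage_blocks_init <- function(cfg, s) {
  C <- cfg$widths[s]
  if (cfg$types[s] == "swin") {
    list(.swin_block_init(C, cfg$window[s], cfg$heads[s], cfg$temb_dim,
                          cfg$mlp_ratio, shift = 0L),
         .swin_block_init(C, cfg$window[s], cfg$heads[s], cfg$temb_dim,
                          cfg$mlp_ratio, shift = cfg$window[s] %/% 2L))
  } else {
    list(.bimamba_block_init(C, cfg$ssm_state, cfg$temb_dim, cfg$mlp_ratio))
  }
}

#' Initialize U-Net weights
#'
#' All residual-branch output projections (attention output, MLP second
#' layer, scan fusion, gated-fusion projection, prediction head) start at
#' zero, so the freshly initialized network computes a zero noise estimate
#' and every residual block is the identity - a stable starting point for
#' diffusion training.
#'
#' @param cfg a `unet_config`.
#' @param seed integer seed.
#' @return nested parameter list (class `unet_params`).
#' @export
unet_init <- function(cfg, seed = 1L) {
  with_seed(seed, {
    S <- cfg$n_stages
    W <- cfg$widths
    p <- list(
      stem = list(W = .rnm(cfg$in_ch, W[1], sd = 0.2), b = numeric(W[1])),
      temb = list(W1 = .rnm(cfg$temb_dim, cfg$temb_dim), b1 = numeric(cfg$temb_dim),
                  W2 = .rnm(cfg$temb_dim, cfg$temb_dim), b2 = numeric(cfg$temb_dim)),
      enc = lapply(seq_len(S), function(s) .stage_blocks_init(cfg, s)),
      down = lapply(seq_len(S - 1), function(s) {
        list(W = .rnm(4 * W[s], W[s + 1]), b = numeric(W[s + 1]))
      }),
      bott = .stage_blocks_init(cfg, S),
      up = lapply(seq_len(S - 1), function(s) {
        list(W = .rnm(W[s + 1], 4 * W[s]), b = numeric(4 * W[s]))
      }),
      fuse = lapply(seq_len(S - 1), function(s) {
        gated_fuse_init(W[s], W[s] + cfg$cond_channels,
                        seed = sample.int(1e8, 1))
      }),
      dec = lapply(seq_len(S - 1), function(s) .stage_blocks_init(cfg, s)),
      head = list(ln = list(g = rep(1, W[1]), b = numeric(W[1])),
                  W = matrix(0, W[1], 1), b = numeric(1))
    )
    class(p) <- "unet_params"
    p
  })
}

#' Total number of trainable scalars in a parameter tree
#' @param params nested list of numeric arrays.
#' @return integer count.
#' @export
param_count <- function(params) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else if (is.numeric(x)) n <<- n + length(x)
    invisible(NULL)
  }
  walk(params)
  n
}

## ---- block forward/backward -------------------------------------------------

.broadcast_rows <- function(n, B) rep_len(seq_len(B), n)

.block_fwd <- function(x, blk, temb, train) {
  d <- dim(x); B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  n <- B * H * W
  X2 <- x; dim(X2) <- c(n, C)
  ln1 <- layernorm_fwd(X2, blk$ln1$g, blk$ln1$b)
  ts <- temb %*% blk$tW + rep(blk$tb, each = B)
  h1 <- ln1$out + ts[.broadcast_rows(n, B), , drop = FALSE]
  if (blk$type == "swin") {
    Zh <- h1; dim(Zh) <- d
    wt <- window_partition(Zh, blk$M, blk$shift)
    at <- window_attention(wt, blk$attn, train)
    y <- window_reverse(at$out)
    x2 <- x + y
    branch_cache <- list(attn = at$cache)
  } else {
    Zs <- h1; dim(Zs) <- d
    Zs <- aperm(Zs, c(3, 2, 1, 4))          # row-major sequence, w fastest
    dim(Zs) <- c(W * H, B, C)
    u2 <- Zs; dim(u2) <- c(W * H * B, C)
    upre <- linear_fwd(u2, blk$Win, blk$bin)
    uact <- gelu(upre)
    dim(uact) <- c(W * H, B, C)
    sc <- bimamba_scan(uact, blk$ssm_f, blk$ssm_b, blk$W_fuse, blk$b_fuse, train)
    yb <- sc$out
    dim(yb) <- c(W, H, B, C)
    yb <- aperm(yb, c(3, 2, 1, 4))
    x2 <- x + yb
    branch_cache <- list(u2 = u2, upre = upre, scan = sc$cache)
  }
  X22 <- x2; dim(X22) <- c(n, C)
  ln2 <- layernorm_fwd(X22, blk$ln2$g, blk$ln2$b)
  hm <- linear_fwd(ln2$out, blk$mlp$W1, blk$mlp$b1)
  ha <- gelu(hm)
  m <- linear_fwd(ha, blk$mlp$W2, blk$mlp$b2)
  out <- X22 + m
  dim(out) <- d
  cache <- if (train) list(X2 = X2, ln1 = ln1, h1dim = d, branch = branch_cache,
                           X22 = X22, ln2 = ln2, hm = hm, ha = ha, temb = temb)
           else NULL
  list(out = out, cache = cache)
}

.block_bwd <- function(dout, cache, blk) {
  d <- cache$h1dim; B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  n <- B * H * W
  g <- list()
  dO <- dout; dim(dO) <- c(n, C)
  ## MLP sub-block
  lb2 <- linear_bwd(dO, cache$ha, blk$mlp$W2)
  dha <- lb2$dX
  dhm <- gelu_bwd(dha, cache$hm)
  lb1 <- linear_bwd(dhm, cache$ln2$out, blk$mlp$W1)
  lnb2 <- layernorm_bwd(lb1$dX, cache$ln2, blk$ln2$g)
  dx2 <- dO + lnb2$dX
  g$mlp <- list(W1 = lb1$dW, b1 = lb1$db, W2 = lb2$dW, b2 = lb2$db)
  g$ln2 <- list(g = lnb2$dg, b = lnb2$db)
  ## attention / scan branch
  if (blk$type == "swin") {
    dy <- dx2; dim(dy) <- d
    ## gradient through window_reverse = partition of dy with same layout
    dpart <- window_partition(dy, blk$M, blk$shift)
    ab <- window_attention_bwd(dpart$tokens, cache$branch$attn, blk$attn)
    g$attn <- ab$grads
    back <- cache$branch$attn$wt
    back$tokens <- ab$dtokens
    dh1 <- window_reverse(back)
    dim(dh1) <- c(n, C)
  } else {
    dy <- dx2; dim(dy) <- d
    dyb <- aperm(dy, c(3, 2, 1, 4))
    dim(dyb) <- c(W * H, B, C)
    sb <- bimamba_scan_bwd(dyb, cache$branch$scan, blk$ssm_f, blk$ssm_b,
                           blk$W_fuse)
    g$ssm_f <- sb$grads_f
    g$ssm_b <- sb$grads_b
    g$W_fuse <- sb$dW_fuse; g$b_fuse <- sb$db_fuse
    duact <- sb$dX; dim(duact) <- c(W * H * B, C)
    dupre <- gelu_bwd(duact, cache$branch$upre)
    li <- linear_bwd(dupre, cache$branch$u2, blk$Win)
    g$Win <- li$dW; g$bin <- li$db
    dZs <- li$dX; dim(dZs) <- c(W, H, B, C)
    dh1 <- aperm(dZs, c(3, 2, 1, 4))
    dim(dh1) <- c(n, C)
  }
  ## time-shift and first layernorm
  dts <- rowsum(dh1, .broadcast_rows(n, B))
  g$tW <- crossprod(cache$temb, dts)
  g$tb <- colSums(dts)
  dtemb <- dts %*% t(blk$tW)
  lnb1 <- layernorm_bwd(dh1, cache$ln1, blk$ln1$g)
  g$ln1 <- list(g = lnb1$dg, b = lnb1$db)
  dx <- dx2 + lnb1$dX
  dim(dx) <- d
  list(dx = dx, grads = g, dtemb = dtemb)
}

## ---- full U-Net --------------------------------------------------------------

#' Denoiser forward pass
#'
#' Predicts the diffusion noise from the noisy image, the diffusion step and
#' the spatial condition channels.  Input channel 1 is the noisy image x_t;
#' channels 2..in_ch are the condition maps (voltage encoding, then prior
#' image), which are also average-pooled to each decoder resolution and fused
#' into the skip connections through gated fusion units.  Condition masking
#' (ablation variants) zeroes the corresponding channel everywhere.
#'
#' @param params a `unet_params` tree.
#' @param cfg the matching `unet_config`.
#' @param x_in input array (B, res, res, in_ch).
#' @param t integer diffusion steps, length B (or scalar, recycled).
#' @param train keep caches for [unet_backward()].
#' @return list(out = (B, res, res, 1) noise estimate, cache).
#' @export
unet_forward <- function(params, cfg, x_in, t, train = FALSE) {
  d <- dim(x_in)
  if (length(d) != 4 || d[2] != cfg$res || d[3] != cfg$res || d[4] != cfg$in_ch) {
    stop("input shape does not match the network configuration", call. = FALSE)
  }
  B <- d[1]
  t <- rep_len(t, B)
  if (cfg$mask_vol) x_in[, , , 2] <- 0
  if (cfg$mask_gn && cfg$in_ch >= 3) x_in[, , , 3] <- 0
  cond <- x_in[, , , 1 + seq_len(cfg$cond_channels), drop = FALSE]

  te0 <- time_embedding(t, cfg$temb_dim)
  te1 <- linear_fwd(te0, params$temb$W1, params$temb$b1)
  tea <- gelu(te1)
  temb <- linear_fwd(tea, params$temb$W2, params$temb$b2)

  n <- B * cfg$res^2
  X2 <- x_in; dim(X2) <- c(n, cfg$in_ch)
  h <- linear_fwd(X2, params$stem$W, params$stem$b)
  dim(h) <- c(B, cfg$res, cfg$res, cfg$widths[1])

  S <- cfg$n_stages
  caches <- list(stem_X2 = X2, te0 = te0, te1 = te1, tea = tea,
                 enc = vector("list", S), down = vector("list", S - 1),
                 bott = NULL, up = vector("list", S - 1),
                 fuse = vector("list", S - 1), dec = vector("list", S - 1))
  skips <- vector("list", S)
  for (s in seq_len(S)) {
    bl_caches <- list()
    for (bi in seq_along(params$enc[[s]])) {
      r <- .block_fwd(h, params$enc[[s]][[bi]], temb, train)
      h <- r$out
      bl_caches[[bi]] <- r$cache
    }
    caches$enc[[s]] <- bl_caches
    skips[[s]] <- h
    if (s < S) {
      hs <- space_to_depth(h)
      dd <- dim(hs)
      h2 <- hs; dim(h2) <- c(prod(dd[1:3]), dd[4])
      caches$down[[s]] <- list(X = h2)
      h <- linear_fwd(h2, params$down[[s]]$W, params$down[[s]]$b)
      dim(h) <- c(B, dd[2], dd[3], cfg$widths[s + 1])
    }
  }
  bl_caches <- list()
  for (bi in seq_along(params$bott)) {
    r <- .block_fwd(h, params$bott[[bi]], temb, train)
    h <- r$out
    bl_caches[[bi]] <- r$cache
  }
  caches$bott <- bl_caches

  for (s in rev(seq_len(S - 1))) {
    dd <- dim(h)
    h2 <- h; dim(h2) <- c(prod(dd[1:3]), dd[4])
    caches$up[[s]] <- list(X = h2)
    hu <- linear_fwd(h2, params$up[[s]]$W, params$up[[s]]$b)
    dim(hu) <- c(B, dd[2], dd[3], 4L * cfg$widths[s])
    h <- depth_to_space(hu)
    pooled <- if (s == 1) cond else avg_pool2(cond, 2L^(s - 1))
    cc <- array(0, c(dim(skips[[s]])[1:3], cfg$widths[s] + cfg$cond_channels))
    cc[, , , seq_len(cfg$widths[s])] <- skips[[s]]
    cc[, , , cfg$widths[s] + seq_len(cfg$cond_channels)] <- pooled
    fz <- gated_fuse(h, cc, params$fuse[[s]], train)
    h <- fz$out
    caches$fuse[[s]] <- fz$cache
    bl_caches <- list()
    for (bi in seq_along(params$dec[[s]])) {
      r <- .block_fwd(h, params$dec[[s]][[bi]], temb, train)
      h <- r$out
      bl_caches[[bi]] <- r$cache
    }
    caches$dec[[s]] <- bl_caches
  }

  H2 <- h; dim(H2) <- c(n, cfg$widths[1])
  lnh <- layernorm_fwd(H2, params$head$ln$g, params$head$ln$b)
  out <- linear_fwd(lnh$out, params$head$W, params$head$b)
  dim(out) <- c(B, cfg$res, cfg$res, 1L)
  cache <- if (train) c(caches, list(H2 = H2, lnh = lnh, B = B)) else NULL
  list(out = out, cache = cache)
}

#' Denoiser backward pass
#'
#' Backpropagates a gradient with respect to the noise estimate through the
#' whole network, returning gradients for every parameter and for the input
#' channels (so the upstream voltage encoder can be trained jointly).
#'
#' @param params a `unet_params`.
#' @param cfg the `unet_config`.
#' @param dout gradient of the loss w.r.t. the network output (B, res, res, 1).
#' @param cache the cache returned by [unet_forward()] with `train = TRUE`.
#' @return list(dx_in, grads).
#' @export
unet_backward <- function(params, cfg, dout, cache) {
  B <- cache$B
  S <- cfg$n_stages
  n <- B * cfg$res^2
  g <- list(enc = vector("list", S), down = vector("list", S - 1),
            up = vector("list", S - 1), fuse = vector("list", S - 1),
            dec = vector("list", S - 1))
  dtemb_tot <- matrix(0, B, cfg$temb_dim)

  dO <- dout; dim(dO) <- c(n, 1L)
  lbh <- linear_bwd(dO, cache$lnh$out, params$head$W)
  lnbh <- layernorm_bwd(lbh$dX, cache$lnh, params$head$ln$g)
  g$head <- list(ln = list(g = lnbh$dg, b = lnbh$db), W = lbh$dW, b = lbh$db)
  dh <- lnbh$dX
  dim(dh) <- c(B, cfg$res, cfg$res, cfg$widths[1])

  dskips <- vector("list", S)
  dcond <- NULL
  for (s in seq_len(S - 1)) {
    for (bi in rev(seq_along(params$dec[[s]]))) {
      bb <- .block_bwd(dh, cache$dec[[s]][[bi]], params$dec[[s]][[bi]])
      dh <- bb$dx
      g$dec[[s]][[bi]] <- bb$grads
      dtemb_tot <- dtemb_tot + bb$dtemb
    }
    fb <- gated_fuse_bwd(dh, cache$fuse[[s]], params$fuse[[s]])
    g$fuse[[s]] <- fb$grads
    dskips[[s]] <- fb$dcond[, , , seq_len(cfg$widths[s]), drop = FALSE]
    dpool <- fb$dcond[, , , cfg$widths[s] + seq_len(cfg$cond_channels),
                      drop = FALSE]
    dcond_s <- if (s == 1) dpool else avg_pool2_bwd(dpool, 2L^(s - 1))
    dcond <- if (is.null(dcond)) dcond_s else dcond + dcond_s
    dhu <- space_to_depth(fb$dmain)      # gradient of depth_to_space
    dd <- dim(dhu)
    dhu2 <- dhu; dim(dhu2) <- c(prod(dd[1:3]), dd[4])
    lbu <- linear_bwd(dhu2, cache$up[[s]]$X, params$up[[s]]$W)
    g$up[[s]] <- list(W = lbu$dW, b = lbu$db)
    dh <- lbu$dX
    dim(dh) <- c(B, dd[2], dd[3], cfg$widths[s + 1])
  }

  for (bi in rev(seq_along(params$bott))) {
    bb <- .block_bwd(dh, cache$bott[[bi]], params$bott[[bi]])
    dh <- bb$dx
    g$bott[[bi]] <- bb$grads
    dtemb_tot <- dtemb_tot + bb$dtemb
  }

  for (s in rev(seq_len(S))) {
    if (s < S) {
      dd <- dim(dh)
      dh2 <- dh; dim(dh2) <- c(prod(dd[1:3]), dd[4])
      lbd <- linear_bwd(dh2, cache$down[[s]]$X, params$down[[s]]$W)
      g$down[[s]] <- list(W = lbd$dW, b = lbd$db)
      dhs <- lbd$dX
      dim(dhs) <- c(B, dd[2], dd[3], 4L * cfg$widths[s])
      dh <- depth_to_space(dhs)          # gradient of space_to_depth
    }
    if (!is.null(dskips[[s]])) dh <- dh + dskips[[s]]
    for (bi in rev(seq_along(params$enc[[s]]))) {
      bb <- .block_bwd(dh, cache$enc[[s]][[bi]], params$enc[[s]][[bi]])
      dh <- bb$dx
      g$enc[[s]][[bi]] <- bb$grads
      dtemb_tot <- dtemb_tot + bb$dtemb
    }
  }

  dh2 <- dh; dim(dh2) <- c(n, cfg$widths[1])
  lbs <- linear_bwd(dh2, cache$stem_X2, params$stem$W)
  g$stem <- list(W = lbs$dW, b = lbs$db)
  dx_in <- lbs$dX
  dim(dx_in) <- c(B, cfg$res, cfg$res, cfg$in_ch)
  dx_in[, , , 1 + seq_len(cfg$cond_channels)] <-
    dx_in[, , , 1 + seq_len(cfg$cond_channels), drop = FALSE] + dcond

  ## time-embedding MLP
  dte <- dtemb_tot
  lbt2 <- linear_bwd(dte, cache$tea, params$temb$W2)
  dtea <- gelu_bwd(lbt2$dX, cache$te1)
  lbt1 <- linear_bwd(dtea, cache$te0, params$temb$W1)
  g$temb <- list(W1 = lbt1$dW, b1 = lbt1$db, W2 = lbt2$dW, b2 = lbt2$db)

  if (cfg$mask_vol) dx_in[, , , 2] <- 0
  if (cfg$mask_gn && cfg$in_ch >= 3) dx_in[, , , 3] <- 0
  list(dx_in = dx_in, grads = g)
}

## ---- parameter-tree arithmetic (for the optimizer) ---------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    out
  } else if (is.numeric(a)) f(a, b) else a
}

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, tree_map, f = f)
  else if (is.numeric(a)) f(a) else a
}

tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)
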