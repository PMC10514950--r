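# Declarative network graphs for the built-in engine.
#
# A graph is built as a flat list of nodes in topological order; every
# trainable tensor is assigned an offset into one flat parameter vector
# and every batch-norm layer an offset into a flat running-statistics
# vector.  The encoder definitions mirror the torchvision ResNet-34/50
# and DenseNet-121 feature extractors; the decoder definitions mirror the
# U-Net / U-Net++ / DeepLabV3(+) heads of the segmentation-models family,
# so that full-width trainable-parameter counts are reproduced exactly.

graph_new <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$ch <- integer()       # channels per node
  g$n_params <- 0
  g$n_state <- 0
  g$shapes <- list()      # one entry per parameter block
  g
}

g_push <- function(g, node, channels) {
  g$nodes[[length(g$nodes) + 1L]] <- node
  g$ch[length(g$nodes)] <- as.integer(channels)
  length(g$nodes)
}

g_input <- function(g, channels = 3L) {
  g_push(g, list(op = "input"), channels)
}

g_conv <- function(g, input, cout, k, stride = 1L, dil = 1L,
                   pad = ((k - 1L) %/% 2L) * dil, bias = FALSE,
                   name = "conv") {
  cin <- g$ch[input]
  off <- g$n_params
  nw <- cin * k * k * cout
  g$n_params <- g$n_params + nw
  offb <- -1
  if (bias) {
    offb <- g$n_params
    g$n_params <- g$n_params + cout
  }
  g$shapes[[length(g$shapes) + 1L]] <- list(
    name = name, type = "conv", cin = cin, cout = cout, k = k,
    off = off, offb = offb, n = nw + if (bias) cout else 0L)
  g_push(g, list(op = "conv", in_ = input, k = as.integer(k),
                 stride = as.integer(stride), pad = as.integer(pad),
                 dil = as.integer(dil), cin = cin, cout = as.integer(cout),
                 bias = bias, off = off, offb = offb), cout)
}

g_bn <- function(g, input, name = "bn") {
  c <- g$ch[input]
  off <- g$n_params
  g$n_params <- g$n_params + 2L * c
  soff <- g$n_state
  g$n_state <- g$n_state + 2L * c
  g$shapes[[length(g$shapes) + 1L]] <- list(
    name = name, type = "bn", c = c, off = off, soff = soff, n = 2L * c)
  g_push(g, list(op = "bn", in_ = input, c = c, off = off, soff = soff), c)
}

g_relu <- function(g, input) g_push(g, list(op = "relu", in_ = input), g$ch[input])

g_maxpool <- function(g, input, k = 3L, stride = 2L, pad = 1L) {
  g_push(g, list(op = "maxpool", in_ = input, k = as.integer(k),
                 stride = as.integer(stride), pad = as.integer(pad)),
         g$ch[input])
}

g_avgpool <- function(g, input, k = 2L, stride = 2L) {
  g_push(g, list(op = "avgpool", in_ = input, k = as.integer(k),
                 stride = as.integer(stride)), g$ch[input])
}

g_gavgpool <- function(g, input) {
  g_push(g, list(op = "gavgpool", in_ = input), g$ch[input])
}

g_upnn <- function(g, input, f = 2L) {
  g_push(g, list(op = "upnn", in_ = input, f = as.integer(f)), g$ch[input])
}

g_upbil <- function(g, input, f) {
  g_push(g, list(op = "upbil", in_ = input, f = as.integer(f)), g$ch[input])
}

g_concat <- function(g, inputs) {
  g_push(g, list(op = "concat", in_ = as.integer(inputs)),
         sum(g$ch[inputs]))
}

g_add2 <- function(g, a, b) {
  stopifnot(g$ch[a] == g$ch[b])
  g_push(g, list(op = "add", in_ = c(a, b)), g$ch[a])
}

g_bcast <- function(g, input, ref) {
  g_push(g, list(op = "bcast", in_ = c(input, ref)), g$ch[input])
}

g_finalize <- function(g) {
  nodes <- lapply(g$nodes, function(n) {
    names(n)[names(n) == "in_"] <- "in"
    n
  })
  list(nodes = nodes, n_params = g$n_params, n_state = g$n_state,
       shapes = g$shapes)
}

# conv-bn-relu shorthand
g_cbr <- function(g, input, cout, k, stride = 1L, dil = 1L,
                  pad = ((k - 1L) %/% 2L) * dil, name = "cbr") {
  x <- g_conv(g, input, cout, k, stride = stride, dil = dil, pad = pad,
              name = name)
  x <- g_bn(g, x, name = name)
  g_relu(g, x)
}

scaled <- function(x, mult) max(1L, as.integer(round(x * mult)))

# ---- encoders ------------------------------------------------------------

# ResNet-34/50 feature extractor.  `dilated` controls whether the stride of
# stage 4 / stage 5 is replaced by dilation (output stride 16 or 8), as the
# DeepLabV3 family requires.  Returns the six stage-output node ids
# (identity, /2, /4, /8 or dilated equivalents ...).
enc_resnet <- function(g, input, depth = 34L, width_mult = 1,
                       dilated = c(FALSE, FALSE)) {
  w <- function(x) scaled(x, width_mult)
  bottleneck <- depth >= 50L
  nblocks <- c(3L, 4L, 6L, 3L)
  planes <- c(w(64), w(128), w(256), w(512))
  expansion <- if (bottleneck) 4L else 1L

  x <- g_conv(g, input, w(64), 7L, stride = 2L, pad = 3L, name = "stem")
  x <- g_bn(g, x, "stem")
  s1 <- g_relu(g, x)
  x <- g_maxpool(g, s1, 3L, 2L, 1L)

  basic_block <- function(x, pl, stride, dil) {
    ident <- x
    if (stride != 1L || g$ch[x] != pl) {
      d <- g_conv(g, x, pl, 1L, stride = stride, pad = 0L, name = "down")
      ident <- g_bn(g, d, "down")
    }
    y <- g_cbr(g, x, pl, 3L, stride = stride, dil = dil, name = "block")
    y <- g_conv(g, y, pl, 3L, dil = dil, name = "block")
    y <- g_bn(g, y, "block")
    g_relu(g, g_add2(g, y, ident))
  }
  bottle_block <- function(x, pl, stride, dil) {
    out <- pl * 4L
    ident <- x
    if (stride != 1L || g$ch[x] != out) {
      d <- g_conv(g, x, out, 1L, stride = stride, pad = 0L, name = "down")
      ident <- g_bn(g, d, "down")
    }
    y <- g_cbr(g, x, pl, 1L, pad = 0L, name = "block")
    y <- g_cbr(g, y, pl, 3L, stride = stride, dil = dil, name = "block")
    y <- g_conv(g, y, out, 1L, pad = 0L, name = "block")
    y <- g_bn(g, y, "block")
    g_relu(g, g_add2(g, y, ident))
  }
  block <- if (bottleneck) bottle_block else basic_block

  stages <- integer(4)
  dil <- 1L
  for (li in 1:4) {
    stride <- if (li == 1L) 1L else 2L
    if (li == 3L && dilated[1]) { dil <- dil * stride; stride <- 1L }
    if (li == 4L && dilated[2]) { dil <- dil * stride; stride <- 1L }
    for (bi in seq_len(nblocks[li])) {
      x <- block(x, planes[li], if (bi == 1L) stride else 1L, dil)
    }
    stages[li] <- x
  }
  list(stages = c(input, s1, stages),
       channels = c(g$ch[input], g$ch[s1], planes * expansion))
}

# DenseNet-121 feature extractor (growth 32, bn_size 4, blocks 6/12/24/16).
enc_densenet121 <- function(g, input, width_mult = 1) {
  init <- scaled(64, width_mult)
  growth <- scaled(32, width_mult)
  bn_size <- 4L
  blocks <- c(6L, 12L, 24L, 16L)

  x <- g_conv(g, input, init, 7L, stride = 2L, pad = 3L, name = "stem")
  x <- g_bn(g, x, "stem")
  s1 <- g_relu(g, x)
  x <- g_maxpool(g, s1, 3L, 2L, 1L)

  dense_layer <- function(x) {
    y <- g_bn(g, x, "dense")
    y <- g_relu(g, y)
    y <- g_conv(g, y, bn_size * growth, 1L, pad = 0L, name = "dense")
    y <- g_bn(g, y, "dense")
    y <- g_relu(g, y)
    y <- g_conv(g, y, growth, 3L, name = "dense")
    g_concat(g, c(x, y))
  }
  transition <- function(x) {
    y <- g_bn(g, x, "trans")
    y <- g_relu(g, y)
    y <- g_conv(g, y, g$ch[x] %/% 2L, 1L, pad = 0L, name = "trans")
    g_avgpool(g, y, 2L, 2L)
  }

  stages <- integer(4)
  for (bi in 1:4) {
    for (li in seq_len(blocks[bi])) x <- dense_layer(x)
    stages[bi] <- x
    if (bi < 4L) x <- transition(x)
  }
  x <- g_bn(g, stages[4], "norm5")
  s5 <- g_relu(g, x)
  stages[4] <- s5
  list(stages = c(input, s1, stages),
       channels = g$ch[c(input, s1, stages)])
}

# ---- decoders ------------------------------------------------------------

# one U-Net decoder block: x2 nearest upsample, concat skip, two 3x3
# conv-bn-relu stages
dec_block <- function(g, input, skip, cout) {
  x <- g_upnn(g, input, 2L)
  if (!is.na(skip)) x <- g_concat(g, c(x, skip))
  x <- g_cbr(g, x, cout, 3L, name = "dec")
  g_cbr(g, x, cout, 3L, name = "dec")
}

dec_unet <- function(g, enc, dec_ch) {
  st <- enc$stages
  x <- st[6]
  skips <- c(st[5], st[4], st[3], st[2], NA)
  for (i in seq_along(dec_ch)) x <- dec_block(g, x, skips[i], dec_ch[i])
  g_conv(g, x, 1L, 3L, bias = TRUE, name = "head")
}

dec_unetpp <- function(g, enc, dec_ch) {
  st <- enc$stages
  feat <- rev(st[2:6])                    # feat[1] deepest .. feat[5] earliest
  enc_ch <- rev(enc$channels[2:6])
  in_ch <- c(enc_ch[1], dec_ch[1:4])
  skip_ch <- c(enc_ch[2:5], 0L)
  X <- matrix(NA_integer_, nrow = 5, ncol = 5)  # X[d+1, l+1]

  for (l in 0:3) {
    for (d in l:0) {
      if (d == l) {
        X[d + 1, l + 1] <- dec_block(g, feat[d + 1], feat[d + 2],
                                     if (l == 0) dec_ch[1] else skip_ch[l + 1])
      } else {
        upstream <- X[d + 1, l]           # same depth, previous column
        others <- X[(d + 2):(l + 1), l + 1]
        skip <- g_concat(g, c(others, feat[l + 2]))
        X[d + 1, l + 1] <- dec_block(g, upstream, skip,
                                     if (d == 0) dec_ch[l + 1] else skip_ch[l + 1])
      }
    }
  }
  final <- dec_block(g, X[1, 4], NA, dec_ch[5])
  g_conv(g, final, 1L, 3L, bias = TRUE, name = "head")
}

# depthwise 3x3 + pointwise 1x1 (separable convolution), no biases
g_dwconv <- function(g, input, k, stride = 1L, dil = 1L,
                     pad = ((k - 1L) %/% 2L) * dil, name = "dwconv") {
  c <- g$ch[input]
  off <- g$n_params
  g$n_params <- g$n_params + k * k * c
  g$shapes[[length(g$shapes) + 1L]] <- list(
    name = name, type = "dwconv", c = c, k = k, off = off, n = k * k * c)
  g_push(g, list(op = "dwconv", in_ = input, k = as.integer(k),
                 stride = as.integer(stride), pad = as.integer(pad),
                 dil = as.integer(dil), c = c, off = off), c)
}

# separable conv-bn-relu: depthwise kxk then pointwise 1x1, one batch norm
g_sep_cbr <- function(g, input, cout, k = 3L, dil = 1L, name = "sep") {
  x <- g_dwconv(g, input, k, dil = dil, name = name)
  x <- g_conv(g, x, cout, 1L, pad = 0L, name = name)
  x <- g_bn(g, x, name)
  g_relu(g, x)
}

# atrous spatial pyramid pooling head (1x1 branch, three dilated 3x3
# branches -- separable in the DeepLabV3+ variant -- a global-pooling
# branch, and a 1x1 projection)
dec_aspp <- function(g, input, cout, rates = c(12L, 24L, 36L),
                     separable = FALSE) {
  b1 <- g_cbr(g, input, cout, 1L, pad = 0L, name = "aspp")
  bs <- vapply(rates, function(r) {
    if (separable) g_sep_cbr(g, input, cout, 3L, dil = r, name = "aspp")
    else g_cbr(g, input, cout, 3L, dil = r, name = "aspp")
  }, integer(1))
  gp <- g_gavgpool(g, input)
  gp <- g_cbr(g, gp, cout, 1L, pad = 0L, name = "aspp_pool")
  gp <- g_bcast(g, gp, input)
  x <- g_concat(g, c(b1, bs, gp))
  g_cbr(g, x, cout, 1L, pad = 0L, name = "aspp_proj")
}

dec_deeplabv3 <- function(g, enc, cout) {
  x <- dec_aspp(g, enc$stages[6], cout)
  x <- g_cbr(g, x, cout, 3L, name = "dec")
  x <- g_conv(g, x, 1L, 1L, pad = 0L, bias = TRUE, name = "head")
  g_upbil(g, x, 8L)                        # encoder runs at output stride 8
}

dec_deeplabv3plus <- function(g, enc, cout, highres_ch) {
  x <- dec_aspp(g, enc$stages[6], cout, separable = TRUE)
  x <- g_sep_cbr(g, x, cout, 3L, name = "dec")
  x <- g_upbil(g, x, 4L)                   # encoder output stride 16 -> /4
  hr <- g_cbr(g, enc$stages[3], highres_ch, 1L, pad = 0L, name = "hr")
  x <- g_concat(g, c(x, hr))
  x <- g_sep_cbr(g, x, cout, 3L, name = "dec")
  x <- g_conv(g, x, 1L, 1L, pad = 0L, bias = TRUE, name = "head")
  g_upbil(g, x, 4L)
}

# ---- full architectures --------------------------------------------------

# Build the node graph for an architecture/encoder pair.  `width_mult`
# scales every channel width (0.25 for the tiny CPU variants).
build_arch_graph <- function(architecture, encoder, width_mult = 1) {
  g <- graph_new()
  input <- g_input(g, 3L)
  dilated <- switch(architecture,
    deeplabv3 = c(TRUE, TRUE),
    deeplabv3plus = c(FALSE, TRUE),
    c(FALSE, FALSE))
  enc <- switch(encoder,
    resnet34 = enc_resnet(g, input, 34L, width_mult, dilated),
    resnet50 = enc_resnet(g, input, 50L, width_mult, dilated),
    densenet121 = enc_densenet121(g, input, width_mult),
    stop("unknown encoder: ", encoder))
  dec_ch <- vapply(c(256, 128, 64, 32, 16), scaled, integer(1),
                   mult = width_mult)
  switch(architecture,
    unet = dec_unet(g, enc, dec_ch),
    unetplusplus = dec_unetpp(g, enc, dec_ch),
    deeplabv3 = dec_deeplabv3(g, enc, scaled(256, width_mult)),
    deeplabv3plus = dec_deeplabv3plus(g, enc, scaled(256, width_mult),
                                      scaled(48, width_mult)),
    stop("unknown architecture: ", architecture))
  g_finalize(g)
}
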