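#' U-Net architecture configuration
#'
#' A 2D U-Net with `depth` contracting levels (each: two 3x3 convolutions,
#' each followed by batch normalization and ReLU, then 2x2 max pooling), a
#' bottleneck block, and `depth` expanding levels (2x2 up-convolution, skip
#' concatenation, two 3x3 conv + batch-norm + ReLU). Dropout is applied
#' after the second convolution of every block during training. The output
#' layer is a 1x1 convolution with either a sigmoid activation (one binary
#' region per model) or a softmax over `nClasses` channels (multiclass).
#'
#' @param inputSize input side length in pixels; must be divisible by
#'   `2^depth`.
#' @param depth number of pooling levels.
#' @param baseFilters channels at the first level; doubled per level.
#' @param dropoutRate dropout fraction in [0, 1).
#' @param head "sigmoid_binary" or "softmax_multiclass".
#' @param nClasses number of classes for the softmax head (including
#'   background; default 4 = background, lumen, wall, fat).
#' @return a list of class `UNetConfig`.
#' @export
unetConfig <- function(inputSize = 128L, depth = 4L, baseFilters = 16L,
                       dropoutRate = 0.2,
                       head = c("sigmoid_binary", "softmax_multiclass"),
                       nClasses = 4L) {
  head <- match.arg(head)
  assertThat(inputSize %% 2^depth == 0,
             "inputSize must be divisible by 2^depth")
  assertThat(dropoutRate >= 0 && dropoutRate < 1,
             "dropoutRate must lie in [0, 1)")
  if (head == "softmax_multiclass")
    assertThat(nClasses >= 2, "softmax head needs nClasses >= 2")
  structure(list(inputSize = as.integer(inputSize), depth = as.integer(depth),
                 baseFilters = as.integer(baseFilters),
                 dropoutRate = dropoutRate, head = head,
                 nClasses = as.integer(nClasses)),
            class = "UNetConfig")
}

# channel plan: level i has base * 2^(i-1) filters, bottleneck doubles again
.channelPlan <- function(config) {
  cs <- config$baseFilters * 2^(seq_len(config$depth) - 1)
  list(enc = cs, bottleneck = config$baseFilters * 2^config$depth,
       out = if (config$head == "softmax_multiclass") config$nClasses else 1L)
}

.heConv <- function(cin, cout) {
  matrix(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))), 9 * cin, cout)
}

#' Build an untrained U-Net
#'
#' Parameters are He-initialized from a seeded RNG; batch-norm scale/shift
#' start at 1/0 with unit running variance.
#'
#' @param config a [unetConfig()].
#' @param seed integer seed for the weight initialization.
#' @return an untrained [UNetModel-class].
#' @export
buildUNet <- function(config, seed = 1L) {
  plan <- .channelPlan(config)
  params <- list(); state <- list()
  addBN <- function(prefix, c) {
    params[[paste0(prefix, ".gamma")]] <<- rep(1, c)
    params[[paste0(prefix, ".beta")]] <<- rep(0, c)
    state[[paste0(prefix, ".mean")]] <<- rep(0, c)
    state[[paste0(prefix, ".var")]] <<- rep(1, c)
  }
  addBlock <- function(prefix, cin, cout) {
    params[[paste0(prefix, ".conv1.W")]] <<- .heConv(cin, cout)
    params[[paste0(prefix, ".conv1.b")]] <<- rep(0, cout)
    addBN(paste0(prefix, ".bn1"), cout)
    params[[paste0(prefix, ".conv2.W")]] <<- .heConv(cout, cout)
    params[[paste0(prefix, ".conv2.b")]] <<- rep(0, cout)
    addBN(paste0(prefix, ".bn2"), cout)
  }
  withSeed(seed, {
    cin <- 1L
    for (i in seq_len(config$depth)) {
      addBlock(paste0("enc", i), cin, plan$enc[i])
      cin <- plan$enc[i]
    }
    addBlock("bot", cin, plan$bottleneck)
    cin <- plan$bottleneck
    for (i in rev(seq_len(config$depth))) {
      cout <- plan$enc[i]
      params[[paste0("dec", i, ".up.W")]] <-
        matrix(rnorm(cin * 4 * cout, sd = sqrt(2 / cin)), cin, 4 * cout)
      params[[paste0("dec", i, ".up.b")]] <- rep(0, cout)
      addBlock(paste0("dec", i), 2L * cout, cout)
      cin <- cout
    }
    params[["out.W"]] <- matrix(rnorm(cin * plan$out, sd = sqrt(2 / cin)),
                                cin, plan$out)
    params[["out.b"]] <- rep(0, plan$out)
  })
  new("UNetModel", config = unclass(config), params = params, state = state,
      trained = FALSE)
}

#' Total number of trainable parameters
#'
#' Includes batch-norm scale/shift but not the running statistics.
#'
#' @param model a [UNetModel-class].
#' @return integer parameter count.
#' @export
countParams <- function(model) {
  sum(vapply(model@params, length, integer(1)))
}

## ---- layer primitives (R side) ----------------------------------------

.bnForward <- function(x, gamma, beta, rmean, rvar, training,
                       momentum = 0.1, eps = 1e-5) {
  out <- .bnForwardCpp(x, gamma, beta, rmean, rvar, training, momentum, eps)
  list(y = out$y, cache = list(xhat = out$xhat, invstd = out$invstd),
       mean = out$mean, var = out$var)
}

.bnBackward <- function(dy, cache, gamma) {
  out <- .bnBackwardCpp(dy, cache$xhat, cache$invstd, gamma, TRUE)
  list(dx = out$dx, dgamma = out$dgamma, dbeta = out$dbeta)
}

.blockForward <- function(x, params, state, prefix, training, dropout) {
  g <- function(s) params[[paste0(prefix, ".", s)]]
  st <- function(s) state[[paste0(prefix, ".", s)]]
  cache <- list(x = x)
  h1 <- .conv2dForward(x, g("conv1.W"), g("conv1.b"))
  bn1 <- .bnForward(h1, g("bn1.gamma"), g("bn1.beta"),
                    st("bn1.mean"), st("bn1.var"), training)
  r1 <- bn1$y > 0
  a1 <- bn1$y * r1
  h2 <- .conv2dForward(a1, g("conv2.W"), g("conv2.b"))
  bn2 <- .bnForward(h2, g("bn2.gamma"), g("bn2.beta"),
                    st("bn2.mean"), st("bn2.var"), training)
  r2 <- bn2$y > 0
  a2 <- bn2$y * r2
  drop <- NULL
  if (training && dropout > 0) {
    drop <- array((runif(length(a2)) >= dropout) / (1 - dropout), dim(a2))
    a2 <- a2 * drop
  }
  cache$bn1 <- bn1$cache; cache$r1 <- r1; cache$a1 <- a1
  cache$bn2 <- bn2$cache; cache$r2 <- r2; cache$drop <- drop
  list(y = a2, cache = cache,
       state = stats::setNames(list(bn1$mean, bn1$var, bn2$mean, bn2$var),
                               paste0(prefix, c(".bn1.mean", ".bn1.var",
                                                ".bn2.mean", ".bn2.var"))))
}

.blockBackward <- function(dy, params, prefix, cache, grads) {
  g <- function(s) params[[paste0(prefix, ".", s)]]
  put <- function(s, v) grads[[paste0(prefix, ".", s)]] <<- v
  if (!is.null(cache$drop)) dy <- dy * cache$drop
  dy <- dy * cache$r2
  bb2 <- .bnBackward(dy, cache$bn2, g("bn2.gamma"))
  put("bn2.gamma", bb2$dgamma); put("bn2.beta", bb2$dbeta)
  cb2 <- .conv2dBackward(cache$a1, g("conv2.W"), bb2$dx)
  put("conv2.W", cb2$dw); put("conv2.b", cb2$db)
  dy <- cb2$dx * cache$r1
  bb1 <- .bnBackward(dy, cache$bn1, g("bn1.gamma"))
  put("bn1.gamma", bb1$dgamma); put("bn1.beta", bb1$dbeta)
  cb1 <- .conv2dBackward(cache$x, g("conv1.W"), bb1$dx)
  put("conv1.W", cb1$dw); put("conv1.b", cb1$db)
  list(dx = cb1$dx, grads = grads)
}

.conv1x1Forward <- function(x, W, b) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  ym <- sweep(xm %*% W, 2, b, `+`)
  aperm(array(ym, c(d[1], d[2], d[4], ncol(W))), c(1, 2, 4, 3))
}

.conv1x1Backward <- function(x, W, dy) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = ncol(W))
  dxm <- dym %*% t(W)
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, dw = crossprod(xm, dym), db = colSums(dym))
}

# numerically stable softmax over the channel axis of (H, W, K, N)
.softmaxChannels <- function(z) {
  d <- dim(z)
  mx <- apply(z, c(1, 2, 4), max)
  expand <- function(m) aperm(array(m, c(d[1], d[2], d[4], d[3])),
                              c(1, 2, 4, 3))
  zs <- exp(z - expand(mx))
  zs / expand(apply(zs, c(1, 2, 4), sum))
}

.concatChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

## ---- full network forward / backward ----------------------------------

# Forward pass over a batch x (H, W, 1, N). Returns activations needed for
# the backward pass when training = TRUE, and updated batch-norm state.
.unetForward <- function(model, x, training = FALSE) {
  cfg <- model@config; p <- model@params; st <- model@state
  depth <- cfg$depth; drop <- cfg$dropoutRate
  caches <- list(); skips <- list(); pools <- list()
  newState <- list()
  cur <- x
  for (i in seq_len(depth)) {
    bf <- .blockForward(cur, p, st, paste0("enc", i), training, drop)
    newState <- c(newState, bf$state)
    skips[[i]] <- bf$y
    caches[[paste0("enc", i)]] <- bf$cache
    mp <- .maxpool2Forward(bf$y)
    pools[[i]] <- list(idx = mp$idx, xdim = dim(bf$y))
    cur <- mp$y
  }
  bf <- .blockForward(cur, p, st, "bot", training, drop)
  newState <- c(newState, bf$state)
  caches[["bot"]] <- bf$cache
  cur <- bf$y
  for (i in rev(seq_len(depth))) {
    up <- .upconv2Forward(cur, p[[paste0("dec", i, ".up.W")]],
                          p[[paste0("dec", i, ".up.b")]])
    caches[[paste0("dec", i, ".upin")]] <- cur
    cat <- .concatChannels(up, skips[[i]])
    bf <- .blockForward(cat, p, st, paste0("dec", i), training, drop)
    newState <- c(newState, bf$state)
    caches[[paste0("dec", i)]] <- bf$cache
    cur <- bf$y
  }
  z <- .conv1x1Forward(cur, p[["out.W"]], p[["out.b"]])
  caches[["head_in"]] <- cur
  if (cfg$head == "softmax_multiclass") {
    probs <- .softmaxChannels(z)
  } else {
    probs <- 1 / (1 + exp(-z))
  }
  list(probs = probs, caches = caches, pools = pools, state = newState,
       training = training)
}

# Backward pass from dL/dprobs (same shape as probs); returns gradient list.
.unetBackward <- function(model, fw, dprobs) {
  cfg <- model@config; p <- model@params
  depth <- cfg$depth
  probs <- fw$probs
  if (cfg$head == "softmax_multiclass") {
    s <- apply(dprobs * probs, c(1, 2, 4), sum)
    K <- dim(probs)[3]
    sFull <- aperm(array(s, c(dim(probs)[1], dim(probs)[2], dim(probs)[4],
                              K)), c(1, 2, 4, 3))
    dz <- probs * (dprobs - sFull)
  } else {
    dz <- dprobs * probs * (1 - probs)
  }
  grads <- list()
  dskips <- vector("list", depth)
  hb <- .conv1x1Backward(fw$caches[["head_in"]], p[["out.W"]], dz)
  grads[["out.W"]] <- hb$dw; grads[["out.b"]] <- hb$db
  dy <- hb$dx
  # decoder levels were applied depth..1 in the forward pass, so the
  # backward sweep visits dec1 first and ends at the bottleneck output
  for (i in seq_len(depth)) {
    bb <- .blockBackward(dy, p, paste0("dec", i),
                         fw$caches[[paste0("dec", i)]], grads)
    grads <- bb$grads
    dcat <- bb$dx
    coutUp <- ncol(p[[paste0("dec", i, ".up.W")]]) / 4
    dup <- dcat[, , seq_len(coutUp), , drop = FALSE]
    dskips[[i]] <- dcat[, , coutUp + seq_len(dim(dcat)[3] - coutUp), ,
                        drop = FALSE]
    ub <- .upconv2Backward(fw$caches[[paste0("dec", i, ".upin")]],
                           p[[paste0("dec", i, ".up.W")]], dup)
    grads[[paste0("dec", i, ".up.W")]] <- ub$dw
    grads[[paste0("dec", i, ".up.b")]] <- ub$db
    dy <- ub$dx
  }
  bb <- .blockBackward(dy, p, "bot", fw$caches[["bot"]], grads)
  grads <- bb$grads
  dy <- bb$dx
  for (i in rev(seq_len(depth))) {
    dpool <- .maxpool2Backward(fw$pools[[i]]$idx, dy, fw$pools[[i]]$xdim)
    dtot <- dpool + dskips[[i]]
    bb <- .blockBackward(dtot, p, paste0("enc", i),
                         fw$caches[[paste0("enc", i)]], grads)
    grads <- bb$grads
    dy <- bb$dx
  }
  grads
}

#' Run slice-wise inference
#'
#' Evaluation-mode forward passes (batch-norm uses running statistics,
#' dropout off) over a batch of slices, preserving order.
#'
#' @param model a [UNetModel-class].
#' @param slices 2D array (one slice), 3D array H x W x N, or list of 2D
#'   arrays, each matching the configured input size.
#' @param batchSize inference batch size.
#' @return list of [ProbabilityMap-class], one per slice.
#' @export
predictSlices <- function(model, slices, batchSize = 16L) {
  if (is.list(slices)) slices <- simplify2array(slices)
  if (length(dim(slices)) == 2) dim(slices) <- c(dim(slices), 1L)
  d <- dim(slices)
  cfg <- model@config
  assertThat(d[1] == cfg$inputSize && d[2] == cfg$inputSize,
             "slice shape does not match the configured input size")
  n <- d[3]
  if (n == 0) return(list())
  out <- vector("list", n)
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(n, start + batchSize - 1)
    x <- array(slices[, , idx], c(d[1], d[2], 1L, length(idx)))
    fw <- .unetForward(model, x, training = FALSE)
    for (j in seq_along(idx)) {
      v <- if (cfg$head == "softmax_multiclass")
        fw$probs[, , , j] else fw$probs[, , 1, j]
      out[[idx[j]]] <- new("ProbabilityMap", values = as.array(v),
                           head = if (cfg$head == "softmax_multiclass")
                             "softmax" else "sigmoid",
                           geometry = list(shape = d[1:2]))
    }
  }
  out
}
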