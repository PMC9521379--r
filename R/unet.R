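# Compact 2D U-Net with analytic gradients.
#
# Architecture per resolution level: two 3x3 "same" convolutions + ReLU,
# channel count doubling per level; 2x2 max pooling between encoder levels;
# 2x2 stride-2 transposed convolutions in the decoder followed by skip
# concatenation; a final 1x1 convolution to class scores and a softmax. In
# the Bayesian variant one (inverted) dropout layer sits before each max
# pooling and one after each up-convolution, so a depth-d network carries
# (d-1) dropout layers on each side.
#
# Convolution weights are stored as (k*k*Cin) x Cout matrices (rows ordered
# kh, kw, ci; identical to flattening an R array dim c(k, k, Cin, Cout)), and
# biases as length-Cout vectors. All heavy lifting happens in the C++ kernels.

.channelsPerLevel <- function(config)
  config@baseFilters * 2L^(seq_len(config@depth) - 1L)

# Table of conv-type layers: name, kernel, in/out channels.
.unetWeightSpec <- function(config) {
  ch <- .channelsPerLevel(config)
  d <- config@depth
  rows <- list()
  addConv <- function(name, k, ci, co)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, k = k, ci = ci, co = co, stringsAsFactors = FALSE)
  for (i in seq_len(d - 1L)) {
    ci <- if (i == 1L) config@inChannels else ch[i - 1L]
    addConv(sprintf("enc%d.c1", i), 3L, ci, ch[i])
    addConv(sprintf("enc%d.c2", i), 3L, ch[i], ch[i])
  }
  addConv("bot.c1", 3L, ch[d - 1L], ch[d])
  addConv("bot.c2", 3L, ch[d], ch[d])
  for (i in rev(seq_len(d - 1L))) {
    addConv(sprintf("dec%d.up", i), 2L, ch[i + 1L], ch[i])
    addConv(sprintf("dec%d.c1", i), 3L, 2L * ch[i], ch[i])
    addConv(sprintf("dec%d.c2", i), 3L, ch[i], ch[i])
  }
  addConv("out", 1L, ch[1L], config@nClasses)
  do.call(rbind, rows)
}

#' Number of trainable parameters of a U-Net configuration
#'
#' Deterministic in the configuration: the sum over all convolution layers of
#' `k^2 * Cin * Cout + Cout` (3x3 double-conv blocks, 2x2 up-convolutions,
#' and the final 1x1 classifier).
#'
#' @param config a [UNetConfig-class].
#' @return Integer parameter count.
#' @export
nParameters <- function(config) {
  spec <- .unetWeightSpec(config)
  as.integer(sum(spec$k^2 * spec$ci * spec$co + spec$co))
}

#' Sequential layer plan of the network
#'
#' Returns the full layer sequence (convolutions, ReLUs, dropout, pooling,
#' up-convolutions, concatenations, softmax) as a data.frame; used by the
#' dropout-placement audit and by tests.
#'
#' @param config a [UNetConfig-class].
#' @return data.frame with columns `name`, `type`, `stage`.
#' @export
unetLayerPlan <- function(config) {
  d <- config@depth
  hasDropout <- config@dropoutRate > 0 && config@dropoutMode != "off"
  rows <- list()
  add <- function(name, type, stage)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, type = type, stage = stage, stringsAsFactors = FALSE)
  for (i in seq_len(d - 1L)) {
    st <- sprintf("encoder%d", i)
    add(sprintf("enc%d.c1", i), "conv", st); add(sprintf("enc%d.relu1", i), "relu", st)
    add(sprintf("enc%d.c2", i), "conv", st); add(sprintf("enc%d.relu2", i), "relu", st)
    if (hasDropout) add(sprintf("enc%d.drop", i), "dropout", st)
    add(sprintf("enc%d.pool", i), "maxpool", st)
  }
  add("bot.c1", "conv", "bottleneck"); add("bot.relu1", "relu", "bottleneck")
  add("bot.c2", "conv", "bottleneck"); add("bot.relu2", "relu", "bottleneck")
  for (i in rev(seq_len(d - 1L))) {
    st <- sprintf("decoder%d", i)
    add(sprintf("dec%d.up", i), "upconv", st)
    if (hasDropout) add(sprintf("dec%d.drop", i), "dropout", st)
    add(sprintf("dec%d.concat", i), "concat", st)
    add(sprintf("dec%d.c1", i), "conv", st); add(sprintf("dec%d.relu1", i), "relu", st)
    add(sprintf("dec%d.c2", i), "conv", st); add(sprintf("dec%d.relu2", i), "relu", st)
  }
  add("out", "conv", "head"); add("softmax", "softmax", "head")
  do.call(rbind, rows)
}

#' Audit dropout placement
#'
#' Traverses the layer plan and reports, for every dropout layer, what it
#' immediately precedes or follows. In a valid Bayesian configuration each
#' encoder dropout directly precedes a max-pooling layer and each decoder
#' dropout directly follows an up-convolution.
#'
#' @param config a [UNetConfig-class].
#' @return data.frame with columns `name`, `stage`, `position`
#'   ("before_maxpool" / "after_upconv" / "other").
#' @export
auditDropoutPlacement <- function(config) {
  plan <- unetLayerPlan(config)
  idx <- which(plan$type == "dropout")
  if (!length(idx))
    return(data.frame(name = character(), stage = character(),
                      position = character(), stringsAsFactors = FALSE))
  position <- vapply(idx, function(i) {
    if (i < nrow(plan) && plan$type[i + 1L] == "maxpool") "before_maxpool"
    else if (i > 1L && plan$type[i - 1L] == "upconv") "after_upconv"
    else "other"
  }, character(1))
  data.frame(name = plan$name[idx], stage = plan$stage[idx],
             position = position, stringsAsFactors = FALSE)
}

#' Build an (untrained) U-Net
#'
#' Weights are drawn from zero-mean Gaussians with He scaling
#' (`sd = sqrt(2 / fan_in)`); biases start at zero. Deterministic given
#' `seed`.
#'
#' @param config a [UNetConfig-class].
#' @param seed initialization seed.
#' @return A [UNetModel-class] with fingerprint `(lambda = NA, seed,
#'   epochs = 0)`.
#' @examples
#' m <- buildUnet(unetConfig(depth = 3, baseFilters = 4), seed = 1)
#' nParameters(modelConfig(m))
#' @export
buildUnet <- function(config, seed = 1L) {
  validObject(config)
  spec <- .unetWeightSpec(config)
  weights <- .withSeed(seed, {
    out <- list()
    for (i in seq_len(nrow(spec))) {
      k <- spec$k[i]; ci <- spec$ci[i]; co <- spec$co[i]
      fanIn <- k * k * ci
      w <- matrix(stats::rnorm(fanIn * co, sd = sqrt(2 / fanIn)), fanIn, co)
      attr(w, "k") <- k
      out[[paste0(spec$name[i], ".w")]] <- w
      out[[paste0(spec$name[i], ".b")]] <- numeric(co)
    }
    out
  })
  new("UNetModel", weights = weights, config = config,
      fingerprint = list(lambda = NA_real_, seed = as.integer(seed),
                         epochs = 0L, lossHistory = numeric()))
}

.checkInputShape <- function(config, x) {
  d <- dim(x)
  if (length(d) == 2L) x <- array(x, dim = c(d, 1L))
  d <- dim(x)
  if (d[3] != config@inChannels)
    stop("image has ", d[3], " channel(s) but the model expects ",
         config@inChannels)
  div <- 2L^(config@depth - 1L)
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop("spatial shape ", d[1], "x", d[2], " must be divisible by 2^(depth-1) = ",
         div)
  x
}

# Core forward pass (single fused C++ call). dropoutActive toggles
# stochastic regularization; dropout masks draw from R's RNG stream.
.unetForward <- function(model, x, dropoutActive = FALSE) {
  cfg <- model@config
  .unetForwardCpp(model@weights, cfg@depth, cfg@dropoutRate, dropoutActive, x)
}

# Retained as a reference implementation: a plain-R forward pass mirroring
# the C++ engine layer by layer. Used by tests as an independent check of
# the fused kernel (deterministic path only).
.unetForwardR <- function(model, x, dropoutActive = FALSE, keepCache = FALSE) {
  cfg <- model@config
  w <- model@weights
  theta <- cfg@dropoutRate
  d <- cfg@depth
  cache <- new.env(parent = emptyenv())
  cache$skipChannels <- integer(d - 1L)

  conv <- function(name, inp, relu = TRUE) {
    wm <- w[[paste0(name, ".w")]]
    k <- attr(wm, "k")
    out <- .conv2dForward(inp, wm, w[[paste0(name, ".b")]], k, (k - 1L) %/% 2L)
    if (relu) out <- pmax(out, 0)
    if (keepCache) {
      cache[[paste0(name, ".in")]] <- inp
      if (relu) cache[[paste0(name, ".act")]] <- out
    }
    out
  }
  dropout <- function(name, inp) {
    if (!dropoutActive || theta <= 0) return(inp)
    keep <- array(stats::runif(length(inp)) >= theta, dim = dim(inp))
    if (keepCache) cache[[paste0(name, ".keep")]] <- keep
    inp * keep / (1 - theta)
  }

  cur <- x
  for (i in seq_len(d - 1L)) {
    cur <- conv(sprintf("enc%d.c2", i), conv(sprintf("enc%d.c1", i), cur))
    cur <- dropout(sprintf("enc%d", i), cur)
    cache[[sprintf("skip%d", i)]] <- cur
    mp <- .maxPool2Forward(cur)
    if (keepCache) {
      cache[[sprintf("pool%d.idx", i)]] <- mp$idx
      cache[[sprintf("pool%d.dim", i)]] <- dim(cur)
    }
    cur <- mp$y
  }
  cur <- conv("bot.c2", conv("bot.c1", cur))
  for (i in rev(seq_len(d - 1L))) {
    nm <- sprintf("dec%d", i)
    if (keepCache) cache[[paste0(nm, ".upin")]] <- cur
    up <- .upconv2Forward(cur, w[[paste0(nm, ".up.w")]], w[[paste0(nm, ".up.b")]])
    up <- dropout(nm, up)
    skip <- cache[[sprintf("skip%d", i)]]
    cache$skipChannels[i] <- dim(up)[3]
    cat3 <- array(c(up, skip), dim = c(dim(up)[1:2], dim(up)[3] + dim(skip)[3]))
    cur <- conv(paste0(nm, ".c2"), conv(paste0(nm, ".c1"), cat3))
  }
  logits <- conv("out", cur, relu = FALSE)
  probs <- .softmax3(logits)
  list(probs = probs, cache = if (keepCache) cache else NULL)
}

# Backward pass for the softmax/cross-entropy head: gLogits is the gradient
# of the loss w.r.t. the pre-softmax scores. Returns gradients named like
# the weights.
.unetBackward <- function(model, cache, gLogits) {
  cfg <- model@config
  w <- model@weights
  theta <- cfg@dropoutRate
  d <- cfg@depth
  grads <- list()

  convBwd <- function(name, gOut, relu = TRUE) {
    wm <- w[[paste0(name, ".w")]]
    k <- attr(wm, "k")
    if (relu) gOut <- gOut * (cache[[paste0(name, ".act")]] > 0)
    res <- .conv2dBackward(cache[[paste0(name, ".in")]], wm, gOut, k,
                           (k - 1L) %/% 2L)
    grads[[paste0(name, ".w")]] <<- res$gw
    grads[[paste0(name, ".b")]] <<- as.numeric(res$gb)
    res$gx
  }
  dropBwd <- function(name, g) {
    keep <- cache[[paste0(name, ".keep")]]
    if (is.null(keep)) g else g * keep / (1 - theta)
  }

  g <- convBwd("out", gLogits, relu = FALSE)
  skipGrads <- vector("list", d - 1L)
  for (i in seq_len(d - 1L)) {   # decoder blocks, reverse of forward order
    nm <- sprintf("dec%d", i)
    g <- convBwd(paste0(nm, ".c1"), convBwd(paste0(nm, ".c2"), g))
    cu <- cache$skipChannels[i]
    gUp <- g[, , seq_len(cu), drop = FALSE]
    skipGrads[[i]] <- g[, , cu + seq_len(dim(g)[3] - cu), drop = FALSE]
    gUp <- dropBwd(nm, gUp)
    res <- .upconv2Backward(cache[[paste0(nm, ".upin")]],
                            w[[paste0(nm, ".up.w")]], gUp)
    grads[[paste0(nm, ".up.w")]] <- res$gw
    grads[[paste0(nm, ".up.b")]] <- as.numeric(res$gb)
    g <- res$gx
  }
  g <- convBwd("bot.c1", convBwd("bot.c2", g))
  for (i in rev(seq_len(d - 1L))) {
    dm <- cache[[sprintf("pool%d.dim", i)]]
    g <- .maxPool2Backward(cache[[sprintf("pool%d.idx", i)]], g, dm[1], dm[2])
    g <- g + skipGrads[[i]]
    g <- dropBwd(sprintf("enc%d", i), g)
    g <- convBwd(sprintf("enc%d.c1", i), convBwd(sprintf("enc%d.c2", i), g))
  }
  grads
}

#' Predict per-pixel class probabilities
#'
#' With `stochastic = FALSE` all dropout is disabled and the output is
#' deterministic. With `stochastic = TRUE` (requires dropout mode
#' `"train_and_inference"` and theta > 0) dropout stays active at inference,
#' yielding one Monte-Carlo sample; deterministic given `seed`.
#'
#' @param model a [UNetModel-class].
#' @param image numeric array H x W x C (or matrix for single-channel).
#' @param stochastic keep dropout active.
#' @param seed seed for the dropout masks (optional; NULL uses the current
#'   RNG stream).
#' @return A [ProbabilityMap-class].
#' @export
predictProbabilities <- function(model, image, stochastic = FALSE,
                                 seed = NULL) {
  x <- .checkInputShape(model@config, image)
  active <- stochastic && model@config@dropoutRate > 0 &&
    model@config@dropoutMode == "train_and_inference"
  run <- function() .unetForward(model, x, dropoutActive = active)
  p <- if (active && !is.null(seed)) .withSeed(seed, run()) else run()
  probabilityMap(p)
}
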