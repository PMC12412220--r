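# Residual-network architecture: descriptor construction for depths
# 18/34/50/101 (basic blocks for 18/34, bottleneck blocks with 4x
# expansion for 50/101; stage widths 64/128/256/512), optional attention
# block after the last residual block of configured stages, optional
# depthwise-separable replacement of every 3x3 convolution in configured
# stages, global-average-pool head.

convD <- function(nm, k, s, p, cin, cout, g = 1L)
  list(t = "conv", nm = nm, k = as.integer(k), s = as.integer(s),
       p = as.integer(p), cin = as.integer(cin), cout = as.integer(cout),
       g = as.integer(g))

bnD <- function(nm, c) list(t = "bn", nm = nm, c = as.integer(c))
reluD <- list(t = "relu")

#' Build a depthwise separable convolution block
#'
#' Factorises a k x k convolution from `inChannels` to `outChannels` into a
#' depthwise k x k convolution (one filter per input channel, same
#' padding, given stride) followed by a 1 x 1 pointwise convolution, each
#' followed by batch normalisation. Weight count is
#' k^2 C_in + C_in C_out, strictly below the standard convolution's
#' k^2 C_in C_out for k >= 3 and C_out >= 2.
#'
#' @param inChannels,outChannels Channel counts (>= 1).
#' @param kernel Odd spatial kernel size (default 3).
#' @param stride Stride of the depthwise stage (default 1).
#' @param name Descriptor name prefix.
#' @return List with `layers` (the four descriptors) and `weightCounts`
#'   (depthwise, pointwise, total, and the replaced standard count;
#'   biases/BN excluded).
#' @export
#' @examples
#' buildDscBlock(64, 128)$weightCounts
buildDscBlock <- function(inChannels, outChannels, kernel = 3, stride = 1,
                          name = "dsc") {
  stopIfNot(inChannels >= 1 && outChannels >= 1,
            "invalid argument: channel counts must be >= 1")
  stopIfNot(kernel %% 2 == 1, "invalid argument: kernel must be odd")
  layers <- list(
    convD(paste0(name, "_dw"), kernel, stride, (kernel - 1) %/% 2,
          inChannels, inChannels, g = inChannels),
    bnD(paste0(name, "_dwbn"), inChannels),
    convD(paste0(name, "_pw"), 1, 1, 0, inChannels, outChannels),
    bnD(paste0(name, "_pwbn"), outChannels))
  list(layers = layers,
       weightCounts = c(depthwise = kernel^2 * inChannels,
                        pointwise = inChannels * outChannels,
                        total = kernel^2 * inChannels + inChannels * outChannels,
                        standard = kernel^2 * inChannels * outChannels))
}

# 3x3 (+BN) stage of a residual block: standard conv or DSC replacement.
conv3Unit <- function(nm, cin, cout, stride, dsc) {
  if (dsc) buildDscBlock(cin, cout, 3, stride, name = nm)$layers
  else list(convD(paste0(nm, "_c"), 3, stride, 1, cin, cout),
            bnD(paste0(nm, "_bn"), cout))
}

basicBlock <- function(nm, cin, width, stride, dsc) {
  body <- c(conv3Unit(paste0(nm, "a"), cin, width, stride, dsc),
            list(reluD),
            conv3Unit(paste0(nm, "b"), width, width, 1, dsc))
  down <- if (stride != 1 || cin != width)
    list(convD(paste0(nm, "_d"), 1, stride, 0, cin, width),
         bnD(paste0(nm, "_dbn"), width))
  list(t = "res", nm = nm, body = body, down = down, cout = width)
}

bottleneckBlock <- function(nm, cin, width, stride, dsc) {
  cout <- width * 4L
  body <- c(list(convD(paste0(nm, "a_c"), 1, 1, 0, cin, width),
                 bnD(paste0(nm, "a_bn"), width), reluD),
            conv3Unit(paste0(nm, "b"), width, width, stride, dsc),
            list(reluD,
                 convD(paste0(nm, "c_c"), 1, 1, 0, width, cout),
                 bnD(paste0(nm, "c_bn"), cout)))
  down <- if (stride != 1 || cin != cout)
    list(convD(paste0(nm, "_d"), 1, stride, 0, cin, cout),
         bnD(paste0(nm, "_dbn"), cout))
  list(t = "res", nm = nm, body = body, down = down, cout = cout)
}

attentionDescriptor <- function(config, nm, C) {
  r <- config@seReduction
  switch(config@attention,
    se = list(t = "se", nm = nm, c = C, r = r),
    cbam = list(t = "cbam", nm = nm, c = C, r = r,
                k = as.integer(config@cbamSpatialKernel)),
    eca = list(t = "eca", nm = nm, c = C,
               k = ecaKernelSize(C, config@ecaGamma, config@ecaB)),
    stop("unknown attention type"))
}

# Full descriptor list for a configuration. `headClasses` picks between
# the training head and the profile-mode head.
resnetArch <- function(config, headClasses) {
  depth <- config@depth
  blocks <- switch(as.character(depth),
                   "18" = c(2, 2, 2, 2), "34" = c(3, 4, 6, 3),
                   "50" = c(3, 4, 6, 3), "101" = c(3, 4, 23, 3))
  bottleneck <- depth >= 50
  widths <- c(64L, 128L, 256L, 512L)
  expansion <- if (bottleneck) 4L else 1L
  arch <- list(convD("conv1", 7, 2, 3, 3, 64),
               bnD("bn1", 64), reluD,
               list(t = "maxpool", k = 3L, s = 2L, p = 1L))
  cin <- 64L
  for (st in 1:4) {
    stageName <- paste0("conv", st + 1)
    dsc <- stageName %in% config@dscStages
    for (b in seq_len(blocks[st])) {
      stride <- if (st > 1 && b == 1) 2L else 1L
      nm <- sprintf("s%db%d", st + 1, b)
      blk <- if (bottleneck) bottleneckBlock(nm, cin, widths[st], stride, dsc)
             else basicBlock(nm, cin, widths[st], stride, dsc)
      arch[[length(arch) + 1]] <- blk
      cin <- blk$cout
    }
    if (config@attention != "none" && stageName %in% config@attentionSites)
      arch[[length(arch) + 1]] <-
        attentionDescriptor(config, paste0("att", st + 1), cin)
  }
  arch[[length(arch) + 1]] <- list(t = "gap")
  arch[[length(arch) + 1]] <- list(t = "fc", nm = "fc", din = cin,
                                   dout = as.integer(headClasses))
  arch
}

# Enumerate parameter specs (name, kind, dims) of a descriptor tree.
paramSpecs <- function(arch) {
  out <- list()
  walk <- function(ds) {
    for (d in ds) {
      switch(d$t,
        conv = out[[length(out) + 1]] <<-
          list(nm = paste0(d$nm, ".w"), kind = "conv",
               dim = c(d$k, d$k, d$cin %/% d$g, d$cout)),
        bn = {
          out[[length(out) + 1]] <<- list(nm = paste0(d$nm, ".g"), kind = "bn_g",
                                          dim = d$c)
          out[[length(out) + 1]] <<- list(nm = paste0(d$nm, ".b"), kind = "bn_b",
                                          dim = d$c)
        },
        fc = {
          out[[length(out) + 1]] <<- list(nm = paste0(d$nm, ".w"), kind = "fc",
                                          dim = c(d$din, d$dout))
          out[[length(out) + 1]] <<- list(nm = paste0(d$nm, ".b"), kind = "fc_b",
                                          dim = d$dout)
        },
        se = {
          h <- max(1L, d$c %/% d$r)
          out[[length(out) + 1]] <<- list(nm = paste0(d$nm, ".w1"), kind = "fc",
                                          dim = c(h, d$c))
          out[[length(out) + 1]] <<- list(nm = paste0(d$nm, ".w2"), kind = "fc",
                                          dim = c(d$c, h))
        },
        cbam = {
          h <- max(1L, d$c %/% d$r)
          out[[length(out) + 1]] <<- list(nm = paste0(d$nm, ".w1"), kind = "fc",
                                          dim = c(h, d$c))
          out[[length(out) + 1]] <<- list(nm = paste0(d$nm, ".w2"), kind = "fc",
                                          dim = c(d$c, h))
          out[[length(out) + 1]] <<- list(nm = paste0(d$nm, ".ws"), kind = "conv",
                                          dim = c(d$k, d$k, 2, 1))
        },
        eca = out[[length(out) + 1]] <<-
          list(nm = paste0(d$nm, ".k"), kind = "eca", dim = d$k),
        res = { walk(d$body); if (!is.null(d$down)) walk(d$down) },
        NULL)
    }
  }
  walk(arch)
  out
}

# He-normal initialisation for convolution/FC weights; BN scale 1, shift 0.
initParams <- function(arch, rngSeed) {
  specs <- paramSpecs(arch)
  params <- list()
  state <- list()
  withSeed(rngSeed, {
    for (sp in specs) {
      params[[sp$nm]] <- switch(sp$kind,
        conv = array(rnorm(prod(sp$dim), 0, sqrt(2 / prod(sp$dim[1:3]))), sp$dim),
        fc = matrix(rnorm(prod(sp$dim), 0, sqrt(2 / sp$dim[1])), sp$dim[1], sp$dim[2]),
        fc_b = numeric(sp$dim),
        bn_g = rep(1, sp$dim),
        bn_b = numeric(sp$dim),
        eca = rnorm(sp$dim, 0, sqrt(2 / sp$dim)))
    }
  })
  collectBn <- function(ds) for (d in ds) {
    if (d$t == "bn") {
      state[[paste0(d$nm, ".rm")]] <<- numeric(d$c)
      state[[paste0(d$nm, ".rv")]] <<- rep(1, d$c)
    } else if (d$t == "res") {
      collectBn(d$body); if (!is.null(d$down)) collectBn(d$down)
    }
  }
  collectBn(arch)
  list(params = params, state = state)
}

#' Build a residual-network classifier
#'
#' Instantiates the configured network with He-normal convolution/FC
#' weights (BN scale 1, shift 0), a `numClasses`-way head, and one
#' attention block of the configured type after the last residual block of
#' each stage in `attentionSites`.
#'
#' @param config A [ModelConfig-class].
#' @param classes Class labels; length must equal `config@numClasses`
#'   (default `class1..classK`).
#' @param rngSeed Integer seed for weight initialisation.
#' @return A [SeedNet-class].
#' @export
buildModel <- function(config, classes = NULL, rngSeed = 1L) {
  validObject(config)
  if (is.null(classes))
    classes <- sprintf("class%d", seq_len(config@numClasses))
  stopIfNot(length(classes) == config@numClasses,
            "invalid argument: classes length must equal numClasses")
  arch <- resnetArch(config, config@numClasses)
  ini <- initParams(arch, rngSeed)
  new("SeedNet", config = config, arch = arch, params = ini$params,
      state = ini$state, classes = as.character(classes))
}

#' Forward a batch through a SeedNet
#'
#' @param model A [SeedNet-class].
#' @param x H x W x 3 x N input array (or H x W x 3 for one sample),
#'   values on the \[0, 1\] scale from [prepareModelInput()].
#' @param train Use batch statistics and build caches (internal; default
#'   FALSE = inference with running statistics).
#' @param neutralAttention Force all attention weights to 1 (diagnostic).
#' @return K x N matrix of softmax class probabilities (columns sum to 1).
#' @export
predictSeedNet <- function(model, x, train = FALSE, neutralAttention = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  r <- netForward(model@arch, model@params, model@state, x, train,
                  list(neutralAttention = neutralAttention))
  softmaxCols(r$y)
}

softmaxCols <- function(logits) {
  z <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(z, 2, colSums(z), "/")
}
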