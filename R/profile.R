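# Analytic model profiling: trainable-parameter and multiply-accumulate
# counts from the architecture descriptors alone (no weight allocation).
# MAC convention: convolution layers contribute
# k_h k_w (C_in/groups) C_out H_out W_out, fully connected layers
# contribute in*out; BN, activations and pooling are excluded. Profile
# mode uses the 1000-way head conventional for architecture tables;
# training uses the task head.

#' Profile a model configuration
#'
#' Counts all trainable weights (convolution, batch norm, fully connected,
#' attention) and the conv+FC multiply-accumulates of one forward pass at
#' `inputShape`.
#'
#' @param config A [ModelConfig-class].
#' @param inputShape Integer (H, W, C), default c(224, 224, 3).
#' @param headClasses Head width used for counting; defaults to
#'   `config@profileHeadClasses` (1000). Pass `config@numClasses` to
#'   profile the training head instead.
#' @return A [ModelProfile-class].
#' @export
#' @examples
#' profileModel(modelConfig(depth = 50))  # 25.6 M params, ~4.09 GFLOPs
profileModel <- function(config, inputShape = c(224, 224, 3),
                         headClasses = config@profileHeadClasses) {
  validObject(config)
  arch <- resnetArch(config, headClasses)
  counts <- walkProfile(arch, inputShape[1], inputShape[2], inputShape[3])
  new("ModelProfile",
      paramsTotal = counts$params,
      paramsMillions = round(counts$params / 1e6, 1),
      macsTotal = counts$macs,
      flopsG = round(counts$macs / 1e9, 2),
      inputShape = as.numeric(inputShape))
}

# Shape-propagating walk; returns params, macs and the output shape.
walkProfile <- function(arch, H, W, C) {
  params <- 0; macs <- 0
  for (d in arch) {
    switch(d$t,
      conv = {
        Ho <- (H + 2 * d$p - d$k) %/% d$s + 1
        Wo <- (W + 2 * d$p - d$k) %/% d$s + 1
        cinG <- d$cin %/% d$g
        params <- params + d$k^2 * cinG * d$cout
        macs <- macs + d$k^2 * cinG * d$cout * Ho * Wo
        H <- Ho; W <- Wo; C <- d$cout
      },
      bn = params <- params + 2 * d$c,
      maxpool = {
        H <- (H + 2 * d$p - d$k) %/% d$s + 1
        W <- (W + 2 * d$p - d$k) %/% d$s + 1
      },
      res = {
        body <- walkProfile(d$body, H, W, C)
        params <- params + body$params
        macs <- macs + body$macs
        if (!is.null(d$down)) {
          down <- walkProfile(d$down, H, W, C)
          params <- params + down$params
          macs <- macs + down$macs
        }
        H <- body$H; W <- body$W; C <- body$C
      },
      se = {
        h <- max(1, d$c %/% d$r)
        params <- params + 2 * h * d$c
        macs <- macs + 2 * h * d$c
      },
      cbam = {
        h <- max(1, d$c %/% d$r)
        params <- params + 2 * h * d$c + d$k^2 * 2
        macs <- macs + 4 * h * d$c + d$k^2 * 2 * H * W
      },
      eca = {
        params <- params + d$k
        macs <- macs + d$k * d$c
      },
      gap = { H <- 1; W <- 1 },
      fc = {
        params <- params + d$din * d$dout + d$dout
        macs <- macs + d$din * d$dout
        C <- d$dout
      },
      NULL)
  }
  list(params = params, macs = macs, H = H, W = W, C = C)
}
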