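# Batched layer engine for the residual networks. Tensors are numeric
# arrays with dim c(H, W, C, N). Each layer descriptor is a plain list
# with a type tag `t` and (where parameterised) a unique name `nm` keying
# into the flat parameter/state lists. Forward passes return a cache that
# the matching backward pass consumes; gradients accumulate into an
# environment so deep recursion stays cheap.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# (C, N) channel matrix -> full-tensor vector, hw fastest then c then n
bcastChan <- function(s, H, W) rep(as.vector(s), each = H * W)

# sum over the spatial plane -> (C, N)
chanSum <- function(x) {
  d <- dim(x)
  matrix(colSums(matrix(x, d[1] * d[2])), d[3], d[4])
}

chanMean <- function(x) chanSum(x) / (dim(x)[1] * dim(x)[2])

# (H, W, 1, N) map -> (H, W, C, N) broadcast
bcastSpat <- function(m, C) {
  d <- dim(m)
  aperm(array(m, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
}

# sum over channels -> (H, W, 1, N)
spatSum <- function(x) {
  d <- dim(x)
  array(rowSums(matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])),
        c(d[1], d[2], 1, d[4]))
}

addGrad <- function(gacc, nm, g) {
  if (is.null(gacc$g[[nm]])) gacc$g[[nm]] <- g else
    gacc$g[[nm]] <- gacc$g[[nm]] + g
}

sharedMlp <- function(z, W1, W2) {
  hpre <- W1 %*% z
  h <- pmax(hpre, 0)
  list(out = W2 %*% h, h = h, hpre = hpre)
}

layerForward <- function(d, params, state, x, train, opts) {
  switch(d$t,
    conv = {
      y <- cpp_conv2d_fw(x, params[[paste0(d$nm, ".w")]], d$s, d$p, d$g)
      list(y = y, cache = list(x = x), state = state)
    },
    bn = {
      dd <- dim(x)
      m <- dd[1] * dd[2] * dd[4]
      nm <- d$nm
      if (train) {
        cs <- chanSum(x)
        mu <- rowSums(cs) / m
        cs2 <- chanSum(x * x)
        v <- rowSums(cs2) / m - mu^2
        state[[paste0(nm, ".rm")]] <-
          (1 - BN_MOMENTUM) * state[[paste0(nm, ".rm")]] + BN_MOMENTUM * mu
        state[[paste0(nm, ".rv")]] <-
          (1 - BN_MOMENTUM) * state[[paste0(nm, ".rv")]] + BN_MOMENTUM * v
      } else {
        mu <- state[[paste0(nm, ".rm")]]
        v <- state[[paste0(nm, ".rv")]]
      }
      istd <- 1 / sqrt(v + BN_EPS)
      muv <- rep(rep(mu, times = dd[4]), each = dd[1] * dd[2])
      istdv <- rep(rep(istd, times = dd[4]), each = dd[1] * dd[2])
      xhat <- (x - muv) * istdv
      g <- params[[paste0(nm, ".g")]]
      b <- params[[paste0(nm, ".b")]]
      gv <- rep(rep(g, times = dd[4]), each = dd[1] * dd[2])
      bv <- rep(rep(b, times = dd[4]), each = dd[1] * dd[2])
      y <- array(gv * xhat + bv, dd)
      list(y = y,
           cache = list(xhat = xhat, istd = istd, m = m, dims = dd, train = train),
           state = state)
    },
    relu = {
      y <- pmax(x, 0)
      list(y = y, cache = list(mask = x > 0), state = state)
    },
    maxpool = {
      r <- cpp_maxpool_fw(x, d$k, d$s, d$p)
      list(y = r$y, cache = list(arg = r$arg, xdim = dim(x)), state = state)
    },
    res = {
      fb <- netForward(d$body, params, state, x, train, opts)
      state <- fb$state
      if (is.null(d$down)) {
        yd <- x; cd <- NULL
      } else {
        fd <- netForward(d$down, params, state, x, train, opts)
        yd <- fd$y; cd <- fd$caches; state <- fd$state
      }
      pre <- fb$y + yd
      list(y = pmax(pre, 0),
           cache = list(body = fb$caches, down = cd, mask = pre > 0),
           state = state)
    },
    gap = {
      list(y = chanMean(x), cache = list(dims = dim(x)), state = state)
    },
    fc = {
      W <- params[[paste0(d$nm, ".w")]]
      b <- params[[paste0(d$nm, ".b")]]
      list(y = crossprod(W, x) + b, cache = list(x = x), state = state)
    },
    se = {
      dd <- dim(x)
      z <- chanMean(x)
      W1 <- params[[paste0(d$nm, ".w1")]]
      W2 <- params[[paste0(d$nm, ".w2")]]
      ml <- sharedMlp(z, W1, W2)
      s <- sigmoid(ml$out)
      if (isTRUE(opts$neutralAttention)) s[] <- 1
      sb <- bcastChan(s, dd[1], dd[2])
      list(y = array(x * sb, dd),
           cache = list(x = x, z = z, h = ml$h, hpre = ml$hpre, s = s, dims = dd),
           state = state)
    },
    eca = {
      dd <- dim(x)
      z <- chanMean(x)
      ker <- params[[paste0(d$nm, ".k")]]
      spre <- conv1dSame(z, ker)
      s <- sigmoid(spre)
      if (isTRUE(opts$neutralAttention)) s[] <- 1
      sb <- bcastChan(s, dd[1], dd[2])
      list(y = array(x * sb, dd),
           cache = list(x = x, z = z, s = s, dims = dd), state = state)
    },
    cbam = {
      dd <- dim(x); H <- dd[1]; W <- dd[2]; C <- dd[3]; N <- dd[4]
      HW <- H * W
      W1 <- params[[paste0(d$nm, ".w1")]]
      W2 <- params[[paste0(d$nm, ".w2")]]
      ws <- params[[paste0(d$nm, ".ws")]]
      # channel attention: shared MLP over spatial avg- and max-pooled z
      M <- matrix(x, HW, C * N)
      zavg <- matrix(colMeans(M), C, N)
      argSpat <- max.col(t(M), ties.method = "first")
      zmax <- matrix(M[cbind(argSpat, seq_len(C * N))], C, N)
      ma <- sharedMlp(zavg, W1, W2)
      mm <- sharedMlp(zmax, W1, W2)
      s <- sigmoid(ma$out + mm$out)
      if (isTRUE(opts$neutralAttention)) s[] <- 1
      sb <- bcastChan(s, H, W)
      x1 <- array(x * sb, dd)
      # spatial attention on the channel-reweighted map
      AP <- matrix(aperm(x1, c(1, 2, 4, 3)), HW * N, C)
      am <- rowMeans(AP)
      argChan <- max.col(AP, ties.method = "first")
      mmax <- AP[cbind(seq_len(HW * N), argChan)]
      x2 <- array(0, c(H, W, 2, N))
      x2[, , 1, ] <- array(am, c(H, W, N))
      x2[, , 2, ] <- array(mmax, c(H, W, N))
      y2 <- cpp_conv2d_fw(x2, ws, 1L, (d$k - 1L) %/% 2L, 1L)
      sm <- sigmoid(y2)
      if (isTRUE(opts$neutralAttention)) sm[] <- 1
      y <- x1 * bcastSpat(sm, C)
      list(y = y,
           cache = list(x = x, x1 = x1, x2 = x2, s = s, sm = sm,
                        zavg = zavg, zmax = zmax, ma = ma, mm = mm,
                        argSpat = argSpat, argChan = argChan, dims = dd),
           state = state)
    },
    stop("unknown layer type: ", d$t)
  )
}

layerBackward <- function(d, params, cache, dy, gacc) {
  switch(d$t,
    conv = {
      r <- cpp_conv2d_bw(cache$x, params[[paste0(d$nm, ".w")]], dy, d$s, d$p, d$g)
      addGrad(gacc, paste0(d$nm, ".w"), r$dw)
      r$dx
    },
    bn = {
      dd <- cache$dims
      xhat <- cache$xhat
      g <- params[[paste0(d$nm, ".g")]]
      dg <- rowSums(chanSum(dy * xhat))
      db <- rowSums(chanSum(dy))
      addGrad(gacc, paste0(d$nm, ".g"), dg)
      addGrad(gacc, paste0(d$nm, ".b"), db)
      gv <- rep(rep(g, times = dd[4]), each = dd[1] * dd[2])
      istdv <- rep(rep(cache$istd, times = dd[4]), each = dd[1] * dd[2])
      dxhat <- dy * gv
      if (!cache$train) return(array(dxhat * istdv, dd))
      m <- cache$m
      s1 <- rowSums(chanSum(dxhat))                 # sum dxhat per channel
      s2 <- rowSums(chanSum(dxhat * xhat))          # sum dxhat*xhat per channel
      s1v <- rep(rep(s1, times = dd[4]), each = dd[1] * dd[2])
      s2v <- rep(rep(s2, times = dd[4]), each = dd[1] * dd[2])
      array(istdv / m * (m * dxhat - s1v - xhat * s2v), dd)
    },
    relu = dy * cache$mask,
    maxpool = cpp_maxpool_bw(cache$arg, dy, cache$xdim),
    res = {
      dpre <- dy * cache$mask
      dxb <- netBackward(d$body, params, cache$body, dpre, gacc)
      dxd <- if (is.null(d$down)) dpre else
        netBackward(d$down, params, cache$down, dpre, gacc)
      dxb + dxd
    },
    gap = {
      dd <- cache$dims
      array(bcastChan(dy, dd[1], dd[2]) / (dd[1] * dd[2]), dd)
    },
    fc = {
      W <- params[[paste0(d$nm, ".w")]]
      addGrad(gacc, paste0(d$nm, ".w"), cache$x %*% t(dy))
      addGrad(gacc, paste0(d$nm, ".b"), rowSums(dy))
      W %*% dy
    },
    se = {
      dd <- cache$dims; HW <- dd[1] * dd[2]
      W1 <- params[[paste0(d$nm, ".w1")]]
      W2 <- params[[paste0(d$nm, ".w2")]]
      s <- cache$s
      ds <- chanSum(dy * cache$x)
      dspre <- ds * s * (1 - s)
      addGrad(gacc, paste0(d$nm, ".w2"), dspre %*% t(cache$h))
      dh <- t(W2) %*% dspre
      dhpre <- dh * (cache$hpre > 0)
      addGrad(gacc, paste0(d$nm, ".w1"), dhpre %*% t(cache$z))
      dz <- t(W1) %*% dhpre
      array(dy * bcastChan(s, dd[1], dd[2]) +
              bcastChan(dz, dd[1], dd[2]) / HW, dd)
    },
    eca = {
      dd <- cache$dims; HW <- dd[1] * dd[2]
      ker <- params[[paste0(d$nm, ".k")]]
      C <- dd[3]; k <- length(ker)
      s <- cache$s; z <- cache$z
      ds <- chanSum(dy * cache$x)
      dspre <- ds * s * (1 - s)
      off <- (k + 1) %/% 2
      dker <- numeric(k)
      dz <- matrix(0, C, ncol(z))
      for (j in seq_len(k)) {
        src <- seq_len(C) + (j - off)
        ok <- src >= 1 & src <= C
        dker[j] <- sum(dspre[ok, , drop = FALSE] * z[src[ok], , drop = FALSE])
        dz[src[ok], ] <- dz[src[ok], ] + ker[j] * dspre[ok, , drop = FALSE]
      }
      addGrad(gacc, paste0(d$nm, ".k"), dker)
      array(dy * bcastChan(s, dd[1], dd[2]) +
              bcastChan(dz, dd[1], dd[2]) / HW, dd)
    },
    cbam = {
      dd <- cache$dims; H <- dd[1]; W <- dd[2]; C <- dd[3]; N <- dd[4]
      HW <- H * W
      W1 <- params[[paste0(d$nm, ".w1")]]
      W2 <- params[[paste0(d$nm, ".w2")]]
      ws <- params[[paste0(d$nm, ".ws")]]
      x <- cache$x; x1 <- cache$x1; s <- cache$s; sm <- cache$sm
      # spatial stage
      dx1 <- dy * bcastSpat(sm, C)
      dm <- spatSum(dy * x1)
      dy2 <- dm * sm * (1 - sm)
      rb <- cpp_conv2d_bw(cache$x2, ws, dy2, 1L, (d$k - 1L) %/% 2L, 1L)
      addGrad(gacc, paste0(d$nm, ".ws"), rb$dw)
      dam <- rb$dx[, , 1, , drop = FALSE]   # (H, W, 1, N)
      dmm <- rb$dx[, , 2, , drop = FALSE]
      dx1 <- dx1 + bcastSpat(dam, C) / C
      # route the max-plane gradient to the argmax channel
      rows <- seq_len(HW * N)
      hw <- (rows - 1) %% HW + 1
      n <- (rows - 1) %/% HW + 1
      lin <- hw + HW * (cache$argChan - 1) + HW * C * (n - 1)
      dmmv <- as.vector(dmm)
      dx1v <- as.vector(dx1)
      dx1v[lin] <- dx1v[lin] + dmmv
      dx1 <- array(dx1v, dd)
      # channel stage (shared MLP, avg + max branches)
      ds <- chanSum(dx1 * x)
      dspre <- ds * s * (1 - s)
      addGrad(gacc, paste0(d$nm, ".w2"),
              dspre %*% t(cache$ma$h) + dspre %*% t(cache$mm$h))
      dhA <- t(W2) %*% dspre * (cache$ma$hpre > 0)
      dhM <- t(W2) %*% dspre * (cache$mm$hpre > 0)
      addGrad(gacc, paste0(d$nm, ".w1"),
              dhA %*% t(cache$zavg) + dhM %*% t(cache$zmax))
      dzavg <- t(W1) %*% dhA
      dzmax <- t(W1) %*% dhM
      dx <- dx1 * bcastChan(s, H, W) + bcastChan(dzavg, H, W) / HW
      cols <- seq_len(C * N)
      cc <- (cols - 1) %% C + 1
      nn <- (cols - 1) %/% C + 1
      lin2 <- cache$argSpat + HW * (cc - 1) + HW * C * (nn - 1)
      dxv <- as.vector(dx)
      dxv[lin2] <- dxv[lin2] + as.vector(dzmax)
      array(dxv, dd)
    },
    stop("unknown layer type: ", d$t)
  )
}

# Sequential composition over a list of descriptors.
netForward <- function(arch, params, state, x, train = FALSE, opts = list()) {
  caches <- vector("list", length(arch))
  for (i in seq_along(arch)) {
    r <- layerForward(arch[[i]], params, state, x, train, opts)
    x <- r$y
    caches[[i]] <- r$cache
    state <- r$state
  }
  list(y = x, caches = caches, state = state)
}

netBackward <- function(arch, params, caches, dy, gacc) {
  for (i in rev(seq_along(arch)))
    dy <- layerBackward(arch[[i]], params, caches[[i]], dy, gacc)
  dy
}
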