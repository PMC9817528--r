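## Internal sequence-model engine.
##
## Self-contained forward/backward passes and Adam optimizer for the four
## architectures, written on base R matrix operations. Gradients are exact
## (verified against finite differences in the test suite). Inputs are
## arrays of shape (batch, channels, time); all recurrences loop over time
## with vectorized batch updates.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

.softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## ---------------------------------------------------------------------------
## parameter initialization
## ---------------------------------------------------------------------------

.initLstmCell <- function(C, H) {
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1   # forget-gate bias
  list(Wx = .glorot(C, 4 * H), Wh = .glorot(H, 4 * H), b = b)
}

.initGruCell <- function(C, H) {
  list(Wx = .glorot(C, 3 * H), Whzr = .glorot(H, 2 * H),
       Whn = .glorot(H, H), b = numeric(3 * H))
}

.initHead <- function(K, headUnits, nClasses) {
  list(W1 = .glorot(K, headUnits), b1 = numeric(headUnits),
       W2 = .glorot(headUnits, nClasses), b2 = numeric(nClasses))
}

.initParams <- function(cfg) {
  C <- cfg$ni; H <- cfg$units
  p <- switch(cfg$arch,
    lstm = { cell <- .initLstmCell(C, H)
             names(cell) <- paste0(names(cell), ".f"); cell },
    bilstm = { f <- .initLstmCell(C, H); b <- .initLstmCell(C, H)
               names(f) <- paste0(names(f), ".f")
               names(b) <- paste0(names(b), ".b")
               c(f, b) },
    gru = .initGruCell(C, H),
    cnn1d = {
      cin <- c(C, cfg$cnnChannels[-length(cfg$cnnChannels)])
      cout <- cfg$cnnChannels
      p <- list()
      for (l in seq_along(cout)) {
        lim <- sqrt(6 / (3 * cin[l] + cout[l]))
        p[[paste0("Wc", l)]] <- array(stats::runif(3 * cin[l] * cout[l],
                                                   -lim, lim),
                                      c(3, cin[l], cout[l]))
        p[[paste0("bc", l)]] <- numeric(cout[l])
      }
      p
    },
    eqConfigError("unsupported architecture '%s'", cfg$arch))
  K <- switch(cfg$arch, lstm = H, gru = H, bilstm = 2 * H,
              cnn1d = cfg$cnnChannels[length(cfg$cnnChannels)])
  c(p, .initHead(K, cfg$headUnits, cfg$nClasses))
}

## ---------------------------------------------------------------------------
## LSTM
## ---------------------------------------------------------------------------

.lstmForward <- function(X, Wx, Wh, b, reverse = FALSE) {
  d <- dim(X); n <- d[1]; Tn <- d[3]; H <- ncol(Wh) / 4
  steps <- if (reverse) Tn:1 else 1:Tn
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  cache <- vector("list", Tn)
  bmat <- matrix(b, n, length(b), byrow = TRUE)
  iH <- 1:H; fH <- (H + 1):(2 * H); gH <- (2 * H + 1):(3 * H)
  oH <- (3 * H + 1):(4 * H)
  for (s in seq_along(steps)) {
    tt <- steps[s]
    x <- X[, , tt, drop = FALSE]; dim(x) <- d[1:2]
    A <- x %*% Wx + h %*% Wh + bmat
    i <- .sigmoid(A[, iH, drop = FALSE]); f <- .sigmoid(A[, fH, drop = FALSE])
    g <- tanh(A[, gH, drop = FALSE]);     o <- .sigmoid(A[, oH, drop = FALSE])
    cPrev <- cc
    cc <- f * cPrev + i * g
    hc <- tanh(cc)
    hPrev <- h
    h <- o * hc
    cache[[s]] <- list(x = x, i = i, f = f, g = g, o = o,
                       cPrev = cPrev, hc = hc, hPrev = hPrev)
  }
  list(h = h, cache = cache, steps = steps, H = H)
}

.lstmBackward <- function(fwd, Wx, Wh, dhT) {
  H <- fwd$H
  Tn <- length(fwd$cache)
  dWx <- Wx * 0; dWh <- Wh * 0; db <- numeric(4 * H)
  dh <- dhT; dc <- dh * 0
  for (s in Tn:1) {
    cc <- fwd$cache[[s]]
    do <- dh * cc$hc
    dc <- dc + dh * cc$o * (1 - cc$hc^2)
    di <- dc * cc$g; dg <- dc * cc$i; df <- dc * cc$cPrev
    dcPrev <- dc * cc$f
    dA <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2), do * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$x, dA)
    dWh <- dWh + crossprod(cc$hPrev, dA)
    db <- db + colSums(dA)
    dh <- dA %*% t(Wh)
    dc <- dcPrev
  }
  list(dWx = dWx, dWh = dWh, db = db)
}

## ---------------------------------------------------------------------------
## GRU
## ---------------------------------------------------------------------------

.gruForward <- function(X, Wx, Whzr, Whn, b) {
  d <- dim(X); n <- d[1]; Tn <- d[3]; H <- ncol(Whn)
  h <- matrix(0, n, H)
  cache <- vector("list", Tn)
  bmat <- matrix(b, n, length(b), byrow = TRUE)
  zH <- 1:H; rH <- (H + 1):(2 * H); nH <- (2 * H + 1):(3 * H)
  for (tt in 1:Tn) {
    x <- X[, , tt, drop = FALSE]; dim(x) <- d[1:2]
    Ax <- x %*% Wx + bmat
    Ah <- h %*% Whzr
    z <- .sigmoid(Ax[, zH, drop = FALSE] + Ah[, zH, drop = FALSE])
    r <- .sigmoid(Ax[, rH, drop = FALSE] + Ah[, rH, drop = FALSE])
    hnLin <- h %*% Whn
    nn <- tanh(Ax[, nH, drop = FALSE] + r * hnLin)
    hPrev <- h
    h <- (1 - z) * nn + z * hPrev
    cache[[tt]] <- list(x = x, z = z, r = r, n = nn, hnLin = hnLin,
                        hPrev = hPrev)
  }
  list(h = h, cache = cache, H = H)
}

.gruBackward <- function(fwd, Wx, Whzr, Whn, dhT) {
  H <- fwd$H; Tn <- length(fwd$cache)
  dWx <- Wx * 0; dWhzr <- Whzr * 0; dWhn <- Whn * 0
  db <- numeric(3 * H)
  dh <- dhT
  for (tt in Tn:1) {
    cc <- fwd$cache[[tt]]
    dz <- dh * (cc$hPrev - cc$n)
    dn <- dh * (1 - cc$z)
    dhPrev <- dh * cc$z
    dAn <- dn * (1 - cc$n^2)
    dr <- dAn * cc$hnLin
    dhPrev <- dhPrev + (dAn * cc$r) %*% t(Whn)
    dWhn <- dWhn + crossprod(cc$hPrev, dAn * cc$r)
    dAz <- dz * cc$z * (1 - cc$z)
    dAr <- dr * cc$r * (1 - cc$r)
    dAx <- cbind(dAz, dAr, dAn)
    dWx <- dWx + crossprod(cc$x, dAx)
    db <- db + colSums(dAx)
    dWhzr <- dWhzr + crossprod(cc$hPrev, cbind(dAz, dAr))
    dhPrev <- dhPrev + cbind(dAz, dAr) %*% t(Whzr)
    dh <- dhPrev
  }
  list(dWx = dWx, dWhzr = dWhzr, dWhn = dWhn, db = db)
}

## ---------------------------------------------------------------------------
## dilated 1-D convolution stack
## ---------------------------------------------------------------------------

.convLayerForward <- function(X, W, b, dil) {
  d <- dim(X); n <- d[1]; Cin <- d[2]; Tn <- d[3]
  To <- Tn - 2 * dil
  if (To < 1) eqShapeError("input too short for dilation %d", dil)
  Cout <- dim(W)[3]
  acc <- matrix(rep(b, each = n * To), n * To, Cout)
  Xk <- vector("list", 3)
  for (k in 1:3) {
    sl <- X[, , (1 + (k - 1) * dil):(To + (k - 1) * dil), drop = FALSE]
    M <- matrix(aperm(sl, c(1, 3, 2)), n * To, Cin)
    Xk[[k]] <- M
    acc <- acc + M %*% matrix(W[k, , ], Cin, Cout)
  }
  Z <- acc                     # pre-activation (n*To, Cout)
  Y <- pmax(Z, 0)
  Yarr <- aperm(array(Y, c(n, To, Cout)), c(1, 3, 2))
  list(Y = Yarr, Z = Z, Xk = Xk, n = n, To = To, Cin = Cin, Cout = Cout,
       Tin = Tn, dil = dil)
}

.convLayerBackward <- function(cache, W, dY) {
  ## dY: array (n, Cout, To)
  n <- cache$n; To <- cache$To; Cin <- cache$Cin; Cout <- cache$Cout
  dYm <- matrix(aperm(dY, c(1, 3, 2)), n * To, Cout)
  dYm <- dYm * (cache$Z > 0)
  dW <- array(0, dim(W)); dil <- cache$dil
  dXm <- array(0, c(n, cache$Tin, Cin))   # (n, T, Cin) layout for scatter
  for (k in 1:3) {
    dW[k, , ] <- crossprod(cache$Xk[[k]], dYm)
    dxk <- array(dYm %*% t(matrix(W[k, , ], Cin, Cout)), c(n, To, Cin))
    idx <- (1 + (k - 1) * dil):(To + (k - 1) * dil)
    dXm[, idx, ] <- dXm[, idx, ] + dxk
  }
  list(dW = dW, db = colSums(dYm), dX = aperm(dXm, c(1, 3, 2)))
}

## ---------------------------------------------------------------------------
## full model forward / backward
## ---------------------------------------------------------------------------

.headForward <- function(hin, p) {
  Z1 <- sweep(hin %*% p$W1, 2, p$b1, "+")
  R <- pmax(Z1, 0)
  logits <- sweep(R %*% p$W2, 2, p$b2, "+")
  list(probs = .softmaxRows(logits), Z1 = Z1, R = R, hin = hin)
}

.headBackward <- function(cache, p, dlogits) {
  dW2 <- crossprod(cache$R, dlogits)
  db2 <- colSums(dlogits)
  dR <- dlogits %*% t(p$W2)
  dZ1 <- dR * (cache$Z1 > 0)
  dW1 <- crossprod(cache$hin, dZ1)
  db1 <- colSums(dZ1)
  dhin <- dZ1 %*% t(p$W1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, dhin = dhin)
}

.modelForward <- function(arch, params, cfg, X) {
  cache <- list()
  hin <- switch(arch,
    lstm = {
      f <- .lstmForward(X, params$Wx.f, params$Wh.f, params$b.f)
      cache$f <- f; f$h
    },
    bilstm = {
      f <- .lstmForward(X, params$Wx.f, params$Wh.f, params$b.f)
      b <- .lstmForward(X, params$Wx.b, params$Wh.b, params$b.b,
                        reverse = TRUE)
      cache$f <- f; cache$b <- b
      cbind(f$h, b$h)
    },
    gru = {
      f <- .gruForward(X, params$Wx, params$Whzr, params$Whn, params$b)
      cache$f <- f; f$h
    },
    cnn1d = {
      cur <- X
      convs <- vector("list", length(cfg$cnnDilations))
      for (l in seq_along(cfg$cnnDilations)) {
        convs[[l]] <- .convLayerForward(cur, params[[paste0("Wc", l)]],
                                        params[[paste0("bc", l)]],
                                        cfg$cnnDilations[l])
        cur <- convs[[l]]$Y
      }
      cache$convs <- convs
      cache$ToLast <- dim(cur)[3]
      apply(cur, c(1, 2), mean)   # global average over time
    })
  hd <- .headForward(hin, params)
  cache$head <- hd
  list(probs = hd$probs, cache = cache)
}

.modelBackward <- function(arch, params, cfg, cache, dlogits) {
  hb <- .headBackward(cache$head, params, dlogits)
  g <- list(W1 = hb$W1, b1 = hb$b1, W2 = hb$W2, b2 = hb$b2)
  dhin <- hb$dhin
  if (arch == "lstm") {
    bk <- .lstmBackward(cache$f, params$Wx.f, params$Wh.f, dhin)
    g$Wx.f <- bk$dWx; g$Wh.f <- bk$dWh; g$b.f <- bk$db
  } else if (arch == "bilstm") {
    H <- ncol(cache$f$h)
    bkf <- .lstmBackward(cache$f, params$Wx.f, params$Wh.f,
                         dhin[, 1:H, drop = FALSE])
    bkb <- .lstmBackward(cache$b, params$Wx.b, params$Wh.b,
                         dhin[, (H + 1):(2 * H), drop = FALSE])
    g$Wx.f <- bkf$dWx; g$Wh.f <- bkf$dWh; g$b.f <- bkf$db
    g$Wx.b <- bkb$dWx; g$Wh.b <- bkb$dWh; g$b.b <- bkb$db
  } else if (arch == "gru") {
    bk <- .gruBackward(cache$f, params$Wx, params$Whzr, params$Whn, dhin)
    g$Wx <- bk$dWx; g$Whzr <- bk$dWhzr; g$Whn <- bk$dWhn; g$b <- bk$db
  } else if (arch == "cnn1d") {
    nl <- length(cache$convs)
    To <- cache$ToLast
    n <- nrow(dhin); Cout <- ncol(dhin)
    dY <- array(rep(dhin / To, To), c(n, Cout, To))
    for (l in nl:1) {
      bk <- .convLayerBackward(cache$convs[[l]],
                               params[[paste0("Wc", l)]], dY)
      g[[paste0("Wc", l)]] <- bk$dW
      g[[paste0("bc", l)]] <- bk$db
      dY <- bk$dX
    }
  }
  g
}

## ---------------------------------------------------------------------------
## loss + Adam
## ---------------------------------------------------------------------------

.xentLoss <- function(probs, yIdx) {
  -mean(log(pmax(probs[cbind(seq_along(yIdx), yIdx)], 1e-12)))
}

.xentGrad <- function(probs, yIdx) {
  d <- probs
  d[cbind(seq_along(yIdx), yIdx)] <- d[cbind(seq_along(yIdx), yIdx)] - 1
  d / length(yIdx)
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

.adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    if (is.null(gnm)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
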