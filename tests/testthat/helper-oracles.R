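# Independent brute-force oracles, written before the implementations they
# check and kept free of any package internals.

# nested-loop spatial hierarchical pooling
naive_shpm <- function(x, levels, combine = "concat", temporal = "mean") {
  d <- dim(x); B <- d[1]; C <- d[2]; Tn <- d[3]; H <- d[4]; W <- d[5]
  pieces <- NULL
  for (lv in levels) {
    hs <- lv[1]; ws <- lv[2]; Hb <- H / hs; Wb <- W / ws
    mu <- array(0, c(B, C, Tn, Hb, Wb)); eta <- mu
    for (bb in 1:B) for (cc in 1:C) for (tt in 1:Tn)
      for (i in 1:Hb) for (j in 1:Wb) {
        blk <- x[bb, cc, tt, ((i - 1) * hs + 1):(i * hs),
                 ((j - 1) * ws + 1):(j * ws)]
        mu[bb, cc, tt, i, j] <- max(blk)
        eta[bb, cc, tt, i, j] <- mean(blk)
      }
    red <- function(a) apply(a, c(1, 2, 4, 5),
                             if (temporal == "mean") mean else max)
    rmu <- red(mu); reta <- red(eta)
    if (Hb * Wb == 1) { rmu <- array(rmu, c(B, C, 1, 1)); reta <- array(reta, c(B, C, 1, 1)) }
    if (combine == "concat")
      pieces <- cbind(pieces, matrix(rmu, B), matrix(reta, B))
    else if (combine == "sum")
      pieces <- cbind(pieces, matrix(rmu + reta, B))
    else pieces <- cbind(pieces, matrix(reta, B))
  }
  pieces
}

# one-vs-rest macro metrics computed by hand
naive_macro <- function(mat) {
  C <- nrow(mat)
  p <- r <- numeric(C)
  for (i in 1:C) {
    tp <- mat[i, i]
    p[i] <- tp / sum(mat[, i])
    r[i] <- tp / sum(mat[i, ])
  }
  mp <- mean(p); mr <- mean(r)
  list(macro_p = mp, macro_r = mr, macro_f1 = 2 * mp * mr / (mp + mr),
       accuracy = sum(diag(mat)) / sum(mat))
}

# PR-AUC by exhaustive threshold enumeration (step rule)
naive_pr_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; auc <- 0
  for (th in ths) {
    sel <- scores >= th
    p <- sum(truth & sel) / sum(sel)
    r <- sum(truth & sel) / sum(truth)
    auc <- auc + (r - prev_r) * p
    prev_r <- r
  }
  auc
}
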