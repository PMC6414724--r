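# independent oracles, written directly from the definitions and kept free of
# any package internals

# all 19 bioclim values for one cell's monthly series, scalar arithmetic only
bioclim_oracle <- function(tmax, tmin, prec) {
  tavg <- (tmax + tmin) / 2
  quarters <- lapply(1:12, function(q) c(q, q %% 12 + 1, (q + 1) %% 12 + 1))
  q_prec <- sapply(quarters, function(ms) sum(prec[ms]))
  q_tavg <- sapply(quarters, function(ms) mean(tavg[ms]))
  out <- numeric(19)
  out[1] <- mean(tavg)
  out[2] <- mean(tmax - tmin)
  out[5] <- max(tmax)
  out[6] <- min(tmin)
  out[7] <- out[5] - out[6]
  out[3] <- if (out[7] > 0) out[2] / out[7] * 100 else 0
  out[4] <- sd(tavg) * 100
  out[8] <- q_tavg[which.max(q_prec)]
  out[9] <- q_tavg[which.min(q_prec)]
  out[10] <- q_tavg[which.max(q_tavg)]
  out[11] <- q_tavg[which.min(q_tavg)]
  out[12] <- sum(prec)
  out[13] <- max(prec)
  out[14] <- min(prec)
  out[15] <- 100 * sd(prec) / (1 + out[12] / 12)
  out[16] <- q_prec[which.max(q_prec)]
  out[17] <- q_prec[which.min(q_prec)]
  out[18] <- q_prec[which.max(q_tavg)]
  out[19] <- q_prec[which.min(q_tavg)]
  out
}

# AUC as the literal fraction of concordant (presence, absence) pairs
auc_bruteforce <- function(pres, abs_) {
  total <- 0
  for (p in pres) for (a in abs_) {
    total <- total + if (p > a) 1 else if (p == a) 0.5 else 0
  }
  total / (length(pres) * length(abs_))
}

# exhaustive threshold scan with independent confusion counting
max_tss_oracle <- function(scores, observed) {
  best_tss <- -Inf
  best_th <- NA_real_
  for (th in sort(unique(scores))) {
    pred <- as.integer(scores >= th)
    sens <- sum(pred & observed) / sum(observed)
    spec <- sum(!pred & !observed) / sum(!observed)
    tss <- sens + spec - 1
    if (tss > best_tss + 1e-12) {
      best_tss <- tss
      best_th <- th
    }
  }
  best_th
}

# exact signed-rank p by explicit enumeration of every sign vector (n <= 12)
wilcoxon_enum_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  p <- min(1, 2 * min(mean(v_all >= v_obs), mean(v_all <= v_obs)))
  list(statistic = v_obs, p_value = p)
}

# brute-force disc rasterization: count cells within radius of any centre
disc_cells_oracle <- function(n_rows, n_cols, centres, radius) {
  hit <- matrix(FALSE, n_rows, n_cols)
  for (i in seq_len(n_rows)) for (j in seq_len(n_cols)) {
    for (k in seq_len(nrow(centres))) {
      if ((i - centres[k, 1])^2 + (j - centres[k, 2])^2 <= radius^2) {
        hit[i, j] <- TRUE
      }
    }
  }
  sum(hit)
}
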