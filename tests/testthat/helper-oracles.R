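# Independent brute-force oracles used to pin the vectorised implementations.
# Everything here is written as plain loops over definitions, sharing no code
# with the package internals.

# spatial self-attention forward, elementwise loops over all positions
oracle_spatial_refine <- function(h, par) {
  H <- dim(h)[1]; W <- dim(h)[2]; C <- dim(h)[3]
  tau <- attr(par, "tau")
  Cp <- nrow(par$psi1)
  H2 <- H / 2; W2 <- W / 2
  # 2x2 mean downsample
  hd <- array(0, c(H2, W2, C))
  for (i in 1:H2) for (j in 1:W2) for (c in 1:C)
    hd[i, j, c] <- mean(h[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
  # flatten row-major over H then W: p = (i-1)*W + j
  Q <- matrix(0, H * W, Cp); K <- matrix(0, H2 * W2, Cp); V <- K
  for (i in 1:H) for (j in 1:W) {
    p <- (i - 1) * W + j
    for (cp in 1:Cp) Q[p, cp] <- sum(par$psi1[cp, ] * h[i, j, ])
  }
  for (i in 1:H2) for (j in 1:W2) {
    p <- (i - 1) * W2 + j
    for (cp in 1:Cp) {
      K[p, cp] <- sum(par$psi2[cp, ] * hd[i, j, ])
      V[p, cp] <- sum(par$psi3[cp, ] * hd[i, j, ])
    }
  }
  A <- matrix(0, H * W, H2 * W2)
  for (p in 1:(H * W)) {
    s <- numeric(H2 * W2)
    for (q in 1:(H2 * W2)) s[q] <- sum(Q[p, ] * K[q, ]) / tau
    e <- exp(s - max(s))
    A[p, ] <- e / sum(e)
  }
  ctx <- A %*% V
  out <- h
  for (i in 1:H) for (j in 1:W) {
    p <- (i - 1) * W + j
    for (c in 1:C)
      out[i, j, c] <- h[i, j, c] + sum(par$psi4[c, ] * ctx[p, ]) + par$b4[c]
  }
  list(out = out, psi12 = A)
}

# gated instance attention, loops over instances
oracle_instance_attention <- function(v, par) {
  n <- nrow(v); D <- nrow(par$Wa); C <- ncol(v)
  a <- numeric(n)
  for (j in 1:n) {
    g <- numeric(D)
    for (d in 1:D) {
      t1 <- tanh(sum(par$Wa[d, ] * v[j, ]))
      t2 <- 1 / (1 + exp(-sum(par$Wb[d, ] * v[j, ])))
      g[d] <- t1 * t2
    }
    a[j] <- sum(par$wc * g)
  }
  e <- exp(a - max(a))
  alpha <- e / sum(e)
  z <- numeric(C)
  for (j in 1:n) z <- z + alpha[j] * v[j, ]
  list(alpha = alpha, z = z)
}

# AUROC by exhaustive pairwise concordance, ties at 1/2
oracle_auroc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# AUPRC by explicit threshold sweep over descending distinct scores
oracle_auprc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0; r_prev <- 0
  for (t in th) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    p <- tp / (tp + fp); r <- tp / n_pos
    area <- area + (r - r_prev) * p
    r_prev <- r
  }
  area
}

# trapezoidal ROC integration (must agree with the rank formulation)
oracle_auroc_trapezoid <- function(scores, labels) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  tpr <- fpr <- numeric(length(th))
  for (i in seq_along(th)) {
    tpr[i] <- sum(scores >= th[i] & labels == 1) / n_pos
    fpr[i] <- sum(scores >= th[i] & labels == 0) / n_neg
  }
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# small fully-specified model used across tests: tiny attention widths,
# no dropout so evaluation and training passes agree where needed
tiny_model <- function(variant = "dual_attention", seed = 1,
                       dropout = 0) {
  mil_model(variant, backbone = "tinycnn",
            iram = list(c_prime = 4L, tau = 4, dropout = dropout),
            isam = list(hidden_dim = 8L, dropout = dropout),
            seed = seed)
}

# small in-memory synthetic cohort (no disk round trip)
tiny_cohort <- function(n_patients = 12, seed = 1, image_size = 32) {
  cfg <- synth_config(n_patients = n_patients, image_size = image_size,
                      seed = seed)
  labels <- rep_len(c(1, 0), n_patients)   # interleaved so any slice is mixed
  bags <- withr::with_seed(substream_seed(seed, "tiny"),
    lapply(seq_len(n_patients), function(i)
      generate_bag(labels[i], cfg, patient_id = sprintf("P%03d", i))))
  structure(bags, class = "mil_bags")
}
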