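# Dual attention: per-instance spatial self-attention with residual
# refinement (IRAM) and gated instance attention pooling (ISAM).

#' Initialise spatial-attention (IRAM) parameters
#'
#' Three bias-free 1x1 projections `psi1, psi2, psi3: C -> C'` form queries,
#' keys and values; `psi4: C' -> C` (with bias) maps the attended context back
#' to the feature space. `psi4` is zero-initialised so the module is exactly
#' the identity at the start of training (the residual branch contributes
#' nothing), which stabilises early optimisation.
#'
#' @param c_in input channel count `C` (512 for the resnet34 backbone).
#' @param c_prime projection width `C'` (default 128).
#' @param tau positive softmax temperature (default 128, a fixed constant
#'   rather than `sqrt(d_k)`).
#' @param dropout dropout rate applied to the attended context during
#'   training (default 0.25).
#' @return A parameter list of class `"iram_params"`.
#' @export
iram_params <- function(c_in, c_prime = 128L, tau = 128, dropout = 0.25) {
  stopifnot(tau > 0, dropout >= 0, dropout < 1)
  sd1 <- sqrt(1 / c_in)
  structure(list(
    psi1 = matrix(rnorm(c_prime * c_in, sd = sd1), c_prime, c_in),
    psi2 = matrix(rnorm(c_prime * c_in, sd = sd1), c_prime, c_in),
    psi3 = matrix(rnorm(c_prime * c_in, sd = sd1), c_prime, c_in),
    psi4 = matrix(0, c_in, c_prime),
    b4 = numeric(c_in)
  ), class = "iram_params",
     tau = tau, dropout = dropout)
}

#' Initialise instance-attention (ISAM) parameters
#'
#' Gated attention: `a_j = w_c' ( tanh(W_a v_j) * sigmoid(W_b v_j) )`, with
#' dropout on the gated hidden activations during training.
#'
#' @param c_in instance-vector dimensionality `C` (the ISAM input width).
#' @param hidden_dim gating width `D` (default 256).
#' @param dropout dropout rate (default 0.25).
#' @return A parameter list of class `"isam_params"`.
#' @export
isam_params <- function(c_in, hidden_dim = 256L, dropout = 0.25) {
  sd1 <- sqrt(1 / c_in)
  structure(list(
    Wa = matrix(rnorm(hidden_dim * c_in, sd = sd1), hidden_dim, c_in),
    Wb = matrix(rnorm(hidden_dim * c_in, sd = sd1), hidden_dim, c_in),
    wc = rnorm(hidden_dim, sd = sqrt(1 / hidden_dim))
  ), class = "isam_params", dropout = dropout)
}

# batched IRAM forward over M instances.
# feats: [H, W, C, M]. Returns flat refined features OUT ((H*W*M) x C, rows
# grouped by instance, row-major over H then W within an instance) + cache.
iram_fwd <- function(feats, par, training = FALSE) {
  d <- dim(feats)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; M <- d[4L]
  tau <- attr(par, "tau"); p_drop <- attr(par, "dropout")
  HW <- H * W; HW4 <- HW %/% 4L
  BF <- flatten_hw(feats)                      # (HW*M) x C
  down <- avgpool2(feats)                      # errors if H or W odd
  BD <- flatten_hw(down)                       # (HW4*M) x C
  Q <- BF %*% t(par$psi1)                      # (HW*M) x C'
  K <- BD %*% t(par$psi2)                      # (HW4*M) x C'
  V <- BD %*% t(par$psi3)
  A <- vector("list", M)
  CTX <- matrix(0, nrow(BF), ncol(Q))
  for (m in seq_len(M)) {
    rq <- ((m - 1L) * HW + 1L):(m * HW)
    rk <- ((m - 1L) * HW4 + 1L):(m * HW4)
    S <- tcrossprod(Q[rq, , drop = FALSE], K[rk, , drop = FALSE]) / tau
    Am <- softmax(S)
    A[[m]] <- Am
    CTX[rq, ] <- Am %*% V[rk, , drop = FALSE]
  }
  if (training && p_drop > 0) {
    mask <- matrix(runif(length(CTX)) >= p_drop, nrow(CTX)) / (1 - p_drop)
    CTXd <- CTX * mask
  } else {
    mask <- NULL
    CTXd <- CTX
  }
  OUT <- CTXd %*% t(par$psi4)
  OUT <- sweep(OUT, 2L, par$b4, "+") + BF      # residual
  list(out = OUT,
       cache = list(BF = BF, BD = BD, Q = Q, K = K, V = V, A = A,
                    CTXd = CTXd, mask = mask, H = H, W = W, M = M, tau = tau))
}

# backward through batched IRAM. dOUT: (HW*M) x C -> list(dfeats, grad)
iram_bwd <- function(par, cache, dOUT) {
  H <- cache$H; W <- cache$W; M <- cache$M
  HW <- H * W; HW4 <- HW %/% 4L
  tau <- cache$tau
  dpsi4 <- crossprod(dOUT, cache$CTXd)         # C x C'
  db4 <- colSums(dOUT)
  dCTXd <- dOUT %*% par$psi4                   # (HW*M) x C'
  dCTX <- if (is.null(cache$mask)) dCTXd else dCTXd * cache$mask
  dBF <- dOUT                                  # residual path (copy)
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (m in seq_len(M)) {
    rq <- ((m - 1L) * HW + 1L):(m * HW)
    rk <- ((m - 1L) * HW4 + 1L):(m * HW4)
    Am <- cache$A[[m]]
    dCm <- dCTX[rq, , drop = FALSE]
    dA <- tcrossprod(dCm, cache$V[rk, , drop = FALSE])   # HW x HW4
    dV[rk, ] <- crossprod(Am, dCm)
    dS <- Am * (dA - rowSums(dA * Am))                   # softmax rows
    dQ[rq, ] <- dS %*% cache$K[rk, , drop = FALSE] / tau
    dK[rk, ] <- crossprod(dS, cache$Q[rq, , drop = FALSE]) / tau
  }
  dpsi1 <- crossprod(dQ, cache$BF)
  dpsi2 <- crossprod(dK, cache$BD)
  dpsi3 <- crossprod(dV, cache$BD)
  dBF <- dBF + dQ %*% par$psi1
  dBD <- dK %*% par$psi2 + dV %*% par$psi3
  dfeats <- unflatten_hw_batch(dBF, H, W, M) +
    avgpool2_bwd(unflatten_hw_batch(dBD, H %/% 2L, W %/% 2L, M), H, W)
  list(dfeats = dfeats,
       grad = list(psi1 = dpsi1, psi2 = dpsi2, psi3 = dpsi3,
                   psi4 = dpsi4, b4 = db4))
}

#' Spatially refine one instance feature map (IRAM)
#'
#' Non-local self-attention over spatial positions with a residual
#' connection. Queries come from the full-resolution map; keys and values
#' from a 2x bilinear downsample (corner-excluding convention, equivalent to
#' 2x2 mean pooling). Each query position distributes unit attention over the
#' downsampled key positions (`Psi12` rows sum to 1); the attended context is
#' projected back to `C` channels and added to the input.
#'
#' @param h numeric array `[H, W, C]`, `H` and `W` even.
#' @param par parameters from [iram_params()].
#' @param training logical; enables dropout on the context.
#' @param return_attention if `TRUE`, attach the `HW x HW/4` attention map as
#'   attribute `"psi12"` (rows ordered row-major over H then W).
#' @return Refined array `[H, W, C]`.
#' @export
spatial_refine <- function(h, par, training = FALSE, return_attention = FALSE) {
  stopifnot(inherits(par, "iram_params"), length(dim(h)) == 3L)
  d <- dim(h)
  r <- iram_fwd(array(h, c(d, 1L)), par, training = training)
  out <- unflatten_hw(r$out, d[1L], d[2L])
  if (return_attention) attr(out, "psi12") <- r$cache$A[[1L]]
  out
}

#' Global average pooling of a feature map to an instance vector
#'
#' @param h numeric array `[H, W, C]` (or `[H, W, C, M]` for a batch).
#' @return Length-`C` vector (or `M x C` matrix).
#' @export
pool_instance <- function(h) {
  d <- dim(h)
  stopifnot(length(d) %in% c(3L, 4L), all(is.finite(h)))
  if (length(d) == 3L) colMeans(matrix(h, d[1L] * d[2L], d[3L]))
  else t(apply(h, 4L, function(m) colMeans(matrix(m, d[1L] * d[2L], d[3L]))))
}

# pooling over flat rows: OUT ((HW*M) x C) -> M x C
pool_flat <- function(OUT, HW, M) {
  grp <- rep(seq_len(M), each = HW)
  V <- rowsum(OUT, grp, reorder = FALSE) / HW
  dimnames(V) <- NULL
  V
}

# ISAM forward for one bag. v: n x C (real instances only). Returns
# alpha, z, cache.
isam_fwd <- function(v, par, training = FALSE) {
  p_drop <- attr(par, "dropout")
  H1 <- tanh(v %*% t(par$Wa))                 # n x D
  H2 <- 1 / (1 + exp(-(v %*% t(par$Wb))))
  G <- H1 * H2
  if (training && p_drop > 0) {
    mask <- matrix(runif(length(G)) >= p_drop, nrow(G)) / (1 - p_drop)
    Gd <- G * mask
  } else {
    mask <- NULL
    Gd <- G
  }
  a <- unname(drop(Gd %*% par$wc))            # raw scores
  alpha <- softmax(a)
  z <- unname(drop(crossprod(v, alpha)))      # length C
  list(alpha = alpha, raw = a, z = z,
       cache = list(v = v, H1 = H1, H2 = H2, Gd = Gd, mask = mask,
                    alpha = alpha))
}

# backward: dz (length C), dalpha optional -> grads + dv (n x C)
isam_bwd <- function(par, cache, dz) {
  v <- cache$v; alpha <- cache$alpha
  n <- nrow(v)
  dalpha <- drop(v %*% dz)                    # from z = sum alpha_j v_j
  dv <- alpha %o% dz
  da <- alpha * (dalpha - sum(dalpha * alpha))
  dwc <- drop(crossprod(cache$Gd, da))
  dGd <- da %o% par$wc                        # n x D
  dG <- if (is.null(cache$mask)) dGd else dGd * cache$mask
  dH1 <- dG * cache$H2
  dH2 <- dG * cache$H1
  dpre1 <- dH1 * (1 - cache$H1^2)
  dpre2 <- dH2 * cache$H2 * (1 - cache$H2)
  dWa <- crossprod(dpre1, v)
  dWb <- crossprod(dpre2, v)
  dv <- dv + dpre1 %*% par$Wa + dpre2 %*% par$Wb
  list(dv = dv, grad = list(Wa = dWa, Wb = dWb, wc = dwc))
}

#' Gated instance attention over a bag (ISAM)
#'
#' Computes a raw relevance score per instance through a tanh/sigmoid gated
#' hidden layer, masks padded slots to `-Inf`, normalises with a softmax, and
#' returns the attention-weighted bag embedding `z = sum_j alpha_j v_j`.
#'
#' @param v numeric matrix `n x C` of instance vectors.
#' @param mask binary vector of length `n`; 1 marks real instances. Padded
#'   slots receive attention weight exactly 0.
#' @param par parameters from [isam_params()].
#' @param training logical; enables dropout on the gated activations.
#' @return A list with `alpha` (length `n`, sums to 1 over real slots),
#'   `raw` (unnormalised scores, `-Inf` on padding) and `z` (length `C`).
#' @export
#' @examples
#' par <- isam_params(4, hidden_dim = 8)
#' v <- matrix(rnorm(12), 3, 4)
#' instance_attention(v, c(1, 1, 1), par)$alpha
instance_attention <- function(v, mask = rep(1, nrow(v)), par,
                               training = FALSE) {
  stopifnot(inherits(par, "isam_params"), is.matrix(v),
            length(mask) == nrow(v))
  keep <- which(mask > 0)
  if (length(keep) == 0L) stop("empty bag: all instances are masked out")
  r <- isam_fwd(v[keep, , drop = FALSE], par, training = training)
  alpha <- numeric(nrow(v))
  raw <- rep(-Inf, nrow(v))
  alpha[keep] <- r$alpha
  raw[keep] <- r$raw
  list(alpha = alpha, raw = raw, z = r$z)
}
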