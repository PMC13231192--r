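make_iram <- function(C = 2, Cp = 1, tau = 4, seed = 10, dropout = 0) {
  set.seed(seed)
  par <- iram_params(C, c_prime = Cp, tau = tau, dropout = dropout)
  # psi4 is zero-initialised by design; give it values for oracle tests
  par$psi4 <- matrix(rnorm(C * Cp, sd = 0.5), C, Cp)
  par$b4 <- rnorm(C, sd = 0.1)
  par
}

test_that("spatial refinement matches the loop-based oracle on small tensors", {
  set.seed(11)
  for (case in list(c(H = 4, W = 4, C = 2, Cp = 1),
                    c(H = 4, W = 2, C = 3, Cp = 2),
                    c(H = 2, W = 4, C = 5, Cp = 3))) {
    h <- array(rnorm(case["H"] * case["W"] * case["C"]),
               c(case["H"], case["W"], case["C"]))
    par <- make_iram(case["C"], case["Cp"], tau = 3)
    got <- spatial_refine(h, par, return_attention = TRUE)
    want <- oracle_spatial_refine(h, par)
    expect_equal(got, want$out, tolerance = 1e-5, ignore_attr = TRUE)
    expect_equal(attr(got, "psi12"), want$psi12, tolerance = 1e-5)
  }
})

test_that("attention map rows are simplex weights; zero query weights give uniform rows", {
  set.seed(12)
  h <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  par <- make_iram(3, 2)
  A <- attr(spatial_refine(h, par, return_attention = TRUE), "psi12")
  expect_equal(rowSums(A), rep(1, 16), tolerance = 1e-6)
  expect_true(all(A >= 0))
  par0 <- par; par0$psi1[] <- 0
  A0 <- attr(spatial_refine(h, par0, return_attention = TRUE), "psi12")
  expect_equal(A0, matrix(1 / 4, 16, 4))
})

test_that("zero-initialised psi4 makes spatial refinement the exact identity", {
  set.seed(13)
  h <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  par <- iram_params(6, c_prime = 3, tau = 8)   # psi4, b4 zero at init
  expect_identical(spatial_refine(h, par), h)
})

test_that("spatial refinement rejects odd feature-map sizes", {
  par <- make_iram(2, 1)
  expect_error(spatial_refine(array(0, c(3, 4, 2)), par), "even")
})

test_that("instance pooling is the channel-wise mean", {
  h <- array(2.5, c(4, 4, 3))
  expect_equal(pool_instance(h), rep(2.5, 3))
  h2 <- array(0, c(2, 2, 1)); h2[, , 1] <- c(1, 2, 3, 4)
  expect_equal(pool_instance(h2), 2.5)
  set.seed(14)
  h3 <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  loop <- vapply(1:16, function(c) {
    s <- 0
    for (i in 1:8) for (j in 1:8) s <- s + h3[i, j, c]
    s / 64
  }, numeric(1))
  expect_equal(pool_instance(h3), loop, tolerance = 1e-6)
})

test_that("gated instance attention matches the loop oracle and handles masks", {
  set.seed(15)
  for (n in c(2, 3, 5)) {
    v <- matrix(rnorm(n * 6), n, 6)
    par <- isam_params(6, hidden_dim = 4, dropout = 0)
    got <- instance_attention(v, rep(1, n), par)
    want <- oracle_instance_attention(v, par)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-5)
    expect_equal(got$z, want$z, tolerance = 1e-5)
    expect_equal(sum(got$alpha), 1, tolerance = 1e-6)
  }
})

test_that("identical instances share attention equally; singletons get weight 1", {
  set.seed(16)
  par <- isam_params(5, hidden_dim = 4)
  v1 <- matrix(rnorm(5), 1, 5)
  v <- v1[rep(1, 3), , drop = FALSE]
  r <- instance_attention(v, rep(1, 3), par)
  expect_equal(r$alpha, rep(1 / 3, 3))
  expect_equal(r$z, drop(v1))
  r1 <- instance_attention(v1, 1, par)
  expect_equal(r1$alpha, 1)
  expect_equal(r1$z, drop(v1))
})

test_that("padded slots carry exactly zero attention and do not shift the embedding", {
  set.seed(17)
  par <- isam_params(4, hidden_dim = 4)
  v_real <- matrix(rnorm(8), 2, 4)
  v_pad <- rbind(v_real, matrix(0, 2, 4))
  r_real <- instance_attention(v_real, c(1, 1), par)
  r_pad <- instance_attention(v_pad, c(1, 1, 0, 0), par)
  expect_identical(r_pad$alpha[3:4], c(0, 0))
  expect_equal(sum(r_pad$alpha), 1, tolerance = 1e-6)
  expect_equal(r_pad$alpha[1:2], r_real$alpha)
  expect_equal(r_pad$z, r_real$z)
  expect_error(instance_attention(v_real, c(0, 0), par), "empty bag")
})

test_that("attention weights are permutation-equivariant, the embedding invariant", {
  set.seed(18)
  par <- isam_params(6, hidden_dim = 8)
  v <- matrix(rnorm(30), 5, 6)
  perm <- c(4, 1, 5, 2, 3)
  r <- instance_attention(v, rep(1, 5), par)
  rp <- instance_attention(v[perm, ], rep(1, 5), par)
  expect_equal(rp$alpha, r$alpha[perm], tolerance = 1e-5)
  expect_equal(rp$z, r$z, tolerance = 1e-5)
})

test_that("attention modules are differentiable: finite differences confirm gradients", {
  set.seed(19)
  # IRAM
  h <- array(rnorm(4 * 4 * 2), c(4, 4, 2, 1))
  par <- make_iram(2, 2, tau = 2)
  fwd <- attnmil:::iram_fwd(h, par)
  dOUT <- matrix(rnorm(16 * 2), 16, 2)
  bwd <- attnmil:::iram_bwd(par, fwd$cache, dOUT)
  lossf <- function(p) sum(attnmil:::iram_fwd(h, p)$out * dOUT)
  eps <- 1e-6
  for (nm in c("psi1", "psi2", "psi3", "psi4", "b4")) {
    for (i in seq_len(min(4, length(par[[nm]])))) {
      pp <- par; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- par; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossf(pp) - lossf(pm)) / (2 * eps)
      expect_equal(bwd$grad[[nm]][i], num, tolerance = 1e-3)
    }
  }
  # input gradient
  fnum <- function(hh) sum(attnmil:::iram_fwd(hh, par)$out * dOUT)
  for (i in sample(length(h), 5)) {
    hp <- h; hp[i] <- hp[i] + eps
    hm <- h; hm[i] <- hm[i] - eps
    expect_equal(bwd$dfeats[i], (fnum(hp) - fnum(hm)) / (2 * eps),
                 tolerance = 1e-3)
  }
  # ISAM
  v <- matrix(rnorm(12), 3, 4)
  ip <- isam_params(4, hidden_dim = 5, dropout = 0)
  dz <- rnorm(4)
  f2 <- attnmil:::isam_fwd(v, ip)
  b2 <- attnmil:::isam_bwd(ip, f2$cache, dz)
  lf <- function(p) sum(attnmil:::isam_fwd(v, p)$z * dz)
  for (nm in c("Wa", "Wb", "wc")) {
    for (i in seq_len(min(4, length(ip[[nm]])))) {
      pp <- ip; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- ip; pm[[nm]][i] <- pm[[nm]][i] - eps
      expect_equal(b2$grad[[nm]][i], (lf(pp) - lf(pm)) / (2 * eps),
                   tolerance = 1e-3)
    }
  }
})
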