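# A small stack + designs shared by the K-select tests.
kselect_fixture <- function(seed = 5, n_animals = 6, n_avail = 250,
                            n_used = 25, prefer = NULL, coupling = FALSE) {
  env <- simulate_env(grid_spec(nx = 50, ny = 50), seed = seed,
                      coupling = coupling)
  st <- env$stack
  V <- sapply(st$layers, as.numeric)
  valid <- which(stats::complete.cases(V))
  set.seed(seed + 100)
  used <- list(); avail <- list()
  for (k in seq_len(n_animals)) {
    av <- sample(valid, n_avail)
    u <- if (is.null(prefer)) sample(av, n_used, replace = TRUE)
         else av[order(V[av, prefer], decreasing = TRUE)[seq_len(n_used)]]
    used[[paste0("a", k)]] <- u
    avail[[paste0("a", k)]] <- av
  }
  list(stack = st, used = used, avail = avail, V = V)
}

test_that("null selection gives zero marginality and zero eigenvalues", {
  fx <- kselect_fixture()
  ks <- kselect(fx$avail, fx$avail, fx$stack)  # used = available
  expect_close(ks$marginality, 0, 1e-12)
  expect_close(ks$eigenvalues, 0, 1e-12)
})

test_that("a single informative variable loads axis 1 almost entirely", {
  fx <- kselect_fixture(prefer = "CHLA")
  ks <- kselect(fx$used, fx$avail, fx$stack)
  expect_gt(ks$eigenvalues[1] / sum(ks$eigenvalues), 0.95)
  expect_gt(abs(ks$loadings["CHLA", 1]), 0.95)
})

test_that("the eigenvalue sum equals the weighted mean squared marginality", {
  fx <- kselect_fixture(prefer = "SST")
  ks <- kselect(fx$used, fx$avail, fx$stack)
  expect_close(sum(ks$eigenvalues),
               sum(ks$weights * rowSums(ks$marginality^2)), 1e-9)
  expect_close(sum(ks$weights), 1, 1e-12)
  expect_true(all(diff(ks$eigenvalues) <= 1e-12))
  expect_true(all(ks$eigenvalues >= 0))
})

test_that("standardization, orthonormality and reconstruction hold", {
  fx <- kselect_fixture(prefer = "SLA")
  ks <- kselect(fx$used, fx$avail, fx$stack)
  # weighted availability moments of the standardized variables
  mu <- ks$standardization$mean; sig <- ks$standardization$sd
  p <- length(ks$variables)
  wm <- rep(0, p); wv <- rep(0, p)
  for (k in seq_along(fx$avail)) {
    Z <- sweep(sweep(fx$V[fx$avail[[k]], ], 2, mu), 2, sig, "/")
    wm <- wm + ks$weights[k] * colMeans(Z)
    wv <- wv + ks$weights[k] * colMeans(Z^2)
  }
  expect_close(wm, 0, 1e-9)
  expect_close(wv - wm^2, 1, 1e-9)
  # orthonormal axes; projections reconstruct the marginality exactly
  expect_close(crossprod(ks$loadings), diag(p), 1e-9)
  expect_close(ks$projections %*% t(ks$loadings), ks$marginality, 1e-9)
  expect_identical(ks$recentred, ks$projections)
})

test_that("depth sign convention: shallow preference scores positive", {
  fx <- kselect_fixture(prefer = "BATHY")  # BATHY negative down, so
  ks <- kselect(fx$used, fx$avail, fx$stack)  # high = shallow
  expect_true(all(ks$marginality[, "BATHY"] > 0))
})

test_that("two preference regimes separate into opposite half-planes", {
  env <- simulate_env(grid_spec(nx = 50, ny = 50), seed = 7)
  st <- env$stack
  V <- sapply(st$layers, as.numeric)
  valid <- which(stats::complete.cases(V))
  set.seed(41)
  used <- list(); avail <- list()
  for (k in 1:10) {
    av <- sample(valid, 250)
    # front-seekers (high CHLA/MLD, avoiding eddy fields) vs
    # eddy-seekers (high SLA/CURR, avoiding front habitat)
    front <- scale(V[av, "CHLA"]) + scale(V[av, "MLD"]) -
      scale(V[av, "SLA"]) - scale(V[av, "CURR"])
    score <- if (k <= 5) front else -front
    used[[paste0("a", k)]] <- av[order(score, decreasing = TRUE)[1:25]]
    avail[[paste0("a", k)]] <- av
  }
  ks <- kselect(used, avail, st)
  pr <- ks$projections[, 1:2]
  g1 <- colMeans(pr[1:5, , drop = FALSE])
  g2 <- colMeans(pr[6:10, , drop = FALSE])
  cosang <- sum(g1 * g2) / sqrt(sum(g1^2) * sum(g2^2))
  expect_lt(cosang, 0)  # group means point into opposite half-planes
})

test_that("degenerate designs raise informative errors", {
  fx <- kselect_fixture()
  st2 <- fx$stack
  st2$layers$SST <- matrix(12, 50, 50)
  expect_error(kselect(fx$used, fx$avail, st2), "SST")
  valid <- which(stats::complete.cases(fx$V))
  bad_used <- fx$used
  bad_used[[1]] <- c(bad_used[[1]], setdiff(valid, fx$avail[[1]])[1])
  expect_error(kselect(bad_used, fx$avail, fx$stack), "outside availability")
  expect_error(kselect(fx$used[1], fx$avail[1], fx$stack), "length")
})

test_that("the randomization test flags real selection only", {
  fx <- kselect_fixture(n_animals = 3, prefer = "CHLA")
  rt <- kselect_randomization(fx$used, fx$avail, fx$stack, n_perm = 49,
                              seed = 2)
  expect_true(all(rt$p < 0.1))
  fx0 <- kselect_fixture(seed = 6, n_animals = 3)
  rt0 <- kselect_randomization(fx0$used, fx0$avail, fx0$stack, n_perm = 49,
                               seed = 2)
  expect_gt(min(rt0$p), 0.02)
})
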