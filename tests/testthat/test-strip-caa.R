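# StripBlock and CAA layer contracts.

randInput <- function(d, seed = 1) {
  set.seed(seed)
  array(rnorm(prod(d)), dim = d)
}

zeroLayerScales <- function(mod) {
  for (p in crownwatch:::nnParams(mod))
    if (inherits(p, "cwParam") && length(dim(p$value)) == 0 &&
        all(p$value == p$value[1]) && p$value[1] == 1e-2)
      p$value[] <- 0
  mod
}

test_that("StripBlock is an exact identity at zero layer scale", {
  set.seed(2)
  blk <- stripBlock(stripBlockConfig(6))
  blk$ls1$gamma$value[] <- 0
  blk$ls2$gamma$value[] <- 0
  x <- randInput(c(13, 17, 6, 2))
  expect_identical(crownwatch:::nnForward(blk, x), x)
})

test_that("zeroing one layer scale isolates the other branch", {
  set.seed(3)
  blk <- stripBlock(stripBlockConfig(4, k = 6))
  blk$ls1$gamma$value[] <- 0
  x <- randInput(c(8, 8, 4, 1))
  y <- crownwatch:::nnForward(blk, x)
  mlp_branch <- crownwatch:::nnForward(
    blk$ls2, crownwatch:::nnForward(
      blk$mlp, crownwatch:::nnForward(blk$bn2, x)))
  expect_equal(y - x, mlp_branch, tolerance = 1e-12)
})

test_that("strip and CAA blocks preserve odd and even spatial shapes", {
  set.seed(4)
  shapes <- list(c(1, 1), c(7, 9), c(8, 8), c(17, 33), c(5, 32))
  sb <- stripBlock(stripBlockConfig(4))
  ca <- caaBlock(caaConfig(4))
  c3s <- c3k2Strip(4, 6, n_blocks = 2)
  c3c <- c3k2Caa(4, 6, n_units = 2)
  for (sh in shapes) {
    x <- randInput(c(sh[1], sh[2], 4, 2), seed = sh[1] * 100 + sh[2])
    expect_equal(dim(crownwatch:::nnForward(sb, x)), dim(x))
    expect_equal(dim(crownwatch:::nnForward(ca, x)), dim(x))
    expect_equal(dim(crownwatch:::nnForward(c3s, x))[c(1, 2, 4)],
                 dim(x)[c(1, 2, 4)])
    expect_equal(dim(crownwatch:::nnForward(c3s, x))[3], 6)
    expect_equal(dim(crownwatch:::nnForward(c3c, x))[3], 6)
  }
})

test_that("strip attention gates multiplicatively", {
  set.seed(5)
  cfg <- stripBlockConfig(3)
  att <- stripAttention(cfg)
  # zero the final pointwise mix: the gate becomes 0, output all-zero
  att$inner$children[[4]]$w$value[] <- 0
  att$inner$children[[4]]$b$value[] <- 0
  x <- randInput(c(9, 11, 3, 2))
  expect_equal(crownwatch:::nnForward(att, x),
               array(0, dim = dim(x)))
})

test_that("identity-configured strip attention squares a 1x1 input", {
  cfg <- stripBlockConfig(1, k = 10)
  att <- stripAttention(cfg)
  # make each depthwise conv pass the single pixel through unchanged: the
  # kernel tap that reads offset 0 sits at the leading-pad index
  for (i in 1:3) {
    cv <- att$inner$children[[i]]
    cv$w$value[] <- 0
    kd <- dim(cv$w$value)
    cv$w$value[floor((kd[1] - 1) / 2) + 1, floor((kd[2] - 1) / 2) + 1, 1, 1] <- 1
    cv$b$value[] <- 0
  }
  att$inner$children[[4]]$w$value[] <- 1
  att$inner$children[[4]]$b$value[] <- 0
  x <- array(1.7, dim = c(1, 1, 1, 1))
  expect_equal(as.numeric(crownwatch:::nnForward(att, x)), 1.7^2,
               tolerance = 1e-12)
})

test_that("strip pair equals the dense outer-product kernel (separability)", {
  set.seed(6)
  k <- 10
  kv <- rnorm(k); kh <- rnorm(k)
  x <- matrix(rnorm(15 * 18), 15, 18)
  ch <- crownwatch:::nnConv2d(1, 1, c(1, k), groups = 1, bias = FALSE)
  ch$w$value[1, , 1, 1] <- kh
  cv <- crownwatch:::nnConv2d(1, 1, c(k, 1), groups = 1, bias = FALSE)
  cv$w$value[, 1, 1, 1] <- kv
  xa <- array(x, dim = c(15, 18, 1, 1))
  got <- crownwatch:::nnForward(cv, crownwatch:::nnForward(ch, xa))
  dense <- naiveConv2d(x, outer(kv, kh), pad_t = floor((k - 1) / 2),
                       pad_l = floor((k - 1) / 2))
  expect_equal(got[, , 1, 1], dense, tolerance = 1e-10)
})

test_that("CAA attenuates elementwise on 100 random inputs", {
  for (i in 1:100) {
    set.seed(1000 + i)
    ca <- caaBlock(caaConfig(3, k = sample(c(4, 10), 1)))
    x <- array(rnorm(7 * 8 * 3 * 1, sd = 2), dim = c(7, 8, 3, 1))
    y <- crownwatch:::nnForward(ca, x)
    expect_true(all(abs(y) <= abs(x) + 1e-12))
  }
})

test_that("a saturated CAA gate passes the input through", {
  set.seed(7)
  ca <- caaBlock(caaConfig(4))
  ca$inner$children[[5]]$w$value[] <- 0
  ca$inner$children[[5]]$b$value[] <- 50  # sigmoid ~ 1
  x <- randInput(c(10, 10, 4, 1))
  expect_equal(crownwatch:::nnForward(ca, x), x, tolerance = 1e-8)
})

test_that("CAA gate reach spans pool plus strip kernel extents", {
  set.seed(8)
  k <- 10; pool <- 7
  ca <- caaBlock(caaConfig(1, k = k, pool_size = pool))
  d <- c(40, 40, 1, 1)
  x0 <- array(0, dim = d)
  x1 <- x0; x1[20, 20, 1, 1] <- 5
  z0 <- crownwatch:::nnForward(ca$inner, x0)
  z1 <- crownwatch:::nnForward(ca$inner, x1)
  changed <- which(abs(z1 - z0) > 1e-12, arr.ind = TRUE)
  h_span <- diff(range(changed[, 2])) + 1
  v_span <- diff(range(changed[, 1])) + 1
  expect_gte(h_span, floor(pool / 2) + (k - 1))
  expect_gte(v_span, floor(pool / 2) + (k - 1))
})

test_that("C3k2 containers respect arity and capacity monotonicity", {
  set.seed(9)
  x <- randInput(c(8, 8, 4, 1))
  n_par <- vapply(1:3, function(nb)
    crownwatch:::nParameters(c3k2Strip(4, 6, n_blocks = nb)), numeric(1))
  expect_true(all(diff(n_par) > 0))
  caa2 <- c3k2Caa(4, 6, n_units = 2)
  expect_equal(dim(caa2$cv2$children[[1]]$w$value)[3], 3 * 3)  # (n+1) x hidden
  # all gates saturated: container output is a linear map of a linear map
  for (u in caa2$units) {
    u$inner$children[[5]]$w$value[] <- 0
    u$inner$children[[5]]$b$value[] <- 50
  }
  y <- crownwatch:::nnForward(caa2, x)
  expect_equal(dim(y), c(8, 8, 6, 1))
})

test_that("every learnable parameter receives gradient", {
  set.seed(10)
  for (make in list(function() stripBlock(stripBlockConfig(4, k = 6)),
                    function() c3k2Caa(4, 6, n_units = 1, k = 6))) {
    mod <- make()
    x <- randInput(c(9, 9, 4, 2), seed = 11)
    y <- crownwatch:::nnForward(mod, x, train = TRUE)
    crownwatch:::zeroGrads(mod)
    crownwatch:::nnBackward(mod, array(rnorm(length(y)), dim = dim(y)))
    for (p in crownwatch:::nnParams(mod)) {
      expect_false(is.null(p$grad))
      expect_true(all(is.finite(p$grad)))
      expect_gt(max(abs(p$grad)), 0)
    }
  }
})

test_that("evaluation-mode forward is bitwise repeatable", {
  set.seed(12)
  blk <- stripBlock(stripBlockConfig(4))
  x <- randInput(c(10, 10, 4, 1), seed = 13)
  expect_identical(crownwatch:::nnForward(blk, x),
                   crownwatch:::nnForward(blk, x))
})
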