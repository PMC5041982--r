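test_that("pIC50 transforms molar IC50s", {
  expect_equal(pic50(1e-6), 6)
  expect_equal(pic50(2.5e-6), 5.602, tolerance = 1e-4)
  expect_equal(pic50(1), 0)
  expect_error(pic50(0), "positive")
  expect_error(pic50(-1e-6), "positive")
})

test_that("rigid alignment recovers an applied rigid motion exactly", {
  set.seed(13)
  X <- matrix(rnorm(24), 8, 3)
  ref <- compound("ref", NA, conformer = data.frame(element = "C",
                                                    x = X[, 1], y = X[, 2],
                                                    z = X[, 3]))
  R <- randomRotation()
  Y <- X %*% R + matrix(c(3, -1, 2), 8, 3, byrow = TRUE)
  cpd <- compound("a", NA, conformer = data.frame(element = "C",
                                                  x = Y[, 1], y = Y[, 2],
                                                  z = Y[, 3]))
  al <- alignRigid(hitlead:::.newLibrary(list(cpd)), ref, cbind(1:8, 1:8))
  expect_lt(al@rmsd[["a"]], 1e-6)
  # an already-aligned compound gets the identity transform
  al2 <- alignRigid(hitlead:::.newLibrary(list(
    compound("b", NA, conformer = ref@conformer))), ref, cbind(1:8, 1:8))
  expect_equal(al2@transforms[[1]]$R, diag(3), tolerance = 1e-8)
  expect_equal(al2@transforms[[1]]$t, rep(0, 3), tolerance = 1e-8)
  expect_error(alignRigid(hitlead:::.newLibrary(list(cpd)), ref,
                          cbind(1:2, 1:2)), "at least 3")
})

test_that("reflections are not absorbed: proper rotation enforced", {
  # chiral 4-point set and its mirror image
  P <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 2, 0), c(0, 0, 2.5))
  M <- P %*% diag(c(-1, 1, 1))
  ref <- compound("ref", NA, conformer = data.frame(element = "C",
                                                    x = P[, 1], y = P[, 2],
                                                    z = P[, 3]))
  cpd <- compound("m", NA, conformer = data.frame(element = "C",
                                                  x = M[, 1], y = M[, 2],
                                                  z = M[, 3]))
  al <- alignRigid(hitlead:::.newLibrary(list(cpd)), ref, cbind(1:4, 1:4))
  expect_equal(det(al@transforms[[1]]$R), 1, tolerance = 1e-10)
  expect_gt(al@rmsd[["m"]], 0.1)
  # brute force over random proper rotations cannot beat the Kabsch optimum
  set.seed(31)
  cm <- colMeans(M); cr <- colMeans(P)
  best <- min(vapply(1:500, function(i) {
    R <- randomRotation()
    sqrt(mean(rowSums((sweep(M, 2, cm) %*% R -
                       sweep(P, 2, cr))^2)))
  }, numeric(1)))
  expect_gte(best, al@rmsd[["m"]] - 1e-9)
})

test_that("field channels follow the Gaussian closed form", {
  st <- data.frame(x = 0, y = 0, z = 0, channel = "donor", weight = 1)
  fg <- computeFields(list(st),
                      gridSpec = fieldGridSpec(c(-2, 0, 0), 1, c(5, 1, 1)))
  donor <- fg$X[1, 1:5]
  expect_equal(unname(donor), exp(-0.5 * c(4, 1, 0, 1, 4)), tolerance = 1e-12)
  # every other channel is identically zero
  expect_equal(unname(fg$X[1, -(1:5)]), rep(0, 15))
  # doubling alpha strictly decreases every off-centre value
  fg2 <- computeFields(list(st),
                       gridSpec = fieldGridSpec(c(-2, 0, 0), 1, c(5, 1, 1)),
                       alpha = 1)
  expect_true(all(fg2$X[1, c(1, 2, 4, 5)] < fg$X[1, c(1, 2, 4, 5)]))
  expect_equal(fg2$X[1, 3], fg$X[1, 3])
  # sites outside an explicit grid raise a bounds error
  expect_error(computeFields(list(st),
                             gridSpec = fieldGridSpec(c(5, 5, 5), 1,
                                                      c(2, 2, 2))),
               "grid-bounds")
})

test_that("a donor-free molecule has a null donor channel", {
  b <- compound("benz", "c1ccccc1", conformer = benzeneConformer())
  # benzene contributes no sites at all, so the grid must be supplied
  fg <- computeFields(hitlead:::.newLibrary(list(b)),
                      gridSpec = fieldGridSpec(c(-4, -4, -4), 2, c(5, 5, 5)))
  m <- prod(fg$gridSpec$dims)
  expect_true(all(fg$X[1, 1:m] == 0))            # no donors
  expect_true(all(fg$X[1, m + 1:m] == 0))        # aromatic C not hydrophobic
  # field values do not depend on compound order
  e <- compound("etoh", "CCO",
                conformer = data.frame(element = c("C", "C", "O"),
                                       x = c(0, 1.5, 2.2), y = 0, z = 0))
  fg12 <- computeFields(hitlead:::.newLibrary(list(b, e)),
                        gridSpec = fieldGridSpec(c(-4, -4, -4), 2,
                                                 c(5, 5, 5)))
  fg21 <- computeFields(hitlead:::.newLibrary(list(e, b)),
                        gridSpec = fieldGridSpec(c(-4, -4, -4), 2,
                                                 c(5, 5, 5)))
  expect_equal(fg12$X["benz", ], fg21$X["benz", ])
  expect_equal(fg12$X["etoh", ], fg21$X["etoh", ])
})

test_that("PLS with full factors equals the least-squares oracle", {
  set.seed(17)
  X <- matrix(rnorm(30), 10, 3)
  y <- drop(X %*% c(1.2, -0.7, 0.4)) + rnorm(10, 0, 0.3)
  fit <- fitPLS(X, y, nFactors = 3)
  ols <- stats::lm(y ~ X)
  expect_lt(max(abs(fit@coefficients - unname(coef(ols)[-1]))), 1e-8)
  expect_lt(abs(fit@intercept - unname(coef(ols)[1])), 1e-8)
  # exact linear truth in one descriptor: with centred orthogonal
  # descriptors a single latent factor reproduces it exactly
  Xo <- qr.Q(qr(scale(matrix(rnorm(30), 10, 3), scale = FALSE)))
  y2 <- drop(Xo %*% c(2, 0, 0))
  fit2 <- fitPLS(Xo, y2, nFactors = 1)
  expect_equal(fit2@r2, 1, tolerance = 1e-10)
  expect_lt(fit2@rmse, 1e-8)
  expect_error(fitPLS(X[1:4, ], y[1:4], nFactors = 3), "under-determined")
  expect_error(fitPLS(X, rep(1, 10)), "degenerate response")
})

test_that("the F formula reproduces the printed model statistic", {
  # r2 = 0.94 with 4 factors back-computes to the printed F at n = 39
  expect_lt(abs(plsFstatistic(0.94, 4, 39) - 133.0) / 133.0, 0.002)
})

test_that("cross-validated q2 equals an explicit brute-force fold loop", {
  gen <- genQsar(3, nCompounds = 24L, noiseSd = 0.4)
  X <- gen$fields$X; y <- gen$y
  cv <- crossValidate(X, y, k = 5, nRepeats = 2, nFactors = 4, seed = 99)
  ## independent recomputation: same seeded partitions, explicit loops
  n <- length(y)
  q2b <- numeric(2)
  withr::with_seed(99L, {
    for (r in 1:2) {
      perm <- sample.int(n)
      fold <- integer(n); fold[perm] <- ceiling(seq_len(n) / 5)
      press <- 0
      for (f in unique(fold)) {
        test <- which(fold == f)
        m <- fitPLS(X[-test, , drop = FALSE], y[-test], nFactors = 4)
        press <- press + sum((y[test] -
                              predict(m, X[test, , drop = FALSE]))^2)
      }
      q2b[r] <- 1 - press / sum((y - mean(y))^2)
    }
  })
  expect_lt(max(abs(cv$q2PerRepeat - q2b)), 1e-10)
  expect_lt(abs(cv$q2 - mean(q2b)), 1e-10)
})

test_that("q2 behaves: near 1 for noiseless truth, negative for pure noise", {
  gen <- genQsar(5, nCompounds = 40L, noiseSd = 0)
  p <- ncol(gen$fields$X)
  cv <- crossValidate(gen$fields$X, gen$y, k = 5, nRepeats = 1,
                      nFactors = p, seed = 1)
  expect_gte(cv$q2, 0.999)
  fit <- fitPLS(gen$fields$X, gen$y, nFactors = 4)
  cv4 <- crossValidate(gen$fields$X, gen$y, k = 5, nRepeats = 2,
                       nFactors = 4, seed = 1)
  expect_lte(cv4$q2, fit@r2 + 1e-8)   # q2 never beats training r2
  ## pure-noise response: mean q2 over seeded replicates is negative
  set.seed(202)
  q2noise <- vapply(1:60, function(i) {
    Xn <- matrix(rnorm(15 * 4), 15, 4)
    yn <- rnorm(15)
    crossValidate(Xn, yn, k = 5, nRepeats = 1, nFactors = 2,
                  seed = i)$q2
  }, numeric(1))
  expect_lt(mean(q2noise), 0)
  expect_error(crossValidate(matrix(rnorm(20), 5, 4), rnorm(5), k = 5),
               "smaller")
})

test_that("prediction honours the planted linear rule", {
  gen <- genQsar(8, nCompounds = 40L, noiseSd = 0)
  p <- ncol(gen$fields$X)
  fit <- fitPLS(gen$fields, gen$y, nFactors = p)
  # training compounds are reproduced within the (tiny) training rmse
  pred <- predict(fit, gen$fields)
  expect_lt(max(abs(pred - gen$y)), 1e-6)
  # an unseen compound generated from the same rule is predicted exactly
  newSites <- genQsar(1234, nCompounds = 1L, noiseSd = 0)$siteTables
  fgNew <- computeFields(newSites, gridSpec = gen$gridSpec)
  yTrue <- drop(fgNew$X %*% gen$beta) + 5
  expect_lt(abs(predict(fit, fgNew) - yTrue), 1e-6)
  # all-zero descriptors predict the centred-model intercept
  expect_equal(unname(predict(fit, rep(0, p))), fit@intercept)
  # grid mismatch is a configuration error
  other <- computeFields(newSites,
                         gridSpec = fieldGridSpec(c(0, 0, 0), 3, c(3, 3, 3)))
  expect_error(predict(fit, other), "grid")
})

test_that("parameter recovery at zero noise: r2, q2 and coefficient direction", {
  for (s in c(2, 4)) {
    gen <- genQsar(s, nCompounds = 40L, noiseSd = 0)
    p <- ncol(gen$fields$X)
    fit <- fitPLS(gen$fields, gen$y, nFactors = p)
    expect_gte(fit@r2, 0.999)
    beta <- numeric(p); beta[fit@keptColumns] <- fit@coefficients
    cosang <- sum(beta * gen$beta) /
      sqrt(sum(beta^2) * sum(gen$beta^2))
    expect_gte(cosang, 0.99)
    cv <- crossValidate(gen$fields$X, gen$y, k = 5, nRepeats = 1,
                        nFactors = min(p, 33L), seed = s)
    expect_gte(cv$q2, 0.95)
  }
})

test_that("field maps reshape coefficients with planted-sign fidelity", {
  gen <- genQsar(6, nCompounds = 40L, noiseSd = 0)
  p <- ncol(gen$fields$X)
  fit <- fitPLS(gen$fields, gen$y, nFactors = p)
  maps <- fieldMaps(fit)
  m <- prod(gen$gridSpec$dims)
  expect_equal(nrow(maps), 4L * m)
  expect_setequal(unique(maps$channel), hitlead:::.FIELD_CHANNELS)
  # strongest planted coefficient keeps its sign in the map
  top <- which.max(abs(gen$beta))
  expect_equal(sign(maps$coefficient[top]), sign(gen$beta[top]))
  # an all-noise model yields visibly smaller coefficients than the
  # planted-signal fit on the same descriptors
  withr::with_seed(60L, yNoise <- rnorm(40, mean(gen$y), sd(gen$y) / 10))
  fitN <- fitPLS(gen$fields, yNoise, nFactors = 4)
  fitS <- fitPLS(gen$fields, gen$y, nFactors = 4)
  expect_lt(max(abs(fitN@coefficients)), max(abs(fitS@coefficients)))
  expect_error(fieldMaps(fitPLS(matrix(rnorm(40), 10, 4), rnorm(10),
                                nFactors = 2)), "field-grid")
})
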