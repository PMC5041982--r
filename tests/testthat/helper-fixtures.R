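# In-code fixtures shared across the suite.

# planar benzene ring, 1.39 A C-C
benzeneConformer <- function() {
  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  data.frame(element = "C", x = 1.39 * cos(th), y = 1.39 * sin(th), z = 0)
}

# minimal SDF V2000 text: one 3-atom molecule with 3D coordinates
sdfThreeAtoms <- function(id = "tri") {
  c(id, "  synthetic 3D", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.5000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000    1.2000    1.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  1  0  0  0  0",
    "M  END", "$$$$")
}

randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# reference pharmacophore geometry with pair distances at bin centres
# (default edges 0,2,4,...): features D, A, N, P
refGeometry <- function() {
  data.frame(ftype = c("D", "A", "N", "P"),
             x = c(0, 3, 0, 3), y = c(0, 0, 5, 5), z = 0,
             stringsAsFactors = FALSE)
}

# library of feature tables: analogs are jittered rigid motions of the
# reference geometry (jitter small enough that no pair changes bin),
# decoys use disjoint feature types (H, R only)
geomLibrary <- function(seed, nAnalogs = 10, nDecoys = 90, jitter = 0.15) {
  withr::with_seed(seed, {
    ref <- refGeometry()
    lib <- list()
    for (i in seq_len(nAnalogs)) {
      R <- randomRotation()
      co <- as.matrix(ref[, c("x", "y", "z")]) %*% R
      co <- sweep(co, 2, rnorm(3, 0, 4), "+") +
        matrix(runif(length(co), -jitter, jitter), ncol = 3)
      f <- ref; f[, c("x", "y", "z")] <- co
      lib[[sprintf("A%03d", i)]] <- f
    }
    for (i in seq_len(nDecoys)) {
      n <- sample(4:8, 1)
      lib[[sprintf("D%03d", i)]] <- data.frame(
        ftype = sample(c("H", "R"), n, replace = TRUE),
        x = runif(n, -5, 5), y = runif(n, -5, 5), z = runif(n, -5, 5),
        stringsAsFactors = FALSE)
    }
  })
  lib
}

# independent pharmacophore score: explicit double loop, no package code
bruteScore <- function(fa, fb, edges = c(0, 2, 4, 6, 8, 10, 12)) {
  keyCounts <- function(f) {
    cnt <- list()
    n <- nrow(f)
    if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((as.numeric(f[i, c("x", "y", "z")]) -
                     as.numeric(f[j, c("x", "y", "z")]))^2))
      b <- sum(d >= edges)  # 1-based bin, overflow past last edge
      ts <- sort(c(f$ftype[i], f$ftype[j]))
      k <- paste(ts[1], ts[2], b)
      cnt[[k]] <- (cnt[[k]] %||% 0) + 1
    }
    cnt
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  ca <- keyCounts(fa); cb <- keyCounts(fb)
  keys <- union(names(ca), names(cb))
  if (!length(keys)) return(100)
  mins <- maxs <- 0
  for (k in keys) {
    av <- if (k %in% names(ca)) ca[[k]] else 0
    bv <- if (k %in% names(cb)) cb[[k]] else 0
    mins <- mins + min(av, bv); maxs <- maxs + max(av, bv)
  }
  if (maxs == 0) 100 else 100 * mins / maxs
}

# write a throwaway activity CSV
writeActivityCsv <- function(path, ids, ic50, assay = "SPR") {
  write.csv(data.frame(compound_id = ids, ic50_molar = ic50, assay = assay),
            path, row.names = FALSE)
}
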