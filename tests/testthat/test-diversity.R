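test_that("shannon entropy and richness match the closed forms", {
  u <- matrix(c(3, 3, 3, 3), 4, dimnames = list(letters[1:4], "s"))
  expect_equal(alphaDiversity(u)$shannon, 2)        # uniform over 4, base 2
  expect_equal(alphaDiversity(u)$richness, 4L)

  one <- matrix(9, 1, dimnames = list("a", "s"))
  expect_equal(alphaDiversity(one)$shannon, 0)
  expect_equal(alphaDiversity(one)$richness, 1L)

  m <- matrix(c(5, 3, 2), 3, dimnames = list(letters[1:3], "s"))
  expect_equal(alphaDiversity(m)$shannon, 1.4855, tolerance = 1e-3)
  # base-e option is a change of base
  expect_equal(alphaDiversity(m, base = exp(1))$shannon,
               alphaDiversity(m)$shannon * log(2))

  expect_error(alphaDiversity(matrix(0, 1, 1,
    dimnames = list("a", "s"))), "zero-total")
})

test_that("shannon is maximal for uniform profiles and label-invariant", {
  set.seed(11)
  for (i in 1:20) {
    v <- rpois(8, 20) + 1
    m <- cbind(obs = v, unif = rep(sum(v) %/% 8 + 1, 8))
    rownames(m) <- paste0("f", 1:8)
    a <- alphaDiversity(m)
    expect_lte(a$shannon[1], log2(8) + 1e-12)
    perm <- m[sample(8), , drop = FALSE]
    expect_equal(alphaDiversity(perm)$shannon, a$shannon)
  }
})

test_that("bray-curtis matches the min-sum formula and its bounds", {
  m <- cbind(a = c(6, 4, 0), b = c(2, 0, 8), a2 = c(6, 4, 0))
  rownames(m) <- paste0("f", 1:3)
  d <- as.matrix(brayCurtisMatrix(m))
  expect_equal(d["a", "b"], 0.8)          # 1 - 2*2/20
  expect_equal(d["a", "a2"], 0)           # identical columns
  disj <- cbind(x = c(5, 0), y = c(0, 7))
  rownames(disj) <- c("f1", "f2")
  expect_equal(as.matrix(brayCurtisMatrix(disj))["x", "y"], 1)

  set.seed(21)
  r <- matrix(rpois(50, 5), 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:5)))
  dr <- as.matrix(brayCurtisMatrix(r))
  expect_true(isSymmetric(dr))
  expect_true(all(dr >= 0 & dr <= 1))
  expect_true(all(diag(dr) == 0))
})

test_that("pcoa embeds euclidean configurations exactly", {
  # colinear points at 0, 3, 5: first axis reproduces the gaps
  x <- c(A = 0, B = 3, C = 5)
  d <- stats::dist(x)
  ord <- pcoaOrdination(d)
  ax1 <- ord$coordinates[, 1]
  expect_equal(unname(abs(ax1["B"] - ax1["A"])), 3, tolerance = 1e-8)
  expect_equal(unname(abs(ax1["C"] - ax1["B"])), 2, tolerance = 1e-8)
  expect_equal(unname(abs(ax1["C"] - ax1["A"])), 5, tolerance = 1e-8)
  expect_true(all(abs(ord$eigenvalues[-1]) < 1e-8))

  # generic euclidean cloud: coordinate distances reconstruct d
  set.seed(31)
  pts <- matrix(rnorm(8 * 3), 8, dimnames = list(paste0("s", 1:8), NULL))
  d8 <- stats::dist(pts)
  ord8 <- pcoaOrdination(d8)
  expect_equal(as.matrix(stats::dist(ord8$coordinates)),
               as.matrix(d8), tolerance = 1e-8)

  # degenerate all-zero distances
  d0 <- stats::as.dist(matrix(0, 3, 3,
    dimnames = list(letters[1:3], letters[1:3])))
  expect_true(all(pcoaOrdination(d0)$coordinates == 0))
})

test_that("pcoa reports the spectrum honestly", {
  # equilateral triangle, side 2: two equal positive eigenvalues (= 2)
  m <- matrix(2, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(m) <- 0
  ord <- pcoaOrdination(m)
  pos <- ord$eigenvalues[ord$eigenvalues > 1e-8]
  expect_length(pos, 2L)
  expect_equal(pos[1], pos[2], tolerance = 1e-8)
  expect_equal(pos[1], 2, tolerance = 1e-8)
  expect_equal(sum(ord$proportionExplained, na.rm = TRUE), 1,
               tolerance = 1e-8)

  expect_error(pcoaOrdination(matrix(c(0, 1, 2, 0), 2)), "symmetric")

  # non-euclidean input -> negative eigenvalues surfaced with a warning
  set.seed(41)
  cnt <- matrix(rpois(60, 3), 10,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  expect_warning(pcoaOrdination(brayCurtisMatrix(cnt)),
                 "negative eigenvalues")
})

test_that("upgma reproduces the hand-run merge order and heights", {
  m <- matrix(c(0, 2, 6,
                2, 0, 6,
                6, 6, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgmaTree(m)
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp["A", "B"], 2)   # merged at height 1
  expect_equal(cp["A", "C"], 6)   # C joins at height 3
  expect_equal(cp["B", "C"], 6)
  expect_true(ape::is.ultrametric(tr))

  # two samples: single root at d/2
  m2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  tr2 <- upgmaTree(m2)
  expect_equal(unname(ape::node.depth.edgelength(tr2)[1:2]), c(1.5, 1.5))

  # all-equal distances: lexicographically first pair merges first
  m3 <- matrix(1, 3, 3, dimnames = list(c("b", "c", "a"), c("b", "c", "a")))
  diag(m3) <- 0
  tr3 <- upgmaTree(m3)
  first <- ape::extract.clade(tr3, ape::getMRCA(tr3, c("a", "b")))
  expect_setequal(first$tip.label, c("a", "b"))
})

test_that("upgma agrees with the reference average-linkage implementation", {
  skip_if_not_installed("phangorn")
  set.seed(51)
  for (i in 1:5) {
    pts <- matrix(rnorm(7 * 4), 7, dimnames = list(paste0("s", 1:7), NULL))
    d <- stats::dist(pts)   # continuous: ties have probability zero
    ours <- ape::cophenetic.phylo(upgmaTree(d))
    ref <- ape::cophenetic.phylo(phangorn::upgma(d))
    expect_equal(ours[rownames(ref), colnames(ref)], ref,
                 tolerance = 1e-8)
  }
})

test_that("permanova pseudo-F and R2 agree with vegan::adonis2", {
  set.seed(61)
  cnt <- matrix(rpois(120, 8), 10,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:12)))
  d <- brayCurtisMatrix(cnt)
  g <- rep(c("u", "v", "w"), each = 4)
  ours <- permanovaTest(d, g, nPermutations = 99, seed = 1)
  meta <- data.frame(g = g)
  ref <- vegan::adonis2(d ~ g, data = meta, permutations = 99)
  expect_equal(ours$pseudoF, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$R2, ref$R2[1], tolerance = 1e-10)
  # determinism and p bounds
  expect_identical(ours$p_value,
                   permanovaTest(d, g, nPermutations = 99, seed = 1)$p_value)
  expect_gte(ours$p_value, 1 / 100)
  expect_lte(ours$p_value, 1)
})

test_that("permanova degenerate and exact cases behave as designed", {
  m <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- 0
  # all distances equal: F constant over permutations, p = 1
  res <- permanovaTest(m, c("x", "x", "y", "y"), nPermutations = 49,
                       seed = 3)
  expect_equal(res$p_value, 1)
  expect_error(permanovaTest(m, rep("x", 4), seed = 1), "two groups")

  # exhaustive mode equals the brute-force oracle over all 3+3 splits
  set.seed(71)
  pts <- matrix(rnorm(6 * 2), 6, dimnames = list(paste0("s", 1:6), NULL))
  d <- stats::dist(pts)
  g <- rep(c("p", "q"), each = 3)
  ours <- permanovaTest(d, g, exact = TRUE)
  # oracle: Gower-centred trace formulation evaluated on every split
  D2 <- as.matrix(d)^2
  J <- diag(6) - matrix(1 / 6, 6, 6)
  G <- -0.5 * J %*% D2 %*% J
  fOf <- function(lab) {
    H <- model.matrix(~lab)
    H <- H %*% solve(crossprod(H)) %*% t(H)
    ssa <- sum(diag(H %*% G))
    ssr <- sum(diag((diag(6) - H) %*% G))
    (ssa / 1) / (ssr / 4)
  }
  fobs <- fOf(factor(g))
  splits <- utils::combn(6, 3)
  fs <- apply(splits, 2, function(ix) {
    lab <- factor(replace(rep("q", 6), ix, "p"))
    fOf(lab)
  })
  p_oracle <- mean(fs >= fobs - 1e-12)
  expect_equal(ours$pseudoF, fobs, tolerance = 1e-10)
  expect_equal(ours$p_value, p_oracle, tolerance = 1e-12)
})
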