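test_that("one-way ANOVA matches the brute-force sum-of-squares decomposition", {
  set.seed(101)
  for (i in 1:10) {
    g <- rep(c("CK", "A", "B", "C", "D"), each = 3)
    y <- rnorm(15, mean = rep(runif(5, 0, 3), each = 3))
    res <- one_way_anova(y, g)
    gm <- mean(y)
    mns <- tapply(y, g, mean)
    ssb <- sum(3 * (mns - gm)^2)
    ssw <- sum((y - mns[g])^2)
    expect_equal(res$table$ss[1], ssb, tolerance = 1e-9)
    expect_equal(res$table$ss[2], ssw, tolerance = 1e-9)
    expect_equal(res$table$df[1:2], c(4, 10))
    expect_equal(res$table$F[1], (ssb / 4) / (ssw / 10), tolerance = 1e-9)
    expect_equal(res$r_squared, ssb / (ssb + ssw), tolerance = 1e-9)
  }
})

test_that("two-group F equals the squared pooled t statistic", {
  set.seed(202)
  for (i in 1:10) {
    y1 <- rnorm(6); y2 <- rnorm(5, 1)
    res <- one_way_anova(c(y1, y2), rep(c("a", "b"), c(6, 5)))
    tt <- t.test(y1, y2, var.equal = TRUE)
    expect_equal(res$table$F[1], unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$table$p[1], tt$p.value, tolerance = 1e-9)
  }
})

test_that("ANOVA handles degenerate and invalid designs", {
  # identical group means with residual noise: F = 0
  y <- c(1, 2, 3, 1, 2, 3, 1, 2, 3)
  res <- one_way_anova(y, rep(c("a", "b", "c"), each = 3))
  expect_equal(res$table$F[1], 0)
  # no variance anywhere: F undefined
  flat <- one_way_anova(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_true(is.na(flat$table$F[1]))
  # perfectly separated constants: infinite F
  sep <- one_way_anova(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3))
  expect_equal(sep$table$F[1], Inf)
  expect_error(one_way_anova(1:5, rep("a", 5)), class = "nema_design_error")
  expect_error(one_way_anova(c(1, 2), c("a", "b")), class = "nema_design_error")
})

test_that("LSD pairwise decisions agree with the per-pair formula", {
  set.seed(303)
  g <- rep(c("CK", "A", "B"), each = 4)
  y <- rnorm(12, mean = rep(c(0, 0.5, 3), each = 4))
  res <- lsd_pairwise(y, g, alpha = 0.05)
  aovr <- one_way_anova(y, g)
  msw <- aovr$table$ms[2]; dfw <- aovr$table$df[2]
  mns <- tapply(y, g, mean); ns <- tapply(y, g, length)
  tcrit <- qt(0.975, dfw)
  for (r in seq_len(nrow(res))) {
    d <- mns[[res$group1[r]]] - mns[[res$group2[r]]]
    lsd <- tcrit * sqrt(msw * (1 / ns[[res$group1[r]]] + 1 / ns[[res$group2[r]]]))
    expect_equal(res$diff[r], d, tolerance = 1e-12)
    expect_equal(res$significant[r], abs(d) > lsd)
  }
  # identical groups: nothing significant
  flatres <- lsd_pairwise(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_false(any(flatres$significant))
  # huge separation: everything significant
  bigres <- lsd_pairwise(c(rnorm(3), rnorm(3, 100)), rep(c("a", "b"), each = 3))
  expect_true(all(bigres$significant))
})

test_that("compact letters encode exactly the non-significant pairs", {
  means <- c(A = 3, B = 2, C = 1)
  none <- data.frame(group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
                     significant = FALSE)
  expect_equal(unname(compact_letters(means, none)), c("a", "a", "a"))
  all_sig <- transform(none, significant = TRUE)
  expect_equal(unname(compact_letters(means, all_sig)), c("a", "b", "c"))
  # chain A != C, A ~ B, B ~ C -> a, ab, b
  chain <- data.frame(group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
                      significant = c(FALSE, TRUE, FALSE))
  expect_equal(unname(compact_letters(means, chain)), c("a", "ab", "b"))
})

test_that("letter displays decode back to the input relation on random cases", {
  set.seed(404)
  for (i in 1:200) {
    k <- sample(3:6, 1)
    gn <- LETTERS[seq_len(k)]
    means <- setNames(runif(k, 0, 10), gn)
    sig <- matrix(FALSE, k, k, dimnames = list(gn, gn))
    up <- which(upper.tri(sig))
    sig[up] <- runif(length(up)) < 0.4
    sig <- sig | t(sig)
    ltr <- compact_letters(means, sig)
    expect_identical(decode_letters(ltr), sig, label = paste("case", i))
  }
})

test_that("balanced two-factor ANOVA reproduces the design df structure", {
  set.seed(505)
  # 5 treatments x 5 layers x 3 replicates
  a <- rep(c("CK", "A", "B", "C", "D"), each = 15)
  b <- rep(rep(depth_layer_labels(), each = 3), times = 5)
  y <- rnorm(75, mean = as.numeric(factor(b)))
  res <- two_way_anova_balanced(y, a, b)
  expect_equal(res$table$df, c(4, 4, 16, 50, 74))
  # 2 x 2 x 2
  y2 <- rnorm(8)
  res2 <- two_way_anova_balanced(y2, rep(c("x", "y"), each = 4),
                                 rep(c("u", "v"), 4))
  expect_equal(res2$table$df, c(1, 1, 1, 4, 7))
  # unbalanced: rejected
  expect_error(two_way_anova_balanced(y[-1], a[-1], b[-1]),
               class = "nema_design_error")
  # single replicate per cell: rejected
  expect_error(
    two_way_anova_balanced(rnorm(4), c("x", "x", "y", "y"), c("u", "v", "u", "v")),
    class = "nema_design_error")
})

test_that("two-factor SS decomposition matches brute-force cell means", {
  set.seed(606)
  for (i in 1:5) {
    a_lv <- 3; b_lv <- 4; r <- 3
    a <- rep(letters[1:a_lv], each = b_lv * r)
    b <- rep(rep(LETTERS[1:b_lv], each = r), times = a_lv)
    y <- rnorm(a_lv * b_lv * r, mean = as.numeric(factor(a)) * 0.5)
    res <- two_way_anova_balanced(y, a, b)
    gm <- mean(y)
    am <- tapply(y, a, mean); bm <- tapply(y, b, mean)
    cm <- tapply(y, interaction(a, b), mean)
    ssa <- b_lv * r * sum((am - gm)^2)
    ssb <- a_lv * r * sum((bm - gm)^2)
    sse <- sum((y - cm[interaction(a, b)])^2)
    sst <- sum((y - gm)^2)
    ssab <- sst - ssa - ssb - sse
    expect_equal(res$table$ss[1:4], c(ssa, ssb, ssab, sse), tolerance = 1e-9)
    # SS conservation
    expect_equal(sum(res$table$ss[1:4]), sst, tolerance = 1e-9)
    expect_equal(res$r_squared, 1 - sse / sst, tolerance = 1e-9)
  }
})
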