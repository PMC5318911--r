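test_that("standardization hits zero mean / unit variance per unit", {
  x <- matrix(c(1, 2, 3, 4, 6, 8), 3, 2)
  s <- standardize(x, "sample")
  expect_equal(unname(s[, 1]), c(-1, 0, 1))
  expect_equal(colMeans(s), c(0, 0))
  expect_equal(apply(s, 2, sd), c(1, 1))
  expect_equal(standardize(s, "sample"), s)  # idempotent
  expect_warning(s0 <- standardize(cbind(c(1, 2, 3), c(5, 5, 5)), "sample"),
                 "zero-variance")
  expect_equal(unname(s0[, 2]), c(0, 0, 0))
  sf <- standardize(matrix(1:6, 2, 3, byrow = TRUE), "feature")
  expect_equal(unname(rowMeans(sf)), c(0, 0))
})

test_that("complement is the mean-zero mirror and an involution", {
  v <- c(-1, 0, 1)
  expect_equal(complement(v), c(1, 0, -1))
  expect_equal(complement(complement(v)), v)
  expect_equal(complement(numeric(3)), numeric(3))
})

test_that("coarse clusters obey the strict similarity radius", {
  lab <- rep(c("A", "B"), each = 4)
  set.seed(3)
  x <- rbind(seed = c(rnorm(4, -3), rnorm(4, 3)),
             dup  = c(rnorm(4, -3), rnorm(4, 3)),
             junk = rnorm(8))
  x["dup", ] <- x["seed", ]            # exact duplicate, S = 1
  fit <- rhsac(x, lab, delta = 0.9, standardize_mode = "none")
  expect_true("dup" %in% fit$rules[[1]]$coarse)
  expect_false("junk" %in% fit$rules[[1]]$coarse)
  # delta = 1 with strict > excludes even an exact duplicate
  fit1 <- rhsac(x, lab, delta = 1, standardize_mode = "none")
  expect_length(fit1$rules[[1]]$coarse, 0)
})

test_that("refinement matches the exhaustive greedy-trace oracle", {
  for (s in c(7, 8, 9, 10)) {
    fx <- fixture_expression(seed = s)
    xs <- standardize(fx$x, "sample")
    gam <- sapply(seq_len(nrow(xs)), function(i)
      rh_relevance(xs[i, ], fx$labels))
    seed_i <- which.max(gam)
    coarse_i <- setdiff(seq_len(nrow(xs)), seed_i)
    got <- rhsac:::.refine_cluster(seed_i, coarse_i, xs, factor(fx$labels))
    want <- oracle_refine(seed_i, coarse_i, xs, fx$labels)
    expect_equal(got$members, want$member)
    expect_equal(got$signs, want$sign)
    expect_equal(got$representative,
                 colSums(xs[want$member, , drop = FALSE] * want$sign) /
                   nrow(want))
  }
})

test_that("an exact duplicate of the seed never joins the finer cluster", {
  lab <- rep(c("A", "B"), each = 4)
  x <- rbind(a = c(1, 2, 1.5, 2.5, 5, 6, 5.5, 6.5))
  x <- rbind(a = x[1, ], b = x[1, ])
  got <- rhsac:::.refine_cluster(1L, 2L, x, factor(lab))
  expect_equal(got$members, 1L)
  expect_equal(got$representative, x[1, ])
})

test_that("rule relevance never falls below the seed relevance", {
  fx <- fixture_expression(seed = 21, n_feat = 10)
  fit <- rhsac(fx$x, fx$labels, delta = 0.5)
  for (r in fit$rules) {
    expect_gte(r$relevance, unname(r$seed_relevance) - 1e-12)
    expect_true(r$seed %in% r$finer$member)
    expect_equal(r$finer$sign[r$finer$member == r$seed], 1)
    expect_true(all(r$finer$member %in% r$members))
  }
})

test_that("clustering emits disjoint rules, terminates, is deterministic", {
  fx <- fixture_expression(seed = 5, n_feat = 12, n = 10)
  fit <- rhsac(fx$x, fx$labels, delta = 0.7)
  memb <- unlist(lapply(fit$rules, `[[`, "members"))
  expect_equal(anyDuplicated(memb), 0L)
  expect_lte(length(fit$rules), nrow(fx$x))
  fit2 <- rhsac(fx$x, fx$labels, delta = 0.7)
  expect_identical(rule_table(fit), rule_table(fit2))
  # max_clusters = 1: single rule seeded by the most relevant feature
  fit3 <- rhsac(fx$x, fx$labels, max_clusters = 1)
  expect_length(fit3$rules, 1L)
  expect_equal(fit3$rules[[1]]$seed,
               names(which.max(fit3$feature_relevance)))
  # delta = 1: all coarse clusters empty, one singleton rule per feature
  fit4 <- rhsac(fx$x, fx$labels, delta = 1)
  expect_length(fit4$rules, nrow(fx$x))
  expect_true(all(lengths(lapply(fit4$rules, `[[`, "members")) == 1L))
})

test_that("rule table and methods expose a consistent view", {
  fx <- fixture_expression(seed = 2)
  fit <- rhsac(fx$x, fx$labels)
  tab <- rule_table(fit)
  expect_setequal(unique(tab$role), intersect(c("seed", "finer", "coarse-only"),
                                              unique(tab$role)))
  expect_equal(sum(tab$role == "seed"), length(fit$rules))
  cf <- coef(fit)
  expect_equal(nrow(cf), length(fit$rules))
  expect_equal(ncol(cf), ncol(fx$x))
  sm <- summary(fit)
  expect_equal(nrow(sm), length(fit$rules))
  expect_output(print(fit), "rule")
})
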