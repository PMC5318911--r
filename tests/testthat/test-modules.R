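test_that("target reduction keeps the union of member targets present", {
  tt <- target_table(data.frame(
    mirna = c("miR1", "miR1", "miR2", "miR2", "miR2"),
    gene = c("g1", "g2", "g2", "g3", "g2")))  # duplicate pair dropped
  expect_equal(nrow(tt), 4L)
  m <- matrix(rnorm(12), 3, 4, dimnames = list(c("g1", "g2", "g4"), NULL))
  red <- suppressMessages(
    reduce_mrna_matrix(list(members = c("miR1", "miR2")), tt, m))
  expect_setequal(rownames(red), c("g1", "g2"))
  expect_warning(r0 <- reduce_mrna_matrix(list(members = "miRx"), tt, m),
                 "no targets")
  expect_equal(nrow(r0), 0L)
})

test_that("module edges require target-table support", {
  tt <- target_table(data.frame(mirna = "miR1", gene = "g1"))
  rules <- list(list(rule_id = 1L, members = "miR1"))
  mr <- list(list(list(members = "g1")))
  mods <- build_modules(rules, mr, tt)
  expect_length(mods, 1L)
  expect_equal(nrow(mods[[1]]$edges), 1L)
  # same nodes, unsupported pair: module keeps nodes, drops the edge
  tt2 <- target_table(data.frame(mirna = "miR9", gene = "g9"))
  mods2 <- build_modules(rules, mr, tt2)
  expect_equal(nrow(mods2[[1]]$edges), 0L)
  expect_equal(mods2[[1]]$mirnas, "miR1")
})

test_that("edge correlations equal the covariance formula", {
  tt <- target_table(data.frame(mirna = c("m1", "m1"),
                                gene = c("g1", "g2")))
  set.seed(8)
  mi <- matrix(rnorm(10), 1, 10, dimnames = list("m1", NULL))
  mr <- rbind(g1 = -mi[1, ], g2 = 2 * mi[1, ] + 1)
  mods <- build_modules(list(list(rule_id = 1, members = "m1")),
                        list(list(list(members = c("g1", "g2")))), tt)
  mods <- edge_correlations(mods, mi, mr)
  e <- mods[[1]]$edges
  expect_equal(e$pearson_r[e$gene == "g1"], -1)
  expect_equal(e$pearson_r[e$gene == "g2"], 1)
  # random fixture against the explicit formula
  set.seed(9)
  a <- rnorm(10); b <- rnorm(10)
  mi2 <- matrix(a, 1, 10, dimnames = list("m1", NULL))
  mr2 <- matrix(b, 1, 10, dimnames = list("g1", NULL))
  mods2 <- edge_correlations(
    build_modules(list(list(rule_id = 1, members = "m1")),
                  list(list(list(members = "g1"))),
                  target_table(data.frame(mirna = "m1", gene = "g1"))),
    mi2, mr2)
  r_formula <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(mods2[[1]]$edges$pearson_r, r_formula, tolerance = 1e-12)
  # zero-variance profile: undefined, recorded as missing
  mr3 <- matrix(5, 1, 10, dimnames = list("g1", NULL))
  mods3 <- edge_correlations(
    build_modules(list(list(rule_id = 1, members = "m1")),
                  list(list(list(members = "g1"))),
                  target_table(data.frame(mirna = "m1", gene = "g1"))),
    mi2, mr3)
  expect_true(is.na(mods3[[1]]$edges$pearson_r))
})

test_that("sign counting ignores zeros and missing values", {
  expect_equal(unname(count_correlation_signs(c(0.5, -0.5, 0.1))), c(2L, 1L))
  expect_equal(unname(count_correlation_signs(c(0, 0, 0))), c(0L, 0L))
  expect_equal(unname(count_correlation_signs(c(NA, -1))), c(0L, 1L))
})

test_that("published module-3 correlation table has 13 positive entries", {
  tab <- read.delim(system.file("extdata", "module3_correlations.tsv",
                                package = "rhsac"))
  cnt <- count_correlation_signs(tab$pearson_r)
  expect_equal(unname(cnt["n_positive"]), 13L)
  expect_equal(nrow(tab), 30L)
})

test_that("overlap test builds consistent tables and matches fisher.test", {
  res <- overlap_fisher(gene_set = c("A", "b ", "C", "D"),
                        reference_list = c("B", "c", "E"),
                        universe_size = 10)
  expect_equal(unname(res$table["in", ]), c(2, 2))   # case-insensitive match
  expect_equal(sum(res$table), 10)
  expect_equal(res$p_value,
               fisher.test(res$table)$p.value, tolerance = 1e-12)
  expect_equal(overlap_fisher(table = c(5, 5, 5, 5))$p_value, 1)
  expect_error(overlap_fisher(gene_set = letters[1:5],
                              reference_list = letters[1:5],
                              universe_size = 4), "universe")
})

test_that("Fisher p equals hypergeometric enumeration across table sizes", {
  # exhaustive at small n, 400 sampled tables per larger n
  for (n in c(8, 20, 41, 60)) {
    combos <- expand.grid(a = 0:n, b = 0:n, cc = 0:n)
    combos <- combos[combos$a + combos$b + combos$cc <= n, ]
    idx <- seq_len(nrow(combos))
    if (n > 20) { set.seed(n); idx <- sample(idx, 400) }
    for (i in idx) {
      tb <- c(combos$a[i], combos$b[i], combos$cc[i],
              n - combos$a[i] - combos$b[i] - combos$cc[i])
      expect_equal(overlap_fisher(table = tb)$p_value,
                   fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                   tolerance = 1e-9)
    }
  }
  # randomized tables up to n = 200
  set.seed(17)
  for (i in 1:300) {
    n <- sample(61:200, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    tb <- c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2], n - cuts[3])
    expect_equal(overlap_fisher(table = tb)$p_value,
                 fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})
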