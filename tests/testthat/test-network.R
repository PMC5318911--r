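toy_tab <- function() {
  data.frame(source = c("A", "B", "C"), target = c("B", "C", "D"),
             sign = c(1, -1, 1),
             source_kind = c("TF", "gene", "gene"),
             target_kind = c("gene", "gene", "gene"),
             stringsAsFactors = FALSE)
}

test_that("construction validates kinds, endpoints and deduplicates", {
  nodes <- data.frame(id = c("A", "B"), kind = c("TF", "gene"))
  net <- signed_network(nodes, data.frame(source = c("A", "A"),
                                          target = c("B", "B"),
                                          sign = c(1, -1)))
  expect_equal(nrow(net$edges), 1L)  # duplicate pair: first kept
  expect_equal(net$edges$sign, 1)
  expect_error(signed_network(data.frame(id = "A", kind = "protein"),
                              NULL), "unknown node kind")
  expect_error(signed_network(nodes, data.frame(source = "A", target = "Z")),
               "not in nodes")
})

test_that("expansion grows layer by layer from the seeds", {
  seeds <- data.frame(id = c("A", "B"), kind = c("TF", "gene"))
  n0 <- expand_network(seeds, toy_tab(), layers = 0)
  expect_equal(nrow(n0$edges), 1L)          # only A -> B among seeds
  n1 <- expand_network(seeds, toy_tab(), layers = 1)
  expect_setequal(n1$nodes$id, c("A", "B", "C"))
  expect_equal(nrow(n1$edges), 2L)
  expect_setequal(n1$nodes$id[n1$nodes$seed], c("A", "B"))
  n2 <- expand_network(seeds, toy_tab(), layers = 2)
  expect_setequal(n2$nodes$id, c("A", "B", "C", "D"))
})

test_that("expansion matches a breadth-limited oracle on random tables", {
  set.seed(5)
  for (i in 1:25) {
    ids <- sprintf("n%d", 1:12)
    tab <- data.frame(source = sample(ids, 20, TRUE),
                      target = sample(ids, 20, TRUE),
                      sign = sample(c(-1, 1), 20, TRUE),
                      source_kind = "gene", target_kind = "gene",
                      stringsAsFactors = FALSE)
    tab <- tab[tab$source != tab$target, ]
    seeds <- data.frame(id = sample(ids, 2), kind = "gene")
    layers <- sample(0:2, 1)
    got <- expand_network(seeds, tab, layers = layers)
    want <- oracle_expand(seeds$id, tab, layers)
    expect_setequal(got$nodes$id, want$nodes)
    expect_equal(nrow(got$edges),
                 nrow(unique(want$edges)))
  }
})

test_that("pruning follows the four single passes and spares seeds", {
  # chain seed -> X -> Y: Y (deg 1) goes in pass 1, X (deg 1 after) in
  # pass 4
  nodes <- data.frame(id = c("S", "X", "Y"), kind = "gene",
                      seed = c(TRUE, FALSE, FALSE))
  edges <- data.frame(source = c("S", "X"), target = c("X", "Y"), sign = 1)
  pr <- prune_network(signed_network(nodes, edges))
  expect_equal(pr$nodes$id, "S")
  expect_equal(nrow(pr$edges), 0L)
  # a network of only seeds is untouched
  nodes2 <- data.frame(id = c("S1", "S2"), kind = c("miRNA", "gene"),
                       seed = TRUE)
  net2 <- signed_network(nodes2, data.frame(source = "S1", target = "S2",
                                            sign = -1))
  expect_equal(prune_network(net2), net2)
  # non-seed isolated node and non-seed miRNA both removed
  nodes3 <- data.frame(id = c("S", "T1", "T2", "M", "I"),
                       kind = c("gene", "TF", "TF", "miRNA", "gene"),
                       seed = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  edges3 <- data.frame(source = c("S", "T1", "S", "T2", "M", "S"),
                       target = c("T1", "S", "T2", "S", "S", "M"),
                       sign = 1)
  pr3 <- prune_network(signed_network(nodes3, edges3))
  expect_false("I" %in% pr3$nodes$id)   # degree 0
  expect_false("M" %in% pr3$nodes$id)   # non-seed miRNA
  expect_setequal(pr3$nodes$id, c("S", "T1", "T2"))
})

test_that("pruning only shrinks the network", {
  set.seed(6)
  for (i in 1:20) {
    net <- random_signed_network(12, 24, seed = i)
    net$nodes$seed <- seq_len(nrow(net$nodes)) %in% sample(12, 3)
    pr <- prune_network(net)
    expect_lte(nrow(pr$nodes), nrow(net$nodes))
    expect_lte(nrow(pr$edges), nrow(net$edges))
    expect_true(all(net$nodes$id[net$nodes$seed] %in% pr$nodes$id))
    pf <- prune_network(net, fixpoint = TRUE)
    expect_lte(nrow(pf$nodes), nrow(pr$nodes))
  }
})

test_that("feedforward loop classification follows the sign identity", {
  nodes <- data.frame(id = c("A", "B", "C"), kind = "TF")
  coh <- signed_network(nodes, data.frame(
    source = c("A", "B", "A"), target = c("B", "C", "C"),
    sign = c(1, -1, -1)))
  f <- find_ffls(coh)
  expect_equal(nrow(f), 1L)
  expect_true(f$coherent)
  inc <- signed_network(nodes, data.frame(
    source = c("A", "B", "A"), target = c("B", "C", "C"),
    sign = c(1, 1, -1)))
  expect_false(find_ffls(inc)$coherent)
  unk <- signed_network(nodes, data.frame(
    source = c("A", "B", "A"), target = c("B", "C", "C"),
    sign = c(1, 0, -1)))
  expect_true(is.na(find_ffls(unk)$coherent))
})

test_that("feedback loops classify by edge-sign product", {
  nodes <- data.frame(id = c("A", "B"), kind = "TF")
  pos <- signed_network(nodes, data.frame(source = c("A", "B"),
                                          target = c("B", "A"),
                                          sign = c(1, 1)))
  expect_true(find_fbls(pos)$positive)
  neg <- signed_network(nodes, data.frame(source = c("A", "B"),
                                          target = c("B", "A"),
                                          sign = c(1, -1)))
  expect_false(find_fbls(neg)$positive)
  expect_error(find_fbls(pos, max_len = 1), "max_len")
})

test_that("motif census equals exhaustive enumeration on random graphs", {
  for (i in 1:100) {
    n <- sample(8:40, 1)
    net <- random_signed_network(n, sample(2:4, 1) * n, seed = 1000 + i)
    want <- oracle_motifs(net)
    ff <- find_ffls(net)
    fb <- find_fbls(net, max_len = 3)
    expect_equal(nrow(ff), want$ffl_total)
    expect_equal(sum(ff$coherent), want$ffl_coherent)
    expect_equal(nrow(fb), want$fbl_total)
    expect_equal(sum(fb$positive), want$fbl_positive)
    # sign identities hold for every reported motif
    if (nrow(ff))
      expect_equal(ff$coherent, ff$sign_ri * ff$sign_it == ff$sign_rt)
    if (nrow(fb))
      expect_true(all((fb$sign_product > 0) == fb$positive))
  }
})

test_that("condensation keeps the extreme quantiles with sign-directions", {
  set.seed(44)
  ids <- sprintf("g%03d", 1:101)
  nodes <- data.frame(id = ids, kind = "gene")
  edges <- data.frame(source = ids[1:100], target = ids[2:101], sign = 1)
  net <- signed_network(nodes, edges)
  ctrl <- setNames(rnorm(101), ids)
  case <- setNames(rnorm(101), ids)
  got <- condense_network(net, case, ctrl, keep_quantile = 0.03)
  score <- case[edges$source] * case[edges$target] -
    ctrl[edges$source] * ctrl[edges$target]
  want <- sort(unname(score))[c(1:3, 98:100)]
  expect_equal(sort(got$link_score), want)
  expect_equal(got$direction, ifelse(got$link_score > 0, "startup",
                                     "shutdown"))
  # adopted product-contrast formula and the never-keep-zero rule
  n2 <- signed_network(data.frame(id = c("a", "b"), kind = "gene"),
                       data.frame(source = "a", target = "b", sign = 1))
  one <- condense_network(n2, c(a = 2, b = 2), c(a = 1, b = 1),
                          keep_quantile = 1)
  expect_equal(one$link_score, 3)
  expect_equal(one$direction, "startup")
  none <- condense_network(n2, c(a = 1, b = 1), c(a = 1, b = 1),
                           keep_quantile = 1)
  expect_equal(nrow(none), 0L)
  expect_warning(condense_network(n2, c(a = 1), c(a = 1)), "skipped")
})

test_that("network and module exports round-trip through SIF/GraphML", {
  net <- random_signed_network(8, 14, seed = 3)
  sif <- tempfile(fileext = ".sif")
  write_sif(net, sif)
  lines <- readLines(sif)
  expect_equal(length(grep("\t", lines)), nrow(net$edges))
  gml <- tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_setequal(igraph::edge_attr(g, "sign"), unique(net$edges$sign))
})
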