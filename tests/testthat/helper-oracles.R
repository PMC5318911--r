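# Independent oracles, written from first principles and kept free of the
# package's internal code paths.

# Rough-hypercuboid dependency by naive per-sample, per-class loops.
oracle_gamma <- function(x, labels) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  confused <- 0L
  for (j in seq_len(n)) {
    n_boxes <- 0L
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      inside <- TRUE
      for (f in seq_len(nrow(x))) {
        if (x[f, j] < min(x[f, idx]) || x[f, j] > max(x[f, idx]))
          inside <- FALSE
      }
      if (inside) n_boxes <- n_boxes + 1L
    }
    if (n_boxes > 1L) confused <- confused + 1L
  }
  1 - confused / n
}

oracle_similarity <- function(v1, v2, labels) {
  g1 <- oracle_gamma(v1, labels)
  g2 <- oracle_gamma(v2, labels)
  if (min(g1, g2) == 0) return(0)
  g12 <- oracle_gamma(rbind(v1, v2), labels)
  max(0, 2 * (g1 + g2 - g12) / (g1 + g2))
}

# Minimum pairwise gap between class value ranges (negative if overlapping).
oracle_margin <- function(v, labels) {
  lv <- unique(labels)
  m <- Inf
  for (p in seq_along(lv)) for (q in seq_along(lv)) {
    if (p >= q) next
    a <- v[labels == lv[p]]; b <- v[labels == lv[q]]
    m <- min(m, max(min(a) - max(b), min(b) - max(a)))
  }
  m
}

# Exhaustive greedy refinement trace: at each pass scores every
# (member, sign) candidate and applies the same lexicographic
# (relevance, margin) admission rule, coded independently.
oracle_refine <- function(seed_i, coarse_i, x, labels) {
  chosen <- data.frame(member = seed_i, sign = 1)
  left <- coarse_i
  repeat {
    cur <- colSums(x[chosen$member, , drop = FALSE] * chosen$sign) /
      nrow(chosen)
    g_cur <- oracle_gamma(cur, labels)
    m_cur <- oracle_margin(cur, labels)
    # candidate order encodes the tie policy: lowest member index first,
    # + sign before complement
    cand <- expand.grid(sign = c(1, -1), member = left)[, c("member", "sign")]
    if (nrow(cand) == 0L) break
    score <- t(apply(cand, 1L, function(cs) {
      prof <- (cur * nrow(chosen) + cs[2L] * x[cs[1L], ]) /
        (nrow(chosen) + 1L)
      c(oracle_gamma(prof, labels), oracle_margin(prof, labels))
    }))
    gain <- score[, 1L] - g_cur
    mgain <- score[, 2L] - m_cur
    ok <- gain > -1e-12 & (gain > 1e-12 | mgain > 1e-12)
    if (!any(ok)) break
    # lexicographic best, earliest candidate wins ties (cand rows are
    # ordered by member index within sign +1 first)
    best <- which(ok)[order(-gain[ok], -mgain[ok])][1L]
    # re-apply exact tie policy: strictly larger gain, else equal gain
    # and strictly larger margin gain
    for (i in which(ok)) {
      if (gain[i] > gain[best] + 1e-12 ||
          (gain[i] > gain[best] - 1e-12 && mgain[i] > mgain[best] + 1e-12))
        best <- i
    }
    chosen <- rbind(chosen,
                    data.frame(member = cand$member[best],
                               sign = cand$sign[best]))
    left <- setdiff(left, cand$member[best])
  }
  chosen
}

# Breadth-limited expansion oracle.
oracle_expand <- function(seed_ids, tab, layers) {
  current <- seed_ids
  keep <- tab$source %in% current & tab$target %in% current
  for (l in seq_len(layers)) {
    inc <- tab$source %in% current | tab$target %in% current
    keep <- keep | inc
    current <- union(current, c(tab$source[inc], tab$target[inc]))
  }
  list(nodes = union(seed_ids,
                     c(tab$source[keep], tab$target[keep])),
       edges = tab[keep, c("source", "target")])
}

# Motif census via adjacency/sign matrices (closed-walk algebra), fully
# independent of the package's hash-based edge enumeration.
oracle_motifs <- function(net) {
  ids <- net$nodes$id
  n <- length(ids)
  A <- Sp <- Sn <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges$source[k]; j <- net$edges$target[k]
    if (i == j) next
    A[i, j] <- 1
    if (net$edges$sign[k] > 0) Sp[i, j] <- 1
    if (net$edges$sign[k] < 0) Sn[i, j] <- 1
  }
  P2 <- A %*% A                       # 2-step paths
  ffl_total <- sum(P2 * A)
  pos_paths <- Sp %*% Sp + Sn %*% Sn  # sign-product positive 2-step paths
  neg_paths <- Sp %*% Sn + Sn %*% Sp
  ffl_coherent <- sum(pos_paths * Sp) + sum(neg_paths * Sn)
  fbl2 <- sum(A * t(A)) / 2
  fbl3 <- sum(diag(A %*% A %*% A)) / 3
  fbl2_pos <- (sum(Sp * t(Sp)) + sum(Sn * t(Sn))) / 2
  fbl3_pos <- sum(diag(Sp %*% Sp %*% Sp)) / 3 +
    sum(diag(Sp %*% Sn %*% Sn))
  list(ffl_total = ffl_total, ffl_coherent = ffl_coherent,
       fbl_total = fbl2 + fbl3, fbl_positive = fbl2_pos + fbl3_pos)
}

# Random signed digraph without self-loops or duplicate edges; all signs
# known (+1/-1) so coherence is defined for every motif.
random_signed_network <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  cand <- expand.grid(source = ids, target = ids,
                      stringsAsFactors = FALSE)
  cand <- cand[cand$source != cand$target, ]
  pick <- cand[sample(nrow(cand), min(n_edges, nrow(cand))), ]
  pick$sign <- sample(c(-1, 1), nrow(pick), replace = TRUE)
  signed_network(data.frame(id = ids, kind = "gene", seed = FALSE), pick)
}

# Tiny labelled fixture shared by clustering tests.
fixture_expression <- function(seed = 7, n_feat = 6, n = 8) {
  set.seed(seed)
  lab <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n_feat * n), n_feat, n,
              dimnames = list(paste0("f", seq_len(n_feat)), NULL))
  x[1, ] <- ifelse(lab == "A", -1, 1) + rnorm(n, sd = 0.6)
  x[2, ] <- ifelse(lab == "A", -1, 1) + rnorm(n, sd = 0.6)
  x[3, ] <- ifelse(lab == "A", 1, -1) + rnorm(n, sd = 0.6)
  list(x = x, labels = lab)
}
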