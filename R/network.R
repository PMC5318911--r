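#' Construct a signed regulatory network
#'
#' Typed nodes (miRNA, gene or TF, with a seed flag) and signed directed
#' edges (+1 activation, -1 repression, 0 unknown). Duplicate edges (same
#' source and target) keep the first occurrence.
#'
#' @param nodes data.frame with columns \code{id}, \code{kind} (one of
#'   \code{"miRNA"}, \code{"gene"}, \code{"TF"}) and optionally \code{seed}
#'   (logical, default \code{FALSE}).
#' @param edges data.frame with columns \code{source}, \code{target},
#'   optionally \code{sign} (+1/-1/0, default 0) and \code{source_db}.
#' @return Object of class \code{"signed_network"} with elements
#'   \code{nodes} and \code{edges}.
#' @export
signed_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(nodes$seed)) nodes$seed <- FALSE
  if (!all(nodes$kind %in% c("miRNA", "gene", "TF")))
    stop("unknown node kind: ",
         paste(setdiff(unique(nodes$kind), c("miRNA", "gene", "TF")),
               collapse = ", "))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (nrow(edges)) {
    if (is.null(edges$sign)) edges$sign <- 0
    if (is.null(edges$source_db)) edges$source_db <- ""
    stopifnot(all(edges$sign %in% c(-1, 0, 1)))
    missing <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(missing))
      stop("edge endpoint(s) not in nodes: ",
           paste(missing, collapse = ", "))
    edges <- edges[!duplicated(edges[c("source", "target")]), , drop = FALSE]
  } else {
    edges <- data.frame(source = character(0), target = character(0),
                        sign = numeric(0), source_db = character(0))
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("Signed network: %d nodes (%d seed), %d edges\n",
              nrow(x$nodes), sum(x$nodes$seed), nrow(x$edges)))
  invisible(x)
}

#' Read a signed interaction table
#'
#' Tab-separated with columns \code{source}, \code{target}, \code{sign}
#' (\code{activation}, \code{repression} or \code{unknown}),
#' \code{source_kind}, \code{target_kind} and optionally \code{source_db}.
#'
#' @param path File path.
#' @return data.frame with numeric \code{sign} (+1/-1/0).
#' @export
read_interactions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("source", "target", "sign", "source_kind", "target_kind")
  if (!all(need %in% names(df)))
    stop("interaction table needs columns: ", paste(need, collapse = ", "))
  map <- c(activation = 1, repression = -1, unknown = 0)
  if (is.character(df$sign)) {
    if (!all(df$sign %in% names(map)))
      stop("sign must be activation/repression/unknown")
    df$sign <- unname(map[df$sign])
  }
  df
}

# Nodes/kinds mentioned in an interaction table.
.table_nodes <- function(tab) {
  data.frame(id = c(tab$source, tab$target),
             kind = c(tab$source_kind, tab$target_kind),
             stringsAsFactors = FALSE)
}

#' Expand a network around seed nodes
#'
#' Layer 0 is the primary network: all recorded interactions among the
#' seeds themselves. Each further layer adds every interaction incident to
#' a current node (bringing in its other endpoint).
#'
#' @param seeds data.frame with columns \code{id}, \code{kind} for the seed
#'   miRNAs/mRNAs.
#' @param interactions Interaction table as from
#'   \code{\link{read_interactions}} (or a list of such tables, which are
#'   concatenated).
#' @param layers Number of expansion layers (default 1).
#' @return A \code{\link{signed_network}} with seed flags set.
#' @export
expand_network <- function(seeds, interactions, layers = 1) {
  if (is.data.frame(interactions)) interactions <- list(interactions)
  tab <- do.call(rbind, interactions)
  if (nrow(seeds) == 0L) stop("seeds must be non-empty")
  kinds <- .table_nodes(tab)
  kinds <- kinds[!duplicated(kinds$id), , drop = FALSE]
  bad <- setdiff(unique(kinds$kind), c("miRNA", "gene", "TF"))
  if (length(bad)) stop("unknown node kind: ", paste(bad, collapse = ", "))

  current <- unique(seeds$id)
  keep <- tab$source %in% current & tab$target %in% current
  for (l in seq_len(layers)) {
    inc <- tab$source %in% current | tab$target %in% current
    keep <- keep | inc
    current <- unique(c(current, tab$source[inc], tab$target[inc]))
  }
  sel <- tab[keep, , drop = FALSE]
  ids <- unique(c(seeds$id, sel$source, sel$target))
  kind <- kinds$kind[match(ids, kinds$id)]
  kind[is.na(kind)] <- seeds$kind[match(ids[is.na(kind)], seeds$id)]
  nodes <- data.frame(id = ids, kind = kind, seed = ids %in% seeds$id,
                      stringsAsFactors = FALSE)
  edges <- data.frame(source = sel$source, target = sel$target,
                      sign = sel$sign,
                      source_db = if (!is.null(sel$source_db)) sel$source_db
                                  else rep("", nrow(sel)),
                      stringsAsFactors = FALSE)
  signed_network(nodes, edges)
}

# Drop the named nodes and any edge touching them.
.drop_nodes <- function(net, drop) {
  if (!length(drop)) return(net)
  net$nodes <- net$nodes[!net$nodes$id %in% drop, , drop = FALSE]
  net$edges <- net$edges[!(net$edges$source %in% drop |
                           net$edges$target %in% drop), , drop = FALSE]
  rownames(net$nodes) <- rownames(net$edges) <- NULL
  net
}

.degree <- function(net) {
  ids <- net$nodes$id
  tabulate(match(net$edges$source, ids), length(ids)) +
    tabulate(match(net$edges$target, ids), length(ids))
}

#' Prune an expanded network
#'
#' Applies, in order, each as a single pass over the current network:
#' (1) remove non-seed nodes of total degree (in + out) zero or one;
#' (2) remove non-seed miRNA nodes; (3) remove nodes not adjacent to any
#' seed; (4) remove non-seed nodes of degree zero or one. Seeds are never
#' removed; dangling edges go with their nodes.
#'
#' @param net A \code{\link{signed_network}}.
#' @param fixpoint If \code{TRUE}, iterate the four passes until the
#'   network stops shrinking.
#' @return The pruned network.
#' @export
prune_network <- function(net, fixpoint = FALSE) {
  repeat {
    before <- nrow(net$nodes) + nrow(net$edges)
    deg <- .degree(net)
    net <- .drop_nodes(net, net$nodes$id[!net$nodes$seed & deg <= 1])
    net <- .drop_nodes(net, net$nodes$id[!net$nodes$seed &
                                         net$nodes$kind == "miRNA"])
    seeds <- net$nodes$id[net$nodes$seed]
    adj <- unique(c(net$edges$target[net$edges$source %in% seeds],
                    net$edges$source[net$edges$target %in% seeds]))
    net <- .drop_nodes(net, setdiff(net$nodes$id[!net$nodes$seed], adj))
    deg <- .degree(net)
    net <- .drop_nodes(net, net$nodes$id[!net$nodes$seed & deg <= 1])
    if (!fixpoint || nrow(net$nodes) + nrow(net$edges) == before) break
  }
  net
}

# Fast edge lookup environment: "src\rtgt" -> sign.
.edge_sign_map <- function(net) {
  stats::setNames(net$edges$sign,
                  paste(net$edges$source, net$edges$target, sep = "\r"))
}

#' Enumerate feedforward loops
#'
#' All ordered triples (regulator r, intermediate i, target t) of distinct
#' nodes with edges r->i, i->t and r->t present. A loop is coherent when
#' the sign of the direct edge equals the product of signs along the
#' indirect path; loops containing an unknown-sign edge get
#' \code{coherent = NA} and are excluded from coherent counts.
#'
#' @param net A \code{\link{signed_network}}.
#' @return data.frame with columns \code{regulator}, \code{intermediate},
#'   \code{target}, \code{sign_ri}, \code{sign_it}, \code{sign_rt},
#'   \code{coherent}.
#' @export
find_ffls <- function(net) {
  e <- net$edges
  out <- data.frame(regulator = character(0), intermediate = character(0),
                    target = character(0), sign_ri = numeric(0),
                    sign_it = numeric(0), sign_rt = numeric(0),
                    coherent = logical(0))
  if (nrow(e) < 3L) return(out)
  smap <- .edge_sign_map(net)
  out_nb <- split(e$target, e$source)
  res <- list()
  for (r in names(out_nb)) {
    tgts <- out_nb[[r]]
    for (i in tgts) {
      if (i == r) next
      via <- out_nb[[i]]
      if (is.null(via)) next
      hits <- intersect(via, setdiff(tgts, c(r, i)))
      for (t in hits) {
        s_ri <- smap[[paste(r, i, sep = "\r")]]
        s_it <- smap[[paste(i, t, sep = "\r")]]
        s_rt <- smap[[paste(r, t, sep = "\r")]]
        coh <- if (s_ri == 0 || s_it == 0 || s_rt == 0) NA
               else s_ri * s_it == s_rt
        res[[length(res) + 1L]] <- data.frame(
          regulator = r, intermediate = i, target = t,
          sign_ri = s_ri, sign_it = s_it, sign_rt = s_rt,
          coherent = coh, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res)) do.call(rbind, res) else out
}

#' Enumerate simple directed feedback loops (cycles)
#'
#' Simple directed cycles of length 2 up to \code{max_len} (at most 3).
#' Each cycle is reported once, rotated so its lexicographically smallest
#' node comes first. A cycle is positive (coherent) when the product of
#' its edge signs is +1; cycles with an unknown-sign edge get
#' \code{positive = NA}.
#'
#' @param net A \code{\link{signed_network}}.
#' @param max_len Maximum cycle length (2 or 3; default 3).
#' @return data.frame with columns \code{nodes} (slash-separated cycle),
#'   \code{length}, \code{sign_product}, \code{positive}.
#' @export
find_fbls <- function(net, max_len = 3) {
  stopifnot(max_len >= 2)
  max_len <- min(max_len, 3L)
  e <- net$edges[net$edges$source != net$edges$target, , drop = FALSE]
  smap <- .edge_sign_map(net)
  has <- function(a, b) !is.na(match(paste(a, b, sep = "\r"), names(smap)))
  sgn <- function(a, b) smap[[paste(a, b, sep = "\r")]]
  res <- list()
  # length 2: reciprocal pairs
  for (k in seq_len(nrow(e))) {
    a <- e$source[k]; b <- e$target[k]
    if (a < b && has(b, a)) {
      p <- sgn(a, b) * sgn(b, a)
      res[[length(res) + 1L]] <- data.frame(
        nodes = paste(a, b, sep = "/"), length = 2L, sign_product = p,
        positive = if (p == 0) NA else p > 0, stringsAsFactors = FALSE)
    }
  }
  if (max_len >= 3L) {
    out_nb <- split(e$target, e$source)
    for (a in names(out_nb)) for (b in out_nb[[a]]) {
      if (b <= a) next  # canonical: a is smallest
      via <- out_nb[[b]]
      for (cc in via) {
        if (cc <= a || cc == b) next
        if (has(cc, a)) {
          p <- sgn(a, b) * sgn(b, cc) * sgn(cc, a)
          res[[length(res) + 1L]] <- data.frame(
            nodes = paste(a, b, cc, sep = "/"), length = 3L,
            sign_product = p, positive = if (p == 0) NA else p > 0,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(nodes = character(0), length = integer(0),
                  sign_product = numeric(0), positive = logical(0))
}

#' Condense a network by expression contrast
#'
#' Per-edge link score contrasting the product of the endpoints' summary
#' expressions between conditions:
#' \deqn{score(s \to t) = \bar{x}^{case}_s \bar{x}^{case}_t -
#'       \bar{x}^{ctrl}_s \bar{x}^{ctrl}_t.}
#' The most strongly altered edges — the lowest and highest
#' \code{keep_quantile} fraction of scores (ties broken by edge order) —
#' are kept; positive scores are "startup" links, negative ones
#' "shutdown". Zero-score edges are never kept. Edges with an endpoint
#' missing from the summaries are skipped with a warning.
#'
#' @param net A \code{\link{signed_network}}.
#' @param case_means,control_means Named numeric vectors: mean log2
#'   expression per node in the case and control condition.
#' @param keep_quantile Fraction kept at each tail (default 0.03).
#' @return data.frame with columns \code{source}, \code{target},
#'   \code{link_score}, \code{direction}, ordered by ascending score.
#' @export
condense_network <- function(net, case_means, control_means,
                             keep_quantile = 0.03) {
  e <- net$edges
  ok <- e$source %in% names(case_means) & e$target %in% names(case_means) &
        e$source %in% names(control_means) & e$target %in% names(control_means)
  if (any(!ok))
    warning(sum(!ok), " edge(s) skipped: missing expression summary")
  e <- e[ok, , drop = FALSE]
  if (nrow(e) == 0L)
    return(data.frame(source = character(0), target = character(0),
                      link_score = numeric(0), direction = character(0)))
  score <- case_means[e$source] * case_means[e$target] -
           control_means[e$source] * control_means[e$target]
  score <- unname(score)
  k <- floor(keep_quantile * nrow(e) + 1e-9)
  nz <- which(score != 0)
  ord <- nz[order(score[nz], nz)]   # ties -> original edge order
  keep <- unique(c(utils::head(ord, k), utils::tail(ord, k)))
  out <- data.frame(source = e$source[keep], target = e$target[keep],
                    link_score = score[keep],
                    direction = ifelse(score[keep] > 0, "startup",
                                       "shutdown"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$link_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a network (or modules) as SIF
#'
#' Three tab-separated columns: source, interaction, target. Signed edges
#' map to \code{activates}/\code{represses}; unknown signs (and module
#' miRNA-target edges) map to \code{regulates}. Isolated nodes are written
#' as single-column rows, as Cytoscape expects.
#'
#' @param x A \code{\link{signed_network}} or \code{mirna_modules} object.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_sif <- function(x, path) {
  lines <- character(0)
  if (inherits(x, "signed_network")) {
    rel <- c(`-1` = "represses", `0` = "regulates", `1` = "activates")
    if (nrow(x$edges))
      lines <- sprintf("%s\t%s\t%s", x$edges$source,
                       rel[as.character(x$edges$sign)], x$edges$target)
    iso <- setdiff(x$nodes$id, c(x$edges$source, x$edges$target))
    lines <- c(lines, iso)
  } else if (inherits(x, "mirna_modules")) {
    for (m in x) {
      if (nrow(m$edges))
        lines <- c(lines, sprintf("%s\tregulates\t%s",
                                  m$edges$mirna, m$edges$gene))
      iso <- setdiff(c(m$mirnas, m$genes),
                     c(m$edges$mirna, m$edges$gene))
      lines <- c(lines, iso)
    }
  } else stop("cannot export object of class ", class(x)[1L])
  writeLines(lines, path)
  invisible(path)
}

#' Export a network (or modules) as GraphML
#'
#' Nodes carry \code{kind} and \code{seed} attributes; edges carry
#' \code{sign} (and \code{pearson_r} for module edges).
#'
#' @inheritParams write_sif
#' @return \code{path}, invisibly.
#' @export
write_graphml <- function(x, path) {
  if (inherits(x, "mirna_modules")) {
    nodes <- data.frame(
      id = unlist(lapply(x, function(m) c(m$mirnas, m$genes))),
      kind = unlist(lapply(x, function(m)
        c(rep("miRNA", length(m$mirnas)), rep("gene", length(m$genes))))),
      stringsAsFactors = FALSE)
    nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
    nodes$seed <- TRUE
    edges <- do.call(rbind, lapply(x, `[[`, "edges"))
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$mirna, to = edges$gene,
                 sign = 0, pearson_r = edges$pearson_r),
      directed = TRUE, vertices = nodes)
  } else if (inherits(x, "signed_network")) {
    ed <- x$edges
    g <- igraph::graph_from_data_frame(
      data.frame(from = ed$source, to = ed$target, sign = ed$sign),
      directed = TRUE, vertices = x$nodes)
  } else stop("cannot export object of class ", class(x)[1L])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
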