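# Canonical gene/miRNA identifier form used for matching: whitespace
# stripped, case folded. Display keeps the original spelling.
.canon_id <- function(x) tolower(gsub("\\s+", "", x))

#' Read a miRNA-to-target interaction table
#'
#' Tab-separated with at least two columns (miRNA id, target gene id); an
#' optional third column is kept as free-text evidence. Duplicate pairs are
#' removed. A header line is detected and skipped if its first field is
#' not a miRNA-like id present later in the column.
#'
#' @param path File path.
#' @param header Does the file carry a header row? Default \code{TRUE}.
#' @return data.frame of class \code{"target_table"} with columns
#'   \code{mirna}, \code{gene} and optionally \code{evidence}.
#' @export
read_target_table <- function(path, header = TRUE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (ncol(df) < 2L) stop("target table needs >= 2 columns")
  names(df)[1:2] <- c("mirna", "gene")
  if (ncol(df) >= 3L) names(df)[3L] <- "evidence"
  target_table(df)
}

#' Construct a target table from a data.frame
#'
#' @param df data.frame whose first two columns are miRNA and target gene
#'   ids.
#' @return Deduplicated data.frame of class \code{"target_table"}.
#' @export
target_table <- function(df) {
  names(df)[1:2] <- c("mirna", "gene")
  key <- paste(.canon_id(df$mirna), .canon_id(df$gene), sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("target_table", "data.frame")
  df
}

#' Reduce an mRNA matrix to the targets of a miRNA rule
#'
#' Keeps only the mRNAs that are a recorded target of at least one member
#' miRNA of the rule (union over members). Targets absent from the
#' expression matrix are dropped; their count is reported in a message.
#'
#' @param rule One rule from a fitted \code{\link{rhsac}} object (a list
#'   with a \code{members} element), or a character vector of miRNA ids.
#' @param targets A \code{\link{target_table}}.
#' @param mrna Numeric mRNA matrix (genes in rows) or
#'   \code{expression_matrix}.
#' @return The reduced matrix (possibly with zero rows, with a warning).
#' @export
reduce_mrna_matrix <- function(rule, targets, mrna) {
  members <- if (is.character(rule)) rule else rule$members
  vals <- if (inherits(mrna, "expression_matrix")) mrna$values else mrna
  hit <- targets$gene[.canon_id(targets$mirna) %in% .canon_id(members)]
  hit <- unique(.canon_id(hit))
  present <- .canon_id(rownames(vals)) %in% hit
  n_missing <- length(hit) - length(unique(.canon_id(rownames(vals))[present]))
  if (n_missing > 0L)
    message(n_missing, " target(s) not present in the expression matrix")
  out <- vals[present, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no targets of this rule are present in the expression matrix")
  out
}

#' Assemble miRNA-mRNA regulatory modules
#'
#' One module per selected miRNA rule: the rule's member miRNAs joined to
#' the members of its selected mRNA rules, with an edge for every
#' (miRNA, gene) pair supported by the target table. miRNAs with no
#' selected target remain as isolated module nodes.
#'
#' @param mirna_rules List of selected miRNA rules (entries of
#'   \code{rhsac()$rules}).
#' @param mrna_rules_per_rule List (parallel to \code{mirna_rules}) of lists
#'   of selected mRNA rules obtained on each rule's reduced matrix.
#' @param targets A \code{\link{target_table}}.
#' @return Object of class \code{"mirna_modules"}: list of modules, each
#'   with \code{module_id}, \code{mirnas}, \code{genes}, and an \code{edges}
#'   data.frame (\code{mirna}, \code{gene}, \code{pearson_r}, initially
#'   \code{NA}).
#' @export
build_modules <- function(mirna_rules, mrna_rules_per_rule, targets) {
  stopifnot(length(mirna_rules) == length(mrna_rules_per_rule))
  tkey <- paste(.canon_id(targets$mirna), .canon_id(targets$gene), sep = "\r")
  mods <- lapply(seq_along(mirna_rules), function(i) {
    mirnas <- mirna_rules[[i]]$members
    genes <- unique(unlist(lapply(mrna_rules_per_rule[[i]], `[[`, "members")))
    if (is.null(genes)) genes <- character(0)
    cand <- expand.grid(mirna = mirnas, gene = genes,
                        stringsAsFactors = FALSE)
    keep <- paste(.canon_id(cand$mirna), .canon_id(cand$gene),
                  sep = "\r") %in% tkey
    edges <- cand[keep, , drop = FALSE]
    edges$pearson_r <- rep(NA_real_, nrow(edges))
    rownames(edges) <- NULL
    list(module_id = i, mirnas = mirnas, genes = genes, edges = edges)
  })
  structure(mods, class = "mirna_modules")
}

#' @export
print.mirna_modules <- function(x, ...) {
  cat(sprintf("%d miRNA-mRNA module(s)\n", length(x)))
  for (m in x)
    cat(sprintf("  module %d: %d miRNA(s), %d mRNA(s), %d edge(s)\n",
                m$module_id, length(m$mirnas), length(m$genes),
                nrow(m$edges)))
  invisible(x)
}

#' Annotate module edges with Pearson correlations
#'
#' For every edge, the Pearson correlation between the miRNA's and the
#' gene's expression across all samples (matrices must share sample
#' order). Zero-variance profiles yield \code{NA}.
#'
#' @param modules A \code{\link{build_modules}} result.
#' @param mirna,mrna Expression matrices (features in rows) or
#'   \code{expression_matrix} objects.
#' @return The modules with \code{pearson_r} filled in.
#' @export
edge_correlations <- function(modules, mirna, mrna) {
  mi <- if (inherits(mirna, "expression_matrix")) mirna$values else mirna
  mr <- if (inherits(mrna, "expression_matrix")) mrna$values else mrna
  if (ncol(mi) != ncol(mr)) stop("matrices must share sample order")
  mi_idx <- stats::setNames(seq_len(nrow(mi)), .canon_id(rownames(mi)))
  mr_idx <- stats::setNames(seq_len(nrow(mr)), .canon_id(rownames(mr)))
  for (k in seq_along(modules)) {
    e <- modules[[k]]$edges
    if (nrow(e) == 0L) next
    e$pearson_r <- vapply(seq_len(nrow(e)), function(j) {
      a <- mi[mi_idx[[.canon_id(e$mirna[j])]], ]
      b <- mr[mr_idx[[.canon_id(e$gene[j])]], ]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b)
    }, numeric(1))
    modules[[k]]$edges <- e
  }
  modules
}

#' Count positive and negative correlations
#'
#' Zeros and missing values are counted in neither class.
#'
#' @param r Numeric vector of correlation coefficients.
#' @return Named integer vector \code{c(n_positive, n_negative)}.
#' @export
count_correlation_signs <- function(r) {
  r <- r[!is.na(r)]
  c(n_positive = sum(r > 0), n_negative = sum(r < 0))
}

#' Fisher's exact test for gene-set overlap
#'
#' Builds the 2x2 contingency table for the overlap of a gene set with a
#' reference list inside a finite gene universe and computes the two-sided
#' Fisher exact p-value by the minimum-likelihood rule: the sum of all
#' hypergeometric point probabilities not exceeding that of the observed
#' table (within a relative tolerance of 1e-7).
#'
#' Either pass \code{gene_set}/\code{reference_list}/\code{universe_size},
#' or pass the table cells directly via \code{table = c(a, b, c, d)} with
#' \code{a} = in set and in list, \code{b} = in set only, \code{c} = in
#' list only, \code{d} = in neither.
#'
#' @param gene_set,reference_list Character vectors of gene ids (matched
#'   case-insensitively after whitespace stripping).
#' @param universe_size Total number of genes in the universe.
#' @param table Optional length-4 numeric vector \code{c(a, b, c, d)}.
#' @return List with \code{table} (2x2 matrix) and \code{p_value}.
#' @examples
#' overlap_fisher(table = c(10, 19, 732, 17730))$p_value  # 1.021e-07
#' @export
overlap_fisher <- function(gene_set = NULL, reference_list = NULL,
                           universe_size = NULL, table = NULL) {
  if (is.null(table)) {
    gs <- unique(.canon_id(gene_set))
    rl <- unique(.canon_id(reference_list))
    a <- length(intersect(gs, rl))
    b <- length(gs) - a
    cc <- length(rl) - a
    d <- universe_size - a - b - cc
    if (d < 0) stop("universe smaller than the union of set and list")
    table <- c(a, b, cc, d)
  }
  stopifnot(length(table) == 4L, all(table >= 0),
            all(table == round(table)))
  a <- table[1L]; b <- table[2L]; cc <- table[3L]; d <- table[4L]
  m <- a + cc          # list size
  nn <- b + d          # not in list
  k <- a + b           # set size
  lo <- max(0L, k - nn); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  tab <- matrix(table, 2L, byrow = TRUE,
                dimnames = list(set = c("in", "out"),
                                list = c("in", "out")))
  list(table = tab, p_value = p)
}

#' Read a reference gene list
#'
#' One gene symbol per line; blank lines and \code{#} comments ignored.
#'
#' @param path File path.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
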