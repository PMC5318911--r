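#' Labelled expression matrix
#'
#' A feature-by-sample log2 expression matrix with a class label per
#' sample.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param labels Class label per sample.
#' @return Object of class \code{"expression_matrix"} with elements
#'   \code{values} and \code{labels} (factor).
#' @export
expression_matrix <- function(values, labels) {
  values <- as.matrix(values)
  if (ncol(values) != length(labels))
    stop("number of samples and labels differ")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (!is.null(colnames(values)) && anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         colnames(values)[duplicated(colnames(values))][1L])
  if (any(!is.finite(values)))
    stop("non-finite expression values")
  structure(list(values = values, labels = factor(labels)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", levels(x$labels),
                            tabulate(x$labels)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a labelled expression matrix from TSV
#'
#' Format: an optional leading \code{#class:<TAB>lab1<TAB>lab2...} line
#' giving the per-sample class labels, then a header row of sample ids
#' (first cell is the feature-id column name) and one row per feature.
#' Alternatively labels can come from a two-column sidecar phenotype file
#' (sample id, class).
#'
#' @param path Matrix file.
#' @param phenotype Optional sidecar phenotype file path.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression <- function(path, phenotype = NULL) {
  first <- readLines(path, n = 1L)
  labels <- NULL
  skip <- 0L
  if (startsWith(first, "#class:")) {
    labels <- strsplit(first, "\t", fixed = TRUE)[[1]][-1]
    skip <- 1L
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = skip,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature id: ", ids[duplicated(ids)][1L])
  m <- as.matrix(df[-1L])
  if (!is.numeric(m)) {
    bad <- which(!apply(df[-1L], 2L, function(cc)
      all(!is.na(suppressWarnings(as.numeric(cc))))))
    stop("non-numeric cells in column(s): ",
         paste(names(df[-1L])[bad], collapse = ", "))
  }
  rownames(m) <- ids
  if (!is.null(phenotype)) {
    ph <- utils::read.table(phenotype, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    labels <- ph[[2L]][match(colnames(m), ph[[1L]])]
  }
  if (is.null(labels)) stop("missing class labels (no #class: line and ",
                            "no phenotype file)")
  if (length(labels) != ncol(m) || anyNA(labels))
    stop("class labels do not cover all ", ncol(m), " samples")
  message(sprintf("read %d features x %d samples from %s",
                  nrow(m), ncol(m), path))
  expression_matrix(m, labels)
}

#' Write a labelled expression matrix as TSV
#'
#' Inverse of \code{\link{read_expression}} (with a \code{#class:} line).
#'
#' @param x An \code{\link{expression_matrix}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#class:", as.character(x$labels)), collapse = "\t"),
             con)
  header <- paste(c("feature_id", colnames(x$values)), collapse = "\t")
  writeLines(header, con)
  utils::write.table(
    data.frame(feature_id = rownames(x$values), x$values,
               check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the two-step module-discovery pipeline
#'
#' End-to-end procedure: standardize the miRNA matrix, cluster it with
#' RH-SAC, evaluate and select rules (100\% LOOCV accuracy, > 1 member);
#' for each selected miRNA rule reduce the mRNA matrix to the rule's
#' recorded targets, cluster the reduced matrix, select mRNA rules the
#' same way; assemble miRNA-mRNA modules with target-table supported
#' edges and Pearson correlations. Optionally writes every table and the
#' module networks (TSV/SIF/GraphML) to an output directory.
#'
#' @param mirna,mrna \code{\link{expression_matrix}} objects (or numeric
#'   matrices if \code{labels} is given).
#' @param targets A \code{\link{target_table}}.
#' @param labels Class labels (defaults to the matrices' labels).
#' @param delta Cluster radius (default 0.9).
#' @param max_clusters Cap on rules per clustering (default 50).
#' @param cv Cross-validation scheme for selection (default
#'   \code{"both"}; selection always uses LOOCV unless \code{"10fold"}).
#' @param seed Seed for the k-fold assignment.
#' @param out_dir Optional output directory; created if missing.
#' @return List of class \code{"rhsac_pipeline"}: \code{mirna_fit},
#'   \code{mirna_eval}, per-rule \code{mrna_fits}/\code{mrna_evals},
#'   \code{modules}, \code{counts} (stage-by-stage sizes), and the
#'   configuration.
#' @export
run_pipeline <- function(mirna, mrna, targets, labels = NULL, delta = 0.9,
                         max_clusters = 50, cv = "both", seed = 42,
                         out_dir = NULL) {
  if (!inherits(mirna, "expression_matrix"))
    mirna <- expression_matrix(mirna, labels)
  if (!inherits(mrna, "expression_matrix"))
    mrna <- expression_matrix(mrna, labels)
  labels <- mirna$labels
  if (!identical(as.character(labels), as.character(mrna$labels)))
    stop("stage miRNA/mRNA: sample classes disagree")

  mirna_fit <- rhsac(mirna, delta = delta, max_clusters = max_clusters)
  mirna_eval <- evaluate_rules(mirna_fit, cv = cv, seed = seed)
  sel <- select_rules(mirna_eval)
  sel_rules <- mirna_fit$rules[sel]

  # standardize the full mRNA matrix once; the reduced per-rule data sets
  # are row subsets of it and are not re-standardized
  mrna_std <- expression_matrix(standardize(mrna$values), labels)

  mrna_fits <- list(); mrna_evals <- list(); mrna_sel <- list()
  for (i in seq_along(sel_rules)) {
    red <- reduce_mrna_matrix(sel_rules[[i]], targets, mrna_std)
    if (nrow(red) < 2L) {
      warning("rule ", sel_rules[[i]]$rule_id,
              ": too few targets in matrix; skipped")
      mrna_fits[i] <- list(NULL); mrna_evals[i] <- list(NULL)
      mrna_sel[[i]] <- list()
      next
    }
    fit <- rhsac(red, labels, delta = delta, max_clusters = max_clusters,
                 standardize_mode = "none")
    ev <- evaluate_rules(fit, cv = cv, seed = seed)
    mrna_fits[[i]] <- fit
    mrna_evals[[i]] <- ev
    mrna_sel[[i]] <- fit$rules[select_rules(ev)]
  }
  modules <- build_modules(sel_rules, mrna_sel, targets)
  modules <- edge_correlations(modules, mirna$values, mrna$values)

  counts <- data.frame(
    stage = c("mirna_features", "mirna_rules", "mirna_rules_selected",
              "mrna_rules_selected", "modules", "module_edges"),
    n = c(nrow(mirna$values), length(mirna_fit$rules), length(sel_rules),
          sum(lengths(mrna_sel)), length(modules),
          sum(vapply(modules, function(m) nrow(m$edges), integer(1)))))

  out <- structure(list(mirna_fit = mirna_fit, mirna_eval = mirna_eval,
                        mrna_fits = mrna_fits, mrna_evals = mrna_evals,
                        modules = modules, counts = counts,
                        config = list(delta = delta,
                                      max_clusters = max_clusters,
                                      cv = cv, seed = seed)),
                   class = "rhsac_pipeline")
  if (!is.null(out_dir)) export_pipeline(out, out_dir)
  out
}

#' @export
print.rhsac_pipeline <- function(x, ...) {
  cat("miRNA-mRNA module discovery pipeline\n")
  print.data.frame(x$counts, row.names = FALSE)
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Emits \code{mirna_rules.tsv}, \code{mirna_evaluations.tsv}, per-rule
#' mRNA rule/evaluation tables, \code{module_correlations.tsv}, and the
#' modules as \code{modules.sif} / \code{modules.graphml}.
#'
#' @param pipeline A \code{\link{run_pipeline}} result.
#' @param out_dir Output directory (created if missing).
#' @return \code{out_dir}, invisibly.
#' @export
export_pipeline <- function(pipeline, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  wt <- function(df, f) utils::write.table(df, p(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  write_rules(pipeline$mirna_fit, p("mirna_rules.tsv"))
  wt(pipeline$mirna_eval, "mirna_evaluations.tsv")
  for (i in seq_along(pipeline$mrna_fits)) {
    if (is.null(pipeline$mrna_fits[[i]])) next
    write_rules(pipeline$mrna_fits[[i]],
                p(sprintf("mrna_rules_rule%d.tsv", i)))
    wt(pipeline$mrna_evals[[i]], sprintf("mrna_evaluations_rule%d.tsv", i))
  }
  cors <- do.call(rbind, lapply(pipeline$modules, function(m) {
    if (nrow(m$edges) == 0L) return(NULL)
    cbind(module_id = m$module_id, m$edges)
  }))
  if (is.null(cors))
    cors <- data.frame(module_id = integer(0), mirna = character(0),
                       gene = character(0), pearson_r = numeric(0))
  wt(cors, "module_correlations.tsv")
  write_sif(pipeline$modules, p("modules.sif"))
  write_graphml(pipeline$modules, p("modules.graphml"))
  invisible(out_dir)
}
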