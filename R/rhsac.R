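#' Standardize an expression matrix
#'
#' Centres and scales to zero mean and unit variance (sample-variance
#' convention, divisor \eqn{n-1}) either each sample column
#' (\code{mode = "sample"}, the default used throughout the pipeline) or
#' each feature row (\code{mode = "feature"}). Zero-variance units are set
#' to all zeros with a warning.
#'
#' @param x Numeric matrix, features in rows, samples in columns.
#' @param mode \code{"sample"} or \code{"feature"}.
#' @return Matrix of the same shape and dimnames.
#' @export
standardize <- function(x, mode = c("sample", "feature")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (mode == "sample") {
    if (nrow(x) < 2L) stop("need >= 2 features to standardize samples")
    m <- colMeans(x)
    s <- apply(x, 2L, stats::sd)
  } else {
    if (ncol(x) < 2L) stop("need >= 2 samples to standardize features")
    m <- rowMeans(x)
    s <- apply(x, 1L, stats::sd)
  }
  if (any(s == 0)) {
    warning(sum(s == 0), " zero-variance ",
            if (mode == "sample") "sample(s)" else "feature(s)",
            " set to zero")
    s[s == 0] <- Inf
  }
  if (mode == "sample") sweep(sweep(x, 2L, m), 2L, s, "/")
  else sweep(sweep(x, 1L, m), 1L, s, "/")
}

#' Complement of a standardized expression profile
#'
#' For mean-zero profiles the complement is the negation: the mirror profile
#' that moves oppositely around the common mean. Averaging a complemented
#' feature into a cluster representative lets anti-correlated features
#' reinforce, rather than cancel, the class signal.
#'
#' @param v Numeric vector (standardized, mean approximately 0).
#' @return \code{-v}.
#' @export
complement <- function(v) -v

# Coarse cluster: pool members whose supervised similarity to the seed
# strictly exceeds the radius delta.
.coarse_cluster <- function(seed, pool, x, labels, delta, gammas) {
  if (length(pool) == 0L) return(integer(0))
  g_seed <- gammas[seed]
  sims <- vapply(pool, function(j) {
    if (min(g_seed, gammas[j]) == 0) return(0)
    g12 <- rh_relevance(x[c(seed, j), , drop = FALSE], labels)
    max(0, 2 * (g_seed + gammas[j] - g12) / (g_seed + gammas[j]))
  }, numeric(1))
  pool[sims > delta]
}

# Minimum pairwise separation between class intervals of a profile:
# positive when every pair of class boxes is disjoint, negative under
# overlap. Secondary refinement criterion (see below).
.class_margin <- function(v, f) {
  iv <- cbind(tapply(v, f, min), tapply(v, f, max))
  k <- nrow(iv)
  m <- Inf
  for (p in seq_len(k - 1L)) for (q in (p + 1L):k)
    m <- min(m, max(iv[p, 1L] - iv[q, 2L], iv[q, 1L] - iv[p, 2L]))
  m
}

# Greedy refinement: repeatedly average one unused coarse member (or its
# complement) into the signed member set, adopting the single (member, sign)
# with the largest relevance gain; ties -> lowest feature index, + sign
# preferred. The relevance gamma is a coarse statistic (multiples of 1/n),
# so it saturates at 1 on well-separated data; a candidate that leaves
# gamma unchanged is therefore admitted iff it strictly widens the
# representative's class-separation margin (an exact duplicate of the
# current representative never does). Stops when no candidate strictly
# improves (relevance, margin) lexicographically.
.refine_cluster <- function(seed, coarse, x, labels) {
  members <- seed          # feature indices in the finer cluster
  signs <- 1
  rep_sum <- x[seed, ]     # running sum of signed member profiles
  gamma <- rh_relevance(rep_sum, labels)
  margin <- .class_margin(rep_sum, labels)
  remaining <- coarse
  while (length(remaining) > 0L) {
    best <- NULL
    best_gain <- 0
    best_mgain <- 0
    k <- length(members) + 1L
    for (j in remaining) {
      for (s in c(1, -1)) {
        cand <- (rep_sum + s * x[j, ]) / k
        g <- rh_relevance(cand, labels)
        gain <- g - gamma
        if (gain < -1e-12) next              # relevance must not drop
        mgain <- .class_margin(cand, labels) - margin
        if (gain < 1e-12 && mgain < 1e-12) next  # no strict improvement
        better <- gain > best_gain + 1e-12 ||
          (gain > best_gain - 1e-12 && mgain > best_mgain + 1e-12)
        if (is.null(best) || better) {
          best_gain <- gain
          best_mgain <- mgain
          best <- c(j, s, g)
        }
      }
    }
    if (is.null(best)) break
    members <- c(members, best[1L])
    signs <- c(signs, best[2L])
    rep_sum <- rep_sum + best[2L] * x[best[1L], ]
    gamma <- best[3L]
    margin <- .class_margin(rep_sum / length(members), labels)
    remaining <- setdiff(remaining, best[1L])
  }
  list(members = members, signs = signs,
       representative = rep_sum / length(members), relevance = gamma)
}

#' Rough-hypercuboid supervised attribute clustering
#'
#' Greedy supervised clustering of features (miRNAs or mRNAs) guided by the
#' rough-hypercuboid dependency measure. Repeatedly: (1) pick the remaining
#' feature with the highest relevance \eqn{\gamma} as the seed of a new
#' cluster (ties broken by input order); (2) form the coarse cluster of all
#' remaining features whose supervised similarity to the seed strictly
#' exceeds the radius \code{delta}; (3) refine by greedily averaging coarse
#' members (or their complements) into the representative, keeping only
#' additions that strictly improve the pair (relevance, class-separation
#' margin) lexicographically — the margin breaks ties once the
#' coarse-grained relevance saturates at 1; (4) emit the rule and discard
#' the seed plus its entire coarse cluster from the pool. Stops when the
#' pool is exhausted or \code{max_clusters} rules have been produced.
#'
#' The input is standardized (per sample by default) before clustering;
#' a rule's representative is the plain arithmetic mean of its signed
#' standardized member profiles and is never re-standardized.
#'
#' @param x Numeric matrix, features in rows and samples in columns, or an
#'   object with \code{values}/\code{labels} as returned by
#'   \code{\link{read_expression}}.
#' @param labels Class label per sample (two classes for the intended use;
#'   any number is accepted).
#' @param delta Cluster radius in \eqn{[0, 1]}; a feature joins a coarse
#'   cluster when its similarity to the seed is \emph{strictly} greater
#'   than \code{delta}. Default 0.9.
#' @param max_clusters Maximum number of rules to emit. Default 50.
#' @param standardize_mode \code{"sample"} (default), \code{"feature"}, or
#'   \code{"none"} if \code{x} is already standardized.
#' @return An object of class \code{"rhsac"}: a list with \code{rules} (one
#'   entry per rule: \code{rule_id}, \code{seed}, \code{coarse},
#'   \code{members} = seed plus coarse, \code{finer} with per-member signs,
#'   \code{representative}, \code{relevance}, \code{seed_relevance}),
#'   \code{labels}, \code{delta}, \code{feature_relevance} and the
#'   standardized matrix \code{x}.
#' @seealso \code{\link{evaluate_rules}}, \code{\link{rule_table}},
#'   \code{\link{run_pipeline}}
#' @examples
#' set.seed(1)
#' x <- rbind(sig = c(rnorm(4, -2), rnorm(4, 2)), matrix(rnorm(24), 3))
#' fit <- rhsac(x, rep(c("N", "T"), each = 4), delta = 0.9)
#' fit
#' @export
rhsac <- function(x, labels = NULL, delta = 0.9, max_clusters = 50,
                  standardize_mode = c("sample", "feature", "none")) {
  if (inherits(x, "expression_matrix")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$values
  }
  standardize_mode <- match.arg(standardize_mode)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("f", seq_len(nrow(x)))
  if (ncol(x) != length(labels))
    stop("number of samples and labels differ")
  stopifnot(delta >= 0, delta <= 1, max_clusters >= 1)
  f <- factor(labels)
  if (nlevels(f) < 2L) stop("need at least 2 classes")
  xs <- if (standardize_mode == "none") x else standardize(x, standardize_mode)

  gammas <- vapply(seq_len(nrow(xs)),
                   function(i) rh_relevance(xs[i, ], f), numeric(1))
  names(gammas) <- rownames(xs)

  pool <- seq_len(nrow(xs))
  rules <- list()
  while (length(pool) > 0L && length(rules) < max_clusters) {
    seed <- pool[which.max(gammas[pool])]   # ties -> lowest index
    rest <- setdiff(pool, seed)
    coarse <- .coarse_cluster(seed, rest, xs, f, delta, gammas)
    fin <- .refine_cluster(seed, coarse, xs, f)
    rules[[length(rules) + 1L]] <- list(
      rule_id = length(rules) + 1L,
      seed = rownames(xs)[seed],
      coarse = rownames(xs)[coarse],
      members = rownames(xs)[c(seed, coarse)],
      finer = data.frame(member = rownames(xs)[fin$members],
                         sign = fin$signs, stringsAsFactors = FALSE),
      representative = fin$representative,
      relevance = fin$relevance,
      seed_relevance = gammas[[seed]])
    pool <- setdiff(pool, c(seed, coarse))
  }
  structure(list(rules = rules, labels = f, delta = delta,
                 max_clusters = max_clusters,
                 feature_relevance = gammas, x = xs),
            class = "rhsac")
}

#' @export
print.rhsac <- function(x, ...) {
  cat("Rough-hypercuboid supervised attribute clustering\n")
  cat(sprintf("  %d features, %d samples (%s), delta = %g\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s: %d", levels(x$labels),
                            tabulate(x$labels)), collapse = ", "),
              x$delta))
  cat(sprintf("  %d rule(s); sizes: %s\n", length(x$rules),
              paste(vapply(x$rules, function(r) length(r$members),
                           integer(1)), collapse = " ")))
  invisible(x)
}

#' @export
summary.rhsac <- function(object, ...) {
  df <- do.call(rbind, lapply(object$rules, function(r)
    data.frame(rule_id = r$rule_id, seed = r$seed,
               n_members = length(r$members),
               n_finer = nrow(r$finer),
               seed_relevance = unname(r$seed_relevance),
               relevance = r$relevance,
               stringsAsFactors = FALSE)))
  class(df) <- c("summary.rhsac", "data.frame")
  df
}

#' @export
print.summary.rhsac <- function(x, ...) {
  cat("RH-SAC rules\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cluster representatives
#'
#' @param object A fitted \code{\link{rhsac}} object.
#' @param ... Unused.
#' @return Matrix of augmented representatives (rules in rows, samples in
#'   columns).
#' @export
coef.rhsac <- function(object, ...) {
  out <- do.call(rbind, lapply(object$rules, `[[`, "representative"))
  rownames(out) <- paste0("rule", vapply(object$rules, `[[`, 1L, "rule_id"))
  colnames(out) <- colnames(object$x)
  out
}

#' Long-format rule membership table
#'
#' One row per (rule, member) with the member's role: \code{seed},
#' \code{finer} (averaged into the representative, with its sign), or
#' \code{coarse-only} (similar to the seed but not averaged).
#'
#' @param fit A fitted \code{\link{rhsac}} object.
#' @return data.frame with columns \code{rule_id}, \code{member_id},
#'   \code{sign}, \code{role}, \code{relevance}.
#' @export
rule_table <- function(fit) {
  stopifnot(inherits(fit, "rhsac"))
  do.call(rbind, lapply(fit$rules, function(r) {
    ids <- r$members
    sign <- r$finer$sign[match(ids, r$finer$member)]
    role <- ifelse(ids == r$seed, "seed",
                   ifelse(is.na(sign), "coarse-only", "finer"))
    sign[is.na(sign)] <- 0
    data.frame(rule_id = r$rule_id, member_id = ids, sign = sign,
               role = role, relevance = r$relevance,
               stringsAsFactors = FALSE)
  }))
}

#' Write the rule membership table as TSV
#'
#' @param fit A fitted \code{\link{rhsac}} object.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_rules <- function(fit, path) {
  utils::write.table(rule_table(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
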