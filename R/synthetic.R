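#' Configuration for the synthetic paired two-class study
#'
#' Defaults emulate the study design the pipeline targets: 8 case/control
#' tissue pairs (16 samples), 126 miRNA features and 2000 mRNA features on
#' the log2 scale, with 3 planted co-expressed differential miRNA clusters
#' of 5 members each that regulate planted target mRNAs through a supplied
#' target table.
#'
#' \code{within_cluster_rho} is the target pairwise correlation of planted
#' cluster members across all samples. The class-mean shift itself
#' contributes \code{effect_size^2/4} of shared variance; a latent factor
#' supplies any remainder needed to reach \code{rho}, and the rest of the
#' noise (total standard deviation \code{noise_sd} around the class mean)
#' is idiosyncratic per feature.
#'
#' @param n_pairs Number of case/control pairs (samples = 2 * n_pairs).
#' @param n_mirna,n_mrna Feature counts.
#' @param n_planted_clusters Number of planted miRNA clusters.
#' @param cluster_size miRNAs per planted cluster.
#' @param targets_per_cluster Planted target mRNAs per cluster.
#' @param effect_size Mean log2 class shift of planted features.
#' @param within_cluster_rho Target within-cluster correlation in [0, 1).
#' @param regulation_sign_mix Fraction of planted regulations that are
#'   negative (miRNA up, target down).
#' @param noise_sd Residual standard deviation around the class mean.
#' @param coupling Regression coefficient of a planted target on its
#'   cluster signal.
#' @param decoy_target_fraction Decoy (non-regulated) table entries as a
#'   fraction of the planted ones.
#' @param seed Integer RNG seed.
#' @return List of class \code{"synth_config"}.
#' @export
synth_config <- function(n_pairs = 8, n_mirna = 126, n_mrna = 2000,
                         n_planted_clusters = 3, cluster_size = 5,
                         targets_per_cluster = 10, effect_size = 2,
                         within_cluster_rho = 0.8,
                         regulation_sign_mix = 0.6, noise_sd = 0.5,
                         coupling = 1, decoy_target_fraction = 0.5,
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_pairs >= 2, n_mirna >= 1, n_mrna >= 1,
            n_planted_clusters >= 0, cluster_size >= 1,
            within_cluster_rho >= 0, within_cluster_rho < 1,
            regulation_sign_mix >= 0, regulation_sign_mix <= 1,
            noise_sd >= 0, decoy_target_fraction >= 0)
  if (cluster_size * n_planted_clusters > n_mirna)
    stop("planted clusters do not fit into n_mirna features")
  if (targets_per_cluster * n_planted_clusters > n_mrna)
    stop("planted targets do not fit into n_mrna features")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic paired two-class expression study
#'
#' Produces a miRNA matrix, an mRNA matrix, a miRNA-to-target table and the
#' ground truth, deterministically from \code{config$seed}. Samples come in
#' pairs (\code{N1/T1, N2/T2, ...}) labelled \code{normal}/\code{tumor}.
#'
#' Planted miRNA clusters share a class-mean shift of
#' \code{effect_size} (sign alternating per cluster) plus a shared latent
#' factor sized to reach the target within-cluster correlation (see
#' \code{\link{synth_config}}). Planted target mRNAs follow their
#' cluster's signal times a per-edge sign (negative with probability
#' \code{regulation_sign_mix}) plus noise. The target table contains every
#' planted (miRNA, target) pair within a cluster plus decoy pairs linking
#' planted miRNAs to background mRNAs. Background features are pure noise.
#'
#' @param config A \code{\link{synth_config}}.
#' @return List with \code{mirna} and \code{mrna}
#'   (\code{expression_matrix} objects), \code{targets}
#'   (\code{\link{target_table}}) and \code{truth} (list with
#'   \code{mirna_clusters}, \code{mrna_targets}, \code{edges} data.frame
#'   (\code{mirna}, \code{gene}, \code{sign}), \code{differential} flags).
#' @export
synth_expression <- function(config = synth_config()) {
  cfg <- config
  rng <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv()))
  set.seed(cfg$seed)

  n <- 2L * cfg$n_pairs
  cls <- rep(c("normal", "tumor"), cfg$n_pairs)
  samples <- paste0(rep(c("N", "T"), cfg$n_pairs),
                    rep(seq_len(cfg$n_pairs), each = 2L))
  shift <- ifelse(cls == "tumor", cfg$effect_size / 2, -cfg$effect_size / 2)

  # shared-variance split (see synth_config)
  total_var <- cfg$effect_size^2 / 4 + cfg$noise_sd^2
  shared_var <- max(0, cfg$within_cluster_rho * total_var -
                      cfg$effect_size^2 / 4)
  shared_var <- min(shared_var, cfg$noise_sd^2)
  idio_sd <- sqrt(cfg$noise_sd^2 - shared_var)

  mirna_ids <- sprintf("miR-%03d", seq_len(cfg$n_mirna))
  mrna_ids <- sprintf("gene%04d", seq_len(cfg$n_mrna))
  X <- matrix(stats::rnorm(cfg$n_mirna * n, sd = cfg$noise_sd),
              cfg$n_mirna, n, dimnames = list(mirna_ids, samples))

  clusters <- list()
  signal <- list()
  k <- cfg$n_planted_clusters
  if (k > 0L) {
    assign_idx <- split(seq_len(k * cfg$cluster_size),
                        rep(seq_len(k), each = cfg$cluster_size))
    for (c_i in seq_len(k)) {
      dir <- if (c_i %% 2L == 1L) 1 else -1  # alternate up/down in tumor
      z <- stats::rnorm(n, sd = sqrt(shared_var))
      base <- dir * shift + z
      ids <- mirna_ids[assign_idx[[c_i]]]
      for (id in ids)
        X[id, ] <- base + stats::rnorm(n, sd = idio_sd)
      clusters[[c_i]] <- ids
      signal[[c_i]] <- base
    }
  }

  Y <- matrix(stats::rnorm(cfg$n_mrna * n, sd = cfg$noise_sd),
              cfg$n_mrna, n, dimnames = list(mrna_ids, samples))
  edges <- NULL
  mrna_targets <- list()
  if (k > 0L && cfg$targets_per_cluster > 0L) {
    tgt_idx <- split(seq_len(k * cfg$targets_per_cluster),
                     rep(seq_len(k), each = cfg$targets_per_cluster))
    for (c_i in seq_len(k)) {
      gids <- mrna_ids[tgt_idx[[c_i]]]
      sgn <- ifelse(stats::runif(length(gids)) < cfg$regulation_sign_mix,
                    -1, 1)
      for (j in seq_along(gids))
        Y[gids[j], ] <- sgn[j] * cfg$coupling * signal[[c_i]] +
          stats::rnorm(n, sd = cfg$noise_sd)
      mrna_targets[[c_i]] <- gids
      edges <- rbind(edges, data.frame(
        mirna = rep(clusters[[c_i]], each = length(gids)),
        gene = rep(gids, times = length(clusters[[c_i]])),
        sign = rep(sgn, times = length(clusters[[c_i]])),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges))
    edges <- data.frame(mirna = character(0), gene = character(0),
                        sign = numeric(0))

  # decoy table entries: planted miRNAs -> background mRNAs
  n_decoy <- round(cfg$decoy_target_fraction * nrow(edges))
  decoys <- NULL
  background <- setdiff(mrna_ids, unlist(mrna_targets))
  if (n_decoy > 0L && length(background) > 0L && length(clusters) > 0L) {
    decoys <- data.frame(
      mirna = sample(unlist(clusters), n_decoy, replace = TRUE),
      gene = sample(background, n_decoy, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  tab <- rbind(edges[c("mirna", "gene")], decoys)
  tab$evidence <- ifelse(seq_len(nrow(tab)) <= nrow(edges),
                         "planted", "decoy")
  targets <- target_table(tab)

  diff_flags <- c(stats::setNames(mirna_ids %in% unlist(clusters), mirna_ids),
                  stats::setNames(mrna_ids %in% unlist(mrna_targets),
                                  mrna_ids))
  list(
    mirna = expression_matrix(X, cls),
    mrna = expression_matrix(Y, cls),
    targets = targets,
    truth = list(mirna_clusters = clusters, mrna_targets = mrna_targets,
                 edges = edges, differential = diff_flags,
                 pairing = rep(seq_len(cfg$n_pairs), each = 2L)))
}

#' Generate a toy signed network with known motif content
#'
#' Builds a signed digraph containing a stated number of planted coherent
#' feedforward loops and positive two-node feedback loops on disjoint node
#' sets, optionally salted with random extra edges (which may create
#' additional motifs; the truth counts refer to the planted ones and are
#' exact when \code{n_random_edges = 0}).
#'
#' @param n_ffl Planted coherent feedforward loops.
#' @param n_fbl Planted positive feedback loops (length 2).
#' @param n_random_edges Extra random signed edges among fresh nodes.
#' @param seed RNG seed.
#' @return List with \code{network} (a \code{\link{signed_network}}) and
#'   \code{truth} (list \code{n_coherent_ffl}, \code{n_positive_fbl}).
#' @export
synth_network <- function(n_ffl = 5, n_fbl = 2, n_random_edges = 0,
                          seed = 1) {
  rng <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv()))
  set.seed(seed)
  nodes <- NULL; edges <- NULL
  for (i in seq_len(n_ffl)) {
    ids <- sprintf("ffl%d_%s", i, c("r", "i", "t"))
    s1 <- sample(c(-1, 1), 1)
    s2 <- sample(c(-1, 1), 1)
    nodes <- rbind(nodes, data.frame(id = ids, kind = c("TF", "miRNA", "gene"),
                                     seed = FALSE))
    edges <- rbind(edges, data.frame(
      source = ids[c(1, 2, 1)], target = ids[c(2, 3, 3)],
      sign = c(s1, s2, s1 * s2)))  # coherent by construction
  }
  for (i in seq_len(n_fbl)) {
    ids <- sprintf("fbl%d_%s", i, c("a", "b"))
    s <- sample(c(-1, 1), 1)
    nodes <- rbind(nodes, data.frame(id = ids, kind = "TF", seed = FALSE))
    edges <- rbind(edges, data.frame(source = ids, target = rev(ids),
                                     sign = c(s, s)))  # product +1
  }
  if (n_random_edges > 0L) {
    extra <- sprintf("rnd%d", seq_len(max(4L, ceiling(n_random_edges / 2))))
    nodes <- rbind(nodes, data.frame(id = extra, kind = "gene", seed = FALSE))
    pool <- nodes$id
    src <- sample(pool, n_random_edges, replace = TRUE)
    tgt <- sample(pool, n_random_edges, replace = TRUE)
    keep <- src != tgt
    edges <- rbind(edges, data.frame(source = src[keep], target = tgt[keep],
                                     sign = sample(c(-1, 1), sum(keep),
                                                   replace = TRUE)))
  }
  list(network = signed_network(nodes, edges),
       truth = list(n_coherent_ffl = n_ffl, n_positive_fbl = n_fbl))
}

#' Recovery of planted clusters by a set of rules
#'
#' For each planted cluster, the best single rule's coverage of its
#' members; the recall is the mean coverage over planted clusters.
#'
#' @param rules List of rules (entries of \code{rhsac()$rules}).
#' @param truth Ground truth from \code{\link{synth_expression}}.
#' @return Recall in [0, 1].
#' @export
planted_cluster_recall <- function(rules, truth) {
  if (length(truth$mirna_clusters) == 0L) return(NA_real_)
  cov <- vapply(truth$mirna_clusters, function(cl) {
    if (length(rules) == 0L) return(0)
    max(vapply(rules, function(r)
      length(intersect(r$members, cl)) / length(cl), numeric(1)))
  }, numeric(1))
  mean(cov)
}

#' Recovery of planted regulatory edges by the assembled modules
#'
#' Fraction of planted (miRNA, gene) regulations that appear among the
#' module edges.
#'
#' @param modules A \code{\link{build_modules}} result.
#' @param truth Ground truth from \code{\link{synth_expression}}.
#' @return Recall in [0, 1].
#' @export
planted_edge_recall <- function(modules, truth) {
  if (nrow(truth$edges) == 0L) return(NA_real_)
  got <- unlist(lapply(modules, function(m)
    if (nrow(m$edges)) paste(m$edges$mirna, m$edges$gene, sep = "\r")))
  mean(paste(truth$edges$mirna, truth$edges$gene, sep = "\r") %in% got)
}
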