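#' Density grid for threshold-robust network analysis
#'
#' Graph metrics computed at a single edge density are sensitive to the
#' arbitrary threshold choice; computing them across a grid of densities and
#' integrating (see [auc_over_densities()]) removes that dependence. The
#' default grid spans densities 0.06 to 0.12 in steps of 0.01 (7 points).
#'
#' @param d_min,d_max,step Grid limits and spacing.
#' @return Numeric vector of densities.
#' @export
density_grid <- function(d_min = 0.06, d_max = 0.12, step = 0.01) {
  stopifnot(d_min > 0, d_min <= d_max, d_max < 1, step > 0)
  seq(d_min, d_max, by = step)
}

#' Normalize a connectome by mean network strength
#'
#' Divides every weight by the mean of all off-diagonal upper-triangle
#' weights (zeros included), so the mean connection weight becomes exactly 1.
#' This removes between-subject differences in overall connectivity strength
#' before topology is analyzed; the subsequent density thresholding is then
#' invariant to any global rescaling of the raw weights.
#'
#' @param conn A `connectome` object.
#' @return The normalized `connectome`.
#' @export
normalize_strength <- function(conn) {
  w <- conn$weights
  mw <- mean(w[upper.tri(w)])
  if (mw <= 0) stop("all-zero connectivity matrix cannot be normalized")
  conn$weights <- w / mw
  conn
}

#' Threshold a weighted connectome to a fixed edge density
#'
#' Keeps the `k = round(d * n(n-1)/2)` strongest edges as an unweighted,
#' undirected graph. Ties at the cutoff weight are broken deterministically
#' by node-index lexicographic order so that thresholding is reproducible.
#' If fewer than `k` nonzero weights exist, all nonzero edges are kept with
#' a warning and the achieved density is recorded.
#'
#' @param conn A `connectome` object.
#' @param d Target density in (0, 1).
#' @return An `igraph` undirected graph with vertex names from
#'   `conn$node_labels` and attributes `target_density` and
#'   `achieved_density`.
#' @export
threshold_to_density <- function(conn, d) {
  stopifnot(d > 0, d < 1)
  w <- conn$weights
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[upper.tri(w)]
  k <- round(d * n * (n - 1) / 2)
  nz <- sum(wt > 0)
  if (nz < k) {
    warning(sprintf(
      "only %d nonzero edges available for target %d (density %.3f); keeping all",
      nz, k, d))
    k <- nz
  }
  ord <- order(-wt, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  g <- igraph::graph_from_edgelist(cbind(ut[keep, 1], ut[keep, 2]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::V(g)$name <- conn$node_labels
  g$target_density <- d
  g$achieved_density <- k / (n * (n - 1) / 2)
  g
}

# Dense 0/1 adjacency matrix of an igraph graph.
dense_adjacency <- function(g) {
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  dimnames(a) <- NULL
  (a > 0) * 1
}

# All-pairs unweighted shortest-path lengths by breadth-first expansion of
# the reachability matrix (dense matrix products; diameter iterations).
# Unreached pairs stay Inf.
apsp_lengths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- A > 0
  D[reach] <- 1
  known <- reach | diag(TRUE, n)
  k <- 1L
  while (k < n) {
    k <- k + 1L
    nxt <- (reach %*% A) > 0
    new <- nxt & !known
    if (!any(new)) break
    D[new] <- k
    known <- known | new
    reach <- nxt
  }
  D
}

# Local clustering per node from the adjacency matrix: closed triplets are
# diag(A^3)/2, possible triplets k(k-1)/2; degree < 2 contributes 0.
local_clustering <- function(A) {
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A)
  cc <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  cc
}

#' Mean clustering coefficient and characteristic path length
#'
#' `C` is the mean over nodes of the local clustering coefficient (closed
#' triplets over possible triplets at each node), with nodes of degree < 2
#' contributing 0. `L` is the mean shortest-path length over all reachable
#' ordered pairs of distinct nodes; disconnected pairs are excluded from the
#' mean and their count reported, since characteristic path length is
#' undefined across fragments.
#'
#' @param g An undirected `igraph` graph.
#' @return List with `C`, `L`, and `n_disconnected_pairs`.
#' @export
clustering_and_path <- function(g) {
  if (igraph::ecount(g) == 0L) stop("edgeless graph has no path structure")
  A <- dense_adjacency(g)
  clustering_and_path_adj(A)
}

clustering_and_path_adj <- function(A) {
  C <- mean(local_clustering(A))
  dm <- apsp_lengths(A)
  off <- dm[row(dm) != col(dm)]
  reach <- is.finite(off)
  list(C = C, L = mean(off[reach]), n_disconnected_pairs = sum(!reach))
}

#' Degree-preserving random reference ensemble
#'
#' Generates `n_random` rewired null graphs that preserve the original
#' degree sequence exactly (repeated double-edge swaps that reject self
#' loops and multi-edges; `10 * |E|` rewiring steps per null graph), and
#' returns the ensemble means of clustering and path length. These provide
#' the `C_rand`/`L_rand` denominators for small-worldness. Fully
#' reproducible given `seed`.
#'
#' @param g An undirected `igraph` graph with at least 2 edges.
#' @param n_random Number of null graphs (default 20).
#' @param seed Optional integer seed.
#' @return A `null_ensemble`: list with `n_random`, `c_rand_mean`,
#'   `l_rand_mean`, and `graphs` (the rewired graphs).
#' @export
random_reference <- function(g, n_random = 20, seed = NULL) {
  if (igraph::ecount(g) < 2L) stop("need at least 2 edges to rewire")
  if (!is.null(seed)) set.seed(seed)
  niter <- 10L * igraph::ecount(g)
  graphs <- vector("list", n_random)
  cs <- ls_ <- numeric(n_random)
  orig_edges <- sorted_edge_key(g)
  unchanged <- 0L
  for (i in seq_len(n_random)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                   niter = niter))
    if (identical(sorted_edge_key(gr), orig_edges)) unchanged <- unchanged + 1L
    cl <- clustering_and_path_adj(dense_adjacency(gr))
    cs[i] <- cl$C
    ls_[i] <- cl$L
    graphs[[i]] <- gr
  }
  if (unchanged == n_random)
    warning("no legal degree-preserving swap changed the graph; ",
            "null ensemble equals the original")
  structure(list(n_random = n_random, c_rand_mean = mean(cs),
                 l_rand_mean = mean(ls_), graphs = graphs),
            class = "null_ensemble")
}

sorted_edge_key <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste(el[, 1], el[, 2], sep = "-", collapse = ";")
}

#' Small-worldness index
#'
#' `SW = (C / C_rand) / (L / L_rand)`. A small-world network clusters much
#' more strongly than degree-matched random graphs (`C/C_rand > 1`) while
#' keeping comparable path lengths (`L/L_rand` near 1), so `SW > 1`.
#'
#' @param C,L Clustering and path length of the observed graph.
#' @param c_rand,l_rand Null-ensemble means from [random_reference()].
#' @return List with `norm_clustering`, `norm_path`, `sw`.
#' @export
small_worldness <- function(C, c_rand, L, l_rand) {
  if (any(c(C, c_rand, L, l_rand) <= 0))
    stop("all inputs to small_worldness must be positive")
  nc <- C / c_rand
  np <- L / l_rand
  list(norm_clustering = nc, norm_path = np, sw = nc / np)
}

#' Global and local efficiency
#'
#' Global efficiency is the mean over ordered pairs of distinct nodes of the
#' inverse shortest-path length (0 for disconnected pairs). Local efficiency
#' is the mean over nodes of the global efficiency of the subgraph induced
#' by each node's neighbors (0 for nodes of degree < 2). Both lie in [0, 1]
#' for unweighted graphs.
#'
#' @param g An undirected `igraph` graph.
#' @return List with `global_efficiency`, `local_efficiency`.
#' @export
efficiencies <- function(g) {
  A <- dense_adjacency(g)
  n <- nrow(A)
  if (n < 2L) return(list(global_efficiency = 0, local_efficiency = 0))
  dm <- apsp_lengths(A)
  inv <- 1 / dm
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  geff <- sum(inv) / (n * (n - 1))
  leff <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    m <- length(nb)
    if (m < 2L) return(0)
    dms <- apsp_lengths(A[nb, nb, drop = FALSE])
    invs <- 1 / dms
    invs[!is.finite(invs)] <- 0
    diag(invs) <- 0
    sum(invs) / (m * (m - 1))
  }, numeric(1))
  list(global_efficiency = geff, local_efficiency = mean(leff))
}

#' Node-level metrics: normalized degree and betweenness centrality
#'
#' Normalized node degree is each node's degree divided by the mean network
#' degree (a convention choice: the value 1 means "average connectivity").
#' Betweenness is the fraction of shortest paths between all other node
#' pairs that pass through the node, counting path multiplicity and
#' normalizing by the `(n-1)(n-2)/2` pairs.
#'
#' @param g An undirected `igraph` graph.
#' @return List with numeric vectors `degree_normalized` and `betweenness`,
#'   named by vertex.
#' @export
node_metrics <- function(g) {
  deg <- igraph::degree(g)
  md <- mean(deg)
  dn <- if (md > 0) deg / md else deg * 0
  bt <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  list(degree_normalized = dn, betweenness = bt)
}

#' Area under the curve across a density grid
#'
#' Trapezoidal integral of a metric over the density grid, multiplied by 100
#' for reporting convenience (the integral of an O(1) metric over a 0.06-wide
#' density window is otherwise a small number).
#'
#' @param values Metric values, one per grid density (no missing values).
#' @param grid Density grid (same length as `values`).
#' @return AUC x 100.
#' @export
auc_over_densities <- function(values, grid) {
  if (length(values) != length(grid))
    stop("need one metric value per grid density")
  if (anyNA(values)) stop("missing metric value on the density grid")
  if (is.unsorted(grid)) stop("density grid must be increasing")
  if (length(grid) == 1L) return(unname(values * 100))
  dx <- diff(grid)
  100 * sum(dx * (values[-length(values)] + values[-1]) / 2)
}

#' Full metric set for one connectome
#'
#' Normalizes the connectome by mean strength, thresholds it at every grid
#' density, computes clustering/path length against a degree-preserving null
#' ensemble, small-worldness, efficiencies, and node metrics, and summarizes
#' every metric as AUC over the grid.
#'
#' @param conn A `connectome` object (raw weights; strength normalization is
#'   applied internally).
#' @param grid Density grid from [density_grid()].
#' @param n_random Null graphs per density (default 20).
#' @param seed Integer seed controlling the null ensembles.
#' @return A `network_metric_set`: list with `per_density` (data frame of
#'   global metrics by density), `node_degree` and `betweenness` (matrices,
#'   node x density), and `auc` (named list: global metric AUCs plus
#'   per-node AUC vectors `node_degree` and `betweenness`).
#' @export
connectome_metrics <- function(conn, grid = density_grid(), n_random = 20,
                               seed = NULL) {
  conn <- normalize_strength(conn)
  nd <- length(grid)
  n_nodes <- length(conn$node_labels)
  glob <- data.frame(density = grid, C = NA_real_, L = NA_real_,
                     c_rand = NA_real_, l_rand = NA_real_,
                     norm_clustering = NA_real_, norm_path = NA_real_,
                     sw = NA_real_, global_efficiency = NA_real_,
                     local_efficiency = NA_real_)
  degm <- matrix(NA_real_, n_nodes, nd,
                 dimnames = list(conn$node_labels, NULL))
  btwm <- degm
  if (!is.null(seed)) set.seed(seed)
  for (j in seq_len(nd)) {
    g <- threshold_to_density(conn, grid[j])
    cl <- clustering_and_path(g)
    nul <- random_reference(g, n_random = n_random, seed = NULL)
    sw <- small_worldness(cl$C, nul$c_rand_mean, cl$L, nul$l_rand_mean)
    ef <- efficiencies(g)
    nm <- node_metrics(g)
    glob[j, -1] <- c(cl$C, cl$L, nul$c_rand_mean, nul$l_rand_mean,
                     sw$norm_clustering, sw$norm_path, sw$sw,
                     ef$global_efficiency, ef$local_efficiency)
    degm[, j] <- nm$degree_normalized
    btwm[, j] <- nm$betweenness
  }
  auc <- list(
    norm_clustering = auc_over_densities(glob$norm_clustering, grid),
    norm_path = auc_over_densities(glob$norm_path, grid),
    sw = auc_over_densities(glob$sw, grid),
    global_efficiency = auc_over_densities(glob$global_efficiency, grid),
    local_efficiency = auc_over_densities(glob$local_efficiency, grid),
    node_degree = apply(degm, 1, auc_over_densities, grid = grid),
    betweenness = apply(btwm, 1, auc_over_densities, grid = grid))
  structure(list(subject_id = conn$subject_id, timepoint = conn$timepoint,
                 per_density = glob, node_degree = degm, betweenness = btwm,
                 auc = auc),
            class = "network_metric_set")
}

#' Metric AUC table for a cohort of connectomes
#'
#' Runs [connectome_metrics()] on every subject-timepoint connectome and
#' stacks the AUC summaries into one long table ready for group analysis.
#'
#' @param connectomes Nested list: `connectomes[[subject_id]]$t1` and `$t2`
#'   are `connectome` objects (as produced by [generate_connectomes()]).
#' @param groups Named character vector mapping subject_id to group label.
#' @param grid,n_random Passed to [connectome_metrics()].
#' @param seed Integer seed; each subject-timepoint gets a distinct
#'   deterministic sub-seed.
#' @return Long data frame: `subject_id`, `group`, `timepoint`, `metric`,
#'   `node` (`NA` for global metrics), `auc`.
#' @export
cohort_network_auc <- function(connectomes, groups, grid = density_grid(),
                               n_random = 20, seed = 1L) {
  out <- list()
  sub_ids <- names(connectomes)
  for (i in seq_along(sub_ids)) {
    sid <- sub_ids[i]
    for (tp in c("t1", "t2")) {
      conn <- connectomes[[sid]][[tp]]
      if (is.null(conn)) next
      sub_seed <- (seed + 7919L * i + 104729L * (tp == "t2")) %% 2147483647L
      ms <- connectome_metrics(conn, grid = grid, n_random = n_random,
                               seed = sub_seed)
      glob_names <- c("norm_clustering", "norm_path", "sw",
                      "global_efficiency", "local_efficiency")
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, group = unname(groups[sid]), timepoint = tp,
        metric = glob_names, node = NA_character_,
        auc = unlist(ms$auc[glob_names], use.names = FALSE),
        stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, group = unname(groups[sid]), timepoint = tp,
        metric = "node_degree", node = names(ms$auc$node_degree),
        auc = unname(ms$auc$node_degree), stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, group = unname(groups[sid]), timepoint = tp,
        metric = "betweenness", node = names(ms$auc$betweenness),
        auc = unname(ms$auc$betweenness), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Repeated-measures group x time interaction for paired values.
mixed_anova_interaction <- function(v1, v2, group) {
  n <- length(v1)
  long <- data.frame(y = c(v1, v2),
                     time = factor(rep(c("t1", "t2"), each = n)),
                     grp = factor(rep(group, 2)),
                     id = factor(rep(seq_len(n), 2)))
  fit <- stats::aov(y ~ grp * time + Error(id / time), data = long)
  tab <- summary(fit)[["Error: id:time"]][[1]]
  ix <- grep("grp:time", rownames(tab))
  list(f = unname(tab[ix, "F value"]), p = unname(tab[ix, "Pr(>F)"]))
}

#' Group-by-time analysis of network metric AUCs
#'
#' For each global metric, a repeated-measures ANOVA (between-subject factor
#' group, within-subject factor time) tests the group x time interaction.
#' For node-level metrics the same test runs per node and the node p-values
#' are adjusted across all nodes by the Benjamini-Hochberg false discovery
#' rate. Change values (`t2 - t1`) are summarized per group for nodes that
#' survive FDR at `alpha`.
#'
#' @param auc_df Long AUC table from [cohort_network_auc()]. Subjects missing
#'   either timepoint are dropped with a message.
#' @param alpha Significance level on the FDR-adjusted node p-values.
#' @return List with `global` (metric, F, p), `nodes` (metric, node, F, p,
#'   p_fdr, significant), and `deltas` (group mean/SD of t2 - t1 for
#'   significant nodes).
#' @export
network_group_analysis <- function(auc_df, alpha = 0.05) {
  complete_ids <- function(df) {
    tab <- table(df$subject_id, df$timepoint)
    ids <- rownames(tab)[tab[, "t1"] > 0 & tab[, "t2"] > 0]
    dropped <- setdiff(unique(df$subject_id), ids)
    if (length(dropped))
      message("dropping subject(s) missing a timepoint: ",
              paste(dropped, collapse = ", "))
    ids
  }
  paired <- function(df) {
    w1 <- df[df$timepoint == "t1", ]
    w2 <- df[df$timepoint == "t2", ]
    w2 <- w2[match(w1$subject_id, w2$subject_id), ]
    list(v1 = w1$auc, v2 = w2$auc, group = w1$group,
         subject_id = w1$subject_id)
  }
  glob_metrics <- unique(auc_df$metric[is.na(auc_df$node)])
  glob <- do.call(rbind, lapply(glob_metrics, function(m) {
    df <- auc_df[auc_df$metric == m & is.na(auc_df$node), ]
    df <- df[df$subject_id %in% complete_ids(df), ]
    pr <- paired(df)
    an <- mixed_anova_interaction(pr$v1, pr$v2, pr$group)
    data.frame(metric = m, f = an$f, p = an$p, stringsAsFactors = FALSE)
  }))
  node_metrics_ids <- unique(auc_df$metric[!is.na(auc_df$node)])
  nodes <- NULL
  deltas <- NULL
  for (m in node_metrics_ids) {
    dfm <- auc_df[auc_df$metric == m & !is.na(auc_df$node), ]
    keep <- complete_ids(dfm)
    dfm <- dfm[dfm$subject_id %in% keep, ]
    res <- do.call(rbind, lapply(unique(dfm$node), function(nd) {
      df <- dfm[dfm$node == nd, ]
      pr <- paired(df)
      an <- mixed_anova_interaction(pr$v1, pr$v2, pr$group)
      data.frame(metric = m, node = nd, f = an$f, p = an$p,
                 stringsAsFactors = FALSE)
    }))
    res$p_fdr <- stats::p.adjust(res$p, method = "BH")
    res$significant <- res$p_fdr < alpha
    nodes <- rbind(nodes, res)
    for (nd in res$node[res$significant]) {
      df <- dfm[dfm$node == nd, ]
      pr <- paired(df)
      dl <- pr$v2 - pr$v1
      for (g in sort(unique(pr$group))) {
        deltas <- rbind(deltas, data.frame(
          metric = m, node = nd, group = g,
          delta_mean = mean(dl[pr$group == g]),
          delta_sd = stats::sd(dl[pr$group == g]),
          stringsAsFactors = FALSE))
      }
    }
  }
  list(global = glob, nodes = nodes, deltas = deltas)
}
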