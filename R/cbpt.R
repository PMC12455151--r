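#' Channel neighbourhood graph from sensor coordinates
#'
#' Connects channels whose Euclidean distance is at most `threshold`. With
#' `threshold = NULL` the threshold is set to 1.5 times the median
#' nearest-neighbour distance, which on regular montages links each sensor
#' to its immediate neighbours.
#'
#' @param channel_coords channels x 3 coordinate matrix.
#' @param threshold distance threshold; `NULL` for the automatic choice.
#' @return a `neighbor_graph`: list with symmetric logical `adjacency`
#'   (no self-edges), `threshold` and `n_channels`. Isolated channels
#'   trigger a warning.
#' @export
build_neighbors <- function(channel_coords, threshold = NULL) {
  coords <- as.matrix(channel_coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 channels")
  d <- as.matrix(stats::dist(coords))
  if (is.null(threshold)) {
    nn <- apply(d + diag(Inf, n), 1, min)
    threshold <- 1.5 * stats::median(nn)
  }
  adj <- d <= threshold
  diag(adj) <- FALSE
  if (any(rowSums(adj) == 0)) {
    warning("isolated channels in neighbour graph: ",
            paste(which(rowSums(adj) == 0), collapse = ", "))
  }
  structure(list(adjacency = adj, threshold = threshold, n_channels = n),
            class = "neighbor_graph")
}

# connected components of suprathreshold channels; returns clusters passing
# the minimum-edge rule with their signed mass
cluster_mass <- function(tvals, tcrit, adj, min_edges) {
  out <- list()
  membership <- integer(length(tvals))
  cid <- 0L
  for (sgn in c(1, -1)) {
    supra <- which(sgn * tvals > tcrit)
    if (!length(supra)) next
    seen <- logical(length(tvals))
    for (start in supra) {
      if (seen[start]) next
      comp <- integer(0)
      queue <- start
      seen[start] <- TRUE
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        comp <- c(comp, v)
        nb <- supra[adj[v, supra] & !seen[supra]]
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
      n_edges <- sum(adj[comp, comp]) / 2
      if (n_edges >= min_edges) {
        cid <- cid + 1L
        membership[comp] <- cid
        out[[cid]] <- list(channels = sort(comp), sign = sgn,
                           mass = sum(tvals[comp]), n_edges = n_edges)
      }
    }
  }
  list(clusters = out, membership = membership)
}

paired_t_map <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s <- sqrt(colSums(sweep(D, 2, m)^2) / (n - 1))
  t <- ifelse(s == 0, 0, m / (s / sqrt(n)))
  t
}

#' Cluster-based permutation test over channels
#'
#' First-level statistic: a paired t test at every channel (zero-variance
#' channels get t = 0 and are logged). Channels significant at
#' `alpha_sample` (two-sided) are grouped into connected components of the
#' neighbour graph, separately for positive and negative t; components
#' containing fewer than `min_edges` neighbouring pairs (graph edges among
#' their channels) are discarded. Each surviving cluster's mass is the sum
#' of its t values. The Monte-Carlo null exchanges the two conditions —
#' sign-flipping each subject's difference (`method = "sign_flip"`), or
#' re-drawing trial assignments within subject (`method = "trial_shuffle"`,
#' requires trial-level input) — and records the maximum absolute cluster
#' mass of each draw. The cluster p value is
#' `(1 + #{null >= |mass|}) / (1 + n_perm)`, guaranteeing p in (0, 1].
#'
#' @param A,B condition data. For `sign_flip`: subjects x channels matrices
#'   of per-subject values. For `trial_shuffle`: lists (one element per
#'   subject) of trials x channels matrices.
#' @param graph a [build_neighbors()] graph.
#' @param alpha_sample per-channel two-sided threshold.
#' @param alpha_cluster cluster-level significance threshold.
#' @param n_perm Monte-Carlo draws (a warning is issued below 100).
#' @param min_edges minimum neighbouring pairs per cluster (the strict
#'   reading of "at least two pairs of neighbouring electrodes").
#' @param method permutation scheme, see above.
#' @param seed integer seed.
#' @return a `cluster_result`: `clusters` data.frame (id, sign, n_channels,
#'   n_edges, mass, p, significant), `t` map, `membership`, `null_max`,
#'   `n_permutations`, and `log` of degenerate channels.
#' @export
cluster_test <- function(A, B, graph, alpha_sample = 0.05,
                         alpha_cluster = 0.05, n_perm = 1000L,
                         min_edges = 2L, method = c("sign_flip", "trial_shuffle"),
                         seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(graph, "neighbor_graph"))
  if (n_perm < 100) warning("n_perm < 100: Monte-Carlo p values are unstable")
  if (method == "trial_shuffle") {
    if (!is.list(A) || !is.list(B) || length(A) != length(B)) {
      stop("trial_shuffle needs per-subject lists of trial matrices")
    }
    subj_means <- function(lst) t(vapply(lst, colMeans, numeric(ncol(lst[[1]]))))
    Am <- subj_means(A); Bm <- subj_means(B)
  } else {
    Am <- as.matrix(A); Bm <- as.matrix(B)
  }
  if (!all(dim(Am) == dim(Bm))) stop("A and B must share subjects and channels")
  if (ncol(Am) != graph$n_channels) stop("channel count does not match graph")
  n <- nrow(Am)
  if (n < 2) stop("need at least 2 subjects")
  D <- Am - Bm
  degenerate <- which(apply(D, 2, stats::sd) == 0)
  tvals <- paired_t_map(D)
  tcrit <- stats::qt(1 - alpha_sample / 2, n - 1)
  obs <- cluster_mass(tvals, tcrit, graph$adjacency, min_edges)
  adj <- graph$adjacency
  set.seed(seed)
  null_max <- numeric(n_perm)
  if (length(obs$clusters)) {
    for (r in seq_len(n_perm)) {
      if (method == "sign_flip") {
        flips <- sample(c(-1, 1), n, replace = TRUE)
        Dp <- D * flips
      } else {
        Dp <- t(vapply(seq_along(A), function(s) {
          pooled <- rbind(A[[s]], B[[s]])
          na <- nrow(A[[s]])
          idx <- sample.int(nrow(pooled))
          colMeans(pooled[idx[seq_len(na)], , drop = FALSE]) -
            colMeans(pooled[idx[-seq_len(na)], , drop = FALSE])
        }, numeric(ncol(Am))))
      }
      tp <- paired_t_map(Dp)
      if (any(abs(tp) > tcrit)) {
        cm <- cluster_mass(tp, tcrit, adj, min_edges)
        if (length(cm$clusters)) {
          null_max[r] <- max(abs(vapply(cm$clusters, `[[`, numeric(1), "mass")))
        }
      }
    }
  }
  clusters <- if (length(obs$clusters)) {
    do.call(rbind, lapply(seq_along(obs$clusters), function(i) {
      cl <- obs$clusters[[i]]
      p <- (1 + sum(null_max >= abs(cl$mass))) / (1 + n_perm)
      data.frame(id = i, sign = cl$sign, n_channels = length(cl$channels),
                 n_edges = cl$n_edges, mass = cl$mass, p = p,
                 significant = p < alpha_cluster)
    }))
  } else {
    data.frame(id = integer(0), sign = numeric(0), n_channels = integer(0),
               n_edges = numeric(0), mass = numeric(0), p = numeric(0),
               significant = logical(0))
  }
  structure(
    list(clusters = clusters, t = tvals, membership = obs$membership,
         channels_per_cluster = lapply(obs$clusters, `[[`, "channels"),
         null_max = null_max, n_permutations = n_perm,
         log = if (length(degenerate)) {
           sprintf("zero-variance channels set to t = 0: %s",
                   paste(degenerate, collapse = ", "))
         } else character(0)),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations\n",
              nrow(x$clusters), x$n_permutations))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Bonferroni correction
#'
#' Multiplies each p value by the number of comparisons and caps at 1.
#'
#' @param p_values numeric vector of uncorrected p values.
#' @param m number of comparisons (default: number of p values).
#' @return corrected p values.
#' @examples
#' bonferroni(c(0.01, 0.5), m = 3)  # 0.03, 1.0
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < 1) stop("m must be >= 1")
  pmin(1, m * p_values)
}
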