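#' Channel adjacency from electrode positions
#'
#' Two channels are neighbors iff their angular distance on the unit
#' sphere is at most `max_angle_deg` (default 40 degrees, which connects
#' each standard 10-20 electrode to its immediate ring and midline
#' neighbors). Self-neighborhood is excluded; isolated channels trigger a
#' warning since they can never join a cluster.
#'
#' @param positions Matrix (channels x 3) of unit-sphere coordinates with
#'   rownames, e.g. `recording$positions`.
#' @param max_angle_deg Neighborhood radius in degrees.
#' @return A `psg_adjacency`: symmetric logical matrix with `FALSE`
#'   diagonal.
#' @export
channel_adjacency <- function(positions, max_angle_deg = 40) {
  stopifnot(is.matrix(positions), ncol(positions) == 3L)
  if (nrow(positions) < 2L) {
    stop("need at least 2 located channels", call. = FALSE)
  }
  cosang <- tcrossprod(positions /
                         sqrt(rowSums(positions^2)))
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  adj <- acos(cosang) * 180 / pi <= max_angle_deg
  diag(adj) <- FALSE
  dimnames(adj) <- list(rownames(positions), rownames(positions))
  isolated <- rownames(positions)[rowSums(adj) == 0]
  if (length(isolated)) {
    warning("isolated channel(s) with no neighbors: ",
            paste(isolated, collapse = ", "))
  }
  structure(adj, class = c("psg_adjacency", "matrix"))
}

#' Cluster-based permutation comparison of two groups
#'
#' Nonparametric family-wise-error-controlled comparison of two
#' independent groups over channels (or channels x frequencies).
#' Per feature, Welch's t is computed; features with `|t|` above the
#' two-sided `alpha_cluster` critical value are clustered by adjacency
#' (separately for positive and negative effects, so opposite-signed
#' neighbors never merge); the cluster statistic is the summed t of its
#' members. The null distribution is the maximum `|mass|` over random
#' group relabelings, and each observed cluster's p-value is
#' `(1 + #(null >= |mass|)) / (n_perm + 1)` — never below
#' `1/(n_perm + 1)`.
#'
#' For channel x frequency data, pass matrices whose columns are ordered
#' channel-major (all frequencies of channel 1, then channel 2, ...) and
#' give `n_freq`; features are adjacent iff they share a channel and are
#' consecutive in frequency, or share a frequency bin and are neighboring
#' channels.
#'
#' @param groupA,groupB Participant x feature matrices on the same
#'   feature space.
#' @param adjacency A [channel_adjacency()] matrix (channels x channels).
#' @param alpha_cluster Two-sided cluster-forming alpha (default 0.05).
#' @param n_perm Number of permutations (default 1000, minimum 100).
#' @param seed Integer seed for the permutation draw.
#' @param n_freq Number of frequency bins per channel (default 1).
#' @return A `cluster_result`: list with `clusters` (data frame: id,
#'   sign, mass, p_value, n_members), `members` (list of feature index
#'   vectors), `t_obs`, `n_permutations`, `null_max_mass`, `seed`.
#' @export
cluster_permutation <- function(groupA, groupB, adjacency,
                                alpha_cluster = 0.05, n_perm = 1000,
                                seed = 1, n_freq = 1L) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (ncol(groupA) != ncol(groupB)) {
    stop("groups have different feature spaces", call. = FALSE)
  }
  n1 <- nrow(groupA); n2 <- nrow(groupB)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 participants",
                               call. = FALSE)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  n_feat <- ncol(groupA)
  n_chan <- n_feat / n_freq
  if (n_chan != round(n_chan) || nrow(adjacency) != n_chan) {
    stop("adjacency size does not match feature space", call. = FALSE)
  }
  nbrs <- .feature_neighbors(adjacency, as.integer(n_freq))
  X <- rbind(groupA, groupB)
  n <- n1 + n2
  obs <- .welch_t(colMeans(groupA), colMeans(groupB),
                  apply(groupA, 2, var), apply(groupB, 2, var), n1, n2)
  obs_cl <- .form_clusters(obs$t, obs$crit(alpha_cluster), nbrs)
  # permutation null: max |mass| over relabelings
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n, n1))
  X2 <- X^2
  null_max <- numeric(n_perm)
  tot_sum <- colSums(X); tot_sq <- colSums(X2)
  for (p in seq_len(n_perm)) {
    ia <- perm_idx[, p]
    s1 <- colSums(X[ia, , drop = FALSE])
    q1 <- colSums(X2[ia, , drop = FALSE])
    m1 <- s1 / n1; m2 <- (tot_sum - s1) / n2
    v1 <- (q1 - n1 * m1^2) / (n1 - 1)
    v2 <- (tot_sq - q1 - n2 * m2^2) / (n2 - 1)
    wt <- .welch_t(m1, m2, v1, v2, n1, n2)
    cl <- .form_clusters(wt$t, wt$crit(alpha_cluster), nbrs,
                         max_only = TRUE)
    null_max[p] <- cl
  }
  if (length(obs_cl$mass)) {
    pvals <- vapply(obs_cl$mass, function(m) {
      (1 + sum(null_max >= abs(m))) / (n_perm + 1)
    }, numeric(1))
  } else {
    pvals <- numeric(0)
  }
  clusters <- data.frame(id = seq_along(obs_cl$mass),
                         sign = sign(obs_cl$mass),
                         mass = obs_cl$mass, p_value = pvals,
                         n_members = lengths(obs_cl$members))
  structure(list(clusters = clusters, members = obs_cl$members,
                 t_obs = obs$t, n_permutations = n_perm,
                 null_max_mass = null_max, seed = seed,
                 n_freq = n_freq),
            class = "cluster_result")
}

.welch_t <- function(m1, m2, v1, v2, n1, n2) {
  # clamp tiny negative variances from the sum-of-squares identity
  v1 <- pmax(v1, 0)
  v2 <- pmax(v2, 0)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  df[!is.finite(df)] <- n1 + n2 - 2
  t[!is.finite(t)] <- 0
  list(t = t, df = df,
       crit = function(alpha) qt(1 - alpha / 2, df))
}

# Feature neighbor lists for channels x freqs (freq varies fastest within
# a channel).
.feature_neighbors <- function(adjacency, n_freq) {
  n_chan <- nrow(adjacency)
  adj_list <- lapply(seq_len(n_chan), function(i) which(adjacency[i, ]))
  n_feat <- n_chan * n_freq
  nbrs <- vector("list", n_feat)
  for (ch in seq_len(n_chan)) {
    for (fr in seq_len(n_freq)) {
      f <- (ch - 1L) * n_freq + fr
      nb <- (adj_list[[ch]] - 1L) * n_freq + fr          # same freq
      if (fr > 1L) nb <- c(nb, f - 1L)                   # same channel
      if (fr < n_freq) nb <- c(nb, f + 1L)
      nbrs[[f]] <- nb
    }
  }
  nbrs
}

# Connected components of supra-threshold features, same-sign only.
.form_clusters <- function(t, crit, nbrs, max_only = FALSE) {
  supra <- which(abs(t) > crit)
  if (length(supra) == 0L) {
    return(if (max_only) 0 else list(mass = numeric(0), members = list()))
  }
  s <- sign(t)
  in_supra <- logical(length(t))
  in_supra[supra] <- TRUE
  visited <- logical(length(t))
  masses <- numeric(0)
  members <- list()
  best <- 0
  for (f0 in supra) {
    if (visited[f0]) next
    comp <- integer(0)
    queue <- f0
    visited[f0] <- TRUE
    while (length(queue)) {
      f <- queue[[1L]]
      queue <- queue[-1L]
      comp <- c(comp, f)
      for (nb in nbrs[[f]]) {
        if (in_supra[nb] && !visited[nb] && s[nb] == s[f0]) {
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    m <- sum(t[comp])
    if (max_only) {
      best <- max(best, abs(m))
    } else {
      masses <- c(masses, m)
      members[[length(members) + 1L]] <- sort(comp)
    }
  }
  if (max_only) best else list(mass = masses, members = members)
}

#' Export a cluster report as CSV
#'
#' One row per cluster with its member feature indices collapsed into a
#' semicolon-separated string.
#'
#' @param result A `cluster_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_csv <- function(result, path) {
  df <- result$clusters
  df$members <- vapply(result$members, paste, character(1),
                       collapse = ";")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
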