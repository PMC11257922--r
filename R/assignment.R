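# Optimal one-to-one assignment for bipartite matching between predicted
# queries and ground-truth objects (the DETR-family matching step).

#' Minimal-cost bipartite assignment (Hungarian algorithm)
#'
#' Shortest-augmenting-path implementation (O(n^3)). The cost matrix may be
#' rectangular; every column (ground truth) is matched to a distinct row
#' (query), which requires `nrow(cost) >= ncol(cost)`. Rows left unmatched are
#' treated as background by the caller.
#'
#' @param cost numeric n_queries x n_gt matrix of finite costs.
#' @return list with `pairs` (k x 2 matrix of (row, col) indices, one row per
#'   ground truth, ordered by column), `cost` (total assigned cost) and
#'   `unmatched_rows`.
#' @export
hungarian_match <- function(cost) {
  if (!is.matrix(cost)) cost <- as.matrix(cost)
  if (length(cost) && any(!is.finite(cost))) {
    stop("hungarian_match: cost matrix contains non-finite values")
  }
  n <- nrow(cost); m <- ncol(cost)
  if (m == 0L) {
    return(list(pairs = matrix(integer(0), 0, 2,
                               dimnames = list(NULL, c("row", "col"))),
                cost = 0, unmatched_rows = seq_len(n)))
  }
  if (n < m) stop("hungarian_match: need at least as many rows as columns")

  a <- t(cost)                      # m x n: assign each of m items to a slot
  INF <- .Machine$double.xmax / 4
  u <- numeric(m + 1)               # item potentials
  v <- numeric(n + 1)               # slot potentials
  p <- integer(n + 1)               # p[slot] = item assigned (0 none); n+1 virtual
  way <- integer(n + 1)

  for (i in seq_len(m)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- a[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }

  col_of_row <- integer(n)          # 0 = unmatched
  for (j in seq_len(n)) if (p[j] > 0L) col_of_row[j] <- p[j]
  pairs <- cbind(row = which(col_of_row > 0L), col = col_of_row[col_of_row > 0L])
  pairs <- pairs[order(pairs[, "col"]), , drop = FALSE]
  total <- if (nrow(pairs)) sum(cost[pairs]) else 0
  list(pairs = pairs, cost = total,
       unmatched_rows = which(col_of_row == 0L))
}
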