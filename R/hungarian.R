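#' Minimum-cost assignment (Munkres / Hungarian algorithm)
#'
#' Solves the linear sum assignment problem: given an `n x m` cost
#' matrix, find the one-to-one pairing of rows to columns that minimises
#' total cost, matching `min(n, m)` pairs. This is the classic
#' star/prime Munkres algorithm on the cost matrix padded to square with
#' a constant, which leaves the optimum over the real entries unchanged.
#' Complexity is O(k^3) for k = max(n, m).
#'
#' Zeros are detected exactly: every value the algorithm compares to zero
#' is produced by subtracting a minimum from itself, so no tolerance is
#' needed. Scanning is row-major, which makes the solution deterministic
#' when several pairings tie.
#'
#' @param cost numeric matrix of non-negative finite costs (rows:
#'   e.g. track heads; columns: e.g. candidate detections).
#' @return list with `pairs`, a `min(n, m) x 2` integer matrix of
#'   (row, col) pairs sorted by row, and `cost`, the minimal total cost.
#' @examples
#' solve_assignment(matrix(c(4, 2, 8, 4, 3, 7, 3, 1, 6), 3, 3))
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost)) cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L)
    return(list(pairs = matrix(integer(0), 0L, 2L,
                               dimnames = list(NULL, c("row", "col"))),
                cost = 0))
  if (any(!is.finite(cost))) stop("costs must be finite")
  k <- max(n, m)
  C <- matrix(0, k, k)
  C[seq_len(n), seq_len(m)] <- cost
  assign <- munkres_square(C)
  pairs <- cbind(row = seq_len(k), col = assign)
  pairs <- pairs[pairs[, 1] <= n & pairs[, 2] <= m, , drop = FALSE]
  list(pairs = pairs,
       cost = sum(cost[pairs]))
}

# Munkres on a square matrix; returns assigned column per row.
munkres_square <- function(C) {
  n <- nrow(C)
  C <- C - apply(C, 1L, min)
  starred <- matrix(FALSE, n, n)
  primed <- matrix(FALSE, n, n)
  # initial greedy starring of independent zeros
  for (i in seq_len(n)) {
    js <- which(C[i, ] == 0 & !apply(starred, 2L, any))
    if (length(js)) starred[i, js[1L]] <- TRUE
  }
  row_cov <- rep(FALSE, n); col_cov <- rep(FALSE, n)
  repeat {
    # step 3: cover columns containing a starred zero
    col_cov <- apply(starred, 2L, any)
    if (sum(col_cov) == n) break
    repeat {
      # step 4: prime an uncovered zero
      z <- find_uncovered_zero(C, row_cov, col_cov)
      while (!is.null(z)) {
        primed[z[1L], z[2L]] <- TRUE
        sj <- which(starred[z[1L], ])
        if (length(sj) == 0L) break
        row_cov[z[1L]] <- TRUE
        col_cov[sj] <- FALSE
        z <- find_uncovered_zero(C, row_cov, col_cov)
      }
      if (!is.null(z)) break
      # step 6: adjust the matrix by the smallest uncovered value
      e <- min(C[!row_cov, !col_cov])
      C[row_cov, ] <- C[row_cov, ] + e
      C[, !col_cov] <- C[, !col_cov] - e
    }
    # step 5: augment along the alternating prime/star path from z
    path <- matrix(z, 1L, 2L)
    repeat {
      r <- which(starred[, path[nrow(path), 2L]])
      if (length(r) == 0L) break
      path <- rbind(path, c(r, path[nrow(path), 2L]))
      cc <- which(primed[r, ])
      path <- rbind(path, c(r, cc[1L]))
    }
    for (i in seq_len(nrow(path))) {
      p <- path[i, ]
      starred[p[1L], p[2L]] <- !starred[p[1L], p[2L]]
    }
    primed[] <- FALSE
    row_cov[] <- FALSE
    col_cov[] <- FALSE
  }
  apply(starred, 1L, which)
}

find_uncovered_zero <- function(C, row_cov, col_cov) {
  # row-major deterministic scan
  rows <- which(!row_cov); cols <- which(!col_cov)
  for (i in rows) {
    j <- cols[C[i, cols] == 0]
    if (length(j)) return(c(i, j[1L]))
  }
  NULL
}
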