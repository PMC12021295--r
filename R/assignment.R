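#' Gated minimum-cost one-to-one assignment
#'
#' Solves the rectangular assignment problem with the Hungarian algorithm
#' (shortest augmenting paths with dual potentials, O(n^3)). Pairs whose cost
#' exceeds `gate` are inadmissible; among all matchings the solver returns
#' one of maximum cardinality over admissible pairs with minimum total cost,
#' which is the behavior frame-to-frame trackers need (an empty matching is
#' never "cheaper" than a valid link).
#'
#' @param costs numeric matrix, `costs[i, j]` the cost of matching row `i`
#'   to column `j`; all entries finite.
#' @param gate maximum admissible cost (default `Inf`).
#' @return List with `matches` (two-column integer matrix of row/col pairs),
#'   `total_cost` (sum over matched admissible pairs), `unmatched_rows` and
#'   `unmatched_cols`.
#' @export
solve_assignment <- function(costs, gate = Inf) {
  costs <- as.matrix(costs)
  nr <- nrow(costs); nc <- ncol(costs)
  empty <- list(matches = matrix(integer(0), 0, 2,
                                 dimnames = list(NULL, c("row", "col"))),
                total_cost = 0,
                unmatched_rows = seq_len(nr), unmatched_cols = seq_len(nc))
  if (nr == 0 || nc == 0) return(empty)
  if (any(!is.finite(costs))) stop("costs must be finite")

  # Square the problem; inadmissible and padded entries share one large cost
  # so the solver first maximizes the number of admissible pairs, then
  # minimizes their total cost.
  big <- (max(abs(costs)) + 1) * (nr + nc + 1)
  n <- max(nr, nc)
  a <- matrix(big, n, n)
  adm <- costs <= gate
  if (!any(adm)) return(empty)
  sub <- a[seq_len(nr), seq_len(nc), drop = FALSE]
  sub[adm] <- costs[adm]
  a[seq_len(nr), seq_len(nc)] <- sub

  # Columns are stored at offset +1: index 1 is the virtual column of the
  # augmenting-path formulation; p[jj] is the row assigned to column jj - 1.
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- logical(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used)
      cur <- a[i0, free - 1L] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used)
      u[p[usedj]] <- u[p[usedj]] + delta
      v[usedj] <- v[usedj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    while (j0 != 1L) {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
    }
  }

  assign_col <- integer(n)            # row -> column (1-based, squared)
  for (jj in 2:(n + 1)) if (p[jj] > 0L) assign_col[p[jj]] <- jj - 1L
  rows <- which(assign_col > 0)
  rows <- rows[rows <= nr]
  cols <- assign_col[rows]
  ok <- cols <= nc
  rows <- rows[ok]; cols <- cols[ok]
  ok <- costs[cbind(rows, cols)] <= gate
  rows <- rows[ok]; cols <- cols[ok]
  matches <- cbind(row = as.integer(rows), col = as.integer(cols))
  list(matches = matches,
       total_cost = if (nrow(matches)) sum(costs[matches]) else 0,
       unmatched_rows = setdiff(seq_len(nr), rows),
       unmatched_cols = setdiff(seq_len(nc), cols))
}
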