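#' @name connectivity_bn
#' @title Discrete Bayesian network for tracklet connectivity
#'
#' @description
#' Whether two tracklets belong to one trajectory is decided from a small
#' discrete Bayesian network over appearance, motion, spatial and temporal
#' evidence: intensity similarity `I`, orientation similarity `Or`, speed
#' similarity `Sp`, end-to-start distance `D`, frame gap `G`, and a
#' `sequence` node with the two parents order `Od` (does the second
#' tracklet start after the first ends) and overlap `Ov` (do they overlap
#' in time). The binary connectivity variable `CS` has all evidence
#' variables as direct parents; its conditional table is generated from an
#' odds table in which each favorable evidence state multiplies the odds of
#' `CS = TRUE`, so the network is fully user-editable through the
#' configuration. Inference is exact enumeration — the network is small
#' enough that sampling is never needed.
NULL

#' Default Bayesian-network parameters
#'
#' Evidence variables are discretized into three ordinal states
#' (`good` / `mid` / `poor`) plus an `unknown` state for evidence a
#' length-1 tracklet cannot supply; thresholds and per-state odds factors
#' are all editable. The published description of this network does not
#' include its probability tables, so these defaults are the package's own
#' calibrated stand-in.
#'
#' @return List with `prior_true`, `thresholds` and `odds`.
#' @export
bn_default_params <- function() {
  list(
    prior_true = 0.5,
    thresholds = list(
      intensity_ratio = c(1.3, 2),   # |brighter/dimmer| terminal ROI means
      angle_deg = c(45, 120),        # terminal-segment heading difference
      speed_ratio = c(1.5, 3),       # terminal-segment speed ratio
      dist_frac = c(1 / 3, 2 / 3),   # end-to-start distance / pair gate
      gap_frames = c(1, 3)           # 0-1 / 2-3 / >3 frames
    ),
    # named lists (not vectors) so the YAML configuration round-trips
    odds = list(
      intensity = list(good = 2.5, mid = 1, poor = 0.3, unknown = 1),
      orientation = list(good = 2.5, mid = 1, poor = 0.15, unknown = 1),
      speed = list(good = 2, mid = 1, poor = 0.4, unknown = 1),
      distance = list(good = 2.5, mid = 1, poor = 0.4),
      gap = list(good = 2, mid = 1, poor = 0.5),
      sequence = list(sequential = 3, overlap = 0.2, reversed = 0.05)
    )
  )
}

# Build the explicit network: named list of nodes with states, parents and
# CPTs (arrays with the node's states as the first dimension).
bn_build <- function(params = bn_default_params()) {
  odds <- params$odds
  st3 <- c("good", "mid", "poor")
  st4 <- c(st3, "unknown")
  uniform <- function(states) {
    setNames(rep(1 / length(states), length(states)), states)
  }
  seq_states <- c("sequential", "overlap", "reversed")
  # deterministic sequence CPT: dims (sequence, Od, Ov)
  seq_cpt <- array(0, c(3, 2, 2),
                   dimnames = list(seq_states, c("TRUE", "FALSE"),
                                   c("TRUE", "FALSE")))
  seq_cpt["overlap", , "TRUE"] <- 1          # any overlap dominates
  seq_cpt["sequential", "TRUE", "FALSE"] <- 1
  seq_cpt["reversed", "FALSE", "FALSE"] <- 1

  parents <- c("I", "Or", "Sp", "sequence", "G", "D")
  pstates <- list(I = st4, Or = st4, Sp = st4, sequence = seq_states,
                  G = st3, D = st3)
  pfactors <- list(I = odds$intensity, Or = odds$orientation,
                   Sp = odds$speed, sequence = odds$sequence,
                   G = odds$gap, D = odds$distance)
  dims <- c(2L, vapply(pstates, length, integer(1)))
  cs_cpt <- array(0, dims, dimnames = c(list(c("TRUE", "FALSE")), pstates))
  grid <- expand.grid(pstates, stringsAsFactors = FALSE)
  base <- params$prior_true / (1 - params$prior_true)
  for (r in seq_len(nrow(grid))) {
    o <- base
    for (v in parents) o <- o * pfactors[[v]][[grid[r, v]]]
    p <- o / (1 + o)
    idx <- as.matrix(cbind(c("TRUE", "FALSE"),
                           grid[rep(r, 2), , drop = FALSE]))
    cs_cpt[idx] <- c(p, 1 - p)
  }

  list(
    Od = list(states = c("TRUE", "FALSE"), parents = character(),
              cpt = uniform(c("TRUE", "FALSE"))),
    Ov = list(states = c("TRUE", "FALSE"), parents = character(),
              cpt = uniform(c("TRUE", "FALSE"))),
    sequence = list(states = seq_states, parents = c("Od", "Ov"),
                    cpt = seq_cpt),
    I = list(states = st4, parents = character(), cpt = uniform(st4)),
    Or = list(states = st4, parents = character(), cpt = uniform(st4)),
    Sp = list(states = st4, parents = character(), cpt = uniform(st4)),
    G = list(states = st3, parents = character(), cpt = uniform(st3)),
    D = list(states = st3, parents = character(), cpt = uniform(st3)),
    CS = list(states = c("TRUE", "FALSE"), parents = parents, cpt = cs_cpt)
  )
}

#' Exact inference on a small discrete Bayesian network
#'
#' Computes `P(query | evidence)` by enumerating the joint distribution
#' over all unobserved variables.
#'
#' @param net network structure from `bn_build()` (a named list of nodes
#'   with `states`, `parents` and `cpt`).
#' @param query node name.
#' @param evidence named list of observed states.
#' @return Named probability vector over the query node's states.
#' @export
bn_infer <- function(net, query = "CS", evidence = list()) {
  vars <- names(net)
  free <- setdiff(vars, names(evidence))
  grids <- lapply(setNames(free, free), function(v) net[[v]]$states)
  grid <- if (length(free)) expand.grid(grids, stringsAsFactors = FALSE)
  else data.frame(row.names = 1)
  post <- setNames(numeric(length(net[[query]]$states)),
                   net[[query]]$states)
  for (r in seq_len(max(1, nrow(grid)))) {
    assign_full <- c(as.list(if (nrow(grid)) grid[r, , drop = FALSE] else NULL),
                     evidence)
    w <- 1
    for (v in vars) {
      node <- net[[v]]
      sv <- as.character(assign_full[[v]])
      w <- w * if (length(node$parents) == 0) node$cpt[[sv]] else {
        idx <- matrix(c(sv, vapply(node$parents,
                                   function(p) as.character(assign_full[[p]]),
                                   character(1))), 1)
        node$cpt[idx]
      }
      if (w == 0) break
    }
    post[[as.character(assign_full[[query]])]] <-
      post[[as.character(assign_full[[query]])]] + w
  }
  if (sum(post) == 0) stop("evidence has zero probability")
  post / sum(post)
}
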