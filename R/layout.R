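# Deterministic force placement of PTM / summary nodes around their reference
# skeleton nodes. The physics: each floating node is attached to its
# reference node by a spring (rest length = node radius + margin) and repels
# the other floating nodes of the *same* reference with an inverse-square
# force. The total potential is minimized by gradient descent with
# backtracking (a step is only accepted if it does not increase the energy),
# which makes the energy trace monotonically non-increasing by construction.
# Initial angular positions are derived from the seed by integer hashing, so
# the whole procedure involves no random number generator state and two runs
# with the same input are bit-identical. A final deterministic separation
# pass guarantees that no two nodes sharing a reference end up closer than
# the collision radius.

#' Layout parameters for PTM node placement
#'
#' @param spring_strength Spring constant pulling a PTM node toward its
#'   reference node (dimensionless multiplier on the displacement from the
#'   rest length, in pixels).
#' @param repulsion_strength Magnitude of the pairwise inverse-square
#'   repulsion between PTM nodes of the same reference (pixel^3 units).
#' @param collision_radius Minimum allowed center distance (pixels) between
#'   two PTM nodes sharing a reference node.
#' @param rest_length Spring rest length (pixels): roughly the reference node
#'   radius plus a margin.
#' @param iterations Gradient-descent iteration budget.
#' @param seed Integer seed for the deterministic initial angular placement.
#' @return A list of class `layout_params`.
#' @export
layout_params <- function(spring_strength = 0.05, repulsion_strength = 400,
                          collision_radius = 18, rest_length = 30,
                          iterations = 300, seed = 1L) {
  stopifnot(iterations >= 1, collision_radius > 0)
  p <- list(spring_strength = spring_strength,
            repulsion_strength = repulsion_strength,
            collision_radius = collision_radius,
            rest_length = rest_length,
            iterations = as.integer(iterations),
            seed = as.integer(seed))
  class(p) <- "layout_params"
  p
}

layout_energy <- function(xy, ref_xy, ref_key, params) {
  d_ref <- sqrt(rowSums((xy - ref_xy)^2))
  e <- sum(0.5 * params$spring_strength * (d_ref - params$rest_length)^2)
  n <- nrow(xy)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (ref_key[i] != ref_key[j]) next
        d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
        e <- e + params$repulsion_strength / max(d, 1e-9)
      }
    }
  }
  e
}

layout_gradient <- function(xy, ref_xy, ref_key, params) {
  g <- matrix(0, nrow(xy), 2)
  delta <- xy - ref_xy
  d_ref <- pmax(sqrt(rowSums(delta^2)), 1e-9)
  # d/dx of 0.5*k*(d - r0)^2 = k*(d - r0) * x/d
  g <- g + params$spring_strength * (d_ref - params$rest_length) / d_ref * delta
  n <- nrow(xy)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (ref_key[i] != ref_key[j]) next
        dij <- xy[i, ] - xy[j, ]
        d <- max(sqrt(sum(dij^2)), 1e-9)
        # d/dx of c/d = -c * x / d^3
        grad <- -params$repulsion_strength * dij / d^3
        g[i, ] <- g[i, ] + grad
        g[j, ] <- g[j, ] - grad
      }
    }
  }
  g
}

separate_colliding <- function(xy, ref_key, radius, seed) {
  n <- nrow(xy)
  if (n < 2) return(xy)
  for (round in 1:500) {
    moved <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (ref_key[i] != ref_key[j]) next
        dij <- xy[i, ] - xy[j, ]
        d <- sqrt(sum(dij^2))
        if (d >= radius) next
        if (d < 1e-9) {
          ang <- 2 * pi * hash_unit(seed, i * 131L + j)
          dij <- c(cos(ang), sin(ang))
          d <- 1
        }
        push <- (radius - d) / 2 * dij / max(d, 1e-9) * 1.0000001
        xy[i, ] <- xy[i, ] + push
        xy[j, ] <- xy[j, ] - push
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  xy
}

#' Place PTM and summary nodes around their reference nodes
#'
#' Assigns coordinates to every floating (PTM or summary) node of a projected
#' graph. Skeleton coordinates are never modified. The procedure is fully
#' deterministic: the same graph and parameters always produce bit-identical
#' coordinates, and the per-iteration energy trace (stored as attribute
#' `energy_trace` on the result) is non-increasing.
#'
#' @param graph A [project_dataset()] result.
#' @param params A [layout_params()].
#' @return The graph with `x`/`y` filled on `ptm_nodes` / `summary_nodes`,
#'   `laid_out = TRUE` and the energy trace stored in `energy_trace`.
#' @export
layout_ptm_nodes <- function(graph, params = layout_params()) {
  stopifnot(inherits(graph, "projected_graph"))
  float <- if (graph$collapse) graph$summary_nodes else graph$ptm_nodes
  if (nrow(float) == 0L) {
    graph$laid_out <- TRUE
    graph$energy_trace <- numeric()
    return(graph)
  }
  ref_key <- float$node_id
  ref_xy <- t(vapply(ref_key, function(id) {
    n <- skeleton_node_by_id(graph$base, id)
    if (is.null(n$x)) stop(sprintf("reference node %s has no coordinates", id))
    c(n$x, n$y)
  }, numeric(2)))

  # Seeded angular initialisation on a circle of the spring rest length,
  # spreading nodes of the same reference evenly with a hashed phase.
  n <- nrow(float)
  idx_within <- stats::ave(seq_len(n), ref_key, FUN = seq_along)
  n_within <- stats::ave(seq_len(n), ref_key, FUN = length)
  phase <- vapply(seq_len(n), function(i) {
    2 * pi * hash_unit(params$seed, match(ref_key[i], unique(ref_key)))
  }, numeric(1))
  ang <- phase + 2 * pi * (idx_within - 1) / n_within
  xy <- ref_xy + params$rest_length * cbind(cos(ang), sin(ang))

  energy <- layout_energy(xy, ref_xy, ref_key, params)
  trace <- numeric(params$iterations)
  step <- 1.0
  for (it in seq_len(params$iterations)) {
    g <- layout_gradient(xy, ref_xy, ref_key, params)
    accepted <- FALSE
    s <- step
    for (try in 1:20) {
      cand <- xy - s * g
      e_cand <- layout_energy(cand, ref_xy, ref_key, params)
      if (e_cand <= energy) {
        xy <- cand
        energy <- e_cand
        step <- s * 1.1
        accepted <- TRUE
        break
      }
      s <- s / 2
    }
    if (!accepted) step <- s
    trace[it] <- energy
  }
  xy <- separate_colliding(xy, ref_key, params$collision_radius, params$seed)

  if (graph$collapse) {
    graph$summary_nodes$x <- xy[, 1]
    graph$summary_nodes$y <- xy[, 2]
  } else {
    graph$ptm_nodes$x <- xy[, 1]
    graph$ptm_nodes$y <- xy[, 2]
  }
  graph$laid_out <- TRUE
  graph$energy_trace <- trace
  graph$layout_params <- params
  graph
}
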