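# Synthetic capillary network inside a tissue voxel.
#
# The generator emulates the morphometry of cortical capillary beds: a
# space-filling tangle of 8-10 um vessels with branching and anastomoses,
# grown by a seeded branching random walk until a target length density is
# reached. It stands in for image-derived network geometry, so all
# network-dependent results are tolerance-based, not exact.

#' Vessel graph constructor
#'
#' @param nodes Numeric matrix (n x 3) of node positions, m, inside the voxel.
#' @param segments Data frame with columns `from`, `to` (node indices),
#'   `outer_diameter` (m) and `wall_thickness` (m).
#' @param voxel_dims Length-3 numeric, voxel edge lengths in m.
#' @param seed Integer seed used to generate the graph (NA for hand-built
#'   graphs).
#' @return A `vessel_graph` object.
#' @export
vessel_graph <- function(nodes, segments, voxel_dims, seed = NA_integer_) {
  nodes <- as.matrix(nodes)
  if (nrow(nodes) > 0) {
    stopifnot(ncol(nodes) == 3)
    for (k in 1:3) {
      if (any(nodes[, k] < -1e-12 | nodes[, k] > voxel_dims[k] + 1e-12)) {
        stop_invalid("all nodes must lie inside the voxel")
      }
    }
  }
  segments <- as.data.frame(segments)
  if (nrow(segments) > 0) {
    need <- c("from", "to", "outer_diameter", "wall_thickness")
    stopifnot(all(need %in% names(segments)))
    lumen <- segments$outer_diameter - 2 * segments$wall_thickness
    if (any(lumen <= 0)) stop_invalid("lumen diameter (outer - 2*wall) must be > 0")
  }
  structure(list(nodes = nodes, segments = segments,
                 voxel_dims = as.numeric(voxel_dims), seed = seed),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  st <- network_stats(x)
  cat(sprintf("Capillary vessel graph: %d nodes, %d segments in a %s mm voxel\n",
              nrow(x$nodes), nrow(x$segments),
              paste(signif(x$voxel_dims * 1e3, 3), collapse = " x ")))
  cat(sprintf("  length density  : %.0f mm/mm^3\n", st$length_density))
  cat(sprintf("  surface density : %.1f mm^2/mm^3\n", st$surface_density))
  cat(sprintf("  volume fraction : %.4f\n", st$volume_fraction))
  invisible(x)
}

.segment_lengths <- function(graph) {
  if (nrow(graph$segments) == 0) return(numeric(0))
  a <- graph$nodes[graph$segments$from, , drop = FALSE]
  b <- graph$nodes[graph$segments$to, , drop = FALSE]
  sqrt(rowSums((a - b)^2))
}

#' Morphometric densities of a vessel graph
#'
#' @param graph A [vessel_graph()].
#' @return A `network_stats` object: list with `length_density` (mm/mm^3),
#'   `surface_density` (mm^2/mm^3, from the outer diameter) and
#'   `volume_fraction` (dimensionless, from the lumen diameter).
#' @examples
#' g <- generate_network(seed = 1)
#' network_stats(g)
#' @export
network_stats <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  vol <- prod(graph$voxel_dims)
  len <- .segment_lengths(graph)
  if (length(len) == 0) {
    return(structure(list(length_density = 0, surface_density = 0,
                          volume_fraction = 0), class = "network_stats"))
  }
  d_out <- graph$segments$outer_diameter
  d_lum <- d_out - 2 * graph$segments$wall_thickness
  structure(list(
    # SI m/m^3 = 1e-6 mm/mm^3; m^2/m^3 = 1e-3 mm^2/mm^3
    length_density = sum(len) / vol * 1e-6,
    surface_density = sum(pi * d_out * len) / vol * 1e-3,
    volume_fraction = sum(pi * (d_lum / 2)^2 * len) / vol
  ), class = "network_stats")
}

#' Generate a synthetic capillary network
#'
#' Grows a connected capillary network inside the voxel by a seeded
#' branching random walk with anastomosis: active tips advance in steps with
#' directional persistence, reflect off the voxel faces, occasionally
#' branch, and terminate by fusing onto a nearby existing node
#' (anastomosis). Growth stops once the summed segment length reaches the
#' target length density. Each segment receives an outer diameter drawn
#' uniformly from `diameter_range`.
#'
#' @param voxel_dims Voxel edge lengths, m (default 0.15 x 0.16 x 0.43 mm).
#' @param target_length_density Target vessel length density, mm/mm^3
#'   (default 557, matching cortical morphometry). 0 returns an empty graph.
#' @param diameter_range Outer diameter range, m (default 8-10 um).
#' @param wall_thickness Wall thickness, m (default 1 um).
#' @param seed Integer seed; the graph is a deterministic function of the
#'   seed and the other arguments.
#' @param step_length Mean walk step, m (default 15 um).
#' @param branch_prob Branching probability per step (default 0.35).
#' @return A [vessel_graph()] whose achieved length density is within 10%
#'   of the target.
#' @examples
#' g <- generate_network(seed = 42)
#' network_stats(g)$length_density  # close to 557
#' @export
generate_network <- function(voxel_dims = c(0.15e-3, 0.16e-3, 0.43e-3),
                             target_length_density = 557,
                             diameter_range = c(8e-6, 10e-6),
                             wall_thickness = 1e-6,
                             seed = 1L,
                             step_length = 15e-6,
                             branch_prob = 0.35) {
  check_nonnegative(target_length_density, "target_length_density")
  if (target_length_density == 0) {
    return(vessel_graph(matrix(numeric(0), 0, 3),
                        data.frame(from = integer(0), to = integer(0),
                                   outer_diameter = numeric(0),
                                   wall_thickness = numeric(0)),
                        voxel_dims, seed))
  }
  vol <- prod(voxel_dims)
  target_length <- target_length_density * 1e6 * vol  # SI total length, m
  # feasibility: the implied lumen volume fraction must leave room to grow
  max_frac <- target_length_density * 1e6 * pi * (max(diameter_range) / 2)^2
  if (max_frac > 0.5) {
    stop_invalid("voxel cannot accommodate the target length density at ",
                 "these diameters (implied volume fraction ",
                 signif(max_frac, 3), ")")
  }
  if (target_length < 2 * step_length) {
    stop_invalid("voxel too small: target length below one walk step")
  }

  with_seed(seed, {
    nodes <- matrix(runif(3) * voxel_dims * 0.8 + 0.1 * voxel_dims, 1, 3)
    from <- integer(0); to <- integer(0)
    rand_dir <- function() {
      v <- rnorm(3)
      v / sqrt(sum(v^2))
    }
    # active tips: list of (node index, direction)
    tips <- list(list(node = 1L, dir = rand_dir()))
    total_len <- 0
    anastomosis_radius <- 0.5 * step_length
    while (total_len < target_length && length(tips) > 0) {
      tip <- tips[[1]]
      tips <- tips[-1]
      p0 <- nodes[tip$node, ]
      dir <- tip$dir + 0.8 * rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      step <- step_length * runif(1, 0.7, 1.3)
      p1 <- p0 + dir * step
      # reflect off voxel faces
      for (k in 1:3) {
        if (p1[k] < 0) { p1[k] <- -p1[k]; dir[k] <- -dir[k] }
        if (p1[k] > voxel_dims[k]) {
          p1[k] <- 2 * voxel_dims[k] - p1[k]; dir[k] <- -dir[k]
        }
        p1[k] <- min(max(p1[k], 0), voxel_dims[k])
      }
      # anastomosis: fuse onto a nearby node other than the parent
      d2 <- rowSums(sweep(nodes, 2, p1)^2)
      d2[tip$node] <- Inf
      hit <- which.min(d2)
      if (length(hit) == 1 && is.finite(d2[hit]) &&
          d2[hit] < anastomosis_radius^2 && nrow(nodes) > 2) {
        from <- c(from, tip$node); to <- c(to, hit)
        total_len <- total_len + sqrt(sum((nodes[hit, ] - p0)^2))
        # tip terminates; respawn from a random existing node if queue empty
      } else {
        nodes <- rbind(nodes, p1)
        new_id <- nrow(nodes)
        from <- c(from, tip$node); to <- c(to, new_id)
        total_len <- total_len + sqrt(sum((p1 - p0)^2))
        tips <- c(tips, list(list(node = new_id, dir = dir)))
        if (runif(1) < branch_prob) {
          tips <- c(tips, list(list(node = new_id, dir = rand_dir())))
        }
      }
      if (length(tips) == 0 && total_len < target_length) {
        tips <- list(list(node = sample.int(nrow(nodes), 1), dir = rand_dir()))
      }
    }
    segments <- data.frame(
      from = from, to = to,
      outer_diameter = runif(length(from), diameter_range[1], diameter_range[2]),
      wall_thickness = wall_thickness
    )
    g <- vessel_graph(nodes, segments, voxel_dims, seed)
    achieved <- network_stats(g)$length_density
    if (abs(achieved - target_length_density) > 0.1 * target_length_density) {
      stop("generator failed to reach the target length density (achieved ",
           signif(achieved, 4), " mm/mm^3)")
    }
    g
  })
}

#' Write a vessel graph to JSON
#'
#' @param graph A [vessel_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vessel_graph <- function(graph, path) {
  stopifnot(inherits(graph, "vessel_graph"))
  obj <- list(
    units = "m",
    voxel_dims = graph$voxel_dims,
    seed = graph$seed,
    nodes = unname(apply(graph$nodes, 1, as.numeric, simplify = FALSE)),
    segments = graph$segments
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a vessel graph from JSON
#'
#' @param path File written by [write_vessel_graph()].
#' @return A [vessel_graph()].
#' @export
read_vessel_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- if (!length(obj$nodes)) {
    matrix(numeric(0), 0, 3)
  } else if (is.matrix(obj$nodes)) {
    obj$nodes
  } else {
    do.call(rbind, lapply(obj$nodes, as.numeric))
  }
  seed <- if (is.null(obj$seed)) NA_integer_ else obj$seed
  vessel_graph(nodes, obj$segments, obj$voxel_dims, seed)
}

#' Write a vessel graph as a CSV edge list
#'
#' Columns: from, to, endpoint coordinates (m), outer diameter and wall
#' thickness (m).
#'
#' @inheritParams write_vessel_graph
#' @return `path`, invisibly.
#' @export
write_vessel_graph_csv <- function(graph, path) {
  stopifnot(inherits(graph, "vessel_graph"))
  s <- graph$segments
  df <- data.frame(
    from = s$from, to = s$to,
    x0_m = graph$nodes[s$from, 1], y0_m = graph$nodes[s$from, 2],
    z0_m = graph$nodes[s$from, 3],
    x1_m = graph$nodes[s$to, 1], y1_m = graph$nodes[s$to, 2],
    z1_m = graph$nodes[s$to, 3],
    outer_diameter_m = s$outer_diameter, wall_thickness_m = s$wall_thickness
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
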