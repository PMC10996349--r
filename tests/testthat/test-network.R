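# Synthetic capillary network generation and morphometry.

test_that("generator hits the target length density within 10%", {
  g <- small_network(seed = 11)
  st <- network_stats(g)
  expect_gte(st$length_density, 501)
  expect_lte(st$length_density, 613)
  # lumen volume fraction at these diameters is near the in vivo 0.021
  expect_gt(st$volume_fraction, 0.01)
  expect_lt(st$volume_fraction, 0.04)
})

test_that("generation is deterministic for a fixed seed", {
  g1 <- generate_network(seed = 7)
  g2 <- generate_network(seed = 7)
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$segments, g2$segments)
  g3 <- generate_network(seed = 8)
  expect_false(identical(g1$nodes, g3$nodes))
})

test_that("zero target yields an empty graph with zero stats", {
  g <- generate_network(target_length_density = 0)
  expect_equal(nrow(g$segments), 0)
  st <- network_stats(g)
  expect_identical(c(st$length_density, st$surface_density, st$volume_fraction),
                   c(0, 0, 0))
})

test_that("generated graphs are connected and stay inside the voxel", {
  g <- small_network(seed = 3)
  # BFS over the undirected segment list
  adj <- split(c(g$segments$to, g$segments$from),
               c(g$segments$from, g$segments$to))
  seen <- logical(nrow(g$nodes))
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    nb <- unlist(adj[as.character(queue)], use.names = FALSE)
    queue <- unique(nb[!seen[nb]])
    seen[queue] <- TRUE
  }
  expect_true(all(seen))
  for (k in 1:3) {
    expect_true(all(g$nodes[, k] >= 0 & g$nodes[, k] <= g$voxel_dims[k]))
  }
  # diameters within the requested range, lumen positive
  expect_true(all(g$segments$outer_diameter >= 8e-6 &
                    g$segments$outer_diameter <= 10e-6))
  expect_true(all(g$segments$outer_diameter -
                    2 * g$segments$wall_thickness > 0))
})

test_that("morphometric densities match hand-computed values", {
  g <- single_vessel_graph(outer_d = 9e-6)
  st <- network_stats(g)
  vol_mm3 <- prod(g$voxel_dims) * 1e9
  # one 0.43 mm axial segment: 0.43 / (0.15*0.16*0.43) mm/mm^3
  expect_equal(st$length_density, 0.43 / vol_mm3, tolerance = 1e-10)
  expect_equal(st$length_density, 41.666, tolerance = 1e-4)
  # surface from outer diameter, volume fraction from lumen diameter
  expect_equal(st$surface_density, pi * 9e-3 * 0.43 / vol_mm3,
               tolerance = 1e-10)
  expect_equal(st$volume_fraction, pi * (3.5e-3)^2 * 0.43 / vol_mm3,
               tolerance = 1e-10)
})

test_that("length density 557 with 3.5 um lumen radius implies 0.021 volume fraction", {
  # the in vivo morphometric identity: 557 mm/mm^3 * pi * (0.0035 mm)^2
  expect_equal(557 * pi * 0.0035^2, 0.021, tolerance = 0.03)
})

test_that("an unreachable target raises an explicit error", {
  expect_error(generate_network(target_length_density = 50000),
               class = "tdcsflow_invalid_parameter")
})

test_that("vessel graphs round-trip through JSON and export to CSV", {
  g <- small_network(seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_vessel_graph(g, path)
  g2 <- read_vessel_graph(path)
  expect_equal(g2$nodes, g$nodes, ignore_attr = TRUE)
  expect_equal(g2$segments$from, g$segments$from)
  expect_equal(g2$segments$outer_diameter, g$segments$outer_diameter)
  expect_equal(g2$voxel_dims, g$voxel_dims)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_vessel_graph_csv(g, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), nrow(g$segments))
  expect_equal(df$outer_diameter_m, g$segments$outer_diameter)
})

test_that("hand-built graphs validate node and lumen constraints", {
  voxel <- c(1e-4, 1e-4, 1e-4)
  expect_error(
    vessel_graph(rbind(c(0, 0, 2e-4)), data.frame(), voxel),
    class = "tdcsflow_invalid_parameter")
  expect_error(
    vessel_graph(rbind(c(0, 0, 0), c(0, 0, 1e-4)),
                 data.frame(from = 1, to = 2, outer_diameter = 1e-6,
                            wall_thickness = 1e-6), voxel),
    class = "tdcsflow_invalid_parameter")
})
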