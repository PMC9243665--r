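test_that("connectome build is deterministic and seed-sensitive", {
  cfg <- default_network_config(scale = 0.2)
  a <- build_connectome(cfg, seed = 1)
  b <- build_connectome(cfg, seed = 1)
  c2 <- build_connectome(cfg, seed = 2)
  expect_identical(a$groups, b$groups)
  expect_identical(a$ie_offsets, b$ie_offsets)
  expect_false(identical(a$groups[["pf-PC"]]$pre, c2$groups[["pf-PC"]]$pre))
  # same degree statistics across seeds: inbound degree is exact by design
  for (g in names(a$groups)) {
    da <- tabulate(a$groups[[g]]$post)
    dc <- tabulate(c2$groups[[g]]$post)
    expect_equal(mean(da), mean(dc))
  }
})

test_that("wiring diagram is complete and has no extra groups", {
  conn <- small_connectome()
  expected <- c("mf-GrC", "mf-GoC", "GrC-GoC", "GoC-GrC", "aa-PC", "pf-PC",
                "GrC-MLI", "MLI-PC", "PC-DCN", "mf-DCN", "IO-PC", "IO-DCN",
                "IO-DCN_GABA", "DCN_GABA-IO")
  expect_setequal(names(conn$groups), expected)
  # excitatory/inhibitory signs follow the physiology
  inhibitory <- c("GoC-GrC", "MLI-PC", "PC-DCN", "DCN_GABA-IO")
  for (g in names(conn$groups)) {
    expect_equal(conn$groups[[g]]$sign, if (g %in% inhibitory) -1L else 1L,
                 info = g)
  }
})

test_that("inbound degree equals configured convergence exactly", {
  cfg <- default_network_config(scale = 0.2)
  conn <- build_connectome(cfg, seed = 3)
  sizes <- stats::setNames(conn$populations$size, conn$populations$name)
  for (g in names(conn$groups)) {
    grp <- conn$groups[[g]]
    deg <- tabulate(grp$post, nbins = sizes[[grp$target]])
    expect_true(all(deg == grp$convergence), info = g)
    # sampling without replacement: no duplicated source per target
    expect_false(any(duplicated(cbind(grp$pre, grp$post))), info = g)
  }
})

test_that("every Purkinje cell has exactly one climbing-fiber source", {
  conn <- small_connectome()
  g <- conn$groups[["IO-PC"]]
  expect_equal(sort(unique(g$post)), seq_len(99))
  expect_true(all(tabulate(g$post, nbins = 99) == 1))
})

test_that("default Purkinje population has 99 cells at any scale", {
  expect_equal(pop_size(build_connectome(default_network_config(scale = 0.2),
                                         seed = 1), "PC"), 99)
  expect_equal(pop_size(build_connectome(seed = 1), "PC"), 99)
})

test_that("count_synapses matches convergence times population size", {
  cfg <- default_network_config(scale = 0.2)
  conn <- build_connectome(cfg, seed = 1)
  k <- conn$groups[["MLI-PC"]]$convergence
  expect_equal(count_synapses(conn, "MLI-PC"), k * 99)
  expect_error(count_synapses(conn, "nope"), "unknown")
})

test_that("zero convergence yields a present-but-empty group", {
  cfg <- default_network_config(scale = 0.2)
  cfg$connections[["mf-DCN"]]$convergence <- 0
  conn <- build_connectome(cfg, seed = 1)
  expect_true("mf-DCN" %in% names(conn$groups))
  expect_equal(count_synapses(conn, "mf-DCN"), 0)
})

test_that("invalid configurations are rejected", {
  cfg <- default_network_config()
  cfg$populations$GoC$size <- 0
  expect_error(build_connectome(cfg, seed = 1), "sizes")
  cfg <- default_network_config()
  cfg$connections[["IO-PC"]]$convergence <- 1000   # exceeds |IO| = 16
  expect_error(build_connectome(cfg, seed = 1), "exceeds")
})

test_that("structural E/I ratio is 62.3 in the control configuration", {
  conn <- build_connectome(seed = 1)
  expect_equal(structural_ei_ratio(conn), 62.3, tolerance = 1e-12)
})

test_that("doubling MLI-PC synapses halves the E/I ratio", {
  conn <- small_connectome()
  r0 <- structural_ei_ratio(conn)
  g <- conn$groups[["MLI-PC"]]
  g$pre <- c(g$pre, g$pre); g$post <- c(g$post, g$post)
  g$weight <- c(g$weight, g$weight)
  conn$groups[["MLI-PC"]] <- g
  expect_equal(structural_ei_ratio(conn), r0 / 2)
})

test_that("degenerate E/I ratio (no inhibition) is an error", {
  conn <- small_connectome()
  g <- conn$groups[["MLI-PC"]]
  g$pre <- integer(0); g$post <- integer(0); g$weight <- numeric(0)
  conn$groups[["MLI-PC"]] <- g
  expect_error(structural_ei_ratio(conn), "degenerate")
})

test_that("connectome archive round-trips losslessly", {
  conn <- small_connectome(seed = 4)
  dir <- withr::local_tempdir()
  write_connectome(conn, dir)
  back <- read_connectome(dir)
  expect_equal(back$populations, conn$populations)
  for (g in names(conn$groups)) {
    expect_equal(back$groups[[g]]$pre, conn$groups[[g]]$pre, info = g)
    expect_equal(back$groups[[g]]$post, conn$groups[[g]]$post, info = g)
    expect_equal(back$groups[[g]]$weight, conn$groups[[g]]$weight, info = g)
    expect_equal(back$groups[[g]]$sign, conn$groups[[g]]$sign, info = g)
  }
  expect_equal(unname(lengths(back$ie_offsets)),
               unname(lengths(conn$ie_offsets)))
  expect_equal(back$ie_offsets$PC, conn$ie_offsets$PC)
  # counts invariant under the round trip
  expect_equal(count_synapses(back, "pf-PC"), count_synapses(conn, "pf-PC"))
  expect_equal(structural_ei_ratio(back), structural_ei_ratio(conn))
})
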