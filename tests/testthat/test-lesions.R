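test_that("zero-severity lesions are identities", {
  conn <- small_connectome()
  expect_identical(apply_reduced_io(conn, 0), conn)
  les <- apply_lesion(conn, NULL)
  expect_identical(les$connectome, conn)
  expect_null(les$overlay)
})

test_that("reduced-IO lesion removes teaching from the right PC count", {
  conn <- small_connectome()
  for (f in c(0.25, 0.5, 0.75)) {
    cut <- apply_reduced_io(conn, f, seed = 2)
    g <- cut$groups[["IO-PC"]]
    expect_equal(length(unique(g$post)), 99 - round(f * 99))
    # surviving climbing-fiber weights scaled by (1 - f)
    w0 <- conn$groups[["IO-PC"]]$weight[1]
    expect_equal(unique(g$weight), w0 * (1 - f))
  }
  # 25% of 99 cells -> 25 disconnected
  cut <- apply_reduced_io(conn, 0.25, seed = 2)
  expect_equal(length(unique(cut$groups[["IO-PC"]]$post)), 74)
})

test_that("fully lesioned teaching leaves potentiation-only drift", {
  conn <- small_connectome()
  cut <- apply_reduced_io(conn, 1, seed = 2)
  expect_equal(count_synapses(cut, "IO-PC"), 0)
  ses <- run_session(cut, protocol_config(n_trials = 2), seed = 3)
  dw <- ses$connectome$groups[["pf-PC"]]$weight -
    conn$groups[["pf-PC"]]$weight
  expect_true(all(dw >= 0))
  expect_gt(mean(dw), 0)
})

test_that("synaptic imbalance removes the printed edge proportions", {
  conn <- small_connectome()
  n_pf <- count_synapses(conn, "pf-PC")
  n_mli <- count_synapses(conn, "MLI-PC")
  mild <- apply_synaptic_imbalance(conn, "mild", seed = 2)
  expect_equal(count_synapses(mild, "pf-PC"), n_pf - round(0.14 * n_pf))
  expect_equal(count_synapses(mild, "MLI-PC"), n_mli - round(0.39 * n_mli))
  expect_equal(unique(mild$groups[["IO-PC"]]$weight),
               unique(conn$groups[["IO-PC"]]$weight) * 1.32)
  severe <- apply_synaptic_imbalance(conn, "severe", seed = 2)
  expect_equal(count_synapses(severe, "pf-PC"), n_pf - round(0.25 * n_pf))
  expect_equal(count_synapses(severe, "MLI-PC"), n_mli - round(0.71 * n_mli))
  # structural E/I ratio strictly increases for both levels
  r0 <- structural_ei_ratio(conn)
  expect_gt(structural_ei_ratio(mild), r0)
  expect_gt(structural_ei_ratio(severe), structural_ei_ratio(mild))
})

test_that("imbalance proportions match the worked examples", {
  # mild on 1000 pf edges leaves 860; severe on 100 MLI edges leaves 29
  expect_equal(1000 - round(0.14 * 1000), 860)
  conn <- small_connectome()
  g <- conn$groups[["MLI-PC"]]
  keep100 <- seq_len(100)
  g$pre <- g$pre[keep100]; g$post <- g$post[keep100]
  g$weight <- g$weight[keep100]
  conn$groups[["MLI-PC"]] <- g
  severe <- apply_synaptic_imbalance(conn, "severe", seed = 1)
  expect_equal(count_synapses(severe, "MLI-PC"), 29)
})

test_that("lesions commute with connectome serialization", {
  conn <- small_connectome(seed = 3)
  dir <- withr::local_tempdir()
  write_connectome(conn, file.path(dir, "a"))
  lesion_then_save <- apply_synaptic_imbalance(conn, "mild", seed = 5)
  write_connectome(lesion_then_save, file.path(dir, "b"))
  load_then_lesion <- apply_synaptic_imbalance(
    read_connectome(file.path(dir, "a")), "mild", seed = 5)
  saved <- read_connectome(file.path(dir, "b"))
  for (g in c("pf-PC", "MLI-PC", "IO-PC")) {
    expect_equal(load_then_lesion$groups[[g]]$pre, saved$groups[[g]]$pre)
    expect_equal(load_then_lesion$groups[[g]]$weight,
                 saved$groups[[g]]$weight)
  }
})

test_that("burst overlays have the configured duty cycles", {
  proto <- protocol_config()
  # intrinsic: 20 ms on, pauses drawn from {20, 30}: duty 20/45 = 0.444
  ov <- apply_burst_lesion(lesion_intrinsic_burst(), proto, n_cells = 5,
                           seed = 1)
  expect_equal(ov$pop, "PC")
  isi <- 1000 / 500
  on_time <- vapply(seq_len(5), function(cell)
    sum(vapply(seq_len(100), function(tr)
      length(ov$trains[[tr]][[cell]]) * isi, 0)), 0)
  expect_equal(mean(on_time) / (100 * 1000), 0.444, tolerance = 0.02)
  # IO-induced: 40 on / 40 off: duty exactly 0.5
  ov2 <- apply_burst_lesion(lesion_io_burst(), proto, n_cells = 3, seed = 1)
  expect_equal(ov2$pop, "IO")
  on2 <- sum(vapply(seq_len(100), function(tr)
    length(ov2$trains[[tr]][[1]]) * isi, 0))
  expect_equal(on2 / (100 * 1000), 0.5, tolerance = 1e-3)
  # intrinsic lesion reduces the Purkinje endogenous current
  expect_lt(ov$ie_scale$PC, 1)
})

test_that("burst lesions raise Purkinje baseline irregularity", {
  cfg <- small_config()
  conn <- build_connectome(cfg$network, seed = 1)
  proto <- protocol_config(n_trials = 1)
  ctrl <- run_session(conn, proto, seed = 2,
                      plasticity = plasticity_config(enabled = FALSE))
  cv_ctrl <- baseline_stats(
    population_spikes(ctrl$recordings[[1]], "PC", 99))$cv_isi
  les <- apply_lesion(conn, lesion_intrinsic_burst(), proto, seed = 2)
  burst <- run_session(les$connectome, proto, seed = 2,
                       plasticity = plasticity_config(enabled = FALSE),
                       overlay = les$overlay, ie_scale = les$ie_scale)
  cv_burst <- baseline_stats(
    population_spikes(burst$recordings[[1]], "PC", 99))$cv_isi
  p <- wilcox.test(cv_ctrl, cv_burst)$p.value
  expect_lt(p, 0.01)
  expect_gt(median(cv_burst, na.rm = TRUE), median(cv_ctrl, na.rm = TRUE))
})
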