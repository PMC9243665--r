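test_that("a delayed spike drives the postsynaptic cell on schedule", {
  # spike source -> strong excitatory synapse (delay 2 ms) -> LIF cell:
  # source spike at 10 ms must fire the target within (12, 14] ms
  conn <- build_connectome(toy_config(weight = 50, delay = 2), seed = 1,
                           neuron_params = toy_neuron_params())
  stim <- list(cs = list(c(10)), us = list())
  names(stim) <- c("cs", "us")
  out <- run_trial(conn, list(cs = list(10), us = list(numeric(0))),
                   duration = 50, seed = 1)
  sp <- out$recording$spikes
  sp <- sp[sp$population == "DCN", ]
  expect_equal(nrow(sp), 1)
  expect_gt(sp$time, 12)
  expect_lte(sp$time, 14)
})

test_that("a quiescent network without stimuli stays silent", {
  conn <- build_connectome(toy_config(), seed = 1,
                           neuron_params = toy_neuron_params(I_e = 0))
  out <- run_trial(conn, list(cs = list(numeric(0)), us = list(numeric(0))),
                   duration = 200, seed = 1)
  expect_equal(nrow(out$recording$spikes), 0)
})

test_that("an inhibitory synapse delays pacemaker firing", {
  np <- toy_neuron_params(I_e = 60)         # suprathreshold pacemaker
  free <- run_trial(build_connectome(toy_config(sign = +1, weight = 0),
                                     seed = 1, neuron_params = np),
                    list(cs = list(numeric(0)), us = list(numeric(0))),
                    duration = 500, seed = 1)
  inh <- run_trial(build_connectome(toy_config(sign = -1, weight = 20),
                                    seed = 1, neuron_params = np),
                   list(cs = list(seq(5, 495, by = 5)),
                        us = list(numeric(0))),
                   duration = 500, seed = 1)
  expect_lt(nrow(inh$recording$spikes), nrow(free$recording$spikes))
})

test_that("sessions are deterministic given configuration and seed", {
  conn <- small_connectome()
  proto <- protocol_config(n_trials = 3)
  a <- run_session(conn, proto, seed = 9)
  b <- run_session(conn, proto, seed = 9)
  for (i in 1:3)
    expect_identical(a$recordings[[i]]$spikes, b$recordings[[i]]$spikes)
  expect_identical(a$connectome$groups[["pf-PC"]]$weight,
                   b$connectome$groups[["pf-PC"]]$weight)
  c2 <- run_session(conn, proto, seed = 10)
  expect_false(identical(a$recordings[[1]]$spikes,
                         c2$recordings[[1]]$spikes))
})

test_that("spike times stay inside the trial and are causally ordered", {
  conn <- small_connectome()
  ses <- run_session(conn, protocol_config(n_trials = 2), seed = 3)
  for (rec in ses$recordings) {
    expect_true(all(rec$spikes$time > 0 & rec$spikes$time <= rec$duration))
  }
})

test_that("plasticity changes pf-PC weights during a session and only then", {
  conn <- small_connectome()
  proto <- protocol_config(n_trials = 2)
  w0 <- conn$groups[["pf-PC"]]$weight
  frozen <- run_session(conn, proto, seed = 4,
                        plasticity = plasticity_config(enabled = FALSE))
  expect_identical(frozen$connectome$groups[["pf-PC"]]$weight, w0)
  learning <- run_session(conn, proto, seed = 4)
  expect_false(identical(learning$connectome$groups[["pf-PC"]]$weight, w0))
  # non-plastic groups never change
  expect_identical(learning$connectome$groups[["MLI-PC"]]$weight,
                   conn$groups[["MLI-PC"]]$weight)
})

test_that("engine plasticity matches the exported batch rule on one trial", {
  conn <- small_connectome()
  proto <- protocol_config(n_trials = 1)
  pl <- plasticity_config()
  ses <- run_session(conn, proto, seed = 6, plasticity = pl,
                     rehearsal = FALSE)
  rec <- ses$recordings[[1]]
  g <- conn$groups[["pf-PC"]]
  n_grc <- pop_size(conn, "GrC")
  n_io <- pop_size(conn, "IO")
  grc_sp <- population_spikes(rec, "GrC", n_grc)
  io_sp <- population_spikes(rec, "IO", n_io)
  io_of_pc <- conn$groups[["IO-PC"]]
  teacher <- integer(99)
  teacher[io_of_pc$post] <- io_of_pc$pre
  pf_spikes <- grc_sp[g$pre]
  io_spikes <- lapply(seq_len(99), function(pc)
    if (teacher[pc] > 0) io_sp[[teacher[pc]]] else numeric(0))
  expected <- apply_pf_pc_plasticity(pf_spikes, io_spikes, g$post,
                                     g$weight, pl)
  expect_equal(ses$connectome$groups[["pf-PC"]]$weight, expected,
               tolerance = 1e-12)
})

test_that("stimulus times outside the trial are rejected", {
  conn <- small_connectome()
  expect_error(run_trial(conn, list(cs = list(c(1500)),
                                    us = list(numeric(0))),
                         duration = 1000, seed = 1),
               "outside")
})

test_that("GDF output round-trips and session spikes are consistent", {
  conn <- small_connectome()
  ses <- run_session(conn, protocol_config(n_trials = 2), seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_gdf(ses, dir)
  df <- session_spikes(ses)
  pc_path <- file.path(dir, "spikes_PC.gdf")
  expect_true(file.exists(pc_path))
  back <- read_gdf(pc_path)
  expect_equal(nrow(back), sum(df$population == "PC"))
  expect_true(all(diff(back$time) >= 0))
})
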