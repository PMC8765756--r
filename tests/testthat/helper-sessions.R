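# small hand-built session: 3 trials, one LC and two ACC units
tiny_session <- function() {
  session(
    session_id = "tiny",
    units = tibble::tibble(unit_id = c("lc1", "a1", "a2"),
                           region = c("LC", "ACC", "ACC")),
    trials = tibble::tibble(
      trial_id = 1:3,
      fix_on = 200, stable_fix_on = 500,
      beep_time = c(NA, 1800, NA),
      trial_end = c(4000, 4200, 2000),
      gaze_ok = c(TRUE, TRUE, TRUE)
    ),
    spikes = tibble::tibble(
      trial_id = c(1L, 1L, 1L, 2L, 2L, 3L),
      unit_id = c("lc1", "a1", "a1", "a1", "a2", "a2"),
      time_ms = c(1600, 1510, 2590, 1700, 1900, 800)
    )
  )
}

# lc-gated pair specs used across tests: shared falls 1.2 -> 0.4 while the
# marginal lambda stays 4, so the implied r_sc drops 0.3 -> 0.1
lc_gate_spec <- function() {
  pair_spec(gate_on = "lc",
            gate = list(zero = c(private = 2.8, shared = 1.2),
                        nonzero = c(private = 3.6, shared = 0.4)))
}

beep_gate_spec <- function() {
  pair_spec(gate_on = "beep",
            gate = list(pre = c(private = 3.5, shared = 0.5),
                        post = c(private = 2.5, shared = 1.5)))
}

truth_pairs <- function(sim) sim$truth$pairs[, c("pair_id", "unit_a", "unit_b")]
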