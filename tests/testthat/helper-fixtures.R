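# memoized fixtures shared across test files (built in code, never stored)
.fix <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fix)) assign(key, force(expr), envir = .fix)
  get(key, envir = .fix)
}

glycerine_bg <- function() cached("bg", get_material("glycerine90"))

# moderate-contrast water-like target used by the recovery experiments:
# eps' = 24 at 1.2 GHz (~1.7:1 over the glycerine background), similar loss
moderate_target <- function()
  cached("tgt_mod", debye_from_anchor(24, 14, 1.2e9, eps_inf = 5, tau = 35e-12))

# small empty-tank sweep at the inversion resolution, reused by several tests
empty_sweep_2mm <- function()
  cached("ds_e_2mm",
         simulate_dataset(scenario(background = glycerine_bg()),
                          c(1.5e9, 2.0e9), sim_config(dx = 2e-3)))

# synthetic (non-simulated) multistatic dataset for pure-arithmetic tests
arith_dataset <- function(values, freqs = 1.5e9, n_ant = 4) {
  grid <- expand.grid(rx = seq_len(n_ant), tx = seq_len(n_ant),
                      freq_hz = freqs)
  grid <- grid[grid$tx != grid$rx, ]
  multistatic_dataset(data.frame(freq_hz = grid$freq_hz, tx = grid$tx,
                                 rx = grid$rx, re = Re(values),
                                 im = Im(values)),
                      metadata = list(ref = data.frame(freq_hz = freqs,
                                                       amp = 1)))
}
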