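# shared fixture builders (everything is generated in code at test time)

# a noiseless triangular ramp cycle with one unfolding step on the way up
# and one refolding step on the way down, at exactly known forces
make_step_cycle <- function(unfold_at = 8, refold_at = 4, delta = 15,
                            rate = 30, f_min = 1, f_max = 25,
                            compliance = 0.2, noise_sd = 0) {
  f_up <- seq(f_min, f_max, by = 1 / rate)
  f <- c(f_up, rev(f_up)[-1])
  ext <- compliance * f
  i_un <- which(f_up >= unfold_at)[1L]
  ext[i_un:length(f_up)] <- ext[i_un:length(f_up)] + delta
  down <- (length(f_up) + 1L):length(f)
  i_re <- down[which(f[down] <= refold_at)[1L]]
  ext[down[1L]:(i_re - 1L)] <- ext[down[1L]:(i_re - 1L)] + delta
  if (noise_sd > 0) ext <- ext + rnorm(length(ext), 0, noise_sd)
  tr <- mfs_trace((seq_along(f) - 1) / rate, ext, f, "stepbead",
                  condition_label("control"), rate)
  cycles <- data.frame(cycle_index = 1L, up_start = 1L,
                       up_end = length(f_up),
                       down_start = length(f_up) + 1L,
                       down_end = length(f), f_min = f_min, f_max = f_max)
  list(trace = tr, cycles = cycles,
       truth = list(unfold_force = f_up[i_un], refold_force = f[i_re],
                    size = delta))
}

# control-condition kinetic model used across tests
control_model <- function(...) kinetic_model(...)

# a kinetic-stabilizer model with a planted half-saturation concentration
stabilizer_model <- function(ec50_unfold = 394e-6, ec50_refold = 456e-6,
                             g = 2) {
  kinetic_model(ligand_mode = "kinetic_stabilizer",
                K_D_ligand = kd_for_half_saturation(ec50_unfold, g),
                stabilization_factor = g,
                fold_enhancement_factor = g,
                K_D_fold = kd_for_half_saturation(ec50_refold, g))
}

pk_model <- function(K_D = 50e-9) {
  kinetic_model(ligand_mode = "pseudoknot_inducer", K_D_ligand = K_D)
}

cohort_traces <- function(cohort) {
  unlist(lapply(cohort, function(b) lapply(b$runs, function(r) r$trace)),
         recursive = FALSE)
}
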