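# Shared fixtures, built in code.

# moderate, symmetric kinetics: dwells are long relative to the detector
# resolution, so noiseless records are fully resolvable
gentle_model <- function(...) {
  motor_model(k0f_plus = 5, df_plus = 1, k0b_plus = 1, db_plus = 1,
              kd0_plus = 0.8, dk_plus = 2,
              k0f_minus = 5, df_minus = 1, k0b_minus = 1, db_minus = 1,
              kd0_minus = 0.8, dk_minus = 2, ...)
}

# wrap a bare position vector as a position_record
as_record <- function(position, dt, force = NULL, config = NULL) {
  structure(list(position = position, force = force, dt = dt,
                 duration = length(position) * dt, config = config,
                 model = NULL, truth = NULL),
            class = "position_record")
}

# noiseless staircase record: plateaus at `levels`, each lasting
# `dwell_s` seconds
staircase_record <- function(levels, dwell_s, dt) {
  n_per <- round(dwell_s / dt)
  as_record(rep(levels, each = n_per), dt = dt)
}

# Michaelis-Menten velocity at the unloaded-motility parameters
mm_velocity <- function(atp, vmax = 691, Kapp = 22) {
  vmax * atp / (Kapp + atp)
}
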