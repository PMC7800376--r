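# Shared, lazily built fixtures. Everything is generated in code; sessions
# are cached so several test files can reuse the same simulation.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

small_config <- function(...) gait_config(n_trials = 8, ...)

# one default small session + its processed pipeline
default_sim <- function() fixture("sim", function() {
  generate_session(small_config(), seed = 7)
})

default_pipeline <- function() fixture("pipe", function() {
  session_pipeline(default_sim())
})

# a medium session for decision/reaction statistics
medium_sim <- function() fixture("sim_med", function() {
  generate_session(gait_config(n_trials = 30), seed = 11)
})

medium_pipeline <- function() fixture("pipe_med", function() {
  session_pipeline(medium_sim())
})

medium_decision <- function() fixture("dd_med", function() {
  gs <- medium_sim()
  pl <- medium_pipeline()
  ctrl <- session_control_steps(pl$steps, gs$truth$trials$contact_frame)
  lmod <- fit_landing_model(ctrl, paws = c("LF", "RF"))
  dd <- decision_dataset(pl$kin, pl$steps, gs$truth$trials$contact_frame, lmod,
                         mouse = "m1")
  attr(dd, "landing_model") <- lmod
  attr(dd, "control_steps") <- ctrl
  dd
})

# noiseless gait: constant speed, no placement or apex noise. The speed is
# chosen so a stride is an integer number of frames (a + b*v = 100*v ms),
# making step lengths exactly a + b*v despite frame quantisation.
noiseless_config <- function(n_trials = 6) {
  gait_config(n_trials = n_trials, mean_speed = 3.7 / 7, speed_sd = 0,
              landing_noise_sd = 0, swing_peak_sd = 0, contact_noise_sd = 0,
              body_angle_sd = 1e-9, tail_height_sd = 1e-9)
}

noiseless_sim <- function() fixture("sim_noiseless", function() {
  generate_session(noiseless_config(), seed = 3)
})
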