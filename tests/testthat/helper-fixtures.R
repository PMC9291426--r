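# Shared fixtures: one default geometry, quick simulated trials, and a
# helper that runs the kinematic chain on one trial.

fixture_geometry <- build_geometry()

sim_trial <- function(fusion_level = 0, movement_time_s = 4,
                      noise_sd_cm = 0, seed = NULL, corrected = FALSE,
                      miss_waypoint = NULL, ...) {
  cfg <- simulation_config(fusion_level = fusion_level,
                           movement_time_s = movement_time_s,
                           noise_sd_cm = noise_sd_cm, seed = seed, ...)
  simulate_trial(fixture_geometry, cfg, corrected = corrected,
                 miss_waypoint = miss_waypoint)
}

analyze_one <- function(traj, geometry = fixture_geometry) {
  vel <- compute_velocity(traj)
  seg <- segment_trial(vel, traj, geometry)
  met <- trial_fusion(trial_metrics(seg, vel, traj, geometry))
  list(vel = vel, seg = seg, met = met)
}

# closed-form straight point-to-point minimum-jerk speed profile
mj_speed_closed_form <- function(L, T, t) {
  tau <- t / T
  (L / T) * 30 * tau^2 * (1 - tau)^2
}
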