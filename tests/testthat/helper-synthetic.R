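# Shared fixtures, built in code at test time.

# small labeled session at the behavior-video rate
quick_labels <- function(duration_s = 120, seed = 1, frame_rate = 40) {
  generate_behavior_sequence(duration_s = duration_s, seed = seed,
                             frame_rate = frame_rate)
}

# a stationary pose track (all parts fixed) for geometric edge cases
stationary_pose <- function(n = 50, frame_rate = 40) {
  part <- function(x, y) data.frame(x = rep(x, n), y = rep(y, n),
                                    likelihood = rep(1, n))
  pose_track(list(
    nose = part(6.5, 0), neck = part(5, 0),
    left_ear = part(5.5, -0.8), right_ear = part(5.5, 0.8),
    camera = part(5.5, 0), body_center = part(2, 0),
    tail_start = part(-1, 0), tail_end = part(-2.5, 0)
  ), frame_rate)
}

# independent naive evaluation of the behavior-information formula
# (deliberately loop-based and separate from the package implementation)
naive_behavior_information <- function(events, lab_vec, frame_rate) {
  keep <- !is.na(lab_vec)
  events <- events[keep]; lab_vec <- lab_vec[keep]
  total_time <- length(lab_vec) / frame_rate
  f <- sum(events) / total_time
  if (f == 0) return(NA_real_)
  bi <- 0
  for (b in unique(lab_vec)) {
    sel <- lab_vec == b
    p_i <- sum(sel) / length(lab_vec)
    f_i <- sum(events[sel]) / (sum(sel) / frame_rate)
    if (f_i > 0) bi <- bi + p_i * (f_i / f) * log2(f_i / f)
  }
  bi
}
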