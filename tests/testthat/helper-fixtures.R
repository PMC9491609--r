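# Shared fixtures: the default model is expensive enough to build once.
the_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- default_model()
    m
  }
})

# published peak isometric strengths (N): base and the three weakened models
strength_table <- data.frame(
  muscle = c("biceps_long_head", "biceps_short_head", "gluteus_maximus",
             "psoas", "rectus_femoris", "vastus_intermedius",
             "gastrocnemius", "soleus", "tibialis_anterior",
             "extensor_hallucis_longus", "flexor_digitorum_longus",
             "flexor_digitorum_brevis"),
  base = c(4105, 557, 4450, 2448, 2192, 9593, 4691, 6194, 1227, 889, 1331, 938),
  w20 = c(3284, 445.6, 3560, 1958.4, 1753.6, 7674.4, 3752.8, 4955.2, 981.6,
          711.2, 1064.8, 750.4),
  w40 = c(2463, 334.2, 2670, 1468.8, 1315.2, 5755.8, 2814.6, 3716.4, 736.2,
          533.4, 798.6, 562.8),
  w60 = c(1642, 222.8, 1780, 979.2, 876.8, 3837.2, 1876.4, 2477.6, 490.8,
          355.6, 532.4, 375.2))

# a cheap synthetic trajectory with prescribed excitation matrix
make_traj <- function(e, tf, disp = NULL, n = ncol(e), a = NULL) {
  q <- matrix(0, 11, n)
  if (!is.null(disp)) q[1, ] <- seq(0, disp, length.out = n)
  q[2, ] <- 0.95
  u <- matrix(0, 11, n)
  if (!is.null(disp)) u[1, ] <- disp / tf
  if (is.null(a)) a <- e
  gait_trajectory(tf, q, u, a = a, ft = a, e = e, dft = matrix(0, 24, n))
}

# walking-like q trajectory whose per-node foot contact follows a prescribed
# on/off pattern (used for the step-time goal and strike detection): a foot is
# grounded when its hip is at zero (leg vertical) and lifted when flexed.
contact_pattern_traj <- function(model, down_r, down_l, tf = 1, lead_shift = 0) {
  n <- length(down_r)
  q <- matrix(0, 11, n)
  q[2, ] <- 0.925
  q[4, ] <- ifelse(down_r, lead_shift, 0.9)
  q[8, ] <- ifelse(down_l, -lead_shift, 0.9)
  u <- matrix(0, 11, n)
  a <- matrix(0.01, 24, n)
  gait_trajectory(tf, q, u, a, a, a, matrix(0, 24, n))
}
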