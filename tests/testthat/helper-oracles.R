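# brute-force bisection inversion of r = x * exp(-x * tau) on the
# below-saturation branch; independent of the package's Lambert-W path
bisect_invert <- function(r_obs, tau, iter = 200) {
  if (r_obs == 0) return(0)
  lo <- r_obs
  hi <- 1 / tau
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (mid * exp(-mid * tau) > r_obs) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# minimal noise-free on-model sample frame: R_Wo = cf * x * exp(-cf * x * tau)
# with constant spectral ratio k, for direct use with the fitting functions
model_samples <- function(activities, cf = 9.36, tau = 0.550e-6, k = 4) {
  x <- k * activities
  r_wo <- cf * x * exp(-cf * x * tau)
  data.frame(acq = seq_along(activities), activity_MBq = activities,
             x_w = x, r_wo = r_wo, r_po = r_wo / k, r_pp = r_wo / k)
}

# small uniform count volume helper
uniform_volume <- function(value = 1, dims = c(8, 8, 4), voxel = 4.8,
                           n_proj = 96, t_proj = 10) {
  count_volume(array(value, dim = dims), voxel_size = voxel,
               n_projections = n_proj, t_projection = t_proj)
}
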