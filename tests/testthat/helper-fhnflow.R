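# shared fixtures: the parameter sets used throughout the analysis
p_mmo <- function(I = 1.45) fhr_params(I = I, b = 0.8, c = 0, eps = 0.1)
p_poincare <- function() fhr_params(I = 0, b = 0.8, c = 0, eps = 0.01)

# sup-norm distance between two trajectories on their common columns
traj_sup_diff <- function(a, b, cols = c("u", "v", "w")) {
  cols <- intersect(cols, intersect(names(a), names(b)))
  n <- min(nrow(a), nrow(b))
  max(vapply(cols, function(cl) max(abs(a[[cl]][1:n] - b[[cl]][1:n])),
             numeric(1)))
}
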